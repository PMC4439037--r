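#' Parameters of the three-atom ephrin tilt measurement
#'
#' The tilt of an ephrin ligand relative to its receptor is summarised by a
#' single three-atom angle: a marker residue on the ligand, a vertex residue
#' on the receptor, and a distal receptor residue.  Defaults are the
#' EphA3/ephrin-A5 markers (ligand L112, vertex F152, distal Y180, CA atoms);
#' residue numbers refer to the reference complex and are mapped onto the
#' query complex by sequence alignment.
#'
#' @param vertex_residue,distal_residue Receptor residue numbers (reference
#'   numbering).
#' @param ligand_residue Ligand residue number (reference numbering).
#' @param atom_name Atom used in all three residues; CA by default, making the
#'   measure independent of side-chain conformation.
#' @return A `tilt_spec` list.
#' @export
tilt_spec <- function(vertex_residue = 152, distal_residue = 180,
                      ligand_residue = 112, atom_name = "CA") {
  if (vertex_residue == distal_residue)
    stop("vertex and distal residues must differ")
  structure(list(vertex_residue = vertex_residue,
                 distal_residue = distal_residue,
                 ligand_residue = ligand_residue,
                 atom_name = atom_name),
            class = "tilt_spec")
}

#' Standard three-atom angle
#'
#' @param a,vertex,c Length-3 coordinate vectors.
#' @return The angle a-vertex-c in degrees, in \[0, 180\].
#' @examples
#' three_atom_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))  # 90
#' @export
three_atom_angle <- function(a, vertex, c) {
  v1 <- a - vertex; v2 <- c - vertex
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-9 || n2 < 1e-9)
    stop("degenerate geometry: zero-length arm at the vertex")
  ct <- sum(v1 * v2) / (n1 * n2)
  acos(min(1, max(-1, ct))) * 180 / pi
}

## map a reference residue number through a correspondence map (a = reference)
map_residue <- function(map, resno, what) {
  i <- which(map$resno_a == resno)
  if (length(i) == 0)
    stop("tilt spec residue ", resno, " (", what,
         ") has no aligned equivalent in the query complex")
  c(resno = map$resno_b[i[1]], icode = map$icode_b[i[1]])
}

#' Measure the ephrin tilt angle of a complex against a reference complex
#'
#' Reproduces the comparative tilt protocol: (1) both complexes are trimmed to
#' the residues they share, via sequence alignment of receptors and of
#' ligands; (2) the query receptor is superposed onto the reference receptor
#' (CA Kabsch fit, transform applied to the whole query complex); (3) the
#' marker residues of the [tilt_spec()] are mapped through the alignments onto
#' the query's own residues; (4) the raw three-atom angle is measured in each
#' complex; (5) the tilt is the signed difference query - reference, so the
#' reference complex defines 0 degrees.
#'
#' @param query,reference `eph_complex` objects.
#' @param spec A [tilt_spec()]; residue numbers refer to `reference`.
#' @return A `tilt_result` list: `raw_angle`, `reference_angle`, `tilt`
#'   (signed degrees), `tilt_abs_rounded` (whole degrees, report style),
#'   `receptor_rmsd`, `pairs_used`, and the atom/convention metadata.
#' @export
measure_tilt <- function(query, reference, spec = tilt_spec()) {
  stopifnot(inherits(spec, "tilt_spec"))
  sup <- superpose_on_receptor(query, reference)
  lig_map <- align_residues(reference$ligand, query$ligand)
  v <- map_residue(sup$map, spec$vertex_residue, "vertex")
  d <- map_residue(sup$map, spec$distal_residue, "distal")
  l <- map_residue(lig_map, spec$ligand_residue, "ligand")
  qc <- sup$complex
  raw <- three_atom_angle(
    get_atom(qc$ligand, as.integer(l["resno"]), spec$atom_name, l["icode"]),
    get_atom(qc$receptor, as.integer(v["resno"]), spec$atom_name, v["icode"]),
    get_atom(qc$receptor, as.integer(d["resno"]), spec$atom_name, d["icode"]))
  ref <- three_atom_angle(
    get_atom(reference$ligand, spec$ligand_residue, spec$atom_name),
    get_atom(reference$receptor, spec$vertex_residue, spec$atom_name),
    get_atom(reference$receptor, spec$distal_residue, spec$atom_name))
  structure(list(raw_angle = raw, reference_angle = ref, tilt = raw - ref,
                 tilt_abs_rounded = round(abs(raw - ref)),
                 receptor_rmsd = sup$rmsd, pairs_used = sup$n_pairs,
                 atom_name = spec$atom_name, sign_convention = "query - reference"),
            class = "tilt_result")
}

#' @export
print.tilt_result <- function(x, ...) {
  cat(sprintf("tilt %.2f deg (raw %.2f, reference %.2f; |tilt| ~ %d deg)\n",
              x$tilt, x$raw_angle, x$reference_angle, x$tilt_abs_rounded))
  cat(sprintf("receptor fit: %d CA pairs, rmsd %.3f A; atom %s; sign: %s\n",
              x$pairs_used, x$receptor_rmsd, x$atom_name, x$sign_convention))
  invisible(x)
}
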