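#' @title Coordinate model
#' @description
#' An `eph_structure` is a light hierarchical coordinate model: a structure id
#' plus a flat atom table (one row per atom) carrying chain, author residue
#' number, insertion code, residue name, atom name, element, Cartesian
#' coordinates in Angstrom, occupancy, B-factor, a HETATM flag and an optional
#' explicit `radius` column (used by pseudo-atom fixtures).  Only the first
#' coordinate model of a file is retained and alternate locations are resolved
#' at load time (highest occupancy wins, ties go to altloc 'A'), so the table
#' holds at most one row per (chain, resno, icode, atom name).
#' @name eph_structure
NULL

.atom_cols <- c("chain", "resno", "icode", "resid", "elety", "elesy",
                "x", "y", "z", "o", "b", "het")

new_structure <- function(id, atoms) {
  atoms$icode[is.na(atoms$icode)] <- ""
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms), class = "eph_structure")
}

#' Read a macromolecular structure from PDB or mmCIF
#'
#' Parses coordinates with \pkg{bio3d} (`read.pdb` / `read.cif`), keeps the
#' first model only, resolves alternate locations (highest occupancy; ties go
#' to altloc 'A') and tags waters/heteroatoms without dropping them.
#'
#' @param path Path to a coordinate file.
#' @param format `"pdb"`, `"cif"` or `"auto"` (by file extension; `.cif` and
#'   `.mmcif` select the mmCIF reader, everything else PDB).
#' @param id Structure identifier; defaults to the file base name.
#' @return An [eph_structure].
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' write_structure(make_sphere_cluster(matrix(0, 1, 3), 1.7), f)
#' s <- load_structure(f)
#' n_atoms(s)
#' @export
load_structure <- function(path, format = c("auto", "pdb", "cif"), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("coordinate file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  raw <- tryCatch(
    if (format == "cif")
      suppressWarnings(bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE))
    else
      bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- raw$atom
  if (is.null(at) || nrow(at) == 0)
    stop("empty structure: no atom records in ", path)
  alt <- at$alt
  alt[is.na(alt) | alt == "." | alt == "?"] <- ""
  at$alt <- alt
  ## altloc resolution: within each (chain, resno, icode, atom name) keep the
  ## highest-occupancy location; tie -> altloc 'A' (then first occurrence)
  if (any(at$alt != "")) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
                 at$elety, sep = "\r")
    ord <- order(key, -occ, at$alt != "A", at$alt, seq_len(nrow(at)))
    at <- at[ord, ]
    at <- at[!duplicated(paste(at$chain, at$resno,
                               ifelse(is.na(at$insert), "", at$insert),
                               at$elety, sep = "\r")), ]
    at <- at[order(as.integer(rownames(at))), ]
  }
  elesy <- at$elesy
  if (is.null(elesy) || all(is.na(elesy)))
    elesy <- guess_element(at$elety)
  miss <- is.na(elesy) | elesy == ""
  elesy[miss] <- guess_element(at$elety[miss])
  atoms <- data.frame(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    icode = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resid = as.character(at$resid),
    elety = as.character(at$elety),
    elesy = toupper(elesy),
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    het = at$type != "ATOM",
    stringsAsFactors = FALSE)
  if (!any(!atoms$het))
    stop("empty structure: ", path, " contains no polymer (ATOM) residues")
  new_structure(id %||% sub("\\.[^.]*$", "", basename(path)), atoms)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## crude element from atom name, enough for protein heavy atoms + pseudo-atoms
guess_element <- function(elety) {
  nm <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", elety)))
  el <- substr(nm, 1, 1)
  el[substr(nm, 1, 2) %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE")] <-
    substr(nm, 1, 2)[substr(nm, 1, 2) %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE")]
  el
}

#' Write an `eph_structure` to a PDB file
#'
#' Coordinates are written via [bio3d::write.pdb()]; an explicit `radius`
#' column, if present (sphere-cluster fixtures), is stored in the B-factor
#' field so the fixture round-trips through plain PDB.
#'
#' @param s An [eph_structure].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "eph_structure"))
  a <- s$atoms
  b <- if (!is.null(a$radius)) a$radius else a$b
  bio3d::write.pdb(file = path,
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   insert = ifelse(a$icode == "", NA, a$icode),
                   elety = a$elety, o = a$o, b = b, elesy = a$elesy)
  invisible(path)
}

#' Number of atoms in a structure
#' @param s An [eph_structure].
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Chain identifiers present in a structure
#' @param s An [eph_structure].
#' @export
chain_ids <- function(s) unique(s$atoms$chain)

#' Per-residue table of a structure (one row per residue, polymer only)
#' @param s An [eph_structure].
#' @param chain Optional chain id filter.
#' @keywords internal
residue_table <- function(s, chain = NULL) {
  a <- s$atoms[!s$atoms$het, ]
  if (!is.null(chain)) a <- a[a$chain %in% chain, ]
  key <- paste(a$chain, a$resno, a$icode, sep = "\r")
  a <- a[!duplicated(key), c("chain", "resno", "icode", "resid")]
  a[order(a$chain, a$resno, a$icode), , drop = FALSE]
}

#' @export
print.eph_structure <- function(x, ...) {
  rt <- residue_table(x)
  cat("<eph_structure> id:", x$id, "\n")
  for (ch in chain_ids(x)) {
    r <- rt[rt$chain == ch, ]
    na <- sum(x$atoms$chain == ch)
    if (nrow(r))
      cat(sprintf("  chain %s: %d residues (%d-%d), %d atoms\n", ch, nrow(r),
                  min(r$resno), max(r$resno), na))
    else
      cat(sprintf("  chain %s: hetero only, %d atoms\n", ch, na))
  }
  invisible(x)
}

#' Define the receptor/ligand selection of a two-chain complex
#'
#' @param receptor_chain,ligand_chain Chain identifiers.
#' @param receptor_range,ligand_range Optional length-2 integer vectors of
#'   author residue numbers (inclusive); `NULL` keeps the whole chain.
#' @return A `complex_spec` list.
#' @export
complex_spec <- function(receptor_chain, ligand_chain,
                         receptor_range = NULL, ligand_range = NULL) {
  if (identical(receptor_chain, ligand_chain) &&
      is.null(receptor_range) && is.null(ligand_range))
    stop("receptor and ligand selections must be disjoint")
  structure(list(receptor = list(chain = receptor_chain, range = receptor_range),
                 ligand   = list(chain = ligand_chain,   range = ligand_range)),
            class = "complex_spec")
}

select_chain <- function(s, chain, range = NULL, keep_het = FALSE) {
  a <- s$atoms
  if (!chain %in% a$chain)
    stop("chain '", chain, "' not present in structure ", s$id)
  a <- a[a$chain == chain & (keep_het | !a$het), , drop = FALSE]
  if (!is.null(range))
    a <- a[a$resno >= range[1] & a$resno <= range[2], , drop = FALSE]
  if (nrow(a) == 0)
    stop("selection on chain '", chain, "' matches no residues")
  new_structure(s$id, a)
}

#' Extract the receptor and ligand chains of a complex
#'
#' Returns deep, independent copies of the two selections; residues outside
#' the requested ranges (and hetero atoms/waters) are dropped.
#'
#' @param s An [eph_structure].
#' @param spec A [complex_spec()].
#' @return An `eph_complex`: list with elements `receptor` and `ligand`, each
#'   an [eph_structure], plus the source `id`.
#' @export
extract_complex <- function(s, spec) {
  stopifnot(inherits(spec, "complex_spec"))
  structure(list(id = s$id,
                 receptor = select_chain(s, spec$receptor$chain, spec$receptor$range),
                 ligand   = select_chain(s, spec$ligand$chain,   spec$ligand$range)),
            class = "eph_complex")
}

#' @export
print.eph_complex <- function(x, ...) {
  cat("<eph_complex> id:", x$id, "\n receptor:\n")
  print(x$receptor)
  cat(" ligand:\n")
  print(x$ligand)
  invisible(x)
}

## coordinates of one named atom per residue, in residue order
atom_coords <- function(s, elety = "CA") {
  a <- s$atoms[s$atoms$elety == elety & !s$atoms$het, , drop = FALSE]
  a <- a[order(a$resno, a$icode), , drop = FALSE]
  list(xyz = as.matrix(a[, c("x", "y", "z")]), resno = a$resno,
       icode = a$icode, resid = a$resid)
}

## xyz matrix of all atoms
all_xyz <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

## fetch a single atom position by residue number (+ atom name)
get_atom <- function(s, resno, elety = "CA", icode = "") {
  i <- which(s$atoms$resno == resno & s$atoms$elety == elety &
             s$atoms$icode == icode & !s$atoms$het)
  if (length(i) == 0)
    stop("atom ", elety, " of residue ", resno, " not found in ", s$id)
  as.numeric(s$atoms[i[1], c("x", "y", "z")])
}
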