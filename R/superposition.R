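#' Residue correspondence between two homologous chains
#'
#' Pairs residues of two chains by global (Needleman-Wunsch) alignment of
#' their one-letter sequences, scored match = +1, mismatch = 0, gap open = -1,
#' gap extend = -0.5.  Only aligned (identical or substituted) positions with
#' a CA atom on both sides enter the map.
#'
#' @param a,b [eph_structure] chains with at least 10 CA-bearing residues.
#' @return A data frame of class `correspondence_map` with one row per pair:
#'   `resno_a`, `icode_a`, `resid_a`, `resno_b`, `icode_b`, `resid_b`.
#' @export
align_residues <- function(a, b) {
  ca <- atom_coords(a, "CA"); cb <- atom_coords(b, "CA")
  if (nrow(ca$xyz) < 10 || nrow(cb$xyz) < 10)
    stop("alignment needs >= 10 CA-bearing residues per chain")
  sa <- bio3d::aa321(ca$resid); sb <- bio3d::aa321(cb$resid)
  sa[sa == "X" | is.na(sa)] <- "X"; sb[sb == "X" | is.na(sb)] <- "X"
  sub <- matrix(0, 26, 26, dimnames = list(LETTERS, LETTERS))
  diag(sub) <- 1
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(sa, collapse = "")),
    Biostrings::AAString(paste(sb, collapse = "")),
    type = "global", substitutionMatrix = sub,
    gapOpening = 1, gapExtension = 0.5)
  al_a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  al_b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ia <- ib <- 0L
  rows <- vector("list", length(al_a))
  for (k in seq_along(al_a)) {
    ga <- al_a[k] == "-"; gb <- al_b[k] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (!ga && !gb)
      rows[[k]] <- c(ia, ib)
  }
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) < 10)
    stop("alignment too sparse: fewer than 10 residue pairs")
  map <- data.frame(resno_a = ca$resno[rows[, 1]], icode_a = ca$icode[rows[, 1]],
                    resid_a = ca$resid[rows[, 1]],
                    resno_b = cb$resno[rows[, 2]], icode_b = cb$icode[rows[, 2]],
                    resid_b = cb$resid[rows[, 2]],
                    stringsAsFactors = FALSE)
  class(map) <- c("correspondence_map", "data.frame")
  map
}

#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD of
#' `q %*% t(R) + t` onto `p`.  A reflection arising from the SVD is corrected
#' by flipping the sign of the smallest singular vector, so the returned
#' rotation always has determinant +1.
#'
#' @param p,q N x 3 coordinate matrices of paired points (N >= 3,
#'   non-collinear).
#' @return A list of class `rigid_transform`: `rotation` (3 x 3),
#'   `translation` (length 3), `rmsd` (Angstrom).
#' @examples
#' p <- matrix(rnorm(30), 10, 3)
#' kabsch(p, p)$rmsd
#' @export
kabsch <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  if (nrow(p) != nrow(q) || ncol(p) != 3 || ncol(q) != 3)
    stop("p and q must be matched N x 3 matrices")
  if (nrow(p) < 3)
    stop("degenerate input: need at least 3 points")
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2, cp); qc <- sweep(q, 2, cq)
  h <- crossprod(qc, pc)             # 3x3 covariance, q -> p
  s <- svd(h)
  if (s$d[2] < 1e-10)
    stop("degenerate input: points are collinear or coincident")
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  qf <- qc %*% t(rot)
  rmsd <- sqrt(mean(rowSums((qf - pc)^2)))
  trans <- cp - as.numeric(rot %*% cq)
  structure(list(rotation = rot, translation = trans, rmsd = rmsd),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates or a structure
#'
#' @param xf A `rigid_transform` from [kabsch()].
#' @param x An N x 3 matrix, an [eph_structure], or an `eph_complex`.
#' @return `x` with transformed coordinates.
#' @export
apply_transform <- function(xf, x) {
  stopifnot(inherits(xf, "rigid_transform"))
  if (inherits(x, "eph_complex")) {
    x$receptor <- apply_transform(xf, x$receptor)
    x$ligand <- apply_transform(xf, x$ligand)
    return(x)
  }
  if (inherits(x, "eph_structure")) {
    xyz <- all_xyz(x) %*% t(xf$rotation)
    xyz <- sweep(xyz, 2, xf$translation, "+")
    x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
    return(x)
  }
  sweep(as.matrix(x) %*% t(xf$rotation), 2, xf$translation, "+")
}

## CA coordinates of chain `s` for the residues named in one side of a map
map_ca <- function(s, resno, icode) {
  xyz <- matrix(NA_real_, length(resno), 3)
  ok <- logical(length(resno))
  a <- s$atoms[s$atoms$elety == "CA" & !s$atoms$het, ]
  key <- paste(a$resno, a$icode, sep = "\r")
  idx <- match(paste(resno, icode, sep = "\r"), key)
  ok <- !is.na(idx)
  xyz[ok, ] <- as.matrix(a[idx[ok], c("x", "y", "z")])
  list(xyz = xyz, ok = ok)
}

#' Superpose one complex onto another through their receptor chains
#'
#' Establishes a receptor-residue correspondence with [align_residues()], fits
#' the corresponding CA atoms with [kabsch()], and applies the resulting
#' transform to every atom of the moving complex (receptor and ligand alike),
#' so the ligand is carried rigidly into the reference receptor frame.
#'
#' @param moving,reference `eph_complex` objects (see [extract_complex()]).
#' @return A list: `complex` (transformed copy of `moving`), `rmsd`
#'   (receptor-CA fit, Angstrom), `n_pairs`, `map` (the correspondence), and
#'   `transform`.
#' @export
superpose_on_receptor <- function(moving, reference) {
  stopifnot(inherits(moving, "eph_complex"), inherits(reference, "eph_complex"))
  map <- align_residues(reference$receptor, moving$receptor)
  pa <- map_ca(reference$receptor, map$resno_a, map$icode_a)
  pb <- map_ca(moving$receptor, map$resno_b, map$icode_b)
  keep <- pa$ok & pb$ok
  if (sum(keep) < 3)
    stop("fewer than 3 CA pairs available for superposition")
  xf <- kabsch(pa$xyz[keep, , drop = FALSE], pb$xyz[keep, , drop = FALSE])
  list(complex = apply_transform(xf, moving), rmsd = xf$rmsd,
       n_pairs = sum(keep), map = map[keep, ], transform = xf)
}
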