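#' Dot surface of a structure selection
#'
#' Approximates the molecular surface by solvent-accessible dots repositioned
#' onto each atom's van der Waals sphere: every atom is covered with a
#' deterministic spiral lattice on its probe-expanded sphere, dots falling
#' inside any neighbour's expanded sphere are discarded, and the survivors are
#' pulled radially back to the vdW radius.  Normals point outward along the
#' atom radius.  The retained dot count approximates `density` times the
#' accessible area.
#'
#' @param s An [eph_structure] selection.
#' @param density Target dots per Angstrom^2 of accessible surface.
#' @param probe Probe radius, Angstrom.
#' @param keep_het Include HETATM records.
#' @return A data frame of surface dots: `x, y, z` (on the vdW sphere),
#'   `nx, ny, nz` (unit outward normal), `atom` (row index into the retained
#'   atom table, returned as attribute `atoms`).
#' @export
dot_surface <- function(s, density = 15, probe = 1.4, keep_het = FALSE) {
  a <- s$atoms
  a <- a[toupper(a$elesy) != "H" & (keep_het | !a$het), , drop = FALSE]
  if (nrow(a) == 0) stop("no atoms selected")
  rvdw <- vdw_radii(a)
  rext <- rvdw + probe
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(a)
  d2 <- as.matrix(stats::dist(xyz))^2
  dots <- vector("list", n)
  for (i in seq_len(n)) {
    np <- max(12L, round(density * 4 * pi * rext[i]^2))
    lat <- sphere_lattice(np)
    pts <- sweep(lat * rext[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, np)
    nb <- which(d2[i, ] < (rext[i] + rext)^2 & seq_len(n) != i)
    for (j in nb) {
      if (!any(free)) break
      dj <- (pts[free, 1] - xyz[j, 1])^2 + (pts[free, 2] - xyz[j, 2])^2 +
        (pts[free, 3] - xyz[j, 3])^2
      free[free] <- dj >= rext[j]^2
    }
    if (!any(free)) next
    lat <- lat[free, , drop = FALSE]
    dots[[i]] <- data.frame(
      x = xyz[i, 1] + lat[, 1] * rvdw[i],
      y = xyz[i, 2] + lat[, 2] * rvdw[i],
      z = xyz[i, 3] + lat[, 3] * rvdw[i],
      nx = lat[, 1], ny = lat[, 2], nz = lat[, 3],
      atom = i)
  }
  out <- do.call(rbind, dots)
  if (is.null(out)) stop("selection produced no surface dots")
  rownames(out) <- NULL
  attr(out, "atoms") <- a
  out
}

## for every row of `from`, index of and distance to the nearest row of `to`
nearest_dot <- function(from, to) {
  fx <- as.matrix(from[, c("x", "y", "z")])
  tx <- as.matrix(to[, c("x", "y", "z")])
  idx <- integer(nrow(fx)); dst <- numeric(nrow(fx))
  for (i in seq_len(nrow(fx))) {
    d2 <- (tx[, 1] - fx[i, 1])^2 + (tx[, 2] - fx[i, 2])^2 + (tx[, 3] - fx[i, 3])^2
    j <- which.min(d2)
    idx[i] <- j; dst[i] <- sqrt(d2[j])
  }
  list(index = idx, dist = dst)
}

#' Lawrence-Colman shape-complementarity statistic Sc
#'
#' For each buried dot x on surface A with nearest partner dot x' on surface
#' B, the local complementarity is S(x) = (n_x . -n_x') exp(-w d(x,x')^2).
#' The directional score is the median of S over A's buried dots; Sc is the
#' mean of the two directional medians and lies in \[-1, 1\], with 1 for
#' perfectly interlocking surfaces.  Buried dots are those within `band` of
#' the partner surface; optionally the peripheral band of the buried region
#' (buried dots within `band` of a non-buried dot on the same surface) is
#' trimmed, as in the original method.
#'
#' @param dots_a,dots_b Dot data frames from [dot_surface()] (or any frame
#'   with columns `x, y, z, nx, ny, nz`).
#' @param w Gaussian distance weight, Angstrom^-2 (original default 0.5).
#' @param band Interface band defining buried dots, Angstrom.
#' @param trim_periphery Drop the peripheral band of the buried region.
#' @return An `sc_report` list: `sc`, `s_ab_median`, `s_ba_median`,
#'   `n_dots_a`, `n_dots_b` (buried dots used per direction), `w`, `band`.
#' @export
sc_statistic <- function(dots_a, dots_b, w = 0.5, band = 1.5,
                         trim_periphery = TRUE) {
  if (nrow(dots_a) == 0 || nrow(dots_b) == 0)
    stop("both dot sets must be non-empty")
  directional <- function(from, to) {
    nn <- nearest_dot(from, to)
    buried <- nn$dist < band
    if (!any(buried))
      stop("no interface: no dots within the buried band of ", band, " A")
    keep <- buried
    if (trim_periphery && any(!buried)) {
      fb <- from[buried, , drop = FALSE]
      fn <- from[!buried, , drop = FALSE]
      edge <- nearest_dot(fb, fn)$dist < band
      if (any(!edge)) keep[buried] <- !edge   # trim only if a core remains
    }
    idx <- which(keep)
    s <- numeric(length(idx))
    for (k in seq_along(idx)) {
      i <- idx[k]; j <- nn$index[i]
      dotn <- -(from$nx[i] * to$nx[j] + from$ny[i] * to$ny[j] +
                  from$nz[i] * to$nz[j])
      s[k] <- dotn * exp(-w * nn$dist[i]^2)
    }
    list(median = stats::median(s), n = length(s))
  }
  ab <- directional(dots_a, dots_b)
  ba <- directional(dots_b, dots_a)
  structure(list(sc = (ab$median + ba$median) / 2,
                 s_ab_median = ab$median, s_ba_median = ba$median,
                 n_dots_a = ab$n, n_dots_b = ba$n, w = w, band = band),
            class = "sc_report")
}

#' @export
print.sc_report <- function(x, ...) {
  cat(sprintf("Sc = %.3f (medians %.3f / %.3f; %d + %d buried dots; w = %g A^-2, band = %g A)\n",
              x$sc, x$s_ab_median, x$s_ba_median, x$n_dots_a, x$n_dots_b,
              x$w, x$band))
  invisible(x)
}

#' Shape complementarity of a receptor/ligand interface
#'
#' Convenience wrapper: builds dot surfaces for the two selections and
#' evaluates [sc_statistic()].  `ligand_range` restricts the ligand side to a
#' residue range (e.g. the ephrin GH loop 121-129) so the score can be
#' evaluated for a sub-interface.
#'
#' @param receptor,ligand [eph_structure] selections.
#' @param ligand_range Optional length-2 residue-number range on the ligand.
#' @param density,probe Passed to [dot_surface()].
#' @param ... Passed to [sc_statistic()].
#' @return An `sc_report`.
#' @export
interface_sc <- function(receptor, ligand, ligand_range = NULL,
                         density = 15, probe = 1.4, ...) {
  if (!is.null(ligand_range)) {
    keep <- ligand$atoms$resno >= ligand_range[1] &
      ligand$atoms$resno <= ligand_range[2]
    ligand <- new_structure(ligand$id, ligand$atoms[keep, , drop = FALSE])
  }
  sc_statistic(dot_surface(receptor, density, probe),
               dot_surface(ligand, density, probe), ...)
}
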