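#' Cumulative twist along a beta-strand
#'
#' Quantifies how far a strand's carbonyl orientation rotates about the local
#' chain axis.  Residues are taken two at a time (i against i+2, stepping by
#' two), which cancels the alternating up/down carbonyl pleat of a beta
#' strand: for each step the carbonyl vectors C(i)->O(i) and C(i+2)->O(i+2)
#' are projected onto the plane perpendicular to the local axis
#' CA(i)->CA(i+2), and the signed angle between the projections (sign from
#' the axis-aligned cross product) is the per-step twist.  The cumulative
#' twist is the sum of absolute per-step values.  Because no community-wide
#' convention exists for this number, every report is stamped with the
#' convention string and values should only be compared within it.
#'
#' @param s An [eph_structure].
#' @param chain Chain identifier.
#' @param first_residue,last_residue Author residue numbers delimiting the
#'   strand (>= 4 residues).
#' @return A `twist_report` list: `per_step` (signed degrees, one per
#'   two-residue step), `step_residues`, `cumulative` (degrees), `skipped`
#'   (steps lacking backbone atoms), `residues`, `convention`.
#' @export
strand_twist <- function(s, chain, first_residue, last_residue) {
  a <- s$atoms[!s$atoms$het & s$atoms$chain == chain &
               s$atoms$resno >= first_residue & s$atoms$resno <= last_residue, ]
  resnos <- sort(unique(a$resno))
  if (length(resnos) < 4)
    stop("strand range must span at least 4 residues")
  bb <- function(resno, name) {
    i <- which(a$resno == resno & a$elety == name)
    if (length(i) == 0) return(NULL)
    as.numeric(a[i[1], c("x", "y", "z")])
  }
  starts <- resnos[seq(1, length(resnos), by = 2)]
  steps <- numeric(0); labels <- character(0); skipped <- character(0)
  for (r1 in starts) {
    k <- match(r1, resnos)
    if (k + 2 > length(resnos)) break
    r2 <- resnos[k + 2]
    ca1 <- bb(r1, "CA"); c1 <- bb(r1, "C"); o1 <- bb(r1, "O")
    ca2 <- bb(r2, "CA"); c2 <- bb(r2, "C"); o2 <- bb(r2, "O")
    if (is.null(ca1) || is.null(c1) || is.null(o1) ||
        is.null(ca2) || is.null(c2) || is.null(o2)) {
      skipped <- c(skipped, sprintf("%d-%d", r1, r2))
      next
    }
    u <- ca2 - ca1; u <- u / sqrt(sum(u^2))
    proj <- function(v) v - sum(v * u) * u
    v1 <- proj(o1 - c1); v2 <- proj(o2 - c2)
    n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
    if (n1 < 1e-9 || n2 < 1e-9) {
      skipped <- c(skipped, sprintf("%d-%d", r1, r2))
      next
    }
    cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
            v1[3] * v2[1] - v1[1] * v2[3],
            v1[1] * v2[2] - v1[2] * v2[1])
    ang <- atan2(sum(u * cr), sum(v1 * v2)) * 180 / pi
    steps <- c(steps, ang)
    labels <- c(labels, sprintf("%d-%d", r1, r2))
  }
  if (length(steps) == 0)
    stop("no usable two-residue steps (missing backbone atoms?)")
  structure(list(per_step = steps, step_residues = labels,
                 cumulative = sum(abs(steps)), skipped = skipped,
                 residues = c(first_residue, last_residue),
                 convention = "carbonyl projection, i vs i+2, sum of |signed step|"),
            class = "twist_report")
}

#' @export
print.twist_report <- function(x, ...) {
  cat(sprintf("cumulative twist %.1f deg over residues %d-%d (%d steps%s)\n",
              x$cumulative, x$residues[1], x$residues[2], length(x$per_step),
              if (length(x$skipped)) paste0("; skipped ",
                                            paste(x$skipped, collapse = ",")) else ""))
  cat(" per step:", paste(sprintf("%s: %+.1f", x$step_residues, x$per_step),
                          collapse = "; "), "\n")
  cat(" convention:", x$convention, "\n")
  invisible(x)
}
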