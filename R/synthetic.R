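#' Synthetic fixtures with analytically known answers
#'
#' The generators in this file build the test fixtures the analysis pipeline
#' needs: two-chain complexes whose ligand has been rotated by a known angle,
#' pseudo-atom sphere clusters with closed-form accessible areas, ideal and
#' uniformly twisted strands, planar dot grids for the Sc statistic, and
#' noisy one-site titration curves.  All randomness is drawn from a seeded
#' generator local to the call; the same seed reproduces the same fixture
#' byte for byte.
#'
#' @name synthetic-fixtures
NULL

## rotate points about an axis (unit u) through point o by theta degrees
rotate_about_axis <- function(xyz, o, u, theta) {
  th <- theta * pi / 180
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep(xyz, 2, o) %*% t(R), 2, o, "+")
}

## poly-alanine-like CA/C/O trace along a list of CA positions
trace_atoms <- function(chain, resnos, ca_xyz) {
  n <- length(resnos)
  rows <- lapply(seq_len(n), function(i) {
    ca <- ca_xyz[i, ]
    data.frame(chain = chain, resno = resnos[i], icode = "", resid = "ALA",
               elety = c("CA", "C", "O"), elesy = c("C", "C", "O"),
               x = c(ca[1], ca[1] + 0.9, ca[1] + 0.9),
               y = c(ca[2], ca[2] + 1.0, ca[2] + 1.6),
               z = c(ca[3], ca[3], ca[3] + 1.0),
               o = 1, b = 0, het = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-chain complex with the ligand rotated by a known tilt angle
#'
#' Builds a rigid receptor scaffold (chain A, residues 140-189, CA/C/O trace
#' on a gentle helix) carrying the vertex marker residue 152 and the distal
#' marker 180, and a ligand scaffold (chain B, residues 105-120) whose marker
#' residue 112 sits 10 Angstrom from the vertex at a 40 degree baseline
#' angle.  The whole ligand is then rotated by `theta` about the axis through
#' the vertex CA perpendicular to the plane of the three marker CAs, so the
#' three-atom angle grows by exactly `theta` and [measure_tilt()] against the
#' `theta = 0` fixture returns `theta`.
#'
#' @param theta Tilt in degrees, 0 to 60.
#' @param seed Seed for the optional coordinate jitter.
#' @param jitter_sd Gaussian jitter (Angstrom) applied to non-marker atoms of
#'   both chains before the rotation; 0 keeps the scaffold exact.
#' @return An [eph_structure] with chains A (receptor) and B (ligand).
#' @export
make_tilted_complex <- function(theta, seed = 1, jitter_sd = 0) {
  stopifnot(theta >= 0, theta <= 60)
  resnos_r <- 140:189
  k <- seq_along(resnos_r) - 1
  ca_r <- cbind(8 * cos(0.45 * k), 8 * sin(0.45 * k), 1.4 * k)
  rec <- trace_atoms("A", resnos_r, ca_r)
  v <- ca_r[match(152, resnos_r), ]        # vertex CA
  dvec <- ca_r[match(180, resnos_r), ] - v # vertex -> distal
  d1 <- dvec / sqrt(sum(dvec^2))
  ## unit vector perpendicular to d1 (stable choice)
  aux <- if (abs(d1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  n1 <- aux - sum(aux * d1) * d1
  n1 <- n1 / sqrt(sum(n1^2))
  alpha0 <- 40 * pi / 180
  marker <- v + 10 * (cos(alpha0) * d1 + sin(alpha0) * n1)
  resnos_l <- 105:120
  j <- seq_along(resnos_l) - match(112, resnos_l)
  ## compact zig-zag around the marker, rigid with it
  ca_l <- cbind(marker[1] + 3.0 * j,
                marker[2] + 1.5 * (j %% 2),
                marker[3] + 0.8 * j)
  lig <- trace_atoms("B", resnos_l, ca_l)
  if (jitter_sd > 0) {
    set.seed(seed)
    keep <- !(rec$resno %in% c(152, 180) & rec$elety == "CA")
    rec$x[keep] <- rec$x[keep] + stats::rnorm(sum(keep), 0, jitter_sd)
    rec$y[keep] <- rec$y[keep] + stats::rnorm(sum(keep), 0, jitter_sd)
    rec$z[keep] <- rec$z[keep] + stats::rnorm(sum(keep), 0, jitter_sd)
  }
  if (theta != 0) {
    axis <- c(d1[2] * n1[3] - d1[3] * n1[2],
              d1[3] * n1[1] - d1[1] * n1[3],
              d1[1] * n1[2] - d1[2] * n1[1])   # d1 x n1: rotating the ligand
    ## about +axis increases the marker-vertex-distal angle by theta
    xyz <- rotate_about_axis(as.matrix(lig[, c("x", "y", "z")]), v, axis, theta)
    lig$x <- xyz[, 1]; lig$y <- xyz[, 2]; lig$z <- xyz[, 3]
  }
  new_structure(sprintf("tilted_%g", theta), rbind(rec, lig))
}

#' Pseudo-atom sphere cluster for surface-area tests
#'
#' One pseudo-atom per sphere, with an explicit per-atom `radius` column that
#' [vdw_radii()] honours, so accessible areas can be compared against
#' closed-form sphere/spherical-cap values.  Written to PDB, the radius is
#' carried in the B-factor column.
#'
#' @param centers N x 3 matrix of sphere centers, Angstrom.
#' @param radii Length-N radii, Angstrom.
#' @param chain Chain id for the pseudo-atoms.
#' @return An [eph_structure].
#' @export
make_sphere_cluster <- function(centers, radii, chain = "S") {
  centers <- matrix(centers, ncol = 3)
  radii <- rep_len(radii, nrow(centers))
  atoms <- data.frame(chain = chain, resno = seq_len(nrow(centers)),
                      icode = "", resid = "SPH", elety = "C", elesy = "C",
                      x = centers[, 1], y = centers[, 2], z = centers[, 3],
                      o = 1, b = radii, het = FALSE, radius = radii,
                      stringsAsFactors = FALSE)
  new_structure("sphere_cluster", atoms)
}

#' Random sphere cluster (convergence fixture)
#'
#' @param n Number of spheres.
#' @param seed Seed fixing the configuration.
#' @param box Edge of the cubic box the centers are drawn in, Angstrom.
#' @param radius Common sphere radius.
#' @export
make_random_cluster <- function(n = 100, seed = 1, box = 20, radius = 1.7) {
  set.seed(seed)
  make_sphere_cluster(matrix(stats::runif(3 * n, 0, box), ncol = 3), radius)
}

#' Ideal or uniformly twisted strand fixture
#'
#' An extended CA/C/O chain along x with identical per-residue geometry.
#' `twist_per_step` rotates the carbonyl of residue i by
#' `twist_per_step * (i-1) / 2` degrees about the chain axis, i.e. each
#' two-residue step adds exactly `twist_per_step` degrees of twist;
#' `pleat = TRUE` additionally flips alternate carbonyls by 180 degrees (the
#' beta-pleat alternation that the i vs i+2 comparison cancels).
#'
#' @param n_res Number of residues.
#' @param twist_per_step Degrees of twist per two-residue step.
#' @param pleat Apply the alternating carbonyl flip.
#' @param chain Chain id.
#' @return An [eph_structure].
#' @export
make_strand <- function(n_res = 8, twist_per_step = 0, pleat = FALSE,
                        chain = "A") {
  rows <- lapply(seq_len(n_res), function(i) {
    ca <- c(3.5 * (i - 1), 0, 0)
    beta <- (twist_per_step / 2) * (i - 1) * pi / 180 +
      if (pleat && i %% 2 == 0) pi else 0
    co <- 1.23 * c(0, cos(beta), sin(beta))    # C -> O carbonyl vector
    cpos <- ca + c(1.2, 0, 0)
    data.frame(chain = chain, resno = i, icode = "", resid = "ALA",
               elety = c("N", "CA", "C", "O"), elesy = c("N", "C", "C", "O"),
               x = c(ca[1] - 1.2, ca[1], cpos[1], cpos[1] + co[1]),
               y = c(0, ca[2], cpos[2], cpos[2] + co[2]),
               z = c(0, ca[3], cpos[3], cpos[3] + co[3]),
               o = 1, b = 0, het = FALSE, stringsAsFactors = FALSE)
  })
  new_structure(sprintf("strand_%g", twist_per_step), do.call(rbind, rows))
}

#' Parallel planar dot grids for the Sc statistic
#'
#' Two square grids of surface dots with opposing normals: grid A in the
#' plane z = 0 with normals +z, grid B in the plane z = `separation` with
#' normals -z.  At zero separation the surfaces are perfectly complementary
#' (Sc = 1); at separation d the closed-form score is `exp(-w d^2)`.
#'
#' @param separation Gap between the planes, Angstrom.
#' @param n Dots per grid edge.
#' @param spacing Grid spacing, Angstrom.
#' @return A list with dot frames `a` and `b` for [sc_statistic()].
#' @export
make_plane_pair <- function(separation, n = 20, spacing = 0.5) {
  g <- expand.grid(x = spacing * (seq_len(n) - (n + 1) / 2),
                   y = spacing * (seq_len(n) - (n + 1) / 2))
  a <- data.frame(x = g$x, y = g$y, z = 0, nx = 0, ny = 0, nz = 1, atom = 1L)
  b <- data.frame(x = g$x, y = g$y, z = separation, nx = 0, ny = 0, nz = -1,
                  atom = 1L)
  list(a = a, b = b)
}

#' Simulate a titration and write it to disk
#'
#' Delegates to [simulate_titration()] and [write_titration()]; defaults
#' mirror the VP-ITC protocol of the EphA3/ephrin-A5 experiment (n = 1,
#' K_d = 9 nM, dH = -2145 cal/mol).
#'
#' @param prefix Output path prefix.
#' @param params A [thermo_params()].
#' @param schedule A [titration_schedule()].
#' @param noise_sd Gaussian noise on normalized heats, cal/mol.
#' @param seed Noise seed.
#' @return The `injection_heats` object, invisibly; files are written as a
#'   side effect.
#' @export
make_itc_curve <- function(prefix,
                           params = thermo_params(n = 1, K_d = 9e-9, dH = -2145),
                           schedule = epha3_schedule(),
                           noise_sd = 0, seed = 1) {
  heats <- simulate_titration(params, schedule, noise_sd = noise_sd, seed = seed)
  write_titration(heats, schedule, prefix)
  invisible(heats)
}
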