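# independent oracles the implementation is checked against

# Horn quaternion superposition: closed-form eigen-decomposition route,
# independent of the SVD path used by kabsch()
quat_superpose <- function(p, q) {
  pc <- sweep(p, 2, colMeans(p)); qc <- sweep(q, 2, colMeans(q))
  M <- crossprod(qc, pc)
  N <- rbind(
    c(M[1, 1] + M[2, 2] + M[3, 3], M[2, 3] - M[3, 2],
      M[3, 1] - M[1, 3], M[1, 2] - M[2, 1]),
    c(M[2, 3] - M[3, 2], M[1, 1] - M[2, 2] - M[3, 3],
      M[1, 2] + M[2, 1], M[3, 1] + M[1, 3]),
    c(M[3, 1] - M[1, 3], M[1, 2] + M[2, 1],
      -M[1, 1] + M[2, 2] - M[3, 3], M[2, 3] + M[3, 2]),
    c(M[1, 2] - M[2, 1], M[3, 1] + M[1, 3],
      M[2, 3] + M[3, 2], -M[1, 1] - M[2, 2] + M[3, 3]))
  e <- eigen(N, symmetric = TRUE)
  v <- e$vectors[, 1]
  w <- v[1]; x <- v[2]; y <- v[3]; z <- v[4]
  R <- rbind(c(w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y)),
             c(2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x)),
             c(2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2))
  list(rotation = R, rmsd = sqrt(mean(rowSums((qc %*% t(R) - pc)^2))))
}

# rmsd of q onto p under a given rotation (after centering), for the
# Monte-Carlo minimality check
rmsd_under_rotation <- function(p, q, R) {
  pc <- sweep(p, 2, colMeans(p)); qc <- sweep(q, 2, colMeans(q))
  sqrt(mean(rowSums((qc %*% t(R) - pc)^2)))
}

random_rotation <- function() {
  v <- stats::rnorm(4); v <- v / sqrt(sum(v^2))
  w <- v[1]; x <- v[2]; y <- v[3]; z <- v[4]
  rbind(c(w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2))
}

# closed-form accessible area of two intersecting spheres of (expanded)
# radii R1, R2 at center distance d: full spheres minus the buried caps
two_sphere_area <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
  x2 <- (d^2 + R2^2 - R1^2) / (2 * d)
  2 * pi * R1 * (R1 + x1) + 2 * pi * R2 * (R2 + x2)
}

# per-injection heats from first-principles binding equilibrium: free
# injectant by bisection on X_f, bound = n*Mt*Ka*X_f/(1+Ka*X_f); independent
# of the closed-form Wiseman expression used by simulate_titration()
equilibrium_heats <- function(params, schedule) {
  cc <- ephcompare:::cell_concentrations(schedule)
  Q <- vapply(seq_along(cc$Mt), function(i) {
    Mt <- cc$Mt[i]; Xt <- cc$Xt[i]
    f <- function(xf) xf + params$n * Mt * params$K_a * xf /
      (1 + params$K_a * xf) - Xt
    xf <- stats::uniroot(f, c(0, Xt), tol = 1e-15 * max(Xt, 1e-12))$root
    bound <- params$n * Mt * params$K_a * xf / (1 + params$K_a * xf)
    bound * params$dH * cc$V0
  }, numeric(1))
  Qprev <- c(0, Q[-length(Q)])
  dQ <- Q - Qprev + (cc$dV / cc$V0) * (Q + Qprev) / 2
  dQ / (schedule$syringe_conc * cc$dV)
}
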