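#' @importFrom minpack.lm nls.lm nls.lm.control
NULL

## gas constant in the calorie units of published ITC tables
.R_cal <- 1.9872  # cal mol^-1 K^-1

#' Thermodynamic parameter set for one-set-of-sites binding
#'
#' Holds the stoichiometry `n`, association constant `K_a` (M^-1) and binding
#' enthalpy `dH` (cal/mol) together with the quantities they imply:
#' `K_d = 1/K_a`, `dG = -R T log(K_a)` with R = 1.9872 cal mol^-1 K^-1, and
#' `TdS = dH - dG`.
#'
#' @param n Sites per macromolecule (dimensionless).
#' @param K_a Association constant, M^-1 (give either `K_a` or `K_d`).
#' @param K_d Dissociation constant, M.
#' @param dH Binding enthalpy, cal/mol.
#' @param T Temperature, K (25 C by default).
#' @return A `thermo_params` list: `n, K_a, K_d, dH, dG, TdS, T`.
#' @examples
#' thermo_params(n = 1, K_d = 9e-9, dH = -2145)
#' @export
thermo_params <- function(n = 1, K_a = NULL, K_d = NULL, dH, T = 298.15) {
  if (is.null(K_a) && is.null(K_d)) stop("give K_a or K_d")
  if (is.null(K_a)) K_a <- 1 / K_d
  if (K_a <= 0 || T <= 0 || n <= 0) stop("n, K_a and T must be positive")
  dG <- -.R_cal * T * log(K_a)
  structure(list(n = n, K_a = K_a, K_d = 1 / K_a, dH = dH, dG = dG,
                 TdS = dH - dG, T = T),
            class = "thermo_params")
}

#' Complete a thermodynamic parameter set from its independent pieces
#'
#' Applies the linkage relations `dG = -R T log(K_a)`, `TdS = dH - dG`,
#' `K_d = 1/K_a`.  Either the association constant or the entropic term may
#' be supplied; the remaining quantities are derived.  With `TdS` given, the
#' free energy is the plain difference `dG = dH - TdS` and `K_a` follows as
#' `exp(-dG / (R T))`.
#'
#' @param dH Binding enthalpy, cal/mol.
#' @param K_a Association constant, M^-1.
#' @param TdS Entropic term T*dS, cal/mol.
#' @param n Stoichiometry carried through.
#' @param T Temperature, K.
#' @return A [thermo_params()] object.
#' @examples
#' p <- thermodynamic_linkage(dH = -2145, TdS = 8855)
#' p$dG          # -11000 cal/mol
#' p$K_d * 1e9   # ~8.6 nM
#' @export
thermodynamic_linkage <- function(dH, K_a = NULL, TdS = NULL, n = 1, T = 298.15) {
  if (is.null(K_a) == is.null(TdS))
    stop("give exactly one of K_a or TdS")
  if (is.null(K_a)) {
    dG <- dH - TdS
    K_a <- exp(-dG / (.R_cal * T))
  }
  thermo_params(n = n, K_a = K_a, dH = dH, T = T)
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf("n = %.3f, K_d = %.3g M (K_a = %.3g M^-1), T = %.2f K\n",
              x$n, x$K_d, x$K_a, x$T))
  cat(sprintf("dH = %.0f, dG = %.0f, TdS = %.0f cal/mol\n", x$dH, x$dG, x$TdS))
  invisible(x)
}

#' Titration schedule of an ITC experiment
#'
#' @param cell_volume Calorimetric cell volume, mL.
#' @param cell_conc Concentration of the species in the cell, M.
#' @param syringe_conc Injectant concentration, M.
#' @param injection_volumes Ordered injection volumes, uL.
#' @param temperature K.
#' @return A `titration_schedule` list.
#' @export
titration_schedule <- function(cell_volume, cell_conc, syringe_conc,
                               injection_volumes, temperature = 298.15) {
  stopifnot(cell_volume > 0, cell_conc > 0, syringe_conc > 0,
            all(injection_volumes > 0), temperature > 0)
  structure(list(cell_volume = cell_volume, cell_conc = cell_conc,
                 syringe_conc = syringe_conc,
                 injection_volumes = as.numeric(injection_volumes),
                 temperature = temperature),
            class = "titration_schedule")
}

#' The published EphA3-into-ephrin-A5 titration protocols
#'
#' `"vp_itc"`: 2 mL of 10 uM ephrin-A5 in the cell, one 5 uL injection of
#' 100 uM EphA3 followed by 19 x 15 uL.  `"itc200"`: 300 uL of 46 uM
#' ephrin-A5, 19 x 2 uL of 460 uM EphA3.  Both at 25 C.
#'
#' @param which `"vp_itc"` (default) or `"itc200"`.
#' @return A [titration_schedule()].
#' @export
epha3_schedule <- function(which = c("vp_itc", "itc200")) {
  which <- match.arg(which)
  if (which == "vp_itc")
    titration_schedule(2.0, 10e-6, 100e-6, c(5, rep(15, 19)))
  else
    titration_schedule(0.3, 46e-6, 460e-6, rep(2, 19))
}

## dilution-corrected concentrations after cumulative injected volume v (L)
## in a perfusion cell of volume V0 (L): standard instrument-software model
cell_concentrations <- function(schedule) {
  V0 <- schedule$cell_volume * 1e-3
  dV <- schedule$injection_volumes * 1e-6
  v <- cumsum(dV)
  list(Mt = schedule$cell_conc * (1 - v / (2 * V0)) / (1 + v / (2 * V0)),
       Xt = schedule$syringe_conc * (v / V0) / (1 + v / (2 * V0)),
       V0 = V0, dV = dV)
}

## Wiseman one-set-of-sites cumulative heat (cal) after each injection
wiseman_Q <- function(n, K_a, dH, schedule) {
  cc <- cell_concentrations(schedule)
  a <- 1 + cc$Xt / (n * cc$Mt) + 1 / (n * K_a * cc$Mt)
  disc <- a^2 - 4 * cc$Xt / (n * cc$Mt)
  if (any(disc < -1e-12))
    stop("internal inconsistency: negative discriminant in binding isotherm")
  (n * cc$Mt * dH * cc$V0 / 2) * (a - sqrt(pmax(disc, 0)))
}

#' Simulate a one-set-of-sites ITC titration
#'
#' Cumulative heat follows the single-class independent-sites (Wiseman)
#' isotherm with standard perfusion-cell dilution corrections; per-injection
#' heats are differences of cumulative heat, optionally with the displacement
#' correction `(dV_i/V0)(Q_i + Q_(i-1))/2` accounting for liquid expelled
#' from the overfilled cell.  Gaussian noise, if requested, is applied to the
#' normalized (per mole of injectant) heats.
#'
#' @param params A [thermo_params()].
#' @param schedule A [titration_schedule()].
#' @param noise_sd Gaussian noise on normalized heats, cal/mol.
#' @param seed Integer seed controlling the noise; required when
#'   `noise_sd > 0`.
#' @param displacement_correction Apply the expelled-volume term.
#' @return An `injection_heats` list: `raw` (ucal per injection),
#'   `normalized` (cal per mol injectant), `molar_ratio` (injectant to cell
#'   species after each injection), `Q` (cumulative, cal).
#' @export
simulate_titration <- function(params, schedule, noise_sd = 0, seed = NULL,
                               displacement_correction = TRUE) {
  stopifnot(inherits(params, "thermo_params"),
            inherits(schedule, "titration_schedule"))
  cc <- cell_concentrations(schedule)
  Q <- wiseman_Q(params$n, params$K_a, params$dH, schedule)
  Qprev <- c(0, Q[-length(Q)])
  dQ <- Q - Qprev
  if (displacement_correction)
    dQ <- dQ + (cc$dV / cc$V0) * (Q + Qprev) / 2
  norm <- dQ / (schedule$syringe_conc * cc$dV)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("a seed is required for noisy simulation")
    rng <- local({set.seed(seed); stats::rnorm(length(norm), 0, noise_sd)})
    norm <- norm + rng
  }
  structure(list(raw = norm * schedule$syringe_conc * cc$dV * 1e6,
                 normalized = norm, molar_ratio = cc$Xt / cc$Mt, Q = Q,
                 noise_sd = noise_sd),
            class = "injection_heats")
}

#' Fit the one-set-of-sites binding model to titration heats
#'
#' Nonlinear least squares (Levenberg-Marquardt, \pkg{minpack.lm}) over
#' (n, log K_a, dH) against the normalized per-injection heats, with the same
#' isotherm and dilution model as [simulate_titration()].  The first
#' injection is excluded by default (conventional for the small pre-injection
#' of a titration protocol).  Asymptotic standard errors come from the
#' Jacobian at the optimum; derived quantities (`K_d`, `dG`, `TdS`) follow
#' the linkage relations, with errors propagated to first order.
#'
#' @param heats An `injection_heats` object (or list with `normalized`).
#' @param schedule The matching [titration_schedule()].
#' @param exclude_first Drop injection 1 from the residuals.
#' @param start Optional named list overriding the default starting values
#'   (`n = 1`, `dH` = first usable heat, `K_a` = 1/cell_conc).
#' @return A list of class `itc_fit`: `params` ([thermo_params()]), `se`
#'   (named standard errors for n, K_a, dH, dG, TdS, K_d), `rss`, `fitted`,
#'   `residuals`, `n_used`, `converged`.
#' @export
fit_one_set_of_sites <- function(heats, schedule, exclude_first = TRUE,
                                 start = NULL) {
  y <- heats$normalized
  use <- seq_along(y)
  if (exclude_first) use <- use[-1]
  if (length(use) < 5) stop("need at least 5 usable injections")
  model_norm <- function(n, K_a, dH) {
    sim <- simulate_titration(thermo_params(n = n, K_a = K_a, dH = dH,
                                            T = schedule$temperature),
                              schedule)
    sim$normalized
  }
  resid_fun <- function(p)
    y[use] - model_norm(p[["n"]], exp(p[["lKa"]]), p[["dH"]])[use]
  start0 <- list(n = 1, K_a = 1 / schedule$cell_conc, dH = y[use][1])
  if (!is.null(start)) start0[names(start)] <- start
  if (abs(start0$dH) < 1e-9) start0$dH <- -1  # avoid a dead start
  ka_factors <- c(1, 10, 0.1, 100, 0.01)
  fit <- NULL
  for (f in ka_factors) {
    p0 <- c(n = start0$n, lKa = log(start0$K_a * f), dH = start0$dH)
    out <- tryCatch(
      minpack.lm::nls.lm(p0, fn = resid_fun,
                         lower = c(n = 1e-3, lKa = log(1e-2), dH = -Inf),
                         upper = c(n = 100, lKa = log(1e18), dH = Inf),
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(out) && out$info %in% 1:4) {fit <- out; break}
  }
  if (is.null(fit))
    stop("one-set-of-sites fit failed to converge after restarts; ",
         "check that the heats describe a binding isotherm")
  p <- fit$par
  prm <- thermo_params(n = p[["n"]], K_a = exp(p[["lKa"]]), dH = p[["dH"]],
                       T = schedule$temperature)
  dof <- length(use) - 3
  sig2 <- sum(fit$fvec^2) / max(dof, 1)
  cv <- tryCatch(sig2 * solve(fit$hessian), error = function(e)
    matrix(NA_real_, 3, 3, dimnames = list(names(p), names(p))))
  se <- sqrt(pmax(diag(cv), 0))
  se_Ka <- prm$K_a * se[["lKa"]]                       # delta method
  se_dG <- .R_cal * schedule$temperature * se[["lKa"]]
  se <- c(n = unname(se[["n"]]), K_a = unname(se_Ka),
          K_d = unname(se_Ka / prm$K_a^2), dH = unname(se[["dH"]]),
          dG = unname(se_dG),
          TdS = unname(sqrt(se[["dH"]]^2 + se_dG^2)))
  structure(list(params = prm, se = se, rss = sum(fit$fvec^2),
                 fitted = y[use] - fit$fvec, residuals = fit$fvec,
                 n_used = length(use), converged = TRUE),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("one-set-of-sites fit on %d injections (rss %.3g)\n",
              x$n_used, x$rss))
  cat(sprintf("  n   = %.4f +/- %.4f\n", p$n, x$se[["n"]]))
  cat(sprintf("  K_d = %.3g +/- %.2g M\n", p$K_d, x$se[["K_d"]]))
  cat(sprintf("  dH  = %.0f +/- %.0f cal/mol\n", p$dH, x$se[["dH"]]))
  cat(sprintf("  dG  = %.0f, TdS = %.0f cal/mol at %.2f K\n", p$dG, p$TdS, p$T))
  invisible(x)
}

#' Write / read a titration as plain-text files
#'
#' The heats go to a two-column TSV (`injection_volume_uL`,
#' `raw_heat_ucal`); the schedule to a YAML side file (`<prefix>.yaml`).
#'
#' @param heats An `injection_heats` object.
#' @param schedule A [titration_schedule()].
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.yaml`.
#' @return `prefix`, invisibly.
#' @export
write_titration <- function(heats, schedule, prefix) {
  utils::write.table(
    data.frame(injection_volume_uL = schedule$injection_volumes,
               raw_heat_ucal = heats$raw),
    paste0(prefix, ".tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(cell_volume_mL = schedule$cell_volume,
                        cell_conc_M = schedule$cell_conc,
                        syringe_conc_M = schedule$syringe_conc,
                        temperature_K = schedule$temperature),
                   paste0(prefix, ".yaml"))
  invisible(prefix)
}

#' @rdname write_titration
#' @export
read_titration <- function(prefix) {
  tab <- utils::read.delim(paste0(prefix, ".tsv"))
  meta <- yaml::read_yaml(paste0(prefix, ".yaml"))
  schedule <- titration_schedule(meta$cell_volume_mL, meta$cell_conc_M,
                                 meta$syringe_conc_M, tab$injection_volume_uL,
                                 meta$temperature_K)
  cc <- cell_concentrations(schedule)
  raw <- tab$raw_heat_ucal
  heats <- structure(list(raw = raw,
                          normalized = raw * 1e-6 / (schedule$syringe_conc * cc$dV),
                          molar_ratio = cc$Xt / cc$Mt, Q = NULL, noise_sd = NA),
                     class = "injection_heats")
  list(heats = heats, schedule = schedule)
}
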