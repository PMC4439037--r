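test_that("linkage relations reproduce the published thermodynamic cycle", {
  p <- thermodynamic_linkage(dH = -2145, TdS = 8855)
  expect_equal(p$dG, -11000)
  expect_equal(p$K_d * 1e9, 8.6, tolerance = 0.01)
  expect_equal(p$TdS, p$dH - p$dG)
  expect_equal(p$K_d, 1 / p$K_a)
  ## K_a = 1 gives dG = 0; and the constructor enforces the same identities
  expect_equal(thermodynamic_linkage(dH = -500, K_a = 1)$dG, 0)
  q <- thermo_params(n = 1, K_d = 9e-9, dH = -2145)
  expect_equal(q$dG, -1.9872 * 298.15 * log(q$K_a), tolerance = 1e-9)
  expect_error(thermodynamic_linkage(dH = 1), "exactly one")
})

test_that("stoichiometric and null limits of the simulator are exact", {
  sch <- epha3_schedule()
  ## K_a so large every injected mole binds: pre-saturation normalized heat
  ## equals dH per mole of injectant (the displacement correction compensates
  ## the dilution of the cell contents)
  tight <- thermo_params(n = 1, K_a = 1e15, dH = -5000)
  sim <- simulate_titration(tight, sch)
  pre <- which(sim$molar_ratio < 0.7)
  expect_equal(sim$normalized[pre], rep(-5000, length(pre)), tolerance = 1e-3)
  ## dH = 0 produces no heat at all
  zero <- thermo_params(n = 1, K_d = 1e-6, dH = 0)
  expect_equal(simulate_titration(zero, sch)$normalized,
               rep(0, length(sch$injection_volumes)))
})

test_that("the closed-form isotherm matches a numerical-equilibrium oracle", {
  sch <- epha3_schedule()
  for (kd in c(1e-6, 9e-9)) {
    p <- thermo_params(n = 1, K_d = kd, dH = -5000)
    sim <- simulate_titration(p, sch)
    oracle <- equilibrium_heats(p, sch)
    expect_equal(sim$normalized, oracle, tolerance = 1e-3,
                 label = paste("Kd =", kd))
  }
})

test_that("cumulative heat telescopes and exothermic pulses point down", {
  sch <- epha3_schedule()
  p <- thermo_params(n = 1, K_d = 9e-9, dH = -2145)
  ## without the displacement term the per-injection heats telescope exactly
  plain <- simulate_titration(p, sch, displacement_correction = FALSE)
  expect_equal(sum(plain$raw) * 1e-6, plain$Q[length(plain$Q)],
               tolerance = 1e-9)
  sim <- simulate_titration(p, sch)
  expect_true(all(sim$raw < 0))
  expect_true(all(diff(sim$molar_ratio) > 0))
  ## sigmoid shape at high c: magnitudes non-increasing past the equivalence
  post <- which(sim$molar_ratio > 1.05)
  expect_true(all(diff(abs(sim$normalized[post])) < 1e-9))
})

test_that("noise-free simulate/fit round-trips across the c range", {
  sch <- epha3_schedule()
  for (cv in c(1, 10, 100, 1000)) {
    truth <- thermo_params(n = 1.1, K_a = cv / (1.1 * sch$cell_conc),
                           dH = -4000)
    fit <- fit_one_set_of_sites(simulate_titration(truth, sch), sch)
    expect_lt(abs(fit$params$n - truth$n) / truth$n, 1e-4)
    expect_lt(abs(fit$params$K_a - truth$K_a) / truth$K_a, 1e-4)
    expect_lt(abs(fit$params$dH - truth$dH) / abs(truth$dH), 1e-4)
  }
})

test_that("noisy paper-protocol titrations recover the thermodynamics", {
  sch <- epha3_schedule()
  truth <- thermo_params(n = 1, K_d = 9e-9, dH = -2145)
  fits <- lapply(1:5, function(s)
    fit_one_set_of_sites(
      simulate_titration(truth, sch, noise_sd = 0.01 * abs(truth$dH),
                         seed = 100 + s), sch))
  for (f in fits) {
    expect_lt(abs(f$params$dH - truth$dH) / abs(truth$dH), 0.05)
    expect_lt(abs(f$params$n - 1), 0.02)
    ratio <- f$params$K_d / truth$K_d
    expect_true(ratio < 3 && ratio > 1 / 3)
    expect_true(all(is.finite(f$se)))
  }
})

test_that("flat traces yield a near-zero enthalpy with huge K uncertainty", {
  sch <- epha3_schedule()
  flat <- structure(list(normalized = rep(0, 20)), class = "injection_heats")
  res <- tryCatch(fit_one_set_of_sites(flat, sch), error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "fit|converge")
  } else {
    expect_lt(abs(res$params$dH), 1)
    expect_true(is.na(res$se[["K_a"]]) ||
                  res$se[["K_a"]] / res$params$K_a > 10 ||
                  res$se[["K_a"]] == 0)
  }
})

test_that("titrations round-trip through the TSV + YAML files", {
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "titration")
  truth <- thermo_params(n = 1, K_d = 9e-9, dH = -2145)
  heats <- make_itc_curve(prefix, params = truth, noise_sd = 10, seed = 42)
  back <- read_titration(prefix)
  expect_equal(back$heats$normalized, heats$normalized, tolerance = 1e-4)
  expect_equal(back$schedule$cell_conc, 10e-6)
  fit <- fit_one_set_of_sites(back$heats, back$schedule)
  expect_lt(abs(fit$params$dH - truth$dH) / abs(truth$dH), 0.05)
  ## same seed, byte-identical file
  prefix2 <- file.path(dir, "titration2")
  make_itc_curve(prefix2, params = truth, noise_sd = 10, seed = 42)
  expect_identical(readLines(paste0(prefix, ".tsv")),
                   readLines(paste0(prefix2, ".tsv")))
})
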