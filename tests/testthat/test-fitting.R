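test_that("noiseless data round-trips through every family", {
  cases <- list(
    linear = c(a = 100, g0 = 320),  # stays positive over the psi grid
    exponential = c(g0 = 0, a = 300, b = -log(2)),
    sigmoidal = c(a = 400, b = 0.4, x0 = -1.5),
    logistic = c(a = 350, b = 3, x0 = -1.2))
  for (fam in names(cases)) {
    d <- make_noiseless_dataset(fam, cases[[fam]], psi_grid(40, -3))
    f <- fit_family(d, fam)
    expect_true(f$converged)
    expect_lt(f$rss, 1e-8)
    expect_equal(unname(f$family$parameters[names(cases[[fam]])]),
                 unname(cases[[fam]]), tolerance = 1e-5)
  }
})

test_that("constant data yields a flat linear fit", {
  d <- species_response("sp", psi_grid(20), rep(150, 20), gmin = 0)
  f <- fit_family(d, "linear")
  expect_equal(unname(f$family$parameters["a"]), 0, tolerance = 1e-10)
  expect_lt(f$rss, 1e-16)
})

test_that("AICc uses the small-sample Gaussian ML form", {
  # hand evaluation: n = 20, k = 3, rss = 20 -> 20*ln(1) + 6 + 24/16 = 7.5
  expect_equal(stomsafe:::.aicc(20, 20, 3), 7.5)
  expect_equal(stomsafe:::.aicc(exp(1) * 10, 10, 2), 10 + 4 + 12 / 7)
  # correction blows up as n -> k + 1
  expect_equal(stomsafe:::.aicc(1, 4, 3), Inf)
})

test_that("fit preconditions are enforced", {
  d <- species_response("sp", c(-1, -1, -1, -1, -1, -1), rep(100, 6), gmin = 0)
  expect_error(fit_family(d, "linear"), "identical")
  d2 <- species_response("sp", c(-1, -2, -3), c(100, 80, 60), gmin = 0)
  expect_error(fit_family(d2, "sigmoidal"), "at least 5")
})

test_that("model selection applies the AICc rule, parsimony, and tie order", {
  stub <- function(fam, k, aicc) {
    structure(list(family_name = fam, k = k, rss = 1, aicc = aicc,
                   converged = TRUE), class = "fitted_response")
  }
  # clear winner (delta > 2)
  sel <- select_model(list(stub("linear", 3, 100), stub("exponential", 4, 90)))
  expect_equal(sel$family_name, "exponential")
  # delta < 2: fewer parameters wins
  sel <- select_model(list(stub("sigmoidal", 4, 90.0), stub("linear", 3, 90.5)))
  expect_equal(sel$family_name, "linear")
  # equal k, delta < 2: fixed family order
  sel <- select_model(list(stub("logistic", 4, 89.9), stub("sigmoidal", 4, 90.2)))
  expect_equal(sel$family_name, "sigmoidal")
  # non-converged fits are ignored; all failing is an error
  bad <- structure(list(family_name = "linear", k = 3, rss = Inf, aicc = Inf,
                        converged = FALSE), class = "fitted_response")
  expect_equal(select_model(list(bad, stub("logistic", 4, 50)))$family_name,
               "logistic")
  expect_error(select_model(list(bad)), "no converged fit")
})

test_that("derived parameters match closed forms and a bisection oracle", {
  # logistic identity: gmax = a, psi_gs50 = x0 exactly
  d <- make_noiseless_dataset("logistic", c(a = 350, b = 3, x0 = -1.2),
                              psi_grid(40, -3))
  f <- derive_parameters(fit_family(d, "logistic"))
  expect_equal(f$gmax, 350, tolerance = 1e-6)
  expect_equal(f$psi_gs50, f$family$parameters[["x0"]])

  # linear: psi_gs50 = -g0 / (2a)
  d <- make_noiseless_dataset("linear", c(a = 100, g0 = 300), psi_grid(40, -3))
  f <- derive_parameters(fit_family(d, "linear"))
  expect_equal(f$psi_gs50, -1.5, tolerance = 1e-6)
  expect_equal(f$psi_gs20, -0.6, tolerance = 1e-6)
  expect_equal(f$psi_gs80, -2.4, tolerance = 1e-6)

  # sigmoidal: numeric root against an independent bisection oracle
  pars <- c(a = 400, b = 0.4, x0 = -1.5)
  d <- make_noiseless_dataset("sigmoidal", pars, psi_grid(60, -4))
  f <- derive_parameters(fit_family(d, "sigmoidal"))
  expect_equal(f$gmax, 400 / (1 + exp(-1.5 / 0.4)), tolerance = 1e-6)
  oracle50 <- bisect_oracle(
    function(p) evaluate_family("sigmoidal", p, pars) - 0.5 * f$gmax, -4, 0)
  expect_equal(f$psi_gs50, oracle50, tolerance = 1e-5)
  expect_equal(f$psi_gs50, -1.52, tolerance = 1e-2)

  # ordering invariant
  expect_true(f$psi_gs20 >= f$psi_gs50 && f$psi_gs50 >= f$psi_gs80)
  expect_true(all(c(f$psi_gs20, f$psi_gs50, f$psi_gs80) <= 0))
})

test_that("thresholds the curve never reaches are flagged, not invented", {
  # a nearly flat line never declines 80% within the bracket
  d <- make_noiseless_dataset("linear", c(a = 5, g0 = 300), psi_grid(30, -2))
  f <- derive_parameters(fit_family(d, "linear"))
  expect_true(is.na(f$psi_gs80))
  expect_true(f$derived_warning)
})

test_that("derived thresholds are invariant to conductance-unit rescaling", {
  set.seed(42)
  psi <- psi_grid(40, -3)
  gs <- evaluate_family("sigmoidal", psi, c(a = 400, b = 0.4, x0 = -1.5)) +
    rnorm(40, 0, 8)
  d_mmol <- species_response("sp", psi, pmax(gs, 0), gmin = 0)
  d_mol <- species_response("sp", psi, pmax(gs, 0) / 1000, gmin = 0)
  f1 <- derive_parameters(fit_family(d_mmol, "sigmoidal"))
  f2 <- derive_parameters(fit_family(d_mol, "sigmoidal"))
  expect_equal(f1$gmax / f2$gmax, 1000, tolerance = 1e-3)
  expect_equal(f1$psi_gs50, f2$psi_gs50, tolerance = 1e-4)
  expect_equal(f1$psi_gs80, f2$psi_gs80, tolerance = 1e-4)
})

test_that("significance test behaves at both extremes", {
  # strong monotone decline, small noise: overwhelming evidence
  set.seed(7)
  psi <- psi_grid(40, -3)
  gs <- pmax(evaluate_family("sigmoidal", psi,
                             c(a = 400, b = 0.3, x0 = -1.5)) + rnorm(40, 0, 5),
             0)
  d <- species_response("sp", psi, gs, gmin = 0)
  res <- fit_response(d, mode = "all")
  expect_lt(res$fit$fit_pvalue, 1e-6)

  # minimum-size dataset: finite p, no crash
  d6 <- species_response("sp", psi_grid(6, -2),
                         c(300, 280, 240, 180, 120, 60), gmin = 0)
  res6 <- fit_response(d6, mode = "all", families = "linear")
  expect_true(is.finite(res6$fit$fit_pvalue))
})

test_that("type-I error of the LRT is near nominal on flat data", {
  # pure-noise flat truth, linear family (df = 1): rejection rate ~ alpha
  set.seed(123)
  n_rep <- 200
  p <- replicate(n_rep, {
    d <- species_response("sp", psi_grid(30, -3),
                          pmax(rnorm(30, 150, 10), 0), gmin = 0)
    f <- fit_significance(d, fit_family(d, "linear"))
    f$fit_pvalue
  })
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.12)
})

test_that("refined fitting recovers truth across a mixed-family sample", {
  cfg <- synth_config(n_species = 40, points_per_species = 40, seed = 21)
  b <- generate_bundle(cfg)
  res <- fit_all_species(b$response_datasets, mode = "refined")
  tb <- merge(res$fits_table, b$truth, by = "species_id",
              suffixes = c("", ".true"))
  ok <- abs(tb$gmax / tb$gmax.true - 1) < 0.05 &
    abs(tb$psi_gs50 - tb$psi_gs50.true) < 0.1
  expect_gte(mean(ok), 0.85)
})
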