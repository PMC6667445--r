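test_that("vulnerability curve hits its anchors", {
  vc <- vulnerability_curve(10, -1, 3)
  expect_equal(conductance_at(vc, -1), 5)
  expect_equal(conductance_at(vc, 0), 10 / (1 + exp(3)))
  expect_equal(conductance_at(vc, -100), 10, tolerance = 1e-10)
  expect_error(vulnerability_curve(-1, -1), "Kmax")
})

test_that("Kirchhoff closed form equals adaptive quadrature", {
  set.seed(11)
  for (i in 1:50) {
    vc <- vulnerability_curve(runif(1, 1, 50), runif(1, -4, -0.3),
                              runif(1, 0.5, 8))
    lo <- runif(1, -6, -0.1); hi <- runif(1, lo, 0)
    closed <- kirchhoff_capacity(vc, lo, hi)
    quad <- stats::integrate(function(p) conductance_at(vc, p), lo, hi,
                             rel.tol = 1e-12, abs.tol = 1e-12)$value
    expect_equal(closed, quad, tolerance = 1e-8)
  }
})

test_that("Kirchhoff capacity limiting cases", {
  vc <- vulnerability_curve(10, -1, 3)
  # bounds straddling psi50 symmetrically: logistic symmetry gives Kmax * hw
  expect_equal(kirchhoff_capacity(vc, -2, 0), 10)
  expect_equal(kirchhoff_capacity(vc, -1.5, -1.5), 0)
  # constant-K limit far below psi50 with steep alpha
  vc2 <- vulnerability_curve(10, -1, 50)
  expect_equal(kirchhoff_capacity(vc2, -8, -6), 20, tolerance = 1e-8)
  # overflow safety at extreme arguments
  expect_true(is.finite(kirchhoff_capacity(vc, -500, 0)))
  expect_error(kirchhoff_capacity(vc, 0, -1), "psi_lo")
  expect_equal(kirchhoff_capacity(vc, 0, -1, allow_reversed = TRUE),
               -kirchhoff_capacity(vc, -1, 0))
})

test_that("stomatal closure anchors and halving behavior", {
  sc <- stomatal_closure(300, -1)
  expect_equal(stomatal_conductance_at(sc, 0), 300)
  expect_equal(stomatal_conductance_at(sc, -1), 150)
  expect_equal(stomatal_conductance_at(sc, -2), 75)
  expect_error(stomatal_closure(300, 0.5), "psi_gs50")
})

test_that("photosynthesis closed form matches spot values and the oracle", {
  expect_equal(photosynthesis(0), 0)
  expect_equal(photosynthesis(200), 8.614, tolerance = 1e-3)
  # gs -> infinity limit: ci -> ca
  p <- photo_params()
  lim <- p$Vcmax * (p$ca - p$gamma_star) / (p$ca + p$Km) - p$R
  expect_equal(photosynthesis(1e9), lim, tolerance = 1e-4)
  expect_equal(lim, 10.027, tolerance = 1e-3)
  # closed form == two-equation numeric solution over random draws
  set.seed(3)
  for (i in 1:100) {
    pp <- photo_params(Vcmax = runif(1, 10, 120), Km = runif(1, 200, 900),
                       gamma_star = runif(1, 20, 80), R = runif(1, 0.2, 3),
                       ca = runif(1, 300, 900))
    gs <- runif(1, 1, 1500)
    expect_equal(photosynthesis(gs, pp), photosynthesis_oracle(gs, pp),
                 tolerance = 1e-9)
  }
  # A(gs) strictly increasing and concave under the default constants
  gs <- seq(1, 2000, by = 1)
  A <- photosynthesis(gs)
  expect_true(all(diff(A) > 0))
  expect_true(all(diff(diff(A)) < 1e-12))
  expect_error(photosynthesis(-1), "gs")
})

test_that("steady state: no-flux fixed point at vpd = 0", {
  s <- solve_steady_state(plant_system(), environment_state(-0.7, 0))
  expect_equal(c(s$psi_leaf, s$psi_stem, s$psi_root), rep(-0.7, 3))
  expect_equal(s$E, 0)
  expect_true(s$converged)
})

test_that("constant-K constant-gs regime matches the series closed form", {
  plant <- plant_system(
    leaf = vulnerability_curve(10, 100, 3),
    stem = vulnerability_curve(20, 100, 3),
    root = vulnerability_curve(10, 100, 3),
    stomata = stomatal_closure(200, -1e9))
  s <- solve_steady_state(plant, environment_state(0, 0.01))
  # E = 2; psi = psi_soil - E * cumulative resistance
  expect_true(s$converged)
  expect_equal(s$E, 2, tolerance = 1e-7)
  expect_equal(s$psi_root, -0.2, tolerance = 1e-9)
  expect_equal(s$psi_stem, -0.3, tolerance = 1e-9)
  expect_equal(s$psi_leaf, -0.5, tolerance = 1e-9)
})

test_that("steady-state solutions satisfy flux balance and ordering", {
  for (ps in c(0, -1.2)) {
    for (gm in c(100, 400)) {
      for (p50 in c(-0.4, -2.8)) {
        plant <- plant_system(stomata = stomatal_closure(gm, p50))
        s <- solve_steady_state(plant, environment_state(ps, 0.01))
        expect_true(s$converged)
        expect_lt(max(abs(s$residuals)), 1e-8)
        expect_true(ps >= s$psi_root && s$psi_root >= s$psi_stem &&
                      s$psi_stem >= s$psi_leaf)
        # series continuity: each segment carries E
        expect_equal(
          kirchhoff_capacity(plant$root, s$psi_root, ps), s$E,
          tolerance = 1e-6)
        expect_equal(
          kirchhoff_capacity(plant$stem, s$psi_stem, s$psi_root), s$E,
          tolerance = 1e-6)
      }
    }
  }
})

test_that("Newton and nested-bisection solvers agree", {
  plant <- plant_system(stomata = stomatal_closure(350, -1.6))
  env <- environment_state(-1.2, 0.01)
  s1 <- stomsafe:::.newton_solve(plant, env, 1e-10)
  s2 <- stomsafe:::.nested_solve(plant, env, 1e-10)
  expect_true(s1$converged && s2$converged)
  expect_equal(s1$psi_leaf, s2$psi_leaf, tolerance = 1e-7)
  expect_equal(s1$A, s2$A, tolerance = 1e-7)
})

test_that("a single-cell grid reproduces solve_steady_state exactly", {
  plant <- plant_system()
  env <- environment_state(-1.2, 0.01)
  g <- run_grid(plant, list(env), gmax_grid = 250, psi_gs50_grid = -1.4)
  plant$stomata <- stomatal_closure(250, -1.4)
  s <- solve_steady_state(plant, env)
  expect_equal(g$A, s$A)
  expect_equal(g$psi_leaf, s$psi_leaf)
  expect_equal(g$gs, s$gs)
  expect_equal(nrow(g), 1)
})

test_that("grid output is tidy and monotone in the expected directions", {
  g <- run_grid(gmax_grid = seq(100, 400, by = 100),
                psi_gs50_grid = seq(-3, -0.5, by = 0.5))
  expect_true(all(g$converged))
  # A non-decreasing in gmax along rows (both soil conditions)
  for (ps in unique(g$psi_soil)) {
    for (p50 in unique(g$psi_gs50)) {
      sub <- g[g$psi_soil == ps & g$psi_gs50 == p50, ]
      sub <- sub[order(sub$gmax), ]
      expect_true(all(diff(sub$A) >= -1e-9))
      if (ps < 0) expect_true(all(diff(sub$psi_stem) <= 1e-9))
    }
    # A non-increasing as psi_gs50 rises toward 0 at fixed gmax
    for (gm in unique(g$gmax)) {
      sub <- g[g$psi_soil == ps & g$gmax == gm, ]
      sub <- sub[order(sub$psi_gs50), ]
      expect_true(all(diff(sub$A) <= 1e-9))
    }
  }
})
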