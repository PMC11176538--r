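test_that("immune kill intensity has its closed-form values", {
  expect_equal(immune_intensity(mmc_params(p2 = 5.5e-6)), 0.0622368,
               tolerance = 1e-6)
  expect_equal(immune_intensity(mmc_params(p2 = 3.7e-6)), 0.0418684,
               tolerance = 1e-6)
  # vanishes as effector mortality dominates
  expect_lt(immune_intensity(mmc_params(mu2 = 1e12)), 1e-12)
})

test_that("chemo kill intensity saturates at p1 and vanishes without drug", {
  expect_identical(chemo_intensity(mmc_params(m = 0)), 0)
  expect_equal(chemo_intensity(mmc_params(p1 = 0.2, m = 6.561)),
               6.21436e-4, tolerance = 1e-5)
  expect_equal(chemo_intensity(mmc_params(m = 1e12)), mmc_params()$p1,
               tolerance = 1e-6)
  set.seed(3)
  for (m in 10^runif(20, -3, 6))
    expect_lt(chemo_intensity(mmc_params(m = m)), mmc_params()$p1)
})

test_that("disease-free equilibria carry the regime's closed form and label", {
  p0 <- mmc_params(m = 0)
  eq <- disease_free_equilibria(p0)[[1]]
  expect_identical(eq$label, "homeostasis_EB1")
  expect_equal(unname(eq$state), c(0, 0, p0$d0 / p0$mu2))
  p <- mmc_params()
  eq2 <- disease_free_equilibria(p)[[1]]
  expect_identical(eq2$label, "tumor_free_EB2")
  expect_equal(unname(eq2$state), c(p$m / p$mu1, 0, p$d0 / p$mu2))
  # rhs residual at both points is numerically zero
  expect_lt(rel_residual(eq$state, p0), 1e-9)
  expect_lt(rel_residual(eq2$state, p), 1e-9)
})

test_that("stability flags equal the r-threshold criteria, strict at the boundary", {
  set.seed(5)
  for (i in 1:30) {
    p <- random_params()
    if (i %% 2 == 0) p$m <- 0
    eq <- disease_free_equilibria(p)[[1]]
    bound <- immune_intensity(p) +
      if (p$m > 0) chemo_intensity(p) else 0
    expect_identical(eq$stable, p$r < bound)
  }
  # r exactly at the bound: one zero eigenvalue, reported non-stable
  p <- mmc_params()
  p_marg <- mmc_params(r = immune_intensity(p) + chemo_intensity(p))
  eqm <- disease_free_equilibria(p_marg)[[1]]
  expect_false(eqm$stable)
  expect_true(eqm$marginal)
  expect_true(any(abs(Re(eqm$eigenvalues)) < 1e-12))
})

test_that("closed-form eigenvalues match the numeric Jacobian to 1e-8", {
  set.seed(9)
  for (i in 1:50) {
    p <- random_params()
    if (i %% 2 == 0) p$m <- 0
    eq <- disease_free_equilibria(p)[[1]]
    num <- sort(Re(eigen(mmc_jacobian(eq$state, p),
                         only.values = TRUE)$values))
    expect_equal(sort(Re(eq$eigenvalues)), num, tolerance = 1e-8)
  }
})

test_that("cancer equilibria are genuine fixed points matching a grid scan", {
  # scalar nullcline condition whose sign changes the roots must match
  scan_roots <- function(p, n_grid = 1e6) {
    Mst <- p$m / p$mu1
    c1 <- p$p1 * Mst / (Mst + p$a)
    g <- function(T) {
      Est <- (p$d0 + p$gamma * c1 * T) / (p$p3 * T + p$mu2)
      p$r * (1 - T / p$k) - c1 - p$p2 * Est
    }
    Ts <- seq(p$k / n_grid, p$k, length.out = n_grid)
    v <- g(Ts)
    idx <- which(v[-1] * v[-length(v)] <= 0 & v[-1] != v[-length(v)])
    vapply(idx, function(i)
      uniroot(g, c(Ts[i], Ts[i + 1]), tol = 1e-6 * p$k)$root, numeric(1))
  }
  cases <- list(mmc_params(),                     # two interior roots
                mmc_params(r = 0.045, p2 = 3.7e-6),  # unstable regime
                mmc_params(m = 0),                # untreated
                mmc_params(r = 0.0101, p2 = 5.5e-6, m = 60))
  for (p in cases) {
    eqs <- find_cancer_equilibria(p)
    expect_lte(length(eqs), 2)       # quadratic after clearing denominators
    roots <- sort(vapply(eqs, function(e) e$state[["T"]], numeric(1)))
    expected <- sort(scan_roots(p, n_grid = 1e5))
    expect_equal(length(roots), length(expected))
    if (length(roots))
      expect_equal(roots, expected, tolerance = 1e-4)
    for (e in eqs) {
      expect_identical(e$label, "cancer_numeric")
      expect_lt(rel_residual(e$state, p), 1e-9)
      expect_gt(e$state[["E"]], 0)
    }
  }
})

test_that("stability verdicts concord with perturbed simulations", {
  set.seed(21)
  n_ok <- 0L
  for (i in 1:50) {
    p <- random_params()
    eq <- disease_free_equilibria(p)[[1]]
    # the tumor eigendirection decays/grows at rate |r - bound|; give the
    # run enough time to resolve it (draws can land near the boundary)
    gap <- abs(Re(eq$eigenvalues[2]))
    horizon <- max(400, ceiling(7 / max(gap, 1e-3)))
    sc <- mmc_scenario(T0 = eq$state[["T"]] + 1e3, M0 = eq$state[["M"]],
                       E0 = eq$state[["E"]], horizon = horizon)
    tr <- integrate_model(p, sc, times = c(0, horizon))
    Tend <- tail(tr$T, 1)
    if (eq$stable) {
      # returns to within 1% of the perturbation of the tumor-free level
      expect_lt(Tend, 0.01 * 1e3)
    } else {
      expect_gt(Tend, 1e3)   # diverges from the equilibrium
    }
    n_ok <- n_ok + 1L
  }
  expect_identical(n_ok, 50L)
})

test_that("the stability report combines intensities, criterion and roots", {
  rep <- stability_report(mmc_params())
  expect_named(rep, c("equilibria", "I1", "I2", "criterion"))
  expect_identical(names(rep$criterion), "r_below_I1_plus_I2")
  labs <- vapply(rep$equilibria, `[[`, character(1), "label")
  expect_identical(labs[1], "tumor_free_EB2")
  rep0 <- stability_report(mmc_params(m = 0))
  expect_identical(names(rep0$criterion), "r_below_I1")
  expect_identical(rep0$I2, 0)
})
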