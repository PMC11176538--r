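test_that("a trajectory started at the tumor-free equilibrium stays there", {
  p <- mmc_params()
  sc <- mmc_scenario(T0 = 0, M0 = p$m / p$mu1, horizon = 100)
  tr <- integrate_model(p, sc)
  expect_equal(tr$M, rep(p$m / p$mu1, nrow(tr)), tolerance = 1e-7)
  expect_equal(tr$T, rep(0, nrow(tr)), tolerance = 1e-9)
  expect_equal(tr$E, rep(p$d0 / p$mu2, nrow(tr)), tolerance = 1e-7)
  expect_identical(tr$t[1], 0)
  expect_equal(unlist(tr[1, c("M", "T", "E")]),
               c(M = p$m / p$mu1, T = 0, E = p$d0 / p$mu2))
})

test_that("numerical drug trajectory matches the linear closed form", {
  p <- mmc_params()
  for (M0 in c(0, 50)) {
    tr <- integrate_model(p, mmc_scenario(T0 = 1e6, M0 = M0, horizon = 30),
                          times = seq(0, 30, by = 0.25))
    expect_lt(max(abs(tr$M - drug_closed_form(tr$t, M0, p)) /
                    pmax(abs(drug_closed_form(tr$t, M0, p)), 1e-12)),
              1e-6)
  }
})

test_that("residual drug converges to m/mu1 (~0.311 uM at protocol dosing)", {
  p <- mmc_params()
  tr <- integrate_model(p, mmc_scenario(T0 = 0, M0 = 0, horizon = 5))
  expect_equal(tail(tr$M, 1), p$m / p$mu1, tolerance = 1e-6)
  expect_equal(p$m / p$mu1, 0.311, tolerance = 3e-3)
})

test_that("compiled and pure-R right-hand sides give the same trajectory", {
  p <- mmc_params()
  sc <- mmc_scenario(T0 = 1e7, horizon = 50)
  a <- integrate_model(p, sc)
  b <- integrate_model(p, sc, compiled = FALSE)
  expect_equal(a$T, b$T, tolerance = 1e-7)
  expect_equal(a$E, b$E, tolerance = 1e-7)
})

test_that("outcome classification is strict at the cure threshold", {
  p <- mmc_params()
  tr <- integrate_model(p, mmc_scenario(T0 = 1e6, horizon = 10))
  Tend <- tail(tr$T, 1)
  expect_identical(classify_outcome(tr, cure_threshold = Tend + 1), "cure")
  expect_identical(classify_outcome(tr, cure_threshold = Tend),
                   "persistence")  # tie -> persistence
  expect_identical(classify_outcome(tr, cure_threshold = 0), "persistence")
  short <- tr[tr$t < 5, ]
  attributes(short) <- c(attributes(short),
                         attributes(tr)[c("params", "scenario", "solver")])
  class(short) <- class(tr)
  expect_error(classify_outcome(short), "incomplete")
})

test_that("final tumor burden is non-increasing in the instillation rate", {
  sc <- mmc_scenario(T0 = 2e7, horizon = 200)
  finals <- vapply(c(0, 2, 6.561, 20, 60), function(m) {
    tail(integrate_model(mmc_params(m = m), sc)$T, 1)
  }, numeric(1))
  expect_true(all(diff(finals) <= 1e-6 * finals[-length(finals)]))
})

test_that("bisection brackets the basin boundary and errors off-bracket", {
  p <- mmc_params()
  th <- find_initial_size_threshold(p, c(1e6, 1e8), rel_tol = 0.01)
  br <- attr(th, "bracket")
  expect_gt(as.numeric(th), 1e6)
  expect_lt(as.numeric(th), 1e8)
  expect_true(br[1] <= th && th <= br[2])
  expect_lt((br[2] - br[1]) / br[1], 0.011)
  # outcome flips exactly once across the bracket
  sc <- mmc_scenario(T0 = 1, horizon = 2000)
  grid <- 10^seq(log10(as.numeric(th)) - 0.5, log10(as.numeric(th)) + 0.5,
                 length.out = 9)
  outs <- vapply(grid, function(T0) {
    sci <- sc; sci$T0 <- T0
    classify_outcome(integrate_model(p, sci))
  }, character(1))
  expect_identical(sum(outs[-1] != outs[-length(outs)]), 1L)
  expect_identical(outs[1], "cure")
  expect_identical(outs[length(outs)], "persistence")
  expect_error(find_initial_size_threshold(p, c(1e2, 1e3)),
               "no threshold in bracket")
})

test_that("the treated basin strictly contains the untreated one", {
  th_tr <- find_initial_size_threshold(mmc_params(), c(1e6, 1e8))
  th_un <- find_initial_size_threshold(mmc_params(m = 0), c(1e5, 1e8))
  expect_gt(as.numeric(th_tr), as.numeric(th_un))
})

test_that("trajectories stay nonnegative within solver tolerance", {
  set.seed(7)
  atol <- 1e-6
  for (i in 1:25) {
    p <- random_params()
    sc <- mmc_scenario(T0 = 10^runif(1, 3, 8), M0 = runif(1, 0, 5),
                       E0 = 10^runif(1, 2, 5), horizon = 60)
    tr <- integrate_model(p, sc, atol = atol)
    expect_gt(min(tr$M, tr$T, tr$E), -10 * atol)
  }
})

test_that("effector dynamics follow the treatment outcome", {
  p <- mmc_params()
  # cure case: effectors at the horizon exceed the day-1 level
  cure <- integrate_model(p, mmc_scenario(T0 = 5.3e6, horizon = 400))
  expect_identical(classify_outcome(cure, cure_threshold = 1e4), "cure")
  expect_gt(tail(cure$E, 1), cure$E[cure$t == 1])
  # persistence: the treated run keeps more effectors than the untreated
  big <- 6.62e7
  tr_on  <- integrate_model(p, mmc_scenario(T0 = big, horizon = 400))
  tr_off <- integrate_model(p, mmc_scenario(T0 = big, treated = FALSE,
                                            horizon = 400))
  expect_identical(classify_outcome(tr_on), "persistence")
  expect_true(all(tr_on$E[-1] > tr_off$E[-1]))
})

test_that("trajectory CSV export uses the documented header", {
  f <- withr::local_tempfile(fileext = ".csv")
  tr <- integrate_model(mmc_params(), mmc_scenario(T0 = 1e6, horizon = 5))
  write_trajectory(tr, f)
  got <- utils::read.csv(f)
  expect_identical(names(got), c("t", "M", "T", "E"))
  expect_equal(got$T, tr$T)
})
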