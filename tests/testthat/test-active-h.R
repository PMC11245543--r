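test_that("mixture endpoints recover p = 0 and p = 1 exactly", {
  f0 <- active_h_labeling(c(0.8, 0.2), c(0.8, 0.2, 0))
  expect_equal(f0$p, 0)
  expect_equal(f0$residual_norm, 0)
  expect_false(f0$clipped)
  f1 <- active_h_labeling(c(0.8, 0.2), c(0, 0.8, 0.2))
  expect_equal(f1$p, 1)
  expect_equal(f1$residual_norm, 0)
})

test_that("the worked mixture recovers p = 0.3 with zero residual", {
  fit <- active_h_labeling(c(0.8, 0.2), c(0.56, 0.38, 0.06))
  expect_equal(unname(coef(fit)), 0.3, tolerance = 1e-12)
  expect_equal(fit$residual_norm, 0, tolerance = 1e-12)
  expect_equal(fit$p, oracle_grid_p(c(0.8, 0.2), c(0.56, 0.38, 0.06), 1e-4),
               tolerance = 1e-4)
  # fitted() reproduces the observed NADPH MID
  expect_equal(fitted(fit), c(0.56, 0.38, 0.06), tolerance = 1e-12)
  expect_equal(residuals(fit), numeric(3), tolerance = 1e-12)
})

test_that("closed form equals brute-force grid search on random instances", {
  set.seed(41)
  for (i in 1:10) {
    a <- random_mid(sample(2:5, 1))
    b <- random_mid(length(a) + 1L)  # arbitrary NADPH MID, generally off-model
    fit <- active_h_labeling(a, b)
    # agreement to the grid resolution (absolute, step/2 = 5e-6)
    expect_lt(abs(fit$p - oracle_grid_p(a, b)), 1e-5)
  }
})

test_that("noise-free parameter recovery is exact on a p grid", {
  set.seed(42)
  for (p in seq(0, 0.6, by = 0.1)) {
    a <- random_mid(3)
    b <- (1 - p) * c(a, 0) + p * c(0, a)
    expect_equal(active_h_labeling(a, b)$p, p, tolerance = 1e-9)
  }
})

test_that("p is invariant to trailing zeros on either MID", {
  a <- c(0.8, 0.2)
  b <- c(0.56, 0.38, 0.06)
  base <- active_h_labeling(a, b)$p
  expect_equal(active_h_labeling(c(a, 0, 0), b)$p, base, tolerance = 1e-12)
  expect_equal(active_h_labeling(a, c(b, 0, 0))$p, base, tolerance = 1e-12)
  expect_equal(active_h_labeling(c(a, 0), c(b, 0))$p, base, tolerance = 1e-12)
})

test_that("fitted MID sums to one whenever inputs do", {
  set.seed(43)
  for (i in 1:10) {
    a <- random_mid(sample(2:4, 1))
    b <- random_mid(length(a) + 1L)
    expect_equal(sum(fitted(active_h_labeling(a, b))), 1, tolerance = 1e-9)
  }
})

test_that("out-of-range optima are clipped and flagged, never silent", {
  a <- c(0.8, 0.2)
  # NADPH even less labeled than NADP+: unconstrained optimum below 0
  fit <- active_h_labeling(a, c(0.85, 0.15, 0))
  expect_true(fit$clipped)
  expect_equal(fit$p, 0)
  expect_lt(fit$p_unconstrained, 0)
  expect_error(active_h_labeling(c(0.8, NA), c(0.5, 0.5, 0)), "finite")
})

test_that("cohort summaries report per-group mean and SEM of p", {
  a <- c(0.85, 0.13, 0.02)
  mk <- function(p) (1 - p) * c(a, 0) + p * c(0, a)
  co <- active_h_cohort(
    nadp_mids = rep(list(a), 4),
    nadph_mids = list(mk(0.05), mk(0.05), mk(0.15), mk(0.15)),
    group = c("WT", "WT", "KO", "KO"))
  expect_equal(co$summary$mean_p[co$summary$group == "WT"], 0.05, tolerance = 1e-9)
  expect_equal(co$summary$mean_p[co$summary$group == "KO"], 0.15, tolerance = 1e-9)
  expect_equal(co$summary$sem_p, c(0, 0), tolerance = 1e-9)  # identical pairs
  # single-sample group: SEM undefined, reported missing
  co1 <- active_h_cohort(list(a, a), list(mk(0.1), mk(0.2)), group = c("A", "B"))
  expect_true(all(is.na(co1$summary$sem_p)))
  expect_error(active_h_cohort(list(), list(), character(0)), "at least one")
  expect_error(active_h_cohort(list(a), list(mk(0.1)), group = ""), "empty group")
})

test_that("stochastic recovery stays unbiased under 2% multiplicative noise", {
  # module-level spot check at two grid points (the full grid runs in the
  # acceptance suite)
  set.seed(44)
  a <- c(0.85, 0.13, 0.02)
  sdlog <- sqrt(log1p(0.02^2))
  for (p in c(0, 0.3)) {
    b_true <- (1 - p) * c(a, 0) + p * c(0, a)
    est <- replicate(200, {
      b <- b_true * rlnorm(length(b_true), -sdlog^2 / 2, sdlog)
      active_h_labeling(a, b / sum(b))$p
    })
    expect_lt(abs(mean(est) - p), 0.01)
    expect_lt(sqrt(mean((est - p)^2)), 0.03)
  }
})
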