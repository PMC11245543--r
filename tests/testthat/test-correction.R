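zero_abundance_isotopes <- function() {
  # a test table with no natural heavy isotopes at all
  data.frame(element = c("C", "H", "N", "O", "P", "S"),
             mass_shift = 0L, abundance = 1, stringsAsFactors = FALSE)
}

test_that("correction matrix reduces to identity with pure tracer and no natural abundance", {
  m <- build_correction_matrix("C2", tracer_spec("C", 2, purity = 1),
                               max_shift = 2, mode = "nominal",
                               isotopes = zero_abundance_isotopes())
  expect_equal(unname(m$matrix), diag(3), tolerance = 1e-15)
})

test_that("high-res columns are the per-column binomial natural-abundance model", {
  a <- 0.0107
  m <- build_correction_matrix("C2", tracer_spec("C", 2, purity = 1),
                               max_shift = 2, mode = "high_res")
  expect_equal(unname(m$matrix[, 1]), c((1 - a)^2, 2 * a * (1 - a), a^2),
               tolerance = 1e-12)
  expect_equal(unname(m$matrix[, 2]), c(0, 1 - a, a), tolerance = 1e-12)
  expect_equal(unname(m$matrix[, 3]), c(0, 0, 1), tolerance = 1e-12)
})

test_that("tracer impurity shifts signal to lower isotopologues", {
  m <- build_correction_matrix("C1", tracer_spec("C", 1, purity = 0.99),
                               max_shift = 1, mode = "nominal",
                               isotopes = zero_abundance_isotopes())
  expect_equal(unname(m$matrix[, 2]), c(0.01, 0.99), tolerance = 1e-15)
  # purity 1 collapses the impurity convolution: column j starts with j zeros
  m1 <- build_correction_matrix("C3H7NO3", tracer_spec("C", 3, purity = 1),
                                max_shift = 3)
  for (j in 1:3) expect_equal(unname(m1$matrix[seq_len(j), j + 1]), numeric(j))
})

test_that("correction matrices match exhaustive multinomial enumeration", {
  set.seed(21)
  for (i in 1:10) {
    el <- sample(c("C", "H"), 1)
    f <- random_formula(12L, must_include = el, min_count = 2L)
    n_label <- sample(1:f[[el]], 1)
    purity <- sample(c(1, 0.99, 0.95), 1)
    mode <- sample(c("high_res", "nominal"), 1)
    ms <- sample(1:4, 1)
    m <- build_correction_matrix(f, tracer_spec(el, n_label, purity),
                                 max_shift = ms, mode = mode)
    o <- oracle_correction_matrix(f, el, n_label, purity, ms, mode)
    expect_equal(unname(m$matrix), o, tolerance = 1e-12)
  }
})

test_that("matrix columns are non-negative and sum to at most 1", {
  set.seed(22)
  for (i in 1:5) {
    f <- random_formula(12L, must_include = "C", min_count = 2L)
    m <- build_correction_matrix(f, tracer_spec("C", f[["C"]], 0.99),
                                 max_shift = f[["C"]], mode = "nominal")
    expect_true(all(m$matrix >= 0))
    expect_true(all(colSums(m$matrix) <= 1 + 1e-9))
  }
})

test_that("matrix construction rejects inconsistent tracer specifications", {
  expect_error(build_correction_matrix("C2H4O2", tracer_spec("C", 3), max_shift = 3),
               "exceeds")
  expect_error(build_correction_matrix("H2O1", tracer_spec("C", 1), max_shift = 1),
               "absent")
  expect_error(build_correction_matrix("C2", tracer_spec("C", 2), max_shift = -1),
               "non-negative")
})

test_that("correction of clean intensities recovers exact fractions", {
  expect_equal(unname(correct_intensities(c(80, 20), diag(2))$fractions),
               c(0.8, 0.2), tolerance = 1e-12)
  m <- build_correction_matrix("C3H7NO3", tracer_spec("C", 3, 0.99), max_shift = 3)
  x_true <- c(0.6, 0.3, 0.1, 0)
  fit <- correct_intensities(as.vector(m$matrix %*% x_true), m)
  expect_equal(unname(fit$fractions), x_true, tolerance = 1e-8)
  expect_lt(fit$residual_norm, 1e-10)
  # an unlabeled standard corrects to a delta at shift 0
  a <- 0.0107
  m2 <- build_correction_matrix("C2", tracer_spec("C", 2), max_shift = 2)
  fit2 <- correct_intensities(c((1 - a)^2, 2 * a * (1 - a), a^2), m2)
  expect_equal(unname(fit2$fractions), c(1, 0, 0), tolerance = 1e-8)
})

test_that("round trip recovers random labeling states across 6 orders of intensity", {
  set.seed(23)
  for (i in 1:10) {
    el <- sample(c("C", "H"), 1)
    f <- random_formula(10L, must_include = el, min_count = 2L)
    n <- f[[el]]
    m <- build_correction_matrix(f, tracer_spec(el, n, 0.99), max_shift = n,
                                 mode = sample(c("high_res", "nominal"), 1))
    x_true <- random_mid(n + 1L)
    for (scale in c(1e2, 1e5, 1e8)) {
      fit <- correct_intensities(as.vector(m$matrix %*% x_true) * scale, m)
      expect_equal(unname(fit$fractions), x_true, tolerance = 1e-7)
      expect_mid(fit$fractions)
    }
  }
})

test_that("2% multiplicative noise leaves median fraction error below 0.01", {
  set.seed(24)
  m <- build_correction_matrix("C3H7NO3", tracer_spec("C", 3, 0.99), max_shift = 3)
  x_true <- c(0.55, 0.25, 0.15, 0.05)
  clean <- as.vector(m$matrix %*% x_true)
  sdlog <- sqrt(log1p(0.02^2))
  errs <- replicate(500, {
    raw <- clean * 1e6 * rlnorm(length(clean), -sdlog^2 / 2, sdlog)
    max(abs(correct_intensities(raw, m)$fractions - x_true))
  })
  expect_lt(median(errs), 0.01)
})

test_that("correction rejects invalid intensity vectors", {
  m <- build_correction_matrix("C2", tracer_spec("C", 2), max_shift = 2)
  expect_error(correct_intensities(c(0, 0, 0), m), "all-zero")
  expect_error(correct_intensities(c(-1, 2, 1), m), "non-negative")
  expect_error(correct_intensities(c(1, 2), m), "rows")
})
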