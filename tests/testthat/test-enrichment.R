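test_that("labeling metrics follow their defining formulas", {
  r <- labeling_metrics(c(1, 0, 0), 2)
  expect_equal(r$labeled_fraction, 0)
  expect_equal(r$fractional_enrichment, 0)
  r <- labeling_metrics(c(0, 0, 1), 2)
  expect_equal(r$labeled_fraction, 1)
  expect_equal(r$fractional_enrichment, 1)
  r <- labeling_metrics(c(0.5, 0.25, 0.25), 2)
  expect_equal(r$labeled_fraction, 0.5)
  expect_equal(r$fractional_enrichment, 0.375)
  expect_error(labeling_metrics(c(0.5, 0.5), 0), "positive integer")
})

test_that("labeling metrics are invariant to uniform intensity scaling upstream", {
  set.seed(31)
  m <- build_correction_matrix("C3H7NO3", tracer_spec("C", 3, 0.99), max_shift = 3)
  x_true <- random_mid(4)
  raw <- as.vector(m$matrix %*% x_true)
  base <- labeling_metrics(correct_intensities(raw, m)$fractions, 3)
  for (s in c(1e-3, 1e4, 1e8)) {
    sc <- labeling_metrics(correct_intensities(raw * s, m)$fractions, 3)
    expect_equal(sc$labeled_fraction, base$labeled_fraction, tolerance = 1e-10)
    expect_equal(sc$fractional_enrichment, base$fractional_enrichment, tolerance = 1e-10)
  }
})

test_that("serum normalization is the stated per-mouse division", {
  expect_equal(normalize_to_serum(0.10, 0.40)$value, 0.25)
  expect_equal(normalize_to_serum(0.40, 0.40)$value, 1.0)
  expect_equal(normalize_to_serum(0, 0.35)$value, 0)
  expect_error(normalize_to_serum(0.2, 0), "positive")
  expect_error(normalize_to_serum(0.2, -0.1), "positive")
  expect_error(normalize_to_serum(c(0.1, 0.2, 0.3), c(0.4, 0.5)), "unmatched")
})

test_that("serum normalization inverts exactly", {
  set.seed(32)
  x <- runif(50)
  s <- runif(50, 0.05, 0.9)
  v <- normalize_to_serum(x, s, mouse_id = seq_len(50))$value
  expect_equal(v * s, x, tolerance = 1e-12)
})

test_that("fatty-acid names map to saponified free-acid formulas", {
  expect_identical(unclass(fatty_acid_formula("C16:0")), c(C = 16L, H = 32L, O = 2L))
  expect_identical(unclass(fatty_acid_formula("C18:2")), c(C = 18L, H = 32L, O = 2L))
  expect_identical(unclass(fatty_acid_formula("C18:0")), c(C = 18L, H = 36L, O = 2L))
  expect_error(fatty_acid_formula("palmitate"), "unknown fatty-acid")
})

test_that("fatty-acid labeling uses the saponified atom counts and carries flags", {
  r <- fatty_acid_labeling(c(0.9, 0.1), "C16:0")
  expect_equal(r$labeled_fraction, 0.1)
  expect_equal(r$n_atoms, 32L)
  expect_false(r$essential)
  r <- fatty_acid_labeling(c(0.9, 0.1), "C18:2", tracer_element = "C", essential = TRUE)
  expect_equal(r$n_atoms, 18L)
  expect_true(r$essential)
})

test_that("forward-simulated fatty-acid labeling matches the synthesis model", {
  # newly-synthesized fraction f with per-H incorporation q:
  # labeled fraction = f * (1 - (1 - q)^nH), recovered noise-free
  f <- 0.3; q <- 0.045
  nh <- fatty_acid_formula("C16:0")[["H"]]
  true_mid <- (1 - f) * c(1, numeric(nh)) + f * dbinom(0:nh, nh, q)
  tr <- tracer_spec("H", nh, purity = 0.99)
  raw <- simulate_measurement(true_mid, fatty_acid_formula("C16:0"), tr,
                              noise_cv = 0, seed = 33)
  m <- build_correction_matrix(fatty_acid_formula("C16:0"), tr, max_shift = nh)
  got <- fatty_acid_labeling(correct_intensities(raw, m)$fractions, "C16:0")
  expect_equal(got$labeled_fraction, f * (1 - (1 - q)^nh), tolerance = 1e-6)
})

test_that("an essential fatty acid shows zero labeling under zero synthesis", {
  nh <- fatty_acid_formula("C18:2")[["H"]]
  tr <- tracer_spec("H", nh, purity = 0.99)
  raw <- simulate_measurement(c(1, numeric(nh)), fatty_acid_formula("C18:2"), tr,
                              noise_cv = 0, seed = 34)
  m <- build_correction_matrix(fatty_acid_formula("C18:2"), tr, max_shift = nh)
  got <- fatty_acid_labeling(correct_intensities(raw, m)$fractions, "C18:2",
                             essential = TRUE)
  expect_lt(got$labeled_fraction, 1e-9)
})
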