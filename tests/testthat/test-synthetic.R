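test_that("true-MID simulation is the stated binomial model", {
  expect_equal(simulate_true_mid(3, 0), c(1, 0, 0, 0))
  expect_equal(simulate_true_mid(1, 0.4), c(0.6, 0.4))
  expect_equal(simulate_true_mid(2, 0.5), c(0.25, 0.5, 0.25))
  expect_equal(simulate_true_mid(2, 0, model = "custom", custom = c(0.7, 0.2, 0.1)),
               c(0.7, 0.2, 0.1))
  expect_error(simulate_true_mid(2, 1.5), "\\[0, 1\\]")
})

test_that("noise-free measurements are exactly proportional to the forward model", {
  tr <- tracer_spec("C", 3, 0.99)
  x <- c(0.5, 0.3, 0.15, 0.05)
  raw <- simulate_measurement(x, "C3H7NO3", tr, noise_cv = 0, seed = 61, scale = 1)
  m <- build_correction_matrix("C3H7NO3", tr, max_shift = 3)
  expect_equal(raw, as.vector(m$matrix %*% x), tolerance = 1e-12)
})

test_that("the same seed reproduces a measurement exactly and preserves caller RNG", {
  tr <- tracer_spec("C", 2, 0.99)
  set.seed(99); before <- runif(1)
  set.seed(99)
  r1 <- simulate_measurement(c(0.6, 0.3, 0.1), "C2H4O2", tr, noise_cv = 0.05, seed = 7)
  after <- runif(1)
  r2 <- simulate_measurement(c(0.6, 0.3, 0.1), "C2H4O2", tr, noise_cv = 0.05, seed = 7)
  expect_identical(r1, r2)
  expect_identical(before, after)  # seeded call did not disturb the RNG stream
})

test_that("measurement round trip recovers the true MID at zero noise", {
  set.seed(62)
  for (i in 1:5) {
    el <- sample(c("C", "H"), 1)
    f <- random_formula(10L, must_include = el, min_count = 2L)
    tr <- tracer_spec(el, f[[el]], 0.99)
    x <- random_mid(f[[el]] + 1L)
    raw <- simulate_measurement(x, f, tr, noise_cv = 0)
    m <- build_correction_matrix(f, tr, max_shift = f[[el]])
    expect_equal(unname(correct_intensities(raw, m)$fractions), x, tolerance = 1e-7)
  }
})

test_that("the simulated NADPH pair is the active-hydride mixture", {
  s0 <- simulate_nadph_pair(c(0.8, 0.2), p = 0, seed = 63)
  expect_equal(s0$nadph_true, c(0.8, 0.2, 0))
  s3 <- simulate_nadph_pair(c(0.8, 0.2), p = 0.3, seed = 63)
  expect_equal(s3$nadph_true, c(0.56, 0.38, 0.06), tolerance = 1e-12)
})

test_that("simulate -> correct -> deconvolve returns p exactly at zero noise", {
  for (p in c(0, 0.07, 0.3, 1)) {
    sim <- simulate_nadph_pair(c(0.85, 0.13, 0.02), p = p, noise_cv = 0,
                               seed = 64, purity = 0.99)
    nadp <- correct_intensities(sim$nadp_raw, sim$nadp_matrix)$fractions
    nadph <- correct_intensities(sim$nadph_raw, sim$nadph_matrix)$fractions
    expect_equal(active_h_labeling(nadp, nadph)$p, p, tolerance = 1e-7)
  }
})

test_that("identical configurations give byte-identical cohort files", {
  cfg <- sim_config(seed = 65, n_per_group = 2)
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  write_sim_cohort(simulate_cohort(cfg), d1)
  write_sim_cohort(simulate_cohort(cfg), d2)
  write_sim_cohort(simulate_cohort(sim_config(seed = 66, n_per_group = 2)), d3)
  files <- list.files(d1)
  expect_identical(files, list.files(d2))
  for (fn in files)
    expect_identical(unname(tools::md5sum(file.path(d1, fn))),
                     unname(tools::md5sum(file.path(d2, fn))),
                     label = paste("md5 of", fn))
  # a different seed must change the simulated intensities
  expect_false(identical(unname(tools::md5sum(file.path(d1, "peaks_serine13C.csv"))),
                         unname(tools::md5sum(file.path(d3, "peaks_serine13C.csv")))))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("every emitted intensity is non-negative and every true MID sums to 1", {
  coh <- simulate_cohort(sim_config(seed = 67, n_per_group = 2))
  for (pt in coh$peak_tables) {
    vals <- as.matrix(pt[, setdiff(names(pt), c("compound", "formula", "isotopeLabel"))])
    expect_true(all(vals >= 0))
  }
  expect_true(all(coh$truth$p_active_h >= 0 & coh$truth$p_active_h <= 1))
  expect_true(all(coh$truth$serine_enrichment >= 0 & coh$truth$serine_enrichment <= 1))
})

test_that("identical groups show no systematic group difference in recovered p", {
  diffs <- vapply(1:6, function(s) {
    cfg <- sim_config(seed = 70 + s, n_per_group = 3,
                      groups = list(A = sim_group(0.10, 0.35, 0.15, 0.3, 0.045),
                                    B = sim_group(0.10, 0.35, 0.15, 0.3, 0.045)))
    coh <- simulate_cohort(cfg)
    d <- tempfile()
    run <- run_pipeline(write_sim_cohort(coh, d))
    unlink(d, recursive = TRUE)
    s <- run$active_h$summary
    s$mean_p[s$group == "A"] - s$mean_p[s$group == "B"]
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.01)
})
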