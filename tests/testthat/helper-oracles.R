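# Independent oracles: brute-force enumeration and grid search, deliberately
# coded along different routes than the package internals.

# all compositions of n into k non-negative parts
oracle_compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, ncol = 1L))
  out <- NULL
  for (i in 0:n) out <- rbind(out, cbind(i, oracle_compositions(n - i, k - 1L)))
  unname(out)
}

# brute-force convolution by explicit double loop
oracle_conv <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) for (j in seq_along(b))
    out[i + j - 1L] <- out[i + j - 1L] + a[i] * b[j]
  out
}

# exhaustive multinomial enumeration of the natural-abundance shift
# distribution of a set of atoms (named counts), truncated and zero-padded
# to max_shift + 1 entries
oracle_natural <- function(counts, max_shift, isotopes = default_isotope_table()) {
  counts <- counts[counts > 0]
  dist <- 1
  for (el in names(counts)) {
    sub <- isotopes[isotopes$element == el, ]
    sub <- sub[order(sub$mass_shift), ]
    n <- counts[[el]]
    comps <- oracle_compositions(n, nrow(sub))
    eldist <- numeric(max(sub$mass_shift) * n + 1L)
    for (r in seq_len(nrow(comps))) {
      k <- comps[r, ]
      pr <- factorial(n) / prod(factorial(k)) * prod(sub$abundance^k)
      sh <- sum(k * sub$mass_shift)
      eldist[sh + 1L] <- eldist[sh + 1L] + pr
    }
    dist <- oracle_conv(dist, eldist)
  }
  out <- dist[seq_len(min(length(dist), max_shift + 1L))]
  c(out, numeric(max_shift + 1L - length(out)))
}

oracle_natural_formula <- function(formula, max_shift, exclude = NULL,
                                   isotopes = default_isotope_table()) {
  f <- parse_formula(formula)
  counts <- stats::setNames(as.integer(f), names(f))
  if (!is.null(exclude))
    counts[names(exclude)] <- counts[names(exclude)] - as.integer(exclude)
  oracle_natural(counts, max_shift, isotopes)
}

# correction matrix by enumeration: column j = impurity binomial (direct
# formula) convolved with the enumerated natural distribution of the
# remaining atoms
oracle_correction_matrix <- function(formula, element, n_label, purity,
                                     max_shift, mode = "high_res",
                                     isotopes = default_isotope_table()) {
  f <- parse_formula(formula)
  counts <- stats::setNames(as.integer(f), names(f))
  cols <- lapply(0:n_label, function(j) {
    imp <- vapply(0:j, function(s)
      choose(j, s) * purity^s * (1 - purity)^(j - s), numeric(1))
    nat_counts <- counts
    nat_counts[[element]] <- counts[[element]] - j
    if (mode == "high_res")
      nat_counts <- nat_counts[names(nat_counts) == element]
    nat <- oracle_natural(nat_counts, max_shift, isotopes)
    col <- oracle_conv(imp, nat)
    col <- col[seq_len(min(length(col), max_shift + 1L))]
    c(col, numeric(max_shift + 1L - length(col)))
  })
  do.call(cbind, cols)
}

# grid-search solution of the active-hydride mixture fit
oracle_grid_p <- function(nadp, nadph, step = 1e-5) {
  k <- max(length(nadp), length(nadph) - 1L)
  a <- c(nadp, numeric(k - length(nadp)))
  b <- c(nadph, numeric(k + 1L - length(nadph)))
  c1 <- c(a, 0); c2 <- c(0, a)
  ps <- seq(0, 1, by = step)
  sse <- vapply(ps, function(p) sum(((1 - p) * c1 + p * c2 - b)^2), numeric(1))
  ps[which.min(sse)]
}

random_mid <- function(k) {
  x <- stats::runif(k)
  x / sum(x)
}

# random formula with <= max_atoms atoms, guaranteed to contain
# `must_include` with at least `min_count` atoms
random_formula <- function(max_atoms = 12L, must_include = "C", min_count = 1L) {
  repeat {
    els <- unique(c(must_include, sample(supported_elements(),
                                         sample(1:3, 1), replace = FALSE)))
    counts <- stats::setNames(sample(1:4, length(els), replace = TRUE), els)
    counts[must_include] <- max(counts[must_include], min_count)
    if (sum(counts) <= max_atoms) return(counts)
  }
}

# convolve then truncate/zero-pad to max_shift + 1 entries
conv_pad <- function(a, b, max_shift) {
  out <- oracle_conv(a, b)
  out <- out[seq_len(min(length(out), max_shift + 1L))]
  c(out, numeric(max_shift + 1L - length(out)))
}

# closed-form OLS slope (textbook formula), independent of stats::lm
oracle_ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

expect_mid <- function(x, tol = 1e-9) {
  expect_true(all(x >= -tol))
  expect_equal(sum(x), 1, tolerance = tol)
}
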