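#' Validate a mass-isotopologue distribution (MID)
#'
#' A MID is a numeric vector of fractions `m0..mk` over integer mass shifts:
#' all entries non-negative and summing to 1 (within `tol`).
#'
#' @param x Numeric vector of isotopologue fractions.
#' @param tol Tolerance on the sum-to-one check.
#' @return `x`, invisibly classed as `mid`.
#' @export
mid <- function(x, tol = 1e-9) {
  x <- as.numeric(x)
  if (!length(x)) stop("a MID must have at least one entry")
  if (any(!is.finite(x))) stop("MID entries must be finite")
  if (any(x < 0)) stop("MID entries must be non-negative")
  if (abs(sum(x) - 1) > tol)
    stop("MID entries must sum to 1 (got ", format(sum(x)), ")")
  structure(x, class = "mid")
}

# soft check used by consumers that accept plain numeric vectors
check_mid <- function(x, tol = 1e-6, what = "MID") {
  x <- as.numeric(x)
  if (!length(x)) stop(what, " must have at least one entry")
  if (any(!is.finite(x))) stop(what, " entries must be finite")
  if (any(x < -tol)) stop(what, " entries must be non-negative")
  if (abs(sum(x) - 1) > tol)
    stop(what, " must sum to 1 (got ", format(sum(x)), ")")
  pmax(x, 0)
}

# Discrete convolution of two non-negative vectors indexed by shift 0..k,
# truncated so that the result covers shifts 0..max_shift. Truncation drops
# tail mass; it never affects the retained entries.
conv_trunc <- function(a, b, max_shift = length(a) + length(b) - 2L) {
  n <- min(length(a) + length(b) - 1L, max_shift + 1L)
  out <- numeric(n)
  for (i in seq_len(min(length(a), n))) {
    m <- min(length(b), n - i + 1L)
    idx <- i:(i + m - 1L)
    out[idx] <- out[idx] + a[i] * b[seq_len(m)]
  }
  out
}

# repeated self-convolution (distribution of the summed shift of n iid atoms),
# truncated at max_shift throughout
conv_power <- function(d, n, max_shift) {
  out <- 1
  base <- d
  while (n > 0L) {
    if (n %% 2L == 1L) out <- conv_trunc(out, base, max_shift)
    base <- conv_trunc(base, base, max_shift)
    n <- n %/% 2L
  }
  out
}

pad_to <- function(x, len) c(x, numeric(max(0L, len - length(x))))

#' Convolve two MIDs
#'
#' Standard discrete convolution of two shift-indexed fraction vectors; the
#' result has length `length(a) + length(b) - 1` and preserves total mass.
#'
#' @param a,b Numeric vectors indexed by mass shift starting at 0.
#' @return Numeric vector of the convolved distribution.
#' @examples
#' convolve_mid(c(0.9, 0.1), c(0.8, 0.2))
#' @export
convolve_mid <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("cannot convolve an empty vector")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("non-finite entries")
  conv_trunc(a, b)
}

#' Natural-abundance isotopologue distribution of a formula
#'
#' Convolves the per-atom natural isotope distributions of every atom in
#' `formula` (optionally excluding some atoms), truncated at `max_shift`.
#' Truncated tail mass is dropped, not renormalized, so columns built from
#' this function honestly reflect detector truncation; callers decide whether
#' to renormalize.
#'
#' @param formula Formula string or parsed counts (see [parse_formula()]).
#' @param max_shift Largest mass shift retained (result has `max_shift + 1`
#'   entries, zero-padded if the support is smaller).
#' @param exclude Optional named integer vector of atoms to leave out, e.g.
#'   `c(C = 2)` excludes two carbons. Counts must not exceed the formula.
#' @param isotopes Isotope abundance table (default [default_isotope_table()]).
#' @return Numeric vector of fractions over shifts `0..max_shift`.
#' @examples
#' natural_mid("C1", max_shift = 1)            # c(0.9893, 0.0107)
#' natural_mid("C16H32O2", max_shift = 3)      # palmitate M+0..M+3
#' @export
natural_mid <- function(formula, max_shift, exclude = NULL,
                        isotopes = default_isotope_table()) {
  f <- parse_formula(formula)
  if (!is.numeric(max_shift) || length(max_shift) != 1L || max_shift < 0 ||
      max_shift != round(max_shift))
    stop("max_shift must be a non-negative integer")
  counts <- stats::setNames(as.integer(f), names(f))
  if (!is.null(exclude)) {
    if (is.null(names(exclude)))
      stop("exclude must be a named count vector, e.g. c(C = 2)")
    for (el in names(exclude)) {
      if (!el %in% names(counts))
        stop("cannot exclude element ", el, " absent from formula")
      if (exclude[[el]] > counts[[el]])
        stop("exclusion count for ", el, " exceeds formula count")
      counts[[el]] <- counts[[el]] - as.integer(exclude[[el]])
    }
  }
  counts <- counts[counts > 0L]
  out <- 1
  for (el in names(counts)) {
    out <- conv_trunc(out, conv_power(iso_dist(isotopes, el), counts[[el]], max_shift),
                      max_shift)
  }
  pad_to(out, max_shift + 1L)
}
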