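#' Tracer specification
#'
#' Describes the isotopic tracer applied in an experiment: the labeled element
#' (C for 13C tracers, H for 2H/D2O tracers), the number of atoms of that
#' element that can carry label, and the per-atom isotopic purity of the
#' tracer (impurity shifts signal to lower isotopologues).
#'
#' @param element `"C"` or `"H"`.
#' @param n_label_atoms Number of label-capable atoms (positive integer).
#' @param purity Per-atom probability that a nominally labeled atom carries
#'   the heavy isotope, in (0, 1]. Default 1 (chemically pure tracer).
#' @return An object of class `tracer_spec`.
#' @examples
#' tracer_spec("C", 6, purity = 0.99)  # [U-13C6]-glucose
#' @export
tracer_spec <- function(element, n_label_atoms, purity = 1) {
  if (!is.character(element) || length(element) != 1L || !element %in% c("C", "H"))
    stop("tracer element must be \"C\" or \"H\"")
  if (!is.numeric(n_label_atoms) || length(n_label_atoms) != 1L ||
      n_label_atoms < 1 || n_label_atoms != round(n_label_atoms))
    stop("n_label_atoms must be a positive integer")
  if (!is.numeric(purity) || length(purity) != 1L || purity <= 0 || purity > 1)
    stop("purity must lie in (0, 1]")
  structure(list(element = element, n_label_atoms = as.integer(n_label_atoms),
                 purity = purity),
            class = "tracer_spec")
}

#' @export
print.tracer_spec <- function(x, ...) {
  cat(sprintf("<tracer_spec> element %s, %d label atom(s), purity %.4g\n",
              x$element, x$n_label_atoms, x$purity))
  invisible(x)
}

#' Build a natural-abundance + tracer-impurity correction matrix
#'
#' Column `j` (for `j = 0..n_label_atoms`) is the isotopologue distribution
#' the instrument is predicted to measure when exactly `j` of the designated
#' tracer atoms are truly labeled. Each column is the convolution of
#'
#' 1. the impurity downshift distribution `Binomial(j, purity)` — of the `j`
#'    nominally labeled atoms, each carries the heavy isotope independently
#'    with probability `purity`;
#' 2. the natural-abundance distribution of the unlabeled atoms of the tracer
#'    element (same-element interference cannot be mass-resolved away);
#' 3. in `"nominal"` mode only, the natural-abundance distributions of all
#'    non-tracer elements. `"high_res"` mode assumes an Orbitrap-class
#'    resolution at which those hetero-element isotopologues are resolved
#'    away and so contribute nothing.
#'
#' Columns are truncated at `max_shift` without renormalization.
#'
#' @param formula Metabolite formula (string or parsed counts).
#' @param tracer A [tracer_spec()].
#' @param max_shift Largest measured mass shift (matrix has `max_shift + 1`
#'   rows).
#' @param mode `"high_res"` (default) or `"nominal"`.
#' @param isotopes Isotope abundance table.
#' @return Object of class `correction_matrix` with elements `matrix`,
#'   `formula`, `tracer`, `mode`, `max_shift`.
#' @examples
#' m <- build_correction_matrix("C3H7NO3", tracer_spec("C", 3, 0.99), max_shift = 3)
#' round(m$matrix, 4)
#' @export
build_correction_matrix <- function(formula, tracer, max_shift,
                                    mode = c("high_res", "nominal"),
                                    isotopes = default_isotope_table()) {
  f <- parse_formula(formula)
  mode <- match.arg(mode)
  if (!inherits(tracer, "tracer_spec")) stop("tracer must be a tracer_spec")
  if (!is.numeric(max_shift) || length(max_shift) != 1L || max_shift < 0 ||
      max_shift != round(max_shift))
    stop("max_shift must be a non-negative integer")
  el <- tracer$element
  if (!el %in% names(f))
    stop("tracer element ", el, " absent from formula ", format(f))
  n <- tracer$n_label_atoms
  if (n > f[[el]])
    stop("n_label_atoms (", n, ") exceeds ", el, " count of formula ", format(f))

  atom <- iso_dist(isotopes, el)
  other <- if (mode == "nominal") {
    natural_mid(f, max_shift, exclude = stats::setNames(f[[el]], el), isotopes)
  } else 1
  cols <- lapply(0:n, function(j) {
    impurity <- stats::dbinom(0:j, j, tracer$purity)
    col <- conv_trunc(impurity, conv_power(atom, f[[el]] - j, max_shift), max_shift)
    if (mode == "nominal") col <- conv_trunc(col, other, max_shift)
    pad_to(col, max_shift + 1L)
  })
  M <- do.call(cbind, cols)
  dimnames(M) <- list(paste0("M+", 0:max_shift), paste0("x", 0:n))
  structure(list(matrix = M, formula = f, tracer = tracer, mode = mode,
                 max_shift = as.integer(max_shift)),
            class = "correction_matrix")
}

#' @export
print.correction_matrix <- function(x, ...) {
  cat(sprintf("<correction_matrix> %s, tracer %s (n = %d, purity %.4g), %s mode, %d x %d\n",
              format(x$formula), x$tracer$element, x$tracer$n_label_atoms,
              x$tracer$purity, x$mode, nrow(x$matrix), ncol(x$matrix)))
  print(round(x$matrix, 6))
  invisible(x)
}

#' Recover a corrected MID from raw isotopologue intensities
#'
#' Solves `min || M x - raw ||_2` subject to `x >= 0` (non-negative least
#' squares, Lawson–Hanson) and renormalizes the solution to fractions. This
#' removes the isotopologue signal caused by natural heavy isotopes and by
#' tracer impurity, leaving the distribution over true tracer-labeling
#' states.
#'
#' @param raw Numeric vector of raw isotopologue intensities (length equal to
#'   the matrix row count; all entries non-negative, at least one positive).
#' @param cmat A [build_correction_matrix()] result (or a plain matrix).
#' @return Object of class `corrected_mid` with elements `fractions` (a valid
#'   MID over labeling states `x0..xn`), `residual_norm` (root-sum-square
#'   misfit on the intensity scale of `raw`), `raw_total` (summed raw
#'   intensity) and `coefficients` (the unnormalized NNLS solution).
#' @examples
#' m <- build_correction_matrix("C2H4O2", tracer_spec("C", 2), max_shift = 2)
#' raw <- as.vector(m$matrix %*% c(0.6, 0.3, 0.1)) * 1e6
#' correct_intensities(raw, m)$fractions
#' @export
correct_intensities <- function(raw, cmat) {
  M <- if (inherits(cmat, "correction_matrix")) cmat$matrix else as.matrix(cmat)
  raw <- as.numeric(raw)
  if (length(raw) != nrow(M))
    stop("raw has ", length(raw), " entries but the correction matrix has ",
         nrow(M), " rows")
  if (any(!is.finite(raw))) stop("raw intensities must be finite")
  if (any(raw < 0)) stop("raw intensities must be non-negative")
  if (all(raw == 0)) stop("all-zero raw intensity vector")
  # NNLS is scale-equivariant; solving on the sum-normalized vector keeps the
  # active-set solver well conditioned across intensity scales
  s <- sum(raw)
  fit <- pracma::lsqnonneg(M, raw / s)
  x <- fit$x * s
  if (sum(x) <= 0)
    stop("degenerate NNLS solution: no non-zero labeling state")
  fractions <- x / sum(x)
  residual <- sqrt(sum((as.vector(M %*% x) - raw)^2))
  structure(list(fractions = stats::setNames(fractions, colnames(M)),
                 residual_norm = residual,
                 raw_total = sum(raw),
                 coefficients = x),
            class = "corrected_mid")
}

#' @export
print.corrected_mid <- function(x, digits = 4, ...) {
  cat("<corrected_mid>\n")
  print(round(x$fractions, digits))
  cat(sprintf("residual norm %.4g on raw total %.4g\n", x$residual_norm, x$raw_total))
  invisible(x)
}

#' @export
coef.corrected_mid <- function(object, ...) object$fractions
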