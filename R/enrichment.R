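#' Labeling fraction and fractional enrichment of a corrected MID
#'
#' Two summary metrics of tracer incorporation: the labeled fraction
#' `1 - m0` (any label present) and the atom-weighted fractional enrichment
#' `sum(i * m_i) / n_atoms` over `n_atoms` label-capable atoms. Both are
#' reported; figure-style outputs of the pipeline use `1 - m0` by default
#' (switchable), since plotted "labeling fractions" in the field are usually
#' that quantity.
#'
#' @param mid A corrected MID (numeric fractions or a `corrected_mid`).
#' @param n_atoms Number of label-capable atoms (denominator of the
#'   enrichment; positive integer).
#' @return A list of class `labeling_result` with `labeled_fraction`,
#'   `fractional_enrichment`, `n_atoms`.
#' @examples
#' labeling_metrics(c(0.5, 0.25, 0.25), n_atoms = 2)
#' @export
labeling_metrics <- function(mid, n_atoms) {
  if (inherits(mid, "corrected_mid")) mid <- mid$fractions
  m <- check_mid(mid)
  if (!is.numeric(n_atoms) || length(n_atoms) != 1L || n_atoms < 1 ||
      n_atoms != round(n_atoms))
    stop("n_atoms must be a positive integer")
  labeled <- min(max(1 - m[1L], 0), 1)
  enr <- sum((seq_along(m) - 1L) * m) / n_atoms
  if (enr > 1 + 1e-9)
    warning("fractional enrichment exceeds 1; is n_atoms correct?")
  enr <- min(max(enr, 0), 1)
  structure(list(labeled_fraction = labeled, fractional_enrichment = enr,
                 n_atoms = as.integer(n_atoms)),
            class = "labeling_result")
}

#' @export
print.labeling_result <- function(x, ...) {
  cat(sprintf("<labeling_result> labeled fraction %.4g, fractional enrichment %.4g (n_atoms = %d)\n",
              x$labeled_fraction, x$fractional_enrichment, x$n_atoms))
  invisible(x)
}

#' Normalize tumor labeling to the serum tracer enrichment of the same mouse
#'
#' In vivo 13C enrichments are reported relative to how labeled the
#' circulating tracer actually was: the labeling metric of a tumor metabolite
#' is divided by the serum [U-13C6]-glucose enrichment measured in the same
#' mouse. Values may exceed 1.
#'
#' @param tumor_metric Labeling metric(s) of the tumor metabolite (fractions).
#' @param serum_enrichment Serum tracer enrichment(s), strictly positive;
#'   either one per tumor value or a single common value.
#' @param mouse_id Optional pairing key(s), recycled like `serum_enrichment`.
#' @return A data frame with columns `mouse_id`, `tumor_metric`,
#'   `serum_enrichment`, `value`.
#' @examples
#' normalize_to_serum(0.10, 0.40)  # value 0.25
#' @export
normalize_to_serum <- function(tumor_metric, serum_enrichment, mouse_id = NA) {
  tumor_metric <- as.numeric(tumor_metric)
  serum_enrichment <- as.numeric(serum_enrichment)
  if (any(!is.finite(tumor_metric)) || any(tumor_metric < 0))
    stop("tumor_metric must be non-negative and finite")
  if (any(!is.finite(serum_enrichment)) || any(serum_enrichment <= 0))
    stop("serum enrichment must be strictly positive")
  n <- length(tumor_metric)
  if (!length(serum_enrichment) %in% c(1L, n))
    stop("serum_enrichment must have length 1 or match tumor_metric (unmatched pairing)")
  if (!length(mouse_id) %in% c(1L, n))
    stop("mouse_id must have length 1 or match tumor_metric (unmatched pairing)")
  serum_enrichment <- rep_len(serum_enrichment, n)
  data.frame(mouse_id = rep_len(mouse_id, n),
             tumor_metric = tumor_metric,
             serum_enrichment = serum_enrichment,
             value = tumor_metric / serum_enrichment,
             stringsAsFactors = FALSE)
}

#' Elemental formula of a saponified fatty acid
#'
#' Converts a lipid shorthand name `"C<carbons>:<double bonds>"` into the
#' formula of the free fatty acid, CnH(2n-2d)O2.
#'
#' @param name Fatty-acid name such as `"C16:0"` (palmitate) or `"C18:2"`
#'   (linoleate).
#' @return An `elemental_formula`.
#' @examples
#' fatty_acid_formula("C16:0")  # C16H32O2
#' @export
fatty_acid_formula <- function(name) {
  m <- regmatches(name, regexec("^C([0-9]+):([0-9]+)$", name))[[1L]]
  if (length(m) != 3L)
    stop("unknown fatty-acid name ", sQuote(name), "; expected e.g. \"C16:0\"")
  nc <- as.integer(m[2L]); nd <- as.integer(m[3L])
  nh <- 2L * nc - 2L * nd
  if (nc < 2L || nh < 2L)
    stop("implausible fatty-acid composition in ", sQuote(name))
  as_formula_counts(c(C = nc, H = nh, O = 2L))
}

#' Labeling metrics of a saponified fatty acid
#'
#' Same metrics as [labeling_metrics()] with `n_atoms` defaulting to the
#' hydrogen (for 2H/D2O tracing) or carbon (for 13C tracing) count of the
#' saponified fatty acid. The `essential` flag marks dietary-only fatty acids
#' (e.g. C18:2) that cannot be synthesized de novo and therefore serve as
#' zero-labeling internal controls; it is carried through for reporting and
#' changes no computation.
#'
#' @param mid Corrected MID of the fatty acid.
#' @param fatty_acid Name such as `"C16:0"`.
#' @param tracer_element `"H"` (default, D2O tracing) or `"C"`.
#' @param essential Logical flag carried into the result.
#' @param n_atoms Optional override of the atom denominator (exchangeable-H
#'   counts are debatable; the default uses the full hydrogen count).
#' @return A `labeling_result` with extra fields `fatty_acid`, `essential`.
#' @examples
#' fatty_acid_labeling(c(0.9, 0.1), "C16:0")
#' @export
fatty_acid_labeling <- function(mid, fatty_acid, tracer_element = c("H", "C"),
                                essential = FALSE, n_atoms = NULL) {
  tracer_element <- match.arg(tracer_element)
  f <- fatty_acid_formula(fatty_acid)
  if (is.null(n_atoms)) n_atoms <- f[[tracer_element]]
  res <- labeling_metrics(mid, n_atoms)
  res$fatty_acid <- fatty_acid
  res$essential <- isTRUE(essential)
  res
}
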