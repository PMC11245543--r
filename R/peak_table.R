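# El-MAVEN-export-style peak tables: rows keyed by (compound, formula,
# isotopeLabel), one numeric intensity column per sample.

parse_label_tag <- function(tag) {
  if (tag == "C12 PARENT") return(list(element = NA_character_, shift = 0L))
  m <- regmatches(tag, regexec("^(C13|D)-label-([0-9]+)$", tag))[[1L]]
  if (length(m) != 3L)
    stop("unknown isotope label tag ", sQuote(tag))
  shift <- as.integer(m[3L])
  if (shift < 1L) stop("unknown isotope label tag ", sQuote(tag))
  list(element = if (m[2L] == "C13") "C" else "H", shift = shift)
}

#' Read an El-MAVEN-style isotopologue peak table
#'
#' Expects a CSV with columns `compound`, `formula`, `isotopeLabel` followed
#' by one numeric intensity column per sample. Label tags follow the
#' El-MAVEN grammar: `"C12 PARENT"` is shift 0; `"C13-label-k"` and
#' `"D-label-k"` are shift `k` for a 13C or 2H tracer. Rows are grouped per
#' compound into ordered raw-intensity vectors over shifts `0..max`;
#' absent shifts are filled with intensity 0 (with a warning), as are
#' missing (`NA`) intensity cells. Duplicate (compound, shift) rows, unknown
#' tags, and non-numeric intensities are errors.
#'
#' @param path Path to the CSV file.
#' @return Object of class `peak_table`: `$compounds` is a named list, each
#'   with `formula` (string), `element` (tracer element, `NA` if only the
#'   parent row is present) and `intensities` (shift x sample matrix);
#'   `$samples` holds the sample column names.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop("peak table not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("compound", "formula", "isotopeLabel")
  if (!all(req %in% names(df)))
    stop("peak table needs columns: ", paste(req, collapse = ", "))
  sample_cols <- setdiff(names(df), req)
  if (!length(sample_cols)) stop("peak table has no sample columns")
  if (!nrow(df)) stop("empty peak table: ", path)
  for (sc in sample_cols)
    if (!is.numeric(df[[sc]]) && !all(is.na(df[[sc]])))
      stop("non-numeric intensity in sample column ", sQuote(sc))
  compounds <- list()
  for (cmp in unique(df$compound)) {
    sub <- df[df$compound == cmp, , drop = FALSE]
    if (length(unique(sub$formula)) != 1L)
      stop("conflicting formulas for compound ", sQuote(cmp))
    tags <- lapply(sub$isotopeLabel, function(tag)
      tryCatch(parse_label_tag(tag),
               error = function(e) stop("compound ", sQuote(cmp), ": ",
                                        conditionMessage(e), call. = FALSE)))
    shifts <- vapply(tags, `[[`, integer(1), "shift")
    els <- stats::na.omit(vapply(tags, `[[`, character(1), "element"))
    if (length(unique(els)) > 1L)
      stop("mixed tracer elements for compound ", sQuote(cmp))
    if (anyDuplicated(shifts))
      stop("duplicate isotopologue shift for compound ", sQuote(cmp))
    n <- max(shifts) + 1L
    mat <- matrix(0, nrow = n, ncol = length(sample_cols),
                  dimnames = list(paste0("M+", 0:(n - 1L)), sample_cols))
    for (i in seq_along(shifts))
      mat[shifts[i] + 1L, ] <- as.numeric(sub[i, sample_cols])
    missing_shifts <- setdiff(0:(n - 1L), shifts)
    if (length(missing_shifts))
      warning("compound ", sQuote(cmp), ": missing isotopologue shift(s) ",
              paste(missing_shifts, collapse = ", "), " filled with 0")
    if (anyNA(mat)) {
      warning("compound ", sQuote(cmp), ": missing intensities treated as 0")
      mat[is.na(mat)] <- 0
    }
    if (any(mat < 0))
      stop("negative intensity for compound ", sQuote(cmp))
    compounds[[cmp]] <- list(
      formula = sub$formula[1L],
      element = if (length(els)) els[1L] else NA_character_,
      intensities = mat)
  }
  structure(list(compounds = compounds, samples = sample_cols),
            class = "peak_table")
}

#' Write a peak table back to CSV
#'
#' Inverse of [read_peak_table()]; emits rows in shift order with
#' reconstructed label tags. Reading the written file reproduces the object.
#'
#' @param pt A `peak_table`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_peak_table <- function(pt, path) {
  if (!inherits(pt, "peak_table")) stop("pt must be a peak_table")
  rows <- list()
  for (cmp in names(pt$compounds)) {
    cc <- pt$compounds[[cmp]]
    n <- nrow(cc$intensities)
    el <- if (is.na(cc$element)) "C" else cc$element  # tag only used for shift >= 1
    meta <- data.frame(compound = cmp, formula = cc$formula,
                       isotopeLabel = label_tag(el, 0:(n - 1L)),
                       stringsAsFactors = FALSE)
    rows[[cmp]] <- cbind(meta, as.data.frame(cc$intensities, check.names = FALSE),
                         stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("<peak_table> %d compound(s), %d sample(s)\n",
              length(x$compounds), length(x$samples)))
  for (cmp in names(x$compounds))
    cat(sprintf("  %s (%s): %d isotopologue(s), tracer element %s\n",
                cmp, x$compounds[[cmp]]$formula,
                nrow(x$compounds[[cmp]]$intensities), x$compounds[[cmp]]$element))
  invisible(x)
}
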