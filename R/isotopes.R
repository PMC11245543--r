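#' Default natural-isotope abundance table
#'
#' Nominal-mass isotope abundances (IUPAC/CIAAW-style values) for the elements
#' supported by the package: C, H, N, O, P, S. Each row gives the fractional
#' natural abundance of an isotope at a given integer mass shift relative to
#' the lightest isotope; 18O counts as shift 2. Per element the abundances sum
#' to 1 and the shift-0 isotope is the most abundant.
#'
#' These constants are replaceable: pass a modified table (or one loaded with
#' [load_isotope_table()]) to any function taking an `isotopes` argument.
#'
#' @return A data frame with columns `element`, `mass_shift`, `abundance`.
#' @examples
#' default_isotope_table()
#' @export
default_isotope_table <- function() {
  data.frame(
    element = c("C", "C", "H", "H", "N", "N", "O", "O", "O", "P", "S", "S", "S"),
    mass_shift = c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 2L, 0L, 0L, 1L, 2L),
    abundance = c(
      0.9893, 0.0107,        # 12C, 13C
      0.999885, 0.000115,    # 1H, 2H
      0.99636, 0.00364,      # 14N, 15N
      0.99757, 0.00038, 0.00205,  # 16O, 17O, 18O
      1,                     # 31P
      0.95, 0.0075, 0.0425   # 32S, 33S, 34S
    ),
    stringsAsFactors = FALSE
  )
}

#' Supported element symbols
#' @return Character vector of element symbols the package handles.
#' @export
supported_elements <- function() c("C", "H", "N", "O", "P", "S")

#' Load an isotope abundance table from CSV
#'
#' The file must have columns `element`, `mass_shift`, `abundance`. The table
#' is validated: only supported elements, per-element abundances summing to 1
#' within 1e-12, and a shift-0 entry present and largest for every element.
#'
#' @param path Path to a CSV file.
#' @return A validated isotope table data frame.
#' @export
load_isotope_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_isotope_table(tab)
}

#' @keywords internal
validate_isotope_table <- function(tab) {
  req <- c("element", "mass_shift", "abundance")
  if (!all(req %in% names(tab)))
    stop("isotope table needs columns: ", paste(req, collapse = ", "))
  bad <- setdiff(unique(tab$element), supported_elements())
  if (length(bad))
    stop("unsupported element(s) in isotope table: ", paste(bad, collapse = ", "))
  if (any(tab$mass_shift < 0) || any(tab$mass_shift != round(tab$mass_shift)))
    stop("mass_shift must be a non-negative integer")
  if (any(tab$abundance < 0) || any(tab$abundance > 1))
    stop("abundances must lie in [0, 1]")
  for (el in unique(tab$element)) {
    sub <- tab[tab$element == el, ]
    if (abs(sum(sub$abundance) - 1) > 1e-12)
      stop("abundances for element ", el, " do not sum to 1")
    if (anyDuplicated(sub$mass_shift))
      stop("duplicate mass shift for element ", el)
    i0 <- which(sub$mass_shift == 0)
    if (!length(i0))
      stop("element ", el, " lacks a shift-0 isotope")
    if (any(sub$abundance > sub$abundance[i0]))
      stop("shift-0 isotope must be the most abundant for element ", el)
  }
  tab
}

# Per-atom isotope distribution for one element as a dense vector over
# shifts 0..max(shift); positions are shift + 1.
iso_dist <- function(isotopes, element) {
  sub <- isotopes[isotopes$element == element, ]
  if (!nrow(sub))
    stop("element ", element, " absent from isotope table")
  out <- numeric(max(sub$mass_shift) + 1L)
  out[sub$mass_shift + 1L] <- sub$abundance
  out
}
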