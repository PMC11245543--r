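#' Parse an elemental formula string
#'
#' Parses strings like `"C3H7NO3"` (serine) or `"C16H32O2"` (palmitate) into a
#' named integer vector of atom counts. The grammar is a sequence of element
#' symbols each followed by an optional positive integer count; an omitted
#' count means one atom. Repeated symbols are summed. Only C, H, N, O, P and S
#' are supported.
#'
#' @param text A single formula string, or an already-parsed named count
#'   vector (returned unchanged after validation).
#' @return A named integer vector of class `elemental_formula`.
#' @examples
#' parse_formula("C3H7NO3")   # serine
#' parse_formula("C6H13O9P")  # glucose 6-phosphate
#' @export
parse_formula <- function(text) {
  if (inherits(text, "elemental_formula")) return(text)
  if (is.numeric(text)) return(as_formula_counts(text))
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string")
  tokens <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1L]]
  if (paste(tokens, collapse = "") != text)
    stop("malformed formula string: ", sQuote(text))
  counts <- integer(0)
  for (tok in tokens) {
    el <- sub("[0-9]*$", "", tok)
    num <- sub("^[A-Za-z]+", "", tok)
    if (!el %in% supported_elements())
      stop("unsupported element ", sQuote(el), " in formula ", sQuote(text))
    n <- if (nzchar(num)) as.integer(num) else 1L
    if (n == 0L)
      stop("zero atom count for element ", sQuote(el), " in formula ", sQuote(text))
    counts[el] <- if (el %in% names(counts)) counts[[el]] + n else n
  }
  structure(counts, class = "elemental_formula")
}

as_formula_counts <- function(x) {
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("formula counts must be named by element symbol")
  bad <- setdiff(names(x), supported_elements())
  if (length(bad))
    stop("unsupported element(s): ", paste(bad, collapse = ", "))
  if (any(x != round(x)) || any(x < 1))
    stop("atom counts must be positive integers")
  structure(stats::setNames(as.integer(x), names(x)), class = "elemental_formula")
}

#' @export
format.elemental_formula <- function(x, ...) {
  paste0(names(x), ifelse(unclass(x) > 1L, unclass(x), ""), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula> ", format(x), "\n", sep = "")
  invisible(x)
}
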