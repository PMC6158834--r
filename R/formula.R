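#' Parse a Hill-notation elemental formula
#'
#' Accepts formulas such as `"C6H12O6"` or `"CHO2R"` and returns element
#' counts. Elements are one capital letter optionally followed by
#' lowercase letters; an omitted count means 1. Wildcard elements (generic
#' R-groups: `R`, `X`, or any `R`-prefixed pseudo-element such as `Ra` is
#' a real element, so only bare `R` and `X` count as wildcards) mark
#' polymeric/underspecified species; such formulas parse but are flagged
#' so mass-balance checking can report them as undetermined rather than
#' (im)balanced.
#'
#' @param formula formula string (or `NA`).
#' @return `NULL` for missing input; otherwise a list with `counts`
#'   (named integer vector) and `wildcard` (logical). Unparseable text
#'   raises an error.
#' @export
parse_formula <- function(formula) {
  if (is.null(formula) || length(formula) == 0 || is.na(formula) || !nzchar(formula)) {
    return(NULL)
  }
  pat <- "([A-Z][a-z]*)([0-9]*)"
  m <- gregexpr(pat, formula, perl = TRUE)[[1]]
  toks <- regmatches(formula, gregexpr(pat, formula, perl = TRUE))[[1]]
  if (paste(toks, collapse = "") != formula) {
    stop("unparseable formula: ", formula)
  }
  els <- sub("^([A-Z][a-z]*).*$", "\\1", toks)
  cnts <- as.integer(ifelse(grepl("[0-9]+$", toks), sub("^[A-Za-z]+", "", toks), "1"))
  counts <- tapply(cnts, els, sum)
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(counts = counts, wildcard = any(names(counts) %in% c("R", "X")))
}
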