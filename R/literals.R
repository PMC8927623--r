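#' Literals with strong negation
#'
#' Literals are plain strings over an atom alphabet; strong negation is
#' written with a leading `~` (so `"emergency"` and `"~emergency"` are
#' complementary). Only single negation is stored: `lit_complement()` strips
#' an existing `~` rather than stacking a second one, so
#' `lit_complement(lit_complement(x)) == x`.
#'
#' @param x character vector of literals.
#' @return `lit_complement()` the complementary literals; `lit_atom()` the
#'   atom names without the negation sign; `lit_negated()` a logical vector.
#' @examples
#' lit_complement(c("emergency", "~emergency"))
#' lit_atom("~co_alert")
#' @export
lit_complement <- function(x) {
  stopifnot(is.character(x))
  ifelse(startsWith(x, "~"), substring(x, 2L), paste0("~", x))
}

#' @rdname lit_complement
#' @export
lit_atom <- function(x) {
  stopifnot(is.character(x))
  sub("^~", "", x)
}

#' @rdname lit_complement
#' @export
lit_negated <- function(x) {
  stopifnot(is.character(x))
  startsWith(x, "~")
}

check_literal <- function(x, what = "literal") {
  ok <- is.character(x) & nzchar(lit_atom(x)) & !grepl("^~~", x) &
    !grepl("[[:space:]:]", x)
  if (!all(ok)) {
    abort(paste0("invalid ", what, ": ", paste(x[!ok], collapse = ", ")))
  }
  invisible(x)
}
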