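#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed condition
#' @noRd
pb_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "parabuffer_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Sample one element safely (no 1:n surprise for length-1 input)
#' @noRd
sample1 <- function(x) if (length(x) == 1L) x else x[[sample.int(length(x), 1L)]]

#' Unordered pair key, order-invariant
#' @noRd
pair_key <- function(a, b) {
  ifelse(as.character(a) < as.character(b),
         paste(a, b, sep = "\r"),
         paste(b, a, sep = "\r"))
}
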