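#' @keywords internal
#' @noRd
.err <- function(class, message) {
  stop(structure(
    class = c(class, "its2cbcError", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

# Error vocabulary used across the package:
#   formatError            malformed input file (empty, duplicate ids, ...)
#   alignmentError         unequal lengths in an aligned set
#   structureError         unbalanced / non-nested dot-bracket
#   crossReferenceError    id mismatch between paired inputs
#   annotationError        helix annotation inconsistent with a structure
#   usageError             argument outside its contract
#   undefinedDistanceError no comparable positions between two sequences
#   dataError              invalid measurement values
#   specError              infeasible simulation specification

#' @noRd
.assertFlag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    .err("usageError", sprintf("'%s' must be TRUE or FALSE", name))
  invisible(x)
}

#' @noRd
.assertNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    .err("usageError",
         sprintf("'%s' must be a single number in [%s, %s]", name, lower, upper))
  invisible(x)
}
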