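#' Division-fate probabilities for a progenitor cell
#'
#' A dividing progenitor (P) cell produces two daughters that are both
#' proliferative (PP), one proliferative and one differentiated (PD), or both
#' differentiated (DD), with probabilities `a`, `b` and `c`. These three
#' numbers drive every homeostasis-side distribution in the package.
#'
#' @param a Probability of a PP division (two proliferating daughters).
#' @param b Probability of a PD division.
#' @param c Probability of a DD division (two post-mitotic daughters).
#' @param tol Numeric tolerance for the simplex constraint `a + b + c = 1`.
#'
#' @return An object of class `fate_probs`: a named list with elements
#'   `a`, `b`, `c`.
#' @examples
#' fate_probabilities(0.415, 0.278, 0.307)
#' @export
fate_probabilities <- function(a, b, c, tol = 1e-8) {
  vals <- c(a = a, b = b, c = c)
  if (!is.numeric(vals) || length(vals) != 3L || anyNA(vals)) {
    stop("`a`, `b` and `c` must be single non-missing numeric values.",
         call. = FALSE)
  }
  if (any(vals < -tol) || any(vals > 1 + tol)) {
    stop("fate probabilities must lie in [0, 1].", call. = FALSE)
  }
  if (abs(sum(vals) - 1) > tol) {
    stop("fate probabilities must satisfy a + b + c = 1 (got sum = ",
         format(sum(vals)), ").", call. = FALSE)
  }
  structure(list(a = unname(a), b = unname(b), c = unname(c)),
            class = "fate_probs")
}

#' @export
print.fate_probs <- function(x, digits = 4, ...) {
  cat("<fate_probs>  a (PP) = ", format(x$a, digits = digits),
      ",  b (PD) = ", format(x$b, digits = digits),
      ",  c (DD) = ", format(x$c, digits = digits), "\n", sep = "")
  invisible(x)
}

#' Coerce to fate probabilities
#'
#' Accepts an existing `fate_probs` object, a length-3 numeric vector
#' (in the order a, b, c) or a list with elements `a`, `b`, `c`.
#'
#' @param x Object to coerce.
#' @param tol Simplex tolerance passed to [fate_probabilities()].
#' @return A `fate_probs` object.
#' @export
as_fate_probs <- function(x, tol = 1e-8) {
  if (inherits(x, "fate_probs")) return(x)
  if (is.numeric(x) && length(x) == 3L) {
    return(fate_probabilities(x[[1]], x[[2]], x[[3]], tol = tol))
  }
  if (is.list(x) && all(c("a", "b", "c") %in% names(x))) {
    return(fate_probabilities(x$a, x$b, x$c, tol = tol))
  }
  stop("cannot interpret `x` as fate probabilities.", call. = FALSE)
}
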