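#' Contact-probability transform parameters
#'
#' The exponential transform that maps a (KR-balanced) Hi-C read count `v`
#' into a contact probability `CP = exp(-a / (v + delta))`. `a` controls how
#' sharply low and high counts are separated; `delta` is a small offset that
#' keeps the transform finite at `v = 0`.
#'
#' @param a Positive coefficient multiplier. Default 8.
#' @param delta Small positive offset, must lie in (0, 1e-6). Default 1e-10.
#' @return An object of class `transform_params`.
#' @examples
#' p <- transform_params()
#' to_probability(8, p)  # exp(-1)
#' @export
transform_params <- function(a = 8, delta = 1e-10) {
  stopifnot(is.numeric(a), length(a) == 1, is.finite(a), a > 0)
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0 || delta >= 1e-6)
    stop("`delta` must be a positive number smaller than 1e-6")
  structure(list(a = a, delta = delta), class = "transform_params")
}

#' @export
print.transform_params <- function(x, ...) {
  cat(sprintf("contact-probability transform: CP = exp(-%g / (v + %g))\n", x$a, x$delta))
  invisible(x)
}

#' Transform read counts to contact probabilities
#'
#' Applies `CP = exp(-a / (v + delta))` elementwise. The transform is strictly
#' increasing in `v`, maps 0 to (numerically) 0 and large counts towards 1,
#' and is exactly inverted by [from_probability()].
#'
#' @param v Numeric vector/matrix of non-negative read counts, or a
#'   `contact_matrix` of kind `"raw_counts"`.
#' @param params A [transform_params()] object.
#' @return Probabilities with the same shape as `v`; for a `contact_matrix`
#'   input, a `contact_matrix` of kind `"probability"`.
#' @export
to_probability <- function(v, params = transform_params()) {
  stopifnot(inherits(params, "transform_params"))
  if (inherits(v, "contact_matrix")) {
    if (v$kind != "raw_counts")
      stop("contact matrix is already of kind 'probability'")
    out <- v
    out$values <- to_probability(v$values, params)
    out$kind <- "probability"
    return(out)
  }
  if (any(!is.finite(v)))
    stop("non-finite read count")
  if (any(v < 0))
    stop("negative read count")
  exp(-params$a / (v + params$delta))
}

#' Invert the contact-probability transform
#'
#' Recovers the read count `CS = a / (-log(cp)) - delta` from a contact
#' probability. `cp = 0` is clamped to a read count of 0 (counts cannot be
#' negative); `cp = 1` would correspond to an infinite count and is an error.
#'
#' @param cp Numeric vector/matrix of probabilities in `[0, 1)`, or a
#'   `contact_matrix` of kind `"probability"`.
#' @param params A [transform_params()] object.
#' @return Read counts of the same shape (or a raw-count `contact_matrix`).
#' @export
from_probability <- function(cp, params = transform_params()) {
  stopifnot(inherits(params, "transform_params"))
  if (inherits(cp, "contact_matrix")) {
    if (cp$kind != "probability")
      stop("contact matrix is of kind 'raw_counts'")
    out <- cp
    out$values <- from_probability(cp$values, params)
    out$kind <- "raw_counts"
    return(out)
  }
  bad <- !is.na(cp) & (cp < 0 | cp >= 1)
  if (any(bad))
    stop("contact probabilities must lie in [0, 1)")
  cs <- params$a / (-log(cp)) - params$delta
  cs[!is.na(cp) & cp == 0] <- 0
  pmax(cs, 0)
}
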