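#' Fractional polynomial machinery
#'
#' Fractional polynomials (FPs) extend ordinary polynomials with the power set
#' S = \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}, where power 0 denotes the natural
#' logarithm and a repeated power p contributes both x^p and x^p * log(x).
#' FPs of degree 1 or 2 are the non-linear basis used for the trajectory
#' models; the argument must be strictly positive, so times measured relative
#' to first pregnancy (which span negative values) are first mapped through an
#' affine positivity transform x = (t - shift) / scale that is fixed once per
#' analysis window and reused identically for fitting and prediction.
#'
#' @name fp-basis
NULL

#' The fractional-polynomial power set
#' @export
FP_POWERS <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' Construct a fractional polynomial specification
#'
#' @param powers numeric vector of length 1 or 2 with values from
#'   [FP_POWERS]. A repeated power `c(p, p)` denotes the basis
#'   (x^p, x^p log x).
#' @param shift,scale constants of the positivity transform
#'   `x = (t - shift) / scale`; `scale` must be positive.
#' @return an object of class `fp_spec` with fields `degree`, `powers`,
#'   `shift`, `scale`.
#' @export
fp_spec <- function(powers, shift = 0, scale = 1) {
  powers <- as.numeric(powers)
  if (!length(powers) %in% c(1L, 2L))
    stop("an FP specification has degree 1 or 2", call. = FALSE)
  if (!all(powers %in% FP_POWERS))
    stop("powers must belong to {", paste(FP_POWERS, collapse = ", "), "}",
         call. = FALSE)
  if (length(powers) == 2L && powers[1] > powers[2])
    powers <- sort(powers)
  if (!is.finite(shift)) stop("'shift' must be finite", call. = FALSE)
  if (!is.finite(scale) || scale <= 0)
    stop("'scale' must be a positive number", call. = FALSE)
  structure(
    list(degree = length(powers), powers = powers,
         shift = shift, scale = scale),
    class = "fp_spec"
  )
}

#' @export
print.fp_spec <- function(x, ...) {
  cat(sprintf("FP spec: degree %d, powers (%s), x = (t - %g) / %g\n",
              x$degree, paste(format(x$powers), collapse = ", "),
              x$shift, x$scale))
  invisible(x)
}

#' @export
format.fp_spec <- function(x, ...) {
  sprintf("FP(%s; shift=%g, scale=%g)",
          paste(x$powers, collapse = ","), x$shift, x$scale)
}

# single FP term on the already-transformed positive argument
fp_term <- function(x, p) {
  if (p == 0) log(x) else x^p
}

#' Evaluate the fractional polynomial basis
#'
#' @param t numeric vector of raw axis values (time in years, or age).
#' @param spec an [fp_spec()].
#' @return a numeric matrix with `length(t)` rows and `spec$degree` columns.
#'   Column names are `fp1`, `fp2`. Non-positive transformed values are an
#'   error, never silently clipped.
#' @export
fp_transform <- function(t, spec) {
  stopifnot(inherits(spec, "fp_spec"))
  x <- (as.numeric(t) - spec$shift) / spec$scale
  if (any(!is.finite(x)))
    stop("non-finite axis values in fp_transform()", call. = FALSE)
  if (any(x <= 0))
    stop("positivity transform produced non-positive values; ",
         "axis values fall outside the window the FP constants were fixed on",
         call. = FALSE)
  p <- spec$powers
  if (spec$degree == 1L) {
    out <- cbind(fp1 = fp_term(x, p[1]))
  } else if (p[1] == p[2]) {
    b1 <- fp_term(x, p[1])
    out <- cbind(fp1 = b1, fp2 = b1 * log(x))
  } else {
    out <- cbind(fp1 = fp_term(x, p[1]), fp2 = fp_term(x, p[2]))
  }
  out
}

#' Enumerate candidate fractional polynomial models
#'
#' Degree 1 yields the 8 single powers; degree 2 adds the 8 repeated powers
#' and the 28 unordered distinct pairs (36 in all), for a combined list of 44
#' candidates in a fixed deterministic order (degree 1 first, then degree 2 in
#' lexicographic power order).
#'
#' @param max_degree 1 or 2.
#' @param shift,scale positivity constants stored in every returned spec.
#' @return list of [fp_spec()] objects.
#' @export
enumerate_fp_models <- function(max_degree = 2, shift = 0, scale = 1) {
  if (!max_degree %in% c(1, 2))
    stop("'max_degree' must be 1 or 2", call. = FALSE)
  specs <- lapply(FP_POWERS, fp_spec, shift = shift, scale = scale)
  if (max_degree == 2) {
    k <- length(FP_POWERS)
    for (i in seq_len(k)) {
      for (j in i:k) {
        specs[[length(specs) + 1L]] <-
          fp_spec(c(FP_POWERS[i], FP_POWERS[j]), shift = shift, scale = scale)
      }
    }
  }
  specs
}

#' Fix the positivity transform for an analysis window
#'
#' Chooses `shift = min(times) - margin` and a scale placing the transformed
#' values in (0, 2.5], a conventional range that keeps powers up to 3 and
#' down to -2 numerically tame. The same constants must be reused for
#' prediction; [fit_trajectory()] therefore computes them from the window
#' endpoints, not from the observed measurement times.
#'
#' @param times numeric vector (typically the two window endpoints).
#' @param margin positive gap between `min(times)` and the transform origin.
#' @return list with `shift` and `scale`.
#' @export
make_positive <- function(times, margin = 1) {
  times <- as.numeric(times)
  if (!length(times) || any(!is.finite(times)))
    stop("'times' must be a non-empty finite vector", call. = FALSE)
  if (!is.finite(margin) || margin <= 0)
    stop("'margin' must be positive", call. = FALSE)
  shift <- min(times) - margin
  spread <- max(times) - min(times)
  scale <- if (spread == 0) 1 else (max(times) - shift) / 2.5
  list(shift = shift, scale = scale)
}
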