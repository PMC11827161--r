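#' Two-level linear mixed models by profiled maximum likelihood
#'
#' The trajectory models are two-level linear models
#' \deqn{y_{ij} = x_{ij}'\beta + u_i + e_{ij}, \quad u_i \sim N(0,\sigma_u^2),
#'   \; e_{ij} \sim N(0,\sigma_e^2)}
#' with woman-level random intercepts (and, as a sensitivity variant, a
#' bivariate intercept + slope random effect). Estimation is by full maximum
#' likelihood, not REML, so deviances are comparable across fixed-effect
#' structures during fractional-polynomial selection and interaction testing.
#'
#' The compound-symmetry within-woman covariance admits closed-form
#' generalised least squares given the variance ratio
#' \eqn{\lambda = \sigma_u^2/\sigma_e^2}: all quantities reduce to per-group
#' sufficient statistics (column sums of the design and outcome within woman),
#' so one likelihood evaluation costs O(p^2) after a single pass over the
#' data. The profiled deviance in \eqn{\lambda} is minimised on a log grid and
#' refined with golden-section search.
#'
#' @name mixed-model
NULL

# Per-group sufficient statistics for the random-intercept likelihood.
ri_suffstats <- function(X, y, groups) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y) || length(groups) != length(y))
    stop("rows of 'X', 'y' and 'groups' must align", call. = FALSE)
  g <- factor(groups)
  S <- rowsum(X, g)                      # group column sums of X
  sy <- rowsum(y, g)[, 1L]
  n_i <- as.numeric(table(g))
  list(XtX = crossprod(X), Xty = crossprod(X, y)[, 1L], yty = sum(y * y),
       S = S, sy = sy, n_i = n_i, N = length(y), G = nlevels(g),
       terms = colnames(X))
}

# Profiled quantities at a given variance ratio lambda = sigma_u^2/sigma_e^2.
# Returns the -2 log-likelihood profiled over beta and sigma_e^2.
ri_profile <- function(st, lambda, want_fit = FALSE) {
  w <- lambda / (1 + st$n_i * lambda)
  A <- st$XtX - crossprod(st$S, st$S * w)
  b <- st$Xty - drop(crossprod(st$S, st$sy * w))
  beta <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(beta)) return(if (want_fit) NULL else Inf)
  yVy <- st$yty - sum(w * st$sy^2)
  rss <- max(yVy - sum(beta * b), 0)
  sigma2 <- max(rss / st$N, 1e-280)      # guard the noise-free limit
  dev <- st$N * log(2 * pi * sigma2) + sum(log1p(st$n_i * lambda)) + st$N
  if (!want_fit) return(dev)
  list(deviance = dev, beta = beta, A = A, sigma2_e = sigma2,
       sigma2_u = lambda * sigma2, lambda = lambda)
}

# Minimise the profiled deviance over log(lambda); returns lambda_hat.
ri_optimise <- function(st, lower = 1e-8, upper = 1e4) {
  grid <- c(0, exp(seq(log(lower), log(upper), length.out = 49)))
  devs <- vapply(grid, function(l) ri_profile(st, l), numeric(1))
  k <- which.min(devs)
  boundary <- FALSE
  if (k == 1L) {
    # interior refinement next to zero, then compare with the boundary
    opt <- stats::optimize(function(ll) ri_profile(st, exp(ll)),
                           interval = log(c(lower / 10, grid[3L])),
                           tol = 1e-10)
    if (opt$objective < devs[1L] - 1e-12) {
      lambda <- exp(opt$minimum)
    } else {
      lambda <- 0
      boundary <- TRUE
    }
  } else {
    if (k == length(grid)) boundary <- TRUE
    lo <- log(grid[max(k - 1L, 2L)])
    hi <- log(grid[min(k + 1L, length(grid))])
    opt <- stats::optimize(function(ll) ri_profile(st, exp(ll)),
                           interval = c(lo, hi), tol = 1e-12)
    # one more contraction for tight oracle agreement
    h <- (hi - lo) / 8
    opt <- stats::optimize(function(ll) ri_profile(st, exp(ll)),
                           interval = c(opt$minimum - h, opt$minimum + h),
                           tol = 1e-12)
    lambda <- exp(opt$minimum)
  }
  list(lambda = lambda, boundary = boundary)
}

check_full_rank <- function(XtX, terms) {
  r <- qr(XtX)$rank
  if (r < ncol(XtX))
    stop("design matrix is rank deficient (rank ", r, " < ", ncol(XtX),
         " columns: ", paste(utils::head(terms, 10), collapse = ", "), " ...)",
         call. = FALSE)
  invisible(TRUE)
}

#' Fit a random-intercept linear model by maximum likelihood
#'
#' @param X numeric design matrix (observations by terms, with column names).
#' @param y numeric outcome vector.
#' @param groups grouping identifiers (one level per woman).
#' @return an object of class `ri_fit` with elements `beta`, `vcov_beta`,
#'   `sigma2_u`, `sigma2_e`, `lambda`, `deviance`, `logLik`, `n_obs`,
#'   `n_groups`, `boundary` and `random = "intercept"`.
#' @export
fit_random_intercept <- function(X, y, groups) {
  st <- ri_suffstats(X, y, groups)
  check_full_rank(st$XtX, st$terms)
  opt <- ri_optimise(st)
  fit <- ri_profile(st, opt$lambda, want_fit = TRUE)
  if (is.null(fit))
    stop("random-intercept fit failed: singular GLS system at the optimum",
         call. = FALSE)
  beta <- drop(fit$beta)
  names(beta) <- st$terms
  vcov <- fit$sigma2_e * solve(fit$A)
  vcov <- (vcov + t(vcov)) / 2
  dimnames(vcov) <- list(st$terms, st$terms)
  structure(
    list(beta = beta, vcov_beta = vcov,
         sigma2_u = fit$sigma2_u, sigma2_e = fit$sigma2_e,
         lambda = fit$lambda, deviance = fit$deviance,
         logLik = -fit$deviance / 2,
         n_obs = st$N, n_groups = st$G,
         boundary = opt$boundary, converged = TRUE,
         random = "intercept"),
    class = "ri_fit"
  )
}

# ---- random intercept + slope -------------------------------------------

# Sufficient statistics with a slope covariate s (random effect design [1, s]).
rs_suffstats <- function(X, y, groups, s) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  s <- as.numeric(s)
  if (length(s) != length(y))
    stop("'slope_covariate' must align with the observations", call. = FALSE)
  g <- factor(groups)
  list(XtX = crossprod(X), Xty = crossprod(X, y)[, 1L], yty = sum(y * y),
       S1 = rowsum(X, g), S2 = rowsum(X * s, g),
       sy1 = rowsum(y, g)[, 1L], sy2 = rowsum(y * s, g)[, 1L],
       n_i = as.numeric(table(g)), ss = rowsum(s, g)[, 1L],
       ss2 = rowsum(s * s, g)[, 1L],
       N = length(y), G = nlevels(g), terms = colnames(X))
}

# Profiled -2 log-likelihood at theta = (l11, l21, l22), the lower Cholesky
# factor of the relative (per sigma_e^2) random-effect covariance.
rs_profile <- function(st, theta, want_fit = FALSE) {
  l11 <- abs(theta[1]); l21 <- theta[2]; l22 <- abs(theta[3])
  a <- st$n_i; b <- st$ss; d <- st$ss2
  # M_i = I + t(L) Z_i'Z_i L, closed form 2x2 per group (vectorised)
  M11 <- 1 + (l11 * a + l21 * b) * l11 + (l11 * b + l21 * d) * l21
  M12 <- (l11 * b + l21 * d) * l22
  M22 <- 1 + l22^2 * d
  detM <- M11 * M22 - M12^2
  if (any(detM <= 0) || any(!is.finite(detM)))
    return(if (want_fit) NULL else Inf)
  # C_i = L M_i^{-1} t(L)
  c11 <- l11^2 * M22 / detM
  c12 <- l11 * (l21 * M22 - l22 * M12) / detM
  c22 <- (l21^2 * M22 - 2 * l21 * l22 * M12 + l22^2 * M11) / detM
  A <- st$XtX -
    (crossprod(st$S1, st$S1 * c11 + st$S2 * c12) +
     crossprod(st$S2, st$S1 * c12 + st$S2 * c22))
  bvec <- st$Xty -
    (drop(crossprod(st$S1, c11 * st$sy1 + c12 * st$sy2)) +
     drop(crossprod(st$S2, c12 * st$sy1 + c22 * st$sy2)))
  beta <- tryCatch(solve(A, bvec), error = function(e) NULL)
  if (is.null(beta)) return(if (want_fit) NULL else Inf)
  yVy <- st$yty - sum(c11 * st$sy1^2 + 2 * c12 * st$sy1 * st$sy2 +
                        c22 * st$sy2^2)
  rss <- max(yVy - sum(beta * bvec), 0)
  sigma2 <- max(rss / st$N, 1e-280)
  dev <- st$N * log(2 * pi * sigma2) + sum(log(detM)) + st$N
  if (!want_fit) return(dev)
  L <- matrix(c(l11, l21, 0, l22), 2, 2)
  list(deviance = dev, beta = beta, A = A, sigma2_e = sigma2,
       G_re = sigma2 * tcrossprod(L), theta = c(l11, l21, l22))
}

#' Fit a random-intercept + random-slope linear model by maximum likelihood
#'
#' The random-effect covariance is a 2x2 unstructured matrix for (intercept,
#' slope on `slope_covariate`), parameterised through its Cholesky factor so
#' it stays positive semi-definite; boundary fits (zero slope variance) are
#' admissible and reduce to [fit_random_intercept()].
#'
#' @inheritParams fit_random_intercept
#' @param slope_covariate numeric vector (e.g. the transformed time basis)
#'   carrying the random slope.
#' @return an `ri_fit` object with `random = "slope"`, plus `G_re` (the 2x2
#'   random-effect covariance) and `sigma2_slope`.
#' @export
fit_random_slope <- function(X, y, groups, slope_covariate) {
  st <- rs_suffstats(X, y, groups, slope_covariate)
  check_full_rank(st$XtX, st$terms)
  # start at the intercept-only optimum: guarantees the nested-deviance bound
  ri <- fit_random_intercept(X, y, groups)
  starts <- list(c(sqrt(ri$lambda), 0, 0),
                 c(sqrt(ri$lambda), 0, 0.05),
                 c(max(sqrt(ri$lambda), 0.05), 0.02, 0.2))
  best <- NULL
  for (th0 in starts) {
    o <- stats::optim(th0, function(th) rs_profile(st, th),
                      method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  fit <- rs_profile(st, best$par, want_fit = TRUE)
  if (is.null(fit))
    stop("random-slope fit failed at the optimiser solution", call. = FALSE)
  # never worse than the nested intercept-only model
  if (fit$deviance > ri$deviance) {
    fit <- rs_profile(st, c(sqrt(ri$lambda), 0, 0), want_fit = TRUE)
  }
  beta <- drop(fit$beta)
  names(beta) <- st$terms
  vcov <- fit$sigma2_e * solve(fit$A)
  vcov <- (vcov + t(vcov)) / 2
  dimnames(vcov) <- list(st$terms, st$terms)
  structure(
    list(beta = beta, vcov_beta = vcov,
         sigma2_u = fit$G_re[1, 1], sigma2_e = fit$sigma2_e,
         sigma2_slope = fit$G_re[2, 2], G_re = fit$G_re,
         theta = fit$theta,
         deviance = fit$deviance, logLik = -fit$deviance / 2,
         n_obs = st$N, n_groups = st$G,
         boundary = fit$theta[3] < 1e-6, converged = TRUE,
         random = "slope"),
    class = "ri_fit"
  )
}

#' Population-average prediction from a fitted mixed model
#'
#' Computes `x' beta` and its Wald standard error `sqrt(x' V x)` for one or
#' more term vectors; the random effects enter at their zero mean.
#'
#' @param fit an `ri_fit`.
#' @param x numeric vector conformable with `fit$beta`, or a matrix with one
#'   row per prediction point.
#' @return a data.frame with columns `estimate` and `se`.
#' @export
predict_mean <- function(fit, x) {
  stopifnot(inherits(fit, "ri_fit"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != length(fit$beta))
    stop("term vector has ", ncol(x), " entries; the model has ",
         length(fit$beta), " coefficients", call. = FALSE)
  est <- drop(x %*% fit$beta)
  se <- sqrt(pmax(rowSums((x %*% fit$vcov_beta) * x), 0))
  data.frame(estimate = est, se = se)
}

#' @export
print.ri_fit <- function(x, ...) {
  cat(sprintf("Two-level ML fit (random %s): %d obs in %d groups\n",
              x$random, x$n_obs, x$n_groups))
  cat(sprintf("  deviance %.4f | sigma_u %.4f | sigma_e %.4f%s\n",
              x$deviance, sqrt(x$sigma2_u), sqrt(x$sigma2_e),
              if (x$random == "slope")
                sprintf(" | sigma_slope %.4f", sqrt(x$sigma2_slope)) else ""))
  cat(sprintf("  %d fixed effects%s\n", length(x$beta),
              if (x$boundary) " [variance at boundary]" else ""))
  invisible(x)
}

#' @export
deviance.ri_fit <- function(object, ...) object$deviance

#' @export
logLik.ri_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$beta) +
              if (object$random == "slope") 4L else 2L,
            class = "logLik")
}

#' @export
coef.ri_fit <- function(object, ...) object$beta

#' @export
vcov.ri_fit <- function(object, ...) object$vcov_beta
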