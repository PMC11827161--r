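# Brute-force maximum-likelihood oracle for the two-level random-intercept
# model: builds the full dense block covariance matrix and maximises the
# likelihood by direct numerical optimisation. Used only on tiny instances
# as an independent check of the profiled-likelihood fitter.
bruteforce_ri <- function(X, y, groups) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  N <- length(y)
  idx <- split(seq_len(N), groups)
  nll <- function(p) {
    su2 <- exp(p[1])
    se2 <- exp(p[2])
    V <- diag(se2, N)
    for (ix in idx) V[ix, ix] <- V[ix, ix] + su2
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Xi <- backsolve(ch, X, transpose = TRUE)
    yi <- backsolve(ch, y, transpose = TRUE)
    b <- qr.solve(Xi, yi)
    r <- yi - Xi %*% b
    as.numeric(N * log(2 * pi) + 2 * sum(log(diag(ch))) + crossprod(r))
  }
  o <- stats::optim(c(0, 0), nll,
                    control = list(reltol = 1e-15, maxit = 10000))
  su2 <- exp(o$par[1]); se2 <- exp(o$par[2])
  V <- diag(se2, N)
  for (ix in idx) V[ix, ix] <- V[ix, ix] + su2
  b <- solve(t(X) %*% solve(V, X), t(X) %*% solve(V, y))
  list(beta = drop(b), sigma2_u = su2, sigma2_e = se2, deviance = o$value)
}

# simulate a small random-intercept data set with known parameters
sim_ri_data <- function(n_groups, n_per, beta, sd_u, sd_e, seed,
                        p = length(beta)) {
  set.seed(seed)
  g <- rep(seq_len(n_groups), each = n_per)
  X <- cbind(1, matrix(rnorm(n_groups * n_per * (p - 1)), ncol = p - 1))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(p - 1)))
  y <- drop(X %*% beta) + rep(rnorm(n_groups, 0, sd_u), each = n_per) +
    rnorm(n_groups * n_per, 0, sd_e)
  list(X = X, y = y, g = g)
}
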