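#' Fractional-polynomial trajectory models
#'
#' The estimation pipeline for one outcome, exposure and time axis:
#' fractional-polynomial (FP) degree/power selection on a baseline
#' main-effects model, construction of the three-way interaction design
#' (FP terms x exposure group x pre/post first pregnancy on the time axis;
#' FP terms x exposure group on the age axis), maximum-likelihood
#' random-intercept fit, and marginal trajectory prediction at average
#' covariate values with Wald 95% confidence intervals.
#'
#' FP powers are selected once on the baseline model and then frozen before
#' interactions are added, so power selection does not leak into the group
#' contrasts; one FP specification is used per outcome and axis.
#'
#' @name trajectory-model
NULL

#' Covariates adjusted for in every trajectory model
#' @export
TRAJ_COVARIATES <- c("age_first_pregnancy", "townsend_quintile", "ethnicity",
                     "smoking_ever", "parity", "ever_nonsingleton",
                     "med_antihypertensive", "med_lipid_lowering",
                     "med_hypoglycaemic")

# Covariate design block: indicators for categorical covariates with the
# most frequent level as reference; continuous covariates as given. Returns
# the matrix and the level bookkeeping needed to rebuild it at prediction
# time.
covariate_block <- function(table) {
  n <- nrow(table)
  cols <- list()
  cols$age_first_pregnancy <- table$age_first_pregnancy
  tq <- factor(table$townsend_quintile, levels = 1:5)
  tq_ref <- names(which.max(table(tq)))
  for (lv in setdiff(levels(tq), tq_ref))
    cols[[paste0("townsend", lv)]] <- as.numeric(tq == lv)
  eth <- factor(table$ethnicity)
  eth_ref <- names(which.max(table(eth)))
  for (lv in setdiff(levels(eth), eth_ref))
    cols[[paste0("ethnicity_", lv)]] <- as.numeric(eth == lv)
  cols$smoking_ever <- as.numeric(table$smoking_ever)
  cols$parity <- pmin(table$parity, 5)
  cols$ever_nonsingleton <- as.numeric(table$ever_nonsingleton)
  cols$med_antihypertensive <- as.numeric(table$med_antihypertensive)
  cols$med_lipid_lowering <- as.numeric(table$med_lipid_lowering)
  cols$med_hypoglycaemic <- as.numeric(table$med_hypoglycaemic)
  if (!is.null(table$fasting)) cols$fasting <- as.numeric(table$fasting)
  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  # constant covariate columns are collinear with the intercept; drop them
  keep <- apply(X, 2, function(col) stats::var(col) > 0)
  X[, keep, drop = FALSE]
}

# Trajectory block (without covariates): intercept, FP terms, exposure
# indicators, post indicator and all interactions. `axis_values` are raw
# axis values (t_rel or age); `post` is NULL on the age axis.
trajectory_block <- function(axis_values, group, fpspec, post = NULL) {
  Fb <- fp_transform(axis_values, fpspec)
  colnames(Fb) <- paste0("fp", seq_len(ncol(Fb)))
  glev <- levels(group)
  G <- NULL
  for (lv in glev[-1])
    G <- cbind(G, as.numeric(group == lv))
  colnames(G) <- paste0("grp_", gsub("[^0-9A-Za-z]", "p", glev[-1]))
  X <- cbind(`(Intercept)` = rep(1, length(axis_values)), Fb, G)
  for (j in seq_len(ncol(Fb))) for (k in seq_len(ncol(G)))
    X <- cbind(X, stats::setNames(Fb[, j] * G[, k], NULL))
  nm <- c(colnames(Fb), colnames(G),
          as.vector(t(outer(colnames(Fb), colnames(G), paste, sep = ":"))))
  if (!is.null(post)) {
    P <- as.numeric(post)
    X <- cbind(X, P)
    nm <- c(nm, "post")
    for (j in seq_len(ncol(Fb))) { X <- cbind(X, Fb[, j] * P) }
    nm <- c(nm, paste0(colnames(Fb), ":post"))
    for (k in seq_len(ncol(G))) { X <- cbind(X, G[, k] * P) }
    nm <- c(nm, paste0(colnames(G), ":post"))
    for (j in seq_len(ncol(Fb))) for (k in seq_len(ncol(G))) {
      X <- cbind(X, Fb[, j] * G[, k] * P)
    }
    nm <- c(nm, as.vector(t(outer(colnames(Fb), colnames(G),
                                  function(a, b) paste0(a, ":", b, ":post")))))
  }
  colnames(X) <- c("(Intercept)", nm)
  X
}

#' Build the full design matrix for a trajectory model
#'
#' On the time axis the columns are: intercept; FP terms f_k(t); exposure
#' indicators A (reference = comparator); post indicator P (t_rel > 0); all
#' two-way products f_k:A, f_k:P, A:P; all three-way products f_k:A:P; then
#' the adjustment covariates (fasting for glucose only). On the age axis the
#' pre/post terms are omitted.
#'
#' @param table an `analysis_table`.
#' @param fpspec an [fp_spec()] with stored positivity constants.
#' @param axis `"time_rel"` or `"age"`.
#' @return list with the design matrix `X`, outcome `y`, `groups`,
#'   `group_levels` and the covariate column means `covariate_means`.
#' @export
build_design <- function(table, fpspec, axis = c("time_rel", "age")) {
  axis <- match.arg(axis)
  group <- droplevels(table$exposure_group)
  if (nlevels(group) < 2L)
    stop("the exposure must have at least two non-empty groups",
         call. = FALSE)
  av <- if (axis == "time_rel") table$t_rel else table$age
  Xt <- trajectory_block(av, group, fpspec,
                         post = if (axis == "time_rel") table$post else NULL)
  Xc <- covariate_block(table)
  X <- cbind(Xt, Xc)
  if (any(colSums(abs(Xt)) == 0))
    stop("design contains an all-zero trajectory column ",
         "(degenerate exposure group?)", call. = FALSE)
  list(X = X, y = table$value, groups = table$woman_id,
       group_levels = levels(group),
       covariate_means = colMeans(Xc),
       n_trajectory_cols = ncol(Xt), axis = axis)
}

#' Select the best-fitting fractional polynomial
#'
#' Fits every candidate FP of degree 1 and 2 in a baseline random-intercept
#' model (FP terms, their products with the post indicator on the time
#' axis, exposure main effects, the post indicator and covariates) and
#' picks the best candidate within each degree by deviance; degree 2
#' replaces degree 1 only when its deviance improvement exceeds the
#' chi-square critical value on 2 df (the conventional closed test). Ties
#' resolve to the lower degree, then enumeration order. Candidates that
#' fail to fit are skipped with a warning.
#'
#' @param table an `analysis_table`.
#' @param axis `"time_rel"` or `"age"`.
#' @param max_degree 1 or 2.
#' @param min_rows minimum number of rows required.
#' @return the selected [fp_spec()]; the candidate deviance table is
#'   attached as attribute `"candidates"`.
#' @export
select_fp <- function(table, axis = c("time_rel", "age"), max_degree = 2,
                      min_rows = 50) {
  axis <- match.arg(axis)
  if (nrow(table) < min_rows)
    stop("too few rows (", nrow(table), ") for FP selection", call. = FALSE)
  window <- attr(table, "window")
  mp <- if (axis == "time_rel") make_positive(window) else
    list(shift = 0, scale = 10)   # conventional age/10 scaling
  cands <- enumerate_fp_models(max_degree, shift = mp$shift,
                               scale = mp$scale)
  group <- droplevels(table$exposure_group)
  av <- if (axis == "time_rel") table$t_rel else table$age
  Gcols <- stats::model.matrix(~g, data.frame(g = group))[, -1, drop = FALSE]
  base <- cbind(`(Intercept)` = 1, Gcols,
                if (axis == "time_rel") cbind(post = as.numeric(table$post)),
                covariate_block(table))
  devs <- rep(NA_real_, length(cands))
  for (i in seq_along(cands)) {
    Fb <- fp_transform(av, cands[[i]])
    # on the time axis the FP terms interact with the pre/post indicator,
    # as in the final model: selecting powers on a single compromise shape
    # makes near-equivalent bases interchangeable and the choice unstable
    if (axis == "time_rel") {
      Fp <- Fb * as.numeric(table$post)
      colnames(Fp) <- paste0(colnames(Fb), ":post")
      Fb <- cbind(Fb, Fp)
    }
    fit <- tryCatch(
      fit_random_intercept(cbind(Fb, base), table$value, table$woman_id),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning("FP candidate ", format(cands[[i]]), " failed to fit; skipped",
              call. = FALSE)
      next
    }
    devs[i] <- fit$deviance
  }
  if (all(is.na(devs)))
    stop("no FP candidate could be fitted", call. = FALSE)
  degree <- vapply(cands, `[[`, numeric(1), "degree")
  # degree chosen by the conventional closed test: the best degree-2 model
  # replaces the best degree-1 model only when its deviance improvement
  # exceeds the chi-square critical value on 2 df; ties and non-significant
  # gains resolve to the lower degree, then enumeration order
  best1 <- order(ifelse(degree == 1, devs, Inf), seq_along(cands))[1L]
  best <- best1
  if (max_degree == 2 && any(degree == 2 & !is.na(devs))) {
    best2 <- order(ifelse(degree == 2, devs, Inf), seq_along(cands))[1L]
    if (is.na(devs[best1]) ||
        devs[best1] - devs[best2] > stats::qchisq(0.95, 2))
      best <- best2
  }
  out <- cands[[best]]
  attr(out, "candidates") <- data.frame(
    powers = vapply(cands, function(s) paste(s$powers, collapse = ","), ""),
    degree = degree, deviance = devs)
  out
}

#' Fit the full trajectory model for one outcome and exposure
#'
#' Runs FP selection on the baseline model, freezes the chosen powers,
#' builds the interaction design and fits the two-level model by maximum
#' likelihood. Covariate means are stored from the fitting rows for marginal
#' prediction.
#'
#' @param table an `analysis_table` built by [build_analysis_table()].
#' @param axis `"time_rel"` or `"age"`.
#' @param max_degree maximum FP degree (1 or 2).
#' @param random `"intercept"` or `"slope"` (random slope on the first FP
#'   term, the systolic-BP sensitivity analysis).
#' @param fpspec optionally, a pre-selected [fp_spec()] to reuse (e.g. to
#'   share one specification across exposures for the same outcome/axis).
#' @return an object of class `trajectory_model`.
#' @export
fit_trajectory <- function(table, axis = c("time_rel", "age"),
                           max_degree = 2,
                           random = c("intercept", "slope"),
                           fpspec = NULL) {
  axis <- match.arg(axis)
  random <- match.arg(random)
  stage <- "fp_selection"
  out <- tryCatch({
    if (is.null(fpspec)) fpspec <- select_fp(table, axis, max_degree)
    stage <- "design"
    d <- build_design(table, fpspec, axis)
    stage <- "fit"
    fit <- if (random == "intercept") {
      fit_random_intercept(d$X, d$y, d$groups)
    } else {
      fit_random_slope(d$X, d$y, d$groups,
                       slope_covariate = fp_transform(
                         if (axis == "time_rel") table$t_rel else table$age,
                         fpspec)[, 1L])
    }
    structure(
      list(outcome = attr(table, "outcome"),
           exposure = attr(table, "exposure"),
           axis = axis, fpspec = fpspec, fit = fit,
           group_levels = d$group_levels,
           covariate_means = d$covariate_means,
           window = attr(table, "window"),
           axis_range = range(if (axis == "time_rel") table$t_rel
                              else table$age),
           eligibility = attr(table, "eligibility"),
           n_obs = fit$n_obs, n_women = fit$n_groups,
           n_excluded_by_mask = attr(table, "n_excluded_by_mask")),
      class = "trajectory_model")
  }, error = function(e) {
    stop("trajectory model failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  out
}

#' @export
print.trajectory_model <- function(x, ...) {
  cat(sprintf("Trajectory model: %s by %s (%s axis)\n",
              x$outcome, x$exposure, x$axis))
  cat(sprintf("  FP powers (%s) | groups: %s\n",
              paste(x$fpspec$powers, collapse = ", "),
              paste(x$group_levels, collapse = ", ")))
  cat(sprintf("  %d observations, %d women | deviance %.2f\n",
              x$n_obs, x$n_women, x$fit$deviance))
  invisible(x)
}

# Term vectors for a set of grid points for one exposure group, with
# covariates at their stored means.
term_rows <- function(model, grid, group) {
  glev <- model$group_levels
  if (!group %in% glev)
    stop("unknown exposure group '", group, "'", call. = FALSE)
  gfac <- factor(rep(group, length(grid)), levels = glev)
  Xt <- trajectory_block(grid, gfac, model$fpspec,
                         post = if (model$axis == "time_rel") grid > 0)
  Xc <- matrix(model$covariate_means, nrow = length(grid),
               ncol = length(model$covariate_means), byrow = TRUE,
               dimnames = list(NULL, names(model$covariate_means)))
  cbind(Xt, Xc)
}

#' Predict group trajectories with 95% confidence bands
#'
#' For every group and grid point, assembles the term vector (FP basis,
#' group indicators, post indicator for points after the first pregnancy,
#' covariates at their means over the fitting rows) and computes the
#' population-average prediction with a Wald 95% interval
#' (estimate +/- 1.96 SE).
#'
#' @param model a `trajectory_model`.
#' @param grid numeric axis values within the model window.
#' @param groups subset of group labels (default: all).
#' @return data.frame with `group`, `axis_value`, `estimate`, `se`,
#'   `lower`, `upper`.
#' @export
predict_trajectories <- function(model, grid = NULL, groups = NULL) {
  stopifnot(inherits(model, "trajectory_model"))
  if (is.null(grid)) {
    grid <- if (model$axis == "time_rel")
      seq(model$window[1], model$window[2], by = 0.5)
    else seq(ceiling(model$axis_range[1]), floor(model$axis_range[2]), by = 1)
  }
  if (model$axis == "time_rel" &&
      (min(grid) < model$window[1] - 1e-9 ||
       max(grid) > model$window[2] + 1e-9))
    stop("prediction grid outside the model window [",
         model$window[1], ", ", model$window[2], "]", call. = FALSE)
  if (is.null(groups)) groups <- model$group_levels
  out <- lapply(groups, function(g) {
    pm <- predict_mean(model$fit, term_rows(model, grid, g))
    data.frame(group = g, axis_value = grid, estimate = pm$estimate,
               se = pm$se,
               lower = pm$estimate - 1.96 * pm$se,
               upper = pm$estimate + 1.96 * pm$se)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Between-group difference curve with 95% confidence band
#'
#' The difference in predicted means between two groups at each grid point;
#' the covariate means are identical in both term vectors and cancel
#' exactly.
#'
#' @inheritParams predict_trajectories
#' @param group_a,group_b group labels present in the model.
#' @return data.frame with `axis_value`, `difference`, `se`, `lower`,
#'   `upper`.
#' @export
contrast <- function(model, group_a, group_b, grid = NULL) {
  stopifnot(inherits(model, "trajectory_model"))
  if (is.null(grid)) {
    grid <- if (model$axis == "time_rel")
      seq(model$window[1], model$window[2], by = 0.5)
    else seq(ceiling(model$axis_range[1]), floor(model$axis_range[2]), by = 1)
  }
  xa <- term_rows(model, grid, group_a)
  xb <- term_rows(model, grid, group_b)
  pm <- predict_mean(model$fit, xa - xb)
  data.frame(axis_value = grid, difference = pm$estimate, se = pm$se,
             lower = pm$estimate - 1.96 * pm$se,
             upper = pm$estimate + 1.96 * pm$se)
}
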