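#' Synthetic EHR cohort generator
#'
#' Generates a synthetic primary-care cohort — women, pregnancies and long
#' repeated cardiometabolic measurements — with known ground-truth mean
#' trajectories, so the whole estimation pipeline can be validated by
#' parameter recovery without access to licence-restricted real data.
#'
#' The generator emulates the printed structure of a UK primary-care
#' pregnancy cohort: covariate marginals (age at first pregnancy, deprivation
#' quintile, ethnicity, smoking, parity, medication), woman-level
#' any-pregnancy APO prevalences with co-occurrence induced by a shared
#' latent frailty, hospital-linkage missingness of birth-derived flags,
#' an APO-dependent observation process with overdispersed per-woman
#' measurement counts, irregular measurement times spanning 10 years before
#' to 15 years after the first pregnancy (including in-pregnancy windows,
#' which are flagged, not dropped, by the generator), and group-specific true
#' mean curves anchored at published predicted values.
#'
#' @name synthetic-cohort
NULL

#' Measurement outcome types
#' @export
SIM_OUTCOMES <- c("sbp", "dbp", "bmi", "total_chol", "hdl_chol", "glucose")

APO_GROUPS <- c("0", "1", "2", "3+")

# ---- default configuration ----------------------------------------------

new_anchor <- function(g0, offsets) {
  m <- rbind(g0, g0 + offsets[2], g0 + offsets[3], g0 + offsets[4])
  dimnames(m) <- list(APO_GROUPS, c("-10", "0", "10"))
  m
}

#' Default synthetic-cohort configuration
#'
#' Returns the packaged calibration: covariate marginals and woman-level
#' APO prevalence targets taken from the published cohort description; the
#' frailty-class probabilities, loading `gamma`, recurrence boost
#' `rho_recur`, comorbidity boost `delta` and saturation `sat` calibrated
#' once so the derived APO-count distribution matches the published
#' 0/1/2/3+ split; per-outcome observation-process parameters calibrated to
#' the published median repeat counts; and per-group true mean curves that
#' interpolate the published predicted systolic-BP values at 10 years
#' before and after first pregnancy.
#'
#' True curves are, per exposure group and outcome, single fractional
#' polynomials with powers (0, 1) on the transformed time axis,
#' interpolating the three anchor values (at -10, 0 and +10 years) exactly
#' and extending smoothly to +15.
#'
#' @return a list of class `sim_config`.
#' @export
default_sim_config <- function() {
  window <- c(-10, 15)
  mp <- make_positive(window)
  cfg <- list(
    window = window,
    fp = list(powers = c(0, 1), shift = mp$shift, scale = mp$scale),
    marginals = list(
      age_mean = 27.1, age_sd = 6.6, age_bounds = c(14, 45),
      townsend = c(0.2120, 0.2035, 0.2090, 0.2158, 0.1597),
      townsend_missing = 0.0011,
      ethnicity = c(white = 0.865, nonwhite = 0.102, unknown = 0.033),
      smoking = 0.45,
      parity = c(0.4164, 0.2813, 0.1502, 0.0801, 0.0720),
      nonsingleton = 0.011,
      med_antihypertensive = 0.059,
      med_lipid_lowering = 0.003,
      med_hypoglycaemic = 0.010,
      hes_linked = 0.5451
    ),
    apo = list(
      targets = c(gestational_hypertension = 0.094, preeclampsia = 0.040,
                  gestational_diabetes = 0.040, ptb_spontaneous = 0.056,
                  ptb_indicated = 0.031, sga = 0.124, lga = 0.117,
                  stillbirth = 0.007, congenital_anomaly = 0.031,
                  miscarriage_any = 0.186, miscarriage_multiple = 0.006),
      frailty = list(values = c(-10, 0, 1), probs = c(0.15, 0.68, 0.17)),
      gamma = 0.55, rho = -6, rho_recur = 0.42, sat = -0.25, delta = 0.5,
      count_targets = c(`0` = 0.717, `1` = 0.212, `2` = 0.057, `3+` = 0.015)
    ),
    timing = list(gap = c(1, 4), gestation_live = 0.75,
                  gestation_miscarriage = 0.55),
    truth = list(
      sbp = list(
        anchors = matrix(
          c(112.9, 116.3, 119.5,
            115.1, 118.2, 121.2,
            116.8, 120.5, 124.3,
            119.6, 123.2, 127.1),
          nrow = 4, byrow = TRUE,
          dimnames = list(APO_GROUPS, c("-10", "0", "10"))),
        sd_u = 9, sd_e = 8, bounds = c(60, 250),
        effects = c(age = 0.10, townsend = 0.40, smoking = 1.5,
                    parity = -0.30, nonsingleton = 0, nonwhite = -1.0,
                    med_antihypertensive = 6, med_lipid_lowering = 1,
                    med_hypoglycaemic = 1)
      ),
      dbp = list(
        anchors = new_anchor(c(70.0, 72.0, 74.0), c(0, 1.2, 2.5, 4.0)),
        sd_u = 7, sd_e = 6.5, bounds = c(40, 150),
        effects = c(age = 0.06, townsend = 0.25, smoking = 1.0,
                    parity = -0.2, nonsingleton = 0, nonwhite = -0.5,
                    med_antihypertensive = 4, med_lipid_lowering = 0.5,
                    med_hypoglycaemic = 0.5)
      ),
      bmi = list(
        anchors = new_anchor(c(23.0, 24.2, 25.5), c(0, 0.8, 1.8, 3.0)),
        sd_u = 3.5, sd_e = 1.2, bounds = c(13, 70),
        effects = c(age = 0.03, townsend = 0.25, smoking = -0.3,
                    parity = 0.2, nonsingleton = 0, nonwhite = 0.3,
                    med_antihypertensive = 1.5, med_lipid_lowering = 0.8,
                    med_hypoglycaemic = 1.5)
      ),
      total_chol = list(
        anchors = new_anchor(c(4.55, 4.70, 4.90),
                             c(0, 0.10, 0.25, 0.40)),
        sd_u = 0.7, sd_e = 0.45, bounds = c(1.5, 15),
        effects = c(age = 0.01, townsend = 0.02, smoking = 0.10,
                    parity = 0, nonsingleton = 0, nonwhite = 0,
                    med_antihypertensive = 0.1, med_lipid_lowering = 0.6,
                    med_hypoglycaemic = 0.2)
      ),
      hdl_chol = list(
        anchors = new_anchor(c(1.55, 1.52, 1.47),
                             c(0, -0.03, -0.06, -0.10)),
        sd_u = 0.28, sd_e = 0.18, bounds = c(0.3, 5),
        effects = c(age = 0, townsend = -0.01, smoking = -0.06,
                    parity = 0, nonsingleton = 0, nonwhite = 0,
                    med_antihypertensive = 0, med_lipid_lowering = -0.05,
                    med_hypoglycaemic = -0.05)
      ),
      glucose = list(
        anchors = new_anchor(c(4.80, 4.90, 5.05),
                             c(0, 0.10, 0.25, 0.50)),
        sd_u = 0.5, sd_e = 0.6, bounds = c(2, 30),
        effects = c(age = 0.005, townsend = 0.01, smoking = 0.05,
                    parity = 0, nonsingleton = 0, nonwhite = 0.1,
                    med_antihypertensive = 0.05, med_lipid_lowering = 0.05,
                    med_hypoglycaemic = 0.8, fasting = -0.6)
      )
    ),
    obs = list(
      sbp = list(mu = 7.0, size = 1.3, mult = c(1, 1.25, 1.40, 1.55)),
      dbp = list(mu = 7.0, size = 1.3, mult = c(1, 1.25, 1.40, 1.55)),
      bmi = list(mu = 3.6, size = 1.2, mult = c(1, 1.30, 1.45, 1.60)),
      total_chol = list(mu = 0.263, size = 1.0,
                        mult = c(1, 1.45, 1.70, 1.95)),
      hdl_chol = list(mu = 0.263, size = 1.0,
                      mult = c(1, 1.45, 1.70, 1.95)),
      glucose = list(mu = 0.80, size = 1.0, mult = c(1, 1.30, 1.50, 1.70),
                     fasting_prob = 0.35)
    ),
    outcomes = SIM_OUTCOMES
  )
  class(cfg) <- "sim_config"
  cfg
}

check_probs <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-6)
    stop("invalid probability configuration for ", what,
         " (values must be in [0,1] and sum to 1)", call. = FALSE)
  invisible(TRUE)
}

# ---- prevalence calibration ---------------------------------------------

# The latent APO risk factor is a discrete frailty class: each woman draws
# a class value z from a small support (default: protected / average /
# high-risk) and her per-pregnancy APO logits are shifted by gamma * z.
# Calibration integrals are exact finite sums over the classes.
frailty_dist <- function(config) {
  f <- config$apo$frailty
  check_probs(f$probs, "frailty classes")
  if (length(f$values) != length(f$probs))
    stop("frailty values and probs must have equal length", call. = FALSE)
  list(nodes = f$values, weights = f$probs)
}

# Woman-level any-pregnancy prevalence of a per-pregnancy event with
# conditional probability plogis(a + loading * z) given no miscarriage in
# that pregnancy (times an optional extra survival factor, e.g. for events
# restricted to live births), mixed over the frailty classes and the parity
# distribution. The miscarriage probability is a two-state chain (base
# probability, recurrence-boosted once a miscarriage has occurred), handled
# by a small dynamic program. Recurrence boosts on the event itself do not
# enter: the "never experienced" probability only involves first
# occurrences.
woman_prevalence <- function(a, loading, parity_probs, pmc0, pmc1,
                             extra_z = 1, fr) {
  pz <- stats::plogis(a + loading * fr$nodes)
  if (length(extra_z) == 1L) extra_z <- rep(extra_z, length(fr$nodes))
  pars <- seq_along(parity_probs)
  none_z <- vapply(seq_along(fr$nodes), function(i) {
    pk <- extra_z[i] * pz[i]
    w <- c(1, 0)                       # P(no event so far; never mc / ever mc)
    none <- numeric(length(pars))
    for (j in pars) {
      w <- c(w[1] * (1 - pmc0) * (1 - pk),
             w[1] * pmc0 + w[2] * (pmc1 + (1 - pmc1) * (1 - pk)))
      none[j] <- sum(w)
    }
    sum(parity_probs * none)
  }, numeric(1))
  1 - sum(fr$weights * none_z)
}

solve_alpha <- function(target, loading, parity_probs, pmc0, pmc1,
                        extra_z = 1, fr) {
  if (target < 0 || target > 1)
    stop("APO prevalence target outside [0, 1]", call. = FALSE)
  if (target == 0) return(-Inf)
  f <- function(a) woman_prevalence(a, loading, parity_probs, pmc0, pmc1,
                                    extra_z, fr) - target
  stats::uniroot(f, c(-30, 8), tol = 1e-12)$root
}

# Distribution of the number of occurrences of a recurrent per-pregnancy
# event over `par` pregnancies: probability p before the first occurrence,
# p_rec afterwards.
recurrent_count_dist <- function(p, p_rec, par) {
  d <- c(1, rep(0, par))
  for (j in seq_len(par)) {
    nd <- rep(0, par + 1)
    nd[1] <- d[1] * (1 - p)
    nd[2] <- d[1] * p
    for (k in seq_len(par)) if (d[k + 1] > 0) {
      nd[k + 1] <- nd[k + 1] + d[k + 1] * (1 - p_rec)
      if (k + 2 <= par + 1) nd[k + 2] <- nd[k + 2] + d[k + 1] * p_rec
    }
    d <- nd
  }
  d
}

# Miscarriage is modelled as a recurrent event (recurrent pregnancy loss):
# a per-pregnancy base probability plus a recurrence log-odds boost once a
# miscarriage has occurred. The base intercept is solved from the
# any-miscarriage target (recurrence does not affect first occurrences) and
# the boost from the 3+-miscarriage target.
solve_miscarriage <- function(any_target, multi_target, parity_probs) {
  pars <- seq_along(parity_probs)
  if (any_target <= 0)
    return(list(alpha = -Inf, rho = 0))
  f_any <- function(a) {
    p <- stats::plogis(a)
    (1 - sum(parity_probs * (1 - p)^pars)) - any_target
  }
  alpha <- stats::uniroot(f_any, c(-30, 8), tol = 1e-12)$root
  p <- stats::plogis(alpha)
  multi_for <- function(r) {
    prec <- stats::plogis(alpha + r)
    sum(parity_probs * vapply(pars, function(k)
      sum(recurrent_count_dist(p, prec, k)[-(1:3)]), numeric(1)))
  }
  if (multi_target <= 0) {
    r <- 0
  } else if (multi_for(0) >= multi_target) {
    r <- 0
  } else if (multi_for(8) <= multi_target) {
    r <- 8
  } else {
    r <- stats::uniroot(function(r) multi_for(r) - multi_target,
                        c(0, 8), tol = 1e-10)$root
  }
  list(alpha = alpha, rho = r)
}

#' Calibrate per-pregnancy event intercepts to the woman-level targets
#'
#' Solves, by one-dimensional root finding under Gauss-Hermite integration
#' over the latent frailty and the parity distribution, the per-pregnancy
#' logit intercepts that reproduce the configured woman-level any-pregnancy
#' prevalences. Deterministic and cheap; called automatically by
#' [simulate_pregnancies()] when the config has not been calibrated yet.
#'
#' @param config a `sim_config`.
#' @return the config with an `apo$alpha` vector (and miscarriage loading)
#'   filled in.
#' @export
calibrate_sim_config <- function(config) {
  if (!is.null(config$apo$alpha)) return(config)
  fr <- frailty_dist(config)
  pp <- config$marginals$parity
  check_probs(pp, "parity")
  tg <- config$apo$targets
  if (any(tg < 0 | tg > 1))
    stop("APO prevalence targets must lie in [0, 1]", call. = FALSE)
  g <- config$apo$gamma
  mc <- solve_miscarriage(tg[["miscarriage_any"]],
                          tg[["miscarriage_multiple"]], pp)
  pmc0 <- stats::plogis(mc$alpha)
  pmc1 <- stats::plogis(mc$alpha + mc$rho)
  alpha <- c(miscarriage = mc$alpha)
  for (k in c("gestational_hypertension", "preeclampsia",
              "gestational_diabetes", "ptb_spontaneous", "ptb_indicated",
              "sga", "lga", "stillbirth"))
    alpha[[k]] <- solve_alpha(tg[[k]], g, pp, pmc0, pmc1, fr = fr)
  # congenital anomalies are restricted to live births
  psb_z <- stats::plogis(alpha[["stillbirth"]] + g * fr$nodes)
  alpha[["congenital_anomaly"]] <-
    solve_alpha(tg[["congenital_anomaly"]], g, pp, pmc0, pmc1,
                extra_z = 1 - psb_z, fr = fr)
  config$apo$alpha <- alpha
  config$apo$rho_mc <- mc$rho
  config
}

# ---- ground-truth curves -------------------------------------------------

# Solve, per outcome and group, the coefficients of a + b*log(x) + c*x
# interpolating the three anchor values; one smooth curve spans the whole
# window (anchored at -10, 0 and +10 years, extended to +15 by the same
# fractional polynomial).
truth_coefs <- function(config) {
  xs <- (c(-10, 0, 10) - config$fp$shift) / config$fp$scale
  H <- function(x) c(1, log(x), x)
  A <- rbind(H(xs[1]), H(xs[2]), H(xs[3]))
  lapply(config$truth, function(tr) {
    co <- matrix(NA_real_, 4, 3, dimnames = list(APO_GROUPS, NULL))
    for (gi in 1:4) co[gi, ] <- solve(A, tr$anchors[gi, ])
    co
  })
}

#' Evaluate the true group-specific mean curve
#'
#' @param group APO-count group label(s): `"0"`, `"1"`, `"2"`, `"3+"`.
#' @param outcome_type one of [SIM_OUTCOMES].
#' @param t_rel time(s) in years relative to first pregnancy start, within
#'   the configured window.
#' @param config a `sim_config`.
#' @return numeric vector of true mean values; exact at the anchor times.
#' @export
truth_curve <- function(group, outcome_type, t_rel,
                        config = default_sim_config()) {
  if (!outcome_type %in% names(config$truth))
    stop("no truth curve configured for outcome '", outcome_type, "'",
         call. = FALSE)
  t_rel <- as.numeric(t_rel)
  if (any(t_rel < config$window[1] - 1e-9 | t_rel > config$window[2] + 1e-9))
    stop("t_rel outside the simulation window [",
         config$window[1], ", ", config$window[2], "]", call. = FALSE)
  gi <- match(as.character(group), APO_GROUPS)
  if (any(is.na(gi)))
    stop("unknown exposure group; expected one of ",
         paste(APO_GROUPS, collapse = ", "), call. = FALSE)
  co <- truth_coefs(config)[[outcome_type]]
  if (length(gi) == 1L) gi <- rep(gi, length(t_rel))
  x <- (t_rel - config$fp$shift) / config$fp$scale
  unname(co[gi, 1] + co[gi, 2] * log(x) + co[gi, 3] * x)
}

# ---- women ---------------------------------------------------------------

# (mu, sigma) of the underlying normal such that the [lo, hi]-truncated
# distribution has the requested mean and SD.
solve_truncnorm <- function(mean, sd, lo, hi) {
  obj <- function(p) {
    mu <- p[1]; s <- exp(p[2])
    a <- (lo - mu) / s; b <- (hi - mu) / s
    Z <- stats::pnorm(b) - stats::pnorm(a)
    da <- stats::dnorm(a); db <- stats::dnorm(b)
    m <- mu + s * (da - db) / Z
    v <- s^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
    (m - mean)^2 + (sqrt(v) - sd)^2
  }
  o <- stats::optim(c(mean, log(sd)), obj,
                    control = list(reltol = 1e-14, maxit = 2000))
  list(mu = o$par[1], sigma = exp(o$par[2]))
}

rtruncnorm <- function(n, mu, sigma, lo, hi) {
  plo <- stats::pnorm((lo - mu) / sigma)
  phi <- stats::pnorm((hi - mu) / sigma)
  mu + sigma * stats::qnorm(stats::runif(n, plo, phi))
}

#' Simulate the women table
#'
#' @param n number of women (>= 1).
#' @param config a `sim_config`.
#' @param seed integer random seed.
#' @return data.frame with one row per woman: identifiers, baseline
#'   covariates, parity, plus the simulation-internal columns `frailty`
#'   (latent APO risk factor) and `hes_linked` (whether birth-derived flags
#'   are derivable).
#' @export
simulate_women <- function(n, config = default_sim_config(), seed = 1) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  m <- config$marginals
  check_probs(m$townsend, "townsend quintiles")
  check_probs(m$ethnicity, "ethnicity")
  check_probs(m$parity, "parity")
  set.seed(seed)
  tn <- solve_truncnorm(m$age_mean, m$age_sd, m$age_bounds[1],
                        m$age_bounds[2])
  age <- rtruncnorm(n, tn$mu, tn$sigma, m$age_bounds[1], m$age_bounds[2])
  tq <- sample.int(5L, n, replace = TRUE, prob = m$townsend)
  tq[stats::runif(n) < m$townsend_missing] <- NA
  # latent risk class shifting all per-pregnancy APO logits by gamma * z
  fr <- frailty_dist(config)
  z <- sample(fr$nodes, n, replace = TRUE, prob = fr$weights)
  parity <- sample.int(length(m$parity), n, replace = TRUE,
                       prob = m$parity)
  data.frame(
    woman_id = sprintf("W%07d", seq_len(n)),
    age_first_pregnancy = age,
    townsend_quintile = tq,
    ethnicity = sample(names(m$ethnicity), n, replace = TRUE,
                       prob = m$ethnicity),
    smoking_ever = stats::runif(n) < m$smoking,
    parity = parity,
    ever_nonsingleton = stats::runif(n) < m$nonsingleton,
    med_antihypertensive = stats::runif(n) < m$med_antihypertensive,
    med_lipid_lowering = stats::runif(n) < m$med_lipid_lowering,
    med_hypoglycaemic = stats::runif(n) < m$med_hypoglycaemic,
    frailty = z,
    hes_linked = stats::runif(n) < m$hes_linked,
    stringsAsFactors = FALSE
  )
}

# ---- pregnancies ---------------------------------------------------------

#' Simulate the pregnancies table
#'
#' Each woman contributes exactly `parity` pregnancies. Outcomes and APO
#' flags are drawn per pregnancy with logits shifted by the woman's shared
#' latent frailty (loading `gamma`; miscarriage has its own loading) and by
#' a within-woman recurrence boost `rho` once an APO has occurred in an
#' earlier pregnancy. Indicated preterm birth and LGA are drawn
#' conditionally on their mutually exclusive counterparts in a way that
#' preserves the per-pregnancy marginals. Birth-derived flags are set to NA
#' for women without hospital linkage.
#'
#' @param women data.frame from [simulate_women()].
#' @param config a `sim_config` (calibrated on the fly if needed).
#' @param seed integer random seed.
#' @return data.frame with one row per pregnancy.
#' @export
simulate_pregnancies <- function(women, config = default_sim_config(),
                                 seed = 1) {
  config <- calibrate_sim_config(config)
  a <- config$apo$alpha
  g <- config$apo$gamma
  rho_mc <- config$apo$rho_mc
  # same-APO recurrence boost across pregnancies: positive for the
  # clinically recurrent conditions, suppressive for the others
  rho_k <- c(gestational_hypertension = config$apo$rho_recur,
             preeclampsia = config$apo$rho,
             gestational_diabetes = config$apo$rho_recur,
             ptb_spontaneous = config$apo$rho,
             ptb_indicated = config$apo$rho,
             sga = config$apo$rho, lga = config$apo$rho)
  rho_suppress <- min(config$apo$rho, 0)
  sat <- config$apo$sat
  delta <- config$apo$delta
  tm <- config$timing
  set.seed(seed)

  n <- nrow(women)
  z <- women$frailty
  parity <- women$parity
  maxp <- max(parity)
  nhad <- matrix(0L, n, length(APO_FLAGS),
                 dimnames = list(NULL, APO_FLAGS))
  n_mc <- integer(n)
  prev_end <- numeric(n)
  pieces <- vector("list", maxp)

  for (j in seq_len(maxp)) {
    act <- which(parity >= j)
    na <- length(act)
    za <- z[act]
    mc <- stats::runif(na) <
      stats::plogis(a[["miscarriage"]] + rho_mc * (n_mc[act] > 0))
    sb <- stats::runif(na) <
      stats::plogis(a[["stillbirth"]] + g * za)
    sb <- sb & !mc
    # recurrence boost applies to the first repeat only; further repeats
    # are suppressed; first occurrences are dampened (saturation) once a
    # woman has accumulated two or more counted APOs
    ntot <- rowSums(nhad)
    rec_shift <- function(key) {
      nh <- nhad[act, key]
      ifelse(nh == 1L, rho_k[[key]],
             ifelse(nh >= 2L, rho_suppress,
                    sat * (ntot[act] >= 2L)))
    }
    draw_flag <- function(key) {
      p <- stats::plogis(a[[key]] + g * za + rec_shift(key))
      list(p = p, hit = (stats::runif(na) < p) & !mc)
    }
    pe_ <- draw_flag("preeclampsia")
    # gestational hypertension and preeclampsia are competing diagnoses:
    # marginal-preserving conditional draw given no preeclampsia
    gh_p <- stats::plogis(a[["gestational_hypertension"]] + g * za +
                            rec_shift("gestational_hypertension"))
    gh_q <- pmin(gh_p / pmax(1 - pe_$p, 1e-12), 1)
    gh_hit <- (stats::runif(na) < gh_q) & !mc & !pe_$hit
    gd_ <- draw_flag("gestational_diabetes")
    ps_ <- draw_flag("ptb_spontaneous")
    # within-pregnancy comorbidity: trigger T (preeclampsia or gestational
    # diabetes) raises the same-pregnancy odds of its sequel by delta on the
    # logit, with the no-trigger arm rescaled so the marginal is unchanged
    comorbid_q <- function(p_k, p_T, T_hit) {
      q1 <- stats::plogis(stats::qlogis(p_k) + delta)
      q0 <- pmax((p_k - p_T * q1) / pmax(1 - p_T, 1e-12), 0)
      ifelse(T_hit, q1, q0)
    }
    pi_p <- stats::plogis(a[["ptb_indicated"]] + g * za +
                            rec_shift("ptb_indicated"))
    pi_c <- comorbid_q(pi_p, pe_$p, pe_$hit)
    pi_q <- pmin(pi_c / pmax(1 - ps_$p, 1e-12), 1)
    pi_hit <- (stats::runif(na) < pi_q) & !mc & !ps_$hit
    sga_p <- stats::plogis(a[["sga"]] + g * za + rec_shift("sga"))
    sga_c <- comorbid_q(sga_p, pe_$p, pe_$hit)
    sga_hit <- (stats::runif(na) < sga_c) & !mc
    lga_p <- stats::plogis(a[["lga"]] + g * za + rec_shift("lga"))
    lga_c <- comorbid_q(lga_p, gd_$p, gd_$hit)
    lga_q <- pmin(lga_c / pmax(1 - sga_p, 1e-12), 1)
    lga_hit <- (stats::runif(na) < lga_q) & !mc & !sga_hit
    live <- !mc & !sb
    anom <- (stats::runif(na) <
               stats::plogis(a[["congenital_anomaly"]] + g * za)) & live

    t_start <- if (j == 1L) numeric(na) else
      prev_end[act] + stats::runif(na, tm$gap[1], tm$gap[2])
    t_end <- t_start +
      ifelse(mc, tm$gestation_miscarriage, tm$gestation_live)
    prev_end[act] <- t_end

    flags <- cbind(gestational_hypertension = gh_hit,
                   preeclampsia = pe_$hit,
                   gestational_diabetes = gd_$hit,
                   ptb_spontaneous = ps_$hit, ptb_indicated = pi_hit,
                   sga = sga_hit, lga = lga_hit)
    nhad[act, ] <- nhad[act, , drop = FALSE] + flags
    n_mc[act] <- n_mc[act] + mc

    piece <- data.frame(
      woman_id = women$woman_id[act], preg_index = j,
      t_start = t_start, t_end = t_end,
      outcome = ifelse(mc, "miscarriage",
                       ifelse(sb, "stillbirth", "live_birth")),
      stringsAsFactors = FALSE
    )
    piece <- cbind(piece, as.data.frame(flags))
    piece$congenital_anomaly <- anom
    unlinked <- !women$hes_linked[act]
    for (k in c("ptb_spontaneous", "ptb_indicated", "sga", "lga"))
      piece[[k]][unlinked] <- NA
    pieces[[j]] <- piece
  }
  out <- do.call(rbind, pieces)
  out <- out[order(match(out$woman_id, women$woman_id), out$preg_index), ]
  rownames(out) <- NULL
  out
}

# ---- measurements --------------------------------------------------------

# Centred covariate contribution of each woman to a given outcome.
covariate_shift <- function(women, eff, marg) {
  tq_mean <- sum(seq_len(5) * marg$townsend / sum(marg$townsend))
  par_mean <- sum(seq_along(marg$parity) * marg$parity)
  tq <- women$townsend_quintile
  tq[is.na(tq)] <- tq_mean
  s <- eff[["age"]] * (women$age_first_pregnancy - marg$age_mean) +
    eff[["townsend"]] * (tq - tq_mean) +
    eff[["smoking"]] * (women$smoking_ever - marg$smoking) +
    eff[["parity"]] * (women$parity - par_mean) +
    eff[["nonsingleton"]] * (women$ever_nonsingleton - marg$nonsingleton) +
    eff[["nonwhite"]] * ((women$ethnicity == "nonwhite") -
                           marg$ethnicity[["nonwhite"]]) +
    eff[["med_antihypertensive"]] *
      (women$med_antihypertensive - marg$med_antihypertensive) +
    eff[["med_lipid_lowering"]] *
      (women$med_lipid_lowering - marg$med_lipid_lowering) +
    eff[["med_hypoglycaemic"]] *
      (women$med_hypoglycaemic - marg$med_hypoglycaemic)
  as.numeric(s)
}

#' Simulate the long measurement table
#'
#' Per-woman measurement counts follow a gamma-mixed Poisson (negative
#' binomial) whose rate is multiplied by the APO-count-group propensity;
#' times are uniform on the window (a homogeneous base process); values are
#' the group truth curve plus centred covariate effects, a woman-level
#' random intercept and residual noise, with implausible draws rejected and
#' redrawn. Measurements falling inside a pregnancy interval are generated
#' and flagged `in_pregnancy = TRUE` — exclusion is the analyst's job, not
#' the generator's. A fasting flag is generated for glucose only.
#'
#' @param women,pregnancies tables from the paired simulators.
#' @param config a `sim_config`.
#' @param seed integer random seed.
#' @param outcomes subset of [SIM_OUTCOMES] to generate (default all).
#' @return long data.frame: `woman_id`, `outcome_type`, `value`, `t_rel`,
#'   `age`, `in_pregnancy`, `fasting`.
#' @export
simulate_measurements <- function(women, pregnancies,
                                  config = default_sim_config(), seed = 1,
                                  outcomes = NULL) {
  if (is.null(outcomes)) outcomes <- config$outcomes
  bad <- setdiff(outcomes, names(config$truth))
  if (length(bad))
    stop("no truth configuration for outcome(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  set.seed(seed)
  n <- nrow(women)
  profiles <- derive_apo_profiles(pregnancies)
  gi <- as.integer(profiles$n_apos[match(women$woman_id,
                                         profiles$woman_id)])
  co_all <- truth_coefs(config)
  out <- vector("list", length(outcomes))

  for (oi in seq_along(outcomes)) {
    o <- outcomes[[oi]]
    tr <- config$truth[[o]]
    ob <- config$obs[[o]]
    lam <- ob$mu * ob$mult[gi] * stats::rgamma(n, ob$size, rate = ob$size)
    cnt <- stats::rpois(n, lam)
    idx <- rep.int(seq_len(n), cnt)
    M <- length(idx)
    t_rel <- stats::runif(M, config$window[1], config$window[2])
    gg <- gi[idx]
    co <- co_all[[o]]
    x <- (t_rel - config$fp$shift) / config$fp$scale
    truth <- co[gg, 1] + co[gg, 2] * log(x) + co[gg, 3] * x
    shift <- covariate_shift(women, tr$effects, config$marginals)[idx]
    fasting <- rep(NA, M)
    if (o == "glucose") {
      fasting <- stats::runif(M) < ob$fasting_prob
      shift <- shift + tr$effects[["fasting"]] *
        (fasting - ob$fasting_prob)
    }
    u <- stats::rnorm(n, 0, tr$sd_u)[idx]
    base <- truth + shift + u
    e <- stats::rnorm(M, 0, tr$sd_e)
    if (tr$sd_e > 0) {
      for (it in 1:100) {
        v <- base + e
        viol <- which(v < tr$bounds[1] | v > tr$bounds[2])
        if (!length(viol)) break
        e[viol] <- stats::rnorm(length(viol), 0, tr$sd_e)
      }
    }
    value <- base + e
    out[[oi]] <- data.frame(
      woman_id = women$woman_id[idx], outcome_type = o, value = value,
      t_rel = t_rel, age = women$age_first_pregnancy[idx] + t_rel,
      in_pregnancy = in_pregnancy_flag(women$woman_id[idx], t_rel,
                                       pregnancies),
      fasting = fasting, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a complete cohort
#'
#' @inheritParams simulate_women
#' @param outcomes subset of [SIM_OUTCOMES] to generate measurements for.
#' @return list of class `apo_cohort` with `women`, `pregnancies`,
#'   `measurements` and the calibrated `config` (seed recorded).
#' @export
simulate_cohort <- function(n, config = default_sim_config(), seed = 1,
                            outcomes = NULL) {
  config <- calibrate_sim_config(config)
  women <- simulate_women(n, config, seed = seed)
  pregnancies <- simulate_pregnancies(women, config, seed = seed + 1L)
  measurements <- simulate_measurements(women, pregnancies, config,
                                        seed = seed + 2L,
                                        outcomes = outcomes)
  structure(list(women = women, pregnancies = pregnancies,
                 measurements = measurements, config = config, seed = seed),
            class = "apo_cohort")
}

#' @export
print.apo_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d women, %d pregnancies, %d measurements\n",
              nrow(x$women), nrow(x$pregnancies), nrow(x$measurements)))
  invisible(x)
}

#' Write / read a cohort as delimited text
#'
#' Writes `women.csv`, `pregnancies.csv` and `measurements.csv` (comma
#' separated, header row, UTF-8, missing values as empty fields) to a
#' directory; `read_cohort()` reads them back. The same schema is accepted
#' for user-supplied data.
#'
#' @param cohort an `apo_cohort` (or list with the three tables).
#' @param dir directory path.
#' @return `write_cohort()` the directory, invisibly; `read_cohort()` a list
#'   with `women`, `pregnancies`, `measurements`.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  data.table::fwrite(cohort$women, file.path(dir, "women.csv"), na = "")
  data.table::fwrite(cohort$pregnancies, file.path(dir, "pregnancies.csv"),
                     na = "")
  data.table::fwrite(cohort$measurements, file.path(dir, "measurements.csv"),
                     na = "")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  rd <- function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing input file: ", path, call. = FALSE)
    as.data.frame(data.table::fread(path, na.strings = ""))
  }
  list(women = rd("women.csv"), pregnancies = rd("pregnancies.csv"),
       measurements = rd("measurements.csv"))
}

# ---- configuration file interface ---------------------------------------

#' Write / read a simulation configuration as YAML
#'
#' The full generator configuration (marginals, APO targets and calibration
#' knobs, timing, truth-curve anchors, variance components, covariate
#' effects, observation process) round-trips through a plain YAML file.
#' A packaged default is shipped at
#' `system.file("extdata", "default_sim_config.yaml", package = "apotraj")`.
#'
#' @param config a `sim_config`.
#' @param path file path.
#' @return `write_sim_config()` the path, invisibly; `read_sim_config()` a
#'   `sim_config` list.
#' @export
write_sim_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$apo$alpha <- NULL          # derived at run time
  cfg$apo$rho_mc <- NULL
  cfg$truth <- lapply(cfg$truth, function(tr) {
    tr$anchors <- list(groups = rownames(tr$anchors),
                       times = as.numeric(colnames(tr$anchors)),
                       values = lapply(seq_len(nrow(tr$anchors)),
                                       function(i) unname(tr$anchors[i, ])))
    tr$effects <- as.list(tr$effects)
    tr
  })
  cfg$apo$targets <- as.list(cfg$apo$targets)
  cfg$apo$count_targets <- as.list(cfg$apo$count_targets)
  cfg$marginals$ethnicity <- as.list(cfg$marginals$ethnicity)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$marginals$ethnicity <- unlist(cfg$marginals$ethnicity)
  cfg$apo$targets <- unlist(cfg$apo$targets)
  cfg$apo$count_targets <- unlist(cfg$apo$count_targets)
  cfg$apo$frailty$values <- as.numeric(unlist(cfg$apo$frailty$values))
  cfg$apo$frailty$probs <- as.numeric(unlist(cfg$apo$frailty$probs))
  cfg$truth <- lapply(cfg$truth, function(tr) {
    an <- tr$anchors
    m <- do.call(rbind, lapply(an$values, as.numeric))
    dimnames(m) <- list(unlist(an$groups), as.character(unlist(an$times)))
    tr$anchors <- m
    tr$effects <- unlist(tr$effects)
    tr$bounds <- as.numeric(unlist(tr$bounds))
    tr
  })
  cfg$window <- as.numeric(unlist(cfg$window))
  class(cfg) <- "sim_config"
  cfg
}
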