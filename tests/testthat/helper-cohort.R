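# Hand-built toy tables for the derivation and filtering rule suites.

toy_pregnancy <- function(woman_id, preg_index = 1, t_start = 0,
                          t_end = 0.75, outcome = "live_birth",
                          gh = FALSE, pe = FALSE, gd = FALSE,
                          ptb_s = FALSE, ptb_i = FALSE,
                          sga = FALSE, lga = FALSE, anomaly = FALSE) {
  data.frame(woman_id = woman_id, preg_index = preg_index,
             t_start = t_start, t_end = t_end, outcome = outcome,
             gestational_hypertension = gh, preeclampsia = pe,
             gestational_diabetes = gd, ptb_spontaneous = ptb_s,
             ptb_indicated = ptb_i, sga = sga, lga = lga,
             congenital_anomaly = anomaly, stringsAsFactors = FALSE)
}

toy_woman <- function(woman_id, age = 27, townsend = 3) {
  data.frame(woman_id = woman_id, age_first_pregnancy = age,
             townsend_quintile = townsend, ethnicity = "white",
             smoking_ever = FALSE, parity = 1L, ever_nonsingleton = FALSE,
             med_antihypertensive = FALSE, med_lipid_lowering = FALSE,
             med_hypoglycaemic = FALSE, stringsAsFactors = FALSE)
}

toy_measurement <- function(woman_id, t_rel, value = 120,
                            outcome_type = "sbp", age = 27 + t_rel,
                            fasting = NA) {
  data.frame(woman_id = woman_id, outcome_type = outcome_type,
             value = value, t_rel = t_rel, age = age,
             in_pregnancy = NA, fasting = fasting, stringsAsFactors = FALSE)
}

# a synthetic analysis table with varying covariates and FP ground truth on
# the transformed time axis; used for selection-consistency checks without
# the full generator
sim_fp_table <- function(n_women, obs_per, powers, coefs, sd_u, sd_e,
                         seed, window = c(-10, 15)) {
  set.seed(seed)
  n <- n_women * obs_per
  wid <- rep(sprintf("W%05d", seq_len(n_women)), each = obs_per)
  t_rel <- runif(n, window[1], window[2])
  mp <- make_positive(window)
  spec <- fp_spec(powers, shift = mp$shift, scale = mp$scale)
  mu <- drop(cbind(1, fp_transform(t_rel, spec)) %*% coefs)
  y <- mu + rep(rnorm(n_women, 0, sd_u), each = obs_per) + rnorm(n, 0, sd_e)
  tab <- data.frame(
    woman_id = wid, outcome_type = "sbp", value = y, t_rel = t_rel,
    age = 27 + t_rel, post = t_rel > 0,
    exposure_group = factor(rep(sample(c("comparator", "exposed"), n_women,
                                       replace = TRUE), each = obs_per),
                            levels = c("comparator", "exposed")),
    age_first_pregnancy = rep(rnorm(n_women, 27, 5), each = obs_per),
    townsend_quintile = rep(sample(1:5, n_women, TRUE), each = obs_per),
    ethnicity = rep(sample(c("white", "nonwhite", "unknown"), n_women,
                           TRUE, prob = c(.85, .1, .05)), each = obs_per),
    smoking_ever = rep(runif(n_women) < 0.45, each = obs_per),
    parity = rep(sample(1:4, n_women, TRUE), each = obs_per),
    ever_nonsingleton = rep(runif(n_women) < 0.01, each = obs_per),
    med_antihypertensive = rep(runif(n_women) < 0.06, each = obs_per),
    med_lipid_lowering = rep(runif(n_women) < 0.05, each = obs_per),
    med_hypoglycaemic = rep(runif(n_women) < 0.05, each = obs_per),
    stringsAsFactors = FALSE)
  structure(tab, class = c("analysis_table", "data.frame"),
            outcome = "sbp", exposure = "toy", window = window,
            eligibility = "any", n_women = n_women,
            n_excluded_by_mask = 0L)
}
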