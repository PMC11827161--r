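#' Deriving woman-level APO exposure groups
#'
#' A woman's exposure status is derived from her full pregnancy history, not
#' just her first pregnancy. Each adverse pregnancy outcome (APO) flag is the
#' OR over pregnancies; the APO count sums, over pregnancies, the indicator
#' contributions of gestational hypertension, preeclampsia, gestational
#' diabetes, preterm birth (either type), SGA, LGA and stillbirth — so a
#' single pregnancy with both preeclampsia and SGA contributes two — plus one
#' if the woman had three or more miscarriages across pregnancies. One or two
#' miscarriages and congenital anomalies contribute nothing to the count.
#' Birth-derived flags (preterm birth, SGA, LGA) may be missing where the
#' hospital linkage needed to derive them is absent; missing flags contribute
#' zero to the count and exclude the woman from the corresponding
#' single-APO contrasts.
#'
#' @name apo-derivation
NULL

#' Per-pregnancy APO flag columns
#' @export
APO_FLAGS <- c("gestational_hypertension", "preeclampsia",
               "gestational_diabetes", "ptb_spontaneous", "ptb_indicated",
               "sga", "lga")

# three-valued any(): TRUE if any TRUE; NA if no TRUE but some missing;
# FALSE only when every value is observed FALSE
any_or_na <- function(sum_true, n_nonmissing, n_total) {
  out <- sum_true > 0
  out[sum_true == 0 & n_nonmissing < n_total] <- NA
  out
}

#' Derive woman-level APO profiles from a pregnancies table
#'
#' @param pregnancies data.frame with one row per pregnancy: `woman_id`,
#'   `preg_index`, `t_start`, `t_end`, `outcome` (one of `live_birth`,
#'   `miscarriage`, `stillbirth`) and the per-pregnancy logical flags
#'   `gestational_hypertension`, `preeclampsia`, `gestational_diabetes`,
#'   `ptb_spontaneous`, `ptb_indicated`, `sga`, `lga`, `congenital_anomaly`
#'   (NA allowed where underivable).
#' @param count_mode `"per_pregnancy"` (default) counts every occurrence of a
#'   counted APO in every pregnancy; `"distinct_type"` counts each APO type
#'   at most once per woman.
#' @return a data.frame of class `apo_profiles`, one row per woman, with the
#'   any-pregnancy flags, `miscarriage_any`, `miscarriage_multiple` (3+
#'   miscarriages, not necessarily consecutive), `stillbirth`,
#'   `congenital_anomaly`, the raw count `apo_count`, the count category
#'   `n_apos` (factor 0/1/2/3+) and the tri-state `any_apo` (factor
#'   healthy/apo/unclassifiable).
#' @export
derive_apo_profiles <- function(pregnancies,
                                count_mode = c("per_pregnancy",
                                               "distinct_type")) {
  count_mode <- match.arg(count_mode)
  if (!is.data.frame(pregnancies) || nrow(pregnancies) == 0L)
    stop("'pregnancies' must be a non-empty data.frame", call. = FALSE)
  need <- c("woman_id", "outcome", APO_FLAGS, "congenital_anomaly")
  miss <- setdiff(need, names(pregnancies))
  if (length(miss))
    stop("pregnancies table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)

  g <- factor(pregnancies$woman_id, levels = unique(pregnancies$woman_id))
  fl <- as.matrix(pregnancies[, c(APO_FLAGS, "congenital_anomaly")])
  storage.mode(fl) <- "logical"
  fl_num <- ifelse(is.na(fl), 0, fl * 1)
  sums <- rowsum(fl_num, g)
  nobs <- rowsum(1 - is.na(fl) * 1, g)
  npreg <- as.numeric(table(g))

  out <- data.frame(woman_id = levels(g), stringsAsFactors = FALSE)
  for (k in c(APO_FLAGS, "congenital_anomaly"))
    out[[k]] <- any_or_na(sums[, k], nobs[, k], npreg)

  n_mc <- rowsum((pregnancies$outcome == "miscarriage") * 1, g)[, 1L]
  n_sb <- rowsum((pregnancies$outcome == "stillbirth") * 1, g)[, 1L]
  n_lb <- rowsum((pregnancies$outcome == "live_birth") * 1, g)[, 1L]
  out$miscarriage_any <- n_mc >= 1
  out$miscarriage_multiple <- n_mc >= 3
  out$stillbirth <- n_sb >= 1
  out$n_miscarriages <- n_mc
  out$has_live_birth <- n_lb >= 1

  counted <- sums[, APO_FLAGS, drop = FALSE]
  if (count_mode == "distinct_type") counted <- pmin(counted, 1)
  sb_contrib <- if (count_mode == "distinct_type") pmin(n_sb, 1) else n_sb
  out$apo_count <- rowSums(counted) + sb_contrib + out$miscarriage_multiple
  out$n_apos <- cut(out$apo_count, breaks = c(-0.5, 0.5, 1.5, 2.5, Inf),
                    labels = c("0", "1", "2", "3+"))

  anomaly <- !is.na(out$congenital_anomaly) & out$congenital_anomaly
  out$any_apo <- factor(
    ifelse(out$apo_count > 0, "apo",
           ifelse(!out$has_live_birth | anomaly, "unclassifiable", "healthy")),
    levels = c("healthy", "apo", "unclassifiable")
  )
  class(out) <- c("apo_profiles", "data.frame")
  out
}

#' Derive the APO profile of a single woman
#'
#' Convenience wrapper around [derive_apo_profiles()] for one woman's
#' pregnancy records; errors on an empty input.
#'
#' @param pregnancies pregnancy rows of a single woman.
#' @inheritParams derive_apo_profiles
#' @return a one-row `apo_profiles` data.frame.
#' @export
derive_apo_profile <- function(pregnancies,
                               count_mode = c("per_pregnancy",
                                              "distinct_type")) {
  if (!is.data.frame(pregnancies) || nrow(pregnancies) == 0L)
    stop("a woman must have at least one pregnancy record", call. = FALSE)
  if (length(unique(pregnancies$woman_id)) != 1L)
    stop("records of more than one woman; use derive_apo_profiles()",
         call. = FALSE)
  derive_apo_profiles(pregnancies, count_mode = match.arg(count_mode))
}

#' Exposure names accepted by [comparator_mask()]
#' @export
APO_EXPOSURES <- c(APO_FLAGS[1:3], "sga", "lga", "ptb", "miscarriage_any",
                   "miscarriage_multiple", "stillbirth", "congenital_anomaly",
                   "any_apo", "n_apos")

#' Per-woman inclusion flag and group label for an exposure contrast
#'
#' Encodes the comparator rules: for the SGA contrast, women with LGA are
#' excluded from the comparator group (and vice versa); preterm birth is a
#' three-group contrast (none / spontaneous / indicated); the any-APO
#' contrast excludes unclassifiable women (no live birth, or congenital
#' anomalies only); women whose flag is missing (underivable) are excluded
#' from that contrast.
#'
#' @param exposure one of [APO_EXPOSURES].
#' @param profiles an `apo_profiles` data.frame.
#' @return data.frame with `woman_id`, logical `include`, and factor `group`
#'   whose first level is the comparator.
#' @export
comparator_mask <- function(exposure, profiles) {
  stopifnot(inherits(profiles, "apo_profiles"))
  if (!exposure %in% APO_EXPOSURES)
    stop("unknown exposure '", exposure, "'; expected one of: ",
         paste(APO_EXPOSURES, collapse = ", "), call. = FALSE)
  wid <- profiles$woman_id
  if (exposure == "n_apos") {
    return(data.frame(woman_id = wid, include = TRUE,
                      group = profiles$n_apos))
  }
  if (exposure == "any_apo") {
    inc <- profiles$any_apo != "unclassifiable"
    grp <- factor(as.character(profiles$any_apo),
                  levels = c("healthy", "apo"))
    grp[!inc] <- NA
    return(data.frame(woman_id = wid, include = inc, group = grp))
  }
  if (exposure == "ptb") {
    sp <- profiles$ptb_spontaneous
    ind <- profiles$ptb_indicated
    inc <- !is.na(sp) & !is.na(ind)
    grp <- factor(ifelse(!inc, NA,
                         ifelse(ind, "indicated",
                                ifelse(sp, "spontaneous", "none"))),
                  levels = c("none", "spontaneous", "indicated"))
    return(data.frame(woman_id = wid, include = inc, group = grp))
  }
  flag <- profiles[[exposure]]
  inc <- !is.na(flag)
  if (exposure == "sga") {
    other <- profiles$lga
    inc <- inc & !(is.na(other) | (other & !flag))
  } else if (exposure == "lga") {
    other <- profiles$sga
    inc <- inc & !(is.na(other) | (other & !flag))
  }
  grp <- factor(ifelse(!inc, NA, ifelse(flag, "exposed", "comparator")),
                levels = c("comparator", "exposed"))
  data.frame(woman_id = wid, include = inc, group = grp)
}

# TRUE where a measurement time falls inside any pregnancy interval of the
# same woman (inclusive endpoints); computed from the pregnancies table.
in_pregnancy_flag <- function(woman_id, t_rel, pregnancies) {
  out <- rep(FALSE, length(t_rel))
  key <- paste(pregnancies$woman_id, pregnancies$preg_index, sep = "\r")
  for (j in seq_len(max(pregnancies$preg_index))) {
    idx <- match(paste(woman_id, j, sep = "\r"), key)
    st <- pregnancies$t_start[idx]
    en <- pregnancies$t_end[idx]
    hit <- !is.na(st) & t_rel >= st & t_rel <= en
    out <- out | hit
  }
  out
}

#' Assemble the analysis measurement table for one outcome and exposure
#'
#' Applies the analysis filters — drop measurements taken during pregnancy
#' (recomputed from the pregnancy intervals, not trusted from a flag), keep
#' the configured time window, apply the comparator mask for the exposure,
#' require complete covariates — and attaches the pre/post indicator
#' (`post = t_rel > 0`; a measurement exactly at the first pregnancy start is
#' classed pre), the exposure group and the adjustment covariates.
#'
#' @param measurements long measurement table (`woman_id`, `outcome_type`,
#'   `value`, `t_rel`, `age`, `fasting`).
#' @param pregnancies pregnancies table (see [derive_apo_profiles()]).
#' @param profiles an `apo_profiles` data.frame (derived if `NULL`).
#' @param women women table with baseline covariates.
#' @param outcome_type one of `"sbp"`, `"dbp"`, `"bmi"`, `"total_chol"`,
#'   `"hdl_chol"`, `"glucose"`.
#' @param exposure one of [APO_EXPOSURES].
#' @param window numeric length-2 analysis window in years relative to first
#'   pregnancy start.
#' @param eligibility `"any"` keeps every woman with at least one retained
#'   measurement; `"pre_and_post"` keeps only women with at least one pre-
#'   and one post-pregnancy measurement.
#' @return a data.frame of class `analysis_table` with the retained rows and
#'   attributes `outcome`, `exposure`, `window`, `eligibility`, `n_women`.
#' @export
build_analysis_table <- function(measurements, pregnancies, profiles = NULL,
                                 women, outcome_type, exposure,
                                 window = c(-10, 15),
                                 eligibility = c("any", "pre_and_post")) {
  eligibility <- match.arg(eligibility)
  if (is.null(profiles)) profiles <- derive_apo_profiles(pregnancies)
  stopifnot(length(window) == 2L, window[1] < window[2])

  ms <- measurements[measurements$outcome_type == outcome_type,
                     , drop = FALSE]
  if (nrow(ms)) {
    inpreg <- in_pregnancy_flag(ms$woman_id, ms$t_rel, pregnancies)
    ms <- ms[!inpreg & ms$t_rel >= window[1] & ms$t_rel <= window[2],
             , drop = FALSE]
  }

  mask <- comparator_mask(exposure, profiles)
  mi <- match(ms$woman_id, mask$woman_id)
  keep <- !is.na(mi) & mask$include[mi]
  ms <- ms[keep, , drop = FALSE]
  ms$exposure_group <- droplevels(mask$group[mi[keep]])

  wi <- match(ms$woman_id, women$woman_id)
  covs <- c("age_first_pregnancy", "townsend_quintile", "ethnicity",
            "smoking_ever", "parity", "ever_nonsingleton",
            "med_antihypertensive", "med_lipid_lowering", "med_hypoglycaemic")
  for (v in covs) ms[[v]] <- women[[v]][wi]
  ms$parity <- pmin(ms$parity, 5L)
  ms <- ms[!is.na(ms$townsend_quintile), , drop = FALSE]
  ms$post <- ms$t_rel > 0

  if (outcome_type == "glucose") {
    ms$fasting <- ifelse(is.na(ms$fasting), FALSE, ms$fasting)
  } else {
    ms$fasting <- NULL
  }

  if (eligibility == "pre_and_post" && nrow(ms)) {
    has_pre <- tapply(!ms$post, ms$woman_id, any)
    has_post <- tapply(ms$post, ms$woman_id, any)
    ok <- names(has_pre)[has_pre & has_post]
    ms <- ms[ms$woman_id %in% ok, , drop = FALSE]
  }
  if (nrow(ms) == 0L)
    stop("no measurements remain after the analysis filters (outcome '",
         outcome_type, "', exposure '", exposure, "')", call. = FALSE)
  if (nlevels(ms$exposure_group) < 2L)
    stop("fewer than two exposure groups remain after filtering",
         call. = FALSE)
  rownames(ms) <- NULL
  structure(ms,
            class = c("analysis_table", "data.frame"),
            outcome = outcome_type, exposure = exposure, window = window,
            eligibility = eligibility,
            n_women = length(unique(ms$woman_id)),
            n_excluded_by_mask = sum(!mask$include))
}
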