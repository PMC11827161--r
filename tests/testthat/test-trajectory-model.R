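test_that("the interaction design has the factorial column structure", {
  tab <- sim_fp_table(60, 4, powers = 1, coefs = c(120, 2), sd_u = 1,
                      sd_e = 1, seed = 41)
  mp <- make_positive(c(-10, 15))
  # degree-2 FP, binary exposure, time axis: 11 trajectory columns plus
  # intercept, plus the covariates
  d2 <- build_design(tab, fp_spec(c(0, 1), mp$shift, mp$scale), "time_rel")
  expect_equal(d2$n_trajectory_cols, 12)   # 11 + intercept
  nm <- colnames(d2$X)
  expect_true(all(c("fp1", "fp2", "grp_exposed", "post",
                    "fp1:grp_exposed", "fp2:grp_exposed",
                    "fp1:post", "fp2:post", "grp_exposed:post",
                    "fp1:grp_exposed:post",
                    "fp2:grp_exposed:post") %in% nm))
  # degree-1 with a 4-level exposure: 3 A, 3 fA, 1 fP, 3 AP, 3 fAP
  tab4 <- tab
  tab4$exposure_group <- factor(sample(c("0", "1", "2", "3+"), nrow(tab4),
                                       TRUE),
                                levels = c("0", "1", "2", "3+"))
  d1 <- build_design(tab4, fp_spec(1, mp$shift, mp$scale), "time_rel")
  expect_equal(d1$n_trajectory_cols, 1 + 1 + 3 + 3 + 1 + 1 + 3 + 3)
  # age axis omits the pre/post terms
  da <- build_design(tab, fp_spec(c(0, 1), 0, 10), "age")
  expect_false(any(grepl("post", colnames(da$X))))
  # degenerate single-group exposure errors
  tab1 <- tab
  tab1$exposure_group <- factor(rep("comparator", nrow(tab1)),
                                levels = c("comparator", "exposed"))
  expect_error(build_design(tab1, fp_spec(1, mp$shift, mp$scale)),
               "two non-empty groups")
})

test_that("glucose models adjust for fasting and others do not", {
  cfg <- default_sim_config()
  co <- simulate_cohort(500, cfg, seed = 61,
                        outcomes = c("sbp", "glucose"))
  pr <- derive_apo_profiles(co$pregnancies)
  tg <- build_analysis_table(co$measurements, co$pregnancies, pr,
                             co$women, "glucose", "any_apo")
  ts <- build_analysis_table(co$measurements, co$pregnancies, pr,
                             co$women, "sbp", "any_apo")
  mp <- make_positive(c(-10, 15))
  expect_true("fasting" %in%
                colnames(build_design(tg, fp_spec(1, mp$shift,
                                                  mp$scale))$X))
  expect_false("fasting" %in%
                 colnames(build_design(ts, fp_spec(1, mp$shift,
                                                   mp$scale))$X))
})

test_that("FP selection finds a straight line and prefers lower degree on ties", {
  tab <- sim_fp_table(300, 5, powers = 1, coefs = c(118, 3), sd_u = 2,
                      sd_e = 2, seed = 43)
  sel <- select_fp(tab, "time_rel")
  cand <- attr(sel, "candidates")
  dev_lin <- cand$deviance[cand$powers == "1"]
  # the returned fit is at least as good as the true linear model up to the
  # parsimony rule
  best <- min(cand$deviance, na.rm = TRUE)
  expect_lte(best, dev_lin + 1e-6)
  # noise-free data from a line: degree-1 and degree-2 supersets tie at an
  # exact fit and the tie must resolve to the lower degree
  tab0 <- sim_fp_table(80, 4, powers = 1, coefs = c(118, 3), sd_u = 0,
                       sd_e = 0, seed = 44)
  sel0 <- select_fp(tab0, "time_rel")
  expect_equal(sel0$degree, 1)
  expect_equal(sel0$powers, 1)
  expect_error(select_fp(tab0[1:10, ], "time_rel"), "too few rows")
})

test_that("FP selection recovers an inverse-square-root shape", {
  hits <- 0
  reps <- 10
  for (r in seq_len(reps)) {
    tab <- sim_fp_table(400, 4, powers = -0.5, coefs = c(100, 20),
                        sd_u = 2, sd_e = 2, seed = 500 + r)
    sel <- select_fp(tab, "time_rel")
    hits <- hits + (sel$degree == 1 && isTRUE(all.equal(sel$powers, -0.5)))
  }
  expect_gte(hits, 8)
})

test_that("the full pipeline reproduces truth exactly on noise-free data", {
  cfg <- default_sim_config()
  for (o in names(cfg$truth)) {
    cfg$truth[[o]]$sd_u <- 0
    cfg$truth[[o]]$sd_e <- 1e-6
    cfg$truth[[o]]$effects[] <- 0
  }
  co <- simulate_cohort(1500, cfg, seed = 45, outcomes = "sbp")
  tab <- build_analysis_table(co$measurements, co$pregnancies, NULL,
                              co$women, "sbp", "n_apos")
  m <- fit_trajectory(tab)
  tr <- predict_trajectories(m, grid = c(-10, -4, 2, 10, 14))
  truth <- truth_curve(tr$group, "sbp", tr$axis_value, cfg)
  expect_lt(max(abs(tr$estimate - truth)), 0.1)
  expect_true(all(tr$lower <= tr$estimate & tr$estimate <= tr$upper))
})

test_that("contrasts are linear in the group curves and recover known offsets", {
  tab <- sim_fp_table(250, 4, powers = 1, coefs = c(110, 2), sd_u = 2,
                      sd_e = 2, seed = 47)
  # constant +5 shift for the exposed group, no interaction
  tab$value <- tab$value + 5 * (tab$exposure_group == "exposed")
  m <- fit_trajectory(tab, fpspec = fp_spec(1, -11, 10.4))
  grid <- c(-8, -2, 3, 9)
  ct <- contrast(m, "exposed", "comparator", grid)
  expect_equal(ct$difference, rep(5, 4), tolerance = 0.5)
  tr <- predict_trajectories(m, grid)
  diff_by_hand <- tr$estimate[tr$group == "exposed"] -
    tr$estimate[tr$group == "comparator"]
  expect_equal(ct$difference, diff_by_hand, tolerance = 1e-10)
  # identical groups give a zero difference with zero SE
  ct0 <- contrast(m, "exposed", "exposed", grid)
  expect_equal(ct0$difference, rep(0, 4))
  expect_equal(ct0$se, rep(0, 4))
  expect_error(contrast(m, "nope", "comparator", grid), "unknown")
})

test_that("interaction models never fit worse than their no-interaction nesting", {
  tab <- sim_fp_table(200, 4, powers = 1, coefs = c(110, 2), sd_u = 2,
                      sd_e = 2, seed = 48)
  mp <- make_positive(c(-10, 15))
  spec <- fp_spec(c(0, 1), mp$shift, mp$scale)
  d <- build_design(tab, spec, "time_rel")
  full <- fit_random_intercept(d$X, d$y, d$groups)
  # no-interaction columns only
  keep <- !grepl(":", colnames(d$X))
  base <- fit_random_intercept(d$X[, keep], d$y, d$groups)
  expect_lte(full$deviance, base$deviance + 1e-8)
})

test_that("confidence bands tighten as the cohort grows", {
  ses <- vapply(c(400, 1600), function(n) {
    co <- simulate_cohort(n, seed = 49, outcomes = "sbp")
    tab <- build_analysis_table(co$measurements, co$pregnancies, NULL,
                                co$women, "sbp", "any_apo")
    m <- fit_trajectory(tab, fpspec = fp_spec(c(0, 1), -11, 10.4))
    tr <- predict_trajectories(m, grid = c(-10, 0, 10))
    mean(tr$se)
  }, numeric(1))
  expect_lt(ses[2], ses[1])
})

test_that("prediction outside the window and model printing behave", {
  tab <- sim_fp_table(100, 4, powers = 1, coefs = c(110, 2), sd_u = 1,
                      sd_e = 1, seed = 50)
  m <- fit_trajectory(tab, fpspec = fp_spec(1, -11, 10.4))
  expect_error(predict_trajectories(m, grid = c(0, 20)), "window")
  expect_output(print(m), "Trajectory model")
})
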