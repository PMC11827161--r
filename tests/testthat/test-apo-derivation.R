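test_that("APO counting follows the per-pregnancy contribution rules", {
  # one pregnancy with both preeclampsia and SGA contributes two
  p <- toy_pregnancy("A", pe = TRUE, sga = TRUE)
  pr <- derive_apo_profile(p)
  expect_equal(pr$apo_count, 2)
  expect_equal(as.character(pr$n_apos), "2")
  expect_equal(as.character(pr$any_apo), "apo")

  # one healthy live birth: zero count, healthy-only
  pr0 <- derive_apo_profile(toy_pregnancy("B"))
  expect_equal(pr0$apo_count, 0)
  expect_equal(as.character(pr0$any_apo), "healthy")

  # GD + LGA in pregnancy 1 plus three later miscarriages:
  # GD, LGA and the multiple-miscarriage flag each count once -> 3+
  p4 <- rbind(
    toy_pregnancy("C", 1, gd = TRUE, lga = TRUE),
    toy_pregnancy("C", 2, t_start = 2, t_end = 2.55,
                  outcome = "miscarriage"),
    toy_pregnancy("C", 3, t_start = 4, t_end = 4.55,
                  outcome = "miscarriage"),
    toy_pregnancy("C", 4, t_start = 6, t_end = 6.55,
                  outcome = "miscarriage"))
  pr4 <- derive_apo_profile(p4)
  expect_equal(pr4$apo_count, 3)
  expect_equal(as.character(pr4$n_apos), "3+")
  expect_true(pr4$miscarriage_multiple)

  # 1-2 miscarriages and anomalies contribute nothing to the count
  p5 <- rbind(toy_pregnancy("D", 1, anomaly = TRUE),
              toy_pregnancy("D", 2, t_start = 2, t_end = 2.55,
                            outcome = "miscarriage"))
  pr5 <- derive_apo_profile(p5)
  expect_equal(pr5$apo_count, 0)
  # anomaly-only women are in neither any-APO category
  expect_equal(as.character(pr5$any_apo), "unclassifiable")

  # stillbirth counts per pregnancy; NA birth flags count zero
  p6 <- rbind(toy_pregnancy("E", 1, outcome = "stillbirth"),
              toy_pregnancy("E", 2, t_start = 2, gh = TRUE,
                            sga = NA, lga = NA, ptb_s = NA, ptb_i = NA))
  pr6 <- derive_apo_profile(p6)
  expect_equal(pr6$apo_count, 2)
  expect_true(is.na(pr6$sga))

  expect_error(derive_apo_profile(toy_pregnancy("F")[0, ]), "at least one")
})

test_that("profile derivation is invariant to pregnancy order and count-mode switch works", {
  p <- rbind(toy_pregnancy("A", 1, gh = TRUE),
             toy_pregnancy("A", 2, t_start = 2, gh = TRUE, pe = TRUE),
             toy_pregnancy("A", 3, t_start = 5))
  pr1 <- derive_apo_profiles(p)
  pr2 <- derive_apo_profiles(p[c(3, 1, 2), ])
  expect_equal(pr1$apo_count, pr2$apo_count)
  expect_equal(pr1$gestational_hypertension, pr2$gestational_hypertension)
  # GH twice counts 2 per-pregnancy but 1 distinct-type
  expect_equal(pr1$apo_count, 3)
  expect_equal(derive_apo_profiles(p, "distinct_type")$apo_count, 2)
})

test_that("count category zero coincides with not being in the APO group", {
  set.seed(33)
  w <- simulate_women(400, seed = 33)
  p <- simulate_pregnancies(w, seed = 34)
  pr <- derive_apo_profiles(p)
  expect_true(all((pr$n_apos == "0") == (pr$any_apo != "apo")))
})

test_that("comparator masks implement the exclusion rules", {
  p <- rbind(toy_pregnancy("sga_w", sga = TRUE),
             toy_pregnancy("lga_w", lga = TRUE),
             toy_pregnancy("none_w"),
             toy_pregnancy("gd_w", gd = TRUE),
             toy_pregnancy("na_w", sga = NA, lga = NA, ptb_s = NA,
                           ptb_i = NA),
             toy_pregnancy("ptbs_w", ptb_s = TRUE),
             toy_pregnancy("ptbi_w", ptb_i = TRUE),
             toy_pregnancy("mc_w", outcome = "miscarriage"))
  pr <- derive_apo_profiles(p)

  m <- comparator_mask("sga", pr)
  expect_true(m$include[m$woman_id == "sga_w"])
  expect_false(m$include[m$woman_id == "lga_w"])     # excluded both groups
  expect_true(m$include[m$woman_id == "none_w"])
  expect_false(m$include[m$woman_id == "na_w"])      # underivable flag
  expect_equal(as.character(m$group[m$woman_id == "sga_w"]), "exposed")

  m2 <- comparator_mask("gestational_diabetes", pr)
  expect_equal(as.character(m2$group[m2$woman_id == "gd_w"]), "exposed")
  expect_true(all(m2$include))

  m3 <- comparator_mask("ptb", pr)
  expect_equal(as.character(m3$group[m3$woman_id == "ptbs_w"]),
               "spontaneous")
  expect_equal(as.character(m3$group[m3$woman_id == "ptbi_w"]),
               "indicated")
  expect_equal(as.character(m3$group[m3$woman_id == "none_w"]), "none")
  expect_false(m3$include[m3$woman_id == "na_w"])

  # a woman with two miscarriages and no live birth is in neither any-APO
  # group
  p2 <- rbind(toy_pregnancy("mm", 1, outcome = "miscarriage"),
              toy_pregnancy("mm", 2, t_start = 2, outcome = "miscarriage"),
              toy_pregnancy("ok", 1))
  m4 <- comparator_mask("any_apo", derive_apo_profiles(p2))
  expect_false(m4$include[m4$woman_id == "mm"])
  expect_equal(as.character(m4$group[m4$woman_id == "ok"]), "healthy")

  expect_error(comparator_mask("nonsense", pr), "unknown exposure")
})

test_that("analysis-table filters drop in-pregnancy and out-of-window rows", {
  w <- rbind(toy_woman("A"), toy_woman("B"))
  p <- rbind(toy_pregnancy("A", 1, t_start = 0, t_end = 0.75, gh = TRUE),
             toy_pregnancy("B", 1, t_start = 0, t_end = 0.75))
  # 6 measurements: 2 inside pregnancy A, 1 beyond the window, 3 valid
  ms <- rbind(toy_measurement("A", 0.2), toy_measurement("A", 0.6),
              toy_measurement("A", 16), toy_measurement("A", -2),
              toy_measurement("B", 1.5), toy_measurement("B", -9.9))
  tab <- build_analysis_table(ms, p, NULL, w, "sbp", "gestational_hypertension")
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$t_rel %in% c(-2, 1.5, -9.9)))
  # measurement exactly at t = 0 is pre-pregnancy by convention but inside
  # the first pregnancy interval, hence dropped by the in-pregnancy rule
  ms0 <- rbind(toy_measurement("B", 0), toy_measurement("B", -1),
               toy_measurement("A", -1))
  tab0 <- build_analysis_table(ms0, p, NULL, w, "sbp",
                               "gestational_hypertension")
  expect_equal(sort(tab0$t_rel), c(-1, -1))
  expect_false(any(tab0$post))
})

test_that("pre_and_post eligibility drops women lacking either period", {
  w <- rbind(toy_woman("A"), toy_woman("B"))
  p <- rbind(toy_pregnancy("A", gh = TRUE), toy_pregnancy("B"))
  ms <- rbind(toy_measurement("A", -1), toy_measurement("A", 2),
              toy_measurement("B", 2), toy_measurement("B", 3))
  tab_any <- build_analysis_table(ms, p, NULL, w, "sbp",
                                  "gestational_hypertension",
                                  eligibility = "any")
  expect_equal(attr(tab_any, "n_women"), 2)
  tab_pp <- build_analysis_table(ms, p, NULL, w, "sbp",
                                 "gestational_hypertension",
                                 eligibility = "pre_and_post")
  expect_equal(attr(tab_pp, "n_women"), 1)
  expect_true(all(tab_pp$woman_id == "A"))
  # post indicator is strict: t = 0 classes as pre
  expect_equal(tab_any$post, tab_any$t_rel > 0)
})

test_that("an empty analysis table is an error", {
  w <- toy_woman("A")
  p <- toy_pregnancy("A", gh = TRUE)
  ms <- toy_measurement("A", 0.3)   # in pregnancy -> everything drops
  expect_error(build_analysis_table(ms, p, NULL, w, "sbp",
                                    "gestational_hypertension"),
               "no measurements|two exposure")
})
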