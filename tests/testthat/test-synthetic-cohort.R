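test_that("a fixed seed reproduces identical cohort tables", {
  c1 <- simulate_cohort(300, seed = 42, outcomes = c("sbp", "glucose"))
  c2 <- simulate_cohort(300, seed = 42, outcomes = c("sbp", "glucose"))
  expect_identical(c1$women, c2$women)
  expect_identical(c1$pregnancies, c2$pregnancies)
  expect_identical(c1$measurements, c2$measurements)
  c3 <- simulate_cohort(300, seed = 43, outcomes = c("sbp", "glucose"))
  expect_false(identical(c1$measurements, c3$measurements))
})

test_that("a single woman yields one fully populated record set", {
  w <- simulate_women(1, seed = 7)
  expect_equal(nrow(w), 1)
  expect_true(all(!is.na(w[, c("woman_id", "age_first_pregnancy",
                               "ethnicity", "smoking_ever", "parity")])))
  expect_gte(w$parity, 1)
  p <- simulate_pregnancies(w, seed = 8)
  expect_equal(nrow(p), w$parity)
  expect_equal(p$t_start[1], 0)
})

test_that("degenerate configurations are rejected or degenerate cleanly", {
  expect_error(simulate_women(0, seed = 1), "positive")
  cfg <- default_sim_config()
  cfg$marginals$townsend <- c(0.5, 0.5, 0.5, 0, 0)
  expect_error(simulate_women(10, cfg, seed = 1), "sum to 1")
  cfg2 <- default_sim_config()
  cfg2$apo$targets[] <- 0
  w <- simulate_women(50, cfg2, seed = 2)
  w$parity <- 1L
  p <- simulate_pregnancies(w, cfg2, seed = 3)
  expect_true(all(p$outcome == "live_birth"))
  flg <- as.matrix(p[, APO_FLAGS])
  expect_true(all(flg[!is.na(flg)] == FALSE))
  cfg3 <- default_sim_config()
  cfg3$apo$targets[["preeclampsia"]] <- 1.4
  expect_error(calibrate_sim_config(cfg3), "\\[0, 1\\]")
})

test_that("truth curves are exact at the anchor values", {
  cfg <- default_sim_config()
  for (o in SIM_OUTCOMES) {
    an <- cfg$truth[[o]]$anchors
    for (g in rownames(an)) {
      tt <- as.numeric(colnames(an))
      expect_equal(truth_curve(g, o, tt, cfg), unname(an[g, ]),
                   tolerance = 1e-10)
    }
  }
  expect_equal(truth_curve("0", "sbp", -10), 112.9)
  expect_equal(truth_curve("3+", "sbp", 10), 127.1)
  expect_error(truth_curve("0", "sbp", 20), "window")
  expect_error(truth_curve("5", "sbp", 0), "group")
  expect_error(truth_curve("0", "nope", 0), "truth")
})

test_that("the noise-free limit reproduces the truth curves exactly", {
  cfg <- default_sim_config()
  cfg$truth$sbp$sd_u <- 0
  cfg$truth$sbp$sd_e <- 0
  cfg$truth$sbp$effects[] <- 0
  co <- simulate_cohort(200, cfg, seed = 5, outcomes = "sbp")
  pr <- derive_apo_profiles(co$pregnancies)
  grp <- as.character(pr$n_apos[match(co$measurements$woman_id,
                                      pr$woman_id)])
  expect_equal(co$measurements$value,
               truth_curve(grp, "sbp", co$measurements$t_rel, cfg),
               tolerance = 1e-12)
})

test_that("in_pregnancy flags agree with an independent interval check", {
  co <- simulate_cohort(250, seed = 19, outcomes = "sbp")
  ms <- co$measurements
  slow <- vapply(seq_len(nrow(ms)), function(i) {
    pp <- co$pregnancies[co$pregnancies$woman_id == ms$woman_id[i], ]
    any(ms$t_rel[i] >= pp$t_start & ms$t_rel[i] <= pp$t_end)
  }, logical(1))
  expect_equal(ms$in_pregnancy, slow)
})

test_that("covariate marginals and APO prevalences converge to their targets", {
  n <- 20000
  w <- simulate_women(n, seed = 55)
  p <- simulate_pregnancies(w, seed = 56)
  pr <- derive_apo_profiles(p)
  mse <- function(p0) 3 * sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(mean(w$age_first_pregnancy) - 27.1),
            3 * 6.6 / sqrt(n) + 0.05)
  expect_lt(abs(mean(w$smoking_ever) - 0.45), mse(0.45))
  expect_lt(abs(mean(pr$preeclampsia) - 0.04), mse(0.04))
  expect_lt(abs(mean(pr$gestational_hypertension) - 0.094), mse(0.094))
  expect_lt(abs(mean(pr$miscarriage_any) - 0.186), mse(0.186))
  lk <- w$hes_linked[match(pr$woman_id, w$woman_id)]
  expect_lt(abs(mean(pr$sga[lk]) - 0.124), mse(0.124) / sqrt(0.545))
  expect_lt(abs(mean(pr$n_apos == "0") - 0.717), mse(0.717))
})

test_that("plausibility bounds hold and values respond to covariates as configured", {
  co <- simulate_cohort(400, seed = 77, outcomes = c("sbp", "glucose"))
  sbp <- co$measurements[co$measurements$outcome_type == "sbp", ]
  b <- default_sim_config()$truth$sbp$bounds
  expect_true(all(sbp$value >= b[1] & sbp$value <= b[2]))
  glu <- co$measurements[co$measurements$outcome_type == "glucose", ]
  expect_true(all(!is.na(glu$fasting)))
  expect_true(all(is.na(sbp$fasting)))
  expect_equal(sbp$age,
               co$women$age_first_pregnancy[match(sbp$woman_id,
                                                  co$women$woman_id)] +
                 sbp$t_rel)
})

test_that("measurement availability is higher for women with APOs", {
  co <- simulate_cohort(6000, seed = 91, outcomes = "sbp")
  pr <- derive_apo_profiles(co$pregnancies)
  has <- pr$woman_id %in% co$measurements$woman_id
  apo <- pr$any_apo == "apo"
  healthy <- pr$any_apo == "healthy"
  expect_gt(mean(has[apo]), mean(has[healthy]))
})

test_that("cohorts round-trip through the delimited-text interface", {
  co <- simulate_cohort(80, seed = 13, outcomes = "sbp")
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, c("women.csv",
                                               "pregnancies.csv",
                                               "measurements.csv")))))
  back <- read_cohort(dir)
  expect_equal(nrow(back$women), 80)
  expect_equal(back$pregnancies$outcome, co$pregnancies$outcome)
  expect_equal(back$measurements$value, co$measurements$value,
               tolerance = 1e-12)
  # NA flags survive the round trip as missing values
  expect_equal(is.na(back$pregnancies$sga), is.na(co$pregnancies$sga))
})

test_that("the packaged YAML configuration reproduces the default calibration", {
  path <- system.file("extdata", "default_sim_config.yaml",
                      package = "apotraj")
  expect_true(nzchar(path))
  cfg <- read_sim_config(path)
  d <- default_sim_config()
  expect_equal(cfg$truth$sbp$anchors, d$truth$sbp$anchors)
  expect_equal(cfg$apo$targets, d$apo$targets)
  expect_identical(simulate_women(150, cfg, seed = 9),
                   simulate_women(150, d, seed = 9))
  # write/read round trip of a modified config
  tmp <- withr::local_tempfile(fileext = ".yaml")
  cfg$apo$targets[["preeclampsia"]] <- 0.05
  write_sim_config(cfg, tmp)
  expect_equal(read_sim_config(tmp)$apo$targets[["preeclampsia"]], 0.05)
})
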