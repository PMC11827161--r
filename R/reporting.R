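#' Pipeline orchestration: simulate, fit, report
#'
#' Thin orchestration layer over the package functions: `cmd_simulate()`
#' writes a synthetic cohort and a truth manifest, `cmd_fit()` runs the
#' trajectory pipeline for every requested outcome/exposure pair and writes
#' trajectory CSVs, coefficient CSVs, run manifests and plots, and
#' `cmd_report()` summarises completed runs. A command-line wrapper lives in
#' `inst/cli/apotraj.R`.
#'
#' @name reporting
NULL

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; exactly one of `input_dir` or `simulate` must
#' be present. The `simulate` block accepts `n` (women) and overrides for
#' the default generator configuration.
#'
#' @param path YAML file path.
#' @return a list of class `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("input_dir", "simulate", "outcomes", "exposures", "axis",
             "window", "eligibility", "random", "grid_by", "seed", "out_dir")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(raw$input_dir) == is.null(raw$simulate))
    stop("exactly one of 'input_dir' or 'simulate' must be given",
         call. = FALSE)
  if (!is.null(raw$simulate) && is.null(raw$seed))
    stop("'seed' is mandatory when simulating", call. = FALSE)
  defaults <- list(outcomes = "sbp", exposures = "n_apos",
                   axis = "time_rel", window = c(-10, 15),
                   eligibility = "any", random = "intercept",
                   grid_by = 0.5, seed = 1, out_dir = ".")
  cfg <- utils::modifyList(defaults, raw)
  class(cfg) <- "run_config"
  cfg
}

#' Simulate a cohort to disk
#'
#' Writes `women.csv`, `pregnancies.csv`, `measurements.csv` and a
#' `truth_manifest.json` recording every generator parameter and the seed,
#' so a run is reproducible from its manifest alone.
#'
#' @param n number of women.
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param config a `sim_config` (default packaged calibration).
#' @param outcomes subset of [SIM_OUTCOMES].
#' @return the output directory, invisibly.
#' @export
cmd_simulate <- function(n, out_dir, seed = 1,
                         config = default_sim_config(), outcomes = NULL) {
  if (!is.numeric(n) || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  config <- calibrate_sim_config(config)
  cohort <- simulate_cohort(n, config, seed = seed, outcomes = outcomes)
  write_cohort(cohort, out_dir)
  manifest <- list(n = n, seed = seed,
                   outcomes = outcomes %||% config$outcomes,
                   config = sim_config_manifest(config))
  jsonlite::write_json(manifest,
                       file.path(out_dir, "truth_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# flatten the sim config into a JSON-serialisable list
sim_config_manifest <- function(config) {
  cfg <- unclass(config)
  cfg$truth <- lapply(cfg$truth, function(tr) {
    tr$anchors <- list(groups = rownames(tr$anchors),
                       times = as.numeric(colnames(tr$anchors)),
                       values = unname(apply(tr$anchors, 1, c,
                                             simplify = FALSE)))
    tr
  })
  cfg
}

sanitize <- function(x) gsub("[^0-9A-Za-z_]", "p", x)

#' Fit trajectory models for every outcome/exposure pair
#'
#' For each pair, derives APO profiles, builds the analysis table, runs FP
#' selection and the random-intercept (or random-slope) fit, and writes:
#' a trajectory CSV (`group, axis_value, estimate, lower, upper`), a
#' coefficients CSV, a JSON manifest (configuration, seed, chosen FP powers,
#' sample sizes, deviance, comparator exclusions) and a PNG plot. Files are
#' written atomically (temp file + rename). Pairs failing are reported and
#' make the function signal an error at the end.
#'
#' @param input_dir directory containing the three cohort CSVs.
#' @param out_dir output directory.
#' @param outcomes character vector of outcome types.
#' @param exposures character vector of exposures (see [APO_EXPOSURES]).
#' @param axis `"time_rel"` or `"age"`.
#' @param window analysis window in years relative to first pregnancy.
#' @param eligibility `"any"` or `"pre_and_post"`.
#' @param random `"intercept"` or `"slope"`.
#' @param grid_by grid resolution on the axis.
#' @param make_plots write PNG plots (default TRUE).
#' @param verbose print per-stage progress lines.
#' @return invisibly, a list of `trajectory_model` objects named
#'   `<outcome>.<exposure>`.
#' @export
cmd_fit <- function(input_dir, out_dir, outcomes = "sbp",
                    exposures = "n_apos", axis = "time_rel",
                    window = c(-10, 15), eligibility = "any",
                    random = "intercept", grid_by = 0.5,
                    make_plots = TRUE, verbose = TRUE) {
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  tabs <- read_cohort(input_dir)
  check_cohort_schema(tabs)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  profiles <- derive_apo_profiles(tabs$pregnancies)
  say("[derive] %d women profiled (%.1fs)", nrow(profiles),
      as.numeric(Sys.time() - t0, units = "secs"))
  models <- list()
  failures <- character()
  for (oc in outcomes) for (ex in exposures) {
    tag <- paste(oc, ex, sep = ".")
    res <- tryCatch({
      tab <- build_analysis_table(tabs$measurements, tabs$pregnancies,
                                  profiles, tabs$women, oc, ex,
                                  window = window,
                                  eligibility = eligibility)
      say("[table] %s: %d rows, %d women", tag, nrow(tab),
          attr(tab, "n_women"))
      m <- fit_trajectory(tab, axis = axis, random = random)
      say("[fit] %s: FP(%s), deviance %.1f", tag,
          paste(m$fpspec$powers, collapse = ","), m$fit$deviance)
      grid <- if (axis == "time_rel")
        seq(window[1], window[2], by = grid_by) else NULL
      tr <- predict_trajectories(m, grid = grid)
      write_run_outputs(m, tr, out_dir, tag, make_plots)
      m
    }, error = function(e) {
      warning("pair ", tag, " failed: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) failures <- c(failures, tag) else models[[tag]] <- res
  }
  say("[done] %d fitted, %d failed (%.1fs)", length(models),
      length(failures), as.numeric(Sys.time() - t0, units = "secs"))
  if (length(failures))
    stop("failed pairs: ", paste(failures, collapse = ", "), call. = FALSE)
  invisible(models)
}

check_cohort_schema <- function(tabs) {
  need <- list(
    women = c("woman_id", "age_first_pregnancy", "townsend_quintile",
              "ethnicity", "smoking_ever", "parity", "ever_nonsingleton",
              "med_antihypertensive", "med_lipid_lowering",
              "med_hypoglycaemic"),
    pregnancies = c("woman_id", "preg_index", "t_start", "t_end", "outcome",
                    APO_FLAGS, "congenital_anomaly"),
    measurements = c("woman_id", "outcome_type", "value", "t_rel"))
  for (nm in names(need)) {
    miss <- setdiff(need[[nm]], names(tabs[[nm]]))
    if (length(miss))
      stop("schema violation in ", nm, ".csv: missing column(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# atomic write helpers
write_atomic_csv <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  data.table::fwrite(df, tmp, na = "")
  file.rename(tmp, path)
}

write_run_outputs <- function(model, trajectories, out_dir, tag,
                              make_plots) {
  tag <- sanitize(tag)
  write_atomic_csv(trajectories[, c("group", "axis_value", "estimate",
                                    "lower", "upper")],
                   file.path(out_dir, paste0("trajectories_", tag, ".csv")))
  co <- data.frame(term = names(model$fit$beta),
                   estimate = unname(model$fit$beta),
                   se = sqrt(diag(model$fit$vcov_beta)))
  write_atomic_csv(co, file.path(out_dir, paste0("coefficients_", tag,
                                                 ".csv")))
  manifest <- list(
    outcome = model$outcome, exposure = model$exposure, axis = model$axis,
    fp_powers = model$fpspec$powers,
    fp_shift = model$fpspec$shift, fp_scale = model$fpspec$scale,
    window = model$window, eligibility = model$eligibility,
    random = model$fit$random,
    n_obs = model$n_obs, n_women = model$n_women,
    n_excluded_by_mask = model$n_excluded_by_mask,
    deviance = model$fit$deviance,
    sigma_u = sqrt(model$fit$sigma2_u), sigma_e = sqrt(model$fit$sigma2_e))
  tmp <- file.path(out_dir, paste0("manifest_", tag, ".json.tmp"))
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, file.path(out_dir, paste0("manifest_", tag, ".json")))
  if (make_plots) {
    p <- plot_trajectories(trajectories, model)
    grDevices::png(file.path(out_dir, paste0("plot_", tag, ".png")),
                   width = 1400, height = 900, res = 150)
    print(p)
    grDevices::dev.off()
  }
  invisible(NULL)
}

#' Plot predicted trajectories with confidence bands
#'
#' @param trajectories output of [predict_trajectories()].
#' @param model the fitted `trajectory_model` (for labels).
#' @return a ggplot object: one mean curve with a 95% ribbon per group;
#'   x axis in years relative to first pregnancy (negative = before) or
#'   age in years.
#' @export
plot_trajectories <- function(trajectories, model) {
  xlab <- if (model$axis == "time_rel")
    "Years relative to first pregnancy (negative = before)" else
      "Age (years)"
  ggplot2::ggplot(trajectories,
                  ggplot2::aes(x = axis_value, y = estimate,
                               colour = group, fill = group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lower, ymax = upper),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = xlab, y = model$outcome,
                  colour = model$exposure, fill = model$exposure,
                  title = sprintf("%s by %s", model$outcome,
                                  model$exposure)) +
    ggplot2::theme_minimal()
}

#' Summarise completed runs in a directory
#'
#' Reads every `manifest_*.json` under `run_dir` and tabulates one row per
#' run with anchor predictions read from the matching trajectory CSV at the
#' requested times (per group, time-axis runs only). Anchor times outside
#' the run's window produce a blank cell and a warning. Missing or broken
#' manifests are listed, not fatal.
#'
#' @param run_dir directory with `cmd_fit()` outputs.
#' @param anchors numeric times at which to report predicted means.
#' @return data.frame with one row per run and group.
#' @export
cmd_report <- function(run_dir, anchors = c(-10, 10)) {
  mf <- list.files(run_dir, pattern = "^manifest_.*\\.json$",
                   full.names = TRUE)
  if (!length(mf))
    stop("no completed runs under ", run_dir, call. = FALSE)
  rows <- list()
  for (f in mf) {
    m <- tryCatch(jsonlite::read_json(f, simplifyVector = TRUE),
                  error = function(e) NULL)
    if (is.null(m)) {
      warning("unreadable manifest: ", f, call. = FALSE)
      next
    }
    tag <- sub("^manifest_(.*)\\.json$", "\\1", basename(f))
    tr_path <- file.path(run_dir, paste0("trajectories_", tag, ".csv"))
    tr <- if (file.exists(tr_path))
      as.data.frame(data.table::fread(tr_path)) else NULL
    groups <- if (is.null(tr)) NA_character_ else unique(tr$group)
    for (a in anchors) {
      if (!is.null(tr) && (a < m$window[1] || a > m$window[2]))
        warning("anchor time ", a, " outside window of run ", tag,
                call. = FALSE)
    }
    for (g in groups) {
      row <- data.frame(run = tag, outcome = m$outcome,
                        exposure = m$exposure, axis = m$axis,
                        fp_powers = paste(m$fp_powers, collapse = ","),
                        n_obs = m$n_obs, n_women = m$n_women,
                        deviance = m$deviance, group = g)
      for (a in anchors) {
        cn <- paste0("pred_t", a)
        if (is.null(tr) || a < m$window[1] || a > m$window[2]) {
          row[[cn]] <- NA_real_
        } else {
          sel <- tr$group == g & abs(tr$axis_value - a) < 1e-8
          row[[cn]] <- if (any(sel)) tr$estimate[which(sel)[1]] else
            NA_real_
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
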