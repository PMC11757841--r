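#' Read and write the pipeline's CSV dialects
#'
#' All artifacts are UTF-8, comma-separated, "." decimal, header row, missing
#' values as empty cells. Trial logs carry columns `participant_id`,
#' `delay_label`, `delay_days`, `trial_index`, `immediate_offer`, `choice`
#' (`I`/`D`); indifference tables `participant_id`, `delay_days`,
#' `subjective_value`; the cohort table one row per participant.
#'
#' @param x Data frame to write.
#' @param path File path.
#' @return `read_*` return a data frame; `write_*` return `path` invisibly.
#' @name dd_csv
NULL

write_dd_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

read_dd_csv <- function(path) {
  if (!file.exists(path)) {
    stop("File not found: ", path,
         " (run the producing pipeline stage first).")
  }
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' @rdname dd_csv
#' @export
write_trial_log <- function(x, path) {
  cols <- c("participant_id", "delay_label", "delay_days", "trial_index",
            "immediate_offer", "choice")
  stopifnot(all(cols %in% names(x)))
  write_dd_csv(x[, cols, drop = FALSE], path)
}

#' @rdname dd_csv
#' @export
read_trial_log <- function(path) {
  x <- read_dd_csv(path)
  if (nrow(x) && !all(x$choice %in% c("I", "D"))) {
    stop("Trial log choices must be coded I or D.")
  }
  x
}

#' @rdname dd_csv
#' @export
write_indifference_csv <- function(x, path) {
  cols <- c("participant_id", "delay_days", "subjective_value")
  stopifnot(all(cols %in% names(x)))
  write_dd_csv(x[, cols, drop = FALSE], path)
}

#' @rdname dd_csv
#' @export
read_indifference_csv <- function(path) read_dd_csv(path)

#' @rdname dd_csv
#' @export
write_cohort_csv <- function(x, path) write_dd_csv(x, path)

#' @rdname dd_csv
#' @export
read_cohort_csv <- function(path) {
  x <- read_dd_csv(path)
  if ("country" %in% names(x)) x$country <- factor(x$country)
  if ("vaccinated" %in% names(x)) x$vaccinated <- as.logical(x$vaccinated)
  x
}

#' Derive a per-stage seed from the run's root seed
#'
#' A single root seed deterministically spawns independent substreams so
#' pipeline stages can be rerun in isolation; all values stay below 2^31.
#'
#' @param root Integer root seed.
#' @param stage Stage name (any string).
#' @return An integer seed.
#' @export
stage_seed <- function(root, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(root) * 48271 + h) %% 2147483647)
}

#' Replay a trial log into indifference points
#'
#' Feeds each participant-by-delay block of a trial log back through the
#' titration rule, verifying the logged offers on the way; the result is a
#' pure function of the choice sequences.
#'
#' @param trial_log Trial-log data frame (see [write_trial_log()]).
#' @param config The [task_config()] the log was produced under.
#' @return Indifference data frame (`participant_id`, `delay_days`,
#'   `subjective_value`).
#' @export
replay_trial_log <- function(trial_log, config = task_config()) {
  key <- interaction(trial_log$participant_id, trial_log$delay_days, drop = TRUE)
  out <- lapply(split(trial_log, key), function(block) {
    block <- block[order(block$trial_index), ]
    state <- titration_start(config, list(label = block$delay_label[1],
                                          days = block$delay_days[1]))
    for (i in seq_len(nrow(block))) {
      if (abs(state$offer - block$immediate_offer[i]) > 1e-9) {
        stop("Trial log inconsistent with the titration rule for participant ",
             block$participant_id[1], " at delay ", block$delay_days[1],
             " trial ", block$trial_index[i], ".")
      }
      state <- titration_choose(state, block$choice[i])
    }
    ip <- indifference_point(state)
    data.frame(participant_id = block$participant_id[1],
               delay_days = ip$days, subjective_value = ip$subjective_value)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$participant_id, out$delay_days), ]
}

#' Pipeline stages
#'
#' Thin orchestration over the package's modules; each stage is a pure
#' function of its inputs plus the seed, writes the documented CSV dialects
#' when `out_dir` is given, and returns its outputs invisibly-usable in R.
#' `pipeline_run_all()` chains generation, scoring and model fitting under a
#' single root seed and writes a run log (seed, package version, spec).
#'
#' @param n_agents Number of simulated hyperbolic agents.
#' @param k_log10_mean,k_log10_sd Distribution of `log10(k)` across agents.
#' @param config A [task_config()].
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (root seed for `pipeline_run_all`).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
pipeline_simulate_task <- function(n_agents, config = task_config(),
                                   k_log10_mean = -2.2, k_log10_sd = 0.6,
                                   seed = 1L, out_dir = NULL) {
  set.seed(as.integer(seed))
  if (n_agents > 0) {
    k <- 10^stats::rnorm(n_agents, k_log10_mean, k_log10_sd)
  } else {
    k <- numeric()
  }
  days <- config$delays$days
  trial_rows <- vector("list", length(days))
  iv <- matrix(NA_real_, n_agents, length(days))
  for (j in seq_along(days)) {
    sv <- config$delayed_amount / (1 + k * days[j])
    res <- titrate_threshold(sv, config, keep_trials = TRUE)
    iv[, j] <- res$indifference
    trial_rows[[j]] <- data.frame(
      participant_id = rep(seq_len(n_agents), times = config$n_trials),
      delay_label = rep(config$delays$label[j], n_agents * config$n_trials),
      delay_days = rep(days[j], n_agents * config$n_trials),
      trial_index = rep(seq_len(config$n_trials), each = n_agents),
      immediate_offer = as.vector(res$offers),
      choice = as.vector(res$choices),
      stringsAsFactors = FALSE
    )
  }
  trial_log <- do.call(rbind, trial_rows)
  indifference <- data.frame(
    participant_id = rep(seq_len(n_agents), times = length(days)),
    delay_days = rep(days, each = n_agents),
    subjective_value = as.vector(iv)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trial_log(trial_log, file.path(out_dir, "trial_log.csv"))
    write_indifference_csv(indifference, file.path(out_dir, "indifference.csv"))
  }
  list(trial_log = trial_log, indifference = indifference, k = k)
}

#' @rdname pipeline
#' @export
pipeline_generate_cohort <- function(spec = cohort_spec(), seed = 1L,
                                     out_dir = NULL) {
  gen <- generate_cohort(spec, seed = seed, keep_trials = !is.null(out_dir))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort_csv(gen$cohort, file.path(out_dir, "cohort.csv"))
    write_indifference_csv(gen$indifference, file.path(out_dir, "indifference.csv"))
    write_trial_log(gen$trial_log, file.path(out_dir, "trial_log.csv"))
  }
  gen
}

#' @rdname pipeline
#' @param cohort A cohort data frame (or path to a cohort CSV) with raw
#'   outcome codes.
#' @export
pipeline_score <- function(cohort, out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort_csv(cohort)
  if (!"vaccinated" %in% names(cohort)) cohort <- code_outcomes(cohort)
  res <- analytic_sample(cohort)
  kept <- res$kept
  # distress index standardized within the analytic sample
  if (all(c("gad7_total", "phq9_total") %in% names(kept)) && nrow(kept) >= 2) {
    kept$distress <- distress_index(kept$gad7_total, kept$phq9_total)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort_csv(kept, file.path(out_dir, "cohort_scored.csv"))
    write_dd_csv(res$exclusions, file.path(out_dir, "exclusions.csv"))
  }
  list(cohort = kept, exclusions = res$exclusions)
}

#' @rdname pipeline
#' @param ... Passed on to [fit_booster_glmm()] (e.g. `predictors`, `nAGQ`).
#' @export
pipeline_fit <- function(cohort, out_dir = NULL, ...) {
  if (is.character(cohort)) cohort <- read_cohort_csv(cohort)
  full <- fit_booster_glmm(cohort, ...)
  null <- fit_booster_glmm(cohort, predictors = NULL, scale_vars = character())
  test <- lrt(full, null)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_dd_csv(full$coefficients, file.path(out_dir, "model_coefficients.csv"))
    con <- file(file.path(out_dir, "model_report.txt"), "w", encoding = "UTF-8")
    sink(con); print(full); print(test); sink(); close(con)
  }
  list(fit = full, null = null, lrt = test)
}

#' @rdname pipeline
#' @export
pipeline_run_all <- function(spec = cohort_spec(), seed = 1L, out_dir = NULL) {
  gen <- pipeline_generate_cohort(spec, seed = stage_seed(seed, "generate"),
                                  out_dir = out_dir)
  scored <- pipeline_score(gen$cohort, out_dir = out_dir)
  fitres <- pipeline_fit(scored$cohort, out_dir = out_dir)
  if (!is.null(out_dir)) {
    log <- c(
      paste0("root_seed: ", seed),
      paste0("generate_seed: ", stage_seed(seed, "generate")),
      paste0("package_version: ",
             as.character(utils::packageVersion("boosterdd"))),
      "spec:",
      paste0("  ", utils::capture.output(utils::str(spec, give.attr = FALSE)))
    )
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  list(generated = gen, scored = scored, model = fitres)
}
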