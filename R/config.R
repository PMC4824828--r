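# Run configuration, log serialization, and the command-style entry
# points that tie synthesis, simulation and analysis together.  Two runs
# with an identical configuration produce identical logs and identical
# WAV banks.

#' Build a run configuration
#'
#' A `run_config` fully determines a run: the seed is expanded into named
#' substreams so the stimulus bank, trial schedules and observer responses
#' are each independently reproducible.
#'
#' @param seed Integer master seed.
#' @param species `"human"` or `"budgerigar"`.
#' @param observer Observer preset name or an `observer_profile`.
#' @param training_set 1 or 2.
#' @param splus_pattern `"trochaic"` or `"iambic"`.
#' @param sample_rate Synthesis sample rate in Hz.
#' @param n_subjects Cohort size for [cmd_simulate()].
#' @param out_dir Output directory for banks and logs.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, species = "human",
                       observer = "human_like", training_set = 1L,
                       splus_pattern = "trochaic", sample_rate = 44100,
                       n_subjects = 1L, out_dir = tempdir()) {
  species <- match.arg(species, c("human", "budgerigar"))
  splus_pattern <- match.arg(splus_pattern, c("trochaic", "iambic"))
  stopifnot(training_set %in% c(1L, 2L), n_subjects >= 1L)
  structure(list(seed = as.integer(seed), species = species,
                 observer = observer, training_set = as.integer(training_set),
                 splus_pattern = splus_pattern,
                 sample_rate = sample_rate,
                 n_subjects = as.integer(n_subjects),
                 out_dir = out_dir),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' Round-trips losslessly (observer given as a preset name or explicit
#' parameter list).
#'
#' @param config A `run_config`.
#' @param path YAML file path.
#' @return `path` (write) or the `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  if (inherits(x$observer, "observer_profile")) {
    x$observer <- unclass(x$observer)
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  obs <- if (is.list(x$observer)) do.call(observer_profile, x$observer)
         else x$observer
  run_config(seed = x$seed, species = x$species, observer = obs,
             training_set = x$training_set,
             splus_pattern = x$splus_pattern,
             sample_rate = x$sample_rate, n_subjects = x$n_subjects,
             out_dir = x$out_dir)
}

#' Write trial records as JSON-lines
#'
#' One trial record per line; the inverse of [read_trial_log()].
#'
#' @param records Trial-record data frame (e.g. `run$records`).
#' @param path Output `.jsonl` path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  jsonlite::stream_out(records, con, verbose = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  con <- file(path, "r")
  on.exit(close(con), add = TRUE)
  jsonlite::stream_in(con, verbose = FALSE)
}

#' Synthesize the stimulus bank for a configuration
#'
#' Delegates to [write_stimulus_bank()] for the configured training set.
#'
#' @param config A `run_config`.
#' @param cue_probes Also render the 48 cue-removal probes?
#' @return The bank manifest, invisibly.
#' @export
cmd_synth <- function(config, cue_probes = FALSE) {
  ws <- build_training_sets()[[config$training_set]]
  dir <- file.path(config$out_dir, "bank")
  invisible(write_stimulus_bank(ws, config$seed, dir,
                                cue_probes = cue_probes,
                                sample_rate = config$sample_rate))
}

#' Simulate the configured cohort through the full protocol
#'
#' Writes one JSONL trial log per subject plus a cohort index CSV under
#' `out_dir/runs/`, and returns the runs.
#'
#' @param config A `run_config`.
#' @param write_logs Write JSONL logs to disk?
#' @return List of `stress_run` objects, invisibly.
#' @export
cmd_simulate <- function(config, write_logs = TRUE) {
  runs <- lapply(seq_len(config$n_subjects), function(i) {
    simulate_subject(
      config$observer, config$species, seed = config$seed,
      training_set = if (config$n_subjects == 1L) config$training_set
                     else 1L + (i - 1L) %% 2L,
      splus_pattern = if (config$n_subjects == 1L) config$splus_pattern
                      else if (((i - 1L) %/% 2L) %% 2L == 0L) "trochaic"
                      else "iambic",
      subject_id = sprintf("s%02d", i))
  })
  if (write_logs) {
    dir <- file.path(config$out_dir, "runs")
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    index <- do.call(rbind, lapply(runs, function(r) {
      f <- file.path(dir, paste0(r$subject_id, ".jsonl"))
      write_trial_log(r$records, f)
      data.frame(subject_id = r$subject_id, species = r$species$name,
                 passed = r$passed, training_set = r$training_set,
                 splus_pattern = r$splus_pattern, log = basename(f),
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(index, file.path(dir, "index.csv"),
                     row.names = FALSE)
  }
  invisible(runs)
}

#' Analyze a set of runs and write report tables
#'
#' Writes the DR traces, and (for runs that completed the tests) the
#' generalization and cue-test tables, as CSV under `out_dir/report/`.
#'
#' @param runs List of `stress_run` objects (e.g. from [cmd_simulate()]).
#' @param out_dir Output directory.
#' @return List with the computed report objects, invisibly.
#' @export
cmd_analyze <- function(runs, out_dir = tempdir()) {
  dir <- file.path(out_dir, "report")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  # a run read back from a bare log counts as passed if it completed the
  # final 240-trial test
  completed <- function(r) {
    if (inherits(r, "stress_run")) return(isTRUE(r$passed))
    sum(r$phase == "cue_test") >= 240L
  }
  passed <- Filter(completed, runs)
  traces <- do.call(rbind, lapply(runs, function(r) {
    tr <- criterion_trace(r)$trace
    if (nrow(tr)) {
      tr$subject_id <- if (inherits(r, "stress_run")) r$subject_id
                       else r$subject_id[1L]
    }
    tr
  }))
  utils::write.csv(traces, file.path(dir, "dr_trace.csv"),
                   row.names = FALSE)
  out <- list(traces = traces)
  if (length(passed)) {
    gen <- generalization_report(passed)
    utils::write.csv(gen$per_subject,
                     file.path(dir, "generalization.csv"),
                     row.names = FALSE)
    cue <- cue_test_report(passed)
    utils::write.csv(as.data.frame(cue), file.path(dir, "cue_test.csv"),
                     row.names = FALSE)
    out$generalization <- gen
    out$cue_test <- cue
  }
  invisible(out)
}
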