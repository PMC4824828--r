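# Simulated go/no-go subjects.
#
# An observer converts a stimulus's cue parameters into a per-syllable
# stress salience (weighted sum of normalized cues plus Gaussian decision
# noise), infers the stress pattern from which slot is more salient, and
# maps the inferred category to a go probability through a learned
# association that is updated by a delta rule after reward or penalty.
# Cue weights parameterize species-like cue reliance; the presets are
# calibrated only to reproduce qualitative significance signatures, not
# fitted to any subject data.

# normalization constants putting the four cues on comparable [0, 1] scales
.ST_MAX <- 12 * log2(280 / 194)   # max pitch excursion, semitones (~6.35)

.cue_pitch <- function(f0_peak) (12 * log2(f0_peak / 194)) / .ST_MAX
.cue_amp   <- function(rms) pmin(1, pmax(0, 1 + 20 * log10(rms / 0.1) / 10))
.cue_dur   <- function(d) (d - 0.3) / 0.2
.cue_vowel <- function(vowel_mode) as.numeric(vowel_mode == "full")

#' Observer profile
#'
#' @param w_pitch,w_amp,w_dur,w_vowel Nonnegative cue weights.
#' @param sigma Decision-noise SD on the same scale as the weighted cue
#'   evidence (each cue is normalized to roughly `[0, 1]`).
#' @param lapse Probability of an attention lapse, on which the response
#'   is a biased coin with `P(go) = go_bias`.
#' @param go_bias Baseline go probability (naive association value and
#'   lapse response rate).
#' @param learn_rate Delta-rule learning rate for the category-to-go
#'   association.
#' @param response_prob_ceiling Maximum go probability.
#' @param ambiguity Perceptual noise floor: salience differences smaller
#'   in magnitude than this are perceived as ambiguous and resolved by a
#'   fair coin (0 disables the floor, leaving a purely linear-Gaussian
#'   readout).
#' @return An `observer_profile` list.
#' @export
observer_profile <- function(w_pitch = 1, w_amp = 1, w_dur = 1,
                             w_vowel = 1, sigma = 0.3, lapse = 0.03,
                             go_bias = 0.5, learn_rate = 0.25,
                             response_prob_ceiling = 0.98,
                             ambiguity = 0) {
  stopifnot(w_pitch >= 0, w_amp >= 0, w_dur >= 0, w_vowel >= 0,
            sigma >= 0, lapse >= 0, lapse <= 1, go_bias >= 0,
            go_bias <= 1, learn_rate >= 0, learn_rate <= 1,
            response_prob_ceiling > 0, response_prob_ceiling <= 1,
            ambiguity >= 0)
  structure(list(w_pitch = w_pitch, w_amp = w_amp, w_dur = w_dur,
                 w_vowel = w_vowel, sigma = sigma, lapse = lapse,
                 go_bias = go_bias, learn_rate = learn_rate,
                 response_prob_ceiling = response_prob_ceiling,
                 ambiguity = ambiguity),
            class = "observer_profile")
}

#' Built-in observer presets
#'
#' `"human_like"` weights pitch and amplitude heavily with near-zero
#' duration and vowel weights and no ambiguity floor; `"budgie_like"`
#' spreads moderate weight over all four cues behind a high ambiguity
#' floor, so single cues rarely clear the floor (low single-cue
#' sensitivity) while multi-cue evidence does; `"nonlearner"` has zero
#' learning rate and never acquires the discrimination.  Presets are
#' calibrated to reproduce qualitative species significance signatures
#' only, not fitted to subject data.
#'
#' @param name Preset name.
#' @return An `observer_profile`.
#' @export
observer_preset <- function(name = c("human_like", "budgie_like",
                                     "nonlearner")) {
  name <- match.arg(name)
  switch(name,
    human_like = observer_profile(
      w_pitch = 1.0, w_amp = 0.9, w_dur = 0.03, w_vowel = 0.03,
      sigma = 0.28, lapse = 0.02, learn_rate = 0.30),
    budgie_like = observer_profile(
      w_pitch = 0.40, w_amp = 0.50, w_dur = 0.40, w_vowel = 0.50,
      sigma = 0.15, lapse = 0.01, learn_rate = 0.15,
      ambiguity = 0.75),
    nonlearner = observer_profile(
      w_pitch = 0, w_amp = 0, w_dur = 0, w_vowel = 0,
      sigma = 0.5, lapse = 0.10, learn_rate = 0))
}

#' Initialize observer state
#'
#' Association strengths (category -> go) start at `go_bias` for every
#' perceivable category, giving a naive go rate of `go_bias`.
#'
#' @param profile An `observer_profile`.
#' @return An `observer_state` list.
#' @export
observer_state <- function(profile) {
  assoc <- rep(profile$go_bias, 5L)
  names(assoc) <- c("trochaic", "iambic", "ambiguous", "sound", "nosound")
  structure(list(assoc = assoc, trial = 0L), class = "observer_state")
}

#' Per-syllable normalized cue evidence for a stimulus-table row
#'
#' Cues are read from the manifest parameters (not measured from audio):
#' pitch excursion in semitones above 194 Hz scaled by the maximum
#' excursion, RMS in dB re 0.1 scaled by 10 dB, duration as
#' `(d - 0.3) / 0.2`, vowel fullness as 0/1.
#'
#' @param row One schedule / stimulus-table row with per-slot parameter
#'   columns.
#' @return 2x4 matrix (slots x cues `pitch`, `amp`, `dur`, `vowel`).
#' @export
percept_cues <- function(row) {
  m <- rbind(
    c(.cue_pitch(row$f0_peak1), .cue_amp(row$rms1),
      .cue_dur(row$duration1), .cue_vowel(row$vowel_mode1)),
    c(.cue_pitch(row$f0_peak2), .cue_amp(row$rms2),
      .cue_dur(row$duration2), .cue_vowel(row$vowel_mode2)))
  dimnames(m) <- list(c("slot1", "slot2"),
                      c("pitch", "amp", "dur", "vowel"))
  m
}

#' Infer the stress pattern of a word stimulus
#'
#' Stress salience per syllable is the weighted sum of its normalized cues
#' plus independent Gaussian noise; the slot with higher salience is
#' perceived as stressed.  Exact ties (possible only at `sigma = 0`) are
#' perceived as ambiguous and resolved by a fair coin.
#'
#' @param row Schedule / stimulus-table row.
#' @param profile An `observer_profile`.
#' @return `"trochaic"` or `"iambic"` (the coin already resolved
#'   ambiguity), with attribute `"ambiguous"`.
#' @export
perceive <- function(row, profile) {
  cues <- percept_cues(row)
  w <- c(profile$w_pitch, profile$w_amp, profile$w_dur, profile$w_vowel)
  sal <- as.numeric(cues %*% w) + stats::rnorm(2L, 0, profile$sigma)
  diff <- sal[1L] - sal[2L]
  if (abs(diff) < max(profile$ambiguity, 1e-12)) {
    out <- if (stats::runif(1L) < 0.5) "trochaic" else "iambic"
    attr(out, "ambiguous") <- TRUE
  } else {
    out <- if (diff > 0) "trochaic" else "iambic"
    attr(out, "ambiguous") <- FALSE
  }
  out
}

#' Generate a go/no-go response
#'
#' `P(go) = lapse * go_bias + (1 - lapse) * association[category]`, capped
#' at the profile's response ceiling.
#'
#' @param category Perceived category (name into the association table).
#' @param state An `observer_state`.
#' @param profile An `observer_profile`.
#' @return Logical: `TRUE` for go.
#' @export
respond <- function(category, state, profile) {
  p <- profile$lapse * profile$go_bias +
    (1 - profile$lapse) * state$assoc[[category]]
  p <- min(p, profile$response_prob_ceiling)
  stats::runif(1L) < p
}

#' Update the association after feedback
#'
#' Delta rule on the perceived category's go association: toward 1 after
#' reward, toward 0 after penalty, by `learn_rate * (target - current)`.
#' Probe trials and trials without feedback leave the state unchanged.
#'
#' @param state An `observer_state`.
#' @param category Perceived category of the trial.
#' @param feedback `"reward"`, `"penalty"` or `"none"`.
#' @param profile An `observer_profile`.
#' @return Updated `observer_state`.
#' @export
update_state <- function(state, category, feedback, profile) {
  state$trial <- state$trial + 1L
  if (feedback == "none") return(state)
  target <- if (feedback == "reward") 1 else 0
  a <- state$assoc[[category]]
  state$assoc[[category]] <- a + profile$learn_rate * (target - a)
  state
}

# Run a whole schedule through the observer, updating state trial by
# trial.  Mean salience per slot is precomputed for all word trials; the
# sequential loop only draws decision noise, the go response, and the
# reward coin, and applies the delta-rule update.  `stop_rule(i, counts)`
# (counts = c(nS+, nS-, goS+, goS-)) may end the run early (human
# cumulative criteria).  Returns records (schedule + percept/responded/
# feedback columns), the updated state, and the final counts.
.run_schedule <- function(sched, state, obs, stop_rule = NULL) {
  n <- nrow(sched)
  role <- sched$role
  rp <- sched$reinforce_prob
  is_word <- !(role %in% c("sound", "nosound"))
  sal1 <- sal2 <- numeric(n)
  if (any(is_word)) {
    w <- c(obs$w_pitch, obs$w_amp, obs$w_dur, obs$w_vowel)
    m1 <- cbind(.cue_pitch(sched$f0_peak1), .cue_amp(sched$rms1),
                .cue_dur(sched$duration1), .cue_vowel(sched$vowel_mode1))
    m2 <- cbind(.cue_pitch(sched$f0_peak2), .cue_amp(sched$rms2),
                .cue_dur(sched$duration2), .cue_vowel(sched$vowel_mode2))
    sal1 <- as.numeric(m1 %*% w)
    sal2 <- as.numeric(m2 %*% w)
  }
  assoc <- state$assoc
  sd_diff <- obs$sigma * sqrt(2)  # two independent per-slot noise draws
  percept <- character(n)
  responded <- logical(n)
  feedback <- character(n)
  counts <- c(nplus = 0, nminus = 0, goplus = 0, gominus = 0)
  used <- n
  for (i in seq_len(n)) {
    cat_i <- if (is_word[i]) {
      d <- sal1[i] - sal2[i] + stats::rnorm(1L, 0, sd_diff)
      if (abs(d) < max(obs$ambiguity, 1e-12)) {
        if (stats::runif(1L) < 0.5) "trochaic" else "iambic"
      } else if (d > 0) "trochaic" else "iambic"
    } else {
      role[i]
    }
    p_go <- min(obs$lapse * obs$go_bias + (1 - obs$lapse) * assoc[[cat_i]],
                obs$response_prob_ceiling)
    go <- stats::runif(1L) < p_go
    fb <- if (!go || role[i] == "probe") {
      "none"
    } else if (role[i] %in% c("Splus", "sound")) {
      if (stats::runif(1L) < rp[i]) "reward" else "none"
    } else {
      "penalty"
    }
    if (fb != "none") {
      target <- if (fb == "reward") 1 else 0
      assoc[[cat_i]] <- assoc[[cat_i]] +
        obs$learn_rate * (target - assoc[[cat_i]])
    }
    percept[i] <- cat_i
    responded[i] <- go
    feedback[i] <- fb
    if (role[i] %in% c("Splus", "sound")) {
      counts[1L] <- counts[1L] + 1
      counts[3L] <- counts[3L] + go
    } else if (role[i] %in% c("Sminus", "nosound")) {
      counts[2L] <- counts[2L] + 1
      counts[4L] <- counts[4L] + go
    }
    if (!is.null(stop_rule) && stop_rule(i, counts)) {
      used <- i
      break
    }
  }
  state$assoc <- assoc
  state$trial <- state$trial + used
  rec <- sched[seq_len(used), , drop = FALSE]
  rec$percept <- percept[seq_len(used)]
  rec$responded <- responded[seq_len(used)]
  rec$feedback <- feedback[seq_len(used)]
  list(records = rec, state = state, counts = counts)
}

.counts_dr <- function(counts) {
  if (counts[[1L]] == 0 || counts[[2L]] == 0) return(NA_real_)
  p_plus <- counts[[3L]] / counts[[1L]] * 100
  p_minus <- counts[[4L]] / counts[[2L]] * 100
  if (p_plus + p_minus == 0) return(NA_real_)
  p_plus / (p_plus + p_minus)
}

# run a criterion phase for a human (trial-counted) subject
.run_human_phase <- function(sched_fn, profile, state, obs, phase) {
  max_t <- profile$max_trials[[phase]]
  sched <- sched_fn(max_t)
  thr <- profile$criterion_dr
  min_t <- profile$min_trials
  stop_rule <- function(i, counts) {
    i >= min_t && {
      d <- .counts_dr(counts)
      !is.na(d) && d >= thr
    }
  }
  out <- .run_schedule(sched, state, obs, stop_rule)
  n_used <- nrow(out$records)
  d <- .counts_dr(out$counts)
  status <- if (!is.na(d) && d >= thr && n_used >= min_t) "advance"
            else "failed"
  out$records$session <- 1L
  list(records = out$records, state = out$state,
       outcome = list(status = status, dr = d, trials_used = n_used,
                      sessions_used = 1L))
}

# session-level criterion on a vector of completed-session DRs
.session_criterion <- function(profile, phase, drs) {
  ok <- !is.na(drs) & drs >= profile$criterion_dr
  k <- length(drs)
  switch(phase,
    preliminary    = sum(ok) >= profile$criterion_sessions[["preliminary"]],
    discrimination = k >= 4L && all(utils::tail(ok, 4L)),
    pretesting     = k >= 3L && all(utils::tail(ok, 2L)),
    pretesting2    = k >= 1L && ok[k])
}

# run a criterion phase for a budgerigar (sessioned) subject
.run_budgie_phase <- function(sched_fn, profile, state, obs, phase) {
  recs <- list()
  drs <- numeric(0)
  repeat {
    sched <- sched_fn(draw_session_length(profile))
    out <- .run_schedule(sched, state, obs)
    state <- out$state
    out$records$session <- length(drs) + 1L
    recs[[length(recs) + 1L]] <- out$records
    drs <- c(drs, .counts_dr(out$counts))
    if (.session_criterion(profile, phase, drs)) {
      status <- "advance"
      break
    }
    if (length(drs) >= profile$max_sessions[[phase]]) {
      status <- "failed"
      break
    }
  }
  all_rec <- do.call(rbind, recs)
  list(records = all_rec, state = state,
       outcome = list(status = status, dr = drs[length(drs)],
                      trials_used = nrow(all_rec),
                      sessions_used = length(drs), session_dr = drs))
}

# run a fixed-length test phase (trial count is the schedule's length);
# budgerigars may split it over sessions via a resumable cursor
.run_test_phase <- function(sched, profile, state, obs) {
  if (profile$sessioned) {
    lens <- integer(0)
    while (sum(lens) < nrow(sched)) {
      lens <- c(lens, draw_session_length(profile))
    }
    session <- rep(seq_along(lens), lens)[seq_len(nrow(sched))]
  } else {
    session <- rep(1L, nrow(sched))
  }
  out <- .run_schedule(sched, state, obs)
  out$records$session <- session
  list(records = out$records, state = out$state,
       outcome = list(status = "advance", dr = .counts_dr(out$counts),
                      trials_used = nrow(out$records),
                      sessions_used = max(session)))
}

#' Simulate one subject through the complete protocol
#'
#' Runs preliminary training, discrimination training, pre-testing, the
#' novel-word generalization test (120 trials), a second pre-testing, and
#' the cue-removal test (240 trials), applying the species' progression
#' criteria between phases.  A subject failing a criterion phase is
#' excluded and the run stops there.  Deterministic under a fixed seed.
#'
#' @param obs An `observer_profile` (or preset name).
#' @param species A `species_profile` (or species name).
#' @param seed Integer seed (expanded into schedule/observer substreams).
#' @param training_set 1 or 2: which word set is trained.
#' @param splus_pattern `"trochaic"` or `"iambic"`.
#' @param subject_id Identifier stored in the logs.
#' @return A `stress_run` list: `records` (all trial records), `phases`
#'   (one row per attempted phase with `status`, `dr`, `trials_used`,
#'   `sessions_used`), `passed`, plus the configuration.
#' @export
#' @examples
#' run <- simulate_subject("human_like", "human", seed = 1)
#' run$phases
simulate_subject <- function(obs, species, seed = 1L,
                             training_set = 1L,
                             splus_pattern = c("trochaic", "iambic"),
                             subject_id = "s01") {
  if (is.character(obs)) obs <- observer_preset(obs)
  if (is.character(species)) species <- species_profile(species)
  splus_pattern <- match.arg(splus_pattern)
  local_seed(substream_seed(seed, paste0("subject_", subject_id)))

  sets <- build_training_sets()
  trained <- sets[[training_set]]
  alternate <- sets[[if (training_set == 1L) 2L else 1L]]
  train_tab <- stimulus_table(trained)
  pool <- syllable_pool(trained)
  state <- observer_state(obs)

  phases <- list()
  records <- list()
  run_phase <- function(phase, runner) {
    out <- runner()
    out$records$phase_label <- phase
    records[[length(records) + 1L]] <<- out$records
    phases[[length(phases) + 1L]] <<- data.frame(
      phase = phase, status = out$outcome$status,
      dr = out$outcome$dr, trials_used = out$outcome$trials_used,
      sessions_used = out$outcome$sessions_used %||% NA_integer_,
      stringsAsFactors = FALSE)
    state <<- out$state
    out$outcome$status
  }

  passed <- TRUE
  steps <- list(
    list("preliminary",
         function(n) make_preliminary_schedule(pool, n)),
    list("discrimination",
         function(n) make_discrimination_schedule(
           train_tab, splus_pattern, n, 1, "discrimination")),
    list("pretesting",
         function(n) make_discrimination_schedule(
           train_tab, splus_pattern, n, 0.85, "pretesting")),
    list("generalization", NULL),
    list("pretesting2",
         function(n) make_discrimination_schedule(
           train_tab, splus_pattern, n, 0.85, "pretesting2")),
    list("cue_test", NULL))

  for (stp in steps) {
    phase <- stp[[1L]]
    if (phase == "generalization") {
      probe_tab <- stimulus_table(alternate)
      sched <- make_generalization_schedule(train_tab, probe_tab,
                                            splus_pattern)
      status <- run_phase(phase, function() {
        .run_test_phase(sched, species, state, obs)
      })
    } else if (phase == "cue_test") {
      bank <- cue_probe_bank(trained)
      sched <- make_cue_test_schedule(train_tab, bank, splus_pattern)
      status <- run_phase(phase, function() {
        .run_test_phase(sched, species, state, obs)
      })
    } else {
      sched_fn <- stp[[2L]]
      status <- run_phase(phase, function() {
        if (species$sessioned) {
          .run_budgie_phase(sched_fn, species, state, obs, phase)
        } else {
          .run_human_phase(sched_fn, species, state, obs, phase)
        }
      })
    }
    if (status == "failed") {
      passed <- FALSE
      break
    }
  }

  recs <- .rbind_fill(records)
  recs$subject_id <- subject_id
  recs$species <- species$name
  recs$splus_pattern <- splus_pattern
  recs$training_set <- training_set
  structure(list(
    records = recs,
    phases = do.call(rbind, phases),
    passed = passed,
    subject_id = subject_id,
    observer = obs, species = species,
    training_set = training_set, splus_pattern = splus_pattern,
    seed = seed), class = "stress_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.stress_run <- function(x, ...) {
  cat(sprintf("<stress_run: subject %s (%s), %s, set %d, S+ = %s>\n",
              x$subject_id, x$species$name,
              if (x$passed) "passed" else "excluded",
              x$training_set, x$splus_pattern))
  print(x$phases)
  invisible(x)
}

#' Simulate a counterbalanced cohort of subjects
#'
#' Training set and S+ pattern are assigned by a deterministic function of
#' subject index (alternating set, then pattern), as in counterbalanced
#' designs.
#'
#' @param n Number of subjects.
#' @param obs Observer profile or preset name.
#' @param species Species profile or name.
#' @param seed Integer master seed.
#' @return List of `stress_run` objects, one per subject.
#' @export
simulate_cohort <- function(n, obs, species, seed = 1L) {
  lapply(seq_len(n), function(i) {
    simulate_subject(
      obs, species, seed = seed,
      training_set = 1L + (i - 1L) %% 2L,
      splus_pattern = if (((i - 1L) %/% 2L) %% 2L == 0L) "trochaic"
                      else "iambic",
      subject_id = sprintf("s%02d", i))
  })
}
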