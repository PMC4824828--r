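# Phase structure, trial scheduling and reinforcement contingencies.
#
# Phase order for a passing subject:
#   preliminary -> discrimination -> pretesting -> generalization (test 1)
#   -> pretesting2 -> cue_test (test 2)
# Humans run trial-counted phases with hard maxima (100 / 150 / 50);
# budgerigars run daily sessions of variable length (mean 103 trials) with
# session-level criteria.  All criteria use the discrimination ratio
# DR = %response(S+) / (%response(S+) + %response(S-)) with threshold 0.8.

.PHASES <- c("preliminary", "discrimination", "pretesting",
             "generalization", "pretesting2", "cue_test")

#' Phase labels in protocol order
#' @return Character vector of the six phase labels.
#' @export
phase_labels <- function() .PHASES

#' Species protocol profile
#'
#' Encodes the per-species phase criteria, maxima and feedback
#' contingencies.  Humans: cumulative-DR criteria over at least 10 trials
#' with maxima of 100 (preliminary), 150 (discrimination) and 50
#' (pre-testing) trials; penalty is -10 points plus a 5 s delay.
#' Budgerigars: session-based criteria (2 sessions with DR >= 0.8 for
#' preliminary; 4 consecutive for discrimination; >= 3 sessions with the
#' last 2 at criterion for pre-testing; 1 session for the second
#' pre-testing), variable session length (Poisson, mean 103, floor 40),
#' penalty is a 30 s delay.
#'
#' @param name `"human"` or `"budgerigar"`.
#' @return A `species_profile` list.
#' @export
species_profile <- function(name = c("human", "budgerigar")) {
  name <- match.arg(name)
  base <- list(name = name, criterion_dr = 0.8, min_trials = 10L,
               response_window = 2)
  prof <- if (name == "human") {
    c(base, list(
      sessioned = FALSE,
      max_trials = c(preliminary = 100L, discrimination = 150L,
                     pretesting = 50L, pretesting2 = 50L),
      penalty_delay = 5, reward = "points", reward_points = 10L))
  } else {
    c(base, list(
      sessioned = TRUE,
      session_trials_mean = 103, session_trials_min = 40L,
      max_sessions = c(preliminary = 40L, discrimination = 130L,
                       pretesting = 40L, pretesting2 = 40L),
      criterion_sessions = c(preliminary = 2L, discrimination = 4L,
                             pretesting = 3L, pretesting2 = 1L),
      penalty_delay = 30, reward = "food"))
  }
  structure(prof, class = "species_profile")
}

# bind data frames with unequal columns (missing filled with NA)
.rbind_fill <- function(dfs) {
  dfs <- Filter(function(d) !is.null(d) && nrow(d) > 0L, dfs)
  if (length(dfs) == 0L) return(NULL)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (cl in setdiff(cols, names(d))) d[[cl]] <- NA
    d[cols]
  }))
}

# scatter per-block role labels: each block gets a random within-block order
.block_roles <- function(roles_per_block, n_blocks) {
  unlist(lapply(seq_len(n_blocks), function(b) sample(roles_per_block)))
}

# cycle through ids in random order without replacement, reshuffling when
# the pool is exhausted
.cycled_sample <- function(ids, n) {
  out <- character(0)
  while (length(out) < n) out <- c(out, sample(ids))
  out[seq_len(n)]
}

#' Single-syllable stimulus pool for preliminary training
#'
#' The 6 syllables of the training set, each realized both stressed and
#' unstressed with freshly drawn cue parameters (12 variants).
#'
#' @param ws A `word_set`.
#' @return Data frame, one row per syllable variant.
#' @export
syllable_pool <- function(ws) {
  syls <- word_set_syllables(ws)
  rows <- lapply(c(TRUE, FALSE), function(stressed) {
    do.call(rbind, lapply(syls, function(sy) {
      p <- draw_cue_params(stressed)
      data.frame(syllable = sy, stressed = stressed,
                 f0_peak = p$f0_peak, duration = p$duration,
                 rms = p$rms_target, vowel_mode = p$vowel_mode,
                 stimulus_id = sprintf("syl_%s_%s", sy,
                                       if (stressed) "str" else "uns"),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Preliminary-training trial schedule
#'
#' Blocks of 10 trials containing exactly 5 sound and 5 no-sound trials in
#' random order.  Sound trials cycle through the syllable pool in random
#' order without replacement, reshuffling once all variants have been
#' presented.  Responding on sound trials is rewarded; responding on
#' no-sound trials is penalized.
#'
#' @param pool Syllable pool from [syllable_pool()].
#' @param n_trials Number of trials (rounded up to a whole block).
#' @return Schedule data frame with one row per trial.
#' @export
make_preliminary_schedule <- function(pool, n_trials) {
  if (is.null(pool) || nrow(pool) == 0L) {
    stop("empty syllable pool", call. = FALSE)
  }
  n_blocks <- ceiling(n_trials / 10L)
  roles <- .block_roles(rep(c("sound", "nosound"), each = 5L), n_blocks)
  n <- n_blocks * 10L
  sched <- data.frame(
    trial = seq_len(n), block = rep(seq_len(n_blocks), each = 10L),
    phase = "preliminary", role = roles,
    stimulus_id = NA_character_, reinforce_prob = 0,
    stringsAsFactors = FALSE)
  is_sound <- sched$role == "sound"
  ids <- .cycled_sample(pool$stimulus_id, sum(is_sound))
  sched$stimulus_id[is_sound] <- ids
  sched$reinforce_prob[is_sound] <- 1
  idx <- match(sched$stimulus_id, pool$stimulus_id)
  sched$syllable <- pool$syllable[idx]
  sched$stressed <- pool$stressed[idx]
  sched[seq_len(n_trials), , drop = FALSE]
}

#' Discrimination-training / pre-testing trial schedule
#'
#' Blocks of 10 with exactly 5 trochaic and 5 iambic word trials in random
#' order; the S+ role follows `splus_pattern`.  During pre-testing the S+
#' reinforcement probability drops from 1 to 0.85.
#'
#' @param stim_tab Training stimulus table ([stimulus_table()]; 12 words x
#'   2 patterns).
#' @param splus_pattern `"trochaic"` or `"iambic"`.
#' @param n_trials Number of trials.
#' @param reinforce_prob_splus Reward probability on S+ responses (1 for
#'   discrimination training, 0.85 for pre-testing).
#' @param phase Phase label stored in the schedule.
#' @return Schedule data frame with one row per trial, carrying the
#'   stimulus cue parameters.
#' @export
make_discrimination_schedule <- function(stim_tab, splus_pattern,
                                         n_trials,
                                         reinforce_prob_splus = 1,
                                         phase = "discrimination") {
  splus_pattern <- match.arg(splus_pattern, c("trochaic", "iambic"))
  n_blocks <- ceiling(n_trials / 10L)
  pats <- .block_roles(rep(c("trochaic", "iambic"), each = 5L), n_blocks)
  n <- n_blocks * 10L
  ids <- character(n)
  for (pat in c("trochaic", "iambic")) {
    sel <- pats == pat
    ids[sel] <- .cycled_sample(
      stim_tab$stimulus_id[stim_tab$pattern == pat], sum(sel))
  }
  sched <- data.frame(
    trial = seq_len(n), block = rep(seq_len(n_blocks), each = 10L),
    phase = phase,
    role = ifelse(pats == splus_pattern, "Splus", "Sminus"),
    stimulus_id = ids,
    reinforce_prob = ifelse(pats == splus_pattern,
                            reinforce_prob_splus, 0),
    stringsAsFactors = FALSE)
  sched <- cbind(sched,
                 stim_tab[match(ids, stim_tab$stimulus_id),
                          setdiff(names(stim_tab), "stimulus_id")])
  rownames(sched) <- NULL
  sched[seq_len(n_trials), , drop = FALSE]
}

# common builder for the two probe tests: blocks of 10 = 2 probes + 4 S+ +
# 4 S-, each probe exactly once, each training stimulus equally often
.probe_test_schedule <- function(train_tab, probe_tab, splus_pattern,
                                 phase) {
  splus_pattern <- match.arg(splus_pattern, c("trochaic", "iambic"))
  n_probes <- nrow(probe_tab)
  n_blocks <- n_probes / 2L
  reps <- (n_blocks * 4L) / (nrow(train_tab) / 2L)
  splus_ids  <- sample(rep(train_tab$stimulus_id[
    train_tab$pattern == splus_pattern], reps))
  sminus_ids <- sample(rep(train_tab$stimulus_id[
    train_tab$pattern != splus_pattern], reps))
  probe_ids <- sample(probe_tab$stimulus_id)
  sched <- list()
  for (b in seq_len(n_blocks)) {
    roles <- sample(c("probe", "probe", rep("Splus", 4L),
                      rep("Sminus", 4L)))
    ids <- character(10L)
    ids[roles == "probe"]  <- probe_ids[(2L * b - 1L):(2L * b)]
    ids[roles == "Splus"]  <- splus_ids[(4L * b - 3L):(4L * b)]
    ids[roles == "Sminus"] <- sminus_ids[(4L * b - 3L):(4L * b)]
    sched[[b]] <- data.frame(
      trial = (b - 1L) * 10L + 1:10, block = b, phase = phase,
      role = roles, stimulus_id = ids,
      reinforce_prob = ifelse(roles == "Splus", 0.85, 0),
      stringsAsFactors = FALSE)
  }
  sched <- do.call(rbind, sched)
  all_tab <- .rbind_fill(list(train_tab, probe_tab))
  sched <- cbind(sched,
                 all_tab[match(sched$stimulus_id, all_tab$stimulus_id),
                         setdiff(names(all_tab), "stimulus_id")])
  rownames(sched) <- NULL
  sched
}

#' Generalization-test schedule (test 1: novel words)
#'
#' 120 trials in 12 blocks of 10; each block holds 2 unreinforced probe
#' trials (novel words from the alternate training set), 4 trained S+ and
#' 4 trained S- trials.  Each of the 24 probe stimuli occurs exactly once
#' and each of the 24 training stimuli exactly 4 times.  Trained S+ trials
#' keep the 0.85 pre-testing reinforcement probability.
#'
#' @param train_tab Stimulus table of the trained set (24 rows).
#' @param probe_tab Stimulus table of the alternate set (24 rows).
#' @param splus_pattern `"trochaic"` or `"iambic"`.
#' @return Schedule data frame of 120 rows.
#' @export
make_generalization_schedule <- function(train_tab, probe_tab,
                                         splus_pattern) {
  if (length(intersect(unique(train_tab$word),
                       unique(probe_tab$word))) > 0L) {
    stop("trained and probe word sets must be disjoint", call. = FALSE)
  }
  if (nrow(probe_tab) != 24L) {
    stop("probe table must hold 24 stimuli (12 words x 2 patterns)",
         call. = FALSE)
  }
  .probe_test_schedule(train_tab, probe_tab, splus_pattern,
                       phase = "generalization")
}

#' Cue-removal test schedule (test 2: absent cues)
#'
#' 240 trials in 24 blocks of 10; each block holds 2 unreinforced probes
#' from the 48-stimulus cue-removal bank, 4 trained S+ and 4 trained S-
#' trials.  Each probe occurs exactly once and each training stimulus 8
#' times.
#'
#' @param train_tab Stimulus table of the trained set (24 rows).
#' @param probe_bank Probe bank from [cue_probe_bank()] (48 rows).
#' @param splus_pattern `"trochaic"` or `"iambic"`.
#' @return Schedule data frame of 240 rows.
#' @export
make_cue_test_schedule <- function(train_tab, probe_bank, splus_pattern) {
  if (nrow(probe_bank) != 48L) {
    stop("cue probe bank must hold exactly 48 stimuli, got ",
         nrow(probe_bank), call. = FALSE)
  }
  .probe_test_schedule(train_tab, probe_bank, splus_pattern,
                       phase = "cue_test")
}

#' Adjudicate one trial
#'
#' Applies the reinforcement contingencies: responding on an S+ (or sound)
#' trial is rewarded with probability `reinforce_prob` (no feedback
#' otherwise); responding on an S- (or no-sound) trial is penalized;
#' probe trials and withheld responses produce no feedback.
#'
#' @param role Trial role: `"Splus"`, `"Sminus"`, `"probe"`, `"sound"` or
#'   `"nosound"`.
#' @param responded Logical: did the subject respond within the window?
#' @param reinforce_prob Reward probability given a response on S+.
#' @return One of `"reward"`, `"penalty"`, `"none"`.
#' @export
adjudicate_trial <- function(role, responded, reinforce_prob = 1) {
  if (!responded || role == "probe") return("none")
  if (role %in% c("Splus", "sound")) {
    if (stats::runif(1L) < reinforce_prob) "reward" else "none"
  } else if (role %in% c("Sminus", "nosound")) {
    "penalty"
  } else {
    stop("unknown trial role: ", role, call. = FALSE)
  }
}

# internal DR on a set of trial records (go/no-go responses)
.dr <- function(records) {
  splus  <- records$role %in% c("Splus", "sound")
  sminus <- records$role %in% c("Sminus", "nosound")
  if (!any(splus) || !any(sminus)) return(NA_real_)
  p_plus  <- mean(records$responded[splus]) * 100
  p_minus <- mean(records$responded[sminus]) * 100
  if (p_plus + p_minus == 0) return(NA_real_)
  p_plus / (p_plus + p_minus)
}

#' Apply the per-phase, per-species progression criterion
#'
#' Given the trial history of the current phase, decides whether the
#' subject advances, continues, or has failed the phase.  Humans advance
#' at the first trial `t >= 10` where the phase-cumulative DR reaches 0.8,
#' and fail on reaching the phase maximum without doing so.  Budgerigars
#' advance on session-level DR criteria: 2 sessions at criterion
#' (preliminary), 4 consecutive sessions (discrimination), at least 3
#' sessions with the last 2 at criterion (pre-testing), 1 session at
#' criterion (second pre-testing); they fail on exceeding the session cap.
#'
#' @param profile A [species_profile()].
#' @param phase One of `"preliminary"`, `"discrimination"`,
#'   `"pretesting"`, `"pretesting2"`.
#' @param history Data frame of trial records with columns `role`,
#'   `responded` and (for budgerigars) `session`.
#' @param session_complete For sessioned species, is the last session in
#'   `history` finished (criteria are only evaluated on completed
#'   sessions)?
#' @return List with elements `status` (`"advance"`, `"continue"` or
#'   `"failed"`), `dr` (final cumulative or last-session DR),
#'   `trials_used`, `sessions_used`, and for advancing humans `at_trial`.
#' @export
phase_controller <- function(profile, phase, history,
                             session_complete = TRUE) {
  phase <- match.arg(phase, c("preliminary", "discrimination",
                              "pretesting", "pretesting2"))
  thr <- profile$criterion_dr
  n <- nrow(history)
  if (!profile$sessioned) {
    max_t <- profile$max_trials[[phase]]
    if (n >= profile$min_trials) {
      for (t in seq(profile$min_trials, n)) {
        d <- .dr(history[seq_len(t), , drop = FALSE])
        if (!is.na(d) && d >= thr) {
          return(list(status = "advance", dr = d, trials_used = t,
                      sessions_used = NA_integer_, at_trial = t))
        }
      }
    }
    d <- .dr(history)
    if (n >= max_t) {
      return(list(status = "failed", dr = d, trials_used = n,
                  sessions_used = NA_integer_))
    }
    return(list(status = "continue", dr = d, trials_used = n,
                sessions_used = NA_integer_))
  }
  # sessioned (budgerigar): evaluate completed sessions
  sess <- sort(unique(history$session))
  if (!session_complete && length(sess)) sess <- utils::head(sess, -1L)
  drs <- vapply(sess, function(s) {
    .dr(history[history$session == s, , drop = FALSE])
  }, numeric(1L))
  ok <- !is.na(drs) & drs >= thr
  k <- length(drs)
  advance <- switch(phase,
    preliminary    = sum(ok) >= profile$criterion_sessions[["preliminary"]],
    discrimination = k >= 4L && any(vapply(4:k, function(i) {
                       all(ok[(i - 3L):i])
                     }, logical(1L))),
    pretesting     = k >= 3L && all(utils::tail(ok, 2L)),
    pretesting2    = k >= 1L && ok[k])
  dr_last <- if (k) drs[k] else NA_real_
  status <- if (isTRUE(advance)) {
    "advance"
  } else if (k >= profile$max_sessions[[phase]]) {
    "failed"
  } else {
    "continue"
  }
  list(status = status, dr = dr_last, trials_used = n, sessions_used = k,
       session_dr = drs)
}

#' Draw a budgerigar session length
#'
#' Poisson with mean 103 trials, truncated below at 40 (sessions are
#' time-limited, not trial-limited, so length varies day to day).
#'
#' @param profile A budgerigar [species_profile()].
#' @return Integer number of trials.
#' @export
draw_session_length <- function(profile) {
  max(profile$session_trials_min,
      stats::rpois(1L, profile$session_trials_mean))
}
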