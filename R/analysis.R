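# Response measures and statistics.
#
# The discrimination ratio is
#   DR = %response(S+) / (%response(S+) + %response(S-)),
# 0.5 meaning equal responding to both classes and 1.0 perfect
# discrimination.  Category tests are binomial against p0 = 0.5 using the
# normal approximation z = (x - n/2) / sqrt(n/4) (no continuity
# correction) with the exact binomial tail reported alongside and treated
# as authoritative for n < 30.

#' Discrimination ratio over a window of trial records
#'
#' @param records Data frame of trial records with columns `role`
#'   (`"Splus"`/`"sound"` counted as S+, `"Sminus"`/`"nosound"` as S-;
#'   probes are ignored) and `responded`.
#' @return A `dr_result` list: `percent_splus`, `percent_sminus`, `dr`
#'   (`NA` and `defined = FALSE` when both response percentages are zero),
#'   `n_splus`, `n_sminus`.
#' @export
#' @examples
#' recs <- data.frame(role = rep(c("Splus", "Sminus"), each = 10),
#'                    responded = rep(c(TRUE, FALSE), c(15, 5)))
#' discrimination_ratio(recs)$dr
discrimination_ratio <- function(records) {
  splus <- records$role %in% c("Splus", "sound")
  sminus <- records$role %in% c("Sminus", "nosound")
  if (!any(splus) || !any(sminus)) {
    stop("window must contain at least one S+ and one S- trial",
         call. = FALSE)
  }
  p_plus <- mean(records$responded[splus]) * 100
  p_minus <- mean(records$responded[sminus]) * 100
  defined <- (p_plus + p_minus) > 0
  structure(list(
    percent_splus = p_plus, percent_sminus = p_minus,
    dr = if (defined) p_plus / (p_plus + p_minus) else NA_real_,
    defined = defined,
    n_splus = sum(splus), n_sminus = sum(sminus)),
    class = "dr_result")
}

#' @export
print.dr_result <- function(x, ...) {
  cat(sprintf("DR = %s  (%%S+ = %.1f over %d, %%S- = %.1f over %d)\n",
              if (x$defined) sprintf("%.3f", x$dr) else "undefined",
              x$percent_splus, x$n_splus, x$percent_sminus, x$n_sminus))
  invisible(x)
}

#' Binomial test of category-directed responding
#'
#' Tests whether responses to unreinforced probes are directed to the
#' trained rewarded category more often than chance (p0 = 0.5).  By
#' default `n` counts go-responses to probes and `x` those directed to
#' probes of the rewarded category; `count = "trials"` instead scores
#' every probe trial as correct/incorrect (response to S+ category or
#' non-response to S- category).
#'
#' @param probes Data frame of probe trial records with columns `pattern`,
#'   `responded`.
#' @param splus_pattern The trained rewarded pattern.
#' @param count Counting convention, `"responses"` (default) or
#'   `"trials"`.
#' @return A `binomial_result`: `x`, `n`, `z`, `p_normal_one`,
#'   `p_normal_two`, `p_exact_one`, `p_exact_two`, `defined`.
#' @export
category_binomial <- function(probes, splus_pattern,
                              count = c("responses", "trials")) {
  count <- match.arg(count)
  if (count == "responses") {
    go <- probes[probes$responded, , drop = FALSE]
    x <- sum(go$pattern == splus_pattern)
    n <- nrow(go)
  } else {
    correct <- ifelse(probes$pattern == splus_pattern,
                      probes$responded, !probes$responded)
    x <- sum(correct)
    n <- nrow(probes)
  }
  binomial_result(x, n)
}

#' Binomial result from raw counts
#'
#' @param x Count in the rewarded direction.
#' @param n Total count.
#' @return A `binomial_result` with the z approximation
#'   `(x - n/2)/sqrt(n/4)` and exact tail probabilities; `defined = FALSE`
#'   (all statistics `NA`) when `n = 0`.
#' @export
binomial_result <- function(x, n) {
  if (n == 0L) {
    return(structure(list(x = 0L, n = 0L, z = NA_real_,
                          p_normal_one = NA_real_, p_normal_two = NA_real_,
                          p_exact_one = NA_real_, p_exact_two = NA_real_,
                          defined = FALSE), class = "binomial_result"))
  }
  z <- (x - n / 2) / sqrt(n / 4)
  p1 <- stats::pnorm(z, lower.tail = FALSE)
  p2 <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  e1 <- stats::pbinom(x - 1L, n, 0.5, lower.tail = FALSE)
  e2 <- stats::binom.test(x, n, 0.5)$p.value
  structure(list(x = x, n = n, z = z,
                 p_normal_one = p1, p_normal_two = p2,
                 p_exact_one = e1, p_exact_two = e2, defined = TRUE),
            class = "binomial_result")
}

#' @export
print.binomial_result <- function(x, ...) {
  if (!x$defined) {
    cat("binomial test: undefined (no counted responses)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "x = %d / n = %d: z = %.2f, p(one) = %.4g [exact %.4g], p(two) = %.4g [exact %.4g]\n",
    x$x, x$n, x$z, x$p_normal_one, x$p_exact_one, x$p_normal_two,
    x$p_exact_two))
  invisible(x)
}

# pull one run's records whether given a stress_run or a bare data frame
.run_records <- function(run) {
  if (inherits(run, "stress_run")) run$records else run
}

# normalize report input to a list of runs / record frames
.as_run_list <- function(runs) {
  if (inherits(runs, "stress_run") || is.data.frame(runs)) list(runs)
  else runs
}

.completed_phase <- function(records, phase, n_required) {
  ph <- records[records$phase == phase, , drop = FALSE]
  if (nrow(ph) < n_required) {
    stop("logs do not contain a completed ", phase, " phase (",
         nrow(ph), "/", n_required, " trials)", call. = FALSE)
  }
  ph
}

#' Generalization-test report (test 1)
#'
#' Per-subject response percentages for the four stimulus categories of
#' the novel-word test (trained S+, trained S-, novel S+ category, novel
#' S- category), per-individual binomial tests on each subject's 24 probe
#' trials (each scored correct when the subject responded to an S+
#' category probe or withheld on an S- category probe, so a perfect
#' subject reaches z = 4.899 at n = 24), and pooled tests across subjects.
#' The pooled test counts go-responses to probes; per-subject tests under
#' that response-counting convention are also reported (they are
#' undefined for a subject who never responded to a probe).
#'
#' @param runs A `stress_run`, or list of them.
#' @return List with `per_subject` (data frame), `per_subject_tests`
#'   (trial-counting `binomial_result` per subject),
#'   `per_subject_tests_responses` (response-counting variant), `pooled`
#'   (a `binomial_result` over pooled go-responses) and
#'   `pooled_percentages` (subject-mean category percentages).
#' @export
generalization_report <- function(runs) {
  runs <- .as_run_list(runs)
  per <- list()
  tests <- list()
  tests_resp <- list()
  pooled_probes <- list()
  for (run in runs) {
    recs <- .run_records(run)
    gen <- .completed_phase(recs, "generalization", 120L)
    sp <- gen$splus_pattern[1L]
    probes <- gen[gen$role == "probe", , drop = FALSE]
    pct <- function(sel) if (any(sel)) mean(gen$responded[sel]) * 100
                         else NA_real_
    per[[length(per) + 1L]] <- data.frame(
      subject_id = gen$subject_id[1L],
      trained_splus  = pct(gen$role == "Splus"),
      trained_sminus = pct(gen$role == "Sminus"),
      novel_splus    = pct(gen$role == "probe" & gen$pattern == sp),
      novel_sminus   = pct(gen$role == "probe" & gen$pattern != sp),
      stringsAsFactors = FALSE)
    sid <- gen$subject_id[1L]
    tests[[sid]] <- category_binomial(probes, sp, count = "trials")
    tests_resp[[sid]] <- category_binomial(probes, sp)
    probes$.splus <- sp
    pooled_probes[[length(pooled_probes) + 1L]] <- probes
  }
  pooled <- do.call(rbind, pooled_probes)
  go <- pooled[pooled$responded, , drop = FALSE]
  pooled_test <- binomial_result(sum(go$pattern == go$.splus), nrow(go))
  per <- do.call(rbind, per)
  list(per_subject = per,
       per_subject_tests = tests,
       per_subject_tests_responses = tests_resp,
       pooled = pooled_test,
       pooled_percentages = colMeans(per[-1L], na.rm = TRUE))
}

#' Cue-removal test report (test 2)
#'
#' Per-manipulation percent correct-category responding with binomial
#' tests, pooled across the supplied runs.  Both counting conventions are
#' reported: `x`/`n` over go-responses to probes (default convention) and
#' `pct_correct_trials` over probe trials.
#'
#' @param runs A `stress_run` or list of them.
#' @param count Counting convention passed to [category_binomial()].
#' @return A `cue_test_summary` data frame, one row per manipulation, with
#'   columns `manipulation`, `x`, `n`, `pct_correct`, `z`, `p_one`,
#'   `p_two`, `p_exact_one`, `p_exact_two`, `n_trials`,
#'   `pct_correct_trials`.
#' @export
cue_test_report <- function(runs, count = "responses") {
  runs <- .as_run_list(runs)
  probes <- list()
  for (run in runs) {
    recs <- .run_records(run)
    ct <- .completed_phase(recs, "cue_test", 240L)
    pr <- ct[ct$role == "probe", , drop = FALSE]
    pr$.splus <- ct$splus_pattern[1L]
    probes[[length(probes) + 1L]] <- pr
  }
  probes <- do.call(rbind, probes)
  labels <- setdiff(manipulation_labels(), "none")
  missing <- setdiff(labels, unique(probes$manipulation))
  if (length(missing)) {
    stop("logs lack probe trials for manipulation(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(labels, function(m) {
    pp <- probes[probes$manipulation == m, , drop = FALSE]
    go <- pp[pp$responded, , drop = FALSE]
    b <- binomial_result(sum(go$pattern == go$.splus), nrow(go))
    correct_trials <- ifelse(pp$pattern == pp$.splus,
                             pp$responded, !pp$responded)
    data.frame(
      manipulation = m, x = b$x, n = b$n,
      pct_correct = if (b$n > 0) 100 * b$x / b$n else NA_real_,
      z = b$z, p_one = b$p_normal_one, p_two = b$p_normal_two,
      p_exact_one = b$p_exact_one, p_exact_two = b$p_exact_two,
      n_trials = nrow(pp),
      pct_correct_trials = 100 * mean(correct_trials),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cue_test_summary", "data.frame")
  out
}

#' Per-phase DR trajectory and audit of phase decisions
#'
#' Recomputes cumulative (and, for sessioned subjects, per-session) DRs
#' from the raw trial records and re-applies the phase criteria,
#' verifying that the recorded phase outcomes agree with the recomputed
#' ones.
#'
#' @param run A `stress_run` (or its `records` plus `phases` attributes).
#' @return List with `trace` (one row per phase x trial: cumulative DR),
#'   `session_dr` (per phase x session), `audit` (per phase: recorded vs
#'   recomputed status, `agree` flag).
#' @export
criterion_trace <- function(run) {
  recs <- .run_records(run)
  if (is.null(recs) || nrow(recs) == 0L) {
    return(list(trace = data.frame(), session_dr = data.frame(),
                audit = data.frame()))
  }
  phases_seen <- unique(recs$phase)
  trace <- list()
  sess_dr <- list()
  audit <- list()
  for (ph in phases_seen) {
    h <- recs[recs$phase == ph, , drop = FALSE]
    splus <- h$role %in% c("Splus", "sound")
    sminus <- h$role %in% c("Sminus", "nosound")
    cum_p <- cumsum(h$responded & splus) / pmax(cumsum(splus), 1L)
    cum_m <- cumsum(h$responded & sminus) / pmax(cumsum(sminus), 1L)
    denom <- cum_p + cum_m
    dr <- ifelse(cumsum(splus) > 0 & cumsum(sminus) > 0 & denom > 0,
                 cum_p / denom, NA_real_)
    trace[[ph]] <- data.frame(phase = ph, trial = seq_len(nrow(h)),
                              dr = dr, stringsAsFactors = FALSE)
    if (!is.null(h$session)) {
      drs <- vapply(split(seq_len(nrow(h)), h$session), function(ix) {
        hh <- h[ix, , drop = FALSE]
        sp <- hh$role %in% c("Splus", "sound")
        sm <- hh$role %in% c("Sminus", "nosound")
        if (!any(sp) || !any(sm)) return(NA_real_)
        pp <- mean(hh$responded[sp]) * 100
        pm <- mean(hh$responded[sm]) * 100
        if (pp + pm == 0) NA_real_ else pp / (pp + pm)
      }, numeric(1L))
      sess_dr[[ph]] <- data.frame(phase = ph,
                                  session = as.integer(names(drs)),
                                  dr = drs, stringsAsFactors = FALSE)
    }
  }
  if (inherits(run, "stress_run") && !is.null(run$phases)) {
    for (i in seq_len(nrow(run$phases))) {
      ph <- run$phases$phase[i]
      h <- recs[recs$phase == ph, , drop = FALSE]
      if (ph %in% c("generalization", "cue_test")) {
        recomputed <- "advance"  # fixed-length tests always complete
      } else {
        dec <- phase_controller(run$species, ph, h)
        recomputed <- dec$status
      }
      audit[[i]] <- data.frame(
        phase = ph, recorded = run$phases$status[i],
        recomputed = recomputed,
        agree = identical(run$phases$status[i], recomputed),
        stringsAsFactors = FALSE)
    }
  }
  list(trace = do.call(rbind, trace),
       session_dr = if (length(sess_dr)) do.call(rbind, sess_dr)
                    else data.frame(),
       audit = if (length(audit)) do.call(rbind, audit)
               else data.frame())
}
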