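# Parametric stimulus synthesis.
#
# The experiment's stimuli are two-syllable CV.CV nonsense words in which
# lexical stress is carried by four independent acoustic cues:
#   pitch     - stressed syllables ramp linearly from 194 Hz to a peak drawn
#               uniformly in [230, 280] Hz; unstressed syllables are flat
#               at 194 Hz;
#   duration  - stressed 0.5 s; unstressed uniform in [0.3, 0.4] s;
#   amplitude - stressed RMS 0.1; unstressed RMS uniform in
#               [0.0316, 0.0447] (7-10 dB quieter);
#   vowel     - stressed syllables carry the full vowel, unstressed the
#               reduced vowel (see vowel_table()).
# Audio is produced from scratch by source-filter formant synthesis
# (impulse-train / noise source, cascade two-pole resonators, stylized
# consonant onsets), so the whole bank is reproducible from a seed.

.F0_BASE       <- 194
.F0_PEAK_RANGE <- c(230, 280)
.DUR_STRESSED  <- 0.5
.DUR_RANGE     <- c(0.3, 0.4)
.RMS_STRESSED  <- 0.1
.RMS_RANGE     <- c(0.0316, 0.0447)

.MANIPULATIONS <- c("none",
                    "pitch_removed", "duration_removed",
                    "amplitude_removed", "vowel_removed",
                    "pitch_only", "duration_only",
                    "amplitude_only", "vowel_only")

#' Cue-removal manipulation labels
#'
#' The eight non-trivial probe categories (each cue removed singly, and
#' each cue presented alone) plus `"none"` for intact stimuli.
#'
#' @return Character vector of the nine labels.
#' @export
manipulation_labels <- function() .MANIPULATIONS

# Stylized consonant onsets: class drives the source, onset_dur the length
# of the consonantal portion, gain its level relative to the vowel.
.CONSONANTS <- data.frame(
  consonant = c("p", "t", "k", "g", "d", "s", "z", "v", "j", "l", "m", "n"),
  class     = c("stop", "stop", "stop", "stop", "stop",
                "fricative", "fricative", "fricative",
                "approximant", "approximant", "nasal", "nasal"),
  voiced    = c(FALSE, FALSE, FALSE, TRUE, TRUE,
                FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
  onset_dur = c(0.065, 0.065, 0.065, 0.065, 0.065,
                0.080, 0.080, 0.060, 0.055, 0.055, 0.060, 0.060),
  burst_f   = c(800, 3500, 1800, 1500, 3000, 5500, 4500, 1800, NA, NA, NA, NA),
  gain      = c(0.30, 0.30, 0.30, 0.35, 0.35,
                0.30, 0.35, 0.35, 0.60, 0.60, 0.50, 0.50),
  stringsAsFactors = FALSE
)

.formant_cache <- new.env(parent = emptyenv())

#' Formant target table for the vowel realizations
#'
#' Read from the editable CSV shipped in `extdata` (columns `ipa`, `F1`,
#' `F2`, `F3`, `B1`, `B2`, `B3`).  Diphthongs are realized with static
#' mid-target formants.
#'
#' @param path Optional path to an alternative formant CSV.
#' @return Data frame of formant frequencies and bandwidths (Hz).
#' @export
formant_table <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.formant_cache$default)) {
      f <- system.file("extdata", "formants.csv", package = "stresslab",
                       mustWork = TRUE)
      .formant_cache$default <- utils::read.csv(f, stringsAsFactors = FALSE,
                                                fileEncoding = "UTF-8")
    }
    return(.formant_cache$default)
  }
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Construct stress-cue parameters for one syllable
#'
#' @param f0_start,f0_peak Pitch contour endpoints (Hz); the contour ramps
#'   linearly over the voiced portion, peaking at syllable end.
#' @param duration Syllable duration in seconds.
#' @param rms_target Linear RMS amplitude target over the full syllable.
#' @param vowel_mode `"full"` (stressed realization) or `"reduced"`.
#' @return A `stress_cue_params` object.
#' @export
stress_cue_params <- function(f0_start, f0_peak, duration, rms_target,
                              vowel_mode = c("full", "reduced")) {
  vowel_mode <- match.arg(vowel_mode)
  stopifnot(f0_start > 0, f0_peak > 0, duration > 0, rms_target > 0)
  structure(list(f0_start = f0_start, f0_peak = f0_peak,
                 duration = duration, rms_target = rms_target,
                 vowel_mode = vowel_mode),
            class = "stress_cue_params")
}

#' Draw stress-cue parameters for a stressed or unstressed syllable
#'
#' Random quantities (stressed pitch peak; unstressed duration and RMS)
#' are drawn uniformly from their defining intervals, independently per
#' call, from the session RNG.
#'
#' @param stressed Logical: draw the stressed or the unstressed bundle.
#' @return A `stress_cue_params` object.
#' @export
#' @examples
#' set.seed(1)
#' draw_cue_params(stressed = TRUE)
draw_cue_params <- function(stressed) {
  if (stressed) {
    stress_cue_params(
      f0_start = .F0_BASE,
      f0_peak = stats::runif(1L, .F0_PEAK_RANGE[1L], .F0_PEAK_RANGE[2L]),
      duration = .DUR_STRESSED, rms_target = .RMS_STRESSED,
      vowel_mode = "full")
  } else {
    stress_cue_params(
      f0_start = .F0_BASE, f0_peak = .F0_BASE,
      duration = stats::runif(1L, .DUR_RANGE[1L], .DUR_RANGE[2L]),
      rms_target = stats::runif(1L, .RMS_RANGE[1L], .RMS_RANGE[2L]),
      vowel_mode = "reduced")
  }
}

# Which cues a manipulation label neutralizes.
.removed_cues <- function(m) {
  m <- match.arg(m, .MANIPULATIONS)
  cues <- c("pitch", "duration", "amplitude", "vowel")
  if (m == "none") return(character())
  cue <- sub("_(removed|only)$", "", m)
  if (endsWith(m, "_removed")) cue else setdiff(cues, cue)
}

#' Apply a cue-removal manipulation to a stressed/unstressed parameter pair
#'
#' For each removed cue both syllables carry the same neutral value: pitch
#' removed gives both the flat 194 Hz contour, amplitude removed the
#' stressed RMS of 0.1, duration removed the stressed 0.5 s, and vowel
#' removed the full (stressed) vowel quality.  `"<cue>_only"` labels are
#' equivalent to removing the other three cues; `"none"` is the identity.
#'
#' @param stressed_params,unstressed_params `stress_cue_params` for the
#'   stressed and unstressed syllable.
#' @param manipulation One of [manipulation_labels()].
#' @return List with elements `stressed` and `unstressed`.
#' @export
apply_manipulation <- function(stressed_params, unstressed_params,
                               manipulation = "none") {
  removed <- .removed_cues(manipulation)
  out <- list(stressed = stressed_params, unstressed = unstressed_params)
  for (cue in removed) {
    out <- lapply(out, function(p) {
      switch(cue,
        pitch     = { p$f0_start <- .F0_BASE; p$f0_peak <- .F0_BASE },
        duration  = p$duration   <- .DUR_STRESSED,
        amplitude = p$rms_target <- .RMS_STRESSED,
        vowel     = p$vowel_mode <- "full")
      p
    })
  }
  out
}

# -- low-level DSP -----------------------------------------------------------

# Two-pole resonator; gain-normalized at the resonance frequency's scale is
# irrelevant because every syllable is RMS-normalized afterwards.
.resonate <- function(x, f, bw, sr) {
  r <- exp(-pi * bw / sr)
  th <- 2 * pi * f / sr
  g <- 1 - 2 * r * cos(th) + r^2
  as.numeric(stats::filter(g * x, c(2 * r * cos(th), -r^2),
                           method = "recursive"))
}

# Impulse-train glottal source with a sample-wise frequency track, plus
# -6 dB/oct spectral tilt.
.voiced_source <- function(f0_track, sr) {
  phase <- cumsum(f0_track) / sr
  imp <- as.numeric(diff(floor(c(0, phase))) >= 1)
  s <- as.numeric(stats::filter(imp, 0.95, method = "recursive"))
  s - mean(s)
}

.vowel_formants <- function(ipa, ftab) {
  row <- ftab[ftab$ipa == ipa, ]
  if (nrow(row) != 1L) stop("no formant targets for vowel [", ipa, "]")
  row
}

.formant_filter <- function(src, row, sr) {
  for (k in 1:3) {
    src <- .resonate(src, row[[paste0("F", k)]], row[[paste0("B", k)]], sr)
  }
  src - mean(src)
}

.raised_cosine_ramp <- function(x, sr, ramp_s = 0.005) {
  n <- min(length(x) %/% 2L, max(1L, round(ramp_s * sr)))
  if (n < 2L) return(x)
  w <- 0.5 * (1 - cos(pi * (seq_len(n) - 1) / (n - 1)))
  x[seq_len(n)] <- x[seq_len(n)] * w
  x[(length(x) - n + 1L):length(x)] <-
    x[(length(x) - n + 1L):length(x)] * rev(w)
  x
}

# -- syllable / word synthesis ----------------------------------------------

#' Synthesize one syllable
#'
#' Source-filter formant synthesis: a stylized consonant onset (stop burst,
#' fricative noise, nasal murmur or approximant glide) followed by a voiced
#' vowel whose fundamental frequency ramps linearly from `f0_start` to
#' `f0_peak` (peak at syllable end) and whose formants realize the full or
#' reduced vowel per [vowel_table()].  The output has exactly
#' `round(duration * sample_rate)` samples and overall RMS equal to
#' `rms_target` (5 ms raised-cosine edge ramps are applied before the final
#' RMS normalization, so both contracts hold exactly).
#'
#' @param syllable Two-character CV syllable, e.g. `"pu"`.
#' @param params A `stress_cue_params`.
#' @param sample_rate Sampling rate in Hz (default 44100).
#' @param formants Formant table, see [formant_table()].
#' @return A `waveform`.
#' @export
#' @examples
#' w <- synthesize_syllable("pu", stress_cue_params(194, 250, 0.5, 0.1))
#' measure_rms(w)
synthesize_syllable <- function(syllable, params, sample_rate = 44100,
                                formants = formant_table()) {
  stopifnot(inherits(params, "stress_cue_params"), nchar(syllable) == 2L)
  sr <- sample_rate
  cons <- substr(syllable, 1L, 1L)
  vlet <- toupper(substr(syllable, 2L, 2L))
  ci <- .CONSONANTS[.CONSONANTS$consonant == cons, ]
  if (nrow(ci) != 1L) stop("unknown consonant: ", cons, call. = FALSE)

  n_total <- round(params$duration * sr)
  n_onset <- round(ci$onset_dur * sr)
  if (n_total < n_onset + round(0.02 * sr)) {
    stop("duration ", params$duration,
         " s too short for consonant onset of ", ci$onset_dur, " s",
         call. = FALSE)
  }
  n_vowel <- n_total - n_onset

  ipa <- vowel_realization(vlet, stressed = params$vowel_mode == "full")
  vrow <- .vowel_formants(ipa, formants)

  # voiced track: ramp spans the voiced region, peaking at syllable end
  if (ci$voiced && ci$class != "stop") {
    f0 <- seq(params$f0_start, params$f0_peak, length.out = n_onset + n_vowel)
    f0_on <- f0[seq_len(n_onset)]
    f0_vow <- f0[(n_onset + 1L):(n_onset + n_vowel)]
  } else {
    f0_on <- rep(params$f0_start, n_onset)
    f0_vow <- seq(params$f0_start, params$f0_peak, length.out = n_vowel)
  }

  vowel <- .formant_filter(.voiced_source(f0_vow, sr), vrow, sr)
  vowel <- vowel / (sqrt(mean(vowel^2)) + 1e-12)

  onset <- switch(ci$class,
    stop = {
      n_burst <- min(n_onset, round(0.020 * sr))
      n_clos <- n_onset - n_burst
      burst <- .resonate(stats::rnorm(n_burst), ci$burst_f, 600, sr)
      burst <- burst / (sqrt(mean(burst^2)) + 1e-12)
      clos <- if (ci$voiced && n_clos > 0L) {
        # voice bar during closure of voiced stops
        0.15 * sin(2 * pi * cumsum(rep(params$f0_start, n_clos)) / sr)
      } else {
        numeric(n_clos)
      }
      c(clos, .raised_cosine_ramp(burst, sr, 0.002))
    },
    fricative = {
      noise <- .resonate(stats::rnorm(n_onset), ci$burst_f, 1200, sr)
      noise <- noise / (sqrt(mean(noise^2)) + 1e-12)
      if (ci$voiced) {
        buzz <- .formant_filter(.voiced_source(f0_on, sr), vrow, sr)
        buzz <- buzz / (sqrt(mean(buzz^2)) + 1e-12)
        0.6 * noise + 0.6 * buzz
      } else {
        noise
      }
    },
    nasal = {
      mur <- .resonate(.voiced_source(f0_on, sr), 250, 100, sr)
      mur <- mur / (sqrt(mean(mur^2)) + 1e-12)
      mur
    },
    approximant = {
      ftab <- vrow
      ftab$F1 <- if (cons == "j") 300 else 360
      ftab$F2 <- if (cons == "j") 2200 else 1300
      gl <- .formant_filter(.voiced_source(f0_on, sr), ftab, sr)
      gl / (sqrt(mean(gl^2)) + 1e-12)
    })

  s <- c(ci$gain * onset, vowel)
  s <- .raised_cosine_ramp(s, sr)
  s <- s * params$rms_target / sqrt(mean(s^2))
  peak <- max(abs(s))
  if (peak >= 1) s <- s * (0.999 / peak)  # guard; never triggers at RMS 0.1
  waveform(s, sr)
}

#' Synthesize a two-syllable word stimulus
#'
#' Draws (or takes) stressed and unstressed cue-parameter bundles, applies
#' the requested cue-removal manipulation, assigns the stressed bundle to
#' the first slot for trochaic patterns and the second for iambic, and
#' concatenates the two syllable waveforms with no intervening silence.
#'
#' @param word A 4-character nonsense word (or one row of a `word_set`).
#' @param pattern `"trochaic"` (first syllable stressed) or `"iambic"`.
#' @param manipulation One of [manipulation_labels()].
#' @param sample_rate Sampling rate in Hz.
#' @param params Optional pre-drawn list
#'   `list(stressed = , unstressed = )` of `stress_cue_params` (before
#'   manipulation); when `NULL`, drawn from the session RNG.
#' @return A `word_stimulus`: list with `word`, `pattern`, `manipulation`,
#'   `syllable_params` (slot-ordered pair) and `audio` (a `waveform`).
#' @export
#' @examples
#' set.seed(7)
#' ws <- synthesize_word("puvo", "trochaic")
#' wave_duration(ws$audio)
synthesize_word <- function(word, pattern = c("trochaic", "iambic"),
                            manipulation = "none", sample_rate = 44100,
                            params = NULL) {
  pattern <- match.arg(pattern)
  if (is.data.frame(word)) word <- word$word[1L]
  stopifnot(nchar(word) == 4L)
  if (is.null(params)) {
    params <- list(stressed = draw_cue_params(TRUE),
                   unstressed = draw_cue_params(FALSE))
  }
  pp <- apply_manipulation(params$stressed, params$unstressed, manipulation)
  slot_params <- if (pattern == "trochaic") {
    list(pp$stressed, pp$unstressed)
  } else {
    list(pp$unstressed, pp$stressed)
  }
  syls <- c(substr(word, 1L, 2L), substr(word, 3L, 4L))
  w1 <- synthesize_syllable(syls[1L], slot_params[[1L]], sample_rate)
  w2 <- synthesize_syllable(syls[2L], slot_params[[2L]], sample_rate)
  structure(list(word = word, pattern = pattern,
                 manipulation = manipulation,
                 syllable_params = slot_params,
                 audio = waveform(c(w1$samples, w2$samples), sample_rate)),
            class = "word_stimulus")
}

# -- measurement -------------------------------------------------------------

#' Root-mean-square amplitude of a waveform
#'
#' @param w A `waveform` (or bare numeric vector).
#' @return `sqrt(mean(samples^2))`.
#' @export
measure_rms <- function(w) {
  x <- if (inherits(w, "waveform")) w$samples else w
  if (length(x) == 0L) stop("empty waveform", call. = FALSE)
  sqrt(mean(x^2))
}

#' Attenuation between two RMS levels in decibels
#'
#' @param rms_a,rms_b Positive linear RMS values.
#' @return `20 * log10(rms_a / rms_b)` in dB.
#' @export
#' @examples
#' rms_to_db_attenuation(0.1, 0.0316)  # ~10 dB
rms_to_db_attenuation <- function(rms_a, rms_b) {
  if (any(rms_a <= 0) || any(rms_b <= 0)) {
    stop("RMS values must be positive", call. = FALSE)
  }
  20 * log10(rms_a / rms_b)
}

#' Frame-wise fundamental-frequency estimate
#'
#' Autocorrelation pitch tracking with parabolic peak interpolation.
#' Frames whose normalized autocorrelation peak falls below
#' `voicing_threshold`, or whose energy is negligible, are flagged
#' unvoiced (`f0 = NA`).
#'
#' @param w A `waveform`.
#' @param frame_s,hop_s Frame length and hop in seconds.
#' @param fmin,fmax Search range in Hz.
#' @param voicing_threshold Normalized autocorrelation threshold in (0, 1).
#' @return Data frame with columns `time` (frame centre, s), `f0` (Hz, NA
#'   when unvoiced), `voiced`, `strength`.  Zero voiced rows means no
#'   voiced content was found.
#' @export
estimate_f0 <- function(w, frame_s = 0.04, hop_s = 0.01,
                        fmin = 100, fmax = 400, voicing_threshold = 0.45) {
  stopifnot(inherits(w, "waveform"))
  x <- w$samples
  sr <- w$sample_rate
  n <- round(frame_s * sr)
  hop <- max(1L, round(hop_s * sr))
  lmin <- max(2L, floor(sr / fmax))
  lmax <- min(n - 2L, ceiling(sr / fmin))
  if (length(x) < n || lmax <= lmin) {
    return(data.frame(time = numeric(), f0 = numeric(),
                      voiced = logical(), strength = numeric()))
  }
  starts <- seq(1L, length(x) - n + 1L, by = hop)
  res <- lapply(starts, function(s0) {
    seg <- x[s0:(s0 + n - 1L)]
    seg <- seg - mean(seg)
    energy <- sqrt(mean(seg^2))
    tm <- (s0 - 1L + n / 2) / sr
    if (energy < 1e-4) {
      return(data.frame(time = tm, f0 = NA_real_, voiced = FALSE,
                        strength = 0))
    }
    nf <- stats::nextn(2L * n, 2)
    sp <- stats::fft(c(seg, numeric(nf - n)))
    ac <- Re(stats::fft(Mod(sp)^2, inverse = TRUE))[seq_len(lmax + 2L)]
    r <- ac / ac[1L]
    lag_idx <- (lmin:lmax) + 1L
    best <- lag_idx[which.max(r[lag_idx])]
    strength <- r[best]
    if (strength < voicing_threshold) {
      return(data.frame(time = tm, f0 = NA_real_, voiced = FALSE,
                        strength = strength))
    }
    # parabolic interpolation around the peak lag
    l <- best - 1L
    y1 <- r[best - 1L]; y2 <- r[best]; y3 <- r[best + 1L]
    denom <- y1 - 2 * y2 + y3
    delta <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
    data.frame(time = tm, f0 = sr / (l + delta), voiced = TRUE,
               strength = strength)
  })
  do.call(rbind, res)
}

# -- stimulus tables and banks -----------------------------------------------

.params_to_row <- function(slot_params) {
  p1 <- slot_params[[1L]]; p2 <- slot_params[[2L]]
  data.frame(
    f0_start1 = p1$f0_start, f0_peak1 = p1$f0_peak,
    duration1 = p1$duration, rms1 = p1$rms_target,
    vowel_mode1 = p1$vowel_mode,
    f0_start2 = p2$f0_start, f0_peak2 = p2$f0_peak,
    duration2 = p2$duration, rms2 = p2$rms_target,
    vowel_mode2 = p2$vowel_mode,
    stringsAsFactors = FALSE
  )
}

.row_to_params <- function(row) {
  list(stress_cue_params(row$f0_start1, row$f0_peak1, row$duration1,
                         row$rms1, row$vowel_mode1),
       stress_cue_params(row$f0_start2, row$f0_peak2, row$duration2,
                         row$rms2, row$vowel_mode2))
}

#' Build a table of concrete stimulus exemplars
#'
#' Draws cue parameters for each requested (word, pattern, manipulation)
#' combination from the session RNG, applies the manipulation, and records
#' the resulting slot-ordered parameter bundles.  The table is the single
#' source of truth shared by audio rendering ([render_stimulus_row()]),
#' bank writing and the simulated observer (which reads cue values from it
#' rather than from audio).
#'
#' @param ws A `word_set`.
#' @param patterns Stress patterns to realize.
#' @param manipulation Single manipulation label applied to every row.
#' @param words Optional subset of words (defaults to all words in `ws`).
#' @return Data frame, one row per stimulus exemplar, with stimulus
#'   identity columns and per-slot parameter columns.
#' @export
stimulus_table <- function(ws, patterns = c("trochaic", "iambic"),
                           manipulation = "none", words = NULL) {
  if (is.null(words)) words <- ws$word
  rows <- list()
  for (pat in patterns) {
    for (wd in words) {
      params <- list(stressed = draw_cue_params(TRUE),
                     unstressed = draw_cue_params(FALSE))
      pp <- apply_manipulation(params$stressed, params$unstressed,
                               manipulation)
      slot <- if (pat == "trochaic") list(pp$stressed, pp$unstressed)
              else list(pp$unstressed, pp$stressed)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(set_id = ws$set_id[1L], word = wd, pattern = pat,
                   manipulation = manipulation, stringsAsFactors = FALSE),
        .params_to_row(slot))
    }
  }
  out <- do.call(rbind, rows)
  out$stimulus_id <- sprintf("s%d_%s_%s_%s", out$set_id, out$word,
                             out$pattern, out$manipulation)
  out
}

#' Build the 48-stimulus cue-removal probe bank
#'
#' Three exemplars per manipulation per stress pattern (8 manipulations
#' x 2 patterns x 3 = 48), each exemplar a word sampled without
#' replacement from the training set with freshly drawn cue parameters.
#'
#' @param ws The trained `word_set`.
#' @param exemplars Exemplars per manipulation per pattern (default 3).
#' @return Stimulus table of `8 * 2 * exemplars` rows with distinct
#'   `stimulus_id`s.
#' @export
cue_probe_bank <- function(ws, exemplars = 3L) {
  rows <- list()
  for (m in setdiff(.MANIPULATIONS, "none")) {
    for (pat in c("trochaic", "iambic")) {
      wds <- sample(ws$word, exemplars)
      rows[[length(rows) + 1L]] <-
        stimulus_table(ws, patterns = pat, manipulation = m, words = wds)
    }
  }
  out <- do.call(rbind, rows)
  out$stimulus_id <- sprintf("s%d_%s_%s_%s_e%02d", out$set_id, out$word,
                             out$pattern, out$manipulation,
                             stats::ave(seq_len(nrow(out)),
                                        paste(out$word, out$pattern,
                                              out$manipulation),
                                        FUN = seq_along))
  rownames(out) <- NULL
  out
}

#' Render the audio for one stimulus-table row
#'
#' @param row One row of a table built by [stimulus_table()] or
#'   [cue_probe_bank()].
#' @param sample_rate Sampling rate in Hz.
#' @return A `word_stimulus`.
#' @export
render_stimulus_row <- function(row, sample_rate = 44100) {
  slot <- .row_to_params(row)
  syls <- c(substr(row$word, 1L, 2L), substr(row$word, 3L, 4L))
  w1 <- synthesize_syllable(syls[1L], slot[[1L]], sample_rate)
  w2 <- synthesize_syllable(syls[2L], slot[[2L]], sample_rate)
  structure(list(word = row$word, pattern = row$pattern,
                 manipulation = row$manipulation, syllable_params = slot,
                 audio = waveform(c(w1$samples, w2$samples), sample_rate)),
            class = "word_stimulus")
}

#' Write a seeded stimulus bank to disk
#'
#' Writes one WAV per (word x pattern) training stimulus, plus the
#' 48-stimulus cue-removal probe bank when `cue_probes = TRUE`, together
#' with a CSV manifest recording every drawn parameter.  Regeneration with
#' the same seed is bit-identical.
#'
#' @param ws A `word_set`.
#' @param seed Integer seed for the synthesis substream.
#' @param dir Output directory (created if missing).
#' @param cue_probes Also write the 48 cue-removal probes?
#' @param sample_rate Sampling rate in Hz.
#' @return The manifest data frame (invisibly written to
#'   `file.path(dir, "manifest.csv")`), with a `filename` column.
#' @export
write_stimulus_bank <- function(ws, seed, dir, cue_probes = FALSE,
                                sample_rate = 44100) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  local_seed(substream_seed(seed, "synthesis"))
  tab <- stimulus_table(ws)
  if (cue_probes) tab <- rbind(tab, cue_probe_bank(ws))
  tab$filename <- paste0(tab$stimulus_id, ".wav")
  tab$seed <- seed
  for (i in seq_len(nrow(tab))) {
    stim <- render_stimulus_row(tab[i, ], sample_rate)
    write_wav(stim$audio, file.path(dir, tab$filename[i]))
  }
  utils::write.csv(tab, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(tab)
}
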