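# Nonsense-word inventory and vowel-realization table.
#
# The two training sets are frozen package data.  The printed table flows
# four columns (set1 syllable1, set1 syllable2, set2 syllable1, set2
# syllable2) row-wise; this transcription is the unique column-interleaved
# reading that satisfies all structural invariants below (6 syllables per
# set, each used twice initially and twice finally, disjoint inventories).
# validate_word_set() is the guard that the transcription stays correct.

.SET1_WORDS <- c("puvo", "puga", "zipu", "gapu", "nake", "navo",
                 "kena", "gazi", "ziga", "kezi", "vona", "voke")
.SET2_WORDS <- c("tosu", "tomi", "jito", "sude", "deji", "delu",
                 "jimi", "luto", "sulu", "miji", "lusu", "mide")

# Stressed vs unstressed (reduced) realization of each orthographic vowel.
.VOWEL_TABLE <- data.frame(
  vowel      = c("A", "E", "I", "O", "U"),
  stressed   = c("ɔ", "eɪ", "i:", "oʊ", "u:"),
  unstressed = c("ə", "ɛ", "ɪ", "ə", "ə"),
  stringsAsFactors = FALSE
)

.word_to_syllables <- function(word) {
  c(substr(word, 1L, 2L), substr(word, 3L, 4L))
}

#' Build the two frozen training sets of nonsense words
#'
#' Each set holds 12 two-syllable nonsense words built from 6 syllables;
#' every syllable appears in four words, twice in first position and twice
#' in second position, and the syllable inventories of the two sets are
#' disjoint.  One set is used for discrimination training and the other as
#' novel probe material, counterbalanced across subjects.
#'
#' @return A list of two `word_set` objects (`set_id` 1 and 2).  Each is a
#'   data frame with columns `set_id`, `word`, `syllable1`, `syllable2`.
#' @export
#' @examples
#' sets <- build_training_sets()
#' sets[[1]]$word
build_training_sets <- function() {
  make <- function(words, id) {
    ws <- data.frame(
      set_id    = id,
      word      = words,
      syllable1 = substr(words, 1L, 2L),
      syllable2 = substr(words, 3L, 4L),
      stringsAsFactors = FALSE
    )
    class(ws) <- c("word_set", "data.frame")
    ws
  }
  list(make(.SET1_WORDS, 1L), make(.SET2_WORDS, 2L))
}

#' Syllable inventory of a word set
#'
#' @param ws A `word_set`.
#' @return Character vector of the distinct syllables, sorted.
#' @export
word_set_syllables <- function(ws) {
  sort(unique(c(ws$syllable1, ws$syllable2)))
}

#' Consonant inventory induced by the frozen word sets
#'
#' Derived from the transcribed syllables rather than hard-coded, so it can
#' never drift from the lexicon.
#'
#' @return Character vector of onset consonants.
#' @export
consonant_inventory <- function() {
  sets <- build_training_sets()
  sort(unique(substr(unlist(lapply(sets, word_set_syllables)), 1L, 1L)))
}

#' Vowel realization under stress or reduction
#'
#' Stressed syllables carry the long/full vowel; unstressed syllables the
#' reduced vowel (schwa for A, O, U).
#'
#' @param vowel One of `"A"`, `"E"`, `"I"`, `"O"`, `"U"` (vectorised).
#' @param stressed Logical; stressed (full) or unstressed (reduced) form.
#' @return IPA label(s) for the realized vowel.
#' @export
#' @examples
#' vowel_realization("A", stressed = TRUE)   # open-o
#' vowel_realization("A", stressed = FALSE)  # schwa
vowel_realization <- function(vowel, stressed) {
  vowel <- toupper(vowel)
  idx <- match(vowel, .VOWEL_TABLE$vowel)
  if (anyNA(idx)) {
    stop("unknown vowel: ", paste(vowel[is.na(idx)], collapse = ", "),
         " (must be one of A, E, I, O, U)", call. = FALSE)
  }
  ifelse(rep_len(stressed, length(idx)),
         .VOWEL_TABLE$stressed[idx], .VOWEL_TABLE$unstressed[idx])
}

#' The vowel realization table
#'
#' @return Data frame with columns `vowel`, `stressed`, `unstressed`.
#' @export
vowel_table <- function() .VOWEL_TABLE

#' Validate the structural invariants of a word set
#'
#' Checks the constraints that make a set usable for scheduling: 12 words,
#' 6 distinct syllables, each syllable used exactly twice in each position,
#' no word repeating its own syllable, and (when `other` is supplied)
#' disjointness of the two sets' syllable inventories.  Reports rather than
#' throws, so a malformed set can be diagnosed.
#'
#' @param ws A `word_set` data frame.
#' @param other Optional second `word_set` to check disjointness against.
#' @return Data frame with columns `check`, `pass`, `detail`; attribute
#'   `"valid"` is `TRUE` iff all checks pass.
#' @export
#' @examples
#' sets <- build_training_sets()
#' validate_word_set(sets[[1]], sets[[2]])
validate_word_set <- function(ws, other = NULL) {
  syl <- c(ws$syllable1, ws$syllable2)
  first_counts  <- table(ws$syllable1)
  second_counts <- table(ws$syllable2)
  inv <- sort(unique(syl))

  checks <- list(
    c("12 words", nrow(ws) == 12L,
      sprintf("%d words", nrow(ws))),
    c("6 distinct syllables", length(inv) == 6L,
      sprintf("%d syllables", length(inv))),
    c("usage counts", nrow(ws) > 0L &&
        all(table(syl) == 4L) &&
        all(first_counts == 2L) && all(second_counts == 2L) &&
        length(first_counts) == length(inv) &&
        length(second_counts) == length(inv),
      "each syllable 4 words: 2 initial + 2 final"),
    c("no self-pair", all(ws$syllable1 != ws$syllable2),
      "first syllable differs from second"),
    c("unique words", !anyDuplicated(ws$word),
      "no duplicated word"),
    c("well-formed syllables", all(nchar(ws$word) == 4L) &&
        all(substr(syl, 1L, 1L) %in% consonant_inventory()) &&
        all(toupper(substr(syl, 2L, 2L)) %in% .VOWEL_TABLE$vowel),
      "CV syllables over the closed inventories")
  )
  if (!is.null(other)) {
    checks <- c(checks, list(
      c("disjoint inventories",
        length(intersect(inv, word_set_syllables(other))) == 0L,
        "no syllable shared with the other set")
    ))
  }
  rep_df <- data.frame(
    check  = vapply(checks, `[[`, "", 1L),
    pass   = vapply(checks, function(x) as.logical(x[[2L]]), NA),
    detail = vapply(checks, `[[`, "", 3L),
    stringsAsFactors = FALSE
  )
  attr(rep_df, "valid") <- all(rep_df$pass)
  rep_df
}

#' Export a word set (or both) to CSV
#'
#' @param ws A `word_set` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_word_sets_csv <- function(ws, path) {
  if (inherits(ws, "word_set")) ws <- list(ws)
  df <- do.call(rbind, lapply(ws, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Import word sets from CSV written by [write_word_sets_csv()]
#'
#' @param path CSV path.
#' @return List of `word_set` objects, one per `set_id`, in `set_id` order.
#' @export
read_word_sets_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(set_id = "integer"))
  lapply(split(df, df$set_id), function(d) {
    rownames(d) <- NULL
    class(d) <- c("word_set", "data.frame")
    d
  })
}
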