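#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' A single experiment seed is expanded into named substreams (synthesis,
#' schedule, observer, ...) so that each pipeline stage is independently
#' reproducible: regenerating the stimulus bank does not perturb the
#' observer's response stream.
#'
#' @param seed Integer master seed.
#' @param name Character scalar naming the substream.
#' @return An integer in `[0, 2^31 - 2]`, deterministic in both arguments.
#' @export
#' @examples
#' substream_seed(7L, "synthesis")
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name),
            length(name) == 1L, nzchar(name))
  m <- 2147483647 # 2^31 - 1, Mersenne prime; keeps results in int range
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% m
  as.integer((abs(seed) %% m * 48271 + h) %% m)
}

# Seed the session RNG for the calling frame only (restored on exit).
local_seed <- function(seed, envir = parent.frame()) {
  if (!is.null(seed)) withr::local_seed(as.integer(seed), .local_envir = envir)
  invisible(seed)
}
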