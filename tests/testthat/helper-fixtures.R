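# Shared fixtures: built in code, no stored data.

training_sets <- build_training_sets()

# a fast, strong learner used where acquisition itself is not under test
strong_observer <- function() {
  observer_profile(w_pitch = 1, w_amp = 1, w_dur = 1, w_vowel = 1,
                   sigma = 0.1, lapse = 0.01, learn_rate = 0.4)
}

# constructed trial records with given response patterns
make_records <- function(n_splus, n_sminus, go_splus, go_sminus,
                         role_plus = "Splus", role_minus = "Sminus") {
  data.frame(
    role = c(rep(role_plus, n_splus), rep(role_minus, n_sminus)),
    responded = c(rep(c(TRUE, FALSE), c(go_splus, n_splus - go_splus)),
                  rep(c(TRUE, FALSE), c(go_sminus, n_sminus - go_sminus))),
    stringsAsFactors = FALSE)
}

# per-session budgerigar histories with prescribed session DRs:
# 10 S+ trials all responded, 100 S- trials with k responded gives
# DR = 100 / (100 + k)
budgie_history <- function(k_per_session) {
  do.call(rbind, lapply(seq_along(k_per_session), function(s) {
    h <- make_records(10, 100, 10, k_per_session[s])
    h$session <- s
    h
  }))
}

# probe records for analysis tests (24 probes: 12 per pattern)
make_probe_records <- function(responded_splus, responded_sminus,
                               splus_pattern = "trochaic",
                               n_each = 12L) {
  pats <- c(rep(splus_pattern, n_each),
            rep(setdiff(c("trochaic", "iambic"), splus_pattern), n_each))
  data.frame(role = "probe", pattern = pats,
             responded = c(rep_len(responded_splus, n_each),
                           rep_len(responded_sminus, n_each)),
             stringsAsFactors = FALSE)
}
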