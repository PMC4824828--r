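test_that("discrimination ratio matches its defining formula", {
  # equal nonzero responding on both classes: DR = 0.5
  expect_equal(discrimination_ratio(make_records(10, 10, 10, 10))$dr, 0.5)
  # perfect discrimination
  expect_equal(discrimination_ratio(make_records(10, 10, 10, 0))$dr, 1.0)
  # 60% vs 20%: DR = 60/(60+20)
  expect_equal(discrimination_ratio(make_records(10, 10, 6, 2))$dr, 0.75)
  # undefined when neither class is responded to
  r0 <- discrimination_ratio(make_records(10, 10, 0, 0))
  expect_false(r0$defined)
  expect_true(is.na(r0$dr))
  # a window lacking either trial role is rejected
  expect_error(discrimination_ratio(
    data.frame(role = "Splus", responded = TRUE)), "S-")
})

test_that("DR stays in [0,1] and equals 0.5 only at equal responding", {
  withr::local_seed(51)
  for (i in 1:200) {
    gp <- sample(0:10, 1)
    gm <- sample(0:10, 1)
    r <- discrimination_ratio(make_records(10, 10, gp, gm))
    if (gp + gm == 0) {
      expect_false(r$defined)
    } else {
      expect_gte(r$dr, 0)
      expect_lte(r$dr, 1)
      expect_equal(isTRUE(all.equal(r$dr, 0.5)), gp == gm)
    }
  }
})

test_that("binomial z statistic and exact tails match their oracles", {
  # saturated count: z = (24 - 12) / sqrt(6)
  b <- binomial_result(24L, 24L)
  expect_equal(b$z, 12 / sqrt(6), tolerance = 1e-12)
  expect_equal(round(b$z, 3), 4.899)
  # null centre
  expect_equal(binomial_result(12L, 24L)$z, 0)
  # exact one-tailed tail mass by direct summation
  b2 <- binomial_result(18L, 20L)
  expect_equal(b2$p_exact_one, sum(stats::dbinom(18:20, 20, 0.5)))
  expect_equal(b2$p_exact_one, 0.000201, tolerance = 2e-3)
  # undefined at n = 0
  b0 <- binomial_result(0L, 0L)
  expect_false(b0$defined)
  expect_true(is.na(b0$z))
})

test_that("normal z tail agrees with the exact mid-p tail for n >= 30", {
  for (n in c(30L, 50L, 100L, 200L)) {
    for (x in seq(n %/% 2, n)) {
      b <- binomial_result(x, n)
      mid_p <- stats::pbinom(x, n, 0.5, lower.tail = FALSE) +
        0.5 * stats::dbinom(x, n, 0.5)
      expect_lt(abs(b$p_normal_one - mid_p), 0.01)
    }
  }
})

test_that("category binomial counts go-responses by default, trials on request", {
  probes <- make_probe_records(responded_splus = TRUE,
                               responded_sminus = c(TRUE, FALSE))
  b <- category_binomial(probes, "trochaic")
  expect_equal(b$x, 12L)
  expect_equal(b$n, 18L)  # 12 S+ responses + 6 S- responses
  bt <- category_binomial(probes, "trochaic", count = "trials")
  expect_equal(bt$n, 24L)
  expect_equal(bt$x, 12L + 6L)  # hits plus correct rejections
})

test_that("generalization report scores a perfect subject", {
  withr::local_seed(52)
  tt <- stimulus_table(training_sets[[1]])
  pt <- stimulus_table(training_sets[[2]])
  sched <- make_generalization_schedule(tt, pt, "trochaic")
  sched$responded <- sched$pattern == "trochaic"  # oracle responder
  sched$subject_id <- "oracle"
  sched$splus_pattern <- "trochaic"
  rep <- generalization_report(sched)
  expect_equal(rep$per_subject$novel_splus, 100)
  expect_equal(rep$per_subject$novel_sminus, 0)
  expect_equal(rep$per_subject$trained_splus, 100)
  expect_equal(rep$per_subject$trained_sminus, 0)
  # all 24 probe trials scored correct: z = (24 - 12)/sqrt(6)
  expect_equal(round(rep$per_subject_tests$oracle$z, 3), 4.899)
  # response-counting convention: 12 go responses, all to the S+ category
  expect_equal(rep$per_subject_tests_responses$oracle$n, 12L)
  expect_equal(round(rep$per_subject_tests_responses$oracle$z, 3), 3.464)
  # a subject with no probe responses is flagged undefined under the
  # response-counting convention
  sched0 <- sched
  sched0$responded <- sched0$role == "Splus"
  rep0 <- generalization_report(sched0)
  expect_false(rep0$per_subject_tests_responses$oracle$defined)
})

test_that("generalization percentages swap under S+/S- relabeling", {
  withr::local_seed(53)
  tt <- stimulus_table(training_sets[[1]])
  pt <- stimulus_table(training_sets[[2]])
  sched <- make_generalization_schedule(tt, pt, "trochaic")
  sched$responded <- stats::runif(nrow(sched)) <
    ifelse(sched$pattern == "trochaic", 0.9, 0.2)
  sched$subject_id <- "s"
  sched$splus_pattern <- "trochaic"
  rep1 <- generalization_report(sched)
  flipped <- sched
  flipped$splus_pattern <- "iambic"
  flipped$role <- c(Splus = "Sminus", Sminus = "Splus",
                    probe = "probe")[sched$role]
  rep2 <- generalization_report(flipped)
  expect_equal(rep2$per_subject$novel_splus, rep1$per_subject$novel_sminus)
  expect_equal(rep2$per_subject$novel_sminus, rep1$per_subject$novel_splus)
  expect_equal(rep2$per_subject$trained_splus,
               rep1$per_subject$trained_sminus)
})

test_that("pooled z grows as sqrt(k) over identical subjects", {
  probes <- make_probe_records(TRUE, c(TRUE, FALSE, FALSE, FALSE))
  b1 <- category_binomial(probes, "trochaic")
  for (k in c(4L, 9L)) {
    bk <- binomial_result(k * b1$x, k * b1$n)
    expect_equal(bk$z, sqrt(k) * b1$z, tolerance = 1e-12)
  }
})

test_that("per-individual test type-I error matches the attained size", {
  withr::local_seed(54)
  # guessing observer: each of 24 probes responded with p = 0.5,
  # responses split at random between the two categories
  n_sim <- 1000L
  alpha <- 0.05
  rejections <- 0L
  for (i in seq_len(n_sim)) {
    probes <- make_probe_records(FALSE, FALSE)
    probes$responded <- stats::runif(24) < 0.5
    b <- category_binomial(probes, "trochaic")
    if (b$defined && !is.na(b$p_exact_one) && b$p_exact_one < alpha) {
      rejections <- rejections + 1L
    }
  }
  # oracle attained size by enumeration of the exact joint law:
  # x ~ Binomial(12, .5) correct-category responses and, independently,
  # y ~ Binomial(12, .5) wrong-category responses; reject when the exact
  # one-tailed tail P(X >= x | n = x + y) falls below alpha
  size <- 0
  for (x in 0:12) {
    for (y in 0:12) {
      n <- x + y
      if (n == 0) next
      tail <- stats::pbinom(x - 1, n, 0.5, lower.tail = FALSE)
      if (tail < alpha) {
        size <- size + stats::dbinom(x, 12, 0.5) * stats::dbinom(y, 12, 0.5)
      }
    }
  }
  expect_lt(abs(rejections / n_sim - size),
            3 * sqrt(size * (1 - size) / n_sim))
})

test_that("cue test report demands complete manipulation coverage", {
  run <- simulate_subject(strong_observer(), "human", seed = 13)
  ct <- cue_test_report(run)
  expect_equal(nrow(ct), 8L)
  expect_setequal(ct$manipulation, setdiff(manipulation_labels(), "none"))
  expect_true(all(ct$n_trials == 6L))  # 3 exemplars x 2 patterns each
  # a log missing one manipulation label is rejected
  recs <- run$records
  hit <- recs$phase == "cue_test" & recs$role == "probe" &
    recs$manipulation == "pitch_only"
  recs$manipulation[hit] <- "vowel_only"
  expect_error(cue_test_report(recs), "pitch_only")
  # an oracle responder is correct on every condition
  sched <- run$records[run$records$phase == "cue_test", ]
  sched$responded <- sched$pattern == sched$splus_pattern
  expect_true(all(cue_test_report(sched)$pct_correct == 100))
})

test_that("criterion trace audits agree with the recorded outcomes", {
  run <- simulate_subject("budgie_like", "budgerigar", seed = 8)
  tr <- criterion_trace(run)
  expect_true(all(tr$audit$agree))
  # discrimination advance happened at the first 4-consecutive run
  disc <- tr$session_dr[tr$session_dr$phase == "discrimination", ]
  ok <- disc$dr >= 0.8
  k <- length(ok)
  expect_true(all(ok[(k - 3):k]))
  if (k > 4L) {
    runs4 <- vapply(4:(k - 1), function(i) all(ok[(i - 3):i]), logical(1))
    expect_false(any(runs4))
  }
  # empty logs give an empty trace
  empty <- criterion_trace(run$records[0, ])
  expect_equal(nrow(empty$trace), 0L)
  # tampered phase status is reported as a mismatch
  bad <- run
  bad$phases$status[2] <- "failed"
  expect_false(all(criterion_trace(bad)$audit$agree))
})
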