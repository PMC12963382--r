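test_that("simulated cohorts reflect the task design", {
  tr <- simulate_behavior(n_participants = 30, trials_per_participant = 400,
                          seed = 2)
  expect_equal(length(unique(tr$participant_id)), 30)
  expect_true(all(tr$occlusion >= 0.70 & tr$occlusion <= 0.90))
  expect_true(all(tr$fixation_ms %in% c(25L, 50L)))
  expect_true(all(tr$condition %in% c("occluder", "random")))
  # attention checks on a random 10% of trials
  expect_lt(abs(mean(tr$is_attention_check) - 0.10), 0.01)
  # determinism
  tr2 <- simulate_behavior(n_participants = 30, trials_per_participant = 400,
                           seed = 2)
  expect_identical(tr, tr2)
})

test_that("QC passes a clean cohort untouched and is idempotent", {
  tr <- simulate_behavior(n_participants = 15, trials_per_participant = 200,
                          fraction_low_quality = 0, seed = 3)
  q <- qc_filter(tr)
  expect_equal(q$report$n_passed, 15)
  expect_equal(q$report$n_trials_dropped, 0)
  q2 <- qc_filter(q$trials)
  expect_identical(q2$trials, q$trials)
  expect_equal(q2$report$n_passed, q$report$n_passed)
  expect_error(qc_filter(tr[0, ]), class = "occlnet_invalid_argument")
})

test_that("QC excludes exactly the hand-counted violators", {
  # constructed cohort of 10: 2 fast responders, 1 low accuracy,
  # 1 failing 30% of attention checks -> 6 pass
  set.seed(9)
  mk <- function(id, rt, acc, att_fail) {
    n <- 60
    is_check <- rep(c(TRUE, rep(FALSE, 9)), 6)
    data.frame(participant_id = id, condition = rep(c("occluder", "random"), 30),
               rt_s = rt, correct = runif(n) < acc,
               occlusion = runif(n, 0.70, 0.90),
               is_attention_check = is_check,
               attention_passed = ifelse(is_check, runif(n) > att_fail, NA),
               fixation_ms = 25L)
  }
  cohort <- rbind(
    mk("fast1", 0.04, 0.9, 0), mk("fast2", 0.05, 0.9, 0),
    mk("lowacc", 0.8, 0.30, 0), mk("attfail", 0.8, 0.9, 1.0),
    mk("g1", 0.8, 0.9, 0), mk("g2", 0.7, 0.85, 0), mk("g3", 0.9, 0.95, 0),
    mk("g4", 0.75, 0.8, 0), mk("g5", 0.85, 0.9, 0), mk("g6", 0.8, 0.88, 0))
  # attfail misses 100% of checks > 20% threshold; make it exactly 30%
  att_rows <- cohort$participant_id == "attfail" & cohort$is_attention_check
  cohort$attention_passed[att_rows] <- rep(c(FALSE, FALSE, TRUE, TRUE, TRUE,
                                             FALSE), length.out = sum(att_rows))
  q <- qc_filter(cohort)
  expect_equal(q$report$n_passed, 6)
  expect_setequal(names(q$report$reasons),
                  c("fast1", "fast2", "lowacc", "attfail"))
  expect_true("mean-RT" %in% q$report$reasons$fast1)
  expect_true("accuracy" %in% q$report$reasons$lowacc)
  expect_true("attention" %in% q$report$reasons$attfail)
})

test_that("planted condition effects are recovered by the paired analysis", {
  tr <- simulate_behavior(n_participants = 41, trials_per_participant = 400,
                          effect_size_acc = 0.04, effect_size_rt = -0.039,
                          seed = 5)
  q <- qc_filter(tr)
  cc <- condition_compare(q$trials)
  expect_lt(abs(cc$accuracy$difference - 0.04), 0.015)
  expect_gt(cc$accuracy$mean_occluder, cc$accuracy$mean_random)
  expect_lt(cc$rt$mean_occluder, cc$rt$mean_random)
  expect_lt(cc$accuracy$p, 0.05)
  # a missing condition is rejected
  sub <- q$trials[!(q$trials$participant_id == q$trials$participant_id[1] &
                      q$trials$condition == "random"), ]
  expect_error(condition_compare(sub), class = "occlnet_invalid_argument")
})

test_that("null effects yield calm t statistics", {
  hits <- 0
  for (s in 1:20) {
    tr <- simulate_behavior(n_participants = 20, trials_per_participant = 120,
                            effect_size_acc = 0, effect_size_rt = 0, seed = s)
    cc <- condition_compare(tr)
    if (abs(cc$accuracy$t) < 2) hits <- hits + 1
  }
  expect_gte(hits, 17)  # |t| < 2 in about 95 percent of null runs
})

test_that("occlusion tertiles have equal counts and stable tie-breaking", {
  tr <- simulate_behavior(n_participants = 10, trials_per_participant = 90,
                          seed = 7)
  ob <- occlusion_bins(tr)
  expect_lte(max(ob$counts) - min(ob$counts), 1)
  task_n <- sum(!tr$is_attention_check)
  expect_equal(sum(ob$counts), task_n)
  if (task_n %% 3 == 0) expect_true(all(ob$counts == task_n / 3))
  # constructed ties at the cut point are broken by original trial order
  tied <- data.frame(participant_id = rep(c("a", "b"), each = 30),
                     condition = rep(c("occluder", "random"), 30),
                     rt_s = 0.8, correct = TRUE,
                     occlusion = rep(0.8, 60),
                     is_attention_check = FALSE, attention_passed = NA,
                     fixation_ms = 25L)
  obt <- occlusion_bins(tied)
  expect_equal(obt$counts, c(20, 20, 20))
  expect_equal(obt$bins[1:20], rep(1L, 20))  # earlier trials fill lower bins
  expect_error(occlusion_bins(tied[1:2, ]),
               class = "occlnet_invalid_argument")
})

test_that("behavioral CSV round trip and column adaptation", {
  tr <- simulate_behavior(n_participants = 3, trials_per_participant = 20,
                          seed = 8)
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tr, f, row.names = FALSE)
  back <- read_behavior_csv(f)
  expect_equal(nrow(back), nrow(tr))
  # adapter for foreign column names
  tr2 <- tr
  names(tr2)[names(tr2) == "rt_s"] <- "reaction_time"
  utils::write.csv(tr2, f, row.names = FALSE)
  back2 <- read_behavior_csv(f, rename = c(rt_s = "reaction_time"))
  expect_true("rt_s" %in% names(back2))
  expect_error(read_behavior_csv(f, rename = c(rt_s = "nope")),
               class = "occlnet_format_error")
})
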