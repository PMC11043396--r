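test_that("max repetition and loci follow the run-length oracle", {
  expect_equal(max_repetition("abcccab", "c"), 3L)
  expect_equal(max_repetition("ccacccacc", "c"), 3L)
  expect_equal(max_repetition("ababab", "c"), 0L)
  expect_equal(max_repetition("", "c"), 0L)
  loci <- repetition_loci("ccacccacc", "c")
  expect_equal(loci$locus, 1:3)
  expect_equal(loci$length, c(2L, 3L, 2L))
  expect_equal(nrow(repetition_loci("ab", "c")), 0L)
  expect_equal(repetition_loci("ccc", "c"),
               data.frame(locus = 1L, length = 3L))
  # random sequences against an independent rle-based computation
  set.seed(8)
  for (k in 1:30) {
    s <- sample(c("a", "c"), 20, TRUE)
    r <- rle(s)
    expect_equal(max_repetition(s, "c"),
                 if (any(r$values == "c")) max(r$lengths[r$values == "c"]) else 0L)
  }
})

test_that("threshold selection finds the smallest qualifying threshold", {
  bouts <- rep("abccccca", 20) # R = 5 everywhere
  sel <- select_threshold(bouts, "c", 0.05)
  expect_equal(sel$threshold_x, 6L)
  expect_equal(sel$achieved_fraction, 0)
  # a permissive fraction admits the smallest threshold
  mixed <- c(rep("abccca", 4), rep("ab", 6)) # 40% of bouts reach R >= 1
  expect_equal(select_threshold(mixed, "c", 0.5)$threshold_x, 1L)
  expect_error(select_threshold(rep("ab", 5), "c"), "absent")
  # exhaustive-scan oracle on random corpora
  set.seed(12)
  for (k in 1:10) {
    seqs <- replicate(60, paste(sample(c("a", "b", "c"), 15, TRUE),
                                collapse = ""))
    if (all(vapply(seqs, max_repetition, integer(1), "c") == 0)) next
    frac <- 0.1
    sel <- select_threshold(seqs, "c", frac)
    rr <- vapply(seqs, max_repetition, integer(1), "c")
    ok <- which(vapply(seq_len(max(rr) + 1L),
                       function(x) mean(rr >= x) <= frac, logical(1)))
    expect_equal(sel$threshold_x, min(ok))
    expect_lte(sel$achieved_fraction, frac)
  }
})

decision_oracle <- function(kind, x, R, margin = 1L) {
  switch(kind,
         REWARD = if (R >= x) "REWARD" else "NONE",
         NOT_TOO_MUCH = if (R > x + margin) "OMISSION"
                        else if (R >= x) "REWARD" else "NONE",
         EXCESS_REWARD = "NONE",
         NO_REWARD = "NONE")
}

test_that("the rule engine reproduces the decision table exhaustively", {
  kinds <- c("REWARD", "NOT_TOO_MUCH", "EXCESS_REWARD", "NO_REWARD")
  for (kind in kinds) {
    for (x in c(1L, 4L, 11L)) {
      rule <- reward_rule(kind, "c", threshold_x = x)
      for (R in 0:50) {
        d <- evaluate_trial(rule, R, clock = 100)
        expect_true(d$decision %in% c("REWARD", "OMISSION", "NONE"))
        expect_equal(d$decision, decision_oracle(kind, x, R))
        if (d$decision == "REWARD") {
          expect_equal(d$feedback_at, 102) # bout end + 2 s delay
        } else {
          expect_true(is.na(d$feedback_at))
        }
      }
    }
  }
})

test_that("documented rule examples hold", {
  expect_equal(evaluate_trial(reward_rule("REWARD", "c", 4), 4)$decision,
               "REWARD")
  expect_equal(evaluate_trial(reward_rule("NOT_TOO_MUCH", "c", 4), 6)$decision,
               "OMISSION")
  expect_equal(evaluate_trial(reward_rule("NOT_TOO_MUCH", "c", 4), 5)$decision,
               "REWARD")
  expect_equal(evaluate_trial(reward_rule("NO_REWARD", "c", 4), 9)$decision,
               "NONE")
  expect_error(reward_rule("BANANA", "c", 4))
  expect_error(reward_rule("REWARD", "c", 0))
})

test_that("the NOT_TOO_MUCH reward set refines the REWARD set", {
  for (x in 1:8) {
    plain <- reward_rule("REWARD", "c", x)
    ntm <- reward_rule("NOT_TOO_MUCH", "c", x)
    for (R in 0:30) {
      if (evaluate_trial(ntm, R)$decision == "REWARD") {
        expect_equal(evaluate_trial(plain, R)$decision, "REWARD")
      }
    }
  }
})

test_that("sessions evaluate bouts under the block rule active at bout end", {
  rule <- reward_rule("NO_REWARD", "c", 4)
  sched <- schedule_hourly_cue(rule, n_hours = 2)
  bouts <- data.frame(time = c(300, 1800, 3650),
                      sequence = c("accccc", "accccc", "abc"))
  log <- run_session(bouts, sched)
  expect_equal(log$trials$rule_kind, c("NO_REWARD", "NONE", "NO_REWARD"))
  expect_equal(log$trials$cue_color, c("YELLOW", "NONE", "GREEN"))
  expect_equal(log$trials$decision, c("NONE", "NONE", "NONE"))
  expect_equal(log$trials$R, c(5L, NA_integer_, 1L))
})

test_that("excess-reward blocks emit one timer reward per full minute", {
  rule <- reward_rule("EXCESS_REWARD", "c", 4)
  sched <- session_schedule(0, 600, list(rule))
  log <- run_session(data.frame(time = numeric(), sequence = character()),
                     sched)
  expect_equal(nrow(log$trials), 0L)
  expect_equal(nrow(log$timer_rewards), 10L)
  expect_equal(log$timer_rewards$time, 60 * (1:10))
  # a partial minute does not trigger a reward
  log2 <- run_session(data.frame(time = numeric(), sequence = character()),
                      session_schedule(0, 90, list(rule)))
  expect_equal(nrow(log2$timer_rewards), 1L)
  # bouts during excess blocks are logged but never rewarded by content
  log3 <- run_session(data.frame(time = 30, sequence = "cccccc"), sched)
  expect_equal(log3$trials$decision, "NONE")
})

test_that("rewarded bouts schedule feedback exactly delay_s after bout end", {
  rule <- reward_rule("REWARD", "c", 2)
  sched <- session_schedule(0, 1000, list(rule))
  bouts <- data.frame(time = c(10, 20, 30), sequence = c("cc", "c", "ccc"))
  log <- run_session(bouts, sched, delay_s = 2)
  rewarded <- log$trials[log$trials$decision == "REWARD", ]
  expect_equal(rewarded$feedback_at - rewarded$time, rep(2, nrow(rewarded)))
  expect_equal(log$trials$decision, c("REWARD", "NONE", "REWARD"))
})

test_that("a zero-learning singer stays stationary", {
  pol <- singer_policy(init_mean = 3, step_up = 0, step_down = 0)
  log <- simulate_closed_loop(reward_rule("REWARD", "c", 4), pol,
                              n_bouts = 300, seed = 5)
  expect_true(all(log$trials$mean_before == 3))
})

test_that("a learning singer increases repetition under REWARD but not NO_REWARD", {
  pol <- singer_policy(init_mean = 3, step_up = 0.25, step_down = 0.25)
  diffs_reward <- diffs_none <- numeric(20)
  for (s in 1:20) {
    lr <- simulate_closed_loop(reward_rule("REWARD", "c", 4), pol,
                               n_bouts = 500, seed = s)
    ln <- simulate_closed_loop(reward_rule("NO_REWARD", "c", 4), pol,
                               n_bouts = 500, seed = s)
    diffs_reward[s] <- mean(tail(lr$trials$R, 50)) - mean(head(lr$trials$R, 50))
    diffs_none[s] <- mean(tail(ln$trials$R, 50)) - mean(head(ln$trials$R, 50))
  }
  expect_lt(t.test(diffs_reward, alternative = "greater")$p.value, 0.01)
  expect_gt(t.test(diffs_none, alternative = "greater")$p.value, 0.05)
  expect_lt(abs(mean(diffs_none)), 0.5)
})

test_that("closed-loop simulations are reproducible and log sequences", {
  pol <- singer_policy()
  l1 <- simulate_closed_loop(reward_rule("REWARD", "c", 3), pol, 100, seed = 9)
  l2 <- simulate_closed_loop(reward_rule("REWARD", "c", 3), pol, 100, seed = 9)
  expect_identical(l1$trials, l2$trials)
  expect_equal(vapply(l1$trials$sequence, max_repetition, integer(1), "c",
                      USE.NAMES = FALSE),
               l1$trials$R)
})
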