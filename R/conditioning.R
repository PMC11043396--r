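RULE_KINDS <- c("REWARD", "NOT_TOO_MUCH", "EXCESS_REWARD", "NO_REWARD")

#' Define a reward rule
#'
#' The four conditioning contingencies evaluated on a bout's maximum
#' repetition count `R` of the target syllable:
#' * `REWARD`: reward iff `R >= threshold_x` (the threshold itself is
#'   rewarded).
#' * `NOT_TOO_MUCH`: reward iff `threshold_x <= R <= threshold_x +
#'   omission_margin`; explicit omission when `R` exceeds the omission
#'   threshold (`R > x + 1` at the default margin of 1); otherwise nothing.
#' * `EXCESS_REWARD`: bout content is ignored; rewards are emitted by a
#'   timer once per `excess_period_s` (60 s), anchored at block start.
#' * `NO_REWARD`: never rewards, whatever the bird sings.
#'
#' @param kind One of `REWARD`, `NOT_TOO_MUCH`, `EXCESS_REWARD`,
#'   `NO_REWARD`.
#' @param target Target syllable letter.
#' @param threshold_x Repetition threshold `x` (>= 1), chosen per bird with
#'   [select_threshold()].
#' @param omission_margin Width of the rewarded window above `x` for
#'   `NOT_TOO_MUCH` (default 1: rewarded range `x` to `x + 1`).
#' @param excess_period_s Timer period for `EXCESS_REWARD`.
#' @return A `reward_rule`.
#' @export
reward_rule <- function(kind, target, threshold_x = 1L,
                        omission_margin = 1L, excess_period_s = 60) {
  kind <- match.arg(kind, RULE_KINDS)
  stopifnot(threshold_x >= 1, omission_margin >= 0, excess_period_s > 0)
  structure(list(kind = kind, target = target,
                 threshold_x = as.integer(threshold_x),
                 omission_margin = as.integer(omission_margin),
                 excess_period_s = excess_period_s),
            class = "reward_rule")
}

#' Context cue shown with a rule block
#'
#' An arbitrary colored frame on the display monitor, paired with a meaning
#' (reward color / no-reward color); the color-to-meaning assignment is
#' fixed per experiment and counterbalanced across subjects.
#'
#' @param frame_color `GREEN`, `YELLOW` or `NONE`.
#' @param meaning `REWARD_COLOR`, `NO_REWARD_COLOR` or `NONE`.
#' @return A `context_cue`.
#' @export
context_cue <- function(frame_color = c("NONE", "GREEN", "YELLOW"),
                        meaning = c("NONE", "REWARD_COLOR", "NO_REWARD_COLOR")) {
  structure(list(frame_color = match.arg(frame_color),
                 meaning = match.arg(meaning)),
            class = "context_cue")
}

#' Maximum repetition count of a target syllable
#'
#' Length of the longest run of consecutive target symbols in the bout
#' sequence; 0 when the target is absent.
#'
#' @param sequence Symbol string or character vector.
#' @param target Target letter.
#' @return Integer `R`.
#' @export
max_repetition <- function(sequence, target) {
  runs <- repetition_loci(sequence, target)
  if (nrow(runs) == 0L) 0L else max(runs$length)
}

#' All repetition loci of a target syllable
#'
#' Every maximal run of the target within the bout, with its ordinal
#' position (1-based locus index among the runs).
#'
#' @param sequence Symbol string or character vector.
#' @param target Target letter.
#' @return Data frame: `locus`, `length`.
#' @export
repetition_loci <- function(sequence, target) {
  s <- as_symbols(sequence)
  if (length(s) == 0L) return(data.frame(locus = integer(), length = integer()))
  r <- rle(s == target)
  lens <- r$lengths[r$values]
  data.frame(locus = seq_along(lens), length = as.integer(lens))
}

#' Choose a repetition threshold from a baseline corpus
#'
#' Smallest `x` such that the fraction of bouts whose maximum repetition
#' reaches `x` is at most `max_exceed_fraction`, so that only a small
#' percentage of baseline songs would be rewarded.
#'
#' @param corpus_sequences Character vector (or list) of bout sequences.
#' @param target Target letter.
#' @param max_exceed_fraction Allowed fraction of qualifying bouts, in
#'   (0, 1).
#' @return List: `threshold_x`, `achieved_fraction` (fraction of bouts with
#'   `R >= threshold_x`).
#' @export
select_threshold <- function(corpus_sequences, target,
                             max_exceed_fraction = 0.05) {
  stopifnot(max_exceed_fraction > 0, max_exceed_fraction < 1,
            length(corpus_sequences) > 0)
  rr <- vapply(corpus_sequences, max_repetition, integer(1), target = target,
               USE.NAMES = FALSE)
  if (all(rr == 0L)) stop("target '", target, "' absent from the corpus")
  for (x in seq_len(max(rr) + 1L)) {
    frac <- mean(rr >= x)
    if (frac <= max_exceed_fraction) {
      return(list(threshold_x = x, achieved_fraction = frac))
    }
  }
}

#' Evaluate one bout against a reward rule
#'
#' Applies the active rule to the bout's maximum repetition count. Rewarded
#' bouts schedule their feedback `delay_s` seconds after the bout end (the
#' deliberate delay that keeps the social reward from arriving
#' unnaturally fast).
#'
#' @param rule A [reward_rule()].
#' @param R Maximum repetition count in the bout (>= 0).
#' @param cue Optional [context_cue()] active at the time; logged, not
#'   interpreted (the schedule decides which rule runs).
#' @param clock Bout end time in seconds (used for `feedback_at`).
#' @param delay_s Feedback delay after bout end.
#' @return A `trial_decision`: `decision` (`REWARD`/`OMISSION`/`NONE`),
#'   `R`, `rule_kind`, `cue`, `feedback_at` (`NA` unless rewarded).
#' @export
evaluate_trial <- function(rule, R, cue = NULL, clock = NA_real_,
                           delay_s = 2.0) {
  stopifnot(inherits(rule, "reward_rule"), R >= 0)
  x <- rule$threshold_x
  decision <- switch(
    rule$kind,
    REWARD = if (R >= x) "REWARD" else "NONE",
    NOT_TOO_MUCH = if (R >= x && R <= x + rule$omission_margin) "REWARD"
                   else if (R > x + rule$omission_margin) "OMISSION"
                   else "NONE",
    EXCESS_REWARD = "NONE", # rewards come from the block timer, not bouts
    NO_REWARD = "NONE",
    stop("unknown rule kind: ", rule$kind))
  structure(list(decision = decision, R = as.integer(R),
                 rule_kind = rule$kind, cue = cue,
                 feedback_at = if (decision == "REWARD") clock + delay_s
                               else NA_real_),
            class = "trial_decision")
}

#' Build a session schedule of rule blocks
#'
#' Ordered, non-overlapping time blocks, each with an active rule and an
#' optional context cue.
#'
#' @param start,end Numeric vectors of block boundaries in seconds
#'   (half-open `[start, end)`).
#' @param rules List of [reward_rule()]s, one per block.
#' @param cues Optional list of [context_cue()]s (recycled `NONE` cue if
#'   omitted).
#' @return A `session_schedule`.
#' @export
session_schedule <- function(start, end, rules, cues = NULL) {
  stopifnot(length(start) == length(end), length(rules) == length(start),
            all(end > start))
  if (length(start) > 1L && any(start[-1L] < end[-length(end)])) {
    stop("schedule blocks must be ordered and non-overlapping")
  }
  if (is.null(cues)) cues <- rep(list(context_cue()), length(start))
  stopifnot(length(cues) == length(start))
  structure(list(start = start, end = end, rules = rules, cues = cues),
            class = "session_schedule")
}

#' Hourly cue-alternation schedule
#'
#' The within-day probe design: each hour shows a colored frame for 10
#' minutes followed by 50 minutes of blank, alternating the no-reward color
#' and the reward color hour by hour; only songs during the 10-minute cue
#' windows are analyzed. Both cue blocks run the same (no-reward) rule --
#' the cue, not the contingency, is what alternates.
#'
#' @param rule Rule active in every block (typically `NO_REWARD` for probe
#'   sessions).
#' @param n_hours Number of one-hour cycles.
#' @param cue_a,cue_b Cues for odd/even hours (default no-reward color
#'   first, then reward color).
#' @param cue_min Cue-window length in minutes.
#' @param t0 Session start time in seconds.
#' @return A `session_schedule` containing only the cue windows (songs in
#'   the blank periods fall outside all blocks and are logged with rule
#'   `NONE`).
#' @export
schedule_hourly_cue <- function(rule, n_hours = 12L,
                                cue_a = context_cue("YELLOW", "NO_REWARD_COLOR"),
                                cue_b = context_cue("GREEN", "REWARD_COLOR"),
                                cue_min = 10, t0 = 0) {
  starts <- t0 + (seq_len(n_hours) - 1L) * 3600
  session_schedule(starts, starts + cue_min * 60,
                   rules = rep(list(rule), n_hours),
                   cues = rep(list(cue_a, cue_b), length.out = n_hours))
}

#' Run a conditioning session over a stream of bouts
#'
#' Every bout is evaluated against the rule of the block containing its end
#' time (decisions happen at bout end; a bout spanning a block boundary is
#' judged by the rule active when it ends). Rewarded bouts schedule
#' feedback at `bout end + delay_s`. `EXCESS_REWARD` blocks additionally
#' emit timer rewards at `block start + k * period` for every `k >= 0`
#' with that time inside the block, independent of singing. Overlapping
#' rewards are logged without suppression.
#'
#' @param bouts Data frame with `time` (bout end, seconds) and `sequence`
#'   (bout symbol string), time-ordered.
#' @param schedule A [session_schedule()].
#' @param delay_s Feedback delay for rewarded bouts.
#' @return A `trial_log`: `trials` (one row per bout: `time`, `sequence`,
#'   `R`, `rule_kind`, `cue_color`, `cue_meaning`, `decision`,
#'   `feedback_at`, `block`) and `timer_rewards` (`time`, `block`).
#' @export
run_session <- function(bouts, schedule, delay_s = 2.0) {
  stopifnot(is.data.frame(bouts), inherits(schedule, "session_schedule"))
  if (nrow(bouts) > 1L && is.unsorted(bouts$time)) {
    stop("bout stream must be time-ordered")
  }
  n <- nrow(bouts)
  trials <- data.frame(
    time = numeric(n), sequence = character(n), R = integer(n),
    rule_kind = character(n), cue_color = character(n),
    cue_meaning = character(n), decision = character(n),
    feedback_at = numeric(n), block = integer(n))
  for (i in seq_len(n)) {
    t <- bouts$time[i]
    blk <- which(schedule$start <= t & t < schedule$end)
    if (length(blk) == 0L) {
      trials[i, ] <- list(t, bouts$sequence[i], NA_integer_, "NONE", "NONE",
                          "NONE", "NONE", NA_real_, NA_integer_)
      next
    }
    rule <- schedule$rules[[blk]]
    cue <- schedule$cues[[blk]]
    R <- max_repetition(bouts$sequence[i], rule$target)
    dec <- evaluate_trial(rule, R, cue = cue, clock = t, delay_s = delay_s)
    trials[i, ] <- list(t, bouts$sequence[i], R, rule$kind, cue$frame_color,
                        cue$meaning, dec$decision, dec$feedback_at, blk)
  }
  timer <- list()
  for (b in seq_along(schedule$start)) {
    rule <- schedule$rules[[b]]
    if (rule$kind != "EXCESS_REWARD") next
    # the k-th timer reward fires when the k-th full period of the block
    # has elapsed: a block of duration d yields floor(d / period) rewards
    k <- floor((schedule$end[b] - schedule$start[b]) / rule$excess_period_s)
    if (k >= 1) {
      times <- schedule$start[b] + rule$excess_period_s * seq_len(k)
      timer[[length(timer) + 1L]] <- data.frame(time = times, block = b)
    }
  }
  timer_rewards <- if (length(timer)) do.call(rbind, timer)
                   else data.frame(time = numeric(), block = integer())
  structure(list(trials = trials, timer_rewards = timer_rewards),
            class = "trial_log")
}

#' @export
print.trial_log <- function(x, ...) {
  cat(sprintf("<trial_log> %d trials (%d rewarded, %d omitted), %d timer rewards\n",
              nrow(x$trials), sum(x$trials$decision == "REWARD"),
              sum(x$trials$decision == "OMISSION"), nrow(x$timer_rewards)))
  invisible(x)
}

#' Policy of the simulated singer
#'
#' The test double for the bird in closed-loop simulations. The singer
#' draws each bout's target-run length from a shifted geometric law with
#' mean `m` and moves `m` according to the feedback it receives: up by
#' `step_up` after a reward, down by `step_down` after an omission, down by
#' `none_step` when nothing happens. `m` is clamped to
#' `[min_mean, max_mean]`. All-zero steps give a stationary
#' (zero-learning) singer.
#'
#' @param init_mean Initial mean run length.
#' @param step_up,step_down,none_step Learning steps (>= 0).
#' @param min_mean,max_mean Clamp range for the mean.
#' @return A `singer_policy`.
#' @export
singer_policy <- function(init_mean = 3, step_up = 0.25, step_down = 0.25,
                          none_step = 0, min_mean = 1, max_mean = 12) {
  stopifnot(init_mean >= min_mean, init_mean <= max_mean,
            step_up >= 0, step_down >= 0, none_step >= 0, min_mean >= 1)
  structure(list(init_mean = init_mean, step_up = step_up,
                 step_down = step_down, none_step = none_step,
                 min_mean = min_mean, max_mean = max_mean),
            class = "singer_policy")
}

draw_run_length <- function(mean_len) {
  if (mean_len <= 1) return(1L)
  1L + stats::rgeom(1L, prob = 1 / mean_len)
}

#' Closed-loop conditioning simulation with a learning singer
#'
#' Composes the rule engine with a [singer_policy()] test double: each
#' simulated bout contains one repetition locus whose length tracks the
#' singer's current mean; the trial decision feeds back into the mean
#' before the next bout. Reproducible given `seed`.
#'
#' @param rule A [reward_rule()].
#' @param policy A [singer_policy()].
#' @param n_bouts Number of bouts to simulate.
#' @param seed RNG seed.
#' @param bout_interval_s Seconds between consecutive bout ends.
#' @return List of class `closed_loop_log`: `trials` (data frame `time`,
#'   `R`, `decision`, `mean_before`), `policy`, `rule`.
#' @export
simulate_closed_loop <- function(rule, policy, n_bouts = 500L, seed = 1L,
                                 bout_interval_s = 30) {
  stopifnot(inherits(rule, "reward_rule"), inherits(policy, "singer_policy"))
  set.seed(seed)
  m <- policy$init_mean
  R <- integer(n_bouts)
  dec <- character(n_bouts)
  mean_before <- numeric(n_bouts)
  for (i in seq_len(n_bouts)) {
    mean_before[i] <- m
    R[i] <- draw_run_length(m)
    d <- evaluate_trial(rule, R[i], clock = i * bout_interval_s)
    dec[i] <- d$decision
    m <- switch(d$decision,
                REWARD = m + policy$step_up,
                OMISSION = m - policy$step_down,
                NONE = m - policy$none_step)
    m <- min(max(m, policy$min_mean), policy$max_mean)
  }
  sequences <- paste0("iab", strrep(rule$target, R), "de")
  structure(list(trials = data.frame(time = seq_len(n_bouts) * bout_interval_s,
                                     sequence = sequences,
                                     R = R, decision = dec,
                                     mean_before = mean_before),
                 policy = policy, rule = rule),
            class = "closed_loop_log")
}
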