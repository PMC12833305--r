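#' Staircase update for the smaller-sooner amount
#'
#' After an SS choice the offered SS amount decreases by `cfg$step` candies
#' (floored at `cfg$ss_min`); after an LL choice it increases by `cfg$step`
#' (capped at `cfg$ss_max`).
#'
#' @param current Current SS amount in candies; must lie in
#'   `[cfg$ss_min, cfg$ss_max]`.
#' @param choice `"SS"` or `"LL"`.
#' @param cfg A [task_config()].
#' @return The SS amount offered on the next trial.
#' @export
next_ss_amount <- function(current, choice, cfg = task_config()) {
  if (current < cfg$ss_min || current > cfg$ss_max)
    stop("current SS amount out of range [ss_min, ss_max]")
  choice <- match.arg(choice, c("SS", "LL"))
  if (choice == "SS") max(current - cfg$step, cfg$ss_min)
  else min(current + cfg$step, cfg$ss_max)
}

#' Indifference points from a trial sequence
#'
#' An indifference point (IP) is the mean SS amount across three consecutive
#' trials with alternating choices (SS-LL-SS or LL-SS-LL), the operational
#' signature of subjective equivalence between the options. By default every
#' consecutive alternating triplet emits an IP (overlapping windows);
#' `cfg$overlap_ips = FALSE` restricts to disjoint triplets.
#'
#' @param trials A data.frame of trials ordered by `trial_index`, with
#'   columns `choice` and `ss_amount`.
#' @param cfg A [task_config()].
#' @return Numeric vector of IP values (candies), in order of window end;
#'   empty when no alternating triplet exists.
#' @export
detect_ips <- function(trials, cfg = task_config()) {
  if (is.null(trials) || nrow(trials) < 3) return(numeric(0))
  ips_from_vectors(trials$choice, trials$ss_amount, cfg$overlap_ips)
}

ips_from_vectors <- function(ch, ss, overlap = TRUE) {
  n <- length(ch)
  if (n < 3) return(numeric(0))
  ips <- numeric(0)
  i <- 3
  while (i <= n) {
    if (ch[i - 2] != ch[i - 1] && ch[i - 1] != ch[i]) {
      ips <- c(ips, mean(ss[(i - 2):i]))
      i <- i + if (overlap) 1L else 3L
    } else {
      i <- i + 1L
    }
  }
  ips
}

termination_from_vectors <- function(ch, ss, cfg) {
  if (length(ips_from_vectors(ch, ss, cfg$overlap_ips)) >= cfg$ips_per_block)
    return("six_ips")
  n <- length(ch)
  L <- cfg$boundary_run_length
  if (n >= L) {
    idx <- (n - L + 1):n
    if (all(ss[idx] == cfg$ss_min) && all(ch[idx] == "SS"))
      return("boundary_run")
    if (all(ss[idx] == cfg$ss_max) && all(ch[idx] == "LL"))
      return("boundary_run")
  }
  "continue"
}

#' Block termination check
#'
#' A block ends when `cfg$ips_per_block` indifference points have been
#' reached (`"six_ips"`), or when the participant has made
#' `cfg$boundary_run_length` consecutive choices while the offered SS amount
#' sat at a staircase boundary — all SS at `ss_min` or all LL at `ss_max` —
#' indicating a stable preference (`"boundary_run"`). Otherwise
#' `"continue"`.
#'
#' @inheritParams detect_ips
#' @return One of `"continue"`, `"six_ips"`, `"boundary_run"`.
#' @export
check_termination <- function(trials, cfg = task_config()) {
  if (is.null(trials) || nrow(trials) == 0) return("continue")
  termination_from_vectors(trials$choice, trials$ss_amount, cfg)
}

#' Run one block of the staircase task
#'
#' Repeatedly offers the SS amount, collects the chooser's decision, applies
#' the staircase update, and stops per [check_termination()]. An LL choice
#' waits the full block delay; an SS choice aborts the wait at the
#' chooser-supplied time (defaulting to the SS lockout).
#'
#' @param delay Block delay in seconds.
#' @param chooser A function `function(ctx)` receiving a list with elements
#'   `ss_amount`, `ll_amount`, `delay`, `trial_index`, `block_index`, and
#'   `config`; it must return either the string `"SS"`/`"LL"` or a list
#'   `list(choice =, wait =)` where `wait` (seconds, only honoured for SS
#'   choices) is the abort time within `[ss_lockout, delay]`.
#' @param cfg A [task_config()].
#' @param block_index 0-based block position within the session.
#' @param points_start Cumulative points carried in from earlier blocks.
#' @param max_trials Safety cap on trials per block.
#' @return A list of class `block_result`: `delay`, `trials` (data.frame of
#'   trial records), `ips`, `termination_reason`.
#' @export
run_block <- function(delay, chooser, cfg = task_config(), block_index = 0L,
                      points_start = 0, max_trials = 1000L) {
  ss_v <- numeric(0); ch_v <- character(0); wait_v <- numeric(0)
  pts_v <- numeric(0)
  ss <- cfg$ss_initial
  points <- points_start
  trial_index <- 0L
  reason <- "continue"
  while (trial_index < max_trials) {
    ctx <- list(ss_amount = ss, ll_amount = cfg$ll_amount, delay = delay,
                trial_index = trial_index, block_index = block_index,
                config = cfg)
    dec <- chooser(ctx)
    if (is.character(dec)) dec <- list(choice = dec, wait = NULL)
    if (!is.list(dec) || !dec$choice %in% c("SS", "LL"))
      stop("chooser must return \"SS\" or \"LL\"")
    if (dec$choice == "LL") {
      wait <- delay
      points <- points + cfg$ll_amount
    } else {
      wait <- if (is.null(dec$wait)) cfg$ss_lockout else dec$wait
      wait <- min(max(wait, cfg$ss_lockout), delay)
      points <- points + ss
    }
    ss_v[trial_index + 1L] <- ss
    ch_v[trial_index + 1L] <- dec$choice
    wait_v[trial_index + 1L] <- wait
    pts_v[trial_index + 1L] <- points
    reason <- termination_from_vectors(ch_v, ss_v, cfg)
    ss <- next_ss_amount(ss, dec$choice, cfg)
    trial_index <- trial_index + 1L
    if (reason != "continue") break
  }
  n <- length(ss_v)
  trials <- data.frame(
    block_index = rep(block_index, n), delay = rep(delay, n),
    trial_index = seq_len(n) - 1L, ss_amount = ss_v, choice = ch_v,
    wait_elapsed = wait_v,
    trial_duration = wait_v + cfg$highlight_duration +
      cfg$feedback_duration + cfg$score_display_duration,
    cumulative_points = pts_v, stringsAsFactors = FALSE)
  structure(list(delay = delay, trials = trials,
                 ips = detect_ips(trials, cfg),
                 termination_reason = reason),
            class = "block_result")
}

#' Run a full session of the task
#'
#' Executes one block per configured delay, in presentation order, carrying
#' cumulative points across blocks. Session duration sums every trial's
#' duration (wait + highlight + feedback + score display) plus the
#' full-delay demonstrations played before each block.
#'
#' @inheritParams run_block
#' @return A list of class `session_result`: `blocks` (list of
#'   `block_result`), `trials` (all trials as one data.frame),
#'   `total_duration` (seconds), `points`.
#' @export
run_session <- function(chooser, cfg = task_config(), max_trials = 1000L) {
  blocks <- vector("list", length(cfg$delays))
  points <- 0
  duration <- 0
  for (b in seq_along(cfg$delays)) {
    blk <- run_block(cfg$delays[b], chooser, cfg, block_index = b - 1L,
                     points_start = points, max_trials = max_trials)
    blocks[[b]] <- blk
    if (!is.null(blk$trials) && nrow(blk$trials) > 0) {
      points <- blk$trials$cumulative_points[nrow(blk$trials)]
      duration <- duration + sum(blk$trials$trial_duration)
    }
    duration <- duration + cfg$demo_repeats * cfg$delays[b]
  }
  trials <- do.call(rbind, lapply(blocks, `[[`, "trials"))
  structure(list(blocks = blocks, trials = trials,
                 total_duration = duration, points = points),
            class = "session_result")
}

#' Scripted choosers
#'
#' Deterministic choosers for worked examples and boundary checks:
#' `chooser_always_ll` waits out every delay, `chooser_always_ss` takes the
#' immediate option as soon as it unlocks, and `chooser_alternating` starts
#' with `first` and then alternates strictly, which reaches the
#' indifference-point termination in the minimum number of trials.
#'
#' @param ctx Trial context (see [run_block()]).
#' @return A choice (or, for the factory `chooser_alternating`, a chooser).
#' @export
chooser_always_ll <- function(ctx) "LL"

#' @rdname chooser_always_ll
#' @export
chooser_always_ss <- function(ctx) list(choice = "SS", wait = ctx$config$ss_lockout)

#' @rdname chooser_always_ll
#' @param first First choice of each block, `"SS"` or `"LL"`.
#' @export
chooser_alternating <- function(first = "SS") {
  first <- match.arg(first, c("SS", "LL"))
  function(ctx) {
    pick <- if (ctx$trial_index %% 2 == 0) first else setdiff(c("SS", "LL"), first)
    if (pick == "SS") list(choice = "SS", wait = ctx$config$ss_lockout) else "LL"
  }
}

#' Replay a logged choice sequence through the staircase
#'
#' Rebuilds the offered SS trajectory implied by a sequence of choices,
#' verifying engine determinism: replaying a logged block reproduces the
#' logged `ss_amount` column exactly.
#'
#' @param choices Character vector of `"SS"`/`"LL"`.
#' @param cfg A [task_config()].
#' @return Numeric vector of offered SS amounts, same length as `choices`.
#' @export
replay_ss_trajectory <- function(choices, cfg = task_config()) {
  ss <- numeric(length(choices))
  cur <- cfg$ss_initial
  for (i in seq_along(choices)) {
    ss[i] <- cur
    cur <- next_ss_amount(cur, choices[i], cfg)
  }
  ss
}
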