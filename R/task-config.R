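#' Task configuration for the experiential delay-discounting game
#'
#' Builds and validates the parameter set that defines one session of the
#' staircase task: the smaller-sooner (SS) option starts at `ss_initial`
#' candies and is adjusted by `step` candies after every choice (down after
#' SS, up after LL), bounded by `ss_min` and `ss_max`; the larger-later (LL)
#' amount is constant. The session runs one block per entry of `delays`, in
#' the order given.
#'
#' @param ss_initial Starting SS amount in candies.
#' @param ss_min Smallest SS amount the staircase may reach.
#' @param ss_max Largest SS amount the staircase may reach.
#' @param ll_amount Constant delayed-reward amount; must exceed `ss_max`.
#' @param delays Block delays in seconds, in presentation order.
#' @param step Staircase adjustment per trial, in candies.
#' @param ips_per_block Number of indifference points that terminates a block.
#' @param boundary_run_length Number of consecutive choices made while the SS
#'   amount sits at `ss_min` (all SS) or `ss_max` (all LL) that terminates a
#'   block as a stable boundary preference.
#' @param highlight_duration,feedback_duration,score_display_duration
#'   Per-trial display durations in seconds (choice highlight, feedback cue,
#'   cumulative-score screen); used only in duration bookkeeping.
#' @param ss_lockout Seconds after trial onset before the SS option can be
#'   selected, hence the minimum possible wait on an SS choice.
#' @param overlap_ips If `TRUE` (default) every consecutive alternating
#'   choice triplet yields an indifference point; if `FALSE` windows are
#'   disjoint (a trial contributes to at most one IP).
#' @param demo_repeats Full-delay demonstrations played at the start of each
#'   block (one per reward option by default); counted in session duration.
#'
#' @return An object of class `task_config` (a validated list).
#' @export
#' @examples
#' cfg <- task_config()
#' cfg$delays
task_config <- function(ss_initial = 16,
                        ss_min = 1,
                        ss_max = 30,
                        ll_amount = 32,
                        delays = c(1, 15, 30, 7),
                        step = 1,
                        ips_per_block = 6,
                        boundary_run_length = 6,
                        highlight_duration = 1,
                        feedback_duration = 1,
                        score_display_duration = 1,
                        ss_lockout = 1,
                        overlap_ips = TRUE,
                        demo_repeats = 2) {
  cfg <- structure(
    list(ss_initial = ss_initial, ss_min = ss_min, ss_max = ss_max,
         ll_amount = ll_amount, delays = delays, step = step,
         ips_per_block = ips_per_block,
         boundary_run_length = boundary_run_length,
         highlight_duration = highlight_duration,
         feedback_duration = feedback_duration,
         score_display_duration = score_display_duration,
         ss_lockout = ss_lockout, overlap_ips = isTRUE(overlap_ips),
         demo_repeats = demo_repeats),
    class = "task_config")
  validate_task_config(cfg)
  cfg
}

#' @rdname task_config
#' @param cfg A `task_config` object.
#' @export
validate_task_config <- function(cfg) {
  stopifnot(inherits(cfg, "task_config"))
  with(cfg, {
    if (ss_min < 1) stop("ss_min must be >= 1")
    if (!(ss_min <= ss_initial && ss_initial <= ss_max))
      stop("need ss_min <= ss_initial <= ss_max")
    if (ss_max >= ll_amount) stop("ss_max must be below ll_amount")
    if (length(delays) > 0 && any(delays <= 0)) stop("delays must all be > 0")
    if (step < 1) stop("step must be >= 1")
    if (ips_per_block < 1 || boundary_run_length < 1)
      stop("ips_per_block and boundary_run_length must be >= 1")
    if (ss_lockout < 0) stop("ss_lockout must be >= 0")
  })
  invisible(cfg)
}
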