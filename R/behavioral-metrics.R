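#' Aggregate a block's indifference points
#'
#' Blocks terminating with the full set of indifference points return their
#' arithmetic mean. Blocks terminating via a boundary run carry the boundary
#' forward: a run at the staircase ceiling is scored as `mean_ip = ss_max`
#' (which normalizes to 1), a run at the floor as a sentinel that normalizes
#' to 0, matching the task's stated extremes of a discounting factor of 1
#' for a consistent LL chooser and 0 for a consistent SS chooser.
#'
#' @param block A `block_result` from [run_block()].
#' @param cfg A [task_config()].
#' @return A list: `mean_ip` (candies, `NA` for a floor run) and
#'   `floor_run` (logical; `TRUE` forces a normalized IP of 0).
#' @export
aggregate_block_ips <- function(block, cfg = task_config()) {
  if (block$termination_reason == "continue")
    stop("block did not terminate; cannot aggregate IPs")
  if (block$termination_reason == "six_ips")
    return(list(mean_ip = mean(block$ips), floor_run = FALSE))
  # boundary_run: inspect which boundary the run sat at
  tr <- block$trials
  last_ss <- tr$ss_amount[nrow(tr)]
  if (last_ss == cfg$ss_max)
    list(mean_ip = cfg$ss_max, floor_run = FALSE)
  else
    list(mean_ip = NA_real_, floor_run = TRUE)
}

#' Session-wide normalizer for indifference points
#'
#' The maximum SS amount offered anywhere in the session's blocks; dividing
#' every block's mean IP by this single value keeps the four curve points on
#' one scale.
#'
#' @param session A `session_result` from [run_session()].
#' @return Maximum offered SS amount (candies).
#' @export
session_ss_max <- function(session) {
  max(session$trials$ss_amount)
}

#' Normalize block mean IPs
#'
#' @param mean_ips Numeric vector of block mean IPs (candies); `NA` where a
#'   block ended in a floor boundary run.
#' @param floor_runs Logical vector marking floor-terminated blocks (scored 0).
#' @param ss_max_reached The session-wide normalizer from [session_ss_max()].
#' @return Normalized IPs clamped to `[0, 1]`.
#' @export
normalize_ips <- function(mean_ips, floor_runs, ss_max_reached) {
  if (ss_max_reached <= 0) stop("ss_max_reached must be positive")
  out <- mean_ips / ss_max_reached
  out[floor_runs] <- 0
  pmin(pmax(out, 0), 1)
}

#' Discounting factor as area under the normalized IP curve
#'
#' The discounting factor (DF) is the trapezoidal area under the curve
#' connecting the normalized indifference points across delays, divided by
#' the delay span so that a constant curve maps to its constant value:
#' DF = 1 for a fully patient responder, 0 for a fully impulsive one. Points
#' are sorted by delay before integration regardless of presentation order.
#'
#' @param delays Delays in seconds (>= 2 distinct values).
#' @param normalized_ips Normalized IPs in `[0, 1]`, one per delay.
#' @return The DF, a dimensionless value in `[0, 1]`.
#' @export
#' @examples
#' compute_df(c(1, 7, 15, 30), c(1, 0.5, 0.5, 0.5))
compute_df <- function(delays, normalized_ips) {
  if (length(delays) < 2) stop("need at least two curve points")
  if (length(delays) != length(normalized_ips))
    stop("delays and normalized_ips must have equal length")
  o <- order(delays)
  x <- delays[o]
  y <- normalized_ips[o]
  if (any(diff(x) <= 0)) stop("delays must be distinct")
  area <- sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  area / (x[length(x)] - x[1])
}

#' Discounting curve for one session
#'
#' Runs the whole behavioral measurement chain for a session: per-block IP
#' aggregation with boundary handling, session-wide normalization, and the
#' AUC discounting factor.
#'
#' @param session A `session_result`.
#' @param cfg A [task_config()].
#' @param participant_id Optional identifier carried into the output.
#' @return A list of class `discount_curve`: `participant_id`, `points`
#'   (data.frame with `delay`, `mean_ip`, `normalized_ip`),
#'   `ss_max_reached`, `df`, `duration_s`, `points_total`.
#' @export
discount_curve <- function(session, cfg = task_config(),
                           participant_id = NA_character_) {
  aggs <- lapply(session$blocks, aggregate_block_ips, cfg = cfg)
  mean_ips <- vapply(aggs, `[[`, numeric(1), "mean_ip")
  floor_runs <- vapply(aggs, `[[`, logical(1), "floor_run")
  ss_max_reached <- session_ss_max(session)
  norm <- normalize_ips(mean_ips, floor_runs, ss_max_reached)
  delays <- vapply(session$blocks, `[[`, numeric(1), "delay")
  o <- order(delays)
  pts <- data.frame(delay = delays[o], mean_ip = mean_ips[o],
                    normalized_ip = norm[o])
  structure(list(participant_id = participant_id, points = pts,
                 ss_max_reached = ss_max_reached,
                 df = compute_df(pts$delay, pts$normalized_ip),
                 duration_s = session$total_duration,
                 points_total = session$points),
            class = "discount_curve")
}

#' Cohort behavioral summary
#'
#' Descriptive statistics of the discounting factor across a cohort plus the
#' Spearman correlation between DF and session duration (patient responders
#' wait longer, so the correlation is expected positive). The correlation
#' uses average ranks for ties, an exact p-value for n <= 10 and the normal
#' approximation otherwise.
#'
#' @param curves A list of `discount_curve` objects.
#' @return A list: `n`, `mean_df`, `sd_df`, `skewness_df` (type-2 sample
#'   skewness), `mean_duration_s`, `sd_duration_s`, `spearman_rho`,
#'   `spearman_p` (`NA` with a warning when either vector is constant), and
#'   `table` (per-participant data.frame).
#' @export
behavioral_summary <- function(curves) {
  df <- vapply(curves, `[[`, numeric(1), "df")
  dur <- vapply(curves, `[[`, numeric(1), "duration_s")
  ids <- vapply(curves, function(x) as.character(x$participant_id), character(1))
  tab <- data.frame(participant_id = ids, df = df, duration_s = dur)
  rho <- p <- NA_real_
  if (length(df) >= 3 && stats::sd(df) > 0 && stats::sd(dur) > 0) {
    ct <- suppressWarnings(
      stats::cor.test(df, dur, method = "spearman",
                      exact = length(df) <= 10))
    rho <- unname(ct$estimate)
    p <- ct$p.value
  } else if (length(df) >= 3) {
    warning("constant DF or duration vector: Spearman correlation undefined")
  }
  list(n = length(df), mean_df = mean(df), sd_df = stats::sd(df),
       skewness_df = if (length(df) >= 3) e1071::skewness(df, type = 2) else NA_real_,
       mean_duration_s = mean(dur), sd_duration_s = stats::sd(dur),
       spearman_rho = rho, spearman_p = p, table = tab)
}

#' Write / read a behavioral trial log
#'
#' Tab-separated trial log, one row per trial, UTF-8, dot decimal separator:
#' columns `participant_id`, `block_index`, `delay_s`, `trial_index`,
#' `ss_amount`, `choice`, `wait_elapsed_s`, `trial_duration_s`,
#' `cumulative_points`.
#'
#' @param session A `session_result`.
#' @param participant_id Identifier written into every row.
#' @param path Output TSV path.
#' @return `path`, invisibly (writer); the trial data.frame (reader).
#' @export
write_behavior_tsv <- function(session, participant_id, path) {
  tr <- session$trials
  out <- data.frame(participant_id = participant_id,
                    block_index = tr$block_index, delay_s = tr$delay,
                    trial_index = tr$trial_index, ss_amount = tr$ss_amount,
                    choice = tr$choice, wait_elapsed_s = tr$wait_elapsed,
                    trial_duration_s = tr$trial_duration,
                    cumulative_points = tr$cumulative_points)
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_behavior_tsv
#' @export
read_behavior_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
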