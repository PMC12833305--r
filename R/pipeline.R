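#' Validate a pipeline configuration file
#'
#' Reads a YAML run configuration, rejects unknown keys, applies defaults
#' for everything unspecified, and checks every sub-configuration's
#' invariants. Top-level keys: `seed`, `output_dir`, `n_agents`, `task`
#' (fields of [task_config()]), `eeg` (fields of [eeg_gen_config()]),
#' `preprocessing` (`low`, `high`, `resample_to`), `spectral` (`freqs_max`,
#' `alpha_band`, `theta_band`, `delta_band`, `theta_window`,
#' `delta_window`, `baseline_window`).
#'
#' @param path Path to a YAML file.
#' @return A validated run configuration (list of class `run_config`).
#' @export
validate_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known_top <- c("seed", "output_dir", "n_agents", "task", "eeg",
                 "preprocessing", "spectral")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  check_sub <- function(given, builder, name) {
    if (is.null(given)) given <- list()
    allowed <- names(formals(builder))
    bad <- setdiff(names(given), allowed)
    if (length(bad) > 0)
      stop("unknown ", name, " key(s): ", paste(bad, collapse = ", "))
    do.call(builder, given)
  }
  cfg <- list(
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
    output_dir = if (is.null(raw$output_dir)) "waitworth_out" else raw$output_dir,
    n_agents = if (is.null(raw$n_agents)) 6L else as.integer(raw$n_agents),
    task = check_sub(raw$task, task_config, "task"),
    eeg = check_sub(raw$eeg, eeg_gen_config, "eeg"),
    preprocessing = utils::modifyList(
      list(low = 0.1, high = 40, resample_to = 250),
      if (is.null(raw$preprocessing)) list() else raw$preprocessing),
    spectral = utils::modifyList(
      list(freqs_max = 35, alpha_band = c(8, 12), theta_band = c(4, 7),
           delta_band = c(1, 3), theta_window = c(0.2, 0.4),
           delta_window = c(0.1, 0.6), baseline_window = c(-0.3, -0.1)),
      if (is.null(raw$spectral)) list() else raw$spectral))
  bad_pp <- setdiff(names(cfg$preprocessing), c("low", "high", "resample_to"))
  if (length(bad_pp) > 0)
    stop("unknown preprocessing key(s): ", paste(bad_pp, collapse = ", "))
  if (cfg$n_agents < 1) stop("n_agents must be >= 1")
  if (length(cfg$task$delays) == 0)
    stop("task delays must contain at least one block delay")
  structure(cfg, class = "run_config")
}

default_run_config <- function(n_agents = 6L, seed = 1L,
                               output_dir = tempfile("waitworth_out")) {
  structure(list(seed = as.integer(seed), output_dir = output_dir,
                 n_agents = as.integer(n_agents), task = task_config(),
                 eeg = eeg_gen_config(),
                 preprocessing = list(low = 0.1, high = 40, resample_to = 250),
                 spectral = list(freqs_max = 35, alpha_band = c(8, 12),
                                 theta_band = c(4, 7), delta_band = c(1, 3),
                                 theta_window = c(0.2, 0.4),
                                 delta_window = c(0.1, 0.6),
                                 baseline_window = c(-0.3, -0.1))),
            class = "run_config")
}

measure_feedback_power <- function(es, sp) {
  clusters <- unique(c("Fz", "FC1", "FC2", "Cz", "CPz"))
  es <- subset_epochs(es, channels = clusters)
  tfr <- morlet_tfr(es, freqs = seq_len(sp$freqs_max))
  tfr <- baseline_correct(tfr, window = sp$baseline_window)
  c(theta = extract_band_window_power(tfr, sp$theta_band,
                                      c("Fz", "FC1", "FC2"),
                                      sp$theta_window),
    delta = extract_band_window_power(tfr, sp$delta_band, c("Cz", "CPz"),
                                      sp$delta_window))
}

#' Run the full simulate-preprocess-measure-analyze pipeline
#'
#' Simulates the behavioral cohort, synthesizes and writes each
#' participant's EEG (EDF + events sidecar), preprocesses, epochs and
#' rejects, measures feedback theta/delta and anticipatory alpha PSD,
#' fits the GLMs and the mixed model, and writes every artifact with a
#' content-hash manifest. Deterministic for a fixed seed.
#'
#' @param config A `run_config` from [validate_config()] or
#'   `default_run_config()`.
#' @return Invisibly, a list with the `manifest` data.frame (file, md5),
#'   the output directory, and the `stats` report.
#' @export
run_pipeline <- function(config = default_run_config()) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  eeg_dir <- file.path(out_dir, "eeg")
  dir.create(eeg_dir, showWarnings = FALSE)
  cohort <- simulate_cohort(config$n_agents, config$task, seed = config$seed)
  ids <- cohort$params$participant_id
  utils::write.table(cohort$params, file.path(out_dir, "cohort_manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (i in seq_along(ids))
    write_behavior_tsv(cohort$sessions[[i]], ids[i],
                       file.path(out_dir, sprintf("%s_behavior.tsv", ids[i])))
  curves <- cohort$curves
  summ <- behavioral_summary(curves)
  per_delay <- do.call(rbind, lapply(curves, function(cu) {
    stats::setNames(as.data.frame(t(cu$points$normalized_ip)),
                    paste0("nip_", cu$points$delay, "s"))
  }))
  behav <- cbind(summ$table,
                 ss_max_reached = vapply(curves, `[[`, numeric(1),
                                         "ss_max_reached"),
                 per_delay)
  utils::write.csv(behav, file.path(out_dir, "behavior_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(summ[c("n", "mean_df", "sd_df", "skewness_df",
                              "mean_duration_s", "sd_duration_s",
                              "spearman_rho", "spearman_p")],
                       file.path(out_dir, "cohort_stats.json"),
                       auto_unbox = TRUE, digits = NA)

  pp <- config$preprocessing
  band_rows <- list(); reject_rows <- list(); count_rows <- list()
  for (i in seq_along(ids)) {
    df_i <- curves[[i]]$df
    rec <- synthesize_session(cohort$sessions[[i]]$trials, df_i, config$eeg,
                              config$task, seed = cohort$params$seed[i] + 1L)
    write_recording(rec, eeg_dir, ids[i])
    rec <- preprocess_recording(rec, low = pp$low, high = pp$high,
                                target = pp$resample_to)
    fb_raw <- extract_feedback_epochs(rec)
    fb <- reject_epochs(fb_raw)
    dl_raw <- segment_delay_epochs(rec)
    dl <- reject_epochs(dl_raw)
    reject_rows[[i]] <- data.frame(
      participant_id = ids[i],
      feedback_total = n_epochs(fb_raw), feedback_rejected = fb$rejected_count,
      delay_total = n_epochs(dl_raw), delay_rejected = dl$rejected_count)
    count_rows[[i]] <- data.frame(participant_id = ids[i],
                                  n_feedback = n_epochs(fb),
                                  n_delay = n_epochs(dl))
    if (n_epochs(fb) > 0) {
      pw <- measure_feedback_power(fb, config$spectral)
      band_rows[[length(band_rows) + 1]] <- data.frame(
        participant_id = ids[i], measure = c("theta_fb", "delta_fb"),
        delay_level = NA_real_, value = unname(pw), df = df_i)
    }
    if (n_epochs(dl) > 0) {
      lv <- compute_alpha_psd(dl, band = config$spectral$alpha_band,
                              by_level = TRUE)
      band_rows[[length(band_rows) + 1]] <- data.frame(
        participant_id = ids[i], measure = "alpha_psd",
        delay_level = lv$delay_level, value = lv$alpha_psd, df = df_i)
    }
  }
  band <- do.call(rbind, band_rows)
  utils::write.csv(band, file.path(out_dir, "band_power.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, reject_rows),
                   file.path(out_dir, "rejection_report.csv"),
                   row.names = FALSE)
  inclusion <- apply_inclusion_rules(do.call(rbind, count_rows))
  utils::write.csv(inclusion, file.path(out_dir, "inclusion.csv"),
                   row.names = FALSE)

  stats_report <- analyze_band_power(band, inclusion)
  jsonlite::write_json(report_as_plain(stats_report),
                       file.path(out_dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(stats_report_markdown(stats_report),
             file.path(out_dir, "stats_report.md"))

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  manifest <- data.frame(file = sub(paste0("^", out_dir, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(list(manifest = manifest, output_dir = out_dir,
                 stats = stats_report))
}

#' Analyze a band-power table
#'
#' The inferential layer on a long band-power table: per-measure ±3 SD
#' outlier trimming, Gaussian GLMs of feedback theta and delta power on
#' DF (participants with enough feedback epochs), and the mixed model of
#' alpha PSD on delay level and DF, with FDR post-hocs / simple slopes
#' when the corresponding omnibus test is significant.
#'
#' @param band Data.frame with columns `participant_id`, `measure`
#'   (`"theta_fb"`, `"delta_fb"`, `"alpha_psd"`), `delay_level`, `value`,
#'   `df`.
#' @param inclusion Optional inclusion table from [apply_inclusion_rules()].
#' @param alpha Significance level gating the follow-up tests.
#' @return A list with elements `theta`, `delta` (each a `model_result` or
#'   `NULL`), `alpha` (`model_result`), `posthoc`, `simple_slopes`,
#'   `outliers_removed`.
#' @export
analyze_band_power <- function(band, inclusion = NULL, alpha = 0.05) {
  out <- list(outliers_removed = list())
  keep_ids <- function(which_col) {
    if (is.null(inclusion)) unique(band$participant_id)
    else inclusion$participant_id[inclusion[[which_col]]]
  }
  for (m in c("theta_fb", "delta_fb")) {
    d <- band[band$measure == m &
                band$participant_id %in% keep_ids("include_feedback"), ]
    key <- sub("_fb", "", m)
    if (nrow(d) >= 3) {
      tr <- remove_outliers(d$value)
      out$outliers_removed[[m]] <- length(tr$removed)
      dd <- data.frame(value = d$value[tr$kept], df = d$df[tr$kept])
      out[[key]] <- fit_power_glm(dd, "value")
    } else out[[key]] <- NULL
  }
  a <- band[band$measure == "alpha_psd" &
              band$participant_id %in% keep_ids("include_alpha"), ]
  # the interaction model spends 2 + 2 x levels fixed-effect df
  if (length(unique(a$participant_id)) >= 2 &&
      nrow(a) > 2 * length(unique(a$delay_level)) + 2) {
    tr <- remove_outliers(a$value)
    out$outliers_removed[["alpha_psd"]] <- length(tr$removed)
    a <- a[tr$kept, ]
    tab <- data.frame(alpha_psd = a$value, delay_level = a$delay_level,
                      df = a$df, participant = a$participant_id)
    out$alpha <- fit_alpha_lmm(tab)
    terms <- out$alpha$terms
    if (terms$p[terms$name == "delay_level"] < alpha)
      out$posthoc <- posthoc_tests(out$alpha)
    if (terms$p[terms$name == "delay_level:df"] < alpha)
      out$simple_slopes <- simple_slopes(out$alpha)
  }
  out
}

report_as_plain <- function(report) {
  lapply(report, function(x) {
    if (inherits(x, "model_result"))
      list(terms = x$terms, coefficients = x$coefficients, n_obs = x$n_obs,
           n_participants = x$n_participants)
    else x
  })
}

stats_report_markdown <- function(report) {
  lines <- c("# Band-power statistics", "")
  fmt <- function(name, mr) {
    if (is.null(mr)) return(sprintf("- %s: not fitted", name))
    t <- mr$terms
    paste0(sprintf("- %s: %s F(%g, %.1f) = %.3f, p = %.4g", name, t$name,
                   t$df_num, t$df_den, t$F, t$p), collapse = "\n")
  }
  c(lines, fmt("theta ~ DF (GLM)", report$theta),
    fmt("delta ~ DF (GLM)", report$delta),
    fmt("alpha PSD ~ delay * DF (LMM)", report$alpha))
}
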