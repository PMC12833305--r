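test_that("outlier trimming removes beyond 3 SD with a strict boundary", {
  set.seed(14)
  x <- c(rnorm(50), 8)
  out <- remove_outliers(x)
  expect_equal(out$removed, 51)
  expect_equal(length(out$values), 50)
  same <- remove_outliers(rep(2, 10))
  expect_equal(length(same$removed), 0)
  # construct a vector whose extreme value sits exactly at 3 SD
  base <- rep(c(-1, 1), 20)
  f <- function(t) (t - mean(c(base, t))) - 3 * sd(c(base, t))
  t_star <- uniroot(f, c(3, 50))$root
  at_boundary <- c(base, t_star)
  expect_equal(abs(t_star - mean(at_boundary)), 3 * sd(at_boundary),
               tolerance = 1e-8)
  expect_equal(length(remove_outliers(at_boundary)$removed), 0)
  expect_error(remove_outliers(c(1, 2)), "3 values")
})

test_that("the Gaussian GLM equals an OLS oracle and reports (1, n-2) df", {
  set.seed(15)
  d <- data.frame(df = runif(51), stringsAsFactors = FALSE)
  d$value <- 1.3 - 0.8 * d$df + rnorm(51, sd = 0.4)
  m <- fit_power_glm(d, "value")
  expect_equal(m$terms$df_num, 1)
  expect_equal(m$terms$df_den, 49)
  # normal-equations oracle
  X <- cbind(1, d$df)
  beta <- solve(t(X) %*% X, t(X) %*% d$value)
  res <- d$value - X %*% beta
  sse <- sum(res^2)
  sst <- sum((d$value - mean(d$value))^2)
  F_oracle <- (sst - sse) / (sse / 49)
  expect_equal(m$terms$F, F_oracle, tolerance = 1e-8)
  expect_equal(m$coefficients$estimate, as.numeric(beta), tolerance = 1e-8)
  expect_equal(m$terms$p, pf(F_oracle, 1, 49, lower.tail = FALSE),
               tolerance = 1e-8)
  # exact linear relation: slope recovered, p essentially zero
  d2 <- data.frame(df = seq(0, 1, length.out = 20))
  d2$value <- 2 * d2$df
  m2 <- fit_power_glm(d2, "value")
  expect_equal(m2$coefficients$estimate[2], 2, tolerance = 1e-10)
  expect_lt(m2$terms$p, 1e-12)
})

sim_alpha_table <- function(n = 52, b_df = -0.6, b_delay = c(0, 0, 0),
                            sd_id = 0.2, sd_eps = 0.1, seed = 1) {
  set.seed(seed)
  df <- pmin(1, pmax(0, rbeta(n, 5, 1.5)))
  id_eff <- rnorm(n, sd = sd_id)
  do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(participant = sprintf("p%02d", i), df = df[i],
               delay_level = c(7, 15, 30),
               alpha_psd = 1 + b_delay + b_df * df[i] + id_eff[i] +
                 rnorm(3, sd = sd_eps))
  }))
}

test_that("the mixed model recovers a negative DF effect on alpha PSD", {
  tab <- sim_alpha_table(seed = 2)
  m <- fit_alpha_lmm(tab)
  expect_equal(m$n_participants, 52)
  t_df <- m$terms[m$terms$name == "df", ]
  expect_lt(t_df$p, 0.01)
  expect_lt(m$coefficients$estimate[m$coefficients$name == "df"], 0)
  expect_equal(t_df$df_num, 1)
  # delay had no simulated effect: interaction F small most of the time;
  # at minimum the model reports valid df and p ranges
  expect_true(all(m$terms$p >= 0 & m$terms$p <= 1))
  expect_true(all(m$terms$df_den > 0))
  expect_error(fit_alpha_lmm(tab[tab$participant == "p01", ]),
               "2 participants")
})

test_that("with zero between-participant variance the LMM matches pooled OLS", {
  tab <- sim_alpha_table(sd_id = 0, sd_eps = 0.3, seed = 3)
  m <- fit_alpha_lmm(tab)
  tab$delay_level <- factor(tab$delay_level)
  ols <- lm(alpha_psd ~ delay_level * df, data = tab,
            contrasts = list(delay_level = contr.sum))
  expect_equal(m$coefficients$estimate, unname(coef(ols)), tolerance = 0.02)
})

test_that("post-hoc comparisons are BH-adjusted and slopes are homogeneous without interaction", {
  tab <- sim_alpha_table(b_delay = c(0, 0.5, 1.2), seed = 4)
  m <- fit_alpha_lmm(tab)
  ph <- posthoc_tests(m)
  expect_equal(nrow(ph), 3)
  expect_equal(ph$p_fdr, p.adjust(ph$p_raw, method = "BH"))
  expect_true(all(ph$p_fdr >= ph$p_raw - 1e-15))
  expect_true(all(ph$p_fdr <= 1))
  ss <- simple_slopes(m)
  expect_equal(nrow(ss), 3)
  # no simulated interaction: per-level slopes agree within joint CIs
  expect_lt(max(ss$slope) - min(ss$slope),
            4 * max(ss$se) + 1e-12)
  expect_lt(max(abs(ss$slope - (-0.6))), 3 * max(ss$se))
})

test_that("analyze_band_power wires trimming, GLMs and the LMM together", {
  set.seed(17)
  n <- 20
  dfv <- runif(n, 0.3, 1)
  band <- rbind(
    data.frame(participant_id = sprintf("p%02d", 1:n), measure = "theta_fb",
               delay_level = NA, value = rnorm(n), df = dfv),
    data.frame(participant_id = sprintf("p%02d", 1:n), measure = "delta_fb",
               delay_level = NA, value = rnorm(n), df = dfv),
    do.call(rbind, lapply(1:n, function(i)
      data.frame(participant_id = sprintf("p%02d", i), measure = "alpha_psd",
                 delay_level = c(7, 15, 30),
                 value = 1 - 0.5 * dfv[i] + rnorm(3, sd = 0.05),
                 df = dfv[i]))))
  report <- analyze_band_power(band)
  expect_s3_class(report$theta, "model_result")
  expect_s3_class(report$delta, "model_result")
  expect_s3_class(report$alpha, "model_result")
  expect_lt(report$alpha$coefficients$estimate[
    report$alpha$coefficients$name == "df"], 0)
  # inclusion filtering drops excluded participants from the GLMs
  incl <- apply_inclusion_rules(data.frame(
    participant_id = sprintf("p%02d", 1:n),
    n_feedback = c(rep(5, 5), rep(20, n - 5)), n_delay = 10))
  report2 <- analyze_band_power(band, incl)
  expect_equal(report2$theta$n_obs, n - 5)
})
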