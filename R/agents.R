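#' Parameters of a simulated discounting agent
#'
#' A synthetic stand-in for a human participant: the agent discounts the
#' delayed reward with a standard temporal-discounting model and chooses
#' with softmax (logistic) noise; while waiting for the delayed option it
#' may abort impulsively with a memoryless per-second hazard, converting the
#' trial into an early SS choice. Agents are a simulation device for
#' recovery experiments, not a model fitted to human data.
#'
#' @param model `"hyperbolic"` (V = A / (1 + kD)) or `"exponential"`
#'   (V = A exp(-kD)).
#' @param k Discount rate in 1/seconds, >= 0.
#' @param beta Softmax inverse temperature in 1/candies, >= 0 (0 = random
#'   choice; large = value maximizer).
#' @param abort_hazard Per-second probability in `[0, 1]` of aborting an
#'   intended wait.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(model = c("hyperbolic", "exponential"),
                         k = 0.01, beta = 2, abort_hazard = 0) {
  model <- match.arg(model)
  stopifnot(k >= 0, beta >= 0, abort_hazard >= 0, abort_hazard <= 1)
  structure(list(model = model, k = k, beta = beta,
                 abort_hazard = abort_hazard),
            class = "agent_params")
}

#' Subjective value of a delayed amount
#'
#' @param amount Reward amount in candies, >= 0.
#' @param delay Delay in seconds, >= 0.
#' @param params An [agent_params()].
#' @return Discounted value in candies; equals `amount` iff `k * delay = 0`.
#' @export
#' @examples
#' subjective_value(32, 30, agent_params(k = 0.1))  # 32 / (1 + 3) = 8
subjective_value <- function(amount, delay, params) {
  if (any(amount < 0) || any(delay < 0))
    stop("amount and delay must be non-negative")
  switch(params$model,
         hyperbolic = amount / (1 + params$k * delay),
         exponential = amount * exp(-params$k * delay))
}

#' Probability of choosing the delayed option
#'
#' Softmax over the discounted values: `plogis(beta * (V_LL - V_SS))`. The
#' immediate option is valued at zero delay.
#'
#' @param ss_amount,ll_amount Amounts in candies.
#' @param delay Delay of the larger-later option, seconds.
#' @param params An [agent_params()].
#' @return P(choose LL) in `[0, 1]`; 0.5 when values tie or `beta = 0`.
#' @export
choice_probability <- function(ss_amount, ll_amount, delay, params) {
  v_ll <- subjective_value(ll_amount, delay, params)
  v_ss <- subjective_value(ss_amount, 0, params)
  stats::plogis(params$beta * (v_ll - v_ss))
}

#' One trial decision with waiting and impulsive aborts
#'
#' Draws the intended choice from [choice_probability()]. An intended SS
#' choice is made as soon as the option unlocks. An intended LL choice
#' requires waiting out the delay; during each whole second of the wait the
#' agent aborts with probability `abort_hazard`, in which case the choice
#' becomes SS at the abort time (never earlier than the lockout).
#'
#' @param ctx Trial context as passed by [run_block()].
#' @param params An [agent_params()].
#' @return `list(choice =, wait =)` suitable for the task engine.
#' @export
decide_trial <- function(ctx, params) {
  lockout <- ctx$config$ss_lockout
  p_ll <- choice_probability(ctx$ss_amount, ctx$ll_amount, ctx$delay, params)
  intended_ll <- stats::runif(1) < p_ll
  if (!intended_ll)
    return(list(choice = "SS", wait = lockout))
  if (params$abort_hazard > 0) {
    n_sec <- ceiling(ctx$delay)
    for (s in seq_len(n_sec)) {
      if (stats::runif(1) < params$abort_hazard) {
        abort_at <- min(max(s, lockout), ctx$delay)
        return(list(choice = "SS", wait = abort_at))
      }
    }
  }
  list(choice = "LL", wait = ctx$delay)
}

#' Wrap agent parameters as a task chooser
#'
#' @param params An [agent_params()].
#' @return A chooser function for [run_block()] / [run_session()]; it uses
#'   the session RNG stream, so seed with `set.seed()` for reproducibility.
#' @export
agent_chooser <- function(params) {
  force(params)
  function(ctx) decide_trial(ctx, params)
}

#' Default cohort parameter sampler
#'
#' Draws discount rates from a log-normal concentrated at small k
#' (`meanlog = log(0.01)`, `sdlog = 1`), so most agents are patient and the
#' cohort's discounting-factor distribution is negatively skewed with a
#' ceiling near 1, the regime the task instructions push human cohorts
#' into. The abort hazard scales with k (`min(0.05, k/2)`) so that more
#' impulsive agents also abort waits more often; softmax beta is fixed at
#' 2 per candy. The hazard scaling is calibrated once so the default
#' cohort's mean discounting factor sits near 0.82; documented as a
#' calibration of the simulator, not ground truth about people.
#'
#' @param n Number of agents.
#' @return A data.frame with columns `model`, `k`, `beta`, `abort_hazard`.
#' @export
sample_agent_params <- function(n) {
  k <- stats::rlnorm(n, meanlog = log(0.01), sdlog = 1)
  data.frame(model = "hyperbolic", k = k, beta = 2,
             abort_hazard = pmin(0.05, 0.5 * k))
}

#' Simulate a cohort of agents through the task
#'
#' Runs `n` independently seeded agents through [run_session()] and computes
#' each discounting curve.
#'
#' @param n Number of agents (>= 1).
#' @param cfg A [task_config()].
#' @param seed Integer seed controlling both parameter draws and choices.
#' @param param_sampler A function `function(n)` returning a parameter
#'   data.frame like [sample_agent_params()].
#' @return A list of class `cohort`: `params` (manifest data.frame with
#'   `participant_id` and true parameters), `sessions` (list of
#'   `session_result`), `curves` (list of `discount_curve`).
#' @export
simulate_cohort <- function(n, cfg = task_config(), seed = 1,
                            param_sampler = sample_agent_params) {
  stopifnot(n >= 1)
  set.seed(seed)
  pars <- param_sampler(n)
  pars$participant_id <- sprintf("sub-%03d", seq_len(n))
  pars$seed <- sample.int(.Machine$integer.max %/% 2, n)
  sessions <- vector("list", n)
  curves <- vector("list", n)
  for (i in seq_len(n)) {
    ap <- agent_params(model = pars$model[i], k = pars$k[i],
                       beta = pars$beta[i],
                       abort_hazard = pars$abort_hazard[i])
    set.seed(pars$seed[i])
    sessions[[i]] <- run_session(agent_chooser(ap), cfg)
    curves[[i]] <- discount_curve(sessions[[i]], cfg,
                                  participant_id = pars$participant_id[i])
  }
  structure(list(params = pars[, c("participant_id", "model", "k", "beta",
                                   "abort_hazard", "seed")],
                 sessions = sessions, curves = curves),
            class = "cohort")
}
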