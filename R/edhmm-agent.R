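#' Explicit-duration HMM agent for reversal learning
#'
#' Creates the belief state of an agent that tracks (i) a joint probability
#' grid over the latent task configuration (non-reversal `NR` vs reversal `R`)
#' and the remaining dwell time of that configuration, and (ii) Beta beliefs
#' over the reward probabilities of the two options. The dwell-time dynamics
#' are a deterministic countdown: the state is kept while the counter exceeds
#' 1 and flips with certainty when the counter is exhausted, at which point a
#' fresh counter value is drawn from the duration prior. With a geometric
#' duration prior the agent reduces exactly to a constant-rate two-state HMM
#' filter.
#'
#' Option `"A"` is the better option in state `NR` (the same convention as
#' [correct_choice()]); in state `R` the outcome of a choice is generated by
#' the other option's reward probability.
#'
#' @param prior A [duration_prior()] over between-reversal intervals.
#' @param a0_A,b0_A,a0_B,b0_B Initial Beta pseudo-counts of the reward beliefs
#'   for options A and B. The simulation default `(8, 2)` / `(2, 8)` encodes
#'   loose initial knowledge that A pays off with ~0.8 in state `NR`.
#' @param theta0 Initial probability assigned to state `NR`; `0.5` means the
#'   agent does not know the starting configuration.
#' @return An object of class `edhmm_agent` with fields `prior`, `joint`
#'   (2 x `d_max` grid, rows `NR`/`R`, holding the prior-predictive beliefs
#'   for the upcoming trial), `a`, `b` (named vectors over options).
#' @export
#' @examples
#' ag <- edhmm_agent(duration_prior(mu = 20, sigma = 20))
#' theta_tilde(ag)  # 0.5: initial configuration unknown
edhmm_agent <- function(prior, a0_A = 8, b0_A = 2, a0_B = 2, b0_B = 8,
                        theta0 = 0.5) {
  stopifnot(inherits(prior, "duration_prior"))
  ab <- c(a0_A, b0_A, a0_B, b0_B)
  if (any(!is.finite(ab)) || any(ab <= 0)) {
    stop("Beta parameters must be positive and finite")
  }
  if (theta0 < 0 || theta0 > 1) stop("`theta0` must lie in [0, 1]")
  joint <- rbind(NR = theta0 * prior$pmf, R = (1 - theta0) * prior$pmf)
  structure(
    list(prior = prior, joint = joint,
         a = c(A = a0_A, B = a0_B),
         b = c(A = b0_A, B = b0_B)),
    class = "edhmm_agent"
  )
}

#' @export
print.edhmm_agent <- function(x, ...) {
  cat(sprintf(
    "ED-HMM agent: theta~ = %.3f, E[rho_A] = %.3f, E[rho_B] = %.3f (d_max = %d)\n",
    theta_tilde(x), x$a["A"] / (x$a["A"] + x$b["A"]),
    x$a["B"] / (x$a["B"] + x$b["B"]), x$prior$d_max))
  invisible(x)
}

#' Marginal probability of the non-reversal state
#'
#' @param agent An `edhmm_agent`.
#' @return Scalar marginal of the `NR` row of the joint grid.
#' @export
theta_tilde <- function(agent) {
  sum(agent$joint[1L, ])
}

other_option <- function(choice) {
  if (choice == "A") "B" else "A"
}

#' Predictive win probability of a choice under each latent state
#'
#' Plug-in (Beta-mean) predictive probability of a win for the chosen option:
#' under state `NR` the chosen option is governed by its own reward belief;
#' under state `R` by the other option's belief (anti-correlated
#' contingencies).
#'
#' @param agent An `edhmm_agent`.
#' @param choice `"A"` or `"B"`.
#' @return Named vector `c(NR = , R = )` of win probabilities.
#' @export
predictive_outcome_likelihood <- function(agent, choice) {
  mu <- agent$a / (agent$a + agent$b)
  c(NR = unname(mu[choice]), R = unname(mu[other_option(choice)]))
}

#' Update state beliefs from an observed outcome
#'
#' Bayes update of the state marginal using the plug-in predictive
#' likelihoods: `theta = theta~ / (theta~ + L (1 - theta~))` with likelihood
#' ratio `L = p(o | R, c) / p(o | NR, c)`. The duration distribution
#' conditional on each state is left unchanged (it carries no additional
#' information about the current outcome); the joint grid is rescaled
#' row-wise to the new state marginals.
#'
#' @param agent An `edhmm_agent` holding prior-predictive beliefs.
#' @param choice Observed choice, `"A"` or `"B"`.
#' @param outcome Observed outcome, `-1` or `+1`.
#' @return The agent with posterior state beliefs.
#' @export
update_state_beliefs <- function(agent, choice, outcome) {
  if (!outcome %in% c(-1, 1)) stop("`outcome` must be -1 or +1")
  p_win <- predictive_outcome_likelihood(agent, choice)
  obar <- (outcome + 1) / 2
  lik <- obar * p_win + (1 - obar) * (1 - p_win)
  tt <- theta_tilde(agent)
  denom <- tt * lik[["NR"]] + (1 - tt) * lik[["R"]]
  if (denom <= 0) stop("outcome has zero predictive probability under both states")
  theta <- tt * lik[["NR"]] / denom
  joint <- agent$joint
  if (tt > 0) joint[1L, ] <- joint[1L, ] * (theta / tt)
  if (tt < 1) joint[2L, ] <- joint[2L, ] * ((1 - theta) / (1 - tt))
  agent$joint <- joint
  agent
}

#' Update reward beliefs from an observed outcome
#'
#' State-weighted Beta-Bernoulli update: with `obar = (o + 1) / 2` and
#' `theta` the posterior probability of state `NR`, the chosen option's
#' pseudo-counts absorb `theta` of the observation and the other option's
#' pseudo-counts absorb the remaining `1 - theta` (under state `R` the
#' outcome is informative about the other option's reward rate). Exactly one
#' unit of pseudo-count mass is added per trial.
#'
#' @inheritParams update_state_beliefs
#' @return The agent with updated Beta parameters.
#' @export
update_reward_beliefs <- function(agent, choice, outcome) {
  if (!outcome %in% c(-1, 1)) stop("`outcome` must be -1 or +1")
  theta <- theta_tilde(agent)
  obar <- (outcome + 1) / 2
  oth <- other_option(choice)
  agent$a[choice] <- agent$a[choice] + theta * obar
  agent$b[choice] <- agent$b[choice] + theta * (1 - obar)
  agent$a[oth] <- agent$a[oth] + (1 - theta) * obar
  agent$b[oth] <- agent$b[oth] + (1 - theta) * (1 - obar)
  agent
}

#' Propagate beliefs to the next trial
#'
#' Sum-product step through the semi-Markov transition kernel: counters above
#' 1 count down with the state kept; exhausted counters (value 1) flip the
#' state and draw a fresh dwell time from the duration prior. The resulting
#' grid is renormalized to absorb floating-point drift on the truncated
#' support.
#'
#' @param agent An `edhmm_agent` holding posterior beliefs for the current
#'   trial.
#' @return The agent with prior-predictive beliefs for the next trial.
#' @export
propagate_beliefs <- function(agent) {
  agent$joint <- propagate_joint(agent$joint, agent$prior$pmf)
  agent
}

#' Full belief update for one trial
#'
#' Observe (choice, outcome), update state beliefs, update reward beliefs,
#' and propagate to the next trial, in that order.
#'
#' @inheritParams update_state_beliefs
#' @return The agent, ready for the next trial's decision.
#' @export
agent_step <- function(agent, choice, outcome) {
  agent <- update_state_beliefs(agent, choice, outcome)
  agent <- update_reward_beliefs(agent, choice, outcome)
  propagate_beliefs(agent)
}

#' Value-form view of the reward beliefs
#'
#' Re-expresses the Beta reward beliefs as choice values
#' `V = 2 a / (a + b) - 1` together with the trial's effective learning rates
#' and fictive-update coupling, the delta-rule form of the state-weighted
#' Beta update: the chosen option moves by `alpha_c (o - V_c)` with
#' `alpha_c = theta / nu_c'` (posterior pseudo-count `nu_c' = nu_c + theta`),
#' and the other option by `kappa alpha_o (o - V_o)` with
#' `alpha_o = theta / nu_o'`, `nu_o' = nu_o + 1 - theta` and
#' `kappa = (1 - theta) / theta`. Note the fictive prediction error has the
#' same sign as the factual one: the coupling reflects state uncertainty,
#' not an assumed anti-correlation of payoffs.
#'
#' @param agent An `edhmm_agent` (reward beliefs not yet updated for the
#'   trial).
#' @param theta Posterior probability of state `NR` for the trial.
#' @param choice The trial's choice (determines which option takes the
#'   factual update).
#' @param kappa_max Ceiling applied to `kappa` as `theta` approaches 0; the
#'   coupling is a diagnostic re-parameterization, unbounded at `theta = 0`.
#' @return List with `V` (named values), `alpha` (named learning rates),
#'   `kappa`.
#' @export
to_value_form <- function(agent, theta, choice, kappa_max = 1e12) {
  if (theta < 0 || theta > 1) stop("`theta` must lie in [0, 1]")
  V <- 2 * agent$a / (agent$a + agent$b) - 1
  oth <- other_option(choice)
  nu_post <- agent$a + agent$b
  nu_post[choice] <- nu_post[choice] + theta
  nu_post[oth] <- nu_post[oth] + 1 - theta
  alpha <- theta / nu_post
  kappa <- if (theta == 0) kappa_max else min((1 - theta) / theta, kappa_max)
  list(V = V, alpha = alpha, kappa = kappa)
}

#' Expected choice values under state uncertainty
#'
#' State-marginalized values entering the response model: for the ED-HMM
#' agent `V~_c = theta~ V_c + (1 - theta~) V_other(c)`; for Rescorla-Wagner
#' agents the values are used directly.
#'
#' @param agent An `edhmm_agent` or `rw_agent`.
#' @return Named numeric vector `c(A = , B = )` of expected values in
#'   `[-1, 1]`.
#' @export
expected_choice_values <- function(agent) {
  UseMethod("expected_choice_values")
}

#' @export
expected_choice_values.edhmm_agent <- function(agent) {
  V <- 2 * agent$a / (agent$a + agent$b) - 1
  tt <- theta_tilde(agent)
  c(A = unname(tt * V["A"] + (1 - tt) * V["B"]),
    B = unname(tt * V["B"] + (1 - tt) * V["A"]))
}

#' @export
expected_choice_values.rw_agent <- function(agent) {
  agent$V
}
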