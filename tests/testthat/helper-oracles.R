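# Independent oracles used across the test files.

# Direct 2-state HMM filter with constant transition rate `delta`, written
# without any duration grid: the reference the ED-HMM must reduce to under a
# geometric duration prior.
hmm_filter_theta <- function(choices, outcomes, delta, a0 = c(A = 8, B = 2),
                             b0 = c(A = 2, B = 8), theta0 = 0.5) {
  a <- a0
  b <- b0
  theta_pred <- theta0
  thetas <- numeric(length(choices))
  for (t in seq_along(choices)) {
    ch <- choices[t]
    ot <- other_opt(ch)
    obar <- (outcomes[t] + 1) / 2
    mu <- a / (a + b)
    l_nr <- obar * mu[ch] + (1 - obar) * (1 - mu[ch])
    l_r <- obar * mu[ot] + (1 - obar) * (1 - mu[ot])
    theta <- theta_pred * l_nr / (theta_pred * l_nr + (1 - theta_pred) * l_r)
    a[ch] <- a[ch] + theta * obar
    b[ch] <- b[ch] + theta * (1 - obar)
    a[ot] <- a[ot] + (1 - theta) * obar
    b[ot] <- b[ot] + (1 - theta) * (1 - obar)
    theta_pred <- theta * (1 - delta) + (1 - theta) * delta
    thetas[t] <- theta_pred
  }
  thetas
}

other_opt <- function(choice) if (choice == "A") "B" else "A"

# Monte-Carlo estimate of the forward reversal probability at trials `taus`,
# by direct sampling of interval sequences from the prior.
mc_reversal_probability <- function(prior, taus, n = 1e5) {
  k <- max(taus)  # intervals are >= 1 trial each
  m <- matrix(sample.int(prior$d_max, n * k, replace = TRUE,
                         prob = prior$pmf), n, k)
  cum <- m
  for (j in 2:k) cum[, j] <- cum[, j - 1] + m[, j]
  vapply(taus, function(tau) {
    rev_at_tau <- rowSums(cum == tau - 1) > 0
    n_before <- rowSums(cum <= tau - 2)
    nr_before <- n_before %% 2 == 0
    est <- sum(rev_at_tau & nr_before) / sum(nr_before)
    se <- sqrt(est * (1 - est) / sum(nr_before))
    c(est = est, se = se)
  }, numeric(2))
}

# Build an ED-HMM agent in an arbitrary (random) belief state.
random_agent_state <- function(prior, seed_joint = NULL) {
  ag <- edhmm_agent(prior)
  j <- matrix(stats::runif(2 * prior$d_max), 2)
  ag$joint <- j / sum(j)
  ag$a <- c(A = stats::runif(1, 0.5, 20), B = stats::runif(1, 0.5, 20))
  ag$b <- c(A = stats::runif(1, 0.5, 20), B = stats::runif(1, 0.5, 20))
  ag
}

# Short deterministic behavioral block for likelihood tests.
fixed_block <- function(n = 12, subject = "s1") {
  choices <- rep(c("A", "A", "B"), length.out = n)
  outcomes <- rep(c(1, -1, 1, 1), length.out = n)
  behavioral_dataset(subject, choices, outcomes)
}
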