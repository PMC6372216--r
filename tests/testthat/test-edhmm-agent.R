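prior20 <- duration_prior(mu = 20, sigma = 20, d_max = 200)

test_that("initial beliefs encode the starting knowledge", {
  ag <- edhmm_agent(prior20)
  expect_equal(theta_tilde(ag), 0.5)
  expect_equal(unname(ag$a["A"] / (ag$a["A"] + ag$b["A"])), 0.8)
  expect_equal(unname(ag$a["B"] / (ag$a["B"] + ag$b["B"])), 0.2)
  expect_equal(sum(ag$joint), 1, tolerance = 1e-12)
  # fitting-style initialization: fixed nu0 = 10, free mean
  ag2 <- edhmm_agent(prior20, a0_A = 0.7 * 10, b0_A = 0.3 * 10,
                     a0_B = 0.4 * 10, b0_B = 0.6 * 10)
  expect_equal(unname(ag2$a["A"] + ag2$b["A"]), 10)
  # known starting configuration puts all mass on the NR row
  ag3 <- edhmm_agent(prior20, theta0 = 1)
  expect_equal(sum(ag3$joint[2, ]), 0)
  expect_equal(rowSums(ag3$joint)[["NR"]], 1, tolerance = 1e-12)
  expect_error(edhmm_agent(prior20, a0_A = -1), "positive")
  expect_error(edhmm_agent(prior20, theta0 = 1.2), "theta0")
})

test_that("predictive win probabilities are Beta means under the state mapping", {
  ag <- edhmm_agent(prior20)
  expect_equal(predictive_outcome_likelihood(ag, "A"), c(NR = 0.8, R = 0.2))
  expect_equal(predictive_outcome_likelihood(ag, "B"), c(NR = 0.2, R = 0.8))
  # mean is scale invariant
  ag$a["A"] <- 16
  ag$b["A"] <- 4
  expect_equal(predictive_outcome_likelihood(ag, "A")[["NR"]], 0.8)
  # symmetric beliefs are uninformative
  ag$a <- c(A = 3, B = 7)
  ag$b <- c(A = 3, B = 7)
  expect_equal(predictive_outcome_likelihood(ag, "A"), c(NR = 0.5, R = 0.5))
})

test_that("state update is the Bayes posterior with the plug-in likelihood ratio", {
  ag <- edhmm_agent(prior20)
  # equal likelihoods leave the marginal untouched
  ag$a <- c(A = 5, B = 5)
  ag$b <- c(A = 5, B = 5)
  up <- update_state_beliefs(ag, "A", 1)
  expect_equal(theta_tilde(up), 0.5, tolerance = 1e-12)
  # hand Bayes: theta~ = 0.5, p(o|NR) = 0.2, p(o|R) = 0.8 -> theta = 0.2
  ag <- edhmm_agent(prior20)
  up <- update_state_beliefs(ag, "B", 1)  # B wins: evidence for R... NR? B pays 0.2 under NR
  expect_equal(theta_tilde(up), 0.2, tolerance = 1e-12)
  # absorbing marginal
  ag1 <- edhmm_agent(prior20, theta0 = 1)
  up1 <- update_state_beliefs(ag1, "A", -1)
  expect_equal(theta_tilde(up1), 1)
  # duration pmfs conditional on each state are unchanged by the update
  ag <- edhmm_agent(prior20)
  up <- update_state_beliefs(ag, "A", 1)
  expect_equal(up$joint[1, ] / sum(up$joint[1, ]),
               ag$joint[1, ] / sum(ag$joint[1, ]), tolerance = 1e-12)
  expect_equal(sum(up$joint), 1, tolerance = 1e-12)
})

test_that("reward update splits one unit of pseudo-count mass by state belief", {
  ag <- edhmm_agent(prior20, theta0 = 1)  # theta = 1 after any update
  up <- update_reward_beliefs(ag, "A", 1)
  expect_equal(unname(up$a["A"]), 9)
  expect_equal(unname(c(up$b["A"], up$a["B"], up$b["B"])), c(2, 2, 8))

  # theta = 0.7: split between the two options
  ag <- edhmm_agent(prior20, theta0 = 0.7)
  up <- update_reward_beliefs(ag, "A", 1)
  expect_equal(unname(up$a["A"] - ag$a["A"]), 0.7)
  expect_equal(unname(up$a["B"] - ag$a["B"]), 0.3)

  # loss branch: mass goes to the b parameters
  ag <- edhmm_agent(prior20, theta0 = 0.5)
  up <- update_reward_beliefs(ag, "A", -1)
  expect_equal(unname(up$b["A"] - ag$b["A"]), 0.5)
  expect_equal(unname(up$b["B"] - ag$b["B"]), 0.5)

  # exactly one unit of mass added per trial, nu is non-decreasing
  tot0 <- sum(ag$a) + sum(ag$b)
  expect_equal(sum(up$a) + sum(up$b), tot0 + 1, tolerance = 1e-12)
})

test_that("belief propagation implements countdown-and-flip dynamics", {
  # point mass at (NR, d = 1) flips to (R, d ~ p0)
  ag <- edhmm_agent(prior20, theta0 = 1)
  ag$joint <- ag$joint * 0
  ag$joint[1, 1] <- 1
  up <- propagate_beliefs(ag)
  expect_equal(up$joint[1, ], rep(0, 200))
  expect_equal(up$joint[2, ], prior20$pmf, tolerance = 1e-14)

  # geometric prior: the marginal follows the constant-rate HMM prediction
  geo <- duration_prior(mu = 20, sigma = 380, d_max = 600)
  ag <- edhmm_agent(geo, theta0 = 0.7)
  up <- propagate_beliefs(ag)
  delta_eff <- geo$pmf[1]  # truncated-geometric hazard at a fresh counter
  expect_equal(theta_tilde(up), 0.7 * (1 - delta_eff) + 0.3 * delta_eff,
               tolerance = 1e-12)
})

test_that("closed-form predicted state marginal equals the grid marginalization", {
  set.seed(123)
  prior <- duration_prior(mu = 8, sigma = 12, d_max = 60)
  for (i in 1:1000) {
    ag <- random_agent_state(prior)
    theta <- sum(ag$joint[1, ])
    q1_nr <- ag$joint[1, 1] / theta
    q1_r <- ag$joint[2, 1] / (1 - theta)
    closed <- (1 - theta) * q1_r + theta * (1 - q1_nr)
    expect_equal(theta_tilde(propagate_beliefs(ag)), closed,
                 tolerance = 1e-12)
  }
})

test_that("geometric-prior ED-HMM reduces to a direct 2-state HMM filter", {
  set.seed(7)
  sched <- experimental_schedule()
  block <- run_block(agent_spec("iri"), sched)$data
  geo <- duration_prior(mu = 20, sigma = 380, d_max = 2000)
  ag <- edhmm_agent(geo)
  thetas <- numeric(160)
  for (t in 1:160) {
    ag <- agent_step(ag, block$choice[t], block$outcome[t])
    thetas[t] <- theta_tilde(ag)
  }
  # oracle: constant-rate filter at the truncated-geometric hazard
  oracle <- hmm_filter_theta(block$choice, block$outcome, delta = geo$pmf[1])
  expect_equal(thetas, oracle, tolerance = 1e-8)
})

test_that("with the state pinned the reward beliefs are conjugate Beta-Bernoulli", {
  set.seed(21)
  choices <- sample(c("A", "B"), 80, replace = TRUE)
  outcomes <- sample(c(-1, 1), 80, replace = TRUE, prob = c(0.3, 0.7))
  ag <- edhmm_agent(prior20, theta0 = 1)
  for (t in 1:80) {
    ag <- update_state_beliefs(ag, choices[t], outcomes[t])
    ag <- update_reward_beliefs(ag, choices[t], outcomes[t])
    # no propagation: theta stays 1
  }
  wins <- outcomes == 1
  expect_equal(unname(ag$a["A"]), 8 + sum(choices == "A" & wins))
  expect_equal(unname(ag$b["A"]), 2 + sum(choices == "A" & !wins))
  expect_equal(unname(ag$a["B"]), 2 + sum(choices == "B" & wins))
  expect_equal(unname(ag$b["B"]), 8 + sum(choices == "B" & !wins))
})

test_that("joint grid normalization survives 160 trials of updating", {
  set.seed(5)
  sched <- experimental_schedule()
  ag <- edhmm_agent(prior20)
  for (t in 1:160) {
    ch <- sample(c("A", "B"), 1)
    ag <- agent_step(ag, ch, sample_outcome(sched, t, ch))
    expect_true(all(ag$joint >= 0))
  }
  expect_lt(abs(sum(ag$joint) - 1), 1e-10)
  expect_true(all(ag$a > 0) && all(ag$b > 0))
})

test_that("value-form delta rules reproduce the Beta-form update exactly", {
  set.seed(31)
  prior <- duration_prior(mu = 10, sigma = 15, d_max = 80)
  for (i in 1:200) {
    ag <- random_agent_state(prior)
    choice <- sample(c("A", "B"), 1)
    outcome <- sample(c(-1, 1), 1)
    st <- update_state_beliefs(ag, choice, outcome)
    theta <- theta_tilde(st)
    vf <- to_value_form(st, theta, choice)
    oth <- if (choice == "A") "B" else "A"
    v_new <- vf$V
    v_new[choice] <- vf$V[choice] +
      vf$alpha[choice] * (outcome - vf$V[choice])
    v_new[oth] <- vf$V[oth] +
      vf$kappa * vf$alpha[oth] * (outcome - vf$V[oth])
    beta_path <- update_reward_beliefs(st, choice, outcome)
    v_beta <- 2 * beta_path$a / (beta_path$a + beta_path$b) - 1
    expect_equal(v_new, v_beta, tolerance = 1e-12)
  }
})

test_that("value-form diagnostics: scale and degenerate-state handling", {
  ag <- edhmm_agent(prior20)
  ag$a <- c(A = 4, B = 8)
  ag$b <- c(A = 4, B = 2)
  vf <- to_value_form(ag, 0.5, "A")
  expect_equal(unname(vf$V["A"]), 0)      # a = b maps to value 0
  expect_equal(unname(vf$V["B"]), 0.6)    # 2 * 0.8 - 1
  expect_equal(vf$kappa, 1)
  vf0 <- to_value_form(ag, 0, "A", kappa_max = 100)
  expect_equal(vf0$kappa, 100)            # clamped at the configured ceiling
})

test_that("expected choice values marginalize over the state belief", {
  ag <- edhmm_agent(prior20)  # V_A = 0.6, V_B = -0.6, theta~ = 0.5
  v <- expected_choice_values(ag)
  expect_equal(v, c(A = 0, B = 0))
  ag$joint <- rbind(0.8 * prior20$pmf, 0.2 * prior20$pmf)
  v <- expected_choice_values(ag)
  expect_equal(unname(v["A"]), 0.8 * 0.6 + 0.2 * (-0.6))
  expect_equal(unname(v["B"]), -unname(v["A"]))
})
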