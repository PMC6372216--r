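test_that("parameter transforms match the tabulated maps and round-trip", {
  nat <- transform_parameters(rep(1, 6), "du_rw")
  expect_equal(nat$alpha, 0.5)
  expect_equal(nat$kappa, 0.5)
  expect_equal(nat$V0A, 0)
  expect_equal(nat$V0B, 0)
  expect_equal(nat$beta, 0.5)
  expect_equal(nat$bias, 0.5)
  nat <- transform_parameters(c(1, 1e-9, 4, 4, 3, 1), "ed_hmm", "positive")
  expect_equal(nat$delta, 0.5)
  expect_equal(nat$r, 1, tolerance = 1e-8)  # HMM limit as lambda2 -> 0
  expect_equal(nat$mu0A, 0.8)
  expect_equal(nat$mu0B, 0.2)
  expect_equal(nat$beta, 3)

  set.seed(1)
  for (model in c("ed_hmm", "du_rw")) {
    for (bt in c("bounded", "positive")) {
      lam <- exp(rnorm(6))
      nat <- transform_parameters(lam, model, bt)
      expect_equal(inverse_transform_parameters(nat, model, bt), lam,
                   tolerance = 1e-10)
    }
  }
  expect_error(transform_parameters(c(-1, 1, 1, 1, 1, 1), "du_rw"),
               "positive")
})

test_that("response log-likelihood: uniform limit, single trial, causality", {
  d <- fixed_block(20)
  unif <- list(alpha = 0.3, kappa = 0.5, V0A = 0, V0B = 0, beta = 0,
               bias = 0.5)
  expect_equal(response_loglikelihood(d, unif, "du_rw"), 20 * log(0.5),
               tolerance = 1e-12)

  # one-trial dataset: hand-computed softmax of the initial values
  d1 <- behavioral_dataset("s", "A", 1)
  nat <- list(alpha = 0.2, kappa = 0.3, V0A = 0.4, V0B = -0.1, beta = 2,
              bias = 0.6)
  expected <- log(exp(2 * 0.4 + log(0.6)) /
                    (exp(2 * 0.4 + log(0.6)) + exp(2 * -0.1 + log(0.4))))
  expect_equal(response_loglikelihood(d1, nat, "du_rw"), expected,
               tolerance = 1e-12)

  # outcomes after the evaluated range cannot influence the likelihood
  nat_ed <- list(delta = 0.1, r = 2, mu0A = 0.8, mu0B = 0.2, beta = 2,
                 bias = 0.5)
  d2 <- fixed_block(20)
  d2$outcome[15:20] <- -d2$outcome[15:20]
  expect_equal(
    response_loglikelihood(d, nat_ed, "ed_hmm", t_to = 14),
    response_loglikelihood(d2, nat_ed, "ed_hmm", t_to = 14))
})

test_that("compiled likelihood equals the pure-R reference on both models", {
  set.seed(17)
  block <- run_block(agent_spec("rri"), experimental_schedule())$data
  nat_ed <- list(delta = 0.12, r = 3.5, mu0A = 0.75, mu0B = 0.3, beta = 2.5,
                 bias = 0.45)
  expect_equal(
    response_loglikelihood(block, nat_ed, "ed_hmm", engine = "cpp"),
    response_loglikelihood(block, nat_ed, "ed_hmm", engine = "r"),
    tolerance = 1e-10)
  nat_rw <- list(alpha = 0.3, kappa = 0.8, V0A = 0.2, V0B = -0.4, beta = 1.5,
                 bias = 0.55)
  expect_equal(
    response_loglikelihood(block, nat_rw, "du_rw", engine = "cpp"),
    response_loglikelihood(block, nat_rw, "du_rw", engine = "r"),
    tolerance = 1e-10)
})

test_that("single-subject variational fit recovers an identified learning rate", {
  # strongly identified data: low-noise DU-RW behavior
  truth <- list(alpha = 0.3, kappa = 0.8, V0A = 0, V0B = 0, beta = 6,
                bias = 0.5)
  sched <- experimental_schedule()
  set.seed(14)
  d <- run_block(agent_from_native(truth, "du_rw"), sched,
                 params = response_params(beta = 6), mode = "sample",
                 subject = "s1")$data
  post <- fit_hierarchical(d, "du_rw", n_iter = 600, seed = 3,
                           beta_transform = "positive")
  draws <- posterior_draws(post, 2000, seed = 1)
  alpha_draws <- draws[, 1, "alpha"]
  ci <- stats::quantile(alpha_draws, c(0.05, 0.95))
  expect_gt(truth$alpha, ci[1] - 0.05)
  expect_lt(truth$alpha, ci[2] + 0.05)
  expect_length(post$elbo, 600)
})

test_that("group scales shrink when subjects share a parameter", {
  # all subjects share alpha; the group scale tau_1 should contract
  # relative to its half-Cauchy(0, 1) prior (median 1)
  set.seed(15)
  sched <- experimental_schedule()
  datasets <- do.call(rbind, lapply(1:4, function(s) {
    truth <- list(alpha = 0.25, kappa = 0.6, V0A = 0, V0B = 0, beta = 4,
                  bias = 0.5)
    run_block(agent_from_native(truth, "du_rw"), sched,
              params = response_params(beta = 4), mode = "sample",
              subject = sprintf("s%d", s))$data
  }))
  post <- fit_hierarchical(datasets, "du_rw", n_iter = 500, seed = 4,
                           beta_transform = "positive")
  # posterior median of tau_1 = exp(m_u[1]) under the log-normal factor
  expect_lt(exp(post$m_u[1]), 1)
})

test_that("posterior predictive evidence has the exact degenerate limits", {
  sched <- experimental_schedule()
  set.seed(16)
  d <- run_block(agent_spec("du_rw"), sched)$data
  # build a near-point posterior predicting 0.5 everywhere: beta -> 0
  lam0 <- inverse_transform_parameters(
    list(alpha = 0.5, kappa = 0.5, V0A = 0, V0B = 0, beta = 1e-9,
         bias = 0.5), "du_rw", "positive")
  post <- structure(
    list(model = "du_rw", subjects = d$subject[1], par_names = model_par_names("du_rw"),
         m_z = matrix(log(lam0), 1), s_z = matrix(1e-12, 1, 6),
         m_u = rep(0, 6), s_u = rep(1, 6), elbo = numeric(0),
         converged = TRUE,
         config = list(k = 125L, n_iter = 0L, lr = 0, seed = 1,
                       d_max = 200L, nu0 = 10,
                       beta_transform = "positive")),
    class = "hierarchical_posterior")
  expect_warning(
    ev <- posterior_predictive_evidence(post, d, k = 125, N = 50, seed = 2),
    "N < 100")
  expect_equal(unname(ev), 35 * log(0.5), tolerance = 1e-6)

  # a point posterior at arbitrary parameters equals the plain held-out
  # likelihood under those parameters
  nat <- list(alpha = 0.3, kappa = 0.7, V0A = 0, V0B = 0, beta = 2,
              bias = 0.5)
  post$m_z <- matrix(log(inverse_transform_parameters(nat, "du_rw",
                                                      "positive")), 1)
  suppressWarnings(
    ev <- posterior_predictive_evidence(post, d, k = 125, N = 10, seed = 2))
  expect_equal(unname(ev),
               response_loglikelihood(d, nat, "du_rw", t_from = 126),
               tolerance = 1e-6)

  # reproducible given a seed
  suppressWarnings({
    e1 <- posterior_predictive_evidence(post, d, k = 125, N = 99, seed = 7)
    e2 <- posterior_predictive_evidence(post, d, k = 125, N = 99, seed = 7)
  })
  expect_identical(e1, e2)
})

test_that("random-effects comparison: symmetry, dominance, per-subject odds", {
  # identical evidences: everything at chance
  ev <- cbind(m1 = rep(-20, 8), m2 = rep(-20, 8))
  cmp <- random_effects_comparison(ev)
  expect_equal(cmp$exceedance, 0.5, tolerance = 1e-6)
  expect_equal(unname(cmp$attribution[, 1]), rep(0.5, 8), tolerance = 1e-6)
  expect_equal(sum(cmp$pi_post), 1, tolerance = 1e-12)

  # overwhelming evidence for model 1
  ev <- cbind(m1 = rep(-10, 8), m2 = rep(-40, 8))
  cmp <- random_effects_comparison(ev)
  expect_gt(cmp$exceedance, 0.99)
  expect_true(all(cmp$attribution[, "m1"] > 0.95))

  # mixed cohort: attribution signs follow the per-subject evidence gaps
  gaps <- c(rep(3, 6), rep(-3, 16))
  ev <- cbind(m1 = -20 + pmax(gaps, 0), m2 = -20 + pmax(-gaps, 0))
  cmp <- random_effects_comparison(ev)
  expect_true(all(cmp$attribution[gaps > 0, "m1"] > 0.5))
  expect_true(all(cmp$attribution[gaps < 0, "m1"] < 0.5))
  expect_true(cmp$exceedance >= 0 && cmp$exceedance <= 1)
  expect_equal(rowSums(cmp$attribution), rep(1, 22), tolerance = 1e-12)
  expect_error(random_effects_comparison(cbind(1, 2, 3)), "two model")
})

test_that("group response-difference permutation test behaves on a known signal", {
  # group 1 switches to option B at trial 140, group 2 stays on A
  set.seed(18)
  subjects <- sprintf("s%02d", 1:12)
  datasets <- do.call(rbind, lapply(seq_along(subjects), function(i) {
    choice <- rep("A", 160)
    if (i <= 6) choice[140:160] <- "B"
    # small response noise
    flip <- runif(160) < 0.05
    choice[flip] <- ifelse(choice[flip] == "A", "B", "A")
    behavioral_dataset(subjects[i], choice,
                       sample(c(-1, 1), 160, replace = TRUE))
  }))
  group <- stats::setNames(rep(c("switchers", "stayers"), each = 6),
                           subjects)
  res <- group_response_difference(datasets, group, trials = 126:160,
                                   n_perm = 500, seed = 5)
  expect_equal(res$trials, 126:160)
  expect_true(res$peak_trial >= 140)
  expect_lt(res$peak_p, 0.05)
  expect_equal(dim(res$perm_quantiles), c(4L, 35L))
})
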