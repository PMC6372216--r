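test_that("negative-binomial interval pmf matches the geometric closed form at r = 1", {
  expect_equal(nb_pmf(0.05, 1, 1), 0.05)
  expect_equal(nb_pmf(0.05, 1, 3), 0.95^2 * 0.05)
  d <- 1:50
  expect_equal(nb_pmf(0.3, 1, d), (1 - 0.3)^(d - 1) * 0.3, tolerance = 1e-15)
})

test_that("nb pmf normalizes and matches a high-precision log-gamma evaluation", {
  # sharply peaked case: delta = 0.95, r = 361 (mu = 20, sigma = 20)
  lp <- lgamma(20 + 361 - 1) - lgamma(20) - lgamma(361) +
    19 * log(0.05) + 361 * log(0.95)
  expect_equal(nb_pmf(0.95, 361, 20), exp(lp), tolerance = 1e-12)
  expect_equal(sum(nb_pmf(0.95, 361, 1:500)), 1, tolerance = 1e-9)
  expect_equal(sum(nb_pmf(0.05, 1, 1:500)), 1, tolerance = 1e-9)
  # non-integer shape still normalizes
  expect_equal(sum(nb_pmf(0.4, 2.7, 1:500)), 1, tolerance = 1e-9)
})

test_that("nb pmf rejects out-of-domain parameters", {
  expect_error(nb_pmf(0, 1, 1), "delta")
  expect_error(nb_pmf(1, 1, 1), "delta")
  expect_error(nb_pmf(0.5, 0, 1), "r")
  expect_error(nb_pmf(0.5, 1, 0), "d")
  expect_error(nb_pmf(0.5, 1, 1.5), "d")
})

test_that("moment inversion reproduces the tabulated parameter pairs", {
  # geometric limit: sigma = mu (mu - 1)
  p <- nb_moments_to_params(20, 20 * 19)
  expect_equal(p$delta, 0.05)
  expect_equal(p$r, 1)
  # regular-interval beliefs: sigma = mu
  p <- nb_moments_to_params(20, 20)
  expect_equal(p$delta, 0.95)
  expect_equal(p$r, 361)
  # degenerate dispersion bound rejected
  expect_error(nb_moments_to_params(2, 1), "sigma")
  expect_error(nb_moments_to_params(1, 10), "mu")
})

test_that("moments recovered from the truncated pmf invert back to (mu, sigma)", {
  for (case in list(c(20, 380), c(20, 20), c(10, 35), c(15, 60))) {
    mu <- case[1]
    sigma <- case[2]
    prior <- duration_prior(mu = mu, sigma = sigma, d_max = 10L * mu)
    d <- seq_len(prior$d_max)
    m1 <- sum(d * prior$pmf)
    m2 <- sum((d - m1)^2 * prior$pmf)
    expect_equal(m1, mu, tolerance = 0.01)
    expect_equal(m2, sigma, tolerance = 0.01)
    p <- nb_moments_to_params(m1, m2)
    expect_equal(p$delta, prior$delta, tolerance = 0.01)
    expect_equal(p$r, prior$r, tolerance = 0.01)
  }
})

test_that("duration prior construction: normalization, shape, truncation policy", {
  iri <- duration_prior(mu = 20, sigma = 380, d_max = 200)
  expect_s3_class(iri, "duration_prior")
  expect_equal(sum(iri$pmf), 1, tolerance = 1e-12)
  expect_equal(iri$pmf[1], 0.05 / sum(nb_pmf(0.05, 1, 1:200)),
               tolerance = 1e-12)
  rri <- duration_prior(mu = 20, sigma = 20, d_max = 200)
  expect_true(abs(which.max(rri$pmf) - 20) <= 1)
  expect_warning(duration_prior(mu = 20, sigma = 380, d_max = 10),
                 "truncation")
})

test_that("duration priors round-trip through JSON", {
  prior <- duration_prior(mu = 20, sigma = 20, d_max = 150)
  back <- prior_from_json(prior_to_json(prior))
  expect_equal(back$delta, prior$delta)
  expect_equal(back$r, prior$r)
  expect_equal(back$pmf, prior$pmf)
  path <- withr::local_tempfile(fileext = ".json")
  prior_to_json(prior, path)
  expect_equal(prior_from_json(path)$pmf, prior$pmf)
})

test_that("forward reversal probability is constant under a geometric prior", {
  prior <- duration_prior(mu = 20, sigma = 380, d_max = 1000)
  dtau <- expected_reversal_probability(prior, 160)
  expect_equal(dtau, rep(0.05, 159), tolerance = 1e-9)
})

test_that("forward reversal probability starts at pmf(1) and peaks near the mean", {
  rri <- duration_prior(mu = 20, sigma = 20, d_max = 200)
  dtau <- expected_reversal_probability(rri, 60)
  expect_equal(dtau[1], rri$pmf[1])  # a reversal at tau = 2 needs d1 = 1
  # low early transition probability with the first sensitivity peak in the
  # twenty-to-thirty trial window after the last reversal
  taus <- 2:60
  first_peak <- taus[which.max(dtau[taus <= 35])]
  expect_true(first_peak >= 20 && first_peak <= 30)
  expect_lt(min(dtau[taus < 10]), 0.05)
  expect_true(all(dtau >= 0 & dtau <= 1))
  expect_error(expected_reversal_probability(rri, 300), "d_max")
})

test_that("forward reversal probability agrees with Monte-Carlo trajectory sampling", {
  set.seed(42)
  for (prior in list(duration_prior(mu = 8, sigma = 8, d_max = 120),
                     duration_prior(mu = 8, sigma = 30, d_max = 120))) {
    taus <- c(3, 6, 9, 16)
    exact <- expected_reversal_probability(prior, max(taus))[taus - 1]
    mc <- mc_reversal_probability(prior, taus, n = 1e5)
    expect_true(all(abs(exact - mc["est", ]) <= 3 * mc["se", ] + 1e-12))
  }
})
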