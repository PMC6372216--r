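#' Free-parameter transforms
#'
#' Both behavioral models expose six free parameters fitted on a positive
#' unconstrained scale `lambda_1..lambda_6` and mapped to their native ranges:
#'
#' | model | parameter | transform |
#' |-------|-----------|-----------|
#' | DU-RW | `alpha`   | `l1 / (1 + l1)` |
#' |       | `kappa`   | `l2 / (1 + l2)` |
#' |       | `V0A`     | `(l3 - 1) / (l3 + 1)` |
#' |       | `V0B`     | `(1 - l4) / (1 + l4)` |
#' | ED-HMM| `delta`   | `l1 / (1 + l1)` |
#' |       | `r`       | `1 + l2` |
#' |       | `mu0A`    | `l3 / (1 + l3)` |
#' |       | `mu0B`    | `1 / (1 + l4)` |
#' | both  | `beta`    | `l5 / (1 + l5)` (`"bounded"`) or `l5` (`"positive"`) |
#' |       | `bias`    | `l6 / (1 + l6)` |
#'
#' The single-update RW and plain HMM variants are the limits `kappa -> 0`
#' and `r -> 1` and are recovered from the posterior rather than fitted
#' separately. The ED-HMM initial pseudo-count totals are fixed at
#' `nu0 = 10` per option (reflecting a balanced 20-trial training phase), so
#' only the initial means `mu0A`, `mu0B` are free. The bounded `beta`
#' transform caps the response precision at 1; the `"positive"` switch leaves
#' it unbounded for data in the near-deterministic regime.
#'
#' @param lambda Positive numeric vector of length 6 (or matrix with 6
#'   columns).
#' @param model `"ed_hmm"` or `"du_rw"`.
#' @param beta_transform `"bounded"` (as tabulated) or `"positive"`.
#' @return Named list (or data frame for matrix input) of native parameters.
#' @export
#' @examples
#' transform_parameters(rep(1, 6), "du_rw")  # alpha = kappa = 0.5, V0 = 0
transform_parameters <- function(lambda, model = c("ed_hmm", "du_rw"),
                                 beta_transform = c("bounded", "positive")) {
  model <- match.arg(model)
  beta_transform <- match.arg(beta_transform)
  if (is.matrix(lambda)) {
    stopifnot(ncol(lambda) == 6L)
    out <- vapply(seq_len(nrow(lambda)), function(i) {
      unlist(transform_parameters(lambda[i, ], model, beta_transform))
    }, numeric(6L))
    res <- as.data.frame(t(out))
    names(res) <- model_par_names(model)
    return(res)
  }
  stopifnot(length(lambda) == 6L)
  if (any(!is.finite(lambda)) || any(lambda <= 0)) {
    stop("`lambda` must be positive and finite")
  }
  l <- unname(lambda)
  beta <- if (beta_transform == "bounded") l[5] / (1 + l[5]) else l[5]
  common <- list(beta = beta, bias = l[6] / (1 + l[6]))
  if (model == "ed_hmm") {
    c(list(delta = l[1] / (1 + l[1]), r = 1 + l[2],
           mu0A = l[3] / (1 + l[3]), mu0B = 1 / (1 + l[4])), common)
  } else {
    c(list(alpha = l[1] / (1 + l[1]), kappa = l[2] / (1 + l[2]),
           V0A = (l[3] - 1) / (l[3] + 1), V0B = (1 - l[4]) / (1 + l[4])),
      common)
  }
}

#' @rdname transform_parameters
#' @param native Named list/vector of native-scale parameters (as produced by
#'   [transform_parameters()]).
#' @return `inverse_transform_parameters` returns the positive `lambda`
#'   vector; it is the exact inverse on the interior of each range.
#' @export
inverse_transform_parameters <- function(native,
                                         model = c("ed_hmm", "du_rw"),
                                         beta_transform = c("bounded",
                                                            "positive")) {
  model <- match.arg(model)
  beta_transform <- match.arg(beta_transform)
  native <- as.list(native)
  logit_pos <- function(p) p / (1 - p)
  l5 <- if (beta_transform == "bounded") logit_pos(native$beta) else
    native$beta
  if (model == "ed_hmm") {
    if (native$r <= 1) stop("`r` must exceed 1 on the lambda scale")
    lam <- c(logit_pos(native$delta), native$r - 1,
             logit_pos(native$mu0A), 1 / native$mu0B - 1,
             l5, logit_pos(native$bias))
  } else {
    lam <- c(logit_pos(native$alpha), logit_pos(native$kappa),
             (1 + native$V0A) / (1 - native$V0A),
             (1 - native$V0B) / (1 + native$V0B),
             l5, logit_pos(native$bias))
  }
  if (any(!is.finite(lam)) || any(lam <= 0)) {
    stop("native parameters lie on or outside the transform boundaries")
  }
  lam
}

model_par_names <- function(model) {
  if (model == "ed_hmm") {
    c("delta", "r", "mu0A", "mu0B", "beta", "bias")
  } else {
    c("alpha", "kappa", "V0A", "V0B", "beta", "bias")
  }
}

# Truncated, renormalized NB pmf evaluated stably in log space.
nb_pmf_trunc <- function(delta, r, d_max) {
  lp <- nb_pmf(delta, r, seq_len(d_max), log = TRUE)
  lp <- lp - max(lp)
  p <- exp(lp)
  p / sum(p)
}

#' Build an agent from native-scale fitted parameters
#'
#' @param native Named list of native parameters (see
#'   [transform_parameters()]).
#' @param model `"ed_hmm"` or `"du_rw"`.
#' @param d_max Duration-grid truncation for the ED-HMM.
#' @param nu0 Fixed initial pseudo-count total per option for the ED-HMM.
#' @param theta0 Initial non-reversal state probability.
#' @return An `edhmm_agent` or `rw_agent`.
#' @export
agent_from_native <- function(native, model = c("ed_hmm", "du_rw"),
                              d_max = 200L, nu0 = 10, theta0 = 0.5) {
  model <- match.arg(model)
  native <- as.list(native)
  if (model == "ed_hmm") {
    prior <- structure(
      list(delta = native$delta, r = native$r,
           mu = (native$r + native$delta * (1 - native$r)) / native$delta,
           sigma = (1 - native$delta) * native$r / native$delta^2,
           d_max = as.integer(d_max),
           pmf = nb_pmf_trunc(native$delta, native$r, d_max)),
      class = "duration_prior")
    edhmm_agent(prior,
                a0_A = native$mu0A * nu0, b0_A = (1 - native$mu0A) * nu0,
                a0_B = native$mu0B * nu0, b0_B = (1 - native$mu0B) * nu0,
                theta0 = theta0)
  } else {
    rw_agent(alpha = native$alpha, kappa = native$kappa,
             V0 = c(native$V0A, native$V0B))
  }
}

#' Response log-likelihood of observed behavior
#'
#' Deterministic forward pass of an agent over a subject's observed choices
#' and outcomes (choices are observables of the generative model: the agent
#' is conditioned on what the subject actually chose), accumulating the log
#' softmax probabilities of the observed choices.
#'
#' @param data Single-subject behavioral data frame (columns `choice`,
#'   `outcome`).
#' @param native Named list of native parameters, including `beta` and
#'   `bias`.
#' @param model `"ed_hmm"` or `"du_rw"`.
#' @param t_from,t_to Trial range over which log-probabilities are summed
#'   (beliefs are propagated from trial 1 through `t_to` regardless); by
#'   default the whole block.
#' @param d_max,nu0 ED-HMM settings, see [agent_from_native()].
#' @param engine `"cpp"` (compiled fast path) or `"r"` (pure-R reference
#'   path built from the exported update operations).
#' @return Scalar log-likelihood.
#' @export
response_loglikelihood <- function(data, native, model = c("ed_hmm", "du_rw"),
                                   t_from = 1L, t_to = nrow(data),
                                   d_max = 200L, nu0 = 10,
                                   engine = c("cpp", "r")) {
  model <- match.arg(model)
  engine <- match.arg(engine)
  native <- as.list(native)
  ch <- match(data$choice, c("A", "B")) - 1L
  if (anyNA(ch)) stop("choices must be \"A\" or \"B\"")
  out <- as.numeric(data$outcome)
  if (engine == "cpp") {
    if (model == "ed_hmm") {
      pmf <- nb_pmf_trunc(native$delta, native$r, d_max)
      edhmm_loglik_cpp(ch, out, pmf,
                       native$mu0A * nu0, (1 - native$mu0A) * nu0,
                       native$mu0B * nu0, (1 - native$mu0B) * nu0,
                       0.5, native$beta, native$bias,
                       as.integer(t_from), as.integer(t_to))
    } else {
      rw_loglik_cpp(ch, out, native$alpha, native$kappa, native$V0A,
                    native$V0B, native$beta, native$bias,
                    as.integer(t_from), as.integer(t_to))
    }
  } else {
    agent <- agent_from_native(native, model, d_max = d_max, nu0 = nu0)
    pars <- response_params(beta = native$beta, bias_A = native$bias)
    ll <- 0
    for (t in seq_len(t_to)) {
      p <- response_probabilities(expected_choice_values(agent), pars)
      if (t >= t_from) ll <- ll + log(p[[data$choice[t]]])
      agent <- update_agent(agent, data$choice[t], data$outcome[t])
    }
    ll
  }
}

split_subjects <- function(datasets) {
  if (is.data.frame(datasets)) {
    validate_behavior(datasets)
    datasets <- split(datasets, datasets$subject)
    datasets <- datasets[order(names(datasets))]
  }
  lapply(datasets, function(d) {
    list(subject = as.character(d$subject[1L]),
         choice = match(d$choice, c("A", "B")) - 1L,
         outcome = as.numeric(d$outcome))
  })
}

# log p(lambda, tau) under the horseshoe prior, plus the log-Jacobians of the
# log transforms, evaluated at z = log lambda (n x 6) and u = log tau (6).
horseshoe_logprior <- function(z, u) {
  lam2 <- exp(2 * z)
  tau2 <- rep(exp(2 * u), each = nrow(z))
  sum(log(2 / pi) - u[col(z)] - log1p(lam2 / tau2) + z) +
    sum(log(2 / pi) - log1p(exp(2 * u)) + u)
}

#' Hierarchical variational fit of a behavioral model
#'
#' Fits the six free parameters of a behavioral model to every subject of a
#' behavioral dataset jointly, under the horseshoe hierarchical prior: each
#' subject-level positive parameter `lambda_i^n` has a half-Cauchy prior with
#' group-level scale `tau_i`, itself half-Cauchy(0, 1). The posterior is
#' approximated in fully factorized mean-field form by stochastic variational
#' inference: independent Gaussian factors on `log lambda` and `log tau`,
#' optimized by stochastic gradient ascent on the evidence lower bound (ELBO)
#' with reparameterized gradients (Adam; likelihood gradients by finite
#' differences, prior and entropy gradients analytic). Factor locations and
#' scales are Polyak-averaged over the final quarter of the iterations.
#'
#' @param datasets Tidy behavioral data frame covering one or more subjects,
#'   or a list of single-subject data frames.
#' @param model `"ed_hmm"` or `"du_rw"`.
#' @param k Fit only the first `k` trials of every subject (`NULL` = all);
#'   used to hold out a prediction segment for model comparison.
#' @param n_iter Number of stochastic gradient iterations.
#' @param lr Adam step size.
#' @param seed Integer seed for the gradient noise.
#' @param d_max,nu0 ED-HMM settings.
#' @param beta_transform `"bounded"` or `"positive"`, see
#'   [transform_parameters()].
#' @param init_lambda Optional positive length-6 vector of initial factor
#'   locations on the lambda scale (defaults to 1).
#' @param verbose Print ELBO progress every 200 iterations.
#' @return An object of class `hierarchical_posterior` holding the Gaussian
#'   factor parameters (`m_z`, `s_z` per subject and parameter; `m_u`, `s_u`
#'   per group scale), the ELBO trace, a `converged` flag (relative change of
#'   the smoothed ELBO below 1%% over the final stretch) and the fit
#'   configuration.
#' @export
fit_hierarchical <- function(datasets, model = c("ed_hmm", "du_rw"),
                             k = NULL, n_iter = 2000L, lr = 0.05, seed = 1L,
                             d_max = 200L, nu0 = 10,
                             beta_transform = c("bounded", "positive"),
                             init_lambda = NULL, verbose = FALSE) {
  model <- match.arg(model)
  beta_transform <- match.arg(beta_transform)
  subs <- split_subjects(datasets)
  n_sub <- length(subs)
  if (n_sub < 1L) stop("need at least one subject")
  P <- 6L
  t_to <- vapply(subs, function(s) {
    tt <- length(s$choice)
    if (!is.null(k)) min(tt, as.integer(k)) else tt
  }, integer(1))

  loglik <- function(z, n) {
    lam <- exp(pmin(pmax(z, -30), 30))
    native <- transform_parameters(lam, model, beta_transform)
    if (model == "ed_hmm") {
      pmf <- nb_pmf_trunc(native$delta, native$r, d_max)
      edhmm_loglik_cpp(subs[[n]]$choice, subs[[n]]$outcome, pmf,
                       native$mu0A * nu0, (1 - native$mu0A) * nu0,
                       native$mu0B * nu0, (1 - native$mu0B) * nu0,
                       0.5, native$beta, native$bias, 1L, t_to[n])
    } else {
      rw_loglik_cpp(subs[[n]]$choice, subs[[n]]$outcome, native$alpha,
                    native$kappa, native$V0A, native$V0B, native$beta,
                    native$bias, 1L, t_to[n])
    }
  }

  set.seed(seed)
  z0 <- if (is.null(init_lambda)) rep(0, P) else log(init_lambda)
  m_z <- matrix(rep(z0, each = n_sub), n_sub, P)
  ls_z <- matrix(log(0.2), n_sub, P)
  m_u <- rep(0, P)
  ls_u <- rep(log(0.2), P)

  adam <- function(d) {
    zero <- if (length(d) > 1L) array(0, d) else numeric(d)
    list(m = zero, v = zero, t = 0)
  }
  st <- list(m_z = adam(dim(m_z)), ls_z = adam(dim(ls_z)),
             m_u = adam(P), ls_u = adam(P))
  adam_step <- function(state, grad, lr) {
    state$t <- state$t + 1
    state$m <- 0.9 * state$m + 0.1 * grad
    state$v <- 0.999 * state$v + 0.001 * grad^2
    mhat <- state$m / (1 - 0.9^state$t)
    vhat <- state$v / (1 - 0.999^state$t)
    state$step <- lr * mhat / (sqrt(vhat) + 1e-8)
    state
  }

  h <- 1e-4
  elbo <- numeric(n_iter)
  avg_from <- max(1L, floor(0.75 * n_iter))
  acc <- list(m_z = 0 * m_z, ls_z = 0 * ls_z, m_u = 0 * m_u,
              ls_u = 0 * ls_u, n = 0L)

  for (it in seq_len(n_iter)) {
    eps_z <- matrix(stats::rnorm(n_sub * P), n_sub, P)
    eps_u <- stats::rnorm(P)
    s_z <- exp(ls_z)
    s_u <- exp(ls_u)
    z <- m_z + s_z * eps_z
    u <- m_u + s_u * eps_u

    ll <- numeric(n_sub)
    g_lik <- matrix(0, n_sub, P)
    for (n in seq_len(n_sub)) {
      base <- loglik(z[n, ], n)
      ll[n] <- base
      for (j in seq_len(P)) {
        zj <- z[n, ]
        zj[j] <- zj[j] + h
        g_lik[n, j] <- (loglik(zj, n) - base) / h
      }
    }

    lam2 <- exp(2 * z)
    tau2 <- matrix(exp(2 * u), n_sub, P, byrow = TRUE)
    ratio <- (lam2 / tau2) / (1 + lam2 / tau2)
    g_z <- g_lik + 1 - 2 * ratio
    tau2v <- exp(2 * u)
    g_u <- colSums(2 * ratio - 1) + 1 - 2 * tau2v / (1 + tau2v)

    st$m_z <- adam_step(st$m_z, g_z, lr)
    st$ls_z <- adam_step(st$ls_z, g_z * s_z * eps_z + 1, lr)
    st$m_u <- adam_step(st$m_u, g_u, lr)
    st$ls_u <- adam_step(st$ls_u, g_u * s_u * eps_u + 1, lr)
    m_z <- m_z + st$m_z$step
    ls_z <- pmin(ls_z + st$ls_z$step, 2)
    m_u <- m_u + st$m_u$step
    ls_u <- pmin(ls_u + st$ls_u$step, 2)

    elbo[it] <- sum(ll) + horseshoe_logprior(z, u) +
      sum(ls_z) + sum(ls_u)
    if (verbose && it %% 200L == 0L) {
      message(sprintf("iter %5d  ELBO %.2f", it, mean(elbo[max(1, it - 99):it])))
    }
    if (it >= avg_from) {
      acc$m_z <- acc$m_z + m_z
      acc$ls_z <- acc$ls_z + ls_z
      acc$m_u <- acc$m_u + m_u
      acc$ls_u <- acc$ls_u + ls_u
      acc$n <- acc$n + 1L
    }
  }

  m_z <- acc$m_z / acc$n
  ls_z <- acc$ls_z / acc$n
  m_u <- acc$m_u / acc$n
  ls_u <- acc$ls_u / acc$n

  half <- elbo[seq.int(floor(n_iter / 2) + 1L, n_iter)]
  a <- mean(half[seq_len(floor(length(half) / 2))])
  b <- mean(half[-seq_len(floor(length(half) / 2))])
  converged <- is.finite(a) && is.finite(b) &&
    abs(b - a) < 0.01 * (abs(a) + 1)
  if (!converged) {
    warning("ELBO still drifting over the final iterations (",
            sprintf("%.2f -> %.2f", a, b),
            "); consider increasing n_iter")
  }

  structure(
    list(model = model, subjects = vapply(subs, `[[`, "", "subject"),
         par_names = model_par_names(model),
         m_z = m_z, s_z = exp(ls_z), m_u = m_u, s_u = exp(ls_u),
         elbo = elbo, converged = converged,
         config = list(k = k, n_iter = n_iter, lr = lr, seed = seed,
                       d_max = d_max, nu0 = nu0,
                       beta_transform = beta_transform)),
    class = "hierarchical_posterior"
  )
}

#' @export
print.hierarchical_posterior <- function(x, ...) {
  cat(sprintf(
    "Hierarchical posterior: model %s, %d subjects, %d iterations (%s)\n",
    x$model, length(x$subjects), x$config$n_iter,
    if (x$converged) "converged" else "NOT converged"))
  cat("Posterior-mean native parameters (group average):\n")
  print(round(colMeans(posterior_mean_native(x)), 4))
  invisible(x)
}

#' Draw native-scale parameters from a fitted posterior
#'
#' @param post A `hierarchical_posterior`.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Array `n x n_subjects x 6` of native-scale draws, with parameter
#'   names on the third dimension.
#' @export
posterior_draws <- function(post, n = 1000L, seed = 1L) {
  stopifnot(inherits(post, "hierarchical_posterior"))
  set.seed(seed)
  n_sub <- nrow(post$m_z)
  P <- ncol(post$m_z)
  out <- array(NA_real_, c(n, n_sub, P),
               dimnames = list(NULL, post$subjects, post$par_names))
  for (s in seq_len(n_sub)) {
    z <- matrix(stats::rnorm(n * P, mean = rep(post$m_z[s, ], each = n),
                             sd = rep(post$s_z[s, ], each = n)), n, P)
    lam <- exp(pmin(pmax(z, -30), 30))
    nat <- transform_parameters(lam, post$model,
                                post$config$beta_transform)
    out[, s, ] <- as.matrix(nat)
  }
  out
}

#' Posterior-mean native parameters per subject
#'
#' @param post A `hierarchical_posterior`.
#' @param n Number of Monte-Carlo draws used for the mean.
#' @param seed Integer seed.
#' @return Matrix `n_subjects x 6` of posterior means on the native scale.
#' @export
posterior_mean_native <- function(post, n = 2000L, seed = 1L) {
  draws <- posterior_draws(post, n, seed)
  apply(draws, c(2, 3), mean)
}

#' Posterior predictive model evidence
#'
#' Monte-Carlo estimate of the marginal probability of each subject's
#' held-out responses (trials `k+1..T`) under the posterior fitted to trials
#' `1..k`: the average over posterior draws of the product of response
#' probabilities of the observed held-out choices, with beliefs propagated
#' through all trials per draw. Computed and returned in log space.
#'
#' @param post A `hierarchical_posterior` (fit with the same `k`).
#' @param datasets The behavioral data (all trials).
#' @param k Last trial of the fitting segment; evidence covers `k+1..T`.
#' @param N Number of posterior draws (default `1e4`); values below 100 give
#'   a high-variance estimate and trigger a warning.
#' @param seed Integer seed.
#' @return Named vector of per-subject log posterior predictive evidences.
#' @export
posterior_predictive_evidence <- function(post, datasets, k = 125L,
                                          N = 10000L, seed = 1L) {
  stopifnot(inherits(post, "hierarchical_posterior"))
  if (N < 100L) warning("N < 100 posterior draws: Monte-Carlo error is large")
  if (!is.null(post$config$k) && post$config$k != k) {
    warning("posterior was fit with k = ", post$config$k,
            " but evidence requested at k = ", k)
  }
  subs <- split_subjects(datasets)
  ids <- vapply(subs, `[[`, "", "subject")
  ord <- match(post$subjects, ids)
  if (anyNA(ord)) stop("datasets do not cover all fitted subjects")
  set.seed(seed)
  P <- ncol(post$m_z)
  ev <- numeric(length(post$subjects))
  names(ev) <- post$subjects
  for (s in seq_along(post$subjects)) {
    dat <- subs[[ord[s]]]
    T_n <- length(dat$choice)
    if (k >= T_n) stop("k must leave at least one held-out trial")
    z <- matrix(stats::rnorm(N * P, mean = rep(post$m_z[s, ], each = N),
                             sd = rep(post$s_z[s, ], each = N)), N, P)
    lp <- numeric(N)
    for (l in seq_len(N)) {
      lam <- exp(pmin(pmax(z[l, ], -30), 30))
      native <- transform_parameters(lam, post$model,
                                     post$config$beta_transform)
      lp[l] <- if (post$model == "ed_hmm") {
        pmf <- nb_pmf_trunc(native$delta, native$r, post$config$d_max)
        edhmm_loglik_cpp(dat$choice, dat$outcome, pmf,
                         native$mu0A * post$config$nu0,
                         (1 - native$mu0A) * post$config$nu0,
                         native$mu0B * post$config$nu0,
                         (1 - native$mu0B) * post$config$nu0,
                         0.5, native$beta, native$bias, k + 1L, T_n)
      } else {
        rw_loglik_cpp(dat$choice, dat$outcome, native$alpha, native$kappa,
                      native$V0A, native$V0B, native$beta, native$bias,
                      k + 1L, T_n)
      }
    }
    m <- max(lp)
    ev[s] <- m + log(mean(exp(lp - m)))
  }
  ev
}

#' Random-effects Bayesian model comparison
#'
#' Treats the data-generating model as a random effect across subjects:
#' each subject's model indicator is a draw from a group frequency vector
#' `pi` with a symmetric Dirichlet prior of concentration `1/gamma`, and
#' `gamma` itself has a half-Cauchy(0, 1) prior that regularizes toward the
#' null of equal model frequencies. Subject indicators are marginalized
#' analytically; the joint posterior over `(pi, gamma)` is computed by
#' quadrature on a probability/Cauchy-quantile grid and reported through its
#' factorized marginals.
#'
#' @param log_evidence Matrix `n_subjects x 2` of per-subject log (posterior
#'   predictive) model evidences; column names label the models (first
#'   column is the focal model for the exceedance probability).
#' @param n_pi,n_gamma Grid resolutions.
#' @return Object of class `model_comparison`: `attribution` (per-subject
#'   posterior model probabilities), `exceedance` (posterior probability
#'   that the focal model's group frequency exceeds 1/2), `pi_grid`/`pi_post`
#'   (marginal posterior of the focal model frequency), `gamma_grid` /
#'   `gamma_post`, and the posterior mean model frequencies.
#' @export
#' @examples
#' ev <- cbind(edhmm = c(-10, -12, -9), rl = c(-11, -9, -12))
#' random_effects_comparison(ev)$exceedance
random_effects_comparison <- function(log_evidence, n_pi = 512L,
                                      n_gamma = 128L) {
  L <- as.matrix(log_evidence)
  if (ncol(L) != 2L) stop("`log_evidence` must have exactly two model columns")
  if (is.null(colnames(L))) colnames(L) <- c("model1", "model2")
  n <- nrow(L)
  A <- exp(L - apply(L, 1L, max))  # per-subject evidences, rescaled

  p <- (seq_len(n_pi) - 0.5) / n_pi
  u <- (seq_len(n_gamma) - 0.5) / n_gamma
  gam <- tan(pi * u / 2)  # half-Cauchy quantiles: prior weight is uniform in u

  # log posterior on the (pi, gamma) grid, subject indicators marginalized
  mix <- outer(p, A[, 1L]) + outer(1 - p, A[, 2L])  # n_pi x n, values > 0
  log_mix <- rowSums(log(mix))                      # length n_pi
  a <- 1 / gam
  log_prior_pi <- outer(log(p) + log1p(-p), a - 1) -
    matrix(rep(lbeta(a, a), each = n_pi), n_pi, n_gamma)
  lp <- log_mix + log_prior_pi  # n_pi x n_gamma
  w <- exp(lp - max(lp))
  w <- w / sum(w)

  pi_post <- rowSums(w)
  gamma_post <- colSums(w)
  exceedance <- sum(pi_post[p > 0.5])

  attr_p <- vapply(seq_len(n), function(i) {
    sum(pi_post * (p * A[i, 1L] / mix[, i]))
  }, numeric(1))
  attribution <- cbind(attr_p, 1 - attr_p)
  colnames(attribution) <- colnames(L)
  rownames(attribution) <- rownames(L)

  structure(
    list(models = colnames(L), attribution = attribution,
         exceedance = exceedance,
         freq_mean = c(sum(pi_post * p), 1 - sum(pi_post * p)),
         pi_grid = p, pi_post = pi_post,
         gamma_grid = gam, gamma_post = gamma_post),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Random-effects model comparison (%s vs %s)\n",
              x$models[1L], x$models[2L]))
  cat(sprintf("  mean group frequency of %s: %.3f\n", x$models[1L],
              x$freq_mean[1L]))
  cat(sprintf("  exceedance probability of %s: %.3f\n", x$models[1L],
              x$exceedance))
  invisible(x)
}

#' Model-family confusion matrix
#'
#' Runs the full attribution pipeline on a simulated corpus (see
#' [generate_confusion_corpus()]): fits both model families hierarchically on
#' the first `k` trials of every block, computes posterior predictive
#' evidences on the held-out trials, attributes each block through the
#' random-effects comparison, and tabulates the mean attribution by true
#' generating family.
#'
#' @param corpus Output of [generate_confusion_corpus()].
#' @param k Fitting segment boundary.
#' @param n_iter Variational iterations per family fit.
#' @param N Posterior draws for the predictive evidence.
#' @param seed Integer seed.
#' @param beta_transform Response-precision transform used in both fits.
#' @param d_max Duration-grid truncation.
#' @return List with `matrix` (rows = true family, columns = assigned
#'   family, rows summing to 1), `comparison` (the `model_comparison`),
#'   `evidence` (per-block log evidences) and `fits`.
#' @export
confusion_experiment <- function(corpus, k = 125L, n_iter = 2000L,
                                 N = 2000L, seed = 1L,
                                 beta_transform = "positive",
                                 d_max = 200L) {
  datasets <- do.call(rbind, lapply(corpus, `[[`, "data"))
  families <- vapply(corpus, `[[`, "", "family")
  names(families) <- vapply(corpus, function(x) x$data$subject[1L], "")
  fit_ed <- fit_hierarchical(datasets, "ed_hmm", k = k, n_iter = n_iter,
                             seed = seed, d_max = d_max,
                             beta_transform = beta_transform)
  fit_rw <- fit_hierarchical(datasets, "du_rw", k = k, n_iter = n_iter,
                             seed = seed + 1L,
                             beta_transform = beta_transform)
  ev <- cbind(
    edhmm = posterior_predictive_evidence(fit_ed, datasets, k = k, N = N,
                                          seed = seed + 2L),
    rl = posterior_predictive_evidence(fit_rw, datasets, k = k, N = N,
                                       seed = seed + 3L))
  cmp <- random_effects_comparison(ev)
  fam <- families[rownames(ev)]
  p_ed <- cmp$attribution[, "edhmm"]
  cm <- rbind(
    edhmm = c(mean(p_ed[fam == "edhmm"]), 1 - mean(p_ed[fam == "edhmm"])),
    rl = c(mean(p_ed[fam == "rl"]), 1 - mean(p_ed[fam == "rl"])))
  colnames(cm) <- c("edhmm", "rl")
  list(matrix = cm, comparison = cmp, evidence = ev,
       fits = list(edhmm = fit_ed, rl = fit_rw),
       families = fam)
}

#' Group response-difference permutation test
#'
#' Compares the per-trial mean response (probability of choosing option A)
#' between two groups of subjects over a trial window, against a null
#' distribution obtained by randomly reallocating subjects into groups of
#' the same sizes.
#'
#' @param datasets Tidy behavioral data frame over subjects.
#' @param group Named character/factor vector mapping each subject to one of
#'   two groups.
#' @param trials Trial window to analyze (default the post-reversal phase of
#'   the 160-trial experimental block).
#' @param n_perm Number of random reallocations.
#' @param seed Integer seed.
#' @return List with `trials`, `observed` (per-trial group difference),
#'   `perm_quantiles` (5/25/75/95 percentiles of the null), `peak_trial`
#'   (trial of the largest absolute observed difference) and
#'   `peak_p` (fraction of permutations whose own peak magnitude reaches the
#'   observed one).
#' @export
group_response_difference <- function(datasets, group, trials = 126:160,
                                      n_perm = 10000L, seed = 1L) {
  validate_behavior(datasets)
  keep <- datasets$trial %in% trials
  d <- datasets[keep, , drop = FALSE]
  resp <- tapply(d$choice == "A", list(d$subject, d$trial), mean)
  resp <- resp[, order(as.integer(colnames(resp))), drop = FALSE]
  group <- group[rownames(resp)]
  if (anyNA(group)) stop("`group` must name every subject in the data")
  lev <- unique(as.character(group))
  if (length(lev) != 2L) stop("exactly two groups are required")
  g1 <- group == lev[1L]
  diff_curve <- function(g) colMeans(resp[g, , drop = FALSE]) -
    colMeans(resp[!g, , drop = FALSE])
  observed <- diff_curve(g1)
  set.seed(seed)
  n1 <- sum(g1)
  perm <- matrix(NA_real_, n_perm, ncol(resp))
  for (b in seq_len(n_perm)) {
    idx <- sample.int(nrow(resp), n1)
    gb <- seq_len(nrow(resp)) %in% idx
    perm[b, ] <- diff_curve(gb)
  }
  qs <- apply(perm, 2L, stats::quantile, probs = c(0.05, 0.25, 0.75, 0.95))
  peak <- which.max(abs(observed))
  peak_p <- mean(apply(abs(perm), 1L, max) >= abs(observed[peak]))
  list(trials = as.integer(colnames(resp)), observed = observed,
       perm_quantiles = qs, groups = stats::setNames(c(sum(g1), sum(!g1)),
                                                     lev),
       peak_trial = as.integer(colnames(resp)[peak]), peak_p = peak_p)
}
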