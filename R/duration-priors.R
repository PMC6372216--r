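#' Negative-binomial probability of a between-reversal interval
#'
#' Probability that the environment dwells exactly `d` trials in one
#' reward-contingency configuration before reversing, under a negative
#' binomial distribution with support starting at `d = 1`:
#' \deqn{p_0(d) = \binom{d + r - 2}{d - 1} (1-\delta)^{d-1} \delta^r.}
#' For `r = 1` this reduces exactly to the geometric distribution
#' \eqn{(1-\delta)^{d-1}\delta}, the dwell-time law implied by a
#' constant-transition-rate hidden Markov model. Non-integer `r` is supported
#' through a log-gamma evaluation of the generalized binomial coefficient.
#'
#' @param delta Success-rate parameter, in (0, 1).
#' @param r Shape parameter, > 0.
#' @param d Interval length(s) in trials; integer(s) >= 1.
#' @param log If `TRUE`, return log-probabilities.
#' @return Numeric vector of (log-)probabilities, same length as `d`.
#' @seealso [duration_prior()], [nb_moments_to_params()]
#' @export
#' @examples
#' nb_pmf(0.05, 1, 1)      # geometric: pmf(1) = delta
#' nb_pmf(0.95, 361, 20)   # sharply peaked near d = 20
nb_pmf <- function(delta, r, d, log = FALSE) {
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) ||
      delta <= 0 || delta >= 1) {
    stop("`delta` must be a single number in (0, 1)")
  }
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r <= 0) {
    stop("`r` must be a single positive number")
  }
  if (any(d < 1) || any(d != floor(d))) {
    stop("`d` must contain integers >= 1")
  }
  # choose(d + r - 2, d - 1) = Gamma(d + r - 1) / (Gamma(d) Gamma(r))
  lp <- lgamma(d + r - 1) - lgamma(d) - lgamma(r) +
    (d - 1) * log1p(-delta) + r * log(delta)
  if (log) lp else exp(lp)
}

#' Convert interval mean and variance to negative-binomial parameters
#'
#' Inverts the moment relations of the shifted (support `d >= 1`) negative
#' binomial, \eqn{\mu = (r + \delta(1-r))/\delta} and
#' \eqn{\sigma = (1-\delta)r/\delta^2}, giving
#' \eqn{\delta = (\mu-1)/\sigma} and \eqn{r = (\mu-1)^2/(\sigma-\mu+1)}.
#' The geometric special case `r = 1` corresponds to
#' \eqn{\sigma = \mu(\mu-1)}.
#'
#' @param mu Mean interval length in trials, > 1.
#' @param sigma Variance of the interval length, in trials^2; must exceed
#'   `mu - 1` (the dispersion floor of the distribution).
#' @return A list with elements `delta` and `r`.
#' @export
#' @examples
#' nb_moments_to_params(20, 20 * 19)  # delta = 0.05, r = 1 (geometric)
#' nb_moments_to_params(20, 20)       # delta = 0.95, r = 361
nb_moments_to_params <- function(mu, sigma) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.numeric(sigma),
            length(sigma) == 1L)
  if (is.na(mu) || mu <= 1) {
    stop("`mu` must be > 1 (interval support starts at 1 trial)")
  }
  if (is.na(sigma) || sigma <= mu - 1) {
    stop("`sigma` must be > mu - 1: no negative binomial has dispersion at ",
         "or below the boundary sigma = mu - 1")
  }
  delta <- (mu - 1) / sigma
  r <- (mu - 1)^2 / (sigma - mu + 1)
  list(delta = delta, r = r)
}

#' Moments of negative-binomial parameters
#'
#' Forward map from `(delta, r)` to the interval mean and variance; inverse of
#' [nb_moments_to_params()].
#'
#' @param delta Rate parameter in (0, 1).
#' @param r Shape parameter > 0.
#' @return A list with elements `mu` and `sigma`.
#' @export
nb_params_to_moments <- function(delta, r) {
  stopifnot(delta > 0, delta < 1, r > 0)
  list(mu = (r + delta * (1 - r)) / delta, sigma = (1 - delta) * r / delta^2)
}

#' Prior beliefs about between-reversal intervals
#'
#' Constructs a truncated, renormalized negative-binomial prior over the
#' number of trials the environment dwells in one contingency configuration.
#' The prior is parameterized either by moments (`mu`, `sigma`) or directly by
#' (`delta`, `r`). `sigma = mu * (mu - 1)` (equivalently `r = 1`) gives the
#' maximal-variance geometric prior of an "irregular reversal interval" (IRI)
#' agent; `sigma = mu` gives the low-variance prior of a "regular reversal
#' interval" (RRI) agent that expects reversals at semi-regular intervals.
#'
#' @param mu,sigma Interval mean and variance (see [nb_moments_to_params()]).
#' @param delta,r Alternative direct parameterization; supply either the
#'   moment pair or the parameter pair, not both.
#' @param d_max Truncation bound of the support, in trials. The probability
#'   mass function is renormalized over `1:d_max`; a warning is emitted when
#'   `d_max < 5 * mu`, where truncation is no longer negligible.
#' @return An object of class `duration_prior` with fields `delta`, `r`,
#'   `mu`, `sigma`, `d_max` and `pmf` (length `d_max`, sums to 1).
#' @export
#' @examples
#' iri <- duration_prior(mu = 20, sigma = 20 * 19)  # geometric beliefs
#' rri <- duration_prior(mu = 20, sigma = 20)       # semi-regular beliefs
#' which.max(rri$pmf)                               # mode near 20
duration_prior <- function(mu = NULL, sigma = NULL, delta = NULL, r = NULL,
                           d_max = 200L) {
  if (!is.null(mu) || !is.null(sigma)) {
    if (is.null(mu) || is.null(sigma) || !is.null(delta) || !is.null(r)) {
      stop("supply either (mu, sigma) or (delta, r)")
    }
    pars <- nb_moments_to_params(mu, sigma)
    delta <- pars$delta
    r <- pars$r
  } else {
    if (is.null(delta) || is.null(r)) stop("supply either (mu, sigma) or (delta, r)")
    mom <- nb_params_to_moments(delta, r)
    mu <- mom$mu
    sigma <- mom$sigma
  }
  d_max <- as.integer(d_max)
  if (d_max < 1L) stop("`d_max` must be >= 1")
  if (d_max < 5 * mu) {
    warning("d_max = ", d_max, " is below 5 * mu = ", 5 * mu,
            "; truncation discards non-negligible probability mass")
  }
  pmf <- nb_pmf(delta, r, seq_len(d_max))
  pmf <- pmf / sum(pmf)
  structure(
    list(delta = delta, r = r, mu = mu, sigma = sigma, d_max = d_max,
         pmf = pmf),
    class = "duration_prior"
  )
}

#' @export
print.duration_prior <- function(x, ...) {
  cat(sprintf(
    "Duration prior: NB(delta = %.4g, r = %.4g), mu = %.4g, sigma = %.4g, d_max = %d\n",
    x$delta, x$r, x$mu, x$sigma, x$d_max))
  invisible(x)
}

#' Forward-predicted reversal probability profile
#'
#' Temporal anticipation profile induced by a duration prior: the probability
#' \eqn{\delta_\tau} that the environment transits from the non-reversal to
#' the reversal state at a future trial \eqn{\tau}, conditioned on starting in
#' the non-reversal state at trial 1 with the dwell-time counter freshly drawn
#' from the prior. Computed by exact forward propagation of the joint
#' (state, duration) chain: the counter counts down deterministically and the
#' state flips exactly when the counter is exhausted (counter value 1), at
#' which point a new counter value is drawn from the prior.
#'
#' A geometric prior yields a constant profile at `delta` (the memoryless
#' hidden-Markov limit); a low-variance prior yields alternating periods of
#' low and high reversal probability peaking near multiples of the mean.
#'
#' @param prior A [duration_prior()].
#' @param horizon Number of trials to look ahead; must not exceed
#'   `prior$d_max` (the truncated grid could not represent longer countdowns).
#' @return Numeric vector of length `horizon - 1` with the reversal
#'   probabilities at trials `2:horizon`.
#' @export
#' @examples
#' expected_reversal_probability(duration_prior(mu = 20, sigma = 20), 60)
expected_reversal_probability <- function(prior, horizon) {
  stopifnot(inherits(prior, "duration_prior"))
  horizon <- as.integer(horizon)
  if (horizon < 2L) stop("`horizon` must be >= 2")
  if (horizon > prior$d_max) {
    stop("`horizon` exceeds d_max = ", prior$d_max,
         "; truncation would corrupt the trajectory")
  }
  d_max <- prior$d_max
  # joint over (state, duration); row 1 = non-reversal, row 2 = reversal
  joint <- rbind(prior$pmf, 0)
  delta_tau <- numeric(horizon - 1L)
  for (tau in 2:horizon) {
    theta <- sum(joint[1L, ])
    # mass flipping out of the non-reversal state this step
    delta_tau[tau - 1L] <- if (theta > 0) joint[1L, 1L] / theta else NA_real_
    joint <- propagate_joint(joint, prior$pmf)
  }
  delta_tau
}

# One step of the deterministic-countdown semi-Markov chain:
# d > 1: state kept, counter decremented; d = 1: state flipped, counter ~ pmf.
propagate_joint <- function(joint, pmf) {
  d_max <- ncol(joint)
  out <- matrix(0, 2L, d_max)
  out[, 1:(d_max - 1L)] <- joint[, 2:d_max]
  out <- out + joint[2:1, 1L] %o% pmf
  out / sum(out)
}

#' Serialize a duration prior to JSON
#'
#' @param prior A [duration_prior()].
#' @param path Optional file path; if omitted the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
prior_to_json <- function(prior, path = NULL) {
  stopifnot(inherits(prior, "duration_prior"))
  js <- jsonlite::toJSON(
    list(mu = prior$mu, sigma = prior$sigma, d_max = prior$d_max),
    auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a duration prior from JSON
#'
#' @param x A JSON string or a path to a JSON file with fields `mu`, `sigma`
#'   and `d_max`.
#' @return A [duration_prior()].
#' @export
prior_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  duration_prior(mu = obj$mu, sigma = obj$sigma, d_max = obj$d_max)
}
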