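#' Agent specification presets
#'
#' Named parameter bundles for the four agent types studied in the
#' simulation experiments:
#' \describe{
#'   \item{`iri`}{ED-HMM agent with geometric (maximal-variance,
#'     `sigma = mu (mu - 1)`) duration prior: expects reversals at irregular
#'     intervals.}
#'   \item{`rri`}{ED-HMM agent with low-variance duration prior
#'     (`sigma = mu` by default): expects reversals at semi-regular
#'     intervals.}
#'   \item{`su_rw`}{single-update Rescorla-Wagner, `alpha = 0.25`,
#'     `kappa = 0`.}
#'   \item{`du_rw`}{dual-update Rescorla-Wagner, `alpha = 0.25`,
#'     `kappa = 1`.}
#' }
#' ED-HMM agents are initialized with Beta pseudo-counts `(8, 2)` / `(2, 8)`
#' and an unknown starting configuration (`theta0 = 0.5`); RW agents start
#' from `V = (0, 0)`.
#'
#' @param type One of `"iri"`, `"rri"`, `"su_rw"`, `"du_rw"`.
#' @param mu,sigma Duration-prior moments for ED-HMM agents. `sigma` defaults
#'   to `mu (mu - 1)` for `iri` and `mu` for `rri`; the model-identification
#'   experiments use an `rri` preset with `sigma = 120`.
#' @param alpha,kappa Rescorla-Wagner parameters.
#' @param d_max Duration-grid truncation for ED-HMM agents.
#' @param a0_A,b0_A,a0_B,b0_B,theta0 ED-HMM initialization.
#' @param V0 RW initial values.
#' @return An object of class `agent_spec`.
#' @export
#' @examples
#' agent_spec("rri")               # sigma = mu = 20
#' agent_spec("rri", sigma = 120)  # identification-experiment preset
agent_spec <- function(type = c("iri", "rri", "su_rw", "du_rw"),
                       mu = 20, sigma = NULL, alpha = 0.25, kappa = NULL,
                       d_max = 200L, a0_A = 8, b0_A = 2, a0_B = 2, b0_B = 8,
                       theta0 = 0.5, V0 = c(0, 0)) {
  type <- match.arg(type)
  if (type %in% c("iri", "rri")) {
    if (is.null(sigma)) sigma <- if (type == "iri") mu * (mu - 1) else mu
    spec <- list(type = type, family = "edhmm", mu = mu, sigma = sigma,
                 d_max = as.integer(d_max), a0_A = a0_A, b0_A = b0_A,
                 a0_B = a0_B, b0_B = b0_B, theta0 = theta0)
  } else {
    if (is.null(kappa)) kappa <- if (type == "du_rw") 1 else 0
    spec <- list(type = type, family = "rl", alpha = alpha, kappa = kappa,
                 V0 = V0)
  }
  structure(spec, class = "agent_spec")
}

#' Instantiate a fresh agent from a specification
#'
#' @param spec An [agent_spec()].
#' @return An `edhmm_agent` or `rw_agent` in its initial state.
#' @export
spawn_agent <- function(spec) {
  stopifnot(inherits(spec, "agent_spec"))
  if (spec$family == "edhmm") {
    edhmm_agent(duration_prior(mu = spec$mu, sigma = spec$sigma,
                               d_max = spec$d_max),
                a0_A = spec$a0_A, b0_A = spec$b0_A,
                a0_B = spec$a0_B, b0_B = spec$b0_B, theta0 = spec$theta0)
  } else {
    rw_agent(alpha = spec$alpha, kappa = spec$kappa, V0 = spec$V0)
  }
}

update_agent <- function(agent, choice, outcome) {
  if (inherits(agent, "edhmm_agent")) {
    agent_step(agent, choice, outcome)
  } else {
    du_rw_update(agent, choice, outcome)
  }
}

#' Simulate one task block
#'
#' Per-trial loop: the agent's expected choice values are mapped to an action
#' (greedy or sampled softmax), an outcome is drawn from the schedule, and
#' the agent's beliefs/values are updated.
#'
#' @param spec An [agent_spec()] (a fresh agent is spawned) or an
#'   already-instantiated agent.
#' @param schedule A `task_schedule`.
#' @param params A [response_params()]; ignored when `mode = "greedy"`.
#'   The simulation experiments default to sampled softmax responses with
#'   moderate precision (`beta = 5`, no bias), which calibrates the agents'
#'   absolute performance levels; see the methods vignette.
#' @param mode `"sample"` (default) or `"greedy"`.
#' @param subject Subject/block identifier placed in the dataset.
#' @param record_trajectory If `TRUE`, attach a per-trial data frame of
#'   internal beliefs (`theta`, Beta parameters) or values.
#' @return List with `data` (a [behavioral_dataset()]), `performance`
#'   (fraction of trials on which the chosen option was the high-probability
#'   one) and optionally `trajectory`. Uses the current RNG state.
#' @export
run_block <- function(spec, schedule, params = response_params(beta = 5),
                      mode = c("sample", "greedy"), subject = "sim",
                      record_trajectory = FALSE) {
  mode <- match.arg(mode)
  agent <- if (inherits(spec, "agent_spec")) spawn_agent(spec) else spec
  n <- schedule$n_trials
  choices <- character(n)
  outcomes <- integer(n)
  traj <- if (record_trajectory) vector("list", n) else NULL
  for (t in seq_len(n)) {
    values <- expected_choice_values(agent)
    ch <- select_action(values, params, mode)
    o <- sample_outcome(schedule, t, ch)
    choices[t] <- ch
    outcomes[t] <- o
    if (record_trajectory) {
      traj[[t]] <- if (inherits(agent, "edhmm_agent")) {
        data.frame(trial = t, theta = theta_tilde(agent),
                   a_A = unname(agent$a["A"]), b_A = unname(agent$b["A"]),
                   a_B = unname(agent$a["B"]), b_B = unname(agent$b["B"]))
      } else {
        data.frame(trial = t, V_A = unname(agent$V["A"]),
                   V_B = unname(agent$V["B"]))
      }
    }
    agent <- update_agent(agent, ch, o)
  }
  data <- behavioral_dataset(subject, choices, outcomes, schedule)
  out <- list(data = data, performance = mean(data$correct))
  if (record_trajectory) out$trajectory <- do.call(rbind, traj)
  out
}

#' Environment presets for the simulation experiments
#'
#' `"irregular"`: between-reversal intervals drawn from a geometric
#' distribution with mean 20; `"semiregular"`: intervals drawn from a
#' negative binomial with mean 20 and variance 20; `"experimental"`: the
#' fixed block of [experimental_schedule()].
#'
#' @param environment Environment name.
#' @param n_trials Block length for the sampled environments.
#' @param p_high Reward probability of the better option.
#' @param d_max Truncation of the sampling prior.
#' @return A function `()` returning a freshly sampled (or the fixed)
#'   `task_schedule`.
#' @export
environment_sampler <- function(environment = c("irregular", "semiregular",
                                                "experimental"),
                                n_trials = 160L, p_high = 0.8, d_max = 200L) {
  environment <- match.arg(environment)
  if (environment == "experimental") {
    sched <- experimental_schedule(p_high = p_high)
    return(function() sched)
  }
  sigma <- if (environment == "irregular") 20 * 19 else 20
  prior <- duration_prior(mu = 20, sigma = sigma, d_max = d_max)
  function() sample_schedule(prior, n_trials = n_trials, p_high = p_high)
}

#' Performance experiment over repeated task blocks
#'
#' Runs each agent specification through `n_blocks` independent blocks of an
#' environment (fresh agent state per block; fresh schedule sample for the
#' stochastic environments, the fixed schedule for `"experimental"`) and
#' collects per-block performance and per-trial correct-choice indicators.
#'
#' @param specs A named list of [agent_spec()]s (a single spec is accepted).
#' @param environment An environment name understood by
#'   [environment_sampler()], or a function returning a `task_schedule`.
#' @param n_blocks Number of simulated blocks per agent.
#' @param seed Integer seed; every source of randomness in the experiment
#'   flows from it.
#' @param params,mode Response model passed to [run_block()].
#' @return An object of class `simulation_result`: list with per-agent
#'   entries holding `performance` (length `n_blocks`), `correct`
#'   (`n_blocks x n_trials` 0/1 matrix), `reversal_trials` (per-block list),
#'   plus the experiment `config`.
#' @export
performance_experiment <- function(specs, environment = "semiregular",
                                   n_blocks = 1000L, seed = 1L,
                                   params = response_params(beta = 5),
                                   mode = "sample") {
  if (inherits(specs, "agent_spec")) specs <- list(agent = specs)
  if (is.null(names(specs)) || any(names(specs) == "")) {
    names(specs) <- vapply(specs, function(s) s$type, character(1))
  }
  sampler <- if (is.function(environment)) environment else
    environment_sampler(environment)
  set.seed(seed)
  agents <- lapply(specs, function(spec) {
    perf <- numeric(n_blocks)
    correct <- NULL
    revs <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      sched <- sampler()
      res <- run_block(spec, sched, params = params, mode = mode,
                       subject = paste0("block", b))
      perf[b] <- res$performance
      if (is.null(correct)) correct <- matrix(0L, n_blocks, sched$n_trials)
      correct[b, ] <- res$data$correct
      revs[[b]] <- sched$reversal_trials
    }
    list(performance = perf, correct = correct, reversal_trials = revs)
  })
  structure(
    list(agents = agents,
         config = list(environment = if (is.function(environment))
           "custom" else environment, n_blocks = n_blocks, seed = seed,
           mode = mode)),
    class = "simulation_result"
  )
}

#' Performance quartiles of a simulation experiment
#'
#' @param result A `simulation_result`.
#' @return Data frame with one row per agent and the 25/50/75 performance
#'   percentiles across blocks.
#' @export
performance_quartiles <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  rows <- lapply(names(result$agents), function(nm) {
    q <- stats::quantile(result$agents[[nm]]$performance,
                         c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(agent = nm, q25 = q[1], median = q[2], q75 = q[3])
  })
  do.call(rbind, rows)
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Simulation result: %d blocks, environment \"%s\"\n",
              x$config$n_blocks, x$config$environment))
  print(performance_quartiles(x), row.names = FALSE)
  invisible(x)
}

#' Reversal-locked adaptation curve
#'
#' Average probability of a correct choice as a function of the trial offset
#' from a reversal, pooled over all reversal events of all blocks. Offset 0
#' is the first trial governed by the new contingencies; negative offsets are
#' pre-reversal trials.
#'
#' @param result A `simulation_result`.
#' @param agent Name of the agent entry (defaults to the first).
#' @param window Integer vector `c(before, after)` of offsets to cover.
#' @return Data frame with columns `offset`, `p_correct`, `n_events`.
#' @export
reversal_locked_average <- function(result, agent = NULL,
                                    window = c(-10L, 15L)) {
  stopifnot(inherits(result, "simulation_result"))
  if (is.null(agent)) agent <- names(result$agents)[1L]
  res <- result$agents[[agent]]
  if (is.null(res)) stop("unknown agent: ", agent)
  n_trials <- ncol(res$correct)
  offsets <- seq.int(window[1L], window[2L])
  if (window[1L] < -(n_trials - 1L) || window[2L] > n_trials - 1L) {
    warning("window exceeds the block length; truncating to available trials")
    offsets <- offsets[offsets > -n_trials & offsets < n_trials]
  }
  sums <- numeric(length(offsets))
  counts <- integer(length(offsets))
  for (b in seq_len(nrow(res$correct))) {
    for (t0 in res$reversal_trials[[b]]) {
      tr <- t0 + offsets
      ok <- tr >= 1L & tr <= n_trials
      sums[ok] <- sums[ok] + res$correct[b, tr[ok]]
      counts[ok] <- counts[ok] + 1L
    }
  }
  if (all(counts == 0L)) stop("no reversal events in the result")
  data.frame(offset = offsets, p_correct = sums / pmax(counts, 1L),
             n_events = counts)
}

#' Generate a model-identification corpus
#'
#' Simulates behavioral blocks on the fixed experimental schedule, half from
#' ED-HMM agents (alternating IRI and RRI with `sigma = 120`) and half from
#' reinforcement-learning agents (alternating SU-RW and DU-RW), for
#' estimating the model-family confusion matrix. Responses are sampled from
#' the softmax response model so the generating process matches the response
#' likelihood used when fitting.
#'
#' @param n_blocks Number of blocks (multiple of 4 recommended; agent types
#'   are cycled).
#' @param seed Integer seed.
#' @param params Response parameters used to sample choices.
#' @param mode `"sample"` (default) or `"greedy"`.
#' @return List of entries `list(data, agent_type, family)` with `family` in
#'   `{"edhmm", "rl"}`.
#' @export
generate_confusion_corpus <- function(n_blocks = 100L, seed = 1L,
                                      params = response_params(beta = 5),
                                      mode = "sample") {
  types <- rep(c("iri", "su_rw", "rri", "du_rw"), length.out = n_blocks)
  specs <- list(
    iri = agent_spec("iri"),
    rri = agent_spec("rri", sigma = 120),
    su_rw = agent_spec("su_rw"),
    du_rw = agent_spec("du_rw")
  )
  sched <- experimental_schedule()
  set.seed(seed)
  lapply(seq_len(n_blocks), function(b) {
    type <- types[b]
    res <- run_block(specs[[type]], sched, params = params, mode = mode,
                     subject = sprintf("block%03d", b))
    list(data = res$data, agent_type = type,
         family = specs[[type]]$family)
  })
}
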