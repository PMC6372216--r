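#' Response model parameters
#'
#' Softmax-with-bias mapping from expected choice values to choice
#' probabilities: `p(c) propto exp(beta V~_c + log p0(c))`. The response
#' precision `beta` scales how deterministically higher-valued options are
#' chosen (`beta = 0` reduces to the bias alone); the bias is the prior
#' probability of choosing option A. Within the expected-free-energy account
#' the utility weight is absorbed into `beta`, and the per-trial information
#' gain is neglected (a single outcome is barely informative about the hidden
#' reversal moment), so choices are driven by expected utility alone.
#'
#' @param beta Response precision, `>= 0`; `Inf` is permitted and equivalent
#'   to greedy selection.
#' @param bias_A Prior probability of choosing A, in (0, 1).
#' @return Object of class `response_params`.
#' @export
response_params <- function(beta = 1, bias_A = 0.5) {
  stopifnot(beta >= 0, bias_A > 0, bias_A < 1)
  structure(list(beta = beta, bias_A = bias_A), class = "response_params")
}

#' Choice probabilities from expected values
#'
#' @param values Named numeric vector `c(A = , B = )` of expected choice
#'   values (see [expected_choice_values()]).
#' @param params A [response_params()].
#' @return Named probabilities `c(A = , B = )` summing to 1.
#' @export
#' @examples
#' response_probabilities(c(A = 0.5, B = -0.5), response_params(beta = 1))
response_probabilities <- function(values, params) {
  if (is.infinite(params$beta)) {
    dv <- values[["A"]] - values[["B"]]
    p_a <- if (dv > 0) 1 else if (dv < 0) 0 else 0.5
    return(c(A = p_a, B = 1 - p_a))
  }
  logits <- c(A = params$beta * values[["A"]] + log(params$bias_A),
              B = params$beta * values[["B"]] + log(1 - params$bias_A))
  logits <- logits - max(logits)
  p <- exp(logits)
  p / sum(p)
}

#' Select an action
#'
#' Greedy mode returns the option with the larger expected value (ties broken
#' uniformly at random); sampling mode draws from the softmax probabilities.
#'
#' @inheritParams response_probabilities
#' @param mode `"greedy"` or `"sample"`.
#' @return `"A"` or `"B"`. Uses the current RNG state (also for greedy
#'   tie-breaks).
#' @export
select_action <- function(values, params = response_params(),
                          mode = c("greedy", "sample")) {
  mode <- match.arg(mode)
  if (mode == "greedy") {
    dv <- values[["A"]] - values[["B"]]
    if (dv > 0) return("A")
    if (dv < 0) return("B")
    return(if (stats::runif(1L) < 0.5) "A" else "B")
  }
  p <- response_probabilities(values, params)
  if (stats::runif(1L) < p[["A"]]) "A" else "B"
}
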