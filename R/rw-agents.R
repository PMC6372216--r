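#' Rescorla-Wagner agent state
#'
#' Baseline reinforcement-learning agents for the reversal-learning task.
#' The single-update (SU-RW) rule moves only the chosen option's value toward
#' the observed outcome; the dual-update (DU-RW) rule additionally moves the
#' unchosen option's value toward the opposite outcome (a fictive prediction
#' error), scaled by the coupling `kappa`. With `kappa = 0` the two rules
#' coincide.
#'
#' @param alpha Learning rate in `[0, 1]`.
#' @param kappa Fictive-update coupling in `[0, 1]` (ignored by
#'   [su_rw_update()]).
#' @param V0 Initial values, length-2 numeric in `[-1, 1]` (options A, B).
#' @return An object of class `rw_agent` with fields `V` (named values),
#'   `alpha`, `kappa`.
#' @export
#' @examples
#' ag <- rw_agent(alpha = 0.25, kappa = 1)
#' du_rw_update(ag, "A", 1)$V  # c(A = 0.25, B = -0.25)
rw_agent <- function(alpha, kappa = 0, V0 = c(0, 0)) {
  stopifnot(alpha >= 0, alpha <= 1, kappa >= 0, kappa <= 1,
            length(V0) == 2L, all(abs(V0) <= 1))
  structure(
    list(V = c(A = V0[[1L]], B = V0[[2L]]), alpha = alpha, kappa = kappa),
    class = "rw_agent"
  )
}

#' @export
print.rw_agent <- function(x, ...) {
  cat(sprintf("RW agent: V_A = %.3f, V_B = %.3f (alpha = %.3g, kappa = %.3g)\n",
              x$V["A"], x$V["B"], x$alpha, x$kappa))
  invisible(x)
}

#' Single-update Rescorla-Wagner rule
#'
#' `V_c <- V_c + alpha (o - V_c)`; the unchosen option is untouched.
#'
#' @param state An [rw_agent()].
#' @param choice `"A"` or `"B"`.
#' @param outcome `-1` or `+1`.
#' @return The updated agent.
#' @export
su_rw_update <- function(state, choice, outcome) {
  if (!outcome %in% c(-1, 1)) stop("`outcome` must be -1 or +1")
  state$V[choice] <- state$V[choice] + state$alpha * (outcome - state$V[choice])
  state
}

#' Dual-update Rescorla-Wagner rule
#'
#' Factual update of the chosen option as in [su_rw_update()], plus a fictive
#' update of the unchosen option toward the opposite outcome:
#' `V_u <- V_u + kappa alpha (-o - V_u)`.
#'
#' @inheritParams su_rw_update
#' @return The updated agent.
#' @export
du_rw_update <- function(state, choice, outcome) {
  state <- su_rw_update(state, choice, outcome)
  oth <- other_option(choice)
  state$V[oth] <- state$V[oth] +
    state$kappa * state$alpha * (-outcome - state$V[oth])
  state
}
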