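# Governing state-update equations as pure functions. The compiled trial
# runner re-implements these maps step-for-step; tests pin the two paths
# against each other and against the closed-form solutions below.

#' Queen rest duration from her internal state
#'
#' The queen's inactive period shrinks exponentially with her internal state:
#' `t_r = trconstant * exp(-delta * Iq)`, rounded to the nearest integer step
#' (half away from zero) and floored at 1 so that a rest can never have zero
#' length, which would merge two patrol bouts into one.
#'
#' @param iq Queen internal state, a non-negative scalar (vectorised).
#' @param params A [model_params()] object.
#' @return Integer number of rest steps in `[1, trconstant]`.
#' @examples
#' p <- model_params()
#' rest_time(0, p)    # 100
#' rest_time(0.1, p)  # 14
#' @export
rest_time <- function(iq, params = model_params()) {
  if (any(!is.finite(iq)) || any(iq < 0))
    stop("queen internal state must be finite and non-negative", call. = FALSE)
  tr <- params$trconstant * exp(-params$delta * iq)
  pmax(1L, as.integer(floor(tr + 0.5)))
}

#' One-step update of the queen's internal state
#'
#' Without contact the state is damped by `(1 - epsilon)`; a queen-worker
#' contact adds `alpha` times the contacted worker's (pre-update) internal
#' state. At most one contact contributes per step.
#'
#' @param iq Queen internal state (non-negative scalar).
#' @param contacted_worker_iw Internal state of the worker contacted this
#'   step, or `NULL` if no contact occurred.
#' @inheritParams rest_time
#' @return The updated queen internal state.
#' @export
update_queen <- function(iq, contacted_worker_iw = NULL,
                         params = model_params()) {
  if (!is.finite(iq) || iq < 0)
    stop("queen internal state must be finite and non-negative", call. = FALSE)
  out <- (1 - params$epsilon) * iq
  if (!is.null(contacted_worker_iw)) {
    if (!is.finite(contacted_worker_iw) || contacted_worker_iw < 0 ||
        contacted_worker_iw > 1)
      stop("contacted worker state must lie in [0, 1]", call. = FALSE)
    out <- out + params$alpha * contacted_worker_iw
  }
  out
}

#' One-step update of a worker's internal state
#'
#' Without contact the state follows `(1 - beta) * Iw + gamma`, drifting
#' toward the fixed point `gamma / beta`. A queen contact additionally
#' removes a fraction `kappa` of the pre-update state (about a 90% drop at
#' defaults). When `feedback_enabled` is `FALSE` the kappa term is always
#' omitted: contact has no effect on the worker.
#'
#' @param iw Worker internal state in `[0, 1]` (vectorised).
#' @param contacted_by_queen Logical: did the queen contact this worker this
#'   step?
#' @inheritParams rest_time
#' @return The updated worker internal state.
#' @export
update_worker <- function(iw, contacted_by_queen = FALSE,
                          params = model_params()) {
  if (any(!is.finite(iw)) || any(iw < 0) || any(iw > 1))
    stop("worker internal state must lie in [0, 1]", call. = FALSE)
  r <- effective_rates(params)
  k <- if (isTRUE(contacted_by_queen) && params$feedback_enabled)
    params$kappa else 0
  (1 - r$beta - k) * iw + r$gamma
}

#' Contact-free fixed point of the worker dynamics
#'
#' Iterating the contact-free worker update converges to `gamma / beta`
#' (the rate multiplier cancels). With defaults this is exactly 1: the state
#' scale is calibrated so an undisturbed worker approaches full ovary
#' development.
#'
#' @inheritParams rest_time
#' @return The asymptotic worker internal state.
#' @export
worker_fixed_point <- function(params = model_params()) {
  if (params$beta <= 0)
    stop("worker dynamics diverge when beta = 0", call. = FALSE)
  params$gamma / params$beta
}

#' Upper bound on the queen's internal state
#'
#' Under the most extreme schedule — one contact per step, always with a
#' worker at the state ceiling of 1 — the queen's state converges to
#' `alpha / epsilon` from below. Used as a test oracle; the realised queen
#' state in simulations stays well under it.
#'
#' @inheritParams rest_time
#' @return The supremum of the queen internal state.
#' @export
queen_steadystate_bound <- function(params = model_params()) {
  if (params$epsilon <= 0)
    stop("queen dynamics diverge when epsilon = 0", call. = FALSE)
  params$alpha / params$epsilon
}

#' Closed-form worker trajectory for a fixed contact schedule
#'
#' The worker update is linear, so for any prescribed set of contact steps
#' the trajectory has a product/geometric-series form:
#' `Iw(t) = (prod of step coefficients up to t) * Iw(0) +
#'  gamma * sum over s < t of (prod of coefficients from s+1 to t)`.
#' This is evaluated non-iteratively (cumulative products) and serves as the
#' independent oracle for the step-by-step engine.
#'
#' @param iw0 Initial worker internal state.
#' @param n_steps Number of steps to evaluate.
#' @param contact_steps Integer vector of step indices in `1..n_steps` at
#'   which a queen contact occurs.
#' @inheritParams rest_time
#' @return Numeric vector of length `n_steps + 1` (trajectory including t=0).
#' @export
worker_closed_form <- function(iw0, n_steps, contact_steps = integer(),
                               params = model_params()) {
  r <- effective_rates(params)
  k <- if (params$feedback_enabled) params$kappa else 0
  a <- rep(1 - r$beta, n_steps)
  a[contact_steps] <- 1 - r$beta - k
  # P[t] = prod(a[1..t]); Iw(t) = P[t]*iw0 + gamma * sum_{s=1..t} P[t]/P[s]
  P <- cumprod(a)
  inv <- cumsum(1 / P)
  c(iw0, P * iw0 + r$gamma * P * inv)
}
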