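#' Model parameters
#'
#' Constructs the full set of constants governing the internal-state dynamics
#' and the contact rules, with defaults equal to the model's standard values.
#' This object is the single source of truth for every rate constant; all
#' simulation and metric functions take it (inside a [sim_config()]) rather
#' than reading globals.
#'
#' @param trconstant Maximum rest time in steps (default 100). The queen's
#'   rest shrinks below this as her internal state rises; workers always rest
#'   exactly this long.
#' @param taconstant Active (patrol) time in steps (default 20), fixed for
#'   queen and workers.
#' @param delta Rest-time sensitivity of the queen to her internal state
#'   (default 20): rest time is `trconstant * exp(-delta * Iq)`.
#' @param epsilon Per-step damping fraction of the queen's internal state
#'   (default 0.01).
#' @param alpha Per-contact gain on the queen's internal state, multiplied by
#'   the contacted worker's state (default 0.1).
#' @param beta Per-step damping fraction of a worker's internal state
#'   (default 1e-4).
#' @param gamma Per-step autonomous increment of a worker's internal state
#'   (default 1e-4). The contact-free dynamics converge to `gamma / beta`.
#' @param kappa Per-contact suppression fraction of a worker's internal state
#'   (default 0.9009, i.e. roughly a 90% drop per queen contact).
#' @param feedback_enabled If `FALSE`, queen contact has no effect on worker
#'   states (the kappa term is dropped everywhere); queen dynamics, movement
#'   and logging are unchanged. This is the no-feedback control.
#' @param worker_rate_multiplier Dimensionless factor applied to both `beta`
#'   and `gamma` (default 1; 10 reproduces the fast-maturation variant).
#' @param neighbourhood Contact neighbourhood on the lattice: `"orthogonal"`
#'   (the four cells at centre-to-centre distance of one body length, the
#'   default) or `"chebyshev"` (all eight surrounding cells, for sensitivity
#'   analysis).
#'
#' @return An object of class `model_params` (a validated list).
#' @examples
#' p <- model_params()
#' worker_fixed_point(p)  # 1
#' @export
model_params <- function(trconstant = 100L,
                         taconstant = 20L,
                         delta = 20.0,
                         epsilon = 0.01,
                         alpha = 0.1,
                         beta = 1e-4,
                         gamma = 1e-4,
                         kappa = 0.9009,
                         feedback_enabled = TRUE,
                         worker_rate_multiplier = 1,
                         neighbourhood = c("orthogonal", "chebyshev")) {
  neighbourhood <- match.arg(neighbourhood)
  p <- list(
    trconstant = as.integer(trconstant),
    taconstant = as.integer(taconstant),
    delta = as.numeric(delta),
    epsilon = as.numeric(epsilon),
    alpha = as.numeric(alpha),
    beta = as.numeric(beta),
    gamma = as.numeric(gamma),
    kappa = as.numeric(kappa),
    feedback_enabled = isTRUE(feedback_enabled),
    worker_rate_multiplier = as.numeric(worker_rate_multiplier),
    neighbourhood = neighbourhood
  )
  class(p) <- "model_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "model_params"))
  num <- c("trconstant", "taconstant", "delta", "epsilon", "alpha",
           "beta", "gamma", "kappa", "worker_rate_multiplier")
  for (f in num) {
    v <- p[[f]]
    if (length(v) != 1L || !is.finite(v))
      stop("parameter '", f, "' must be a single finite number", call. = FALSE)
  }
  if (p$trconstant < 1L || p$taconstant < 1L)
    stop("trconstant and taconstant must be at least 1 step", call. = FALSE)
  if (p$delta <= 0 || p$epsilon <= 0 || p$alpha < 0 ||
      p$beta <= 0 || p$gamma < 0 || p$kappa < 0)
    stop("rate constants must be positive (alpha, gamma, kappa may be 0)",
         call. = FALSE)
  if (p$epsilon >= 1) stop("epsilon must be < 1", call. = FALSE)
  if (p$beta >= 1) stop("beta must be < 1", call. = FALSE)
  if (p$kappa > 1) stop("kappa must be <= 1", call. = FALSE)
  if (p$worker_rate_multiplier <= 0)
    stop("worker_rate_multiplier must be positive", call. = FALSE)
  # contraction guard: the worker map's contact-step coefficient must stay in
  # (-1, 1) or states could oscillate unboundedly
  if (1 - p$beta * p$worker_rate_multiplier - p$kappa <= -1)
    stop("1 - beta*multiplier - kappa must exceed -1", call. = FALSE)
  invisible(p)
}

# beta and gamma with the rate multiplier applied; everything downstream of
# the constructor uses these effective values
effective_rates <- function(p) {
  list(beta = p$beta * p$worker_rate_multiplier,
       gamma = p$gamma * p$worker_rate_multiplier)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Model parameters\n")
  cat(sprintf("  rest/active times : trconstant=%d, taconstant=%d steps\n",
              x$trconstant, x$taconstant))
  cat(sprintf("  queen dynamics    : delta=%g, epsilon=%g, alpha=%g\n",
              x$delta, x$epsilon, x$alpha))
  cat(sprintf("  worker dynamics   : beta=%g, gamma=%g, kappa=%g (x%g)\n",
              x$beta, x$gamma, x$kappa, x$worker_rate_multiplier))
  cat(sprintf("  feedback=%s, neighbourhood=%s\n",
              x$feedback_enabled, x$neighbourhood))
  invisible(x)
}

#' Simulation configuration
#'
#' Bundles the model parameters with the trial-level settings: colony size,
#' initial conditions and the termination criterion.
#'
#' @param n_workers Number of workers (the queen is added on top).
#' @param params A [model_params()] object.
#' @param termination `"all_contacted"` (default; the trial ends once the
#'   queen has contacted every worker at least once) or `"fixed_horizon"`
#'   (run exactly `max_steps` steps).
#' @param max_steps Horizon for `"fixed_horizon"` termination (default 300).
#' @param queen_initial_state Queen's internal state at t = 0 (default 0.1;
#'   0.8 reproduces the high-initialisation robustness variant).
#' @param queen_initial_rest `"max"` (default): if the queen starts at rest,
#'   her first rest lasts the full `trconstant`; `"random"`: drawn uniformly
#'   from 1..trconstant.
#' @param record_states Record the full worker-state matrix (one row per
#'   recorded step)? Needed by [state_distribution()]; turn off for long
#'   sweeps where only summary series are used.
#' @param state_stride Record worker states every this many steps
#'   (default 1).
#' @param safety_cap Hard upper bound on steps for `"all_contacted"` runs;
#'   hitting it raises an `antpatrol_incomplete_trial` error carrying the
#'   partial logs.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_workers = 20L,
                       params = model_params(),
                       termination = c("all_contacted", "fixed_horizon"),
                       max_steps = 300L,
                       queen_initial_state = 0.1,
                       queen_initial_rest = c("max", "random"),
                       record_states = TRUE,
                       state_stride = 1L,
                       safety_cap = 1e7) {
  termination <- match.arg(termination)
  queen_initial_rest <- match.arg(queen_initial_rest)
  validate_params(params)
  n_workers <- as.integer(n_workers)
  if (is.na(n_workers) || n_workers < 1L)
    stop("n_workers must be a positive integer", call. = FALSE)
  if (queen_initial_state < 0)
    stop("queen_initial_state must be non-negative", call. = FALSE)
  max_steps <- as.integer(max_steps)
  if (termination == "fixed_horizon" && max_steps < 1L)
    stop("max_steps must be positive for fixed_horizon termination",
         call. = FALSE)
  structure(list(
    n_workers = n_workers,
    params = params,
    termination = termination,
    max_steps = max_steps,
    queen_initial_state = queen_initial_state,
    queen_initial_rest = queen_initial_rest,
    record_states = isTRUE(record_states),
    state_stride = as.integer(state_stride),
    safety_cap = as.numeric(safety_cap)
  ), class = "sim_config")
}
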