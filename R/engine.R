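# Trial orchestration: initialisation, single-step advancement, full runs.
# The per-step schedule lives in src/engine.cpp; these wrappers own the
# world representation and the TrialResult assembly.

cpp_par <- function(params) {
  r <- effective_rates(params)
  list(trconstant = params$trconstant,
       taconstant = params$taconstant,
       delta = params$delta,
       epsilon = params$epsilon,
       alpha = params$alpha,
       beta = r$beta,
       gamma = r$gamma,
       kappa = params$kappa,
       feedback_enabled = params$feedback_enabled,
       chebyshev = identical(params$neighbourhood, "chebyshev"))
}

#' Initialise a trial
#'
#' Places the queen and `n_workers` workers on distinct random cells of a
#' density-matched nest, draws worker internal states uniformly from
#' (0, 0.5), sets the queen's internal state to its configured initial value
#' (0.1 by default), assigns every agent a random activity phase with a
#' timer drawn uniformly over that phase's full duration, and — under the
#' default convention — sets the queen's first rest, if she starts at rest,
#' to the full maximum rest time.
#'
#' The draw order under a given seed is fixed: placements (queen first),
#' worker internal states, activities (queen first), then phase timers.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed (calls `set.seed()` when given).
#' @return A `patrol_world` object holding agent states, occupancy and an
#'   empty log.
#' @export
initialize_trial <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  p <- config$params
  n <- config$n_workers

  grid <- grid_for_colony(n, p)
  placed <- place_agents(grid, n + 1L)  # id 1 = queen, 2..n+1 = workers
  pos <- placed$positions

  iw <- runif(n) * 0.5
  act <- sample(c(TRUE, FALSE), n + 1L, replace = TRUE)

  q_active <- act[1L]
  q_timer <- if (q_active) {
    sample.int(p$taconstant, 1L)
  } else if (config$queen_initial_rest == "max") {
    p$trconstant
  } else {
    sample.int(p$trconstant, 1L)
  }
  w_timer <- integer(n)
  for (j in seq_len(n)) {
    w_timer[j] <- if (act[j + 1L]) sample.int(p$taconstant, 1L)
    else sample.int(p$trconstant, 1L)
  }

  world <- list(
    config = config,
    side_cells = grid$side_cells,
    qx = pos$x[1L], qy = pos$y[1L],
    q_active = q_active, q_timer = q_timer,
    wx = pos$x[-1L], wy = pos$y[-1L],
    w_active = act[-1L], w_timer = w_timer,
    iq = config$queen_initial_state, iw = iw,
    last_contacted = 0L,
    contacted = logical(n),
    contact_counts = integer(n),
    step = 0L,
    # per-step logs; row 1 is t = 0
    log = list(iq = config$queen_initial_state,
               q_active = as.integer(q_active),
               mean_iw = mean(iw),
               ww = NA_integer_),
    events = data.frame(step = integer(0), worker = integer(0),
                        queen_active = logical(0),
                        worker_state_before = numeric(0)),
    states = if (config$record_states)
      matrix(iw, nrow = 1L, dimnames = NULL) else NULL,
    state_steps = if (config$record_states) 0L else integer(0),
    initial_iw = iw
  )
  class(world) <- "patrol_world"
  world
}

merge_cpp_result <- function(world, res) {
  for (f in c("qx", "qy", "q_active", "q_timer", "wx", "wy", "w_active",
              "w_timer", "iq", "iw", "last_contacted", "contacted",
              "contact_counts", "step"))
    world[[f]] <- res[[f]]
  world$log$iq <- c(world$log$iq, res$log_iq)
  world$log$q_active <- c(world$log$q_active, res$log_qact)
  world$log$mean_iw <- c(world$log$mean_iw, res$log_meaniw)
  world$log$ww <- c(world$log$ww, res$log_ww)
  if (length(res$ev_step)) {
    world$events <- rbind(world$events, data.frame(
      step = res$ev_step, worker = res$ev_worker,
      queen_active = as.logical(res$ev_qact),
      worker_state_before = res$ev_iw_before))
  }
  if (!is.null(world$states) && nrow(res$states)) {
    world$states <- rbind(world$states, res$states)
    world$state_steps <- c(world$state_steps, res$state_steps)
  }
  world
}

#' Advance a trial world by one or more steps
#'
#' Each step runs the fixed schedule: phase flips, shuffled movement of
#' active agents, contact detection (queen-worker, then worker-worker pair
#' counting), synchronous state updates from pre-step values, logging.
#' Repeated single-step calls and one multi-step call consume the RNG stream
#' identically, so they produce identical worlds.
#'
#' @param world A `patrol_world` from [initialize_trial()].
#' @param n_steps Number of steps to advance (default 1).
#' @return The advanced `patrol_world`.
#' @export
advance_step <- function(world, n_steps = 1L) {
  stopifnot(inherits(world, "patrol_world"))
  cfg <- world$config
  res <- sim_steps_cpp(world, cpp_par(cfg$params), as.integer(n_steps),
                       until_all = FALSE,
                       record_states = cfg$record_states,
                       state_stride = cfg$state_stride)
  merge_cpp_result(world, res)
}

#' Run one complete trial
#'
#' Initialises a world and advances it until termination: by default until
#' the queen has contacted every worker at least once; under
#' `termination = "fixed_horizon"`, for exactly `max_steps` steps. A hard
#' safety cap aborts pathological runs with an error of class
#' `antpatrol_incomplete_trial` carrying the partial world.
#'
#' @inheritParams initialize_trial
#' @return A `patrol_trial` object: the config snapshot, `termination_step`,
#'   a per-step `series` data frame (queen internal state, queen activity,
#'   mean worker state, worker-worker contact count), the queen-worker
#'   contact event log, per-worker contact counts, initial and final worker
#'   states, and (if recorded) the worker-state matrix.
#' @examples
#' tr <- run_trial(sim_config(n_workers = 5), seed = 1)
#' tr$termination_step
#' @export
run_trial <- function(config, seed = NULL) {
  world <- initialize_trial(config, seed)
  until_all <- config$termination == "all_contacted"
  cap <- if (until_all) as.integer(min(config$safety_cap, 2^31 - 2))
  else config$max_steps
  res <- sim_steps_cpp(world, cpp_par(config$params), cap,
                       until_all = until_all,
                       record_states = config$record_states,
                       state_stride = config$state_stride)
  world <- merge_cpp_result(world, res)
  if (until_all && !res$terminated) {
    cond <- structure(
      class = c("antpatrol_incomplete_trial", "error", "condition"),
      list(message = sprintf(
        "trial hit the safety cap of %d steps with %d of %d workers contacted",
        cap, res$n_contacted, config$n_workers),
        call = sys.call(), world = world))
    stop(cond)
  }
  as_patrol_trial(world)
}

as_patrol_trial <- function(world) {
  T <- world$step
  series <- data.frame(
    step = 0:T,
    queen_internal = world$log$iq,
    queen_active = as.logical(world$log$q_active),
    mean_worker_state = world$log$mean_iw,
    worker_contacts = c(NA_integer_, world$log$ww[-1L])
  )
  structure(list(
    config = world$config,
    termination_step = T,
    series = series,
    events = world$events,
    contact_counts = world$contact_counts,
    initial_worker_states = world$initial_iw,
    final_worker_states = world$iw,
    final_queen_state = world$iq,
    states = world$states,
    state_steps = world$state_steps
  ), class = "patrol_trial")
}

#' @export
print.patrol_trial <- function(x, ...) {
  cat(sprintf(
    "Patrol trial: N=%d, %d steps, %d queen contacts, mean worker state %.4f -> %.4f\n",
    x$config$n_workers, x$termination_step, nrow(x$events),
    mean(x$initial_worker_states), mean(x$final_worker_states)))
  invisible(x)
}

#' Extract the queen's patrol bouts
#'
#' A patrol bout is a maximal run of steps in which the queen is active.
#' Bout boundaries feed the patrol-frequency and rest-time statistics.
#'
#' @param trial A `patrol_trial`, or a logical vector of per-step queen
#'   activity.
#' @return Data frame with columns `start`, `end` (step indices, inclusive)
#'   and `length`; zero rows if the queen was never active.
#' @export
extract_patrol_bouts <- function(trial) {
  act <- if (inherits(trial, "patrol_trial"))
    trial$series$queen_active else as.logical(trial)
  if (!any(act))
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0)))
  r <- rle(act)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  # convert from series row index (1-based, row 1 = t 0) to step index
  off <- if (inherits(trial, "patrol_trial")) 2L else 1L
  data.frame(start = starts[keep] - off + 1L, end = ends[keep] - off + 1L,
             length = r$lengths[keep])
}
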