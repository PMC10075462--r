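# Hand-built worlds and trials with pinned agents, used to exercise single
# steps and metrics against analytically known outcomes.

# A patrol_world with agents at fixed cells. By default every agent is
# inactive with an effectively infinite phase timer, so nothing moves and
# contact geometry stays frozen across steps.
make_world <- function(side_cells, queen_xy, worker_xy, iw,
                       iq = 0.1, params = model_params(),
                       q_active = FALSE, w_active = NULL,
                       timers = 10000000L, record_states = TRUE) {
  n <- nrow(worker_xy)
  cfg <- sim_config(n_workers = n, params = params,
                    record_states = record_states)
  if (is.null(w_active)) w_active <- rep(FALSE, n)
  world <- list(
    config = cfg,
    side_cells = as.integer(side_cells),
    qx = as.integer(queen_xy[1]), qy = as.integer(queen_xy[2]),
    q_active = q_active, q_timer = as.integer(timers),
    wx = as.integer(worker_xy[, 1]), wy = as.integer(worker_xy[, 2]),
    w_active = w_active, w_timer = rep(as.integer(timers), n),
    iq = iq, iw = iw,
    last_contacted = 0L,
    contacted = logical(n),
    contact_counts = integer(n),
    step = 0L,
    log = list(iq = iq, q_active = as.integer(q_active),
               mean_iw = mean(iw), ww = NA_integer_),
    events = data.frame(step = integer(0), worker = integer(0),
                        queen_active = logical(0),
                        worker_state_before = numeric(0)),
    states = if (record_states) matrix(iw, nrow = 1L) else NULL,
    state_steps = if (record_states) 0L else integer(0),
    initial_iw = iw
  )
  class(world) <- "patrol_world"
  world
}

# A patrol_trial assembled directly from scripted logs (no simulation).
make_fake_trial <- function(n_workers, queen_active_series, events = NULL,
                            ww_counts = NULL, initial_iw = NULL,
                            final_iw = NULL) {
  T <- length(queen_active_series) - 1L
  if (is.null(events))
    events <- data.frame(step = integer(0), worker = integer(0),
                         queen_active = logical(0),
                         worker_state_before = numeric(0))
  if (is.null(ww_counts)) ww_counts <- rep(0L, T)
  if (is.null(initial_iw)) initial_iw <- rep(0.25, n_workers)
  if (is.null(final_iw)) final_iw <- rep(0.25, n_workers)
  structure(list(
    config = sim_config(n_workers = n_workers),
    termination_step = T,
    series = data.frame(
      step = 0:T,
      queen_internal = rep(0.1, T + 1L),
      queen_active = as.logical(queen_active_series),
      mean_worker_state = rep(mean(initial_iw), T + 1L),
      worker_contacts = c(NA_integer_, ww_counts)),
    events = events,
    contact_counts = tabulate(events$worker, nbins = n_workers),
    initial_worker_states = initial_iw,
    final_worker_states = final_iw,
    final_queen_state = 0.1,
    states = NULL,
    state_steps = integer(0)
  ), class = "patrol_trial")
}
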