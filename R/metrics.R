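# Summary statistics computed from trial logs: patrol effort, contact
# rates, and worker internal-state distributions, plus the across-N sweep
# aggregation with trend diagnostics.

#' Patrol statistics of the queen
#'
#' Patrol frequency is the number of patrol bouts divided by the trial
#' length (bouts per step); the raw bout count is reported alongside it.
#' Mean rest time averages the lengths of the inactive gaps strictly between
#' two bouts — the initial partial gap (before the first bout) and any
#' trailing gap are excluded, since their lengths are censored.
#'
#' @param trial A `patrol_trial` from [run_trial()].
#' @return One-row data frame: `n_bouts`, `patrol_frequency` (bouts/step),
#'   `mean_rest_time` (steps; `NA` with `rest_defined = FALSE` when fewer
#'   than two bouts exist).
#' @export
patrol_stats <- function(trial) {
  stopifnot(inherits(trial, "patrol_trial"))
  T <- trial$termination_step
  bouts <- extract_patrol_bouts(trial)
  nb <- nrow(bouts)
  freq <- if (T > 0) nb / T else 0
  if (nb >= 2L) {
    gaps <- bouts$start[-1L] - bouts$end[-nb] - 1L
    rest <- mean(gaps)
    defined <- TRUE
  } else {
    rest <- NA_real_
    defined <- FALSE
  }
  data.frame(n_bouts = nb, patrol_frequency = freq,
             mean_rest_time = rest, rest_defined = defined)
}

#' Contact rates
#'
#' Rates are event counts divided by step counts. The queen rate is
#' queen-worker contacts per step; the per-worker rate divides it by the
#' number of workers, so `per_worker_rate * N == queen_rate` identically.
#' Rest/patrol splits restrict both the numerator (the queen's activity at
#' the moment of contact) and the denominator (her inactive/active step
#' counts). Worker-worker rates count adjacent unordered pairs per step;
#' the per-worker version divides by N.
#'
#' @param trial A `patrol_trial`.
#' @return One-row data frame of rates (see Details).
#' @export
contact_rates <- function(trial) {
  stopifnot(inherits(trial, "patrol_trial"))
  T <- trial$termination_step
  if (T < 1L) stop("trial has no steps", call. = FALSE)
  N <- trial$config$n_workers
  act <- trial$series$queen_active[-1L]  # activity during steps 1..T
  n_active <- sum(act)
  n_rest <- T - n_active
  nq <- nrow(trial$events)
  nq_patrol <- sum(trial$events$queen_active)
  nq_rest <- nq - nq_patrol
  ww_total <- sum(trial$series$worker_contacts[-1L])
  rate_or_na <- function(count, denom) if (denom > 0) count / denom else NA_real_
  data.frame(
    queen_rate = nq / T,
    per_worker_rate = nq / T / N,
    queen_rate_patrol = rate_or_na(nq_patrol, n_active),
    per_worker_rate_patrol = rate_or_na(nq_patrol, n_active) / N,
    queen_rate_rest = rate_or_na(nq_rest, n_rest),
    per_worker_rate_rest = rate_or_na(nq_rest, n_rest) / N,
    worker_worker_rate = ww_total / T,
    per_worker_worker_rate = ww_total / T / N,
    n_active_steps = n_active, n_rest_steps = n_rest
  )
}

#' Pooled worker internal-state distribution over time
#'
#' Pools the recorded worker-state matrices of one or more trials on a
#' common time grid and histograms them per time point. Trials of unequal
#' length are truncated to the shortest recorded span (alignment is on
#' absolute step index; nothing is extrapolated).
#'
#' @param trials A `patrol_trial` or list of them, run with
#'   `record_states = TRUE` and identical `state_stride`.
#' @param bins Number of equal histogram bins on `[0, 1]` (default 50).
#' @param time_grid Optional integer vector of step indices to evaluate;
#'   defaults to all commonly recorded steps.
#' @return A `state_distribution` object: `time` (steps), `breaks`, a
#'   `density` matrix (time x bin, rows summing to 1), and per-time `mean`
#'   and `var` of the pooled states.
#' @export
state_distribution <- function(trials, bins = 50L, time_grid = NULL) {
  if (inherits(trials, "patrol_trial")) trials <- list(trials)
  if (length(trials) == 0L) stop("no trials supplied", call. = FALSE)
  for (tr in trials)
    if (is.null(tr$states))
      stop("trials must be run with record_states = TRUE", call. = FALSE)
  common <- Reduce(intersect, lapply(trials, function(tr) tr$state_steps))
  if (!is.null(time_grid)) {
    missing_t <- setdiff(time_grid, common)
    if (length(missing_t))
      stop("time grid steps not recorded in every trial: ",
           paste(utils::head(missing_t, 5L), collapse = ", "), call. = FALSE)
    common <- time_grid
  }
  common <- sort(common)
  breaks <- seq(0, 1, length.out = bins + 1L)
  dens <- matrix(0, length(common), bins)
  mu <- numeric(length(common))
  va <- numeric(length(common))
  for (i in seq_along(common)) {
    pooled <- unlist(lapply(trials, function(tr) {
      tr$states[match(common[i], tr$state_steps), ]
    }), use.names = FALSE)
    h <- tabulate(pmin(bins, pmax(1L, findInterval(
      pooled, breaks, rightmost.closed = TRUE))), nbins = bins)
    dens[i, ] <- h / length(pooled)
    mu[i] <- mean(pooled)
    va[i] <- stats::var(pooled)
  }
  structure(list(time = common, breaks = breaks, density = dens,
                 mean = mu, var = va, n_trials = length(trials)),
            class = "state_distribution")
}

#' @export
print.state_distribution <- function(x, ...) {
  cat(sprintf(
    "Worker state distribution: %d time points, %d bins, %d trial(s)\n",
    length(x$time), ncol(x$density), x$n_trials))
  cat(sprintf("  mean %.4f at t=%d -> %.4f at t=%d\n",
              x$mean[1L], x$time[1L],
              x$mean[length(x$mean)], x$time[length(x$time)]))
  invisible(x)
}

#' Tidy export of a state distribution
#'
#' @param x A `state_distribution`.
#' @return Data frame of (`time`, `bin_low`, `bin_high`, `density`) suitable
#'   for heatmap replots.
#' @export
as_tidy_distribution <- function(x) {
  stopifnot(inherits(x, "state_distribution"))
  bins <- ncol(x$density)
  data.frame(
    time = rep(x$time, each = bins),
    bin_low = rep(x$breaks[-(bins + 1L)], length(x$time)),
    bin_high = rep(x$breaks[-1L], length(x$time)),
    density = as.vector(t(x$density)))
}

trial_metric_row <- function(trial) {
  ps <- patrol_stats(trial)
  cr <- contact_rates(trial)
  cbind(
    data.frame(
      n_workers = trial$config$n_workers,
      termination_step = trial$termination_step,
      initial_mean_state = mean(trial$initial_worker_states),
      terminal_mean_state = mean(trial$final_worker_states)),
    ps[, c("n_bouts", "patrol_frequency", "mean_rest_time")],
    cr[, c("queen_rate", "per_worker_rate", "queen_rate_patrol",
           "queen_rate_rest", "worker_worker_rate",
           "per_worker_worker_rate")])
}

#' Aggregate a colony-size sweep
#'
#' Collapses per-trial metrics to per-colony-size mean and SD for every
#' patrol and contact-rate quantity plus the initial and terminal mean
#' worker states, and computes Spearman rank correlations of each per-N mean
#' against colony size as trend diagnostics.
#'
#' @param results Named list: one entry per colony size (names are the N
#'   values), each a list of `patrol_trial` objects.
#' @return A `sweep_summary` object with `summary` (tidy long data frame:
#'   `colony_size`, `metric`, `mean`, `sd`, `n_trials`) and `trends`
#'   (`metric`, `spearman_rho`).
#' @export
sweep_aggregate <- function(results) {
  if (length(results) < 2L)
    stop("need at least two colony sizes to aggregate a sweep", call. = FALSE)
  sizes <- as.integer(names(results))
  if (any(is.na(sizes)))
    stop("results must be a list named by colony size", call. = FALSE)
  rows <- do.call(rbind, lapply(results, function(trs)
    do.call(rbind, lapply(trs, trial_metric_row))))
  sweep_from_trial_rows(rows)
}

# shared by sweep_aggregate and run_experiment (which keeps rows, not trials)
sweep_from_trial_rows <- function(rows) {
  metrics <- setdiff(names(rows), "n_workers")
  long <- do.call(rbind, lapply(metrics, function(m) {
    ag_m <- stats::aggregate(rows[[m]], by = list(colony_size = rows$n_workers),
                             FUN = function(v) mean(v, na.rm = TRUE))
    ag_s <- stats::aggregate(rows[[m]], by = list(colony_size = rows$n_workers),
                             FUN = function(v) stats::sd(v, na.rm = TRUE))
    ag_n <- stats::aggregate(rows[[m]], by = list(colony_size = rows$n_workers),
                             FUN = length)
    data.frame(colony_size = ag_m$colony_size, metric = m,
               mean = ag_m$x, sd = ag_s$x, n_trials = ag_n$x)
  }))
  long <- long[order(long$metric, long$colony_size), ]
  rownames(long) <- NULL
  trends <- do.call(rbind, lapply(split(long, long$metric), function(d) {
    rho <- if (nrow(d) >= 2L && !all(is.na(d$mean)))
      suppressWarnings(stats::cor(d$colony_size, d$mean,
                                  method = "spearman",
                                  use = "complete.obs"))
    else NA_real_
    data.frame(metric = d$metric[1L], spearman_rho = rho)
  }))
  rownames(trends) <- NULL
  structure(list(summary = long, trends = trends), class = "sweep_summary")
}

#' @export
print.sweep_summary <- function(x, ...) {
  cat("Colony-size sweep summary\n")
  print(x$trends, row.names = FALSE)
  invisible(x)
}
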