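# Experiment presets, config files, sweep execution and persistence, and
# deterministic micro-fixtures for tests.

preset_defaults <- function() {
  list(
    name = "ad_hoc",
    colony_sizes = seq(20L, 200L, by = 20L),
    trials_per_size = 50L,
    termination = "all_contacted",
    max_steps = 300L,
    queen_initial_state = 0.1,
    queen_initial_rest = "max",
    feedback_arms = TRUE,          # logical vector; c(TRUE, FALSE) runs both
    worker_rate_multiplier = 1,
    neighbourhood = "orthogonal",
    record_states = FALSE,
    state_stride = 1L,
    base_seed = 20L
  )
}

#' Shipped experiment presets
#'
#' Named, seeded experiment designs covering the standard analyses:
#' \describe{
#'   \item{sweep_default}{50 trials per colony size N = 20..200 (step 20),
#'     all-contacted termination; the main patrol/contact-rate sweep.}
#'   \item{n20_feedback_control}{N = 20, 50 trials, feedback on and off with
#'     matched seeds, worker states recorded; the small-colony suppression
#'     comparison.}
#'   \item{n120_feedback_control}{As above at N = 120; the large-colony
#'     comparison.}
#'   \item{queen_init_high}{Sweep with the queen's internal state initialised
#'     at 0.8 instead of 0.1 (initialisation robustness).}
#'   \item{fixed_horizon_300}{Sweep terminated at a fixed horizon of 300
#'     steps for every colony size (steady-state robustness).}
#'   \item{rates_10x}{Sweep with worker maturation rates beta and gamma at
#'     10 times their default values (fast-maturation robustness).}
#' }
#'
#' @param name Preset name, or `"ad_hoc"` for plain defaults.
#' @param ... Overrides of preset fields (e.g. `trials_per_size = 5`).
#' @return An `experiment_preset` object.
#' @export
experiment_preset <- function(name = "ad_hoc", ...) {
  base <- preset_defaults()
  specialise <- switch(
    name,
    ad_hoc = list(),
    sweep_default = list(),
    n20_feedback_control = list(
      colony_sizes = 20L, feedback_arms = c(TRUE, FALSE),
      record_states = TRUE, state_stride = 10L),
    n120_feedback_control = list(
      colony_sizes = 120L, feedback_arms = c(TRUE, FALSE),
      record_states = TRUE, state_stride = 10L),
    queen_init_high = list(queen_initial_state = 0.8),
    fixed_horizon_300 = list(termination = "fixed_horizon", max_steps = 300L),
    rates_10x = list(worker_rate_multiplier = 10),
    stop("unknown preset: ", name, call. = FALSE)
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(base))
  if (length(bad))
    stop("unknown preset field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  p <- utils::modifyList(base, c(specialise, overrides))
  p$name <- name
  validate_preset(p)
}

validate_preset <- function(p) {
  p$colony_sizes <- as.integer(p$colony_sizes)
  p$trials_per_size <- as.integer(p$trials_per_size)
  p$base_seed <- as.integer(p$base_seed)
  if (any(p$colony_sizes < 1L)) stop("colony sizes must be >= 1", call. = FALSE)
  if (p$trials_per_size < 1L) stop("trials_per_size must be >= 1", call. = FALSE)
  if (!p$termination %in% c("all_contacted", "fixed_horizon"))
    stop("termination must be all_contacted or fixed_horizon", call. = FALSE)
  if (!is.logical(p$feedback_arms) || length(p$feedback_arms) < 1L)
    stop("feedback_arms must be a logical vector", call. = FALSE)
  # constructing params validates the rate constants
  model_params(worker_rate_multiplier = p$worker_rate_multiplier,
               neighbourhood = p$neighbourhood)
  structure(p, class = "experiment_preset")
}

preset_config <- function(preset, n_workers, feedback) {
  sim_config(
    n_workers = n_workers,
    params = model_params(
      feedback_enabled = feedback,
      worker_rate_multiplier = preset$worker_rate_multiplier,
      neighbourhood = preset$neighbourhood),
    termination = preset$termination,
    max_steps = preset$max_steps,
    queen_initial_state = preset$queen_initial_state,
    queen_initial_rest = preset$queen_initial_rest,
    record_states = preset$record_states,
    state_stride = preset$state_stride)
}

#' Load an experiment preset from a YAML config file
#'
#' Reads a key-value config, validates it, rejects unknown keys, and fills
#' every unspecified field with the model's defaults. Rate-constant
#' overrides (`kappa`, `epsilon`, ...) are not accepted here — those are
#' fixed model constants; variants go through the documented switches
#' (`worker_rate_multiplier`, `feedback_arms`, `queen_initial_state`,
#' `neighbourhood`).
#'
#' @param path Path to a YAML file; an empty file yields the all-defaults
#'   preset.
#' @return An `experiment_preset`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  base <- preset_defaults()
  bad <- setdiff(names(raw), names(base))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  validate_preset(utils::modifyList(base, raw))
}

#' Save a preset to a YAML config file
#'
#' @param preset An `experiment_preset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(preset, path) {
  stopifnot(inherits(preset, "experiment_preset"))
  yaml::write_yaml(unclass(preset), path)
  invisible(path)
}

trial_seed <- function(base_seed, size_index, arm_index, trial_index) {
  # documented layout; keeps every derived seed well below 2^31
  base_seed + (arm_index - 1L) * 100000L + size_index * 1000L + trial_index
}

#' Run an experiment preset
#'
#' Executes `trials_per_size` seeded trials per colony size (and per
#' feedback arm, when the preset runs both), collects per-trial metrics,
#' aggregates them into a [sweep_aggregate()]-style summary per arm, and
#' optionally persists everything as diff-able CSV/JSON artifacts. The
#' per-trial seed is a fixed function of `base_seed`, the colony-size index,
#' the arm and the trial index, so a preset is reproducible from its
#' manifest alone.
#'
#' @param preset An [experiment_preset()] (or name passed to it).
#' @param out_dir Optional directory; when given, writes
#'   `trial_metrics.csv`, `summary.csv`, `manifest.json` and, for
#'   state-recording presets, `state_distribution.csv` per arm.
#' @param keep_trials Keep the full `patrol_trial` objects in the return
#'   value (memory-heavy for large sweeps; default keeps them only for
#'   state-recording presets).
#' @param progress Print per-size progress to standard error.
#' @return An `experiment_result`: `preset`, `trial_metrics` (per-trial data
#'   frame with `arm`, `seed`), `summaries` (named by arm), optional
#'   `trials` and `distributions`.
#' @export
run_experiment <- function(preset, out_dir = NULL,
                           keep_trials = preset$record_states,
                           progress = FALSE) {
  if (is.character(preset)) preset <- experiment_preset(preset)
  stopifnot(inherits(preset, "experiment_preset"))
  arms <- preset$feedback_arms
  all_rows <- list()
  trials_kept <- list()
  for (ai in seq_along(arms)) {
    arm_name <- if (arms[ai]) "feedback" else "no_feedback"
    for (si in seq_along(preset$colony_sizes)) {
      n <- preset$colony_sizes[si]
      cfg <- preset_config(preset, n, arms[ai])
      if (progress)
        message(sprintf("[%s] N=%d (%d trials)", arm_name, n,
                        preset$trials_per_size))
      for (ti in seq_len(preset$trials_per_size)) {
        seed <- trial_seed(preset$base_seed, si, ai, ti)
        tr <- run_trial(cfg, seed = seed)
        row <- cbind(data.frame(arm = arm_name, seed = seed, trial = ti),
                     trial_metric_row(tr))
        all_rows[[length(all_rows) + 1L]] <- row
        if (keep_trials)
          trials_kept[[arm_name]][[as.character(n)]][[ti]] <- tr
      }
    }
  }
  rows <- do.call(rbind, all_rows)
  summaries <- lapply(split(rows, rows$arm), function(d)
    if (length(unique(d$n_workers)) >= 2L)
      sweep_from_trial_rows(d[, !(names(d) %in% c("arm", "seed", "trial"))])
    else NULL)
  distributions <- NULL
  if (preset$record_states && length(trials_kept)) {
    distributions <- lapply(trials_kept, function(by_n)
      lapply(by_n, state_distribution))
  }
  res <- structure(list(preset = preset, trial_metrics = rows,
                        summaries = summaries,
                        trials = if (keep_trials) trials_kept else NULL,
                        distributions = distributions),
                   class = "experiment_result")
  if (!is.null(out_dir)) persist_experiment(res, out_dir)
  res
}

persist_experiment <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(res$trial_metrics, file.path(out_dir, "trial_metrics.csv"),
            row.names = FALSE)
  summary_rows <- do.call(rbind, lapply(names(res$summaries), function(a) {
    s <- res$summaries[[a]]
    if (is.null(s)) return(NULL)
    cbind(data.frame(arm = a), s$summary)
  }))
  if (!is.null(summary_rows))
    write.csv(summary_rows, file.path(out_dir, "summary.csv"),
              row.names = FALSE)
  if (!is.null(res$distributions)) {
    dist_rows <- do.call(rbind, lapply(names(res$distributions), function(a) {
      do.call(rbind, lapply(names(res$distributions[[a]]), function(n) {
        cbind(data.frame(arm = a, colony_size = as.integer(n)),
              as_tidy_distribution(res$distributions[[a]][[n]]))
      }))
    }))
    write.csv(dist_rows, file.path(out_dir, "state_distribution.csv"),
              row.names = FALSE)
  }
  manifest <- list(
    preset = unclass(res$preset),
    seed_rule = "base_seed + (arm_index-1)*100000 + size_index*1000 + trial_index",
    package_version = as.character(utils::packageVersion("antpatrol")),
    r_version = R.version.string,
    created = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Deterministic micro-fixtures for tests
#'
#' Small scripted scenarios with analytically known outcomes, used by the
#' unit tests of the dynamics, spatial and engine modules.
#'
#' \describe{
#'   \item{corridor_oracle}{A 1 x 6-cell corridor scenario: a worker starts
#'     at state 0.5 and receives queen contacts on a fixed periodic schedule
#'     (every 8th step, as if the queen shuttled back and forth); the exact
#'     trajectory follows the closed-form linear recursion.}
#'   \item{blocked_walker}{A 3 x 3 grid with the centre agent surrounded on
#'     all four orthogonal sides: the centre agent can never move.}
#'   \item{adjacency_cases}{All eight neighbour offsets around a queen with
#'     the expected contact eligibility under both neighbourhood variants.}
#'   \item{two_worker_tiebreak}{A queen flanked east and west by two workers,
#'     both eligible: selection frequencies are 1/2 each by symmetry.}
#' }
#'
#' @param kind Fixture name (see Details).
#' @return A list describing the scenario; fields vary by kind.
#' @export
generate_fixture <- function(kind) {
  switch(
    kind,
    corridor_oracle = {
      n_steps <- 2000L
      contact_steps <- seq(4L, n_steps, by = 8L)
      list(kind = kind, corridor_cells = c(6L, 1L), iw0 = 0.5,
           n_steps = n_steps, contact_steps = contact_steps)
    },
    blocked_walker = {
      g <- nest_grid(3L)
      centre <- c(1L, 1L)
      around <- cbind(x = c(1L, 1L, 0L, 2L), y = c(0L, 2L, 1L, 1L))
      g$occ[centre[1] + 1 + centre[2] * 3] <- 1L
      for (k in 1:4) g$occ[around[k, 1] + 1 + around[k, 2] * 3] <- k + 1L
      list(kind = kind, grid = g, centre = centre, blockers = around)
    },
    adjacency_cases = {
      off <- expand.grid(dx = -1:1, dy = -1:1)
      off <- off[!(off$dx == 0 & off$dy == 0), ]
      off$dist_units <- sqrt(off$dx^2 + off$dy^2) * CELL_UNITS
      off$contact_orthogonal <- off$dist_units <= CELL_UNITS
      off$contact_chebyshev <- pmax(abs(off$dx), abs(off$dy)) == 1
      rownames(off) <- NULL
      list(kind = kind, queen = c(2L, 2L), offsets = off, grid_cells = 5L)
    },
    two_worker_tiebreak = {
      g <- nest_grid(5L)
      queen <- c(2L, 2L)
      workers <- data.frame(id = c(2L, 3L), x = c(1L, 3L), y = c(2L, 2L))
      g$occ[queen[1] + 1 + queen[2] * 5] <- 1L
      g$occ[workers$x + 1 + workers$y * 5] <- workers$id
      list(kind = kind, grid = g, queen = queen, workers = workers)
    },
    stop("unknown fixture kind: ", kind, call. = FALSE)
  )
}
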