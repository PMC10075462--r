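# Nest lattice and spatial rules. Agents are one body length (5 units)
# across, so the lattice cell side equals one body length: "within 5 units"
# contact and "unable to overlap" are then both exact cell relations.

CELL_UNITS <- 5

#' Build the nest grid for a colony size
#'
#' The nest is an L x L square whose side grows with the square root of the
#' number of workers so density stays constant: `L = 100 * sqrt(N / 20)`
#' units, rounded to the nearest multiple of the 5-unit cell size. The anchor
#' case N = 20 gives exactly L = 100 units (a 20 x 20-cell lattice) and a
#' density of 0.002 agents per square unit.
#'
#' @param n_workers Number of workers.
#' @param params A [model_params()] object (reserved; the grid depends only
#'   on `n_workers`).
#' @return An object of class `nest_grid`: side length in units and cells,
#'   and an occupancy matrix (0 = empty, otherwise agent id).
#' @examples
#' grid_for_colony(20)$side_units   # 100
#' grid_for_colony(80)$side_units   # 200
#' @export
grid_for_colony <- function(n_workers, params = model_params()) {
  n_workers <- as.integer(n_workers)
  if (is.na(n_workers) || n_workers < 1L)
    stop("n_workers must be a positive integer", call. = FALSE)
  L_raw <- 100 * sqrt(n_workers / 20)
  cells <- max(1L, as.integer(floor(L_raw / CELL_UNITS + 0.5)))
  nest_grid(cells)
}

#' @rdname grid_for_colony
#' @param side_cells Lattice side length in cells.
#' @export
nest_grid <- function(side_cells) {
  side_cells <- as.integer(side_cells)
  stopifnot(side_cells >= 1L)
  structure(list(
    side_cells = side_cells,
    side_units = side_cells * CELL_UNITS,
    cell_units = CELL_UNITS,
    occ = matrix(0L, side_cells, side_cells)
  ), class = "nest_grid")
}

#' @export
print.nest_grid <- function(x, ...) {
  cat(sprintf("Nest grid: %d x %d cells (%d x %d units), %d occupied\n",
              x$side_cells, x$side_cells, x$side_units, x$side_units,
              sum(x$occ != 0L)))
  invisible(x)
}

#' Place agents on distinct random cells
#'
#' Draws `n_agents` distinct unoccupied cells uniformly at random and marks
#' them with agent ids starting from `first_id` (id 1 is the queen by
#' convention).
#'
#' @param grid A [nest_grid()].
#' @param n_agents Number of agents to place.
#' @param first_id Id of the first agent placed.
#' @return List with the updated `grid` and a `positions` data frame of
#'   0-based cell coordinates (`id`, `x`, `y`).
#' @export
place_agents <- function(grid, n_agents, first_id = 1L) {
  stopifnot(inherits(grid, "nest_grid"))
  free <- which(grid$occ == 0L)
  if (n_agents > length(free))
    stop("cannot place ", n_agents, " agents on ", length(free),
         " free cells", call. = FALSE)
  sel <- free[sample.int(length(free), n_agents)]
  ids <- seq.int(first_id, length.out = n_agents)
  grid$occ[sel] <- ids
  # column-major linear index -> 0-based (x, y)
  x <- (sel - 1L) %% grid$side_cells
  y <- (sel - 1L) %/% grid$side_cells
  list(grid = grid, positions = data.frame(id = ids, x = x, y = y))
}

occ_at <- function(grid, x, y) grid$occ[x + 1L + y * grid$side_cells]

#' One random-walk step for a single agent
#'
#' Draws one of the four cardinal directions uniformly; if the target cell is
#' outside the nest or occupied the agent forfeits the move (no re-sampling),
#' otherwise it moves one cell and the occupancy map is updated atomically.
#'
#' @param grid A [nest_grid()].
#' @param x,y Current 0-based cell coordinates of the agent.
#' @return List with updated `grid` and the new `x`, `y`.
#' @export
step_agent <- function(grid, x, y) {
  stopifnot(inherits(grid, "nest_grid"))
  id <- occ_at(grid, x, y)
  if (id == 0L) stop("no agent at the stated cell", call. = FALSE)
  d <- sample.int(4L, 1L)  # 1=N(+y) 2=S(-y) 3=E(+x) 4=W(-x)
  nx <- x + c(0L, 0L, 1L, -1L)[d]
  ny <- y + c(1L, -1L, 0L, 0L)[d]
  ok <- nx >= 0L && ny >= 0L && nx < grid$side_cells && ny < grid$side_cells &&
    occ_at(grid, nx, ny) == 0L
  if (ok) {
    grid$occ[x + 1L + y * grid$side_cells] <- 0L
    grid$occ[nx + 1L + ny * grid$side_cells] <- id
    x <- nx; y <- ny
  }
  list(grid = grid, x = x, y = y)
}

neighbour_offsets <- function(neighbourhood) {
  if (neighbourhood == "chebyshev")
    cbind(x = c(0L, 0L, 1L, -1L, 1L, 1L, -1L, -1L),
          y = c(1L, -1L, 0L, 0L, 1L, -1L, 1L, -1L))
  else  # orthogonal: centre-to-centre distance exactly one body length
    cbind(x = c(0L, 0L, 1L, -1L), y = c(1L, -1L, 0L, 0L))
}

#' Detect a queen-worker contact
#'
#' Workers within one body length of the queen (the four orthogonal
#' neighbour cells at centre-to-centre distance 5 units; diagonals at ~7
#' units are out of range under the default neighbourhood) are eligible,
#' except the worker the queen contacted most recently — she never contacts
#' the same worker twice in a row. One eligible worker is chosen uniformly
#' at random; at most one contact occurs per step.
#'
#' @param grid A [nest_grid()].
#' @param queen_xy Integer vector `c(x, y)` of the queen's cell.
#' @param workers Data frame with columns `id`, `x`, `y` for all workers.
#' @param last_contacted_id Id of the most recently contacted worker, or
#'   `NA` if none.
#' @param neighbourhood `"orthogonal"` or `"chebyshev"`.
#' @return The contacted worker's id, or `NA_integer_` if no eligible worker
#'   is in range.
#' @export
detect_queen_contact <- function(grid, queen_xy, workers,
                                 last_contacted_id = NA_integer_,
                                 neighbourhood = "orthogonal") {
  off <- neighbour_offsets(neighbourhood)
  nx <- queen_xy[1] + off[, "x"]
  ny <- queen_xy[2] + off[, "y"]
  keep <- nx >= 0L & ny >= 0L & nx < grid$side_cells & ny < grid$side_cells
  ids <- grid$occ[nx[keep] + 1L + ny[keep] * grid$side_cells]
  elig <- ids[ids %in% workers$id & !(ids %in% last_contacted_id)]
  if (length(elig) == 0L) return(NA_integer_)
  if (length(elig) == 1L) return(as.integer(elig))
  as.integer(elig[sample.int(length(elig), 1L)])
}

#' Detect worker-worker contacts
#'
#' Returns every unordered pair of workers whose cells are adjacent under
#' the contact neighbourhood, each pair once. Worker-worker contacts are
#' logged for contact-rate statistics only; they have no effect on any
#' internal state.
#'
#' @inheritParams detect_queen_contact
#' @return Data frame with columns `a`, `b` (worker ids, `a < b`).
#' @export
detect_worker_contacts <- function(grid, workers,
                                   neighbourhood = "orthogonal") {
  # scan "forward" offsets only so each pair is counted exactly once
  off <- if (neighbourhood == "chebyshev")
    cbind(x = c(1L, 0L, 1L, 1L), y = c(0L, 1L, 1L, -1L))
  else cbind(x = c(1L, 0L), y = c(0L, 1L))
  a <- integer(0); b <- integer(0)
  for (k in seq_len(nrow(off))) {
    nx <- workers$x + off[k, "x"]
    ny <- workers$y + off[k, "y"]
    keep <- nx >= 0L & ny >= 0L & nx < grid$side_cells & ny < grid$side_cells
    ids <- rep(NA_integer_, nrow(workers))
    ids[keep] <- grid$occ[nx[keep] + 1L + ny[keep] * grid$side_cells]
    hit <- !is.na(ids) & ids %in% workers$id
    a <- c(a, workers$id[hit]); b <- c(b, ids[hit])
  }
  if (length(a) == 0L)
    return(data.frame(a = integer(0), b = integer(0)))
  pairs <- data.frame(a = pmin(a, b), b = pmax(a, b))
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs$a, pairs$b), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}
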