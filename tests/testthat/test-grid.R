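# Nest sizing, placement, random-walk moves and contact detection.

test_that("nest side scales as sqrt(N) at constant density", {
  expect_equal(grid_for_colony(20)$side_units, 100)   # anchor case
  expect_equal(grid_for_colony(20)$side_cells, 20L)
  expect_equal(grid_for_colony(80)$side_units, 200)
  expect_equal(grid_for_colony(5)$side_units, 50)
  expect_error(grid_for_colony(0), "positive")
  # density within 5% of 0.002 agents per square unit for all study sizes
  for (n in seq(20L, 200L, by = 20L)) {
    g <- grid_for_colony(n)
    dens <- n / g$side_units^2
    expect_lt(abs(dens - 0.002) / 0.002, 0.05)
  }
})

test_that("placement fills distinct cells and is seed-reproducible", {
  g <- grid_for_colony(20)
  set.seed(7)
  a <- place_agents(g, 21L)
  expect_equal(nrow(unique(a$positions[, c("x", "y")])), 21L)
  expect_equal(sum(a$grid$occ != 0L), 21L)
  expect_true(all(a$positions$x >= 0 & a$positions$x < 20 &
                    a$positions$y >= 0 & a$positions$y < 20))
  set.seed(7)
  b <- place_agents(g, 21L)
  expect_identical(a$positions, b$positions)
  # saturation: 400 agents fill every cell of a 20x20 lattice
  set.seed(1)
  full <- place_agents(g, 400L)
  expect_true(all(full$grid$occ != 0L))
  expect_error(place_agents(g, 401L), "free cells")
})

test_that("a fully surrounded walker never moves", {
  fx <- generate_fixture("blocked_walker")
  set.seed(3)
  for (i in 1:50) {
    out <- step_agent(fx$grid, fx$centre[1], fx$centre[2])
    expect_identical(c(out$x, out$y), fx$centre)
  }
})

test_that("a corner agent on an empty grid moves with probability 1/2", {
  # two of the four draws point off-grid and are forfeited
  set.seed(11)
  moved <- 0L
  for (i in 1:4000) {
    g <- nest_grid(5L); g$occ[1, 1] <- 1L
    out <- step_agent(g, 0L, 0L)
    if (out$x != 0L || out$y != 0L) moved <- moved + 1L
  }
  expect_equal(moved / 4000, 0.5, tolerance = 0.06)
})

test_that("direction draws are uniform over the four cardinal moves", {
  set.seed(13)
  dirs <- character(4000)
  for (i in 1:4000) {
    g <- nest_grid(3L); g$occ[2, 2] <- 1L  # centre of an empty 3x3
    out <- step_agent(g, 1L, 1L)
    dirs[i] <- paste(out$x - 1L, out$y - 1L)
  }
  freq <- table(dirs) / 4000
  expect_equal(length(freq), 4L)
  expect_true(all(abs(freq - 0.25) < 0.03))
})

test_that("queen contact: range, repeat exclusion and uniform tie-break", {
  g <- nest_grid(5L)
  g$occ[3, 3] <- 1L  # queen at (2,2)
  workers <- data.frame(id = integer(0), x = integer(0), y = integer(0))
  expect_true(is.na(detect_queen_contact(g, c(2L, 2L), workers)))

  # a lone adjacent worker who was contacted last is ineligible
  g1 <- g; g1$occ[4, 3] <- 2L
  w1 <- data.frame(id = 2L, x = 3L, y = 2L)
  expect_identical(detect_queen_contact(g1, c(2L, 2L), w1, 2L), NA_integer_)
  expect_identical(detect_queen_contact(g1, c(2L, 2L), w1, NA), 2L)

  # three eligible neighbours are picked uniformly
  g3 <- g; g3$occ[4, 3] <- 2L; g3$occ[2, 3] <- 3L; g3$occ[3, 4] <- 4L
  w3 <- data.frame(id = 2:4, x = c(3L, 1L, 2L), y = c(2L, 2L, 3L))
  set.seed(5)
  picks <- replicate(3000, detect_queen_contact(g3, c(2L, 2L), w3))
  freq <- table(picks) / 3000
  expect_equal(length(freq), 3L)
  expect_true(all(abs(freq - 1 / 3) < 0.03))
})

test_that("contact eligibility by neighbour offset matches both variants", {
  fx <- generate_fixture("adjacency_cases")
  g0 <- nest_grid(fx$grid_cells)
  g0$occ[fx$queen[1] + 1, fx$queen[2] + 1] <- 1L
  for (k in seq_len(nrow(fx$offsets))) {
    o <- fx$offsets[k, ]
    wx <- fx$queen[1] + o$dx; wy <- fx$queen[2] + o$dy
    g <- g0; g$occ[wx + 1, wy + 1] <- 2L
    w <- data.frame(id = 2L, x = wx, y = wy)
    hit_orth <- !is.na(detect_queen_contact(g, fx$queen, w,
                                            neighbourhood = "orthogonal"))
    hit_cheb <- !is.na(detect_queen_contact(g, fx$queen, w,
                                            neighbourhood = "chebyshev"))
    expect_identical(hit_orth, o$contact_orthogonal)
    expect_identical(hit_cheb, o$contact_chebyshev)
  }
})

test_that("worker-worker contacts: once per adjacent pair, no diagonals", {
  g <- nest_grid(6L)
  # L-shaped triple: (1,1), (2,1), (2,2) -> two orthogonal pairs,
  # the diagonal (1,1)-(2,2) pair excluded
  w <- data.frame(id = c(2L, 3L, 4L), x = c(1L, 2L, 2L), y = c(1L, 1L, 2L))
  g$occ[cbind(w$x + 1, w$y + 1)] <- w$id
  pairs <- detect_worker_contacts(g, w)
  expect_equal(pairs, data.frame(a = c(2L, 3L), b = c(3L, 4L)))
  # iteration order does not change the pair set
  w_rev <- w[3:1, ]
  expect_equal(detect_worker_contacts(g, w_rev), pairs)
  # chebyshev variant adds the diagonal pair
  expect_equal(nrow(detect_worker_contacts(g, w, "chebyshev")), 3L)
  # isolated workers produce nothing
  g2 <- nest_grid(9L)
  w2 <- data.frame(id = c(2L, 3L), x = c(0L, 5L), y = c(0L, 5L))
  g2$occ[cbind(w2$x + 1, w2$y + 1)] <- w2$id
  expect_equal(nrow(detect_worker_contacts(g2, w2)), 0L)
})

test_that("a lone walker's occupancy converges to uniform (mixing oracle)", {
  set.seed(17)
  g <- nest_grid(5L); g$occ[1, 1] <- 1L
  x <- 0L; y <- 0L
  n <- 100000L
  visits <- integer(n)
  for (i in seq_len(n)) {
    out <- step_agent(g, x, y)
    g <- out$grid; x <- out$x; y <- out$y
    visits[i] <- x + 1L + y * 5L
  }
  # thin to roughly independent samples before the goodness-of-fit test
  thinned <- visits[seq(20L, n, by = 20L)]
  counts <- tabulate(thinned, nbins = 25L)
  pval <- suppressWarnings(stats::chisq.test(counts)$p.value)
  expect_gt(pval, 0.01)
})
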