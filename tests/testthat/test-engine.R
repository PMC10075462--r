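# Trial orchestration: initialisation, the per-step schedule, termination
# and run-level invariants.

test_that("initialisation matches the stated starting conditions", {
  cfg <- sim_config(n_workers = 20)
  w <- initialize_trial(cfg, seed = 1)
  expect_equal(w$side_cells, 20L)
  expect_length(w$iw, 20L)
  expect_equal(w$iq, 0.1)
  expect_true(all(w$iw > 0 & w$iw < 0.5))
  # 21 distinct cells
  cells <- c(w$qx + w$qy * 20L, w$wx + w$wy * 20L)
  expect_length(unique(cells), 21L)
  # queen at rest starts with the full maximum rest under the default
  if (!w$q_active) expect_equal(w$q_timer, 100L)
  # determinism
  w2 <- initialize_trial(cfg, seed = 1)
  expect_identical(w[setdiff(names(w), "config")],
                   w2[setdiff(names(w2), "config")])
  # alternative convention: queen's first rest drawn from 1..trconstant
  cfg_r <- sim_config(n_workers = 20, queen_initial_rest = "random")
  timers <- replicate(200, {
    wr <- initialize_trial(cfg_r)
    if (wr$q_active) NA_integer_ else wr$q_timer
  })
  timers <- timers[!is.na(timers)]
  expect_true(any(timers < 100L))
  expect_true(all(timers >= 1L & timers <= 100L))
})

test_that("initial worker states pool to mean 1/4", {
  cfg <- sim_config(n_workers = 20)
  set.seed(99)
  pooled <- unlist(lapply(1:1000, function(i) initialize_trial(cfg)$iw))
  expect_lt(abs(mean(pooled) - 0.25), 0.01)
})

test_that("inactive agents never move and drift toward the fixed point", {
  w <- make_world(10L, c(5L, 5L),
                  cbind(c(0L, 9L), c(0L, 9L)), iw = c(0.2, 0.8))
  set.seed(2)
  w2 <- advance_step(w, 50L)
  expect_identical(c(w2$qx, w2$qy), c(5L, 5L))
  expect_identical(w2$wx, c(0L, 9L))
  expect_identical(w2$wy, c(0L, 9L))
  # both states move toward gamma/beta = 1 with no contacts
  expect_equal(w2$iw,
               sapply(c(0.2, 0.8), function(v) worker_closed_form(v, 50L)[51L]))
})

test_that("a queen beside a lone worker contacts it once, not twice in a row", {
  w <- make_world(6L, c(2L, 2L), cbind(3L, 2L), iw = 0.5, iq = 0.1)
  set.seed(4)
  w1 <- advance_step(w)
  expect_equal(nrow(w1$events), 1L)
  expect_equal(w1$events$worker, 1L)
  expect_equal(w1$events$worker_state_before, 0.5)
  expect_equal(w1$iw, 0.0496)                      # suppression applied
  expect_equal(w1$iq, 0.99 * 0.1 + 0.1 * 0.5)      # damped + alpha*iw_pre
  # the same worker is the only neighbour: no contact on the next step
  w2 <- advance_step(w1)
  expect_equal(nrow(w2$events), 1L)
  expect_equal(w2$iw, update_worker(w1$iw, FALSE))
  expect_equal(w2$iq, update_queen(w1$iq, NULL))
})

test_that("no-feedback control leaves worker state untouched by contact", {
  p_off <- model_params(feedback_enabled = FALSE)
  w <- make_world(6L, c(2L, 2L), cbind(3L, 2L), iw = 0.5, iq = 0.1,
                  params = p_off)
  set.seed(4)
  w1 <- advance_step(w)
  expect_equal(nrow(w1$events), 1L)                # contact still logged
  expect_equal(w1$iw, 0.50005)                     # kappa term omitted
  expect_equal(w1$iq, 0.99 * 0.1 + 0.1 * 0.5)      # queen side unchanged
})

test_that("repeated single steps equal one multi-step call", {
  cfg <- sim_config(n_workers = 8)
  set.seed(21)
  a <- initialize_trial(cfg)
  set.seed(21)
  b <- initialize_trial(cfg)
  set.seed(31)
  for (i in 1:40) a <- advance_step(a)
  set.seed(31)
  b <- advance_step(b, 40L)
  expect_identical(a[setdiff(names(a), "config")],
                   b[setdiff(names(b), "config")])
})

test_that("termination criteria: first full coverage, or a fixed horizon", {
  tr1 <- run_trial(sim_config(n_workers = 1), seed = 5)
  expect_equal(nrow(tr1$events), 1L)
  expect_equal(tr1$events$step, tr1$termination_step)
  expect_true(all(tr1$contact_counts >= 1L))

  trh <- run_trial(sim_config(n_workers = 10, termination = "fixed_horizon",
                              max_steps = 300), seed = 6)
  expect_equal(trh$termination_step, 300L)
  expect_equal(nrow(trh$series), 301L)

  # the safety cap aborts with a partial-world condition
  err <- tryCatch(
    run_trial(sim_config(n_workers = 50, safety_cap = 5), seed = 7),
    antpatrol_incomplete_trial = function(e) e)
  expect_s3_class(err, "antpatrol_incomplete_trial")
  expect_equal(err$world$step, 5L)
})

test_that("identical config and seed give bit-identical trials", {
  cfg <- sim_config(n_workers = 12)
  a <- run_trial(cfg, seed = 8)
  b <- run_trial(cfg, seed = 8)
  expect_identical(a[setdiff(names(a), "config")],
                   b[setdiff(names(b), "config")])
})

test_that("feedback only diverges trajectories after the first contact", {
  cfg_on <- sim_config(n_workers = 10, termination = "fixed_horizon",
                       max_steps = 500)
  cfg_off <- sim_config(n_workers = 10, termination = "fixed_horizon",
                        max_steps = 500,
                        params = model_params(feedback_enabled = FALSE))
  a <- run_trial(cfg_on, seed = 9)
  b <- run_trial(cfg_off, seed = 9)
  expect_gt(nrow(a$events), 0L)
  s1 <- a$events$step[1L]
  # identical logs up to and including the first contact step
  expect_identical(a$series$queen_internal[1:(s1 + 1)],
                   b$series$queen_internal[1:(s1 + 1)])
  expect_identical(a$events$step[1L], b$events$step[1L])
  expect_identical(a$events$worker[1L], b$events$worker[1L])
  # worker states differ from the first suppression onward
  expect_false(isTRUE(all.equal(a$final_worker_states,
                                b$final_worker_states)))
})

test_that("run-level invariants hold on a complete default trial", {
  tr <- run_trial(sim_config(n_workers = 20), seed = 10)
  T <- tr$termination_step
  expect_equal(nrow(tr$series), T + 1L)
  expect_true(all(tr$contact_counts >= 1L))

  # internal states bounded: workers in [0,1], queen in [0, alpha/epsilon]
  expect_true(all(tr$states >= 0 & tr$states <= 1))
  expect_true(all(tr$series$queen_internal >= 0 &
                    tr$series$queen_internal <= 10))

  # patrol bouts are exactly taconstant long (first/last may be censored),
  # rest gaps within [1, trconstant]
  bouts <- extract_patrol_bouts(tr)
  inner <- bouts$length[-c(1L, nrow(bouts))]
  expect_true(all(inner == 20L))
  gaps <- bouts$start[-1L] - bouts$end[-nrow(bouts)] - 1L
  expect_true(all(gaps >= 1L & gaps <= 100L))
  # every rest gap equals the exponential rest rule evaluated at the
  # queen's internal state when she entered rest
  iq_entry <- tr$series$queen_internal[bouts$end[-nrow(bouts)] + 1L]
  expect_identical(gaps, rest_time(iq_entry))

  # at most one queen contact per step, never the same worker twice running
  expect_false(any(duplicated(tr$events$step)))
  expect_false(any(diff(tr$events$worker) == 0L))
})

test_that("patrol bouts are maximal active runs", {
  expect_equal(
    extract_patrol_bouts(c(0, 0, 0, 1, 1, 1, 0, 0, 0) == 1),
    data.frame(start = 4L, end = 6L, length = 3L))
  expect_equal(nrow(extract_patrol_bouts(rep(FALSE, 10))), 0L)
})
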