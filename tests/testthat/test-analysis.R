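# Trajectory analysis: distances, visit tallies, rank-size, popularity
# tiers, boundary profiles and power-law tail fits.

# Hand-built simulation fixture: two agents, known movements.
toy_sim <- function() {
  env <- small_mixed_env()
  events <- data.frame(
    agent_id = c(1L, 1L, 1L, 2L),
    iteration = c(1L, 2L, 3L, 5L),
    origin = c(10L, 50L, 10L, 20L),
    destination = c(50L, 10L, 50L, 23L),
    distance_m = c(100, 100, 100, 75),
    kind = "irregular", stringsAsFactors = FALSE
  )
  structure(list(events = events,
                 agents = data.frame(id = 1:2, type = c("married", "senior"),
                                     home = c(10L, 20L)),
                 homes = c(10L, 20L), env = env, days = 1, seed = NULL),
            class = "mobility_sim")
}

test_that("movement distances conserve counts and handle single events", {
  sim <- toy_sim()
  sim$events <- sim$events[4, ]   # one horizontal 3-cell trip
  md <- movement_distances(sim)
  expect_equal(md$distances_m, 75)
  expect_equal(sum(md$histogram$count), 1)

  md_all <- movement_distances(toy_sim())
  expect_equal(sum(md_all$histogram$count), 4)
  sim$events <- sim$events[0, ]
  expect_error(movement_distances(sim), "empty")
})

test_that("visit tallies count arrivals plus the initial home", {
  vf <- visit_frequencies(toy_sim())
  # agent 1: home 10 (initial + 1 return), cell 50 twice
  a1 <- vf$agent_cell[vf$agent_cell$agent_id == 1, ]
  expect_equal(a1$visits[a1$cell == 10], 2)
  expect_equal(a1$visits[a1$cell == 50], 2)
  # agent 2: home 20 initial only, cell 23 once
  a2 <- vf$agent_cell[vf$agent_cell$agent_id == 2, ]
  expect_equal(a2$visits[a2$cell == 20], 1)
  expect_equal(a2$visits[a2$cell == 23], 1)
  # cell totals consistent with per-agent totals
  expect_equal(sum(vf$cell_counts), nrow(toy_sim()$events) + 2)
})

test_that("tallies equal an independent group-by recount on a real run", {
  env <- small_mixed_env()
  sim <- run_simulation(env, n_agents = 15, days = 1, seed = 31)
  vf <- visit_frequencies(sim)
  # naive recount oracle
  arrivals <- c(sim$homes, sim$events$destination)
  naive <- table(arrivals)
  expect_identical(unname(vf$cell_counts[names(naive)]),
                   as.integer(naive), ignore_attr = TRUE)
  expect_equal(sum(vf$agent_cell$visits), length(arrivals))
})

test_that("an agent that never moves has exactly one visited location", {
  sim <- toy_sim()
  sim$events <- sim$events[0, ]
  sim$events <- data.frame(agent_id = 1L, iteration = 1L, origin = 10L,
                           destination = 50L, distance_m = 100,
                           kind = "irregular")
  vf <- visit_frequencies(sim)
  expect_identical(nrow(vf$agent_cell[vf$agent_cell$agent_id == 2, ]), 1L)
})

test_that("rank-size output is sorted, stable and conserving", {
  vf <- visit_frequencies(toy_sim())
  rs <- rank_size(vf, include_unvisited = FALSE)
  expect_true(all(diff(rs$visits) <= 0))
  expect_equal(sum(rs$visits), sum(vf$cell_counts))
  # ties broken by cell index: cells 10 and 50 both have 2 visits
  two <- rs$cell[rs$visits == 2]
  expect_identical(two, sort(two))
  rs_full <- rank_size(vf)
  expect_identical(nrow(rs_full), 144L)  # whole 12x12 grid ranked
})

test_that("popularity partition is exhaustive, disjoint and ordered", {
  ranked <- data.frame(rank = 1:3, cell = 1:3,
                       visits = c(12000L, 5000L, 10L))
  pg <- popularity_groups(ranked)
  expect_identical(c(nrow(pg$A), nrow(pg$B), nrow(pg$C)), c(1L, 1L, 1L))
  all_low <- data.frame(rank = 1:4, cell = 1:4, visits = c(999L, 5L, 0L, 1L))
  pg2 <- popularity_groups(all_low)
  expect_identical(nrow(pg2$A) + nrow(pg2$B), 0L)
  expect_identical(nrow(pg2$C), 4L)
  expect_error(popularity_groups(ranked, thresholds = c(10, 100)), "ordered")
})

test_that("boundary profiles match the exhaustive distance oracle", {
  land <- matrix(1L, 8, 8); land[, 5:8] <- 2L  # straight frontier
  env <- env_from_matrix(land)
  frontier_cells <- which(matrix(col(land) == 4, 8, 8))
  part <- list(A = data.frame(cell = frontier_cells),
               B = data.frame(cell = integer(0)),
               C = data.frame(cell = setdiff(1:64, frontier_cells)))
  bp <- boundary_profile(part, env, proximity = 1)
  expect_equal(bp$frac_A_near_boundary, 1.0)
  for (cell in part$C$cell[1:10]) {
    r <- ((cell - 1) %% 8) + 1; c <- ((cell - 1) %/% 8) + 1
    expect_identical(bp$distances$C[match(cell, part$C$cell)],
                     as.integer(oracle_boundary_distance(env, r, c)))
  }
  # degenerate single-use grid: distances reported as absent
  uni <- env_from_matrix(matrix(1L, 6, 6))
  bp2 <- boundary_profile(part, uni)
  expect_true(is.na(bp2$frac_A_near_boundary))
})

test_that("per-agent top-k curves are cumulative and padded", {
  vf <- visit_frequencies(toy_sim())
  curve <- top_location_curve(vf, k = 5)
  expect_identical(dim(curve), c(2L, 5L))
  expect_true(all(diff(t(curve)) >= 0))
  expect_equal(unname(curve[1, 5]), 4)  # agent 1 total arrivals
})

test_that("tail fitting recovers a known Pareto exponent", {
  set.seed(55)
  x <- (1 - stats::runif(10000))^(-1 / 1.5)  # Pareto, alpha = 2.5, xmin = 1
  fit <- fit_tail(x)
  expect_lt(abs(fit$alpha - 2.5), 0.15)
  expect_identical(fit$prefers, "power_law")
  expect_true(fit$xmin >= min(x) && fit$xmin <= max(x))
})

test_that("tail fitting prefers an exponential model on exponential data", {
  set.seed(56)
  y <- stats::rexp(10000, rate = 1) + 1
  fit <- fit_tail(y)
  expect_identical(fit$prefers, "exponential")
})

test_that("tail fitting rejects degenerate input", {
  expect_error(fit_tail(rep(2, 100)), "degenerate")
  expect_error(fit_tail(stats::runif(10)), "at least 50")
})
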