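# Movement engine: IAC arithmetic, Stage-1 decisions, land-use choice,
# IAC-ranked destination selection and the stepping loop.

test_that("the IAC product matches closed-form and log-domain evaluation", {
  # worked example: 27.22 cell units away, 29-cell cluster, theta 0.93,
  # mood 1.03, not favored
  expect_equal(round(compute_iac(27.22, 29, 0.93, 1.03, 1), 2), 0.42)
  # degenerate identity
  expect_equal(compute_iac(0, 0, 1, 1, 1), 1)
  # independent log-domain oracle
  p <- iac_params()
  expect_equal(compute_iac(10, 10, 1, 1, 1, p),
               exp(10 * log(p$d) + 10 * log(p$g)))
  expect_error(compute_iac(Inf, 1, 1, 1, 1), "finite")
})

test_that("IAC is monotone: decreasing in distance, increasing in cluster size", {
  p <- iac_params()
  d <- compute_iac(c(5, 10, 30), 20, 1, 1, 1, p)
  expect_true(all(diff(d) < 0))
  g <- compute_iac(10, c(5, 50, 500), 1, 1, 1, p)
  expect_true(all(diff(g) > 0))
})

test_that("iac_params rejects out-of-range parameters", {
  expect_error(iac_params(d = 1.5), "d must")
  expect_error(iac_params(g = 0.9), "g must")
  expect_error(iac_params(top_k = 0), "top_k")
})

test_that("Stage-1 decisions follow their probabilities", {
  tab <- flat_table(move_p = 1)
  # weekend noon, unanchored: pure table draw
  it <- 5 * 96 + 52  # Saturday 13:00
  expect_true(all(vapply(1:20, function(i)
    decide_move("married", 5L, 5L, NA, FALSE, it, tab), logical(1))))
  tab0 <- flat_table(move_p = 0)
  expect_false(any(vapply(1:20, function(i)
    decide_move("married", 5L, 5L, NA, FALSE, it, tab0), logical(1))))

  # p = 0.3: empirical frequency within 3 binomial standard errors
  tab3 <- flat_table(move_p = 0.3)
  set.seed(21)
  hits <- sum(stats::runif(10000) <
                urbanflow:::move_probability(rep("married", 10000), 5L, 5L,
                                             NA, FALSE, it, tab3))
  expect_lt(abs(hits / 10000 - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
})

test_that("anchored agents get the routine probability on weekday mornings", {
  tab <- flat_table(move_p = 0.05, routine_prob = 0.95)
  it <- 32  # Monday 08:00
  # away from anchor in the routine window: routine probability applies
  expect_equal(urbanflow:::move_probability("married", 1L, 1L, 9L, TRUE, it, tab),
               0.95)
  # already at the anchor: ordinary at-anchor probability
  expect_equal(urbanflow:::move_probability("married", 9L, 1L, 9L, TRUE, it, tab),
               0.05)
  # weekend: no routine pull
  expect_equal(urbanflow:::move_probability("married", 1L, 1L, 9L, TRUE,
                                            5 * 96 + 32, tab), 0.05)
  # departure iteration at the anchor: routine leave
  expect_equal(urbanflow:::move_probability("married", 9L, 1L, 9L, TRUE,
                                            68, tab), 0.95)  # 17:00
  expect_equal(urbanflow:::move_probability("teenager", 9L, 1L, 9L, TRUE,
                                            56, tab), 0.95)  # 14:00
})

test_that("land-use choice follows the weights", {
  tab <- flat_table()
  tab$landuse["bachelor", "noon", ] <- c(0, 0, 0, 0, 1, 0)
  set.seed(3)
  draws <- vapply(1:50, function(i) choose_land_use("bachelor", "noon", tab),
                  character(1))
  expect_true(all(draws == "entertainment_retail"))

  # uniform weights: multinomial 3-sigma bound per category
  set.seed(4)
  u <- table(factor(vapply(1:6000, function(i)
    choose_land_use("senior", "evening", tab), character(1)),
    levels = land_uses()))
  expect_true(all(abs(u - 1000) < 3 * sqrt(6000 * (1/6) * (5/6))))

  tabz <- flat_table(); tabz$landuse["senior", "evening", ] <- 0
  expect_error(choose_land_use("senior", "evening", tabz), "zero")
})

test_that("destination selection matches the exhaustive argmax oracle", {
  p <- iac_params(top_k = 1, mood_sd = 0)
  for (s in c(1, 9)) {
    env <- generate_environment(dims = c(15, 15), seed = s)
    set.seed(s + 100)
    for (rep in 1:10) {
      pos <- sample.int(225, 1)
      fav <- sample.int(225, 40)
      lu <- sample(land_uses(), 1)
      got <- select_destination(pos, fav, lu, env, p)
      expect_identical(got, oracle_best_destination(pos, fav, lu, env, p))
    }
  }
})

test_that("destination selection honours candidates, top-k and exclusion", {
  land <- matrix(1L, 6, 6); land[3, 3] <- 2L
  env <- env_from_matrix(land)
  # exactly one candidate cell of the target use
  expect_identical(select_destination(1L, integer(0), "employment", env,
                                      iac_params()),
                   (3L - 1L) * 6L + 3L)
  # the agent's own cell is never returned even when it matches the use
  got <- replicate(20, select_destination(15L, integer(0), "employment",
                                          env_from_matrix(matrix(2L, 4, 4)),
                                          iac_params(top_k = 3)))
  expect_false(any(got == 15L))
  expect_error(select_destination(15L, integer(0), "public_open_space", env),
               "no candidate")
})

test_that("nearer of two otherwise identical cells ranks first", {
  land <- matrix(1L, 1, 40)
  land[1, c(11, 31)] <- 2L  # two isolated employment cells at 10 and 30
  env <- env_from_matrix(land)
  p <- iac_params(top_k = 1, mood_sd = 0)
  expect_identical(select_destination(1L, integer(0), "employment", env, p),
                   11L)
})

test_that("favored cells outrank equal unfavored ones", {
  land <- matrix(1L, 1, 21)
  land[1, c(1, 21)] <- 2L  # equidistant from the middle
  env <- env_from_matrix(land)
  p <- iac_params(top_k = 1, mood_sd = 0)
  expect_identical(select_destination(11L, 21L, "employment", env, p), 21L)
  expect_identical(select_destination(11L, 1L, "employment", env, p), 1L)
})

test_that("stepping with zero move probability produces no events", {
  env <- small_mixed_env()
  set.seed(1)
  ag <- generate_agents(30, env)
  state <- list(agents = ag, iteration = 40L)
  out <- sim_step(state, env, flat_table(move_p = 0, routine_prob = 0))
  expect_null(out$events)
  expect_identical(out$agents$position, ag$position)
  expect_identical(out$iteration, 41L)
})

test_that("routine movers all head to their anchor", {
  env <- small_mixed_env()
  mix <- default_population_mix()
  mix$proportions[] <- c(0, 0, 1, 0); mix$employment["married"] <- 1
  set.seed(2)
  ag <- generate_agents(25, env, mix = mix)
  tab <- flat_table(move_p = 0, routine_prob = 1)
  state <- list(agents = ag, iteration = 32L)  # Monday 08:00
  out <- sim_step(state, env, tab)
  moved <- out$events
  expect_identical(sort(moved$agent_id), sort(ag$id[ag$home != ag$anchor]))
  expect_true(all(moved$kind == "routine"))
  expect_identical(moved$destination,
                   ag$anchor[match(moved$agent_id, ag$id)])
})

test_that("trajectories chain: consecutive origins match prior destinations", {
  env <- small_mixed_env()
  set.seed(3)
  sim <- run_simulation(env, n_agents = 20, days = 1, seed = 9)
  for (id in unique(sim$events$agent_id)) {
    ev <- sim$events[sim$events$agent_id == id, ]
    expect_identical(ev$origin[1], sim$homes[id])
    if (nrow(ev) > 1)
      expect_identical(ev$origin[-1], ev$destination[-nrow(ev)])
    expect_true(all(ev$origin != ev$destination))
    expect_equal(ev$distance_m, {
      nr <- env$dims[1]
      dr <- ((ev$destination - 1) %% nr) - ((ev$origin - 1) %% nr)
      dc <- ((ev$destination - 1) %/% nr) - ((ev$origin - 1) %/% nr)
      sqrt(dr^2 + dc^2) * env$cell_size_m
    })
  }
})

test_that("the same seed reproduces an identical trajectory log", {
  env <- small_mixed_env()
  s1 <- run_simulation(env, n_agents = 10, days = 1, seed = 42)
  s2 <- run_simulation(env, n_agents = 10, days = 1, seed = 42)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$agents, s2$agents)
})
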