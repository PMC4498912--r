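# Simulation configuration (YAML/JSON) and reproducible batch execution:
# one environment shared across runs, fresh agents per run with seeds
# derived deterministically from the master seed.

#' Default simulation configuration
#'
#' All tunables of a run: grid dimensions and cell size, the land-use quota
#' table, attractiveness-field parameters, agent count and mix, the
#' probability-table path, IAC parameters, run length and seeds.
#'
#' @return A \code{sim_config} list.
#' @export
default_config <- function() {
  structure(list(
    grid = list(dims = c(100L, 100L), cell_size_m = 25,
                adjacency = "von_neumann"),
    land_uses = default_quotas(),
    theta = list(mean = 1.0, sd = 0.05, floor = 0.05),
    agents = list(n = 10000L,
                  proportions = default_population_mix()$proportions,
                  employment = default_population_mix()$employment,
                  n_favored = 40L),
    probability_table = NULL,   # NULL = package default
    iac = list(d = 0.95, g = 1.02, top_k = 10L, mood_sd = 0.05,
               favored_boost = 1.5),
    run = list(days = 28L, n_runs = 20L),
    master_seed = 1L
  ), class = "sim_config")
}

#' Load and validate a configuration file
#'
#' Reads YAML (or JSON) and overlays it on [default_config()]; all
#' validation problems are collected and reported together.
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return A validated \code{sim_config}.
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in names(raw)) {
    if (nm == "land_uses") {
      cfg$land_uses <- as.data.frame(raw$land_uses, stringsAsFactors = FALSE)
    } else if (is.list(cfg[[nm]]) && is.list(raw[[nm]])) {
      for (k in names(raw[[nm]])) cfg[[nm]][[k]] <- raw[[nm]][[k]]
    } else cfg[[nm]] <- raw[[nm]]
  }
  # YAML maps come back as lists; restore named numeric vectors
  for (k in c("proportions", "employment"))
    cfg$agents[[k]] <- unlist(cfg$agents[[k]])
  cfg$grid$dims <- as.integer(unlist(cfg$grid$dims))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(length(cfg$grid$dims) == 2 && all(cfg$grid$dims >= 2),
      "grid.dims must be two values >= 2")
  chk(cfg$grid$cell_size_m > 0, "grid.cell_size_m must be positive")
  n_cells <- prod(cfg$grid$dims)
  qsum <- sum(cfg$land_uses$cell_quota)
  chk(qsum == n_cells,
      sprintf("land_uses quotas sum to %d, grid has %d cells", qsum, n_cells))
  chk(cfg$theta$mean > 0, "theta.mean must be positive")
  chk(cfg$theta$sd >= 0, "theta.sd must be non-negative")
  chk(cfg$iac$d > 0 && cfg$iac$d < 1, "iac.d must be in (0, 1)")
  chk(cfg$iac$g > 1, "iac.g must exceed 1")
  chk(cfg$iac$top_k >= 1, "iac.top_k must be at least 1")
  chk(abs(sum(cfg$agents$proportions) - 1) < 1e-6,
      "agents.proportions must sum to 1")
  chk(cfg$run$days >= 1, "run.days must be at least 1")
  chk(is.null(cfg$probability_table) || file.exists(cfg$probability_table),
      "probability_table file does not exist")
  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  class(cfg) <- "sim_config"
  cfg
}

#' Save a configuration as YAML
#'
#' @param cfg A \code{sim_config}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
save_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$land_uses <- as.list(out$land_uses)
  # write named vectors as maps so their names survive the round-trip
  out$agents$proportions <- as.list(out$agents$proportions)
  out$agents$employment <- as.list(out$agents$employment)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Derive a per-run seed from the master seed
#'
#' Deterministic integer mix, kept within the 32-bit range.
#'
#' @param master Master seed (integer).
#' @param index Run index (1-based).
#' @return An integer seed.
#' @export
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 69069 + 104729 * as.numeric(index)) %%
               2147483647)
}

#' Run a batch of simulations
#'
#' Generates the environment once from the master seed, then runs
#' \code{n_runs} simulations on it, regenerating the agents for each run
#' with a derived seed (same city, new people). Logs and a JSON manifest
#' are written under \code{out_dir}.
#'
#' @param cfg A \code{sim_config}.
#' @param out_dir Output directory.
#' @param n_runs Number of runs (defaults to the config's).
#' @return Character vector of log paths (invisibly); the manifest is
#'   written as \code{manifest.json}.
#' @export
batch_run <- function(cfg, out_dir, n_runs = NULL) {
  cfg <- validate_config(cfg)
  if (is.null(n_runs)) n_runs <- cfg$run$n_runs
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  env_seed <- derive_seed(cfg$master_seed, 0L)
  env <- generate_environment(dims = cfg$grid$dims, quotas = cfg$land_uses,
                              cell_size_m = cfg$grid$cell_size_m,
                              theta_mean = cfg$theta$mean,
                              theta_sd = cfg$theta$sd,
                              theta_floor = cfg$theta$floor,
                              adjacency = cfg$grid$adjacency,
                              seed = env_seed)
  write_environment(env, file.path(out_dir, "environment"))
  table <- if (is.null(cfg$probability_table)) default_probability_table()
           else read_probability_table(cfg$probability_table)
  params <- iac_params(cfg$iac$d, cfg$iac$g, cfg$iac$top_k,
                       cfg$iac$mood_sd, cfg$iac$favored_boost)
  env_hash <- sum(as.numeric(env$land_use) * seq_along(env$land_use)) %% 1e9
  paths <- character(n_runs)
  for (run in seq_len(n_runs)) {
    run_seed <- derive_seed(cfg$master_seed, run)
    set.seed(run_seed)
    agents <- generate_agents(cfg$agents$n, env,
                              mix = list(proportions = cfg$agents$proportions,
                                         employment = cfg$agents$employment,
                                         workplace_side_prob =
                                           default_population_mix()$workplace_side_prob),
                              n_favored = cfg$agents$n_favored)
    sim <- run_simulation(env, agents, table, params, days = cfg$run$days)
    paths[run] <- file.path(out_dir, sprintf("run_%03d.csv", run))
    write_trajectory(sim, paths[run])
  }
  manifest <- list(master_seed = cfg$master_seed, env_seed = env_seed,
                   env_hash = env_hash, n_runs = n_runs,
                   days = cfg$run$days, n_agents = cfg$agents$n,
                   logs = basename(paths))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}

#' Persist / reload a trajectory log as CSV
#'
#' Events are written with grid coordinates (one row per movement); the
#' agent roster (id, type, home) rides along in a sidecar CSV so the
#' analysis module can rebuild initial visits.
#'
#' @param sim A \code{mobility_sim}.
#' @param path CSV path for the events; the sidecar gets suffix
#'   \code{_agents.csv}.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(sim, path) {
  nr <- sim$env$dims[1]
  ev <- sim$events
  out <- data.frame(
    agent_id = ev$agent_id, iteration = ev$iteration,
    o_row = ((ev$origin - 1L) %% nr) + 1L,
    o_col = ((ev$origin - 1L) %/% nr) + 1L,
    d_row = ((ev$destination - 1L) %% nr) + 1L,
    d_col = ((ev$destination - 1L) %/% nr) + 1L,
    distance_m = ev$distance_m, kind = ev$kind
  )
  utils::write.csv(out, path, row.names = FALSE)
  roster <- data.frame(agent_id = sim$agents$id, type = sim$agents$type,
                       home = sim$homes)
  utils::write.csv(roster, sub("\\.csv$", "_agents.csv", path),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @param env The environment the run used (rebuilds cell indices).
#' @export
read_trajectory <- function(path, env) {
  ev <- utils::read.csv(path)
  roster <- utils::read.csv(sub("\\.csv$", "_agents.csv", path))
  nr <- env$dims[1]
  events <- data.frame(
    agent_id = ev$agent_id, iteration = ev$iteration,
    origin = (ev$o_col - 1L) * nr + ev$o_row,
    destination = (ev$d_col - 1L) * nr + ev$d_row,
    distance_m = ev$distance_m, kind = ev$kind, stringsAsFactors = FALSE
  )
  structure(list(events = events,
                 agents = data.frame(id = roster$agent_id, type = roster$type,
                                     home = roster$home),
                 homes = roster$home, env = env, days = NA, seed = NA,
                 params = NULL),
            class = "mobility_sim")
}
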