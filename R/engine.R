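# Movement engine: Stage 1 decides whether an agent moves; Stage 2 routes
# routine movers to their anchor and scores irregular destinations with the
# Integrated Attraction Coefficient (IAC), a gravity-style product of
# distance decay, cluster size, cell attractiveness, a random mood factor
# and personal preference:  IAC_i = d^delta_i * g^gamma_i * theta_i * m_i * f.

#' IAC parameters
#'
#' @param d Distance-decay base, 0 < d < 1 (default 0.95): attraction falls
#'   geometrically with distance in cell units.
#' @param g Gravity base, g > 1 (default 1.02): attraction grows
#'   geometrically with the destination cluster's size in cells.
#' @param top_k Rank cutoff: the destination is drawn uniformly from the
#'   \code{top_k} highest-IAC candidate cells (default 10).
#' @param mood_sd Spread of the per-cell random mood multiplier, drawn from
#'   normal(1, \code{mood_sd}) truncated below at 0.5 (default 0.05).
#' @param favored_boost Preference multiplier applied on an agent's favored
#'   cells (default 1.5); all other cells use 1.
#' @return An \code{iac_params} list.
#' @export
iac_params <- function(d = 0.95, g = 1.02, top_k = 10,
                       mood_sd = 0.05, favored_boost = 1.5) {
  if (!(d > 0 && d < 1)) stop("d must be in (0, 1)")
  if (!(g > 1)) stop("g must exceed 1")
  if (top_k < 1) stop("top_k must be at least 1")
  if (mood_sd < 0) stop("mood_sd must be non-negative")
  structure(list(d = d, g = g, top_k = as.integer(top_k),
                 mood_sd = mood_sd, favored_boost = favored_boost),
            class = "iac_params")
}

#' Integrated Attraction Coefficient
#'
#' \code{d^delta * g^gamma * theta * mood * f}. Vectorized over all
#' arguments.
#'
#' @param delta Distance from the agent's position in cell units.
#' @param gamma Size (cells) of the cluster containing the candidate cell.
#' @param theta Specific attractiveness of the candidate cell.
#' @param mood Random mood multiplier.
#' @param f Personal preference multiplier (favored cells > 1, else 1).
#' @param params An [iac_params()] object supplying \code{d} and \code{g}.
#' @return Attraction values.
#' @examples
#' # a public-open-space cell 27.22 cell units away, in a 29-cell cluster,
#' # attractiveness 0.93, mood 1.03, not favored:
#' round(compute_iac(27.22, 29, 0.93, 1.03, 1), 2)  # 0.42
#' @export
compute_iac <- function(delta, gamma, theta, mood, f, params = iac_params()) {
  if (any(!is.finite(delta)) || any(!is.finite(gamma)) ||
      any(!is.finite(theta)) || any(!is.finite(mood)) || any(!is.finite(f)))
    stop("non-finite IAC input")
  params$d^delta * params$g^gamma * theta * mood * f
}

# Per-iteration routine windows. Anchored agents are pulled toward their
# anchor from 06:00 until their departure time on weekdays; at the departure
# iteration an agent sitting at its anchor leaves with the routine
# probability. Departure minutes by role: teenagers (school) 14:00, working
# seniors 13:00, all other anchored agents 17:00.
departure_minute <- function(type, employed) {
  ifelse(type == "teenager", 840L,
         ifelse(type == "senior" & employed, 780L, 1020L))
}

#' Stage-1 move decision for one agent
#'
#' On weekday mornings (and until their scheduled departure), anchored
#' agents away from their anchor move with the high routine probability;
#' otherwise the draw uses the move probability for the agent's type,
#' period and location context (at home / at anchor / elsewhere).
#'
#' @param type Agent type tag.
#' @param position,home,anchor Cell indices (anchor may be NA).
#' @param employed Logical.
#' @param iteration Clock iteration.
#' @param table A \code{probability_table}.
#' @return Logical: does the agent move this iteration?
#' @export
decide_move <- function(type, position, home, anchor, employed, iteration,
                        table) {
  p <- move_probability(type, position, home, anchor, employed, iteration,
                        table)
  stats::runif(1) < p
}

# The probability behind decide_move (deterministic, used by tests and the
# vectorized engine path).
move_probability <- function(type, position, home, anchor, employed,
                             iteration, table) {
  period <- period_of(iteration)
  minute <- minute_of_day(iteration)
  anchored <- !is.na(anchor)
  routine_pull <- anchored & is_weekday(iteration) &
    minute >= 360L & minute < departure_minute(type, employed) &
    position != ifelse(is.na(anchor), -1L, anchor)
  routine_leave <- anchored & is_weekday(iteration) &
    minute == departure_minute(type, employed) &
    position == ifelse(is.na(anchor), -1L, anchor)
  ctx <- ifelse(position == home, "at_home",
         ifelse(anchored & position == ifelse(is.na(anchor), -1L, anchor),
                "at_anchor", "elsewhere"))
  base <- table$move[cbind(type, period, ctx)]
  ifelse(routine_pull | routine_leave, table$routine_prob, base)
}

#' Stage-2 land-use choice
#'
#' Categorical draw from the agent type's land-use weights for the current
#' period.
#'
#' @param type Agent type tag.
#' @param period Period tag.
#' @param table A \code{probability_table}.
#' @return A land-use name.
#' @export
choose_land_use <- function(type, period, table) {
  w <- table$landuse[type, period, ]
  if (sum(w) <= 0) stop("all-zero land-use weights")
  sample(land_uses(), 1L, prob = w)
}

#' Select a destination cell by IAC ranking
#'
#' Computes the IAC for every cell of the chosen land use (excluding the
#' agent's current cell): distance from the agent's position (Euclidean,
#' cell units), the cell's cluster size, its attractiveness, a fresh
#' truncated-normal mood draw per candidate, and the preference multiplier
#' on the agent's favored cells. Candidates are ranked by IAC (ties broken
#' by cell index) and the destination drawn uniformly from the top
#' \code{min(top_k, n)} candidates.
#'
#' @param position Agent's current cell index.
#' @param favored Integer vector of the agent's favored cell indices.
#' @param land_use Land-use name to search.
#' @param env An \code{urban_environment}.
#' @param params An [iac_params()] object.
#' @return The destination cell index.
#' @export
select_destination <- function(position, favored, land_use, env,
                               params = iac_params()) {
  lu <- match(land_use, land_uses())
  if (is.na(lu)) stop("unknown land use: ", land_use)
  cand <- which(as.integer(env$land_use) == lu)
  cand <- cand[cand != position]
  if (length(cand) == 0L) stop("no candidate cell of land use ", land_use)
  nr <- env$dims[1]
  r0 <- ((position - 1L) %% nr) + 1L
  c0 <- ((position - 1L) %/% nr) + 1L
  r <- ((cand - 1L) %% nr) + 1L
  cc <- ((cand - 1L) %/% nr) + 1L
  delta <- sqrt((r - r0)^2 + (cc - c0)^2)
  gamma <- env$cluster_size[env$cluster_id[cand]]
  theta <- env$theta[cand]
  mood <- if (params$mood_sd > 0)
    pmax(stats::rnorm(length(cand), 1, params$mood_sd), 0.5) else rep(1, length(cand))
  f <- ifelse(cand %in% favored, params$favored_boost, 1)
  iac <- compute_iac(delta, gamma, theta, mood, f, params)
  ord <- order(-iac, cand)
  k <- min(params$top_k, length(cand))
  top <- ord[seq_len(k)]
  cand[top[if (k == 1L) 1L else sample.int(k, 1L)]]
}

#' Advance the simulation by one iteration
#'
#' Applies Stage 1 and Stage 2 to every agent (in a fresh random order each
#' iteration) and returns the movement events generated. Routine movers go
#' to their anchor; other movers either head home (with the period's
#' stay-home probability; staying put if already there) or pick a land use
#' and an IAC-ranked destination. Recorded event kinds: \code{routine},
#' \code{return_home}, \code{irregular}.
#'
#' @param state List with \code{agents} (an \code{agent_population}) and
#'   \code{iteration}.
#' @param env,table,params Environment, probability table and IAC
#'   parameters.
#' @return Updated state plus \code{events}, a data.frame of movements.
#' @export
sim_step <- function(state, env, table, params = iac_params()) {
  agents <- state$agents
  it <- state$iteration
  n <- nrow(agents)
  ord <- sample.int(n)
  period <- period_of(it)
  favored <- attr(agents, "favored")

  pos <- agents$position
  p_move <- move_probability(agents$type, pos, agents$home, agents$anchor,
                             agents$employed, it, table)
  moves <- stats::runif(n) < p_move
  minute <- minute_of_day(it)
  routine_pull <- !is.na(agents$anchor) & is_weekday(it) &
    minute >= 360L & minute < departure_minute(agents$type, agents$employed) &
    pos != ifelse(is.na(agents$anchor), -1L, agents$anchor)

  ev_agent <- integer(0); ev_from <- integer(0); ev_to <- integer(0)
  ev_kind <- character(0)
  stay_p <- table$stay_home[cbind(agents$type, rep(period, n))]

  for (i in ord) {
    if (!moves[i]) next
    from <- pos[i]
    if (routine_pull[i]) {
      to <- agents$anchor[i]; kind <- "routine"
    } else if (stats::runif(1) < stay_p[i]) {
      if (from == agents$home[i]) next   # staying put: no event
      to <- agents$home[i]; kind <- "return_home"
    } else {
      lu <- choose_land_use(agents$type[i], period, table)
      to <- select_destination(from, favored[i, ], lu, env, params)
      kind <- "irregular"
    }
    if (to == from) next
    pos[i] <- to
    ev_agent <- c(ev_agent, agents$id[i])
    ev_from <- c(ev_from, from); ev_to <- c(ev_to, to)
    ev_kind <- c(ev_kind, kind)
  }
  agents$position <- pos
  events <- if (length(ev_agent)) {
    nr <- env$dims[1]
    dr <- ((ev_to - 1L) %% nr) - ((ev_from - 1L) %% nr)
    dc <- ((ev_to - 1L) %/% nr) - ((ev_from - 1L) %/% nr)
    data.frame(agent_id = ev_agent, iteration = it,
               origin = ev_from, destination = ev_to,
               distance_m = sqrt(dr^2 + dc^2) * env$cell_size_m,
               kind = ev_kind, stringsAsFactors = FALSE)
  } else NULL
  list(agents = agents, iteration = it + 1L, events = events)
}

#' Run a full simulation
#'
#' Iterates [sim_step()] over \code{days} model days (96 iterations per
#' day) and collects the trajectory log.
#'
#' @param env An \code{urban_environment}.
#' @param agents An \code{agent_population} (generated if NULL).
#' @param table A \code{probability_table} (defaults shipped with the
#'   package).
#' @param params An [iac_params()] object.
#' @param days Run length in model days (default 28, a model month).
#' @param n_agents Number of agents to generate when \code{agents} is NULL.
#' @param seed Optional RNG seed covering agent generation and the run.
#' @param validate Check the probability table's constraints before
#'   running (default TRUE; disable for deliberately perturbed tables in
#'   experiments).
#' @return A \code{mobility_sim} object: \code{events} data.frame
#'   (agent_id, iteration, origin, destination, distance_m, kind),
#'   \code{agents} (final population with initial homes), \code{env},
#'   \code{days}, \code{seed}.
#' @examples
#' \donttest{
#' env <- generate_environment(dims = c(30, 30), seed = 1)
#' sim <- run_simulation(env, days = 2, n_agents = 50, seed = 2)
#' summary(sim)
#' }
#' @export
run_simulation <- function(env, agents = NULL, table = NULL,
                           params = iac_params(), days = 28,
                           n_agents = 10000, seed = NULL, validate = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(table)) table <- default_probability_table()
  if (validate) {
    val <- validate_probability_table(table)
    if (!val$ok)
      stop("invalid probability table: ", paste(val$violations, collapse = "; "))
  }
  if (is.null(agents)) agents <- generate_agents(n_agents, env)
  homes <- agents$home
  state <- list(agents = agents, iteration = 0L)
  n_iter <- as.integer(days * ITERATIONS_PER_DAY)
  chunks <- vector("list", n_iter)
  for (k in seq_len(n_iter)) {
    state <- sim_step(state, env, table, params)
    chunks[[k]] <- state$events
  }
  events <- do.call(rbind, chunks[!vapply(chunks, is.null, logical(1))])
  if (is.null(events))
    events <- data.frame(agent_id = integer(0), iteration = integer(0),
                         origin = integer(0), destination = integer(0),
                         distance_m = numeric(0), kind = character(0))
  rownames(events) <- NULL
  structure(list(events = events, agents = state$agents, homes = homes,
                 env = env, days = days, seed = seed,
                 params = params),
            class = "mobility_sim")
}
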