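# Agent population: four archetypes with homes, anchors (work or
# school/university), employment flags and 40 individually favored cells.

#' Default agent-type mix and employment rates
#'
#' Population shares for the four archetypes and the fraction of each group
#' in work. Teenagers all attend school; non-working bachelors are students
#' attending university, so every teenager and bachelor carries a
#' public-building or workplace anchor. Working seniors keep shorter
#' anchored hours than the other working groups.
#'
#' @return List with \code{proportions} and \code{employment} named vectors.
#' @export
default_population_mix <- function() {
  list(
    proportions = c(teenager = 0.15, bachelor = 0.25,
                    married = 0.45, senior = 0.15),
    employment = c(teenager = 0, bachelor = 0.6, married = 0.85, senior = 0.3),
    workplace_side_prob = c(public_building = 0.05, entertainment_retail = 0.05)
  )
}

#' Generate the agent population
#'
#' Homes are drawn uniformly from residential and mixed
#' residential/employment/retail cells. Teenagers and student (non-working)
#' bachelors get a school/university anchor drawn from public-building
#' cells; working agents get a workplace drawn from employment and mixed
#' cells, with a small probability of a public-building or
#' entertainment/retail workplace. Every agent favors 40 cells drawn
#' uniformly without replacement from the whole grid, and starts at home.
#'
#' @param n Number of agents.
#' @param env An \code{urban_environment}.
#' @param mix Population mix, defaults to [default_population_mix()].
#' @param n_favored Number of favored cells per agent (default 40).
#' @param seed Optional RNG seed.
#' @return An \code{agent_population}: data.frame with one row per agent and
#'   columns \code{id}, \code{type}, \code{home}, \code{employed},
#'   \code{anchor} (cell index or NA), \code{position}; the favored-cell
#'   sets are kept in the \code{favored} attribute (integer matrix,
#'   agents x n_favored).
#' @export
generate_agents <- function(n, env, mix = default_population_mix(),
                            n_favored = 40, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(abs(sum(mix$proportions) - 1) < 1e-9)
  land <- as.integer(env$land_use)
  n_cells <- length(land)
  code <- function(u) match(u, land_uses())
  home_pool <- which(land %in% code(c("residential", "mixed_R_E_retail")))
  school_pool <- which(land == code("public_building"))
  work_main_pool <- which(land %in% code(c("employment", "mixed_R_E_retail")))
  side_pools <- list(
    public_building = school_pool,
    entertainment_retail = which(land == code("entertainment_retail"))
  )
  for (pool in list(home_pool, school_pool, work_main_pool))
    if (length(pool) == 0L)
      stop("environment lacks cells of a land use required for agent generation")

  types <- sample(names(mix$proportions), n, replace = TRUE,
                  prob = mix$proportions)
  home <- home_pool[sample.int(length(home_pool), n, replace = TRUE)]
  employed <- stats::runif(n) < mix$employment[types]

  anchor <- rep(NA_integer_, n)
  # students: teenagers always; bachelors when not working
  student <- types == "teenager" | (types == "bachelor" & !employed)
  if (any(student))
    anchor[student] <- school_pool[sample.int(length(school_pool),
                                              sum(student), replace = TRUE)]
  workers <- employed & !student
  if (any(workers)) {
    nw <- sum(workers)
    side_p <- mix$workplace_side_prob
    u <- stats::runif(nw)
    dest <- ifelse(u < side_p[1], "public_building",
            ifelse(u < side_p[1] + side_p[2], "entertainment_retail", "main"))
    wa <- integer(nw)
    for (d in unique(dest)) {
      pool <- if (d == "main") work_main_pool else side_pools[[d]]
      sel <- dest == d
      wa[sel] <- pool[sample.int(length(pool), sum(sel), replace = TRUE)]
    }
    anchor[workers] <- wa
  }

  favored <- t(vapply(seq_len(n),
                      function(i) sample.int(n_cells, n_favored),
                      integer(n_favored)))

  agents <- data.frame(
    id = seq_len(n),
    type = types,
    home = home,
    employed = employed,
    anchor = anchor,
    position = home,
    stringsAsFactors = FALSE
  )
  attr(agents, "favored") <- favored
  attr(agents, "n_cells") <- n_cells
  class(agents) <- c("agent_population", "data.frame")
  agents
}

#' @export
print.agent_population <- function(x, ...) {
  cat("Agent population:", nrow(x), "agents\n")
  tab <- table(x$type)
  cat("  types:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  employed: %d; anchored: %d\n",
              sum(x$employed), sum(!is.na(x$anchor))))
  invisible(x)
}
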