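# Behavioural probability tables: per (agent type, period, location context)
# move probabilities, per (agent type, period) land-use choice weights and
# stay-home probabilities, plus the scalar preference/mood parameters.
#
# The shipped defaults (inst/extdata/default_probabilities.csv) are
# reconstructed: they satisfy the two published ratio constraints — a married
# agent is 2.5 times as likely as a teenager to head for a public building
# during the morning rush, and a bachelor is 25 times as likely as a married
# agent to head for entertainment and retail at night — and qualitative
# statements (high routine-morning move probability, low night-time movement).

agent_types <- function() c("teenager", "bachelor", "married", "senior")
move_contexts <- function() c("at_home", "at_anchor", "elsewhere")

#' Read a probability table from CSV
#'
#' The file is long-format with columns \code{agent_type}, \code{period},
#' \code{kind} (\code{landuse}, \code{move}, \code{stay_home} or
#' \code{param}), \code{key} and \code{value}. Land-use weights are
#' normalized to sum to 1 within each (agent type, period).
#'
#' @param path CSV path; defaults to the table shipped with the package.
#' @return A \code{probability_table}: list of arrays \code{landuse}
#'   (type x period x land use), \code{move} (type x period x context),
#'   matrix \code{stay_home} (type x period), and scalars
#'   \code{favored_boost}, \code{mood_sd}, \code{routine_prob}.
#' @export
read_probability_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default_probabilities.csv",
                        package = "urbanflow", mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  types <- agent_types(); periods <- day_periods()
  uses <- land_uses(); ctx <- move_contexts()

  landuse <- array(NA_real_, dim = c(length(types), length(periods), length(uses)),
                   dimnames = list(types, periods, uses))
  move <- array(NA_real_, dim = c(length(types), length(periods), length(ctx)),
                dimnames = list(types, periods, ctx))
  stay <- matrix(NA_real_, length(types), length(periods),
                 dimnames = list(types, periods))
  params <- list(favored_boost = 1.5, mood_sd = 0.05, routine_prob = 0.95)

  for (i in seq_len(nrow(raw))) {
    r <- raw[i, ]
    switch(r$kind,
      landuse = { landuse[r$agent_type, r$period, r$key] <- r$value },
      move = { move[r$agent_type, r$period, r$key] <- r$value },
      stay_home = { stay[r$agent_type, r$period] <- r$value },
      param = { params[[r$key]] <- r$value },
      stop("unknown kind in probability table: ", r$kind)
    )
  }
  if (anyNA(landuse) || anyNA(move) || anyNA(stay))
    stop("probability table incomplete: every (type, period) combination ",
         "needs land-use weights, move probabilities and a stay-home probability")
  # normalize land-use weights
  for (t in types) for (p in periods) {
    s <- sum(landuse[t, p, ])
    if (s <= 0) stop("all-zero land-use weights for ", t, "/", p)
    landuse[t, p, ] <- landuse[t, p, ] / s
  }
  structure(c(list(landuse = landuse, move = move, stay_home = stay), params),
            class = "probability_table")
}

#' @rdname read_probability_table
#' @export
default_probability_table <- function() read_probability_table()

#' Validate a probability table
#'
#' Checks value ranges, per-(type, period) normalization of the land-use
#' weights and the two published ratio constraints: married vs teenager
#' public-building weight at morning rush (2.5:1) and bachelor vs married
#' entertainment weight at night (25:1).
#'
#' @param table A \code{probability_table}.
#' @param tol Relative tolerance for the ratio and normalization checks.
#' @return List with \code{ok} (logical) and \code{violations}
#'   (character vector; empty when the table is valid).
#' @export
validate_probability_table <- function(table, tol = 1e-6) {
  v <- character(0)
  if (any(table$move < 0 | table$move > 1))
    v <- c(v, "move probabilities outside [0, 1]")
  if (any(table$stay_home < 0 | table$stay_home > 1))
    v <- c(v, "stay-home probabilities outside [0, 1]")
  if (any(table$landuse < 0))
    v <- c(v, "negative land-use weight")
  sums <- apply(table$landuse, c(1, 2), sum)
  bad <- abs(sums - 1) > tol
  if (any(bad))
    v <- c(v, paste0("land-use weights not normalized for: ",
                     paste(outer(rownames(sums), colnames(sums), paste,
                                 sep = "/")[bad], collapse = ", ")))
  if (table$favored_boost <= 1)
    v <- c(v, "favored_boost must exceed 1")
  r1 <- table$landuse["married", "morning_rush", "public_building"] /
        table$landuse["teenager", "morning_rush", "public_building"]
  if (!is.finite(r1) || abs(r1 - 2.5) > tol * 2.5)
    v <- c(v, sprintf("married:teenager public-building morning-rush ratio is %.4g, expected 2.5", r1))
  r2 <- table$landuse["bachelor", "night", "entertainment_retail"] /
        table$landuse["married", "night", "entertainment_retail"]
  if (!is.finite(r2) || abs(r2 - 25) > tol * 25)
    v <- c(v, sprintf("bachelor:married entertainment night ratio is %.4g, expected 25", r2))
  list(ok = length(v) == 0L, violations = v)
}

#' @export
print.probability_table <- function(x, ...) {
  cat("Behavioural probability table\n")
  cat("  agent types:", paste(dimnames(x$landuse)[[1]], collapse = ", "), "\n")
  cat("  periods:    ", paste(dimnames(x$landuse)[[2]], collapse = ", "), "\n")
  cat(sprintf("  favored_boost = %.3g, mood_sd = %.3g, routine_prob = %.3g\n",
              x$favored_boost, x$mood_sd, x$routine_prob))
  val <- validate_probability_table(x)
  cat(if (val$ok) "  constraints: satisfied\n"
      else paste0("  constraint violations:\n    ",
                  paste(val$violations, collapse = "\n    "), "\n"))
  invisible(x)
}
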