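# Model clock: 15-minute iterations, 96 per day, 7-day weeks (5 working
# days + weekend), 28-day model month, six daily periods with the morning
# rush hour carved out of the morning window.

MINUTES_PER_ITERATION <- 15L
ITERATIONS_PER_DAY <- 96L
DAYS_PER_WEEK <- 7L
DAYS_PER_MONTH <- 28L

#' Minute of day for an iteration
#'
#' @param iteration Non-negative iteration index; iteration 0 is Monday 00:00.
#' @return Minutes since midnight, in \code{[0, 1440)}.
#' @export
minute_of_day <- function(iteration) {
  (iteration %% ITERATIONS_PER_DAY) * MINUTES_PER_ITERATION
}

#' Day index for an iteration
#'
#' @inheritParams minute_of_day
#' @return 0-based day number since the start of the run.
#' @export
day_of <- function(iteration) iteration %/% ITERATIONS_PER_DAY

#' Is the iteration on a working day?
#'
#' Days 0-4 of each week are working days, days 5-6 the weekend.
#'
#' @inheritParams minute_of_day
#' @return Logical.
#' @export
is_weekday <- function(iteration) (day_of(iteration) %% DAYS_PER_WEEK) < 5L

#' Daily period of an iteration
#'
#' Maps the iteration's start minute to one of six periods: morning
#' (06:00-12:00), morning rush hour (07:30-09:30, taking precedence over
#' the enclosing morning window), noon (12:00-17:00), evening rush hour
#' (17:00-19:00), evening (19:00-22:00) and night (22:00-06:00). All
#' intervals are half-open \code{[start, end)}.
#'
#' @inheritParams minute_of_day
#' @return Character vector of period tags, one of \code{"morning"},
#'   \code{"morning_rush"}, \code{"noon"}, \code{"evening_rush"},
#'   \code{"evening"}, \code{"night"}.
#' @export
period_of <- function(iteration) {
  m <- minute_of_day(iteration)
  out <- character(length(m))
  out[m >= 360 & m < 720] <- "morning"
  out[m >= 450 & m < 570] <- "morning_rush"
  out[m >= 720 & m < 1020] <- "noon"
  out[m >= 1020 & m < 1140] <- "evening_rush"
  out[m >= 1140 & m < 1320] <- "evening"
  out[m >= 1320 | m < 360] <- "night"
  out
}

#' The six daily periods
#'
#' @return Character vector of period tags in chronological order.
#' @export
day_periods <- function() {
  c("morning", "morning_rush", "noon", "evening_rush", "evening", "night")
}
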