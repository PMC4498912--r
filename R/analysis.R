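# Emergent-statistics analysis of a trajectory log: trip-length
# distribution, per-agent visit regularity, rank-size cell popularity with
# a three-tier partition, boundary-proximity profiles, and a continuous
# power-law tail fit (MLE with KS-minimised xmin, compared against an
# exponential tail by likelihood ratio).

#' Trip distances and histogram
#'
#' One distance per movement event, plus a fixed-width histogram.
#'
#' @param sim A \code{mobility_sim} (or any list with an \code{events}
#'   data.frame carrying \code{distance_m}).
#' @param bin_width_m Histogram bin width in metres (default 250).
#' @return List with \code{distances_m} (numeric vector) and
#'   \code{histogram} (data.frame: bin_lo, bin_hi, count).
#' @export
movement_distances <- function(sim, bin_width_m = 250) {
  d <- sim$events$distance_m
  if (length(d) == 0L) stop("empty trajectory log")
  breaks <- seq(0, ceiling(max(d) / bin_width_m) * bin_width_m, bin_width_m)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE, right = FALSE)
  list(distances_m = d,
       histogram = data.frame(bin_lo = utils::head(breaks, -1),
                              bin_hi = breaks[-1],
                              count = h$counts))
}

#' Visit frequencies per cell and per agent
#'
#' Arrival-based tallies: every movement event counts one visit to its
#' destination, and each agent's starting home counts as one initial
#' visit. Staying put accrues no repeat visits.
#'
#' @param sim A \code{mobility_sim}.
#' @return A \code{visit_table}: list with \code{cell_counts} (named
#'   integer vector over visited cells), \code{agent_cell} (data.frame:
#'   agent_id, cell, visits) and \code{n_cells}.
#' @export
visit_frequencies <- function(sim) {
  ev <- sim$events
  init <- data.frame(agent_id = sim$agents$id, cell = sim$homes)
  arr <- rbind(init, data.frame(agent_id = ev$agent_id, cell = ev$destination))
  ag <- stats::aggregate(list(visits = rep(1L, nrow(arr))),
                         by = list(agent_id = arr$agent_id, cell = arr$cell),
                         FUN = sum)
  cells <- tapply(ag$visits, ag$cell, sum)
  structure(list(
    cell_counts = structure(as.integer(cells), names = names(cells)),
    agent_cell = ag[order(ag$agent_id, -ag$visits), ],
    n_cells = prod(sim$env$dims)
  ), class = "visit_table")
}

#' Per-agent top-k visit curve
#'
#' Cumulative visit counts over each agent's k most-visited locations,
#' the per-agent regularity summary behind the heavy-tailed
#' visits-per-location curves.
#'
#' @param visits A \code{visit_table}.
#' @param k Number of top locations (default 25).
#' @return Matrix (agents x k) of cumulative visit counts; rows named by
#'   agent id. Agents with fewer than k locations are padded with their
#'   total.
#' @export
top_location_curve <- function(visits, k = 25) {
  sp <- split(visits$agent_cell$visits, visits$agent_cell$agent_id)
  out <- t(vapply(sp, function(v) {
    v <- sort(v, decreasing = TRUE)
    cs <- cumsum(v)
    if (length(cs) >= k) cs[seq_len(k)] else c(cs, rep(cs[length(cs)], k - length(cs)))
  }, numeric(k)))
  out
}

#' Rank-size distribution of visits per cell
#'
#' @param visits A \code{visit_table}.
#' @param include_unvisited Append never-visited cells with zero counts
#'   (default TRUE, so ranks cover the whole grid).
#' @return data.frame (rank, cell, visits) sorted by visits descending,
#'   ties broken by cell index.
#' @export
rank_size <- function(visits, include_unvisited = TRUE) {
  counts <- visits$cell_counts
  cells <- as.integer(names(counts))
  if (include_unvisited) {
    missing <- setdiff(seq_len(visits$n_cells), cells)
    cells <- c(cells, missing)
    counts <- c(as.integer(counts), rep(0L, length(missing)))
  }
  ord <- order(-counts, cells)
  data.frame(rank = seq_along(ord), cell = cells[ord],
             visits = as.integer(counts)[ord])
}

#' Three-tier cell-popularity partition
#'
#' Splits cells into group A (visited more than the upper threshold),
#' group B (between the thresholds) and group C (below the lower
#' threshold).
#'
#' @param ranked Output of [rank_size()].
#' @param thresholds Numeric c(upper, lower), default c(10000, 1000).
#' @return A \code{popularity_partition}: list of data.frames \code{A},
#'   \code{B}, \code{C} plus \code{thresholds}.
#' @export
popularity_groups <- function(ranked, thresholds = c(10000, 1000)) {
  if (thresholds[1] <= thresholds[2]) stop("thresholds must be ordered (upper, lower)")
  grp <- ifelse(ranked$visits > thresholds[1], "A",
         ifelse(ranked$visits >= thresholds[2], "B", "C"))
  structure(list(A = ranked[grp == "A", ], B = ranked[grp == "B", ],
                 C = ranked[grp == "C", ], thresholds = thresholds),
            class = "popularity_partition")
}

#' Boundary-proximity profile of the popularity tiers
#'
#' For each popularity group, tabulates the distance of its cells to the
#' nearest land-use boundary and reports the fraction of top-tier cells
#' within the proximity cutoff.
#'
#' @param partition A \code{popularity_partition}.
#' @param env The \code{urban_environment} the run used.
#' @param proximity Cells within this boundary distance count as "near a
#'   boundary" (default 2).
#' @return List with per-group distance tables and
#'   \code{frac_A_near_boundary} (NA when the grid has no boundary or
#'   group A is empty).
#' @export
boundary_profile <- function(partition, env, proximity = 2) {
  field <- boundary_distance_field(env)
  if (all(is.na(field)))
    return(list(distances = NULL, frac_A_near_boundary = NA_real_,
                note = "single land use: no boundaries exist"))
  f <- as.integer(field)
  dists <- lapply(partition[c("A", "B", "C")], function(g) {
    if (nrow(g) == 0L) return(integer(0))
    f[g$cell]
  })
  fracA <- if (length(dists$A) == 0L) NA_real_ else mean(dists$A <= proximity)
  list(distances = dists, frac_A_near_boundary = fracA,
       proximity = proximity)
}

#' Fit a power-law tail
#'
#' Continuous power-law fit by maximum likelihood: for each candidate lower
#' cutoff xmin the exponent is the Hill estimator
#' \code{alpha = 1 + n / sum(log(x / xmin))}, and xmin is chosen to
#' minimise the Kolmogorov-Smirnov distance between the tail data and the
#' fitted distribution. The fitted tail is compared against a shifted
#' exponential alternative on the same tail by a normalised log-likelihood
#' ratio (positive favors the power law).
#'
#' @param values Positive sample (at least 50 values).
#' @param xmins Candidate cutoffs; defaults to up to 100 quantiles of the
#'   unique values below the top decile.
#' @return A \code{tail_fit}: list with \code{alpha}, \code{xmin},
#'   \code{ks}, \code{n_tail}, \code{loglik_ratio},
#'   \code{prefers} ("power_law" or "exponential").
#' @export
fit_tail <- function(values, xmins = NULL) {
  x <- values[is.finite(values) & values > 0]
  if (length(x) < 50) stop("need at least 50 positive values")
  if (length(unique(x)) < 2) stop("degenerate (constant) sample")
  if (is.null(xmins)) {
    u <- sort(unique(x))
    u <- u[u <= stats::quantile(x, 0.9)]
    if (length(u) > 100) u <- u[unique(round(seq(1, length(u), length.out = 100)))]
    xmins <- u
  }
  best <- NULL
  for (xm in xmins) {
    tail_x <- x[x >= xm]
    n <- length(tail_x)
    if (n < 25) next
    s <- sum(log(tail_x / xm))
    if (s <= 0) next
    alpha <- 1 + n / s
    cdf_emp <- (seq_len(n) - 0.5) / n
    xs <- sort(tail_x)
    cdf_fit <- 1 - (xs / xm)^(1 - alpha)
    ks <- max(abs(cdf_emp - cdf_fit))
    if (is.null(best) || ks < best$ks)
      best <- list(alpha = alpha, xmin = xm, ks = ks, n_tail = n)
  }
  if (is.null(best)) stop("no viable tail cutoff found")
  tail_x <- x[x >= best$xmin]
  n <- best$n_tail
  # log-likelihoods on the common tail
  ll_pl <- n * log((best$alpha - 1) / best$xmin) -
    best$alpha * sum(log(tail_x / best$xmin))
  rate <- 1 / mean(tail_x - best$xmin)
  ll_exp <- n * log(rate) - rate * sum(tail_x - best$xmin)
  lr <- ll_pl - ll_exp
  # Vuong-style normalisation
  li <- (log(best$alpha - 1) - log(best$xmin) -
           best$alpha * log(tail_x / best$xmin)) -
        (log(rate) - rate * (tail_x - best$xmin))
  sd_lr <- stats::sd(li) * sqrt(n)
  z <- if (sd_lr > 0) lr / sd_lr else sign(lr) * Inf
  structure(list(alpha = best$alpha, xmin = best$xmin, ks = best$ks,
                 n_tail = n, loglik_ratio = lr, vuong_z = z,
                 prefers = if (lr >= 0) "power_law" else "exponential"),
            class = "tail_fit")
}

#' @export
print.tail_fit <- function(x, ...) {
  cat(sprintf("Power-law tail fit: alpha = %.3f, xmin = %.4g (n_tail = %d)\n",
              x$alpha, x$xmin, x$n_tail))
  cat(sprintf("  KS = %.4f; loglik ratio vs exponential = %.2f (z = %.2f) -> prefers %s\n",
              x$ks, x$loglik_ratio, x$vuong_z, x$prefers))
  invisible(x)
}
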