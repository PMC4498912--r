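# S3 print / summary / plot methods for the package's core objects.

#' @export
print.urban_environment <- function(x, ...) {
  cat(sprintf("Synthetic urban environment: %d x %d cells (%g m edge)\n",
              x$dims[1], x$dims[2], x$cell_size_m))
  counts <- land_use_counts(x)
  for (i in seq_along(counts))
    cat(sprintf("  %-22s %5d cells\n", names(counts)[i], counts[i]))
  cat(sprintf("  %d clusters; adjacency: %s\n",
              length(x$cluster_size), x$adjacency))
  invisible(x)
}

#' @export
summary.urban_environment <- function(object, ...) {
  comps <- connected_components(object)
  agg <- stats::aggregate(size ~ land_use, comps,
                          function(s) c(n = length(s), max = max(s)))
  cat("Connected same-land-use components:\n")
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-22s %4d components, largest %4d cells\n",
                agg$land_use[i], agg$size[i, "n"], agg$size[i, "max"]))
  cat(sprintf("theta: mean %.3f, sd %.3f, min %.3f\n",
              mean(object$theta), stats::sd(object$theta), min(object$theta)))
  invisible(comps)
}

#' @export
plot.urban_environment <- function(x, ...) {
  graphics::image(t(x$land_use)[, rev(seq_len(x$dims[1]))],
                  col = grDevices::hcl.colors(6, "Spectral"),
                  axes = FALSE, asp = x$dims[1] / x$dims[2], ...)
  graphics::legend("topright", legend = land_uses(), cex = 0.6,
                   fill = grDevices::hcl.colors(6, "Spectral"), bg = "white")
  invisible(x)
}

#' @export
print.mobility_sim <- function(x, ...) {
  cat(sprintf("Mobility simulation: %d agents, %s days, %d movements\n",
              nrow(x$agents), format(x$days), nrow(x$events)))
  invisible(x)
}

#' @export
summary.mobility_sim <- function(object, ...) {
  ev <- object$events
  cat(sprintf("Mobility simulation: %d agents, %s days\n",
              nrow(object$agents), format(object$days)))
  cat(sprintf("  %d movements (%.2f per agent per day)\n", nrow(ev),
              nrow(ev) / nrow(object$agents) / as.numeric(object$days)))
  if (nrow(ev)) {
    kinds <- table(ev$kind)
    cat("  kinds:", paste(sprintf("%s=%d", names(kinds), kinds),
                          collapse = ", "), "\n")
    q <- stats::quantile(ev$distance_m, c(0.5, 0.9, 0.99))
    cat(sprintf("  trip distance: median %.0f m, p90 %.0f m, p99 %.0f m, max %.0f m\n",
                q[1], q[2], q[3], max(ev$distance_m)))
    cat(sprintf("  share under 500 m: %.1f%%; share over 2500 m: %.2f%%\n",
                100 * mean(ev$distance_m < 500),
                100 * mean(ev$distance_m > 2500)))
  }
  invisible(object)
}

#' @export
plot.mobility_sim <- function(x, log = "y", ...) {
  md <- movement_distances(x)
  h <- md$histogram
  keep <- h$count > 0
  graphics::plot((h$bin_lo + h$bin_hi)[keep] / 2, h$count[keep], log = log,
                 xlab = "trip distance (m)", ylab = "frequency",
                 main = "Trip-length distribution", pch = 16, ...)
  invisible(x)
}

#' @export
print.popularity_partition <- function(x, ...) {
  cat(sprintf("Cell-popularity partition (thresholds > %g, >= %g):\n",
              x$thresholds[1], x$thresholds[2]))
  cat(sprintf("  A: %d cells, B: %d cells, C: %d cells\n",
              nrow(x$A), nrow(x$B), nrow(x$C)))
  invisible(x)
}
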