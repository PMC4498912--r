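#' Land-use categories
#'
#' The six land uses carried by every grid cell, in canonical order. Integer
#' land-use codes used throughout the package index into this vector.
#'
#' @return Character vector of the six land-use names.
#' @export
land_uses <- function() {
  c("residential", "employment", "public_building",
    "mixed_R_E_retail", "entertainment_retail", "public_open_space")
}

#' Default land-use quota table
#'
#' Per-land-use cell quotas and maximum cluster sizes for the default
#' 100 x 100 grid, mirroring the mix of a dense city centre: 34%
#' residential, 10% employment, 12% public buildings, 24% mixed
#' residential/employment/retail, 8% entertainment and retail, and 12%
#' public open space. Cluster sizes are drawn from a truncated exponential
#' with mean \code{max_cluster / 3} unless overridden.
#'
#' @param n_cells Total number of grid cells the quotas must sum to
#'   (default 10000). For non-default grids the canonical percentages are
#'   apportioned by largest remainder so the quotas sum exactly.
#' @return A data.frame with columns \code{land_use}, \code{cell_quota},
#'   \code{max_cluster}, \code{size_distribution}, \code{size_mean}.
#' @export
default_quotas <- function(n_cells = 10000) {
  percent <- c(34, 10, 12, 24, 8, 12)
  max_cluster <- c(1000, 500, 200, 300, 40, 100)
  quota <- apportion_largest_remainder(percent / 100, n_cells)
  data.frame(
    land_use = land_uses(),
    cell_quota = quota,
    max_cluster = max_cluster,
    size_distribution = "exponential",
    size_mean = max_cluster / 3,
    stringsAsFactors = FALSE
  )
}

# Largest-remainder apportionment: integer quotas that sum exactly to total.
apportion_largest_remainder <- function(shares, total) {
  raw <- shares / sum(shares) * total
  base <- floor(raw)
  short <- total - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

validate_quotas <- function(quotas, n_cells) {
  stopifnot(is.data.frame(quotas))
  req <- c("land_use", "cell_quota", "max_cluster")
  if (!all(req %in% names(quotas)))
    stop("quota table must have columns: ", paste(req, collapse = ", "))
  if (!all(quotas$land_use %in% land_uses()))
    stop("unknown land use in quota table: ",
         paste(setdiff(quotas$land_use, land_uses()), collapse = ", "))
  if (anyDuplicated(quotas$land_use))
    stop("duplicated land use in quota table")
  if (any(quotas$max_cluster < 1))
    stop("max_cluster must be >= 1 for every land use")
  if (sum(quotas$cell_quota) != n_cells)
    stop("cell quotas sum to ", sum(quotas$cell_quota),
         " but the grid has ", n_cells, " cells")
  invisible(quotas)
}

#' Build the list of clusters to allocate
#'
#' Turns a quota table into a list of cluster specifications (land use +
#' target size). Sizes are drawn from each land use's configured size
#' distribution (normal or exponential), rounded and truncated to
#' \code{[1, max_cluster]}; the final cluster of each land use is clipped so
#' target sizes sum to the cell quota exactly.
#'
#' @param quotas Quota table as returned by [default_quotas()].
#' @return data.frame with columns \code{land_use} and \code{target_size};
#'   for each land use the target sizes sum exactly to its quota.
#' @export
build_cluster_list <- function(quotas) {
  validate_quotas(quotas, sum(quotas$cell_quota))
  if (is.null(quotas$size_distribution)) quotas$size_distribution <- "exponential"
  if (is.null(quotas$size_mean)) quotas$size_mean <- quotas$max_cluster / 3
  if (is.null(quotas$size_sd)) quotas$size_sd <- quotas$size_mean / 2

  specs <- lapply(seq_len(nrow(quotas)), function(i) {
    quota <- quotas$cell_quota[i]
    maxc <- quotas$max_cluster[i]
    sizes <- integer(0)
    remaining <- quota
    while (remaining > 0) {
      s <- draw_cluster_size(quotas$size_distribution[i],
                             quotas$size_mean[i], quotas$size_sd[i], maxc)
      s <- min(s, remaining)
      sizes <- c(sizes, s)
      remaining <- remaining - s
    }
    data.frame(land_use = quotas$land_use[i], target_size = sizes,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, specs)
  rownames(out) <- NULL
  out
}

draw_cluster_size <- function(dist, mean, sd, max_cluster) {
  s <- switch(dist,
    exponential = stats::rexp(1, rate = 1 / mean),
    normal = stats::rnorm(1, mean = mean, sd = sd),
    stop("unknown size distribution: ", dist)
  )
  s <- as.integer(round(s))
  min(max(s, 1L), as.integer(max_cluster))
}
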