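# Synthetic city environment: seed-and-grow land-use allocation on a lattice,
# per-cell attractiveness field, connected components and boundary distances.

neighbor_offsets <- function(adjacency = c("von_neumann", "moore")) {
  adjacency <- match.arg(adjacency)
  if (adjacency == "von_neumann") {
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  } else {
    cbind(dr = rep(c(-1L, 0L, 1L), each = 3L)[-5L],
          dc = rep(c(-1L, 0L, 1L), times = 3L)[-5L])
  }
}

# Linear-index neighbours of cell idx on an nr x nc grid (column-major).
cell_neighbors <- function(idx, nr, nc, offs) {
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  rr <- r + offs[, 1L]
  cc <- c + offs[, 2L]
  ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
  (cc[ok] - 1L) * nr + rr[ok]
}

#' Allocate land-use clusters onto the grid
#'
#' Seed-and-grow allocation: specifications are processed in random order;
#' each cluster starts at a uniformly chosen vacant cell and grows by
#' repeatedly annexing a uniformly chosen vacant neighbour (von Neumann
#' 4-adjacency by default) until it reaches its target size or is walled in.
#' A walled-in cluster is closed and its shortfall re-queued as a fresh
#' specification of the same land use, so per-land-use totals always equal
#' the quotas and no cell is left vacant.
#'
#' @param dims Integer vector \code{c(rows, cols)}.
#' @param specs Cluster specification data.frame from [build_cluster_list()].
#' @param adjacency "von_neumann" (default) or "moore".
#' Because independently placed clusters of the same land use may end up
#' adjacent, merged same-use regions are tracked with a union-find
#' structure and any seeding or annexation that would push a merged
#' connected component past its land use's \code{max_cluster} is refused,
#' so realized connected components always respect the bound. On the rare
#' layouts where the end-game deadlocks (a vacant pocket admits no queued
#' land use), allocation restarts with a fresh random arrangement.
#'
#' @param dims Integer vector \code{c(rows, cols)}.
#' @param specs Cluster specification data.frame from [build_cluster_list()];
#'   needs a \code{max_cluster} lookup via the \code{quotas} argument.
#' @param quotas Quota table giving each land use's \code{max_cluster}
#'   bound; defaults to [default_quotas()] resized to the grid.
#' @param adjacency "von_neumann" (default) or "moore".
#' @param max_retries Allocation restarts allowed before giving up.
#' @return List with integer matrices \code{land_use} (codes indexing
#'   [land_uses()]) and \code{cluster_id}, plus \code{cluster_land_use} and
#'   \code{cluster_size} vectors indexed by cluster id (cluster ids label
#'   the merged connected components).
#' @export
allocate_clusters <- function(dims, specs, quotas = NULL,
                              adjacency = "von_neumann", max_retries = 50) {
  nr <- as.integer(dims[1]); nc <- as.integer(dims[2])
  n <- nr * nc
  if (sum(specs$target_size) != n)
    stop("target sizes sum to ", sum(specs$target_size),
         " but the grid has ", n, " cells")
  if (is.null(quotas)) quotas <- default_quotas(n)
  maxc <- rep.int(n, length(land_uses()))
  maxc[match(quotas$land_use, land_uses())] <- quotas$max_cluster
  offs <- neighbor_offsets(adjacency)
  lu_code <- match(specs$land_use, land_uses())
  if (anyNA(lu_code)) stop("unknown land use in specs")

  for (attempt in seq_len(max_retries)) {
    out <- try(allocate_once(nr, nc, lu_code, as.integer(specs$target_size),
                             maxc, offs), silent = TRUE)
    if (!inherits(out, "try-error")) {
      out$adjacency <- adjacency
      return(out)
    }
  }
  stop("cluster allocation deadlocked after ", max_retries, " attempts: ",
       attr(out, "condition")$message)
}

# One allocation attempt; signals an error on deadlock.
allocate_once <- function(nr, nc, queue_lu, queue_sz, maxc, offs) {
  n <- nr * nc
  land <- integer(n)        # 0 = vacant
  vacant_left <- n
  # union-find over cells for same-use connected components
  parent <- seq_len(n)
  csize <- rep.int(1L, n)
  uf_find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # distinct same-use component roots among assigned neighbours of cell
  nb_roots <- function(cell, lu) {
    nb <- cell_neighbors(cell, nr, nc, offs)
    nb <- nb[land[nb] == lu]
    if (!length(nb)) return(integer(0))
    unique(vapply(nb, uf_find, integer(1L)))
  }
  # would assigning `cell` to `lu` keep the merged component within bound?
  merged_size <- function(cell, lu) 1L + sum(csize[nb_roots(cell, lu)])
  assign_cell <- function(cell, lu) {
    roots <- nb_roots(cell, lu)
    land[cell] <<- lu
    vacant_left <<- vacant_left - 1L
    r0 <- cell
    for (r in roots) {
      # union by size
      if (csize[r] >= csize[r0]) { parent[r0] <<- r; csize[r] <<- csize[r] + csize[r0]; r0 <- r }
      else { parent[r] <<- r0; csize[r0] <<- csize[r0] + csize[r] }
    }
    invisible(r0)
  }

  while (vacant_left > 0L) {
    if (length(queue_lu) == 0L) stop("queue exhausted with vacant cells left")
    # pick a queued spec (random order) that can seed somewhere
    ord <- sample.int(length(queue_lu))
    seeded <- FALSE
    for (k in ord) {
      lu <- queue_lu[k]
      vac <- which(land == 0L)
      vac <- vac[sample.int(length(vac))]
      # try a bounded number of random seeds before scanning the rest
      seed <- NA_integer_
      for (cand in vac) {
        if (merged_size(cand, lu) <= maxc[lu]) { seed <- cand; break }
      }
      if (!is.na(seed)) {
        target <- queue_sz[k]
        queue_lu <- queue_lu[-k]; queue_sz <- queue_sz[-k]
        assign_cell(seed, lu)
        placed <- 1L
        frontier <- cell_neighbors(seed, nr, nc, offs)
        frontier <- frontier[land[frontier] == 0L]
        while (placed < target && length(frontier) > 0L) {
          pick <- if (length(frontier) == 1L) 1L else sample.int(length(frontier), 1L)
          cell <- frontier[pick]
          frontier <- frontier[-pick]
          if (land[cell] != 0L) next
          if (merged_size(cell, lu) > maxc[lu]) next  # would over-merge
          assign_cell(cell, lu)
          placed <- placed + 1L
          nb <- cell_neighbors(cell, nr, nc, offs)
          nb <- nb[land[nb] == 0L]
          if (length(nb)) frontier <- unique(c(frontier, nb))
        }
        if (placed < target) {   # walled in: re-queue shortfall
          queue_lu <- c(queue_lu, lu)
          queue_sz <- c(queue_sz, target - placed)
        }
        seeded <- TRUE
        break
      }
    }
    if (!seeded) stop("no queued land use can occupy the remaining vacant cells")
  }
  # component labels from union-find roots
  roots <- vapply(seq_len(n), uf_find, integer(1L))
  ids <- match(roots, unique(roots))
  ncl <- max(ids)
  cl_sz <- tabulate(ids, nbins = ncl)
  cl_lu <- integer(ncl)
  cl_lu[ids] <- land
  list(land_use = matrix(land, nr, nc),
       cluster_id = matrix(ids, nr, nc),
       cluster_land_use = cl_lu,
       cluster_size = cl_sz)
}

#' Draw the per-cell attractiveness field
#'
#' Every cell receives a specific attractiveness theta drawn from a normal
#' distribution, truncated below at a small positive floor so the
#' gravity-style destination score stays positive.
#'
#' @param n Number of cells.
#' @param mean,sd Normal parameters (defaults 1.0 and 0.05).
#' @param floor Lower truncation bound (default 0.05).
#' @return Numeric vector of length \code{n}, all values \code{>= floor}.
#' @export
draw_attractiveness <- function(n, mean = 1.0, sd = 0.05, floor = 0.05) {
  if (mean <= 0) stop("attractiveness mean must be positive")
  if (sd < 0) stop("attractiveness sd must be non-negative")
  pmax(stats::rnorm(n, mean, sd), floor)
}

#' Generate a synthetic urban environment
#'
#' Full pipeline: build the cluster list from the quota table, allocate
#' clusters by seed-and-grow, and draw the attractiveness field. The result
#' is an \code{urban_environment} object: per-cell land use, cluster id and
#' attractiveness on a lattice of square cells.
#'
#' @param dims Grid dimensions, default \code{c(100, 100)}.
#' @param quotas Quota table; default [default_quotas()] scaled to the grid.
#' @param cell_size_m Physical cell edge length in metres (default 25).
#' @param theta_mean,theta_sd,theta_floor Attractiveness field parameters.
#' @param adjacency Cluster growth adjacency, "von_neumann" or "moore".
#' @param seed Optional RNG seed for a reproducible environment.
#' @return An object of class \code{urban_environment}.
#' @examples
#' env <- generate_environment(dims = c(20, 20), seed = 1)
#' summary(env)
#' @export
generate_environment <- function(dims = c(100, 100), quotas = NULL,
                                 cell_size_m = 25,
                                 theta_mean = 1.0, theta_sd = 0.05,
                                 theta_floor = 0.05,
                                 adjacency = "von_neumann", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- prod(dims)
  if (is.null(quotas)) quotas <- default_quotas(n)
  validate_quotas(quotas, n)
  specs <- build_cluster_list(quotas)
  alloc <- allocate_clusters(dims, specs, quotas, adjacency)
  theta <- matrix(draw_attractiveness(n, theta_mean, theta_sd, theta_floor),
                  dims[1], dims[2])
  structure(list(
    dims = as.integer(dims),
    cell_size_m = cell_size_m,
    land_use = alloc$land_use,
    cluster_id = alloc$cluster_id,
    cluster_land_use = alloc$cluster_land_use,
    cluster_size = alloc$cluster_size,
    theta = theta,
    quotas = quotas,
    adjacency = adjacency,
    seed = seed
  ), class = "urban_environment")
}

#' Connected same-land-use components
#'
#' Flood-fills the grid into maximal connected components of equal land use
#' under the environment's growth adjacency. Used to validate that realized
#' contiguous regions respect each land use's maximum cluster size.
#'
#' @param env An \code{urban_environment}.
#' @return data.frame with one row per component: \code{land_use},
#'   \code{size}; sizes sum to the total cell count.
#' @export
connected_components <- function(env) {
  land <- env$land_use
  if (any(land == 0L)) stop("grid has unassigned cells")
  nr <- nrow(land); nc <- ncol(land); n <- nr * nc
  offs <- neighbor_offsets(env$adjacency)
  comp <- integer(n)
  land_v <- as.integer(land)
  sizes <- integer(0); lus <- integer(0)
  ncomp <- 0L
  stack <- integer(n)
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    ncomp <- ncomp + 1L
    lu <- land_v[start]
    comp[start] <- ncomp
    top <- 1L; stack[1L] <- start
    sz <- 0L
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      sz <- sz + 1L
      nb <- cell_neighbors(cur, nr, nc, offs)
      nb <- nb[comp[nb] == 0L & land_v[nb] == lu]
      for (x in nb) {
        comp[x] <- ncomp
        top <- top + 1L; stack[top] <- x
      }
    }
    sizes <- c(sizes, sz); lus <- c(lus, lu)
  }
  data.frame(land_use = land_uses()[lus], size = sizes,
             stringsAsFactors = FALSE)
}

#' Distance to the nearest land-use boundary
#'
#' Minimum number of lattice steps (under the environment's adjacency) from
#' a cell to any cell of a different land use; 1 means the cell touches a
#' boundary. Computed for the whole grid by per-land-use multi-source
#' breadth-first search.
#'
#' @param env An \code{urban_environment}.
#' @return Integer matrix of distances; \code{NA} if the grid carries a
#'   single land use (no boundary exists).
#' @export
boundary_distance_field <- function(env) {
  land <- env$land_use
  nr <- nrow(land); nc <- ncol(land); n <- nr * nc
  land_v <- as.integer(land)
  if (length(unique(land_v)) < 2L)
    return(matrix(NA_integer_, nr, nc))
  offs <- neighbor_offsets(env$adjacency)
  dist <- rep(NA_integer_, n)
  for (lu in unique(land_v)) {
    idx_lu <- which(land_v == lu)
    # sources: all cells of a *different* use, at distance 0
    d <- rep(NA_integer_, n)
    queue <- which(land_v != lu)
    d[queue] <- 0L
    level <- 0L
    while (length(queue) > 0L) {
      level <- level + 1L
      r <- ((queue - 1L) %% nr) + 1L
      cc0 <- ((queue - 1L) %/% nr) + 1L
      nxt <- integer(0)
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs[k, 1L]; cc <- cc0 + offs[k, 2L]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        nb <- (cc[ok] - 1L) * nr + rr[ok]
        nxt <- c(nxt, nb[is.na(d[nb])])
      }
      nxt <- unique(nxt)
      nxt <- nxt[is.na(d[nxt])]
      d[nxt] <- level
      queue <- nxt
    }
    dist[idx_lu] <- d[idx_lu]
  }
  matrix(dist, nr, nc)
}

#' @rdname boundary_distance_field
#' @param row,col Cell indices (1-based).
#' @return \code{boundary_distance}: the distance for one cell.
#' @export
boundary_distance <- function(env, row, col) {
  boundary_distance_field(env)[row, col]
}

#' Per-land-use cell counts
#'
#' @param env An \code{urban_environment}.
#' @return Named integer vector of realized cell counts per land use.
#' @export
land_use_counts <- function(env) {
  counts <- tabulate(as.integer(env$land_use), nbins = length(land_uses()))
  names(counts) <- land_uses()
  counts
}

#' Export / import the environment as plain text
#'
#' Writes (and reads back) the per-cell table — row, col, land_use,
#' cluster_id, theta — as CSV, plus an integer land-use raster as
#' whitespace-delimited text.
#'
#' @param env An \code{urban_environment}.
#' @param path Output directory (created if needed).
#' @return \code{write_environment} returns the paths invisibly;
#'   \code{read_environment} returns the reconstructed
#'   \code{urban_environment}.
#' @export
write_environment <- function(env, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  nr <- env$dims[1]; nc <- env$dims[2]
  cells <- data.frame(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    land_use = land_uses()[as.integer(env$land_use)],
    cluster_id = as.integer(env$cluster_id),
    theta = as.numeric(env$theta)
  )
  cells_path <- file.path(path, "cells.csv")
  raster_path <- file.path(path, "land_use_raster.txt")
  meta_path <- file.path(path, "environment.json")
  utils::write.csv(cells, cells_path, row.names = FALSE)
  write(t(env$land_use), raster_path, ncolumns = nc)
  jsonlite::write_json(list(dims = env$dims, cell_size_m = env$cell_size_m,
                            adjacency = env$adjacency, seed = env$seed),
                       meta_path, auto_unbox = TRUE, null = "null")
  invisible(c(cells = cells_path, raster = raster_path, meta = meta_path))
}

#' @rdname write_environment
#' @export
read_environment <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "environment.json"),
                              simplifyVector = TRUE)
  cells <- utils::read.csv(file.path(path, "cells.csv"))
  nr <- meta$dims[1]; nc <- meta$dims[2]
  idx <- (cells$col - 1L) * nr + cells$row
  land <- integer(nr * nc); land[idx] <- match(cells$land_use, land_uses())
  clid <- integer(nr * nc); clid[idx] <- cells$cluster_id
  theta <- numeric(nr * nc); theta[idx] <- cells$theta
  clid_m <- matrix(clid, nr, nc)
  land_m <- matrix(land, nr, nc)
  ncl <- max(clid)
  cl_sz <- tabulate(clid, nbins = ncl)
  cl_lu <- integer(ncl)
  cl_lu[clid] <- land
  env <- structure(list(
    dims = c(nr, nc), cell_size_m = meta$cell_size_m,
    land_use = land_m, cluster_id = clid_m,
    cluster_land_use = cl_lu, cluster_size = cl_sz,
    theta = matrix(theta, nr, nc),
    quotas = NULL, adjacency = meta$adjacency,
    seed = if (is.null(meta$seed)) NULL else meta$seed
  ), class = "urban_environment")
  env
}
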