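# Shared fixtures: tiny environments built in code, plus independent
# oracles used to cross-check the package's implementations.

# Build an urban_environment directly from a land-use code matrix
# (clusters labelled by flood fill, constant attractiveness unless given).
env_from_matrix <- function(land, theta = 1, cell_size_m = 25,
                            adjacency = "von_neumann") {
  nr <- nrow(land); nc <- ncol(land); n <- nr * nc
  land_v <- as.integer(land)
  offs <- if (adjacency == "von_neumann")
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1)) else
    cbind(rep(-1:1, each = 3)[-5], rep(-1:1, 3)[-5])
  comp <- integer(n)
  ncomp <- 0L
  for (start in seq_len(n)) {
    if (comp[start]) next
    ncomp <- ncomp + 1L
    queue <- start; comp[start] <- ncomp
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- ((cur - 1) %% nr) + 1; c <- ((cur - 1) %/% nr) + 1
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs[k, 1]; cc <- c + offs[k, 2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        idx <- (cc - 1) * nr + rr
        if (!comp[idx] && land_v[idx] == land_v[cur]) {
          comp[idx] <- ncomp; queue <- c(queue, idx)
        }
      }
    }
  }
  cl_sz <- tabulate(comp, nbins = ncomp)
  cl_lu <- integer(ncomp); cl_lu[comp] <- land_v
  th <- if (length(theta) == 1) matrix(theta, nr, nc) else theta
  structure(list(dims = c(nr, nc), cell_size_m = cell_size_m,
                 land_use = matrix(land_v, nr, nc),
                 cluster_id = matrix(comp, nr, nc),
                 cluster_land_use = cl_lu, cluster_size = cl_sz,
                 theta = th, quotas = NULL, adjacency = adjacency,
                 seed = NULL),
            class = "urban_environment")
}

# A small mixed environment with all six land uses present (12 x 12).
small_mixed_env <- function(theta = 1) {
  land <- matrix(1L, 12, 12)
  land[1:6, 7:12] <- 2L    # employment
  land[7:12, 1:6] <- 3L    # public_building
  land[7:12, 7:9] <- 4L    # mixed
  land[7:9, 10:12] <- 5L   # entertainment_retail
  land[10:12, 10:12] <- 6L # public_open_space
  env_from_matrix(land, theta)
}

# Independent oracle: minimum Manhattan distance from each cell to any cell
# of a different land use (exhaustive search).
oracle_boundary_distance <- function(env, row, col) {
  land <- env$land_use
  lu <- land[row, col]
  other <- which(land != lu, arr.ind = TRUE)
  if (nrow(other) == 0) return(NA_integer_)
  min(abs(other[, 1] - row) + abs(other[, 2] - col))
}

# Independent oracle: argmax-IAC destination by direct enumeration
# (mood = 1, i.e. mood_sd = 0).
oracle_best_destination <- function(position, favored, land_use, env, params) {
  lu <- match(land_use, urbanflow::land_uses())
  cand <- which(as.integer(env$land_use) == lu)
  cand <- cand[cand != position]
  nr <- env$dims[1]
  r0 <- ((position - 1) %% nr) + 1; c0 <- ((position - 1) %/% nr) + 1
  best <- NA_integer_; best_iac <- -Inf
  for (cell in cand) {
    r <- ((cell - 1) %% nr) + 1; cc <- ((cell - 1) %/% nr) + 1
    delta <- sqrt((r - r0)^2 + (cc - c0)^2)
    gamma <- env$cluster_size[env$cluster_id[cell]]
    f <- if (cell %in% favored) params$favored_boost else 1
    iac <- params$d^delta * params$g^gamma * env$theta[cell] * f
    if (iac > best_iac + 1e-15) { best_iac <- iac; best <- cell }
  }
  best
}

# A probability table with every move probability set to a constant and
# uniform land-use weights (built from the shipped default's structure).
flat_table <- function(move_p = 0.5, stay_home = 0, routine_prob = 0.95,
                       mood_sd = 0.05) {
  tab <- urbanflow::default_probability_table()
  tab$move[] <- move_p
  tab$stay_home[] <- stay_home
  tab$landuse[] <- 1 / 6
  tab$routine_prob <- routine_prob
  tab$mood_sd <- mood_sd
  tab
}
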