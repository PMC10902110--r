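# Independent oracles used across tests. These deliberately avoid the
# package's sparse solve path: dense pseudoinverse linear algebra and
# brute-force enumeration only.

# dense weighted Laplacian of a raster_graph
dense_laplacian <- function(graph) {
  L <- matrix(0, graph$n, graph$n)
  for (e in seq_along(graph$a)) {
    i <- graph$a[e]; j <- graph$b[e]; g <- graph$g[e]
    L[i, j] <- L[i, j] - g
    L[j, i] <- L[j, i] - g
    L[i, i] <- L[i, i] + g
    L[j, j] <- L[j, j] + g
  }
  L
}

# potentials via Moore-Penrose pseudoinverse, grounded at `target`
oracle_potentials <- function(graph, source, target) {
  L <- dense_laplacian(graph)
  e <- numeric(graph$n); e[source] <- 1; e[target] <- -1
  v <- MASS::ginv(L) %*% e
  as.numeric(v - v[target])
}

oracle_effective_resistance <- function(graph, a, b) {
  v <- oracle_potentials(graph, a, b)
  v[a] - v[b]
}

# per-cell current density from oracle potentials
oracle_density <- function(graph, source, target) {
  v <- oracle_potentials(graph, source, target)
  cur <- numeric(graph$n)
  for (e in seq_along(graph$a)) {
    f <- abs(graph$g[e] * (v[graph$a[e]] - v[graph$b[e]]))
    cur[graph$a[e]] <- cur[graph$a[e]] + f / 2
    cur[graph$b[e]] <- cur[graph$b[e]] + f / 2
  }
  cur[c(source, target)] <- 1
  cur
}

# uniform-resistance raster of given shape
uniform_raster <- function(nr, nc, value = 1, cell_size = 10) {
  grid_raster(matrix(value, nr, nc), cell_size = cell_size)
}

# random-resistance raster drawn from the three resistance classes
random_resistance_raster <- function(nr, nc, seed) {
  set.seed(seed)
  grid_raster(matrix(sample(c(1, 10, 100), nr * nc, replace = TRUE), nr, nc))
}

# a two-corridor toy landscape: two horizontal low-resistance corridors
# through a hostile matrix, joined by conductive end columns; terminals at
# the mid-left and mid-right cells. Returns graph plus corridor cell indices.
two_corridor_graph <- function(r_top = 10, r_bottom = 10, ncols = 11) {
  m <- matrix(100, 5, ncols)
  m[2, ] <- r_top
  m[4, ] <- r_bottom
  m[, 1] <- 1
  m[, ncols] <- 1
  g <- build_raster_graph(grid_raster(m), neighbourhood = 4)
  idx <- matrix(seq_len(5 * ncols), 5, ncols)
  list(graph = g,
       source = idx[3, 1], target = idx[3, ncols],
       top = idx[2, 2:(ncols - 1)], bottom = idx[4, 2:(ncols - 1)])
}

# site metrics table with externally supplied connectivity, for community
# generation without running the raster stages
toy_metrics <- function(n, connectivity, scale_m = 900, types = NULL) {
  data.frame(pond_id = sprintf("P%03d", seq_len(n)), scale_m = scale_m,
             mean_current = connectivity, sd_current = abs(connectivity) / 2,
             n_neighbours = seq_len(n) %% 7,
             type = types %||% rep("stormwater", n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
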