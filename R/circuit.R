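#' Build the electrical graph of a resistance raster
#'
#' Every cell becomes a graph node (column-major cell index, matching R's
#' matrix indexing); every orthogonally — and, with the 8-neighbourhood,
#' diagonally — adjacent cell pair becomes an undirected edge of conductance
#' `g = 1 / (mean(r_a, r_b) * d)` with centre-to-centre distance `d = 1` for
#' orthogonal and `d = sqrt(2)` for diagonal neighbours (in cell units).
#'
#' @param r a resistance [grid_raster()]; all values must be finite and > 0.
#' @param neighbourhood 4 or 8 (default 8).
#' @return an object of class `raster_graph`: cell count, grid dimensions,
#'   edge arrays (`a`, `b`, `g`), the sparse weighted Laplacian, and a sparse
#'   cell-by-edge incidence pattern used to accumulate per-cell current.
#' @export
build_raster_graph <- function(r, neighbourhood = 8) {
  stopifnot(inherits(r, "grid_raster"))
  neighbourhood <- match.arg(as.character(neighbourhood), c("8", "4"))
  neighbourhood <- as.integer(neighbourhood)
  res <- r$data
  if (any(!is.finite(res)) || any(res <= 0)) {
    stop("all resistance values must be finite and > 0")
  }
  nr <- nrow(res); nc <- ncol(res)
  n <- nr * nc
  idx <- matrix(seq_len(n), nr, nc)

  a <- integer(0); b <- integer(0); d <- numeric(0)
  if (nc > 1) { # horizontal
    a <- c(a, as.vector(idx[, -nc])); b <- c(b, as.vector(idx[, -1]))
    d <- c(d, rep(1, nr * (nc - 1)))
  }
  if (nr > 1) { # vertical
    a <- c(a, as.vector(idx[-nr, ])); b <- c(b, as.vector(idx[-1, ]))
    d <- c(d, rep(1, (nr - 1) * nc))
  }
  if (neighbourhood == 8 && nr > 1 && nc > 1) {
    a <- c(a, as.vector(idx[-nr, -nc])); b <- c(b, as.vector(idx[-1, -1]))
    a <- c(a, as.vector(idx[-1, -nc]));  b <- c(b, as.vector(idx[-nr, -1]))
    d <- c(d, rep(sqrt(2), 2 * (nr - 1) * (nc - 1)))
  }
  rv <- as.vector(res)
  g <- 1 / (((rv[a] + rv[b]) / 2) * d)

  lap <- Matrix::sparseMatrix(
    i = c(a, b, a, b), j = c(b, a, a, b), x = c(-g, -g, g, g),
    dims = c(n, n)
  )
  # cell-by-edge incidence (unsigned): accumulates |edge current| per cell
  inc <- Matrix::sparseMatrix(
    i = c(a, b), j = rep(seq_along(a), 2), x = 1, dims = c(n, length(a))
  )
  structure(
    list(n = n, dim = c(nr, nc), a = a, b = b, g = g,
         laplacian = lap, incidence = inc,
         neighbourhood = neighbourhood, raster = r),
    class = "raster_graph"
  )
}

#' @export
print.raster_graph <- function(x, ...) {
  cat(sprintf("raster_graph: %d cells (%d x %d), %d edges, %d-neighbourhood\n",
              x$n, x$dim[1], x$dim[2], length(x$a), x$neighbourhood))
  invisible(x)
}

# Solve L v = e with v[ground] = 0 on the reduced Laplacian (the grounded
# system is symmetric positive definite). `rhs` is the full-length injection
# vector; returns full-length potentials. A cached Cholesky factor of the
# reduced Laplacian can be supplied to amortize repeated solves.
solve_grounded <- function(graph, rhs, ground, chol_factor = NULL) {
  keep <- setdiff(seq_len(graph$n), ground)
  if (is.null(chol_factor)) {
    chol_factor <- Matrix::Cholesky(
      Matrix::forceSymmetric(graph$laplacian[keep, keep, drop = FALSE]),
      LDL = FALSE)
  }
  v <- numeric(graph$n)
  v[keep] <- as.numeric(Matrix::solve(chol_factor, rhs[keep]))
  v
}

check_pair_residual <- function(graph, v, rhs, source, target, tol = 1e-8) {
  resid <- as.numeric(graph$laplacian %*% v) - rhs
  rel <- sqrt(sum(resid^2)) / sqrt(sum(rhs^2))
  if (!is.finite(rel) || rel > tol) {
    stop(sprintf(
      "linear solve failed between cells %d and %d (relative residual %.3g); are they connected?",
      source, target, rel))
  }
  rel
}

#' Solve the circuit for one source/target pair
#'
#' Injects one unit of current at `source`, extracts it at `target`
#' (grounded at 0 V), and solves Kirchhoff's laws `L v = e` on the reduced
#' weighted graph Laplacian.
#'
#' @param graph a [build_raster_graph()] result.
#' @param source,target distinct cell indices (column-major).
#' @return an object of class `pair_solve`: `potentials` (volts per unit
#'   current, `potentials[target] == 0`), `source`, `target`, and the
#'   relative residual of the solve.
#' @export
solve_pair <- function(graph, source, target) {
  stopifnot(inherits(graph, "raster_graph"))
  source <- as.integer(source); target <- as.integer(target)
  if (source == target) stop("source and target must differ")
  stopifnot(source >= 1, source <= graph$n, target >= 1, target <= graph$n)
  rhs <- numeric(graph$n)
  rhs[source] <- 1; rhs[target] <- -1
  v <- tryCatch(
    solve_grounded(graph, rhs, ground = target),
    error = function(e) stop(sprintf(
      "cannot solve pair (%d, %d): %s", source, target, conditionMessage(e)))
  )
  resid <- check_pair_residual(graph, v, rhs, source, target)
  structure(list(potentials = v, source = source, target = target,
                 residual = resid),
            class = "pair_solve")
}

#' Per-cell current density for one pair solve
#'
#' For every non-terminal cell `i`, half the summed absolute currents on its
#' incident edges, `c_i = 0.5 * sum_j |g_ij (v_i - v_j)|` (current enters and
#' leaves, so the raw sum double-counts the through-flow). Terminal cells
#' carry the injected current (1).
#'
#' @param graph a [build_raster_graph()] result.
#' @param solve a [solve_pair()] result on that graph.
#' @return numeric vector of length `graph$n` of current densities.
#' @export
pair_current_density <- function(graph, solve) {
  stopifnot(inherits(graph, "raster_graph"), inherits(solve, "pair_solve"))
  v <- solve$potentials
  flow <- graph$g * (v[graph$a] - v[graph$b])
  cur <- 0.5 * as.numeric(graph$incidence %*% abs(flow))
  cur[c(solve$source, solve$target)] <- 1
  cur
}

#' Effective resistance between two cells
#'
#' Potential difference per unit injected current; the circuit-theory
#' distance that shrinks as parallel pathways multiply.
#'
#' @inheritParams solve_pair
#' @param a,b distinct cell indices.
#' @return a single positive number.
#' @export
effective_resistance <- function(graph, a, b) {
  s <- solve_pair(graph, a, b)
  s$potentials[a] - s$potentials[b]
}

#' Mean current-density map over random perimeter node pairs
#'
#' Iterates node pairs (by default all `choose(n, 2)` unordered pairs),
#' solves each circuit, and averages the per-cell current densities into an
#' omnidirectional connectivity surface. Because raw current density is
#' non-negative and strongly right-skewed, the map is log10-transformed by
#' default after flooring at `log10_floor`; the transform and floor are
#' recorded on the result.
#'
#' @param graph a [build_raster_graph()] result.
#' @param nodes a [place_perimeter_nodes()] data.frame (columns `row`, `col`).
#' @param log10_floor positive floor applied before log10, or `NULL` to keep
#'   the raw mean densities. Default `1e-12`.
#' @param pair_mode `"all"` (default): all unordered pairs; `"nearest"`:
#'   each node paired only with its 8 nearest node neighbours (unique
#'   unordered pairs).
#' @param progress print a line every 200 pairs (default `FALSE`).
#' @return a [grid_raster()] of mean current density with attributes
#'   `n_pairs`, `log10_applied` and `log10_floor`.
#' @export
mean_current_map <- function(graph, nodes, log10_floor = 1e-12,
                             pair_mode = c("all", "nearest"),
                             progress = FALSE) {
  stopifnot(inherits(graph, "raster_graph"))
  pair_mode <- match.arg(pair_mode)
  nr <- graph$dim[1]
  node_cells <- (nodes$col - 1L) * nr + nodes$row
  k <- length(node_cells)
  if (k < 2) stop("need at least 2 nodes")
  if (anyDuplicated(node_cells)) stop("node cells must be distinct")

  if (pair_mode == "all") {
    pairs <- utils::combn(k, 2)
  } else {
    dx <- outer(nodes$x, nodes$x, "-"); dy <- outer(nodes$y, nodes$y, "-")
    dist <- sqrt(dx^2 + dy^2); diag(dist) <- Inf
    m <- min(8, k - 1)
    pl <- lapply(seq_len(k), function(i) {
      nb <- order(dist[i, ])[seq_len(m)]
      rbind(pmin(i, nb), pmax(i, nb))
    })
    pairs <- unique(t(do.call(cbind, pl)))
    pairs <- t(pairs)
  }
  n_pairs <- ncol(pairs)

  # one Cholesky factorization of the Laplacian grounded at a fixed
  # non-node cell, reused for every pair (potentials are shift-invariant)
  ground <- setdiff(seq_len(graph$n), node_cells)[1]
  if (is.na(ground)) stop("no non-node cell available for grounding")
  keep <- setdiff(seq_len(graph$n), ground)
  ch <- Matrix::Cholesky(
    Matrix::forceSymmetric(graph$laplacian[keep, keep, drop = FALSE]),
    LDL = FALSE)

  acc <- numeric(graph$n)
  for (p in seq_len(n_pairs)) {
    s <- node_cells[pairs[1, p]]; t <- node_cells[pairs[2, p]]
    rhs <- numeric(graph$n)
    rhs[s] <- 1; rhs[t] <- -1
    v <- numeric(graph$n)
    v[keep] <- as.numeric(Matrix::solve(ch, rhs[keep]))
    resid <- as.numeric(graph$laplacian %*% v) - rhs
    if (sqrt(sum(resid^2)) / sqrt(2) > 1e-8) {
      stop(sprintf("disconnected or ill-conditioned node pair (cells %d, %d)", s, t))
    }
    flow <- graph$g * (v[graph$a] - v[graph$b])
    cur <- 0.5 * as.numeric(graph$incidence %*% abs(flow))
    cur[c(s, t)] <- 1
    acc <- acc + cur
    if (progress && p %% 200 == 0) {
      message(sprintf("  pair %d / %d", p, n_pairs))
    }
  }
  mean_cur <- acc / n_pairs

  log10_applied <- !is.null(log10_floor)
  vals <- if (log10_applied) log10(pmax(mean_cur, log10_floor)) else mean_cur
  r <- graph$raster
  out <- grid_raster(matrix(vals, nr, graph$dim[2]),
                     cell_size = r$cell_size, xll = r$xll, yll = r$yll,
                     study_mask = r$study_mask)
  attr(out, "n_pairs") <- n_pairs
  attr(out, "log10_applied") <- log10_applied
  attr(out, "log10_floor") <- if (log10_applied) log10_floor else NA_real_
  out
}
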