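#' Mean and SD of current within a circular buffer
#'
#' Summarizes a current map over all cells whose centre lies within
#' Euclidean distance `radius_m` of a site (inclusive boundary). The SD is
#' the sample standard deviation (n - 1), recorded in the result.
#'
#' @param map a current [grid_raster()] (see [mean_current_map()]).
#' @param x,y site coordinates, same projection as the map.
#' @param radius_m buffer radius in metres (> 0).
#' @return named vector `c(mean=, sd=, n=)`; `sd` is 0 for a single cell.
#' @export
extract_buffer_stats <- function(map, x, y, radius_m) {
  stopifnot(inherits(map, "grid_raster"), radius_m > 0)
  dx <- cell_x(map) - x
  dy <- cell_y(map) - y
  # squared-distance matrix via outer sums; rows = y, cols = x
  within <- outer(dy^2, dx^2, "+") <= radius_m^2
  vals <- map$data[within]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) {
    stop(sprintf("no cell centres within %.6g m of (%.6g, %.6g)", radius_m, x, y))
  }
  c(mean = mean(vals),
    sd = if (length(vals) > 1) stats::sd(vals) else 0,
    n = length(vals))
}

#' Count habitat neighbours within a radius
#'
#' Number of habitat points (wetland/water centroids plus active stormwater
#' facility points) within `radius_m` of a site, inclusive boundary. Points
#' closer than `self_tolerance` (default half a 10 m cell) are treated as
#' the focal pond's own point and excluded.
#'
#' @param x,y site coordinates.
#' @param radius_m radius in metres (> 0).
#' @param points data.frame with columns `x`, `y`.
#' @param self_tolerance exclusion distance for the focal point (default 5).
#' @return a non-negative integer count.
#' @export
count_neighbours <- function(x, y, radius_m, points, self_tolerance = 5) {
  stopifnot(radius_m > 0)
  if (is.null(points) || nrow(points) == 0) return(0L)
  d <- sqrt((points$x - x)^2 + (points$y - y)^2)
  sum(d <= radius_m & d >= self_tolerance)
}

#' Area-weighted centroids of habitat polygons
#'
#' Computes the shoelace-formula centroid of each simple polygon, dropping
#' polygons whose class is excluded (large rivers by default — the focal
#' species are pond breeders) and, with a warning, degenerate zero-area
#' polygons.
#'
#' @param polygons data.frame of vertex rows with columns `id`, `class`,
#'   `x`, `y`; vertices of each polygon in order (closure optional).
#' @param exclude_classes classes to drop (default `"large_rivers"`).
#' @return data.frame `id`, `class`, `x`, `y` of centroids.
#' @export
polygon_centroids <- function(polygons, exclude_classes = "large_rivers") {
  stopifnot(is.data.frame(polygons),
            all(c("id", "class", "x", "y") %in% names(polygons)))
  ids <- unique(polygons$id)
  out <- lapply(ids, function(pid) {
    p <- polygons[polygons$id == pid, , drop = FALSE]
    if (p$class[1] %in% exclude_classes) return(NULL)
    x <- p$x; y <- p$y
    if (x[1] == x[length(x)] && y[1] == y[length(y)] && length(x) > 1) {
      x <- x[-length(x)]; y <- y[-length(y)]
    }
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    cross <- x * yn - xn * y
    area <- sum(cross) / 2
    if (abs(area) < .Machine$double.eps * 100) {
      warning(sprintf("dropping degenerate zero-area polygon '%s'", pid))
      return(NULL)
    }
    data.frame(id = pid, class = p$class[1],
               x = sum((x + xn) * cross) / (6 * area),
               y = sum((y + yn) * cross) / (6 * area),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(id = character(0), class = character(0),
                      x = numeric(0), y = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Centroids of contiguous habitat patches on a categorical raster
#'
#' Labels orthogonally connected components of the requested land-cover
#' classes and returns each patch's cell-centroid — the raster analogue of
#' wetland/water polygon centroids, used to assemble the neighbour point
#' set for synthetic landscapes.
#'
#' @param land a categorical [grid_raster()].
#' @param classes class names to include (default wetlands and water).
#' @return data.frame `id`, `class`, `x`, `y`, `n_cells`.
#' @export
patch_centroids <- function(land, classes = c("wetlands", "water")) {
  stopifnot(inherits(land, "grid_raster"), !is.null(land$levels))
  nr <- nrow(land$data); nc <- ncol(land$data)
  codes <- match(classes, land$levels)
  lab <- matrix(0L, nr, nc)
  nextlab <- 0L
  res <- list()
  for (code in codes) {
    todo <- which(land$data == code & lab == 0L)
    while (length(todo) > 0) {
      nextlab <- nextlab + 1L
      frontier <- todo[1]
      lab[frontier] <- nextlab
      patch <- frontier
      repeat {
        nb <- neighbours4(frontier, nr, nc)
        nb <- nb[land$data[nb] == code & lab[nb] == 0L]
        if (length(nb) == 0) break
        lab[nb] <- nextlab
        patch <- c(patch, nb)
        frontier <- nb
      }
      row <- (patch - 1L) %% nr + 1L
      col <- (patch - 1L) %/% nr + 1L
      res[[nextlab]] <- data.frame(
        id = sprintf("patch_%04d", nextlab),
        class = land$levels[code],
        x = mean(land$xll + (col - 0.5) * land$cell_size),
        y = mean(land$yll + (nr - row + 0.5) * land$cell_size),
        n_cells = length(patch), stringsAsFactors = FALSE)
      todo <- which(land$data == code & lab == 0L)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(id = character(0), class = character(0),
                                      x = numeric(0), y = numeric(0),
                                      n_cells = integer(0))
  out
}

#' Select the taxon-specific scale of analysis from a flight table
#'
#' The analysis radius for a suborder is the maximum of its species' mean
#' daily flight distances, rounded half-up to the nearest 100 m — strong
#' dispersers (dragonflies) get wide buffers, weak dispersers (damselflies)
#' narrow ones.
#'
#' @param flights data.frame with columns `suborder` and `mean_m`.
#' @param suborder `"Anisoptera"` or `"Zygoptera"`.
#' @return radius in metres (multiple of 100).
#' @export
select_scale <- function(flights, suborder) {
  stopifnot(is.data.frame(flights), all(c("suborder", "mean_m") %in% names(flights)))
  means <- flights$mean_m[flights$suborder == suborder]
  means <- means[is.finite(means)]
  if (length(means) == 0) {
    stop(sprintf("no flight-distance records for suborder '%s'", suborder))
  }
  round_half_up(max(means), 100)
}

#' Per-pond connectivity metrics at one or more scales
#'
#' For every pond and scale: mean and sample SD of the current map within
#' the radius, and the count of habitat neighbours.
#'
#' @param map a current [grid_raster()].
#' @param sites data.frame `id`, `x`, `y` and optionally `type`.
#' @param habitat_points data.frame `x`, `y` of neighbour habitat points.
#' @param scales numeric radii in metres (default `c(900, 300)`).
#' @param self_tolerance passed to [count_neighbours()].
#' @return tidy data.frame keyed by (`pond_id`, `scale_m`) with columns
#'   `mean_current`, `sd_current`, `n_neighbours` (and `type` if present);
#'   `attr(., "log10_current")` records whether the map was log10-scaled.
#' @export
compute_site_metrics <- function(map, sites, habitat_points,
                                 scales = c(900, 300), self_tolerance = 5) {
  stopifnot(inherits(map, "grid_raster"), is.data.frame(sites),
            all(c("id", "x", "y") %in% names(sites)))
  if (anyDuplicated(sites$id)) stop("pond ids must be unique")
  rows <- lapply(scales, function(sc) {
    st <- t(vapply(seq_len(nrow(sites)), function(i) {
      extract_buffer_stats(map, sites$x[i], sites$y[i], sc)
    }, c(mean = 0, sd = 0, n = 0)))
    nn <- vapply(seq_len(nrow(sites)), function(i) {
      count_neighbours(sites$x[i], sites$y[i], sc, habitat_points,
                       self_tolerance = self_tolerance)
    }, integer(1))
    df <- data.frame(pond_id = sites$id, scale_m = sc,
                     mean_current = st[, "mean"], sd_current = st[, "sd"],
                     n_neighbours = nn, stringsAsFactors = FALSE)
    if ("type" %in% names(sites)) df$type <- sites$type
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "log10_current") <- isTRUE(attr(map, "log10_applied"))
  attr(out, "sd_type") <- "sample"
  out
}
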