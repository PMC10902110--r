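#' Default land-cover resistance scheme for odonates
#'
#' The low/medium/high resistance classification of the ten urban land-cover
#' classes used throughout the pipeline: primary habitat (wetlands, water)
#' carries resistance 1; land covers that provide resources but are not main
#' habitat (crop/pasture, grassland, large rivers, rock barren, sand/gravel,
#' wooded area) carry 10; hostile urban covers (settlement, transportation)
#' that impede movement and cause mortality carry 100.
#'
#' @return a data.frame with columns `class`, `level` (low/medium/high) and
#'   `resistance` (1, 10 or 100), one row per land-cover class.
#' @export
default_resistance_scheme <- function() {
  data.frame(
    class = c("crop_pasture", "grassland", "large_rivers", "rock_barren",
              "sand_gravel", "settlement", "transportation", "wooded_area",
              "wetlands", "water"),
    level = c("medium", "medium", "medium", "medium", "medium",
              "high", "high", "medium", "low", "low"),
    resistance = c(10, 10, 10, 10, 10, 100, 100, 10, 1, 1),
    stringsAsFactors = FALSE
  )
}

#' Read a resistance scheme from CSV
#'
#' @param path CSV with columns `class` and `resistance` (values 1, 10, 100).
#' @return a scheme data.frame as in [default_resistance_scheme()].
#' @export
read_resistance_scheme <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("class", "resistance") %in% names(s)))
  if (!all(s$resistance %in% c(1, 10, 100))) {
    stop("resistance values must be 1, 10 or 100")
  }
  s$level <- c("1" = "low", "10" = "medium", "100" = "high")[as.character(s$resistance)]
  s[, c("class", "level", "resistance")]
}

#' Reclassify a land-cover raster to a resistance surface
#'
#' Cell-wise lookup of each land-cover class's resistance value. Shape,
#' resolution and origin are preserved; the output `study_mask` is all-TRUE
#' (no buffer yet).
#'
#' @param land a categorical [grid_raster()] whose `levels` name the classes.
#' @param scheme a scheme data.frame (see [default_resistance_scheme()]).
#' @return a resistance [grid_raster()] with values in \{1, 10, 100\}.
#' @export
classify_resistance <- function(land, scheme = default_resistance_scheme()) {
  stopifnot(inherits(land, "grid_raster"))
  if (is.null(land$levels)) stop("land raster has no class legend (`levels`)")
  present <- sort(unique(as.vector(land$data)))
  present <- present[!is.na(present)]
  classes <- land$levels[present]
  missing <- setdiff(classes, scheme$class)
  if (length(missing) > 0) {
    stop("land-cover class(es) not in resistance scheme: ",
         paste(missing, collapse = ", "))
  }
  lut <- rep(NA_real_, length(land$levels))
  lut[match(scheme$class, land$levels)] <- scheme$resistance
  out <- matrix(lut[land$data], nrow(land$data), ncol(land$data))
  grid_raster(out, cell_size = land$cell_size, xll = land$xll, yll = land$yll,
              study_mask = matrix(TRUE, nrow(out), ncol(out)))
}

#' Proportions of low/medium/high resistance cells
#'
#' @param r a resistance [grid_raster()] with values in \{1, 10, 100\}.
#' @param mask_to_study if `TRUE` (default) and `r` has a study mask, only
#'   study-area cells are counted; `FALSE` counts every cell.
#' @return named numeric vector `c(low=, medium=, high=)` summing to 1.
#' @export
resistance_proportions <- function(r, mask_to_study = TRUE) {
  stopifnot(inherits(r, "grid_raster"))
  v <- as.vector(r$data)
  if (mask_to_study && !is.null(r$study_mask)) v <- v[as.vector(r$study_mask)]
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("no cells selected (empty mask)")
  if (!all(v %in% c(1, 10, 100))) stop("resistance values must be 1, 10 or 100")
  c(low = mean(v == 1), medium = mean(v == 10), high = mean(v == 100))
}

#' Add a randomized representative edge-correction buffer
#'
#' Pads the raster on all four sides with `ceiling(width_m / cell_size)`
#' cells whose resistance values are independent draws from \{1, 10, 100\}
#' at `target_ratio` — a margin with the same low/medium/high ratio as the
#' study area, so map edges do not artificially inflate resistance near the
#' boundary. Interior cells and the interior study mask are untouched.
#'
#' @param r a resistance [grid_raster()].
#' @param width_m buffer width in metres (default 15000).
#' @param target_ratio length-3 proportions (low, medium, high) summing to 1;
#'   default `c(0.142, 0.348, 0.510)`, the study-area ratio.
#' @param seed RNG seed for the buffer draw.
#' @return a larger resistance [grid_raster()]; `study_mask` is `FALSE` on
#'   buffer cells.
#' @export
add_random_buffer <- function(r, width_m = 15000,
                              target_ratio = c(0.142, 0.348, 0.510),
                              seed = NULL) {
  stopifnot(inherits(r, "grid_raster"), width_m > 0, length(target_ratio) == 3)
  if (any(target_ratio < 0) || abs(sum(target_ratio) - 1) > 1e-9) {
    stop("target_ratio must be non-negative and sum to 1")
  }
  pad <- as.integer(ceiling(width_m / r$cell_size))
  nr <- nrow(r$data); nc <- ncol(r$data)
  NR <- nr + 2L * pad; NC <- nc + 2L * pad
  inner_rows <- (pad + 1L):(pad + nr)
  inner_cols <- (pad + 1L):(pad + nc)
  out <- matrix(NA_real_, NR, NC)
  n_buf <- NR * NC - nr * nc
  out_vals <- with_seed(seed, sample(c(1, 10, 100), n_buf, replace = TRUE,
                                     prob = target_ratio))
  is_buf <- matrix(TRUE, NR, NC)
  is_buf[inner_rows, inner_cols] <- FALSE
  out[is_buf] <- out_vals
  out[inner_rows, inner_cols] <- r$data
  mask <- matrix(FALSE, NR, NC)
  mask[inner_rows, inner_cols] <- if (is.null(r$study_mask)) TRUE else r$study_mask
  grid_raster(out, cell_size = r$cell_size,
              xll = r$xll - pad * r$cell_size,
              yll = r$yll - pad * r$cell_size,
              study_mask = mask)
}

#' Randomly place focal nodes around the raster perimeter
#'
#' Samples `n` distinct cells uniformly without replacement from the
#' outermost one-cell ring of the (buffered) raster; current is later solved
#' between every pair of these nodes so connectivity is measured
#' omnidirectionally rather than between chosen habitat patches.
#'
#' @param r a [grid_raster()] (normally the output of [add_random_buffer()]).
#' @param n number of nodes (default 50).
#' @param seed RNG seed.
#' @return data.frame with columns `row`, `col`, `x`, `y`; the seed is kept
#'   in `attr(., "seed")`.
#' @export
place_perimeter_nodes <- function(r, n = 50, seed = NULL) {
  stopifnot(inherits(r, "grid_raster"), n >= 2)
  nr <- nrow(r$data); nc <- ncol(r$data)
  ring <- rbind(
    cbind(row = 1L, col = seq_len(nc)),
    cbind(row = nr, col = seq_len(nc)),
    cbind(row = seq_len(nr), col = 1L),
    cbind(row = seq_len(nr), col = nc)
  )
  ring <- unique(ring)
  if (n > nrow(ring)) {
    stop(sprintf("requested %d nodes but the perimeter ring has only %d cells",
                 n, nrow(ring)))
  }
  pick <- with_seed(seed, sample.int(nrow(ring), n))
  nodes <- as.data.frame(ring[pick, , drop = FALSE])
  nodes$x <- r$xll + (nodes$col - 0.5) * r$cell_size
  nodes$y <- r$yll + (nr - nodes$row + 0.5) * r$cell_size
  attr(nodes, "seed") <- seed
  nodes
}
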