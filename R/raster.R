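#' Lightweight projected raster grid
#'
#' A `grid_raster` is a matrix of cell values plus the georeferencing needed
#' by this pipeline: square cell size in metres and the coordinates of the
#' lower-left corner (ESRI ASCII grid convention). Row 1 of the matrix is the
#' northernmost row. Optional attributes carry a categorical legend
#' (`levels`, a character vector indexed by cell code) and a logical
#' `study_mask` separating the study area from an edge-correction buffer.
#'
#' @param data numeric or integer matrix of cell values; row 1 = north.
#' @param cell_size cell edge length in metres (default 10).
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param levels optional character vector naming categorical codes
#'   (`levels[k]` is the class of code `k`).
#' @param study_mask optional logical matrix, same shape as `data`; `TRUE`
#'   marks study-area cells, `FALSE` buffer cells.
#' @return an object of class `grid_raster`.
#' @export
grid_raster <- function(data, cell_size = 10, xll = 0, yll = 0,
                        levels = NULL, study_mask = NULL) {
  stopifnot(is.matrix(data), nrow(data) >= 1, ncol(data) >= 1,
            is.numeric(cell_size), cell_size > 0)
  if (!is.null(study_mask)) {
    stopifnot(is.logical(study_mask), all(dim(study_mask) == dim(data)))
  }
  structure(
    list(data = data, cell_size = cell_size, xll = xll, yll = yll,
         levels = levels, study_mask = study_mask),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("grid_raster: %d x %d cells, %.6g m resolution, origin (%.6g, %.6g)\n",
              nrow(x$data), ncol(x$data), x$cell_size, x$xll, x$yll))
  if (!is.null(x$levels)) {
    cat("categorical classes:", paste(x$levels, collapse = ", "), "\n")
  }
  if (!is.null(x$study_mask)) {
    cat(sprintf("study mask: %d study cells, %d buffer cells\n",
                sum(x$study_mask), sum(!x$study_mask)))
  }
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$data)

# x coordinate of every column's cell centre / y of every row's cell centre
cell_x <- function(r) r$xll + (seq_len(ncol(r$data)) - 0.5) * r$cell_size
cell_y <- function(r) r$yll + (nrow(r$data) - seq_len(nrow(r$data)) + 0.5) * r$cell_size

# full coordinate matrices (recycled cheaply where needed)
cell_centres <- function(r) {
  nr <- nrow(r$data); nc <- ncol(r$data)
  list(x = matrix(cell_x(r), nr, nc, byrow = TRUE),
       y = matrix(cell_y(r), nr, nc))
}

#' Write a raster as an ESRI ASCII grid
#'
#' @param r a [grid_raster()].
#' @param path output file path.
#' @param nodata value written for `NA` cells (default -9999).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  stopifnot(inherits(r, "grid_raster"))
  hdr <- c(
    sprintf("NCOLS %d", ncol(r$data)),
    sprintf("NROWS %d", nrow(r$data)),
    sprintf("XLLCORNER %.10g", r$xll),
    sprintf("YLLCORNER %.10g", r$yll),
    sprintf("CELLSIZE %.10g", r$cell_size),
    sprintf("NODATA_VALUE %.10g", nodata)
  )
  m <- r$data
  m[is.na(m)] <- nodata
  body <- apply(m, 1, function(row) paste(format(row, trim = TRUE, scientific = FALSE,
                                                 digits = 15), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path of an ASCII grid.
#' @param cell_size,xll,yll overrides; taken from the header by default.
#' @return a [grid_raster()]; nodata cells become `NA`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  stopifnot(length(vals) == nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  grid_raster(m, cell_size = hdr$cellsize %||% 10,
              xll = hdr$xllcorner %||% 0, yll = hdr$yllcorner %||% 0)
}

#' Majority-rule resampling of a categorical raster
#'
#' Aggregates a fine categorical grid to a coarser one by taking the modal
#' class in each `factor` x `factor` block (e.g. 1 m land cover to 10 m).
#' Ties are broken by the lowest class code, a fixed deterministic order.
#'
#' @param r a categorical [grid_raster()] with integer codes.
#' @param factor integer aggregation factor; grid dimensions must be
#'   divisible by it.
#' @return a [grid_raster()] with `factor`-times larger cells.
#' @export
majority_resample <- function(r, factor) {
  stopifnot(inherits(r, "grid_raster"), factor >= 1, factor == round(factor))
  nr <- nrow(r$data); nc <- ncol(r$data)
  if (nr %% factor != 0 || nc %% factor != 0) {
    stop("grid dimensions must be divisible by the aggregation factor")
  }
  out <- matrix(NA_integer_, nr / factor, nc / factor)
  for (i in seq_len(nrow(out))) {
    rows <- ((i - 1) * factor + 1):(i * factor)
    for (j in seq_len(ncol(out))) {
      cols <- ((j - 1) * factor + 1):(j * factor)
      block <- r$data[rows, cols]
      tab <- table(block)
      # which.max returns the first maximum; table is sorted by code, so ties
      # resolve to the lowest code
      out[i, j] <- as.integer(names(tab)[which.max(tab)])
    }
  }
  grid_raster(out, cell_size = r$cell_size * factor, xll = r$xll, yll = r$yll,
              levels = r$levels)
}
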