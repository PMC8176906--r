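# Matrix-backed georeferenced grid container and plain-text raster I/O.
# Grids are north-up, row-major (row 1 = northernmost), cell centers at
# (xll + (col - 0.5) * cell_size, yll + (nrow - row + 0.5) * cell_size).
# NA marks nodata.

#' Georeferenced grid
#'
#' A lightweight container for a single-band raster: a numeric matrix plus
#' cell size (m) and the coordinates of the lower-left corner. `NA` cells are
#' nodata. Categorical grids carry a `legend` mapping integer codes to class
#' labels.
#'
#' @param values numeric matrix (row 1 = northernmost row).
#' @param cell_size cell edge length in meters, > 0.
#' @param xll,yll coordinates of the lower-left corner of the grid footprint.
#' @param legend optional named character vector: names are integer codes (as
#'   strings), values are class labels.
#' @return an object of class `lcv_grid`.
#' @export
lcv_grid <- function(values, cell_size, xll = 0, yll = 0, legend = NULL) {
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || !is.finite(cell_size) ||
      cell_size <= 0) {
    stop("`cell_size` must be a single positive number", call. = FALSE)
  }
  if (!is.null(legend)) {
    if (is.null(names(legend)) || anyNA(suppressWarnings(as.integer(names(legend))))) {
      stop("`legend` must be a named vector with integer-coercible names", call. = FALSE)
    }
    legend <- stats::setNames(as.character(legend), names(legend))
  }
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         xll = as.numeric(xll), yll = as.numeric(yll), legend = legend),
    class = "lcv_grid"
  )
}

#' @export
dim.lcv_grid <- function(x) dim(x$values)

#' @export
as.matrix.lcv_grid <- function(x, ...) x$values

#' @export
print.lcv_grid <- function(x, ...) {
  d <- dim(x$values)
  kind <- if (is.null(x$legend)) "continuous" else "categorical"
  cat(sprintf("<lcv_grid> %d x %d cells, %g m cell size, %s\n", d[1], d[2],
              x$cell_size, kind))
  v <- x$values[!is.na(x$values)]
  if (length(v)) {
    cat(sprintf("  values: [%g, %g], %d nodata cells\n", min(v), max(v),
                sum(is.na(x$values))))
  } else {
    cat("  all cells nodata\n")
  }
  if (!is.null(x$legend)) {
    cat("  legend:", paste(sprintf("%s=%s", names(x$legend), x$legend),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' Coordinates of cell centers
#'
#' @param grid an [lcv_grid].
#' @return list with matrices `x` and `y` of cell-center coordinates.
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "lcv_grid"))
  d <- dim(grid$values)
  cs <- grid$cell_size
  x <- matrix(grid$xll + (seq_len(d[2]) - 0.5) * cs, d[1], d[2], byrow = TRUE)
  y <- matrix(grid$yll + (d[1] - seq_len(d[1]) + 0.5) * cs, d[1], d[2])
  list(x = x, y = y)
}

#' Check that two grids share footprint, cell size and georeferencing
#' @noRd
check_aligned <- function(a, b, what = "grids") {
  if (!identical(dim(a$values), dim(b$values)) ||
      !isTRUE(all.equal(a$cell_size, b$cell_size)) ||
      !isTRUE(all.equal(a$xll, b$xll)) || !isTRUE(all.equal(a$yll, b$yll))) {
    stop(sprintf("%s are not aligned (shape, cell size or origin differ)", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a grid as an Esri ASCII raster
#'
#' Values are written with 17 significant digits so that doubles round-trip
#' bit-exactly. Categorical grids get a JSON legend sidecar at
#' `<path>.legend.json`.
#'
#' @param grid an [lcv_grid].
#' @param path output path (conventionally `.asc`).
#' @param nodata the nodata sentinel written to file.
#' @return `path`, invisibly.
#' @export
write_grid_asc <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "lcv_grid"))
  d <- dim(grid$values)
  v <- grid$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.17g", grid$xll),
    sprintf("yllcorner %.17g", grid$yll),
    sprintf("cellsize %.17g", grid$cell_size),
    sprintf("NODATA_value %.17g", nodata)
  ), con)
  writeLines(apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             con)
  if (!is.null(grid$legend)) {
    jsonlite::write_json(as.list(grid$legend), paste0(path, ".legend.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read an Esri ASCII raster
#'
#' Reads the header and value block; a `<path>.legend.json` sidecar, if
#' present, is attached as the grid legend. A missing `NODATA_value` header
#' leaves all cells unmasked with a warning.
#'
#' @param path path to the `.asc` file.
#' @return an [lcv_grid].
#' @export
read_grid_asc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^[A-Za-z_]+\\s", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("not an Esri ASCII grid (missing header fields): ", path, call. = FALSE)
  }
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop("value block does not match nrows x ncols in ", path, call. = FALSE)
  }
  m <- matrix(vals, nr, nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) {
    m[m == hdr$nodata_value] <- NA_real_
  } else {
    warning("no NODATA_value header in ", path, "; all cells treated as valid")
  }
  legend <- NULL
  side <- paste0(path, ".legend.json")
  if (file.exists(side)) {
    leg <- jsonlite::read_json(side)
    legend <- stats::setNames(vapply(leg, as.character, ""), names(leg))
    codes <- unique(m[!is.na(m)])
    if (length(setdiff(as.character(as.integer(codes)), names(legend)))) {
      stop("grid contains codes absent from its legend: ", path, call. = FALSE)
    }
  }
  lcv_grid(m, hdr$cellsize, hdr$xllcorner, hdr$yllcorner, legend = legend)
}

#' Nearest-neighbour resampling to a new cell size
#'
#' Convenience helper for bringing two rasters onto a common grid before
#' overlay; the overlay itself never resamples implicitly.
#'
#' @param grid an [lcv_grid].
#' @param new_cell_size target cell size in meters.
#' @return an [lcv_grid] covering the same footprint.
#' @export
resample_nearest <- function(grid, new_cell_size) {
  stopifnot(inherits(grid, "lcv_grid"), new_cell_size > 0)
  d <- dim(grid$values)
  width <- d[2] * grid$cell_size
  height <- d[1] * grid$cell_size
  nc <- max(1L, round(width / new_cell_size))
  nr <- max(1L, round(height / new_cell_size))
  xc <- grid$xll + (seq_len(nc) - 0.5) * new_cell_size
  yc <- grid$yll + (nr - seq_len(nr) + 0.5) * new_cell_size
  src_col <- pmin(d[2], pmax(1L, ceiling((xc - grid$xll) / grid$cell_size)))
  src_row <- pmin(d[1], pmax(1L, d[1] - floor((yc - grid$yll) / grid$cell_size)))
  lcv_grid(grid$values[src_row, src_col, drop = FALSE], new_cell_size,
           grid$xll, grid$yll, legend = grid$legend)
}

# 8-neighbour stencil shared by the terrain and focal operators: offsets are
# (drow, dcol); distance factors are in units of the cell size.
neighbor_offsets <- function() {
  data.frame(
    dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
    dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L),
    dist = c(sqrt(2), 1, sqrt(2), 1, 1, sqrt(2), 1, sqrt(2))
  )
}

# Shift a matrix by (dr, dc), padding the exposed edge with NA.
shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- seq_len(nr) + dr
  cs <- seq_len(nc) + dc
  ok_r <- rs >= 1L & rs <= nr
  ok_c <- cs >= 1L & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}
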