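# Conservation-value mapping: matrix lookup, zonal statistics, focal SD and
# the susceptibility mask.

#' Map matrix values onto a landscape-type grid
#'
#' Per-cell lookup of the conservation value of each cell's (landform,
#' land-cover) pair. The matrix must be normalized; any type code whose pair
#' is missing a matrix entry raises an error naming the code.
#'
#' @param types landscape-type [lcv_grid] from [overlay_types()].
#' @param matrix a normalized `lcv_matrix`.
#' @return an [lcv_grid] of conservation values in `[1, 10]`.
#' @export
apply_lcv_matrix <- function(types, matrix) {
  stopifnot(inherits(types, "lcv_grid"), inherits(matrix, "lcv_matrix"))
  if (!isTRUE(attr(matrix, "normalized"))) {
    stop("the LCV matrix must be normalized to [1, 10] before mapping",
         call. = FALSE)
  }
  codes <- unique(types$values[!is.na(types$values)])
  dec <- decode_type(codes)
  bad <- !(dec$landcover %in% rownames(matrix)) |
    !(dec$landform %in% colnames(matrix))
  if (any(bad)) {
    stop("type code(s) without a matrix entry: ",
         paste(codes[bad], collapse = ", "), call. = FALSE)
  }
  lut <- stats::setNames(
    unclass(matrix)[cbind(dec$landcover, dec$landform)],
    codes
  )
  out <- base::matrix(NA_real_, nrow(types$values), ncol(types$values))
  ok <- !is.na(types$values)
  out[ok] <- lut[as.character(types$values[ok])]
  lcv_grid(out, types$cell_size, types$xll, types$yll)
}

#' Zonal mean and standard deviation of conservation value
#'
#' For each zone, the mean and population SD of the cells whose centers fall
#' inside the polygon, plus a whole-site row over all unmasked cells. A zone
#' covering no cell center yields an `NA` row with a warning.
#'
#' @param lcv an [lcv_grid] of conservation values.
#' @param zones an `lcv_zones` set.
#' @param sd_type `"population"` (divide by n, the raster-GIS focal/zonal
#'   convention, default) or `"sample"` (divide by n - 1).
#' @return data.frame with columns `zone`, `cells`, `area_km2`, `mean_lcv`,
#'   `sd`; last row is `"Whole site"`.
#' @export
zonal_lcv_stats <- function(lcv, zones, sd_type = c("population", "sample")) {
  stopifnot(inherits(lcv, "lcv_grid"), inherits(zones, "lcv_zones"))
  sd_type <- match.arg(sd_type)
  rows <- lapply(zones, function(f) {
    inside <- zone_membership(lcv, f)
    vals <- lcv$values[inside & !is.na(lcv$values)]
    if (!length(vals)) {
      warning("zone '", f$name, "' covers no cell centers")
      return(data.frame(zone = f$name, cells = 0L, area_km2 = 0,
                        mean_lcv = NA_real_, sd = NA_real_))
    }
    data.frame(zone = f$name, cells = length(vals),
               area_km2 = length(vals) * lcv$cell_size^2 / 1e6,
               mean_lcv = mean(vals), sd = pop_sd(vals, sd_type))
  })
  all_vals <- lcv$values[!is.na(lcv$values)]
  rows <- c(rows, list(data.frame(
    zone = "Whole site", cells = length(all_vals),
    area_km2 = length(all_vals) * lcv$cell_size^2 / 1e6,
    mean_lcv = mean(all_vals), sd = pop_sd(all_vals, sd_type)
  )))
  do.call(rbind, rows)
}

pop_sd <- function(x, sd_type = "population") {
  n <- length(x)
  if (sd_type == "sample") {
    if (n < 2L) return(NA_real_)
    return(stats::sd(x))
  }
  sqrt(sum((x - mean(x))^2) / n)
}

#' Focal standard deviation
#'
#' Per-cell population SD of the values in a `window x window` neighbourhood
#' centred on the cell (the cell itself included). Edge cells use the
#' truncated window; cells with fewer than 2 unmasked neighbours in the
#' window become nodata. High focal SD marks cells where high- and low-value
#' landscape types adjoin.
#'
#' @param lcv an [lcv_grid].
#' @param window odd window edge length, >= 3.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return an [lcv_grid] of focal SD values.
#' @export
focal_sd <- function(lcv, window = 3L, sd_type = c("population", "sample")) {
  stopifnot(inherits(lcv, "lcv_grid"))
  sd_type <- match.arg(sd_type)
  if (window < 3L || window %% 2L == 0L) {
    stop("window must be an odd integer >= 3", call. = FALSE)
  }
  v <- lcv$values
  k <- (window - 1L) %/% 2L
  s <- matrix(0, nrow(v), ncol(v))
  s2 <- matrix(0, nrow(v), ncol(v))
  n <- matrix(0L, nrow(v), ncol(v))
  for (dr in -k:k) {
    for (dc in -k:k) {
      vn <- shift_matrix(v, dr, dc)
      ok <- !is.na(vn)
      vn[!ok] <- 0
      s <- s + vn
      s2 <- s2 + vn^2
      n <- n + ok
    }
  }
  mean_ <- s / n
  var_ <- pmax(s2 / n - mean_^2, 0)
  if (sd_type == "sample") {
    var_ <- var_ * ifelse(n > 1L, n / (n - 1L), NA_real_)
  }
  out <- sqrt(var_)
  out[n < 2L] <- NA_real_
  out[is.na(v)] <- NA_real_
  lcv_grid(out, lcv$cell_size, lcv$xll, lcv$yll)
}

#' Susceptibility mask from focal SD
#'
#' Cells in the top `(100 - percentile)%` of focal SD — the default 80th
#' percentile flags the top 20% most heterogeneous cells. The threshold is the
#' linear-interpolation percentile of the unmasked SD values; cells with
#' `sd >= threshold` (ties included) form the mask.
#'
#' @param sd an [lcv_grid] of focal SD values (from [focal_sd()]).
#' @param percentile percentile in (0, 100); default 80.
#' @return an object of class `lcv_susceptibility`: list with `focal_sd`,
#'   `percentile`, `threshold`, and `mask` (a 0/1 [lcv_grid]).
#' @export
susceptibility_mask <- function(sd, percentile = 80) {
  stopifnot(inherits(sd, "lcv_grid"))
  if (percentile <= 0 || percentile >= 100) {
    stop("percentile must be in (0, 100)", call. = FALSE)
  }
  vals <- sd$values[!is.na(sd$values)]
  if (!length(vals)) stop("focal SD field is all nodata", call. = FALSE)
  threshold <- stats::quantile(vals, percentile / 100, type = 7, names = FALSE)
  mask <- matrix(NA_real_, nrow(sd$values), ncol(sd$values))
  ok <- !is.na(sd$values)
  mask[ok] <- as.numeric(sd$values[ok] >= threshold)
  structure(list(
    focal_sd = sd, percentile = percentile, threshold = threshold,
    mask = lcv_grid(mask, sd$cell_size, sd$xll, sd$yll,
                    legend = c("0" = "stable", "1" = "susceptible"))
  ), class = "lcv_susceptibility")
}

#' @export
print.lcv_susceptibility <- function(x, ...) {
  n_mask <- sum(x$mask$values == 1, na.rm = TRUE)
  n_all <- sum(!is.na(x$mask$values))
  cat(sprintf(
    "<lcv_susceptibility> threshold %.4f (%gth percentile); %d / %d cells (%.1f%%) susceptible\n",
    x$threshold, x$percentile, n_mask, n_all, 100 * n_mask / n_all))
  invisible(x)
}

#' Write zonal statistics as CSV
#'
#' @param stats_table table from [zonal_lcv_stats()].
#' @param path file path.
#' @export
write_zonal_stats_csv <- function(stats_table, path) {
  utils::write.csv(stats_table, path, row.names = FALSE)
  invisible(path)
}
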