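# Terrain derivatives and nine-unit landscape model (NULM) classification.
#
# The two quantities at the core of the landform workflow:
#   * specific upslope contributing area  AS = (1/b) * sum_i p_i * A_i,
#     the per-cell drainage area routed from upslope (plus the cell's own
#     area) divided by the contour width b, taken equal to the cell size;
#   * surface curvature  C_s = mean over the n available neighbours of
#     (Z_self - Z_neighbour) / d, with d the centre-to-centre distance
#     (b cardinal, sqrt(2) b diagonal); positive = convex.

#' Slope in degrees from central differences
#'
#' Gradient components are estimated with central differences in the interior
#' and one-sided differences at edges (and next to nodata cells); slope is
#' `atan(|grad|)` in degrees. Nodata propagates.
#'
#' @param dem an [lcv_grid] of elevations (m).
#' @return an [lcv_grid] of slope in degrees, in `[0, 90)`.
#' @export
compute_slope <- function(dem) {
  stopifnot(inherits(dem, "lcv_grid"))
  z <- dem$values
  if (nrow(z) < 3L || ncol(z) < 3L) {
    stop("DEM must be at least 3x3 to compute slope", call. = FALSE)
  }
  b <- dem$cell_size
  gx <- directional_gradient(z, shift_matrix(z, 0L, 1L), shift_matrix(z, 0L, -1L), b)
  gy <- directional_gradient(z, shift_matrix(z, -1L, 0L), shift_matrix(z, 1L, 0L), b)
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  slope[is.na(z)] <- NA_real_
  lcv_grid(slope, b, dem$xll, dem$yll)
}

# Central difference where both neighbours exist, one-sided otherwise, 0 when
# neither does. `plus` is the neighbour in the +direction, `minus` in the -.
directional_gradient <- function(z, plus, minus, b) {
  g <- (plus - minus) / (2 * b)
  one_plus <- (plus - z) / b
  one_minus <- (z - minus) / b
  g[is.na(g)] <- one_plus[is.na(g)]
  g[is.na(g)] <- one_minus[is.na(g)]
  g[is.na(g) & !is.na(z)] <- 0
  g
}

#' Surface curvature (mean elevation difference per distance)
#'
#' For each cell, the mean over available 8-neighbours of
#' `(Z_self - Z_neighbour) / d` with `d` the centre-to-centre distance.
#' Positive values are convex, negative concave; a plane's interior is 0.
#' Off-grid and nodata neighbours are excluded from the mean; a cell with no
#' valid neighbour becomes nodata.
#'
#' @param dem an [lcv_grid] of elevations (m).
#' @return an [lcv_grid] of curvature (dimensionless, m elevation per m).
#' @export
surface_curvature <- function(dem) {
  stopifnot(inherits(dem, "lcv_grid"))
  z <- dem$values
  if (nrow(z) < 3L || ncol(z) < 3L) {
    stop("DEM must be at least 3x3 to compute curvature", call. = FALSE)
  }
  off <- neighbor_offsets()
  acc <- matrix(0, nrow(z), ncol(z))
  n <- matrix(0L, nrow(z), ncol(z))
  for (k in seq_len(nrow(off))) {
    zn <- shift_matrix(z, off$dr[k], off$dc[k])
    d <- off$dist[k] * dem$cell_size
    term <- (z - zn) / d
    ok <- !is.na(term)
    acc[ok] <- acc[ok] + term[ok]
    n <- n + ok
  }
  curv <- ifelse(n > 0L, acc / n, NA_real_)
  curv[is.na(z)] <- NA_real_
  lcv_grid(curv, dem$cell_size, dem$xll, dem$yll)
}

#' Partition outflow to the 8 neighbours
#'
#' Computes per-cell outflow fractions. With `method = "mfd"` (multiple flow
#' direction, the default) flow is split among all strictly lower neighbours
#' proportionally to the downhill slope toward each (drop divided by distance,
#' `sqrt(2)` times the cell size on diagonals). With `method = "d8"` the whole
#' unit fraction goes to the single steepest-descent neighbour (ties broken by
#' a fixed neighbour order, NW..SE row-major). A cell with no strictly lower
#' in-grid neighbour — an interior pit or an edge outlet — has zero outflow.
#'
#' @param dem an [lcv_grid] of elevations; see [fill_sinks()] for pit removal.
#' @param method `"mfd"` or `"d8"`.
#' @return an object of class `lcv_flow`: a list with `frac`, an
#'   `nrow x ncol x 8` array of outflow fractions in the [neighbor_offsets()]
#'   order, and the grid geometry.
#' @export
flow_partition <- function(dem, method = c("mfd", "d8")) {
  stopifnot(inherits(dem, "lcv_grid"))
  method <- match.arg(method)
  z <- dem$values
  off <- neighbor_offsets()
  nr <- nrow(z); nc <- ncol(z)
  drops <- array(0, c(nr, nc, 8L))
  for (k in 1:8) {
    zn <- shift_matrix(z, off$dr[k], off$dc[k])
    s <- (z - zn) / (off$dist[k] * dem$cell_size)
    s[is.na(s) | s <= 0] <- 0
    drops[, , k] <- s
  }
  frac <- array(0, c(nr, nc, 8L))
  if (method == "mfd") {
    tot <- apply(drops, c(1, 2), sum)
    pos <- tot > 0
    for (k in 1:8) {
      fk <- drops[, , k]
      fk[pos] <- fk[pos] / tot[pos]
      fk[!pos] <- 0
      frac[, , k] <- fk
    }
  } else {
    best <- apply(drops, c(1, 2), function(s) {
      if (all(s <= 0)) 0L else which.max(s)
    })
    for (k in 1:8) frac[, , k][best == k] <- 1
  }
  for (k in 1:8) frac[, , k][is.na(z)] <- 0
  structure(list(frac = frac, dim = c(nr, nc), cell_size = dem$cell_size),
            class = "lcv_flow")
}

#' Remove interior sinks by epsilon-raising
#'
#' Iteratively raises every interior cell with no strictly lower in-grid
#' neighbour to its lowest neighbour plus `eps`, until none remain. Boundary
#' cells are never raised (they drain off-grid). Flat interior regions acquire
#' a tiny gradient toward the nearest lower cell as the raising propagates.
#'
#' @param dem an [lcv_grid].
#' @param eps elevation increment in meters.
#' @param max_iter safety cap on sweeps.
#' @return an [lcv_grid] with no interior pits.
#' @export
fill_sinks <- function(dem, eps = 1e-3, max_iter = 10000L) {
  stopifnot(inherits(dem, "lcv_grid"), eps > 0)
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  interior <- matrix(FALSE, nr, nc)
  interior[2:(nr - 1), 2:(nc - 1)] <- TRUE
  off <- neighbor_offsets()
  for (iter in seq_len(max_iter)) {
    nmin <- matrix(Inf, nr, nc)
    for (k in 1:8) {
      zn <- shift_matrix(z, off$dr[k], off$dc[k])
      zn[is.na(zn)] <- Inf
      nmin <- pmin(nmin, zn)
    }
    pit <- interior & !is.na(z) & z <= nmin
    if (!any(pit)) break
    z[pit] <- nmin[pit] + eps
    if (iter == max_iter) {
      warning("fill_sinks did not converge within max_iter sweeps")
    }
  }
  lcv_grid(z, dem$cell_size, dem$xll, dem$yll)
}

#' Upslope contributing area
#'
#' Accumulates cell areas down the flow field in topological (decreasing
#' elevation) order and divides by the contour width `b`, taken equal to the
#' cell size: `AS = (1/b) (sum over upslope cells of routed fraction x A_i +
#' A_self)`. Every cell therefore has `AS >= cell_area / b`.
#'
#' @param dem the [lcv_grid] the flow field was derived from.
#' @param flow an `lcv_flow` from [flow_partition()].
#' @return an [lcv_grid] of specific catchment area in meters.
#' @export
upslope_contributing_area <- function(dem, flow) {
  stopifnot(inherits(dem, "lcv_grid"), inherits(flow, "lcv_flow"))
  z <- dem$values
  if (!identical(dim(z), as.integer(flow$dim)) &&
      !identical(dim(z), flow$dim)) {
    stop("flow field shape does not match the DEM", call. = FALSE)
  }
  nr <- nrow(z); nc <- ncol(z)
  cell_area <- dem$cell_size^2
  acc <- matrix(cell_area, nr, nc)
  acc[is.na(z)] <- NA_real_
  off <- neighbor_offsets()
  ord <- order(z, decreasing = TRUE, na.last = NA)
  rows <- ((ord - 1L) %% nr) + 1L
  cols <- ((ord - 1L) %/% nr) + 1L
  for (i in seq_along(ord)) {
    r <- rows[i]; c <- cols[i]
    a <- acc[r, c]
    if (is.na(a)) next
    for (k in 1:8) {
      f <- flow$frac[r, c, k]
      if (f > 0) {
        rr <- r + off$dr[k]; cc <- c + off$dc[k]
        acc[rr, cc] <- acc[rr, cc] + f * a
      }
    }
  }
  lcv_grid(acc / dem$cell_size, dem$cell_size, dem$xll, dem$yll)
}

#' All terrain derivatives in one pass
#'
#' Convenience wrapper returning slope, curvature and upslope contributing
#' area (plus the DEM itself, needed for the summit local-maximum test in
#' [classify_nulm()]).
#'
#' @param dem an [lcv_grid] of elevations.
#' @param method flow-partition rule, `"mfd"` (default) or `"d8"`.
#' @param fill fill interior sinks before routing (default `TRUE`).
#' @return an object of class `lcv_terrain`: list with `dem`, `slope_deg`,
#'   `curvature`, `upslope_area` ([lcv_grid]s) and `cell_area` (m^2).
#' @export
terrain_derivatives <- function(dem, method = c("mfd", "d8"), fill = TRUE) {
  stopifnot(inherits(dem, "lcv_grid"))
  method <- match.arg(method)
  routed <- if (fill) fill_sinks(dem) else dem
  flow <- flow_partition(routed, method)
  structure(list(
    dem = dem,
    slope_deg = compute_slope(dem),
    curvature = surface_curvature(dem),
    upslope_area = upslope_contributing_area(routed, flow),
    cell_area = dem$cell_size^2
  ), class = "lcv_terrain")
}

# NULM unit codes. The literature's model has nine units; the eight with
# operational rules here are the ones with published topographic definitions
# (interfluve is reserved and never assigned by the default cascade).
NULM_UNITS <- c(
  "interfluve" = 1L, "summit" = 2L, "shoulder" = 3L, "fall face" = 4L,
  "backslope" = 5L, "footslope" = 6L, "toeslope" = 7L, "channel" = 8L
)

# Final five-class legend (column order of the conservation-value matrix).
LANDFORM_CLASSES <- c("Flat land", "Slope", "Shoulder", "Channel", "Summit")

#' Landform class legend
#' @return character vector of the 5 final landform classes, in matrix order.
#' @export
landform_classes <- function() LANDFORM_CLASSES

#' NULM classification thresholds
#'
#' Only the fall-face bound (slope >= 45 degrees) is fixed by the published
#' definition of the units; the remaining cutoffs are configuration. When
#' `derivs` is supplied, data-driven defaults are taken from the distribution
#' of the derivatives: summit / shoulder curvature minima at the 95th / 80th
#' curvature percentiles, footslope curvature maximum at the 20th, channel
#' threshold at the 99th percentile of upslope contributing area (quantile
#' based so the default is stable across D8 and MFD routing; channel cells
#' are rare, on the order of 1-2% of a study area), flat-slope bound 5
#' degrees. Any argument given explicitly overrides its default.
#'
#' @param derivs optional `lcv_terrain` used to derive percentile defaults.
#' @param summit_curvature_min,shoulder_curvature_min,footslope_curvature_max
#'   curvature cutoffs (m/m).
#' @param fallface_slope_min_deg fall-face slope bound, degrees, in (0, 90).
#' @param flat_slope_max_deg slope below which relief counts as flat, degrees.
#' @param channel_upslope_min upslope contributing area (m) above which a cell
#'   is channel; must be > 0.
#' @return a named list of class `nulm_thresholds`.
#' @export
nulm_thresholds <- function(derivs = NULL,
                            summit_curvature_min = NULL,
                            shoulder_curvature_min = NULL,
                            footslope_curvature_max = NULL,
                            fallface_slope_min_deg = 45,
                            flat_slope_max_deg = 5,
                            channel_upslope_min = NULL) {
  if (!is.null(derivs)) {
    stopifnot(inherits(derivs, "lcv_terrain"))
    curv <- derivs$curvature$values
    as_ <- derivs$upslope_area$values
    q <- stats::quantile(curv, c(0.20, 0.80, 0.95), na.rm = TRUE, names = FALSE)
    if (is.null(footslope_curvature_max)) footslope_curvature_max <- q[1]
    if (is.null(shoulder_curvature_min)) shoulder_curvature_min <- q[2]
    if (is.null(summit_curvature_min)) summit_curvature_min <- q[3]
    if (is.null(channel_upslope_min)) {
      channel_upslope_min <- stats::quantile(as_, 0.99, na.rm = TRUE,
                                             names = FALSE)
    }
  }
  th <- list(
    summit_curvature_min = summit_curvature_min,
    shoulder_curvature_min = shoulder_curvature_min,
    footslope_curvature_max = footslope_curvature_max,
    fallface_slope_min_deg = fallface_slope_min_deg,
    flat_slope_max_deg = flat_slope_max_deg,
    channel_upslope_min = channel_upslope_min
  )
  if (any(vapply(th, is.null, TRUE))) {
    stop("all thresholds must be set (supply `derivs` for data-driven defaults)",
         call. = FALSE)
  }
  if (th$fallface_slope_min_deg <= 0 || th$fallface_slope_min_deg >= 90) {
    stop("fallface_slope_min_deg must be in (0, 90)", call. = FALSE)
  }
  if (th$channel_upslope_min <= 0) {
    stop("channel_upslope_min must be > 0", call. = FALSE)
  }
  structure(th, class = "nulm_thresholds")
}

#' Classify cells into NULM units
#'
#' Applies a fixed-priority decision cascade to the terrain derivatives:
#' channel (upslope area >= threshold) > fall face (slope >= 45 degrees) >
#' summit (curvature >= summit bound, slope below the flat bound, and a local
#' elevation maximum over the 8-neighbourhood) > shoulder (curvature >=
#' shoulder bound) > footslope (curvature <= footslope bound) > toeslope
#' (slope below the flat bound) > backslope (everything else). Channel
#' dominates because stream cells override any other unit they coincide with.
#'
#' @param derivs an `lcv_terrain` from [terrain_derivatives()].
#' @param thresholds an [nulm_thresholds()]; defaults derived from `derivs`.
#' @return an [lcv_grid] of NULM unit codes with the unit legend.
#' @export
classify_nulm <- function(derivs, thresholds = nulm_thresholds(derivs)) {
  stopifnot(inherits(derivs, "lcv_terrain"), inherits(thresholds, "nulm_thresholds"))
  for (f in c("slope_deg", "curvature", "upslope_area", "dem")) {
    if (is.null(derivs[[f]])) stop("missing terrain derivative: ", f, call. = FALSE)
  }
  z <- derivs$dem$values
  slope <- derivs$slope_deg$values
  curv <- derivs$curvature$values
  as_ <- derivs$upslope_area$values
  # local elevation maximum: >= all available 8-neighbours
  off <- neighbor_offsets()
  is_max <- matrix(TRUE, nrow(z), ncol(z))
  for (k in 1:8) {
    zn <- shift_matrix(z, off$dr[k], off$dc[k])
    lower_ok <- is.na(zn) | z >= zn
    is_max <- is_max & lower_ok
  }
  th <- thresholds
  out <- matrix(NULM_UNITS[["backslope"]], nrow(z), ncol(z))
  out[slope < th$flat_slope_max_deg] <- NULM_UNITS[["toeslope"]]
  out[curv <= th$footslope_curvature_max] <- NULM_UNITS[["footslope"]]
  out[curv >= th$shoulder_curvature_min] <- NULM_UNITS[["shoulder"]]
  summit <- curv >= th$summit_curvature_min & slope < th$flat_slope_max_deg & is_max
  out[summit] <- NULM_UNITS[["summit"]]
  out[slope >= th$fallface_slope_min_deg] <- NULM_UNITS[["fall face"]]
  out[as_ >= th$channel_upslope_min] <- NULM_UNITS[["channel"]]
  out[is.na(z) | is.na(slope) | is.na(curv) | is.na(as_)] <- NA_real_
  lcv_grid(out, derivs$dem$cell_size, derivs$dem$xll, derivs$dem$yll,
           legend = stats::setNames(names(NULM_UNITS), NULM_UNITS))
}

#' Default NULM-to-landform merge table
#'
#' The first-round expert relabelling merged the nine units to six display
#' classes and the second round simplified six to five: backslope and fall
#' face become Slope, footslope ("mild slope") joins Slope by default
#' (configurable to Flat land), toeslope becomes Flat land, stream becomes
#' Channel. Interfluve, a flat upland divide, maps to Flat land.
#'
#' @param mild_slope_to where the footslope / mild-slope unit goes,
#'   `"Slope"` (default) or `"Flat land"`.
#' @return named character vector: NULM unit name -> final class name.
#' @export
default_landform_mapping <- function(mild_slope_to = c("Slope", "Flat land")) {
  mild_slope_to <- match.arg(mild_slope_to)
  c("interfluve" = "Flat land", "summit" = "Summit", "shoulder" = "Shoulder",
    "fall face" = "Slope", "backslope" = "Slope", "footslope" = mild_slope_to,
    "toeslope" = "Flat land", "channel" = "Channel")
}

#' Re-map NULM units to the five final landform classes
#'
#' @param nulm an [lcv_grid] of NULM unit codes (from [classify_nulm()]).
#' @param mapping named character vector NULM unit name -> final class; every
#'   unit occurring in the grid must be mapped.
#' @return an [lcv_grid] over the 5 landform classes (codes 1-5 in the order
#'   of [landform_classes()]), with the NULM unit grid attached as `$nulm`.
#' @export
remap_landform <- function(nulm, mapping = default_landform_mapping()) {
  stopifnot(inherits(nulm, "lcv_grid"))
  codes <- unique(nulm$values[!is.na(nulm$values)])
  unit_names <- stats::setNames(names(NULM_UNITS), NULM_UNITS)
  present <- unit_names[as.character(as.integer(codes))]
  missing <- setdiff(present, names(mapping))
  if (length(missing)) {
    stop("NULM unit(s) not in the mapping: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unname(mapping), LANDFORM_CLASSES)
  if (length(bad)) {
    stop("mapping targets unknown landform class(es): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  final_code <- stats::setNames(seq_along(LANDFORM_CLASSES), LANDFORM_CLASSES)
  lut <- rep(NA_real_, max(NULM_UNITS))
  for (u in names(mapping)) lut[NULM_UNITS[[u]]] <- final_code[[mapping[[u]]]]
  out <- matrix(NA_real_, nrow(nulm$values), ncol(nulm$values))
  ok <- !is.na(nulm$values)
  out[ok] <- lut[nulm$values[ok]]
  g <- lcv_grid(out, nulm$cell_size, nulm$xll, nulm$yll,
                legend = stats::setNames(LANDFORM_CLASSES, final_code))
  g$nulm <- nulm
  g
}
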