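# Labelled polygon zones: container, GeoJSON round-trip, cell membership.

#' Zone set
#'
#' A list of labelled polygons in the grid's coordinate system. Each feature
#' is a list with `name` and ring coordinate vectors `x`, `y` (unclosed; the
#' closing vertex is implied).
#'
#' @param features list of `list(name=, x=, y=)` polygons.
#' @return an object of class `lcv_zones`.
#' @export
zones <- function(features) {
  for (f in features) {
    if (is.null(f$name) || length(f$x) < 3L || length(f$x) != length(f$y) ||
        anyNA(f$x) || anyNA(f$y)) {
      stop("each zone needs a name and a valid ring of >= 3 vertices",
           call. = FALSE)
    }
  }
  structure(features, class = "lcv_zones")
}

#' @export
print.lcv_zones <- function(x, ...) {
  cat(sprintf("<lcv_zones> %d zone(s): %s\n", length(x),
              paste(vapply(x, `[[`, "", "name"), collapse = ", ")))
  invisible(x)
}

#' Write / read zones as GeoJSON
#'
#' A FeatureCollection of Polygons with a `name` property.
#'
#' @param z an [zones()] object.
#' @param path file path.
#' @return `read_zones_geojson` returns an `lcv_zones`.
#' @export
write_zones_geojson <- function(z, path) {
  stopifnot(inherits(z, "lcv_zones"))
  feats <- lapply(z, function(f) {
    ring <- cbind(c(f$x, f$x[1]), c(f$y, f$y[1]))
    list(
      type = "Feature",
      properties = list(name = f$name),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)),
                                                function(i) ring[i, ])))
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_zones_geojson
#' @export
read_zones_geojson <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  }
  feats <- lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    x <- vapply(ring, function(p) as.numeric(p[[1]]), 0)
    y <- vapply(ring, function(p) as.numeric(p[[2]]), 0)
    n <- length(x)
    if (n > 3L && x[1] == x[n] && y[1] == y[n]) {
      x <- x[-n]; y <- y[-n]
    }
    list(name = f$properties$name, x = x, y = y)
  })
  zones(feats)
}

# Logical matrix of cells whose centers fall inside the polygon (boundary
# counts as inside).
zone_membership <- function(grid, feature) {
  ctr <- cell_centers(grid)
  inside <- pracma::inpolygon(as.vector(ctr$x), as.vector(ctr$y),
                              feature$x, feature$y, boundary = TRUE)
  matrix(inside, nrow(grid$values), ncol(grid$values))
}
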