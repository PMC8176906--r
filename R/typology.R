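# Landscape typology: cross landform and land cover into pair-coded types.

#' Overlay landform and land cover into landscape types
#'
#' Per-cell pair code `landform_code * 10 + landcover_code` — stable and
#' human-decodable without a lookup file (tens digit = landform 1-5, units
#' digit = land cover 1-7). Nodata in either input propagates. Inputs must
#' already share footprint, cell size and origin; use [resample_nearest()]
#' first if they do not.
#'
#' @param landform categorical [lcv_grid] over the 5 landform classes.
#' @param landcover categorical [lcv_grid] over the 7 land-cover classes.
#' @return a categorical [lcv_grid] with a legend of occurring pair codes.
#' @export
overlay_types <- function(landform, landcover) {
  stopifnot(inherits(landform, "lcv_grid"), inherits(landcover, "lcv_grid"))
  check_aligned(landform, landcover, "landform and land-cover grids")
  lf <- landform$values; lc <- landcover$values
  if (any(!is.na(lf) & !(lf %in% 1:5))) {
    stop("landform codes must be 1..5", call. = FALSE)
  }
  if (any(!is.na(lc) & !(lc %in% 1:7))) {
    stop("land-cover codes must be 1..7", call. = FALSE)
  }
  code <- lf * 10 + lc
  codes <- sort(unique(code[!is.na(code)]))
  legend <- stats::setNames(
    paste(landform_classes()[codes %/% 10], "x",
          landcover_classes()[codes %% 10]),
    codes
  )
  lcv_grid(code, landform$cell_size, landform$xll, landform$yll,
           legend = legend)
}

#' Decode a landscape-type code
#'
#' @param code pair code(s) as produced by [overlay_types()].
#' @return data.frame with `landform` and `landcover` class names.
#' @export
decode_type <- function(code) {
  lf <- code %/% 10; lc <- code %% 10
  if (any(!(lf %in% 1:5) | !(lc %in% 1:7), na.rm = TRUE)) {
    stop("invalid landscape-type code(s): ",
         paste(code[!(lf %in% 1:5) | !(lc %in% 1:7)], collapse = ", "),
         call. = FALSE)
  }
  data.frame(landform = landform_classes()[lf],
             landcover = landcover_classes()[lc],
             stringsAsFactors = FALSE)
}

#' Tabulate landscape-type areas
#'
#' One row per occurring type with cell count, area (km^2) and the proportion
#' of the unmasked footprint (%), sorted by decreasing area (ties by code).
#' Proportions sum to 100.
#'
#' @param types a landscape-type [lcv_grid] from [overlay_types()].
#' @return data.frame with columns `landform`, `landcover`, `cells`,
#'   `area_km2`, `proportion_pct`.
#' @export
tabulate_type_areas <- function(types) {
  stopifnot(inherits(types, "lcv_grid"))
  v <- types$values[!is.na(types$values)]
  if (!length(v)) stop("all cells are nodata; nothing to tabulate", call. = FALSE)
  tab <- table(v)
  codes <- as.integer(names(tab))
  cells <- as.integer(tab)
  dec <- decode_type(codes)
  area_km2 <- cells * types$cell_size^2 / 1e6
  df <- data.frame(
    landform = dec$landform, landcover = dec$landcover, cells = cells,
    area_km2 = area_km2,
    proportion_pct = 100 * cells / sum(cells),
    stringsAsFactors = FALSE
  )
  df[order(-df$area_km2, codes), , drop = FALSE]
}

#' Write a type-area table as CSV
#'
#' @param tab table from [tabulate_type_areas()].
#' @param path file path.
#' @export
write_type_areas_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
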