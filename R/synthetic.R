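# Synthetic volcanic-island generators: terrain, land cover, zones, surveys.
# All randomness flows from a single integer seed per call (withr::with_seed),
# never from the global RNG state.

# Land-cover legend (row order of the conservation-value matrix).
LANDCOVER_CLASSES <- c("Barren land", "Developed", "Agriculture", "Grassland",
                       "Forest", "Open water", "Wetland")

#' Land-cover class legend
#' @return character vector of the 7 land-cover classes, in matrix order.
#' @export
landcover_classes <- function() LANDCOVER_CLASSES

#' Parameters for the synthetic island DEM
#'
#' The template emulates a shield-volcano island: one dominant central cone,
#' scattered secondary cones ("oreums"), radially incised channels with
#' monotone-descending beds, and Gaussian elevation noise. Defaults describe a
#' 64 x 64 grid of 30 m cells (a ~1.9 km island) with a 400 m peak, five
#' 80-150 m secondary cones and three channels.
#'
#' @param grid_shape integer `(rows, cols)`, both >= 16.
#' @param cell_size cell size in meters, > 0.
#' @param peak_height central cone apex height, m, >= 0.
#' @param n_oreums number of secondary cones, >= 0.
#' @param oreum_height_range `(min, max)` secondary-cone heights, m.
#' @param oreum_sigma_cells Gaussian radius of secondary cones, in cells.
#' @param channel_count number of incised radial channels, >= 0.
#' @param channel_depth maximum incision depth at the coast, m.
#' @param noise_sd Gaussian elevation noise SD, m, >= 0.
#' @param seed integer seed controlling all randomness of [gen_dem()].
#' @return a validated list of class `island_params`.
#' @export
island_params <- function(grid_shape = c(64L, 64L), cell_size = 30,
                          peak_height = 400, n_oreums = 5L,
                          oreum_height_range = c(80, 150),
                          oreum_sigma_cells = 1.5,
                          channel_count = 3L, channel_depth = 40,
                          noise_sd = 2, seed = 1L) {
  if (length(grid_shape) != 2L || any(grid_shape < 16L)) {
    stop("grid_shape must be two integers >= 16", call. = FALSE)
  }
  if (cell_size <= 0) stop("cell_size must be > 0", call. = FALSE)
  if (peak_height < 0 || noise_sd < 0 || channel_depth < 0) {
    stop("heights, depths and noise_sd must be >= 0", call. = FALSE)
  }
  if (n_oreums < 0 || channel_count < 0) {
    stop("counts must be >= 0", call. = FALSE)
  }
  if (length(oreum_height_range) != 2L ||
      oreum_height_range[1] > oreum_height_range[2] ||
      any(oreum_height_range < 0)) {
    stop("oreum_height_range must be (min, max) with 0 <= min <= max", call. = FALSE)
  }
  structure(list(
    grid_shape = as.integer(grid_shape), cell_size = cell_size,
    peak_height = peak_height, n_oreums = as.integer(n_oreums),
    oreum_height_range = oreum_height_range,
    oreum_sigma_cells = oreum_sigma_cells,
    channel_count = as.integer(channel_count), channel_depth = channel_depth,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "island_params")
}

#' Generate a synthetic island DEM
#'
#' Deterministic per seed. The base surface is a radial cone dropping linearly
#' from `peak_height` at the grid centre to 0 at the island radius (the
#' half-extent of the shorter grid side); cells beyond the radius are coast at
#' elevation 0. Secondary cones are Gaussian bumps placed in the mid-radius
#' band with mutual separation, tall and narrow enough to be strict local
#' maxima against the background cone gradient. Channels are carved along
#' random radial rays with incision deepening seaward, so channel beds descend
#' monotonically. Elevations are clamped at 0.
#'
#' @param params an [island_params()].
#' @return an [lcv_grid] of elevations (m), minimum 0 at the coast.
#' @export
gen_dem <- function(params = island_params()) {
  stopifnot(inherits(params, "island_params"))
  p <- params
  nr <- p$grid_shape[1]; nc <- p$grid_shape[2]
  withr::with_seed(p$seed, {
    r0 <- (nr + 1) / 2; c0 <- (nc + 1) / 2
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    dist_cells <- sqrt((rows - r0)^2 + (cols - c0)^2)
    radius <- (min(nr, nc) - 2) / 2
    z <- p$peak_height * pmax(1 - dist_cells / radius, 0)
    if (p$n_oreums > 0L) {
      centers <- place_oreums(p$n_oreums, r0, c0, radius, p$oreum_sigma_cells)
      heights <- stats::runif(p$n_oreums, p$oreum_height_range[1],
                              p$oreum_height_range[2])
      for (i in seq_len(p$n_oreums)) {
        d2 <- (rows - centers$r[i])^2 + (cols - centers$c[i])^2
        z <- z + heights[i] * exp(-d2 / (2 * p$oreum_sigma_cells^2))
      }
    }
    if (p$channel_count > 0L) {
      angles <- stats::runif(p$channel_count, 0, 2 * pi)
      for (a in angles) {
        # signed distance of each cell from the ray, and along-ray distance
        ur <- -cos(a); uc <- sin(a)
        along <- (rows - r0) * ur + (cols - c0) * uc
        across <- abs(-(rows - r0) * uc + (cols - c0) * ur)
        corridor <- along > 1 & along < radius & across < 1.2
        depth <- p$channel_depth * (along / radius) *
          exp(-(across / 1.2)^2)
        z[corridor] <- z[corridor] - depth[corridor]
      }
    }
    if (p$noise_sd > 0) {
      z <- z + matrix(stats::rnorm(nr * nc, 0, p$noise_sd), nr, nc)
    }
    z <- pmax(z, 0)
    lcv_grid(z, p$cell_size)
  })
}

# Rejection-sample oreum centres in the mid-radius band with mutual
# separation of 4 sigma, so each bump stands clear of its neighbours.
place_oreums <- function(n, r0, c0, radius, sigma) {
  rs <- numeric(0); cs <- numeric(0)
  attempts <- 0L
  while (length(rs) < n) {
    attempts <- attempts + 1L
    if (attempts > 1000L) {
      stop("could not place the requested number of oreums", call. = FALSE)
    }
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- stats::runif(1, 0.35 * radius, 0.75 * radius)
    rr <- round(r0 + rad * -cos(ang)); cc <- round(c0 + rad * sin(ang))
    if (length(rs) &&
        any(sqrt((rs - rr)^2 + (cs - cc)^2) < 4 * sigma + 2)) next
    rs <- c(rs, rr); cs <- c(cs, cc)
  }
  list(r = rs, c = cs)
}

#' Generate elevation-banded land cover
#'
#' Assigns each cell one of the 7 land-cover classes by elevation band:
#' `class_breaks` are 6 strictly increasing elevation cut points splitting the
#' range into 7 bands, ordered from coast to summit as Open water, Wetland,
#' Developed, Agriculture, Forest, Grassland, Barren land — the co-occurrence
#' structure a volcanic island exhibits (built-up and farmed lowlands, forest
#' mid-slopes, open upper slopes). A seeded speckle reassigns a fraction of
#' cells to uniformly random classes so every class can meet every landform.
#'
#' @param dem an [lcv_grid] of elevations.
#' @param class_breaks 6 strictly increasing elevation cut points; default the
#'   six interior septile quantiles of the DEM.
#' @param seed integer seed.
#' @param speckle_rate fraction of cells reassigned at random, in `[0, 1]`.
#' @return a categorical [lcv_grid] with the land-cover legend (codes 1-7 in
#'   the order of [landcover_classes()]).
#' @export
gen_landcover <- function(dem, class_breaks = NULL, seed = 1L,
                          speckle_rate = 0.05) {
  stopifnot(inherits(dem, "lcv_grid"))
  z <- dem$values
  if (anyNA(z)) stop("DEM must be finite/unmasked for land-cover generation",
                     call. = FALSE)
  if (is.null(class_breaks)) {
    class_breaks <- stats::quantile(z, probs = (1:6) / 7, names = FALSE)
  }
  if (length(class_breaks) != 6L || any(diff(class_breaks) <= 0)) {
    stop("class_breaks must be 6 strictly increasing values", call. = FALSE)
  }
  if (speckle_rate < 0 || speckle_rate > 1) {
    stop("speckle_rate must be in [0, 1]", call. = FALSE)
  }
  # band 1 (lowest) .. band 7 (highest) -> legend codes
  band_to_class <- match(
    c("Open water", "Wetland", "Developed", "Agriculture", "Forest",
      "Grassland", "Barren land"),
    LANDCOVER_CLASSES
  )
  band <- matrix(findInterval(z, class_breaks) + 1L, nrow(z), ncol(z))
  lc <- matrix(band_to_class[band], nrow(z), ncol(z))
  withr::with_seed(as.integer(seed), {
    if (speckle_rate > 0) {
      n <- length(lc)
      hit <- stats::runif(n) < speckle_rate
      lc[hit] <- sample.int(7L, sum(hit), replace = TRUE)
    }
  })
  lcv_grid(lc, dem$cell_size, dem$xll, dem$yll,
           legend = stats::setNames(LANDCOVER_CLASSES, 1:7))
}

#' Generate labelled circular zones
#'
#' Places `n_zones` disjoint disc polygons (64-gon approximations) inside the
#' grid footprint, as a stand-in for designated / protected areas. Fails if
#' the requested number cannot be placed disjointly.
#'
#' @param dem an [lcv_grid] defining the footprint.
#' @param n_zones number of zones, >= 1.
#' @param seed integer seed.
#' @return an `lcv_zones` object (see [zones()]).
#' @export
gen_zones <- function(dem, n_zones = 3L, seed = 1L) {
  stopifnot(inherits(dem, "lcv_grid"))
  if (n_zones < 1L) stop("n_zones must be >= 1", call. = FALSE)
  d <- dim(dem$values)
  cs <- dem$cell_size
  width <- d[2] * cs; height <- d[1] * cs
  withr::with_seed(as.integer(seed), {
    feats <- list()
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    for (i in seq_len(n_zones)) {
      placed <- FALSE
      for (try in 1:200) {
        r <- stats::runif(1, 5 * cs, 10 * cs)
        cx <- stats::runif(1, dem$xll + r + cs, dem$xll + width - r - cs)
        cy <- stats::runif(1, dem$yll + r + cs, dem$yll + height - r - cs)
        if (nrow(centers) == 0 ||
            all(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) >
                radii + r + cs)) {
          ang <- seq(0, 2 * pi, length.out = 65L)[-65L]
          feats[[i]] <- list(name = sprintf("zone_%02d", i),
                             x = cx + r * cos(ang), y = cy + r * sin(ang))
          centers <- rbind(centers, c(cx, cy))
          radii <- c(radii, r)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place ", n_zones, " disjoint zones in the footprint",
             call. = FALSE)
      }
    }
    zones(feats)
  })
}

#' Parameters for the simulated expert survey
#'
#' @param n_experts panel size, >= 2 (default 13, a typical expert board).
#' @param latent_landcover_scores 7 latent conservation ratings in `[1, 5]`,
#'   in [landcover_classes()] order.
#' @param latent_landform_scores 5 latent ratings in `[1, 5]`, in
#'   [landform_classes()] order.
#' @param rating_noise_sd SD of per-expert rating noise before discretization.
#' @param seed integer seed.
#' @return a validated list of class `survey_sim_params`.
#' @export
survey_sim_params <- function(n_experts = 13L,
                              latent_landcover_scores =
                                c(1.2, 1.8, 2.5, 3.2, 3.9, 4.4, 4.9),
                              latent_landform_scores =
                                c(1.5, 2.3, 3.2, 4.1, 5.0),
                              rating_noise_sd = 0.3, seed = 1L) {
  if (n_experts < 2L) stop("n_experts must be >= 2", call. = FALSE)
  if (length(latent_landcover_scores) != 7L ||
      any(latent_landcover_scores < 1 | latent_landcover_scores > 5)) {
    stop("latent_landcover_scores must be 7 values in [1, 5]", call. = FALSE)
  }
  if (length(latent_landform_scores) != 5L ||
      any(latent_landform_scores < 1 | latent_landform_scores > 5)) {
    stop("latent_landform_scores must be 5 values in [1, 5]", call. = FALSE)
  }
  if (rating_noise_sd < 0) stop("rating_noise_sd must be >= 0", call. = FALSE)
  structure(list(
    n_experts = as.integer(n_experts),
    latent_landcover_scores = latent_landcover_scores,
    latent_landform_scores = latent_landform_scores,
    rating_noise_sd = rating_noise_sd, seed = as.integer(seed)
  ), class = "survey_sim_params")
}

#' Simulate an expert Likert survey
#'
#' Each expert rates all 12 items (7 land-cover + 5 landform classes) on the
#' 1-5 Likert grid: latent score plus Gaussian noise, rounded half-up and
#' clamped to `{1..5}`. Each expert also draws one importance category for the
#' land-cover-versus-landform comparison, attached to their land-cover rows
#' (landform rows carry "Same"), mirroring a pairwise importance survey.
#'
#' @param params a [survey_sim_params()].
#' @return a data.frame with columns `expert_id`, `item`, `rating`,
#'   `importance`; one row per expert x item.
#' @export
gen_survey <- function(params = survey_sim_params()) {
  stopifnot(inherits(params, "survey_sim_params"))
  p <- params
  items <- c(LANDCOVER_CLASSES, LANDFORM_CLASSES)
  latent <- c(p$latent_landcover_scores, p$latent_landform_scores)
  categories <- names(importance_weights())
  withr::with_seed(p$seed, {
    out <- vector("list", p$n_experts)
    for (e in seq_len(p$n_experts)) {
      noise <- if (p$rating_noise_sd > 0) {
        stats::rnorm(length(items), 0, p$rating_noise_sd)
      } else rep(0, length(items))
      rating <- pmin(5L, pmax(1L, as.integer(floor(latent + noise + 0.5))))
      imp_lc <- sample(categories, 1L)
      out[[e]] <- data.frame(
        expert_id = sprintf("expert_%02d", e),
        item = items,
        rating = rating,
        importance = c(rep(imp_lc, 7L), rep("Same", 5L)),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
}

#' Write / read survey tables
#'
#' CSV with header `expert_id,item,rating,importance`.
#'
#' @param ratings a survey data.frame as returned by [gen_survey()].
#' @param path file path.
#' @return `read_survey_csv` returns the validated data.frame.
#' @export
write_survey_csv <- function(ratings, path) {
  utils::write.csv(ratings, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("expert_id", "item", "rating", "importance")
  if (!all(need %in% names(df))) {
    stop("survey CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  validate_ratings(df)
  df
}

validate_ratings <- function(df) {
  if (!all(df$rating %in% 1:5)) {
    stop("ratings must be integers in 1..5", call. = FALSE)
  }
  known <- c(LANDCOVER_CLASSES, LANDFORM_CLASSES)
  bad <- setdiff(unique(df$item), known)
  if (length(bad)) {
    stop("unknown survey item(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}
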