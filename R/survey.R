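# Expert-survey aggregation into the landscape-conservation-value matrix.
#
# Scheme: each expert's Likert rating (1-5) of a landform or land-cover class
# is multiplied by an importance factor from a pairwise comparison; the
# weighted landform and land-cover scores are multiplied into a 7 x 5 product
# matrix per expert; the panel mean matrix is rescaled linearly so its minimum
# is exactly 1 and its maximum exactly 10.

#' Importance-category weights
#'
#' Multiplicative factors applied to ratings: 1.75 for "Very Important", 1.5
#' for "Important", 1.25 for "Merely Important" and (by the only available
#' evidence) also for "Somewhat Important", and exactly 1 for "Same".
#'
#' @param somewhat_important factor for the "Somewhat Important" category,
#'   default 1.25.
#' @return named numeric vector, category -> factor.
#' @export
importance_weights <- function(somewhat_important = 1.25) {
  c("Very Important" = 1.75, "Important" = 1.5, "Merely Important" = 1.25,
    "Somewhat Important" = somewhat_important, "Same" = 1)
}

#' Apply an importance weight to a rating
#'
#' @param rating numeric rating(s), >= 0.
#' @param category importance category name(s), recycled against `rating`.
#' @param weights a map as returned by [importance_weights()].
#' @return `rating * factor`.
#' @export
apply_importance_weight <- function(rating, category,
                                    weights = importance_weights()) {
  if (any(rating < 0)) stop("ratings must be >= 0", call. = FALSE)
  bad <- setdiff(unique(category), names(weights))
  if (length(bad)) {
    stop("unknown importance category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rating * unname(weights[category])
}

#' Raw landscape-type score matrix
#'
#' Outer product of weighted class scores: entry `(i, j)` is
#' `landcover_score[i] * landform_score[j]`. The result is rank 1 by
#' construction.
#'
#' @param landform_scores 5 weighted scores, > 0, in [landform_classes()]
#'   order (names optional).
#' @param landcover_scores 7 weighted scores, > 0, in [landcover_classes()]
#'   order.
#' @return a 7 x 5 matrix with class labels as dimnames.
#' @export
score_landscape_types <- function(landform_scores, landcover_scores) {
  if (length(landform_scores) != 5L || length(landcover_scores) != 7L) {
    stop("need 5 landform and 7 land-cover scores", call. = FALSE)
  }
  if (any(landform_scores <= 0) || any(landcover_scores <= 0)) {
    stop("scores must be > 0", call. = FALSE)
  }
  m <- outer(as.numeric(landcover_scores), as.numeric(landform_scores))
  dimnames(m) <- list(landcover_classes(), landform_classes())
  m
}

#' Rescale a matrix linearly onto [1, 10]
#'
#' The affine map `v -> 1 + 9 (v - min) / (max - min)`: the minimum cell maps
#' to exactly 1 and the maximum to exactly 10, matching the published
#' endpoints; ties at either extreme are preserved. The map is invariant to
#' positive affine pre-transforms of the input.
#'
#' @param m numeric matrix with at least 2 distinct values.
#' @return an `lcv_matrix`: the rescaled matrix with a `normalized` attribute.
#' @export
rescale_1_10 <- function(m) {
  v <- as.numeric(m)
  rng <- range(v, na.rm = TRUE)
  if (!is.finite(diff(rng)) || diff(rng) <= 0) {
    stop("matrix is constant; cannot rescale to [1, 10]", call. = FALSE)
  }
  out <- 1 + 9 * (m - rng[1]) / (rng[2] - rng[1])
  lcv_matrix(out, normalized = TRUE)
}

#' Conservation-value matrix container
#'
#' @param m 7 x 5 numeric matrix; dimnames default to the class legends.
#' @param normalized logical: has the matrix been rescaled onto [1, 10]?
#' @return an object of class `lcv_matrix`.
#' @export
lcv_matrix <- function(m, normalized = FALSE) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(7L, 5L))) {
    stop("an LCV matrix is 7 land-cover rows x 5 landform columns", call. = FALSE)
  }
  if (is.null(dimnames(m))) {
    dimnames(m) <- list(landcover_classes(), landform_classes())
  }
  if (normalized) {
    rng <- range(m)
    if (abs(rng[1] - 1) > 1e-9 || abs(rng[2] - 10) > 1e-9) {
      stop("a normalized LCV matrix must have min 1 and max 10", call. = FALSE)
    }
  }
  structure(m, normalized = normalized, class = c("lcv_matrix", "matrix"))
}

#' @export
print.lcv_matrix <- function(x, ...) {
  cat(sprintf("<lcv_matrix> 7 x 5, %s\n",
              if (isTRUE(attr(x, "normalized"))) "normalized to [1, 10]"
              else "raw scores"))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Per-expert product matrices from a ratings table
#'
#' Splits the table by expert, applies each row's importance weight to its
#' rating, and forms the 7 x 5 outer-product matrix of weighted land-cover by
#' weighted landform scores. Every expert must rate all 12 classes.
#'
#' @param ratings data.frame with `expert_id`, `item`, `rating`, `importance`.
#' @param weights an [importance_weights()] map.
#' @return named list of 7 x 5 matrices, one per expert.
#' @export
expert_score_matrices <- function(ratings, weights = importance_weights()) {
  validate_ratings(ratings)
  lapply(split(ratings, ratings$expert_id), function(df) {
    w <- apply_importance_weight(df$rating, df$importance, weights)
    names(w) <- df$item
    if (!all(c(landcover_classes(), landform_classes()) %in% names(w))) {
      stop("each expert must rate all 7 land-cover and 5 landform classes",
           call. = FALSE)
    }
    score_landscape_types(w[landform_classes()], w[landcover_classes()])
  })
}

#' Aggregate expert matrices into a normalized LCV matrix
#'
#' Default: cell-wise arithmetic mean across experts, then a single rescaling
#' onto [1, 10]. `method = "rescale_then_mean"` rescales each expert first and
#' averages afterwards (the mean of per-expert normalized matrices is then
#' rescaled again so the output contract holds) — useful as a sensitivity
#' check on the aggregation order.
#'
#' @param per_expert list of 7 x 5 matrices with identical dimnames.
#' @param method aggregation order.
#' @return a normalized `lcv_matrix`.
#' @export
aggregate_expert_matrices <- function(per_expert,
                                      method = c("mean_then_rescale",
                                                 "rescale_then_mean")) {
  method <- match.arg(method)
  if (length(per_expert) < 1L) stop("need at least one expert matrix", call. = FALSE)
  ref <- dimnames(per_expert[[1]])
  for (m in per_expert) {
    if (!identical(dim(as.matrix(m)), c(7L, 5L)) ||
        !identical(dimnames(as.matrix(m)), ref)) {
      stop("expert matrices must share shape and labels", call. = FALSE)
    }
  }
  mats <- lapply(per_expert, as.matrix)
  if (method == "rescale_then_mean") {
    mats <- lapply(mats, function(m) unclass(rescale_1_10(m)))
  }
  mean_m <- Reduce(`+`, mats) / length(mats)
  rescale_1_10(mean_m)
}

#' Aggregate a raw ratings table end to end
#'
#' @param ratings data.frame as from [gen_survey()] / [read_survey_csv()].
#' @param weights an [importance_weights()] map.
#' @param method see [aggregate_expert_matrices()].
#' @return a normalized `lcv_matrix`.
#' @export
aggregate_survey <- function(ratings, weights = importance_weights(),
                             method = "mean_then_rescale") {
  aggregate_expert_matrices(expert_score_matrices(ratings, weights),
                            method = method)
}

#' The packaged reference conservation-value matrix
#'
#' The published consensus matrix from a 13-member expert panel for a volcanic
#' island study region, on the normalized 1-10 scale: 7 land-cover rows by 5
#' landform columns, minimum 1.00 at Barren land x Flat land, maximum 10.00
#' tied at Wetland x Summit and Open water x Summit.
#'
#' @return a normalized `lcv_matrix`.
#' @export
load_reference_matrix <- function() {
  path <- system.file("extdata", "reference_lcv_matrix.csv", package = "lcvmap",
                      mustWork = TRUE)
  read_matrix_csv(path)
}

#' Read / write an LCV matrix as labelled CSV
#'
#' First column `landcover`, remaining columns the 5 landform classes.
#'
#' @param m an `lcv_matrix`.
#' @param path file path.
#' @return `read_matrix_csv` returns an `lcv_matrix` (normalized when its
#'   range is exactly [1, 10]).
#' @export
write_matrix_csv <- function(m, path) {
  stopifnot(inherits(m, "lcv_matrix"))
  df <- data.frame(landcover = rownames(m), unclass(m), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "landcover" ||
      !identical(df$landcover, landcover_classes()) ||
      !identical(names(df)[-1], landform_classes())) {
    stop("matrix CSV must be labelled with the land-cover / landform legends",
         call. = FALSE)
  }
  m <- as.matrix(df[, -1])
  rownames(m) <- df$landcover
  rng <- range(m)
  lcv_matrix(m, normalized = abs(rng[1] - 1) < 1e-9 && abs(rng[2] - 10) < 1e-9)
}
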