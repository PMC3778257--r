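#' Back-project SVM weights into voxel space
#'
#' Places each selected voxel's weight at its grid coordinate; everything
#' else is zero. Positive weights mark voxels where larger WM intensity
#' pushes the decision toward the favorable class, negative weights toward
#' the non-favorable class.
#'
#' @param model an `svm_model` whose `selected_columns` index rows of
#'   `voxel_index_map`.
#' @param voxel_index_map n x 3 matrix mapping in-mask columns to 1-based
#'   voxel coordinates (from [build_dataset()]).
#' @param grid_shape integer triple.
#' @param provenance `"final_refit"` or `"fold_average"` provenance tag.
#' @return An object of class `discrimination_map`: list with `volume` (3D
#'   array), `grid_shape`, `provenance`.
#' @export
weights_to_volume <- function(model, voxel_index_map, grid_shape,
                              provenance = "final_refit") {
  stopifnot(inherits(model, "svm_model"))
  coords <- voxel_index_map[model$selected_columns, , drop = FALSE]
  if (any(coords < 1) || any(coords > rep(grid_shape, each = nrow(coords)))) {
    stop("selected voxel coordinate outside the grid", call. = FALSE)
  }
  vol <- array(0, dim = grid_shape)
  vol[coords] <- model$w
  structure(list(volume = vol, grid_shape = as.integer(grid_shape),
                 provenance = provenance),
            class = "discrimination_map")
}

#' Fold-averaged discrimination map
#'
#' Averages the per-fold weight vectors of a nested-CV run in voxel space
#' (each fold's weights land on its own selected voxels; voxels a fold did
#' not select contribute zero for that fold). An alternative to the single
#' full-cohort refit map.
#'
#' @param cv a `cv_result` from [outer_loso()].
#' @param voxel_index_map,grid_shape as in [weights_to_volume()].
#' @return A `discrimination_map` with provenance `"fold_average"`.
#' @export
fold_average_map <- function(cv, voxel_index_map, grid_shape) {
  stopifnot(inherits(cv, "cv_result"))
  vol <- array(0, dim = grid_shape)
  for (f in cv$folds) {
    coords <- voxel_index_map[f$columns, , drop = FALSE]
    vol[coords] <- vol[coords] + f$w
  }
  structure(list(volume = vol / length(cv$folds),
                 grid_shape = as.integer(grid_shape),
                 provenance = "fold_average"),
            class = "discrimination_map")
}

# chi-square goodness of fit against a 50/50 split, df = 1, no continuity
# correction
chisq_5050 <- function(a, b) {
  e <- (a + b) / 2
  if (e == 0) return(list(statistic = NA_real_, p = NA_real_))
  stat <- (a - e)^2 / e + (b - e)^2 / e
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Hemispheric and sign distribution of discriminative weight
#'
#' Splits the non-zero voxels of a discrimination map by hemisphere (first
#' grid axis; 1-based indices at or below `floor(dim1 / 2)` are LEFT) and
#' by weight sign, and tests each contrast against a uniform 50/50
#' expectation with a df = 1 chi-square goodness-of-fit test (no continuity
#' correction): (a) left vs right overall, (b) positive vs negative, and
#' (c) left vs right within each sign. The test unit is the voxel count by
#' default; `unit = "weight"` applies the same statistic to the summed
#' absolute weights instead.
#'
#' @param map a `discrimination_map`.
#' @param unit `"count"` (default) or `"weight"`.
#' @return An object of class `lateralization_summary`: list with `table`
#'   (data frame: hemisphere, sign, n_voxels, sum_abs_weight), `tests`
#'   (data frame: comparison, statistic, p), `unit`.
#' @export
lateralization_summary <- function(map, unit = c("count", "weight")) {
  stopifnot(inherits(map, "discrimination_map"))
  unit <- match.arg(unit)
  vol <- map$volume
  nz <- which(vol != 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) stop("all-zero discrimination map", call. = FALSE)
  w <- vol[nz]
  hemi <- hemisphere_of_index(nz[, 1], map$grid_shape[1])
  sign_lab <- ifelse(w > 0, "positive", "negative")
  cells <- expand.grid(hemisphere = c("left", "right"),
                       sign = c("positive", "negative"),
                       stringsAsFactors = FALSE)
  cells$n_voxels <- mapply(function(h, s) sum(hemi == h & sign_lab == s),
                           cells$hemisphere, cells$sign)
  cells$sum_abs_weight <- mapply(function(h, s) {
    sum(abs(w[hemi == h & sign_lab == s]))
  }, cells$hemisphere, cells$sign)

  amount <- if (unit == "count") cells$n_voxels else cells$sum_abs_weight
  take <- function(h = NULL, s = NULL) {
    sel <- rep(TRUE, nrow(cells))
    if (!is.null(h)) sel <- sel & cells$hemisphere == h
    if (!is.null(s)) sel <- sel & cells$sign == s
    sum(amount[sel])
  }
  tests <- rbind(
    data.frame(comparison = "left_vs_right",
               chisq_5050(take(h = "left"), take(h = "right"))),
    data.frame(comparison = "positive_vs_negative",
               chisq_5050(take(s = "positive"), take(s = "negative"))),
    data.frame(comparison = "left_vs_right_positive",
               chisq_5050(take("left", "positive"),
                          take("right", "positive"))),
    data.frame(comparison = "left_vs_right_negative",
               chisq_5050(take("left", "negative"),
                          take("right", "negative"))))
  structure(list(table = cells, tests = tests, unit = unit),
            class = "lateralization_summary")
}
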