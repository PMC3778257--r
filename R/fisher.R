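#' Fisher-criterion voxel scores
#'
#' Scores each feature (voxel) by the squared distance between the class
#' means relative to the sum of the intra-class standard deviations,
#'
#' \deqn{f_v = (\hat\mu_{+} - \hat\mu_{-})^2 / (\hat\sigma_{+} + \hat\sigma_{-}),}
#'
#' where + is the favorable-outcome (positively labeled) class. Note the
#' denominator is the sum of *standard deviations*, not of variances; the
#' conventional variance-sum ratio is available via `denominator =
#' "variance"`. Standard deviations are population (divide by class size) by
#' default; both choices affect only the scale, and rarely the ranking.
#'
#' Voxels where both class standard deviations are zero get score 0 when the
#' means are equal and are otherwise assigned the maximum finite score among
#' the remaining voxels (so that perfectly separating constant voxels rank
#' first and the ranking stays total).
#'
#' @param X numeric matrix, subjects x features.
#' @param y labels in {+1, -1}; each class needs >= 2 members.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @param denominator `"sd"` (sum of standard deviations, default) or
#'   `"variance"` (sum of variances).
#' @return An object of class `fisher_scores`: list with `scores`,
#'   `mu_pos`, `mu_neg`, `sd_pos`, `sd_neg`.
#' @export
fisher_scores <- function(X, y, sd_type = c("population", "sample"),
                          denominator = c("sd", "variance")) {
  sd_type <- match.arg(sd_type)
  denominator <- match.arg(denominator)
  X <- as.matrix(X)
  check_labels(y)
  pos <- X[y == 1, , drop = FALSE]
  neg <- X[y == -1, , drop = FALSE]
  if (nrow(pos) < 2L || nrow(neg) < 2L) {
    stop("each class needs at least 2 members for Fisher scoring",
         call. = FALSE)
  }
  mu_pos <- colMeans(pos)
  mu_neg <- colMeans(neg)
  ssd <- function(M, mu) {
    n <- nrow(M)
    ss <- colSums((M - rep(mu, each = n))^2)
    sqrt(ss / if (sd_type == "population") n else n - 1L)
  }
  sd_pos <- ssd(pos, mu_pos)
  sd_neg <- ssd(neg, mu_neg)
  den <- if (denominator == "sd") sd_pos + sd_neg else sd_pos^2 + sd_neg^2
  num <- (mu_pos - mu_neg)^2
  scores <- ifelse(den > 0, num / den,
                   ifelse(num == 0, 0, Inf))
  if (any(is.infinite(scores))) {
    finite_max <- suppressWarnings(max(scores[is.finite(scores)], 0))
    scores[is.infinite(scores)] <- max(finite_max, 1)
  }
  structure(
    list(scores = unname(scores), mu_pos = unname(mu_pos),
         mu_neg = unname(mu_neg), sd_pos = unname(sd_pos),
         sd_neg = unname(sd_neg)),
    class = "fisher_scores"
  )
}

#' Select the top-k features by Fisher score
#'
#' @param scores a [fisher_scores()] object (or a bare numeric vector of
#'   scores).
#' @param k number of features to keep, `1 <= k <= length(scores)`.
#' @return Integer vector of the k column indices with the largest scores,
#'   in descending score order; ties broken by ascending column index.
#' @export
rank_and_select <- function(scores, k) {
  s <- if (inherits(scores, "fisher_scores")) scores$scores else scores
  n <- length(s)
  if (length(k) != 1L || k < 1 || k > n) {
    stop(sprintf("k must be in [1, %d]", n), call. = FALSE)
  }
  order(-s, seq_len(n))[seq_len(k)]
}

#' Export Fisher scores as a score volume
#'
#' Places each in-mask voxel's score at its grid coordinate for inspection
#' (e.g. writing to NIfTI); out-of-mask voxels are 0.
#'
#' @param scores a [fisher_scores()] object.
#' @param dataset the [build_dataset()] result the scores came from.
#' @return 3D numeric array of scores.
#' @export
scores_to_volume <- function(scores, dataset) {
  stopifnot(inherits(scores, "fisher_scores"),
            inherits(dataset, "cohort_dataset"))
  v <- array(0, dim = dataset$grid_shape)
  v[dataset$voxel_index_map] <- scores$scores
  v
}
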