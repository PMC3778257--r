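#' Hyperparameter grid for nested cross-validation
#'
#' Candidate regularization constants and voxel counts for the inner
#' leave-one-subject-out search. The default C grid is the usual log-spaced
#' libsvm convention; the default k grid spans sparse to moderately dense
#' selections and includes 310 and 360 voxels.
#'
#' @param C_values strictly increasing positive scalars.
#' @param k_values strictly increasing positive integer feature counts.
#' @return An object of class `hyper_grid`.
#' @export
hyper_grid <- function(C_values = 2^seq(-5, 15, by = 2),
                       k_values = c(10L, 20L, 50L, 100L, 200L, 310L, 360L,
                                    500L)) {
  if (length(C_values) == 0 || any(C_values <= 0) ||
      any(diff(C_values) <= 0)) {
    abort_field("C_values", "must be non-empty, positive, strictly increasing")
  }
  if (length(k_values) == 0 || any(k_values < 1) ||
      any(k_values != round(k_values)) || any(diff(k_values) <= 0)) {
    abort_field("k_values",
                "must be non-empty positive integers, strictly increasing")
  }
  structure(list(C_values = as.numeric(C_values),
                 k_values = as.integer(k_values)),
            class = "hyper_grid")
}

# Sample balanced accuracy of predictions vs actual labels; NA if a class
# is unobserved.
balanced_accuracy <- function(actual, predicted) {
  pos <- actual == 1
  if (!any(pos) || all(pos)) return(NA_real_)
  (mean(predicted[pos] == 1) + mean(predicted[!pos] == -1)) / 2
}

#' Inner LOSO grid search
#'
#' For every grid cell (C, k), runs leave-one-subject-out over the training
#' set: each inner fold recomputes Fisher scores on its own remaining
#' subjects, selects the top-k voxels, trains the SVM at C and predicts the
#' left-out subject. The cell with the highest inner balanced accuracy wins;
#' ties are broken toward smaller k, then smaller C (prefer the sparser,
#' smoother model). Inner folds whose remaining subjects do not contain at
#' least two members of each class are skipped and the balanced accuracy is
#' computed over the evaluated folds only.
#'
#' k values larger than the number of available features are dropped from
#' the search.
#'
#' @param X training feature matrix (subjects x voxels).
#' @param y training labels in {+1, -1}, >= 2 per class.
#' @param grid a [hyper_grid()].
#' @param ... passed to [fisher_scores()] (e.g. `sd_type`).
#' @return List with `C`, `k`, `inner_balanced_accuracy`, and `cells`, a
#'   data frame of per-cell inner balanced accuracies.
#' @export
inner_select <- function(X, y, grid, ...) {
  stopifnot(inherits(grid, "hyper_grid"))
  X <- as.matrix(X)
  y <- check_labels(y)
  if (sum(y == 1) < 2L || sum(y == -1) < 2L) {
    stop("inner grid search needs >= 2 training subjects per class",
         call. = FALSE)
  }
  k_values <- grid$k_values[grid$k_values <= ncol(X)]
  if (length(k_values) == 0L) {
    stop("all grid k values exceed the number of features", call. = FALSE)
  }
  C_values <- grid$C_values
  M <- nrow(X)
  n_cells <- length(k_values) * length(C_values)
  # decisions[fold, cell]; cells ordered k-major then C (the tie-break order)
  dec <- matrix(NA_real_, M, n_cells)
  for (i in seq_len(M)) {
    tr <- setdiff(seq_len(M), i)
    ytr <- y[tr]
    if (sum(ytr == 1) < 2L || sum(ytr == -1) < 2L) next  # degenerate fold
    fs <- fisher_scores(X[tr, , drop = FALSE], ytr, ...)
    cell <- 0L
    for (k in k_values) {
      cols <- rank_and_select(fs, k)
      Xtr <- X[tr, cols, drop = FALSE]
      Xte <- X[i, cols, drop = FALSE]
      for (C in C_values) {
        cell <- cell + 1L
        m <- train_linear_svm(Xtr, ytr, C)
        dec[i, cell] <- decision_values(m, Xte)
      }
    }
  }
  cells <- expand.grid(C = C_values, k = k_values,
                       KEEP.OUT.ATTRS = FALSE)[, c("k", "C")]
  cells$inner_balanced_accuracy <- vapply(seq_len(n_cells), function(cl) {
    got <- !is.na(dec[, cl])
    if (!any(got)) return(NA_real_)
    balanced_accuracy(y[got], ifelse(dec[got, cl] > 0, 1, -1))
  }, numeric(1))
  if (all(is.na(cells$inner_balanced_accuracy))) {
    stop("no inner fold could be evaluated", call. = FALSE)
  }
  # cells is already sorted by (k, C); the first strict maximum realizes the
  # tie-break smaller k, then smaller C, independent of grid input order
  best <- which.max(cells$inner_balanced_accuracy)
  list(C = cells$C[best], k = cells$k[best],
       inner_balanced_accuracy = cells$inner_balanced_accuracy[best],
       cells = cells)
}

#' Nested leave-one-subject-out cross-validation
#'
#' The outer loop leaves each subject out once. For every outer fold the
#' inner LOSO grid search ([inner_select()]) picks (C*, k*) on the N-1
#' training subjects only, Fisher scores and the top-k* voxels are then
#' recomputed on those same N-1 subjects, the SVM is trained at C*, and the
#' held-out subject's decision value is recorded. Feature selection and
#' model selection therefore never see the test subject.
#'
#' @param dataset a [build_dataset()] result with N >= 4 subjects and >= 2
#'   per class.
#' @param grid a [hyper_grid()].
#' @param ... passed to [fisher_scores()].
#' @return An object of class `cv_result`: list with `subjects` (data frame:
#'   `id`, `actual`, `decision`, `predicted`), `folds` (per-fold list:
#'   `C`, `k`, `columns`, `w`, `b`, `inner_balanced_accuracy`) and `grid`.
#' @export
outer_loso <- function(dataset, grid = hyper_grid(), ...) {
  stopifnot(inherits(dataset, "cohort_dataset"), inherits(grid, "hyper_grid"))
  X <- dataset$X
  y <- dataset$y
  N <- nrow(X)
  if (N < 4L || sum(y == 1) < 2L || sum(y == -1) < 2L) {
    stop("nested LOSO needs N >= 4 with >= 2 subjects per class",
         call. = FALSE)
  }
  decision <- numeric(N)
  folds <- vector("list", N)
  for (i in seq_len(N)) {
    tr <- setdiff(seq_len(N), i)
    sel <- inner_select(X[tr, , drop = FALSE], y[tr], grid, ...)
    fs <- fisher_scores(X[tr, , drop = FALSE], y[tr], ...)
    cols <- rank_and_select(fs, sel$k)
    model <- train_linear_svm(X[tr, cols, drop = FALSE], y[tr], sel$C,
                              selected_columns = cols)
    decision[i] <- decision_values(model, X[i, cols, drop = FALSE])
    folds[[i]] <- list(C = sel$C, k = sel$k, columns = cols,
                       w = model$w, b = model$b,
                       inner_balanced_accuracy = sel$inner_balanced_accuracy)
  }
  structure(
    list(subjects = data.frame(id = dataset$subject_ids, actual = y,
                               decision = decision,
                               predicted = ifelse(decision > 0, 1, -1),
                               stringsAsFactors = FALSE),
         folds = folds, grid = grid),
    class = "cv_result"
  )
}

#' Fit one model on the full cohort
#'
#' Runs the inner-style LOSO grid search over all N subjects to pick
#' (C*, k*), then recomputes Fisher scores on all subjects, selects the
#' top-k* voxels and fits a single SVM. This is the model whose weight
#' vector is back-projected as the cohort's discrimination map; a fold-
#' averaged map from [outer_loso()] folds is available as an alternative
#' ([fold_average_map()]).
#'
#' @inheritParams outer_loso
#' @return List with `model` (an `svm_model`), `columns`, `C`, `k`.
#' @export
final_model <- function(dataset, grid = hyper_grid(), ...) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  sel <- inner_select(dataset$X, dataset$y, grid, ...)
  fs <- fisher_scores(dataset$X, dataset$y, ...)
  cols <- rank_and_select(fs, sel$k)
  model <- train_linear_svm(dataset$X[, cols, drop = FALSE], dataset$y,
                            sel$C, selected_columns = cols)
  list(model = model, columns = cols, C = sel$C, k = sel$k)
}

#' Write out-of-fold predictions as CSV (+ per-fold JSON sidecar)
#'
#' The CSV mirrors the per-patient prediction tables: subject id, actual
#' label, decision value, predicted label.
#'
#' @param cv a `cv_result`.
#' @param csv_path output CSV path.
#' @param json_path optional path for the per-fold (C, k, columns) sidecar.
#' @export
write_cv_result <- function(cv, csv_path, json_path = NULL) {
  stopifnot(inherits(cv, "cv_result"))
  utils::write.csv(cv$subjects, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      lapply(cv$folds, function(f) f[c("C", "k", "columns")]),
      json_path, digits = NA, auto_unbox = TRUE)
  }
  invisible(csv_path)
}
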