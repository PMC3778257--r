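#' Train a linear soft-margin SVM
#'
#' Solves the standard soft-margin problem
#' minimize `0.5 ||w||^2 + C sum(xi_i)` subject to
#' `y_i (w . x_i + b) >= 1 - xi_i`, `xi_i >= 0`, via the libsvm SMO solver
#' (through \pkg{e1071}), and exposes the primal weight vector, bias and the
#' dual coefficients. No feature standardization is applied by default: WM
#' intensities already share the \[0, 1\] scale.
#'
#' The returned model satisfies, up to the solver tolerance, the KKT
#' conditions (`alpha = 0 => y f >= 1`, `0 < alpha < C => y f = 1`,
#' `alpha = C => y f <= 1`), the representation identity
#' `w = sum_i alpha_i y_i x_i`, and `sum_i alpha_i y_i = 0`.
#'
#' @param X numeric matrix (training subjects x selected features).
#' @param y labels in {+1, -1}, both classes present.
#' @param C regularization constant (> 0). Larger C penalizes margin
#'   violations harder.
#' @param selected_columns optional integer vector recording which dataset
#'   columns `X` consists of (stored for back-projection).
#' @param tolerance SMO termination tolerance.
#' @param scale standardize features before training (default FALSE).
#' @return An object of class `svm_model`: list with `w`, `b`, `alpha`
#'   (length N, in \[0, C\]), `support_indices`, `C`, `selected_columns`,
#'   `y`, `X`.
#' @export
train_linear_svm <- function(X, y, C, selected_columns = seq_len(ncol(X)),
                             tolerance = 1e-7, scale = FALSE) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) abort_field("X", "features must be finite")
  y <- check_labels(y)
  if (length(y) != nrow(X)) abort_field("y", "length must match rows of X")
  if (length(C) != 1L || !is.finite(C) || C <= 0) {
    abort_field("C", "must be a single positive scalar")
  }
  fit <- e1071::svm(X, factor(y, levels = c(1, -1)), type = "C-classification",
                    kernel = "linear", cost = C, scale = scale,
                    tolerance = tolerance)
  w <- drop(t(X[fit$index, , drop = FALSE]) %*% fit$coefs)
  b <- -fit$rho
  # libsvm orients the decision value toward the first factor level; flip if
  # it reports the opposite orientation
  dv <- attr(stats::predict(fit, X[1, , drop = FALSE], decision.values = TRUE),
             "decision.values")
  if (identical(colnames(dv), "-1/1")) {
    w <- -w
    b <- -b
  }
  alpha <- numeric(length(y))
  alpha[fit$index] <- abs(as.vector(fit$coefs))
  structure(
    list(w = unname(w), b = unname(b), alpha = alpha,
         support_indices = sort(fit$index), C = C,
         selected_columns = as.integer(selected_columns),
         y = y, X = unname(X)),
    class = "svm_model"
  )
}

#' SVM decision values
#'
#' `f(x) = w . x + b` per row. A positive value predicts the favorable
#' class; the magnitude expresses how far the subject lies from the
#' hyperplane, i.e. the strength of evidence.
#'
#' @param model an [train_linear_svm()] model.
#' @param X matrix whose columns match `model$selected_columns` (same width
#'   as the training matrix).
#' @return Numeric vector of decision values.
#' @export
decision_values <- function(model, X) {
  stopifnot(inherits(model, "svm_model"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$w)) {
    stop(sprintf("feature dimension mismatch: model has %d, data has %d",
                 length(model$w), ncol(X)), call. = FALSE)
  }
  drop(X %*% model$w) + model$b
}

#' Predict class labels from decision values
#'
#' Strictly positive decision values map to +1 (favorable); zero or negative
#' values map to -1. Mapping an exact zero to the non-favorable class is the
#' conservative clinical direction and is the documented tie rule.
#'
#' @param model an `svm_model`.
#' @param X feature matrix.
#' @return Numeric vector of labels in {+1, -1}.
#' @export
predict_labels <- function(model, X) {
  f <- decision_values(model, X)
  ifelse(f > 0, 1, -1)
}

#' Serialize / deserialize an SVM model as JSON
#'
#' @param model an `svm_model`.
#' @param path file path.
#' @return `read_svm_model` returns an `svm_model` (without the training
#'   matrix).
#' @export
write_svm_model <- function(model, path) {
  stopifnot(inherits(model, "svm_model"))
  jsonlite::write_json(
    list(w = model$w, b = model$b, alpha = model$alpha,
         support_indices = model$support_indices, C = model$C,
         selected_columns = model$selected_columns, y = model$y),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_svm_model
#' @export
read_svm_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(w = as.numeric(o$w), b = as.numeric(o$b),
         alpha = as.numeric(o$alpha),
         support_indices = as.integer(o$support_indices), C = o$C,
         selected_columns = as.integer(o$selected_columns),
         y = as.numeric(o$y), X = NULL),
    class = "svm_model"
  )
}
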