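#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p by the minimum-likelihood rule: the sum of
#' hypergeometric probabilities of all tables (with the observed margins)
#' whose probability does not exceed that of the observed table. This is
#' the convention implemented by [stats::fisher.test()], which backs this
#' function.
#'
#' @param a,b,c_,d non-negative integer cell counts; rows are e.g. febrile
#'   yes/no, columns favorable/non-favorable outcome.
#' @return List with `p` (two-sided) and `odds_ratio` (conditional MLE).
#' @examples
#' fisher_exact_2x2(4, 4, 7, 4)$p  # ~0.66
#' @export
fisher_exact_2x2 <- function(a, b, c_, d) {
  counts <- c(a, b, c_, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort_field("counts", "must be non-negative integers")
  }
  ft <- stats::fisher.test(matrix(c(a, c_, b, d), 2, 2))
  list(p = unname(ft$p.value), odds_ratio = unname(ft$estimate))
}

#' Mann-Whitney U test
#'
#' U computed from midranks. The p-value uses the exact U distribution when
#' there are no ties and the smaller group has at most `exact_max`
#' observations, and otherwise the normal approximation with tie and
#' continuity correction (both via [stats::wilcox.test()]). The backend
#' actually used is reported.
#'
#' @param group_a,group_b numeric observation vectors (non-empty).
#' @param exact_max largest min-group size for the exact backend.
#' @return List with `U` (statistic for `group_a`), `p` (two-sided),
#'   `backend` (`"exact"` or `"approximate"`).
#' @export
mann_whitney_u <- function(group_a, group_b, exact_max = 12L) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (length(unique(c(group_a, group_b))) == 1L) {
    # every observation tied: no evidence either way
    return(list(U = length(group_a) * length(group_b) / 2, p = 1,
                backend = "approximate"))
  }
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  exact <- !ties && min(length(group_a), length(group_b)) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = unname(wt$p.value),
       backend = if (exact) "exact" else "approximate")
}

#' Kruskal-Wallis rank sum test
#'
#' Tie-corrected H with a chi-square p-value on `length(groups) - 1`
#' degrees of freedom (via [stats::kruskal.test()]).
#'
#' @param groups named list of numeric observation vectors (>= 2 groups,
#'   each non-empty).
#' @return List with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L ||
      any(lengths(groups) == 0L)) {
    abort_field("groups", "need >= 2 non-empty groups")
  }
  if (length(unique(unlist(groups))) == 1L) {
    # every observation tied: H degenerates to 0
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = unname(kt$p.value))
}

#' Rank correlation between subject weighting and a clinical covariate
#'
#' Spearman rank correlation with a tie-safe two-sided p-value (t
#' approximation). The per-subject "weighting" is, by default, the
#' magnitude of the out-of-fold SVM decision value — the printed
#' per-subject quantity; the dual coefficient alpha is the alternative
#' reading (see [sv_vs_nonsv_comparison()] for the SV partition itself).
#'
#' @param weighting per-subject numeric vector.
#' @param covariate equal-length numeric covariate (length >= 3).
#' @return List with `rho` and `p`.
#' @export
weighting_covariate_correlation <- function(weighting, covariate) {
  if (length(weighting) != length(covariate) || length(weighting) < 3L) {
    stop("need equal-length vectors with n >= 3", call. = FALSE)
  }
  if (stats::sd(weighting) == 0 || stats::sd(covariate) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(weighting, covariate, method = "spearman",
                    exact = FALSE))
  list(rho = unname(ct$estimate), p = unname(ct$p.value))
}

#' Compare support-vector and non-support-vector patients
#'
#' Partitions the cohort by whether a subject is a support vector of the
#' full-cohort model (`alpha > 0`), crossed with the outcome group, and
#' runs a four-group Kruskal-Wallis test per clinical characteristic. With
#' fewer than two distinct cells (e.g. every subject a support vector) the
#' partition is degenerate and reported as such.
#'
#' @param model the full-cohort `svm_model` (from [final_model()]).
#' @param clinical clinical data frame, rows in training order, with a
#'   `label` column.
#' @param characteristics character vector of clinical column names to
#'   test.
#' @return List with `groups` (per-subject factor:
#'   `FO_SV`/`FO_NonSV`/`NonFO_SV`/`NonFO_NonSV`), `degenerate` flag and
#'   `tests` (per characteristic: H, df, p — NULL when degenerate).
#' @export
sv_vs_nonsv_comparison <- function(model, clinical,
                                   characteristics = c(
                                     "age_at_onset", "followup_months",
                                     "seizure_freq_per_month")) {
  stopifnot(inherits(model, "svm_model"))
  if (nrow(clinical) != length(model$alpha)) {
    stop("clinical table must have one row per training subject",
         call. = FALSE)
  }
  sv <- model$alpha > 0
  grp <- paste0(ifelse(clinical$label == 1, "FO", "NonFO"),
                ifelse(sv, "_SV", "_NonSV"))
  # the SV/non-SV contrast is degenerate when every subject (or none) is a
  # support vector; the outcome split still allows a two-group test, which
  # is reported together with the flag
  degenerate <- length(unique(sv)) < 2L
  tests <- NULL
  if (length(unique(grp)) >= 2L) {
    tests <- lapply(characteristics, function(ch) {
      kruskal_wallis(split(clinical[[ch]], grp))
    })
    names(tests) <- characteristics
  }
  list(groups = grp, degenerate = degenerate, tests = tests)
}
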