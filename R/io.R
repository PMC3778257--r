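#' Write / read a subject volume as NIfTI-1
#'
#' Single-file `.nii.gz` with the voxel size in the header. Only the voxel
#' size is interpreted on the way back in; orientation is taken as-is.
#'
#' @param volume a [subject_volume()].
#' @param path output `.nii` / `.nii.gz` path.
#' @param label,subject_id metadata to attach on read (NIfTI stores
#'   neither).
#' @export
write_volume_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "subject_volume"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path, subject_id = basename(path), label = 1) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1:3]
  subject_volume(array(as.numeric(img), dim = dim(img)), vox,
                 subject_id, label, clip = FALSE)
}

#' Write a cohort to a directory
#'
#' One NIfTI volume per subject (named by subject id), the clinical table
#' as `clinical.csv` (exact column names of the record fields), and the
#' generating spec as `spec.json` when the cohort is synthetic.
#'
#' @param cohort a [generate_cohort()] result (or a list with `volumes` and
#'   `clinical`).
#' @param dir output directory (created if missing).
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (v in cohort$volumes) {
    write_volume_nifti(v, file.path(dir, paste0(v$subject_id, ".nii.gz")))
  }
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$spec)) {
    s <- cohort$spec
    jsonlite::write_json(
      list(grid_shape = s$grid_shape, voxel_size_mm = s$voxel_size_mm,
           n_positive = s$n_positive, n_negative = s$n_negative,
           baseline = s$baseline, noise_sd = s$noise_sd,
           smooth_fwhm_mm = s$smooth_fwhm_mm, seed = s$seed,
           effects = lapply(s$effects, function(e) {
             list(center = e$center, radius = e$radius,
                  hemisphere = e$hemisphere, delta = e$delta,
                  shape = e$shape)
           })),
      file.path(dir, "spec.json"), digits = NA, auto_unbox = TRUE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  clinical <- utils::read.csv(file.path(dir, "clinical.csv"),
                              stringsAsFactors = FALSE)
  volumes <- lapply(seq_len(nrow(clinical)), function(i) {
    read_volume_nifti(file.path(dir, paste0(clinical$id[i], ".nii.gz")),
                      subject_id = clinical$id[i],
                      label = clinical$label[i])
  })
  list(volumes = volumes, clinical = clinical, spec = NULL)
}

#' Read a cohort spec from JSON
#'
#' @param path path to a `spec.json` written by [write_cohort()] (or
#'   hand-authored in the same shape).
#' @return A [cohort_spec()].
#' @export
read_cohort_spec <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  effects <- list()
  if (!is.null(o$effects) && length(o$effects)) {
    # simplifyVector may give a data frame or a list of lists
    eff_list <- if (is.data.frame(o$effects)) {
      lapply(seq_len(nrow(o$effects)), function(i) as.list(o$effects[i, ]))
    } else {
      o$effects
    }
    effects <- lapply(eff_list, function(e) {
      planted_effect(unlist(e$center), e$radius, e$hemisphere, e$delta)
    })
  }
  cohort_spec(grid_shape = o$grid_shape, voxel_size_mm = o$voxel_size_mm,
              n_positive = o$n_positive, n_negative = o$n_negative,
              baseline = o$baseline, noise_sd = o$noise_sd,
              effects = effects, smooth_fwhm_mm = o$smooth_fwhm_mm,
              seed = o$seed)
}

#' Write a discrimination map as signed NIfTI
#'
#' @param map a `discrimination_map`.
#' @param path output path.
#' @param voxel_size_mm voxel size for the header.
#' @export
write_map_nifti <- function(map, path, voxel_size_mm = c(1, 1, 1)) {
  stopifnot(inherits(map, "discrimination_map"))
  img <- RNifti::asNifti(map$volume)
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Run the full analysis flow on a cohort
#'
#' Image processing (smoothing already applied at generation for synthetic
#' cohorts), masking and flattening, nested leave-one-subject-out
#' cross-validation with inner Fisher-selection/grid search, performance
#' evaluation, discrimination-map back-projection with lateralization
#' tests, and the clinical covariate statistics — the end-to-end pipeline.
#'
#' @param cohort a cohort list (`volumes`, `clinical`) from
#'   [generate_cohort()] or [read_cohort()].
#' @param grid a [hyper_grid()].
#' @param mask_threshold cohort-mean intensity cutoff for [default_mask()].
#' @param level,draws,seed credible-interval options.
#' @param lateralization_unit `"count"` or `"weight"`.
#' @return List with `dataset`, `cv`, `evaluation`, `final`, `map`,
#'   `lateralization`, `clinical_tests`.
#' @export
run_pipeline <- function(cohort, grid = hyper_grid(),
                         mask_threshold = 0.05, level = 0.95,
                         draws = 1e6, seed = 1L,
                         lateralization_unit = "count") {
  mask <- default_mask(cohort$volumes, mask_threshold)
  dataset <- build_dataset(cohort$volumes, mask, cohort$clinical)
  cv <- outer_loso(dataset, grid)
  evaluation <- evaluate_predictions(cv$subjects$actual,
                                     cv$subjects$decision,
                                     level = level, draws = draws,
                                     seed = seed)
  final <- final_model(dataset, grid)
  map <- weights_to_volume(final$model, dataset$voxel_index_map,
                           dataset$grid_shape)
  lateralization <- lateralization_summary(map, lateralization_unit)
  clinical_tests <- NULL
  if (!is.null(dataset$clinical)) {
    weighting <- abs(cv$subjects$decision)
    covs <- intersect(c("age_at_onset", "followup_months", "febrile",
                        "seizure_freq_per_month"),
                      names(dataset$clinical))
    correlations <- lapply(covs, function(cv_name) {
      tryCatch(
        weighting_covariate_correlation(weighting,
                                        dataset$clinical[[cv_name]]),
        error = function(e) list(rho = NA_real_, p = NA_real_))
    })
    names(correlations) <- covs
    clinical_tests <- list(
      correlations = correlations,
      sv_vs_nonsv = sv_vs_nonsv_comparison(final$model, dataset$clinical))
  }
  list(dataset = dataset, cv = cv, evaluation = evaluation, final = final,
       map = map, lateralization = lateralization,
       clinical_tests = clinical_tests)
}

#' Write a Table-2-style performance report
#'
#' JSON summary (confusion counts, sensitivity, specificity, balanced
#' accuracy with credible interval, PPV, likelihood ratio, F-measure, AUC)
#' plus ROC and precision-recall point lists as CSV.
#'
#' @param evaluation an [evaluate_predictions()] result.
#' @param dir output directory.
#' @export
write_report <- function(evaluation, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cs <- evaluation$confusion
  ci <- evaluation$interval
  jsonlite::write_json(
    list(TP = cs$TP, FP = cs$FP, TN = cs$TN, FN = cs$FN,
         sensitivity = cs$sensitivity, specificity = cs$specificity,
         balanced_accuracy = cs$balanced_accuracy, ppv = cs$ppv,
         positive_likelihood_ratio = cs$positive_likelihood_ratio,
         f_measure = cs$f_measure, auc = evaluation$roc$auc,
         credible_interval = list(lower = ci$lower, upper = ci$upper,
                                  level = ci$level,
                                  posterior_mean = ci$posterior_mean)),
    file.path(dir, "summary.json"), digits = NA, auto_unbox = TRUE)
  utils::write.csv(evaluation$roc$points, file.path(dir, "roc.csv"),
                   row.names = FALSE)
  utils::write.csv(evaluation$pr, file.path(dir, "precision_recall.csv"),
                   row.names = FALSE)
  invisible(dir)
}
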