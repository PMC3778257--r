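#' Describe a planted group-discriminative effect
#'
#' A spherical region whose mean white-matter intensity differs between the
#' favorable (+1) and non-favorable (-1) outcome classes by `delta`. The
#' first grid axis is the left-right axis: 1-based indices at or below
#' `floor(dim1 / 2)` are the LEFT hemisphere, the rest are RIGHT.
#'
#' @param center integer triple, 1-based voxel coordinate of the sphere
#'   center.
#' @param radius sphere radius in voxels (>= 1).
#' @param hemisphere `"left"` or `"right"`; every voxel of the effect must
#'   lie on that side of the midline plane.
#' @param delta signed difference between the class mean intensities inside
#'   the sphere (positive class minus negative class), on the \[0, 1\] WM
#'   intensity scale.
#' @return An object of class `planted_effect`.
#' @seealso [cohort_spec()], [generate_cohort()]
#' @export
planted_effect <- function(center, radius, hemisphere = c("left", "right"),
                           delta) {
  hemisphere <- match.arg(hemisphere)
  if (length(center) != 3L || any(center < 1) || any(center != round(center))) {
    abort_field("center", "must be a 1-based integer voxel triple")
  }
  if (length(radius) != 1L || !is.finite(radius) || radius < 1) {
    abort_field("radius", "must be a single value >= 1")
  }
  if (length(delta) != 1L || !is.finite(delta)) {
    abort_field("delta", "must be a single finite number")
  }
  structure(
    list(center = as.integer(center), radius = radius,
         hemisphere = hemisphere, delta = delta, shape = "sphere"),
    class = "planted_effect"
  )
}

#' Specify a synthetic cohort
#'
#' Parameters of a simulated cohort of smoothed white-matter probability
#' volumes with planted class differences. Per-voxel Gaussian noise is added
#' *before* smoothing so the generated volumes carry the spatial correlation
#' characteristic of smoothed VBM segments; intensities are clipped to
#' \[0, 1\] at the end because WM segments are tissue probabilities.
#'
#' @param grid_shape integer triple, volume dimensions (each >= 8).
#' @param voxel_size_mm length-3 voxel size in mm.
#' @param n_positive,n_negative class sizes (each >= 2); positive = favorable
#'   outcome.
#' @param baseline mean WM intensity outside any effect, in \[0, 1\].
#' @param noise_sd standard deviation of the pre-smoothing voxel noise (> 0).
#' @param effects list of [planted_effect()] objects (possibly empty).
#' @param smooth_fwhm_mm isotropic Gaussian smoothing FWHM in mm (0 = none).
#' @param seed integer seed; the cohort is fully reproducible from the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(grid_shape = c(16L, 16L, 16L),
                        voxel_size_mm = c(1, 1, 1),
                        n_positive = 10L, n_negative = 10L,
                        baseline = 0.5, noise_sd = 0.05,
                        effects = list(),
                        smooth_fwhm_mm = 3, seed = 1L) {
  if (length(grid_shape) != 3L || any(grid_shape < 8)) {
    abort_field("grid_shape", "must be a triple with all components >= 8")
  }
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0)) {
    abort_field("voxel_size_mm", "must be a positive length triple")
  }
  if (n_positive < 2L) abort_field("n_positive", "must be >= 2")
  if (n_negative < 2L) abort_field("n_negative", "must be >= 2")
  if (length(baseline) != 1L || baseline < 0 || baseline > 1) {
    abort_field("baseline", "must be a scalar in [0, 1]")
  }
  if (length(noise_sd) != 1L || !is.finite(noise_sd) || noise_sd <= 0) {
    abort_field("noise_sd", "must be > 0")
  }
  if (length(smooth_fwhm_mm) != 1L || smooth_fwhm_mm < 0) {
    abort_field("smooth_fwhm_mm", "must be >= 0")
  }
  if (length(seed) != 1L || !is.finite(seed)) {
    abort_field("seed", "must be a single integer")
  }
  if (!is.list(effects) ||
      !all(vapply(effects, inherits, logical(1), "planted_effect"))) {
    abort_field("effects", "must be a list of planted_effect objects")
  }
  grid_shape <- as.integer(grid_shape)
  for (i in seq_along(effects)) {
    validate_effect_placement(effects[[i]], grid_shape, sprintf("effects[[%d]]", i))
  }
  structure(
    list(grid_shape = grid_shape, voxel_size_mm = as.numeric(voxel_size_mm),
         n_positive = as.integer(n_positive),
         n_negative = as.integer(n_negative),
         baseline = baseline, noise_sd = noise_sd, effects = effects,
         smooth_fwhm_mm = smooth_fwhm_mm, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Midline: 1-based first-axis indices <= floor(d1/2) are LEFT.
hemisphere_of_index <- function(i1, dim1) {
  ifelse(i1 <= floor(dim1 / 2), "left", "right")
}

#' @keywords internal
validate_effect_placement <- function(effect, grid_shape, field) {
  if (any(effect$center > grid_shape)) {
    abort_field(field, "center lies outside the grid")
  }
  mask <- effect_mask(effect, grid_shape)
  i1 <- which(apply(mask, 1, any))
  sides <- unique(hemisphere_of_index(i1, grid_shape[1]))
  if (!identical(sides, effect$hemisphere)) {
    abort_field(field, sprintf(
      "effect voxels must all lie on the %s side of the midline",
      effect$hemisphere))
  }
  invisible(TRUE)
}

# Logical mask of the voxels inside one spherical effect.
effect_mask <- function(effect, grid_shape) {
  d <- grid_shape
  i <- array(rep(seq_len(d[1]), times = d[2] * d[3]), dim = d)
  j <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), dim = d)
  k <- array(rep(seq_len(d[3]), each = d[1] * d[2]), dim = d)
  c0 <- effect$center
  (i - c0[1])^2 + (j - c0[2])^2 + (k - c0[3])^2 <= effect$radius^2
}

# Union of all effect masks (all-FALSE if no effects).
effects_union_mask <- function(effects, grid_shape) {
  m <- array(FALSE, dim = grid_shape)
  for (e in effects) m <- m | effect_mask(e, grid_shape)
  m
}

#' Generate a synthetic cohort of white-matter volumes
#'
#' Each subject's volume is `baseline` plus, inside each planted effect,
#' `+delta/2` for the positive class and `-delta/2` for the negative class,
#' plus independent per-voxel Gaussian noise; the sum is Gaussian-smoothed at
#' `smooth_fwhm_mm` and clipped to \[0, 1\]. In expectation the two class
#' means therefore differ by `delta` inside each (smoothed) effect region and
#' are identical elsewhere.
#'
#' @param spec a [cohort_spec()].
#' @param clinical_params optional list of location parameters forwarded to
#'   [generate_clinical_table()].
#' @return A list with elements `volumes` (list of [subject_volume()]
#'   objects, positives first), `clinical` (data frame of one row per
#'   subject) and `spec`.
#' @examples
#' spec <- cohort_spec(grid_shape = c(12, 12, 12), n_positive = 3,
#'                     n_negative = 3, seed = 7)
#' coh <- generate_cohort(spec)
#' length(coh$volumes)
#' @export
generate_cohort <- function(spec, clinical_params = list()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_positive + spec$n_negative
  labels <- c(rep(1, spec$n_positive), rep(-1, spec$n_negative))
  ids <- sprintf("S%02d", seq_len(n))

  masks <- lapply(spec$effects, effect_mask, grid_shape = spec$grid_shape)

  volumes <- with_seed(spec$seed, {
    lapply(seq_len(n), function(s) {
      v <- array(spec$baseline, dim = spec$grid_shape)
      for (e in seq_along(spec$effects)) {
        shift <- spec$effects[[e]]$delta / 2 * labels[s]
        v[masks[[e]]] <- v[masks[[e]]] + shift
      }
      v <- v + array(stats::rnorm(prod(spec$grid_shape), sd = spec$noise_sd),
                     dim = spec$grid_shape)
      sv <- subject_volume(v, spec$voxel_size_mm, ids[s], labels[s],
                           clip = FALSE)
      if (spec$smooth_fwhm_mm > 0) {
        sv <- gaussian_smooth(sv, spec$smooth_fwhm_mm)
      }
      sv$data <- pmin(pmax(sv$data, 0), 1)
      sv
    })
  })

  clinical <- do.call(generate_clinical_table, c(
    list(n_positive = spec$n_positive, n_negative = spec$n_negative,
         seed = spec$seed + 1L),
    clinical_params))
  clinical$id <- ids
  list(volumes = volumes, clinical = clinical, spec = spec)
}

#' Generate a synthetic clinical covariate table
#'
#' Emulates the structure of the cohorts' clinical characteristics tables:
#' ages (onset, MRI, surgery), childhood febrile-seizure history, monthly
#' seizure frequency and post-surgical follow-up duration. Only marginal
#' plausibility is intended: ages are discrete uniform around the location
#' medians, frequencies log-normal, febrile history Bernoulli. The record
#' invariants `age_at_surgery >= age_at_mri >= age_at_onset` and
#' `followup_months >= 12` (the one-year outcome-rating inclusion criterion)
#' always hold.
#'
#' @param n_positive,n_negative class sizes (>= 2 each).
#' @param seed integer seed.
#' @param median_onset,median_mri_age named per-class location parameters
#'   (`pos`, `neg`), in years.
#' @param onset_spread,mri_spread half-widths of the discrete uniform age
#'   ranges in years (0 gives a degenerate, constant column).
#' @param febrile_prob per-class probability of a febrile-seizure history.
#' @param freq_meanlog,freq_sdlog log-normal parameters of the monthly
#'   seizure frequency (`freq_sdlog = 0` is degenerate).
#' @param followup_median,followup_spread follow-up months location and
#'   half-width (floored at 12).
#' @param surgery_delay_prob probability that surgery happened the year
#'   after the MRI rather than the same year (0 or 1 is degenerate).
#' @return data frame with columns `id`, `label`, `age_at_onset`,
#'   `age_at_mri`, `age_at_surgery`, `febrile`, `seizure_freq_per_month`,
#'   `followup_months`.
#' @export
generate_clinical_table <- function(n_positive, n_negative, seed = 1L,
                                    median_onset = c(pos = 18, neg = 13),
                                    onset_spread = 12,
                                    median_mri_age = c(pos = 41, neg = 48),
                                    mri_spread = 10,
                                    febrile_prob = c(pos = 0.36, neg = 0.5),
                                    freq_meanlog = log(5), freq_sdlog = 0.8,
                                    followup_median = 21,
                                    followup_spread = 9,
                                    surgery_delay_prob = 0.5) {
  if (n_positive < 2L || n_negative < 2L) {
    abort_field("n_positive/n_negative", "counts must be >= 2")
  }
  if (any(onset_spread < 0, mri_spread < 0, followup_spread < 0,
          freq_sdlog < 0)) {
    abort_field("spread", "spread parameters must be >= 0")
  }
  if (any(febrile_prob < 0 | febrile_prob > 1)) {
    abort_field("febrile_prob", "must be probabilities in [0, 1]")
  }
  if (any(median_onset < 0) || any(median_mri_age < 0)) {
    abort_field("median", "age locations must be non-negative")
  }
  n <- n_positive + n_negative
  labels <- c(rep(1, n_positive), rep(-1, n_negative))
  cls <- ifelse(labels == 1, "pos", "neg")

  runif_discrete <- function(center, spread, lo = 0) {
    lo_v <- pmax(round(center - spread), lo)
    hi_v <- pmax(round(center + spread), lo_v)
    lo_v + floor(stats::runif(length(center)) * (hi_v - lo_v + 1))
  }

  with_seed(seed, {
    onset <- runif_discrete(median_onset[cls], onset_spread)
    mri <- pmax(runif_discrete(median_mri_age[cls], mri_spread), onset)
    surgery <- mri + stats::rbinom(n, 1, surgery_delay_prob)
    febrile <- stats::rbinom(n, 1, febrile_prob[cls])
    freq <- pmax(1, round(stats::rlnorm(n, freq_meanlog, freq_sdlog)))
    fu <- pmax(12, runif_discrete(rep(followup_median, n), followup_spread))
    data.frame(
      id = sprintf("S%02d", seq_len(n)), label = labels,
      age_at_onset = as.numeric(onset), age_at_mri = as.numeric(mri),
      age_at_surgery = as.numeric(surgery), febrile = febrile,
      seizure_freq_per_month = as.numeric(freq),
      followup_months = as.numeric(fu),
      stringsAsFactors = FALSE)
  })
}
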