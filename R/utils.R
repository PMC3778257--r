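# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_labels <- function(y) {
  if (!all(y %in% c(-1, 1))) {
    abort_field("y", "labels must be +1 or -1")
  }
  if (length(unique(y)) < 2L) {
    stop("both classes (+1 and -1) must be present", call. = FALSE)
  }
  invisible(as.numeric(y))
}

# FWHM (mm) -> Gaussian sigma in voxel units, per axis.
fwhm_to_sigma <- function(fwhm_mm, voxel_size_mm) {
  fwhm_mm / voxel_size_mm / (2 * sqrt(2 * log(2)))
}
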