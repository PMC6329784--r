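#' Ellipsoid brain-like mask
#'
#' @param dims Grid dimensions (3 positive integers).
#' @param center Ellipsoid centre in voxel coordinates; defaults to the grid
#'   centre.
#' @param semiaxes Semi-axes in voxels; default \code{dims / 2 - 1}.
#' @return Logical 3-D array.
#' @export
ellipsoid_mask <- function(dims, center = NULL, semiaxes = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 3L))
  center <- center %||% ((dims + 1) / 2)
  semiaxes <- semiaxes %||% (dims / 2 - 1)
  x <- (seq_len(dims[1]) - center[1]) / semiaxes[1]
  y <- (seq_len(dims[2]) - center[2]) / semiaxes[2]
  z <- (seq_len(dims[3]) - center[3]) / semiaxes[3]
  r2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  array(r2 <= 1, dims)
}

#' Voxel coordinates of an axis-aligned cube
#'
#' @param center Cube centre (3-vector, voxel coordinates).
#' @param width Cube edge length in voxels.
#' @return Integer matrix with columns x, y, z.
#' @export
cube_roi <- function(center, width) {
  half_lo <- floor((width - 1) / 2)
  half_hi <- width - 1 - half_lo
  rng <- lapply(1:3, function(a) (center[a] - half_lo):(center[a] + half_hi))
  as.matrix(expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]]))
}

#' Region-of-interest specification
#'
#' Declares a set of voxels carrying class-dependent signal, how the region
#' responds across modalities, and the strength of its multivoxel pattern and
#' univariate intensity effects.
#'
#' @param id Unique region identifier.
#' @param voxels Integer matrix of voxel coordinates (columns x, y, z).
#' @param responsiveness One of \code{"tactile_only"}, \code{"visual_only"},
#'   \code{"shared"} (one class-to-pattern map reused by both modalities) or
#'   \code{"independent"} (two unrelated maps, one per modality).
#' @param pattern_amp Standard deviation of the multivoxel pattern component
#'   (signal units).
#' @param intensity_gain Slope of the common (univariate) activation over the
#'   class index.
#' @return A list of class \code{"roi_spec"}.
#' @export
roi_spec <- function(id, voxels,
                     responsiveness = c("shared", "tactile_only",
                                        "visual_only", "independent"),
                     pattern_amp = 1, intensity_gain = 0.5) {
  responsiveness <- match.arg(responsiveness)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            pattern_amp >= 0, is.finite(intensity_gain))
  voxels <- matrix(as.integer(as.matrix(voxels)), ncol = 3L)
  structure(list(id = id, voxels = voxels, responsiveness = responsiveness,
                 pattern_amp = pattern_amp, intensity_gain = intensity_gain),
            class = "roi_spec")
}

#' Phantom specification
#'
#' The full description of a synthetic subject's "brain": grid, mask, signal
#' regions, and noise model. ROI voxels are clipped to the mask (an ROI that
#' loses all its voxels is an error); ids must be unique. The seed fixes the
#' subject's class-to-pattern maps, which are drawn once and reused across
#' runs, so that information is spatially consistent within a subject.
#'
#' @param grid_shape Grid dimensions; default \code{c(24, 24, 24)}.
#' @param mask Logical array over the grid; default an ellipsoid with
#'   semi-axes 11.
#' @param rois List of [roi_spec()] objects.
#' @param noise_sd Marginal standard deviation of the AR(1) scanner noise
#'   (signal units).
#' @param drift_amp Amplitude of the slow cosine drift.
#' @param ar1_rho Lag-1 autocorrelation of the noise, in \code{[0, 1)}.
#' @param drift_period Drift period (s); longer than the 128 s high-pass
#'   cutoff so the drift model in the GLM can absorb it.
#' @param seed Integer seed for the subject's pattern maps.
#' @return A list of class \code{"phantom_spec"}.
#' @export
phantom_spec <- function(grid_shape = c(24, 24, 24), mask = NULL,
                         rois = list(), noise_sd = 14, drift_amp = 1,
                         ar1_rho = 0.3, drift_period = 310, seed = 1) {
  grid_shape <- as.integer(grid_shape)
  mask <- mask %||% ellipsoid_mask(grid_shape, semiaxes = rep(11, 3) *
                                     grid_shape / 24)
  stopifnot(identical(dim(mask), grid_shape), is.logical(mask),
            noise_sd >= 0, drift_amp >= 0,
            ar1_rho >= 0, ar1_rho < 1, drift_period > 0)
  ids <- vapply(rois, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("ROI ids must be unique")
  mask_idx <- which(mask)
  rois <- lapply(rois, function(r) {
    idx <- coords_to_index(r$voxels, grid_shape)
    keep <- idx %in% mask_idx
    if (!any(keep)) stop("ROI '", r$id, "' has no voxels inside the mask")
    r$voxels <- r$voxels[keep, , drop = FALSE]
    r
  })
  structure(list(grid_shape = grid_shape, mask = mask, rois = rois,
                 noise_sd = noise_sd, drift_amp = drift_amp,
                 ar1_rho = ar1_rho, drift_period = drift_period, seed = seed),
            class = "phantom_spec")
}

#' Four-region recovery phantom
#'
#' The reference phantom for recovery simulations: four width-7 cube ROIs on
#' a 24^3 grid, one per responsiveness type (tactile-only, visual-only,
#' shared, independent), placed inside the ellipsoid mask. Cube corners
#' falling outside the mask are clipped (319 of 343 voxels survive per
#' region). Placement keeps every pair of regions that can be detected by the
#' same searchlight scheme at Chebyshev distance 11 (a 4-voxel gap), so that
#' one region's cluster plus its one-voxel searchlight spill cannot touch
#' another's; only the tactile-only and visual-only regions, which no scheme
#' co-detects, share a smaller separation budget.
#'
#' The independent region gets \code{intensity_gain = 0}: a univariate
#' activation ramp over intensity is identical in both modalities and would
#' itself constitute a cross-modally shared code, confounding the
#' multivoxel-pattern dissociation this phantom exists to probe.
#'
#' @param seed Subject pattern seed.
#' @param pattern_amp,intensity_gain,noise_sd,... Passed through to
#'   [roi_spec()] / [phantom_spec()].
#' @return A \code{"phantom_spec"}.
#' @export
demo_phantom <- function(seed = 1, pattern_amp = 1, intensity_gain = 0.5,
                         noise_sd = 14, ...) {
  mk <- function(id, center, resp, gain = intensity_gain) {
    roi_spec(id, cube_roi(center, 7), resp,
             pattern_amp = pattern_amp, intensity_gain = gain)
  }
  rois <- list(
    mk("tactile_only", c(7, 12, 7), "tactile_only"),
    mk("visual_only", c(18, 12, 7), "visual_only"),
    mk("shared", c(7, 12, 18), "shared"),
    mk("independent", c(18, 12, 18), "independent", gain = 0)
  )
  phantom_spec(rois = rois, noise_sd = noise_sd, seed = seed, ...)
}

## Draw the class-to-pattern maps of every ROI, deterministically from the
## phantom seed. Returns, per ROI, a list with elements `tactile` and
## `visual`, each a 5 x n_vox matrix of pattern values (NULL when the ROI is
## silent in that modality). Shared ROIs reuse one map for both modalities.
phantom_patterns <- function(phantom) {
  with_seed(phantom$seed, {
    lapply(phantom$rois, function(r) {
      nv <- nrow(r$voxels)
      draw <- function() matrix(stats::rnorm(5 * nv), 5, nv)
      switch(r$responsiveness,
        shared = { p <- draw(); list(tactile = p, visual = p) },
        independent = list(tactile = draw(), visual = draw()),
        tactile_only = list(tactile = draw(), visual = NULL),
        visual_only = list(tactile = NULL, visual = draw())
      )
    })
  })
}

#' Simulate BOLD volume series for a session
#'
#' Forward model of the scanner data: every voxel's time course is the sum of
#' per-trial responses (box-car convolved with the canonical HRF, scaled by
#' the voxel's amplitude for the trial's condition and modality), a slow
#' cosine drift with random per-voxel phase, and AR(1) Gaussian noise. Inside
#' an ROI the amplitude is
#' \code{intensity_gain * condition + pattern_amp * pattern(condition, voxel)};
#' outside all ROIs it is zero. Pattern maps are fixed per subject (drawn from
#' the phantom seed) so that information is consistent across runs.
#'
#' @param phantom [phantom_spec()].
#' @param trials Trial table (all runs); one volume series is produced per run.
#' @param tr Repetition time (s).
#' @param hrf [hrf_params()].
#' @param n_scans Volumes per run; default covers the longest trial window
#'   (\code{ceiling(310 / tr)} under default timing).
#' @param seed Seed for noise and drift phases (distinct from the phantom's
#'   pattern seed).
#' @return A list of \code{"volume_series"} objects, one per run, each with
#'   \code{data} (scans x in-mask voxels), \code{mask}, \code{tr}, \code{run},
#'   \code{modality} and the run's \code{trials}.
#' @export
simulate_bold <- function(phantom, trials, tr = 1.52, hrf = hrf_params(),
                          n_scans = NULL, seed = NULL) {
  stopifnot(inherits(phantom, "phantom_spec"), tr > 0)
  run_length <- attr(trials, "run_length") %||%
    max(trials$onset + trials$duration)
  n_scans <- n_scans %||% ceiling(run_length / tr)
  mask_idx <- which(phantom$mask)
  V <- length(mask_idx)
  slot <- integer(prod(phantom$grid_shape))
  slot[mask_idx] <- seq_len(V)
  patterns <- phantom_patterns(phantom)
  runs <- sort(unique(trials$run))

  with_seed(seed, {
    lapply(runs, function(r) {
      tt <- trials[trials$run == r, , drop = FALSE]
      mod <- tt$modality[1]
      reg <- trial_regressors(tt$onset, tt$duration, n_scans, tr, hrf)
      amp <- matrix(0, nrow(tt), V)
      for (k in seq_along(phantom$rois)) {
        roi <- phantom$rois[[k]]
        pat <- patterns[[k]][[mod]]
        if (is.null(pat)) next
        cols <- slot[coords_to_index(roi$voxels, phantom$grid_shape)]
        amp[, cols] <- roi$intensity_gain * tt$condition +
          roi$pattern_amp * pat[tt$condition, , drop = FALSE]
      }
      signal <- reg %*% amp
      t_sec <- (seq_len(n_scans) - 1) * tr
      if (phantom$drift_amp > 0) {
        phase <- stats::runif(V, 0, 2 * pi)
        drift <- phantom$drift_amp *
          cos(outer(2 * pi * t_sec / phantom$drift_period, phase, `+`))
        signal <- signal + drift
      }
      if (phantom$noise_sd > 0) {
        e <- matrix(stats::rnorm(n_scans * V), n_scans, V)
        if (phantom$ar1_rho > 0) {
          # stationary AR(1): first innovation keeps the marginal sd
          e[-1, ] <- e[-1, , drop = FALSE] * sqrt(1 - phantom$ar1_rho^2)
          e <- apply(e, 2, function(col) {
            as.numeric(stats::filter(col, phantom$ar1_rho,
                                     method = "recursive"))
          })
        }
        signal <- signal + phantom$noise_sd * e
      }
      structure(list(data = signal, mask = phantom$mask, tr = tr, run = r,
                     modality = mod, trials = tt, n_scans = n_scans),
                class = "volume_series")
    })
  })
}
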