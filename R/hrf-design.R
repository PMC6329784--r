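#' Canonical double-gamma HRF parameters
#'
#' The canonical haemodynamic response is modelled as a difference of two
#' gamma densities: a positive peak followed by a smaller undershoot. The
#' defaults are the widely used canonical settings (peak at 6 s, undershoot
#' at 16 s, unit dispersions, peak:undershoot ratio 6, 32 s support).
#'
#' @param peak_delay Delay of the response peak (s).
#' @param undershoot_delay Delay of the undershoot (s).
#' @param peak_dispersion Dispersion of the peak gamma (s).
#' @param undershoot_dispersion Dispersion of the undershoot gamma (s).
#' @param peak_undershoot_ratio Ratio of peak to undershoot amplitude.
#' @param kernel_length Kernel support (s); the kernel is truncated here.
#' @return A list of class \code{"hrf_params"}.
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_dispersion = 1, undershoot_dispersion = 1,
                       peak_undershoot_ratio = 6, kernel_length = 32) {
  p <- list(
    peak_delay = peak_delay, undershoot_delay = undershoot_delay,
    peak_dispersion = peak_dispersion,
    undershoot_dispersion = undershoot_dispersion,
    peak_undershoot_ratio = peak_undershoot_ratio,
    kernel_length = kernel_length
  )
  if (any(unlist(p) <= 0)) stop("all HRF parameters must be positive")
  structure(p, class = "hrf_params")
}

#' Sample the canonical HRF
#'
#' Evaluates the double-gamma kernel on a regular time grid and scales it to
#' unit peak. Unit-peak scaling makes the fitted regression coefficients
#' carry the same units as the simulated response amplitudes, so forward
#' simulation and GLM estimation are exact inverses in the noiseless case.
#'
#' @param params [hrf_params()] list.
#' @param tr Repetition time (s); only used for the default grid spacing.
#' @param dt Sampling step of the returned kernel (s); defaults to
#'   \code{tr / 16}.
#' @return List with \code{kernel} (numeric vector, first sample at t = 0),
#'   \code{dt} and \code{time}.
#' @examples
#' h <- canonical_hrf(hrf_params(), tr = 1.52)
#' max(h$kernel)  # 1 by construction
#' @export
canonical_hrf <- function(params = hrf_params(), tr, dt = NULL) {
  stopifnot(inherits(params, "hrf_params"), tr > 0)
  dt <- dt %||% (tr / 16)
  t <- seq(0, params$kernel_length, by = dt)
  k <- stats::dgamma(t, shape = params$peak_delay / params$peak_dispersion,
                     scale = params$peak_dispersion) -
    stats::dgamma(t, shape = params$undershoot_delay / params$undershoot_dispersion,
                  scale = params$undershoot_dispersion) /
      params$peak_undershoot_ratio
  k <- k / max(k)
  list(kernel = k, dt = dt, time = t)
}

## Box-car stimulus time courses convolved with the canonical HRF, sampled at
## volume acquisition times (t = 0, tr, 2 tr, ...). Shared by the forward
## simulator and the GLM design builder so that the two use bit-identical
## regressors. Returns an n_scans x n_trials matrix.
trial_regressors <- function(onsets, durations, n_scans, tr,
                             hrf = hrf_params(), dt = NULL) {
  stopifnot(tr > 0, n_scans >= 1, length(onsets) == length(durations))
  h <- canonical_hrf(hrf, tr, dt)
  dt <- h$dt
  run_len <- n_scans * tr
  if (any(onsets < 0) || any(onsets + durations > run_len + 1e-9)) {
    stop("trial window extends past the end of the run")
  }
  n_fine <- ceiling(run_len / dt) + length(h$kernel)
  nk <- length(h$kernel)
  scan_idx <- pmin(round((seq_len(n_scans) - 1L) * tr / dt) + 1L, n_fine)
  out <- matrix(0, n_scans, length(onsets))
  for (j in seq_along(onsets)) {
    stim <- numeric(n_fine)
    i0 <- floor(onsets[j] / dt) + 1L
    i1 <- min(n_fine, ceiling((onsets[j] + durations[j]) / dt))
    stim[i0:i1] <- 1
    padded <- c(rep(0, nk - 1L), stim)
    conv <- stats::filter(padded, h$kernel, method = "convolution", sides = 1)
    conv <- as.numeric(conv)[nk:(nk + n_fine - 1L)] * dt
    out[, j] <- conv[scan_idx]
  }
  out
}

#' Discrete-cosine drift basis
#'
#' High-pass filtering is implemented by including low-frequency discrete
#' cosine regressors in the design: all cosines with period longer than the
#' cutoff. For a run of duration \eqn{T} and cutoff \eqn{c} this yields
#' \eqn{\lfloor 2T/c \rfloor} cosine columns (none when the cutoff is
#' infinite). Columns are mutually orthogonal.
#'
#' @param n_scans Number of volumes.
#' @param tr Repetition time (s).
#' @param cutoff High-pass cutoff period (s); default 128.
#' @return An \code{n_scans x k} matrix (possibly zero columns).
#' @export
dct_basis <- function(n_scans, tr, cutoff = 128) {
  stopifnot(n_scans >= 1, tr > 0, cutoff > 0)
  n_basis <- if (is.finite(cutoff)) floor(2 * n_scans * tr / cutoff) else 0
  if (n_basis < 1) return(matrix(0, n_scans, 0))
  s <- seq_len(n_scans) - 1L
  vapply(seq_len(n_basis),
         function(r) cos(pi * r * (2 * s + 1) / (2 * n_scans)),
         numeric(n_scans))
}

#' Build a trial-wise design matrix for one run
#'
#' One regressor per trial (the classifier's examples), each a 3 s box-car at
#' the trial's stimulation onset convolved with the canonical HRF, plus the
#' discrete-cosine drift basis below the high-pass cutoff and a constant.
#' All trials are modelled simultaneously in a single design
#' (least-squares-all).
#'
#' @param trials Trial table rows belonging to one run.
#' @param n_scans Number of volumes in the run.
#' @param tr Repetition time (s).
#' @param hrf [hrf_params()].
#' @param hp_cutoff High-pass cutoff (s), default 128; \code{Inf} disables
#'   drift columns.
#' @return A list of class \code{"design_matrix"} with elements \code{X}
#'   (scans x regressors), \code{labels} (data frame describing each column),
#'   \code{task_cols} (indices of the trial regressors) and \code{tr}.
#' @export
build_trial_design <- function(trials, n_scans, tr, hrf = hrf_params(),
                               hp_cutoff = 128) {
  stopifnot(nrow(trials) >= 1, length(unique(trials$run)) == 1L)
  if (anyDuplicated(trials$onset)) {
    warning("overlapping identical trial regressors: duplicated onsets")
  }
  task <- trial_regressors(trials$onset, trials$duration, n_scans, tr, hrf)
  drift <- dct_basis(n_scans, tr, hp_cutoff)
  X <- cbind(task, drift, 1)
  labels <- data.frame(
    column = c(sprintf("trial_%03d", seq_len(nrow(trials))),
               if (ncol(drift)) sprintf("drift_%02d", seq_len(ncol(drift))),
               "constant"),
    type = c(rep("task", nrow(trials)),
             rep("drift", ncol(drift)), "constant"),
    condition = c(trials$condition, rep(NA_integer_, ncol(drift) + 1L)),
    run = c(trials$run, rep(NA_integer_, ncol(drift) + 1L)),
    modality = c(trials$modality, rep(NA_character_, ncol(drift) + 1L)),
    block = c(trials$block, rep(NA_integer_, ncol(drift) + 1L)),
    stringsAsFactors = FALSE
  )
  colnames(X) <- labels$column
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  structure(list(X = X, labels = labels, task_cols = seq_len(nrow(trials)),
                 tr = tr), class = "design_matrix")
}

#' Build a condition-wise design matrix for one run
#'
#' One regressor per roughness intensity: the box-cars of all trials of that
#' condition in the run, convolved with the HRF. Used by the confirmatory
#' condition-versus-rest contrasts.
#'
#' @inheritParams build_trial_design
#' @return A \code{"design_matrix"} whose task columns are the five
#'   conditions (in intensity order).
#' @export
build_condition_design <- function(trials, n_scans, tr, hrf = hrf_params(),
                                   hp_cutoff = 128) {
  stopifnot(nrow(trials) >= 1, length(unique(trials$run)) == 1L)
  conds <- sort(unique(trials$condition))
  reg <- trial_regressors(trials$onset, trials$duration, n_scans, tr, hrf)
  task <- vapply(conds, function(cc) {
    rowSums(reg[, trials$condition == cc, drop = FALSE])
  }, numeric(n_scans))
  drift <- dct_basis(n_scans, tr, hp_cutoff)
  X <- cbind(task, drift, 1)
  labels <- data.frame(
    column = c(sprintf("cond_%d", conds),
               if (ncol(drift)) sprintf("drift_%02d", seq_len(ncol(drift))),
               "constant"),
    type = c(rep("task", length(conds)), rep("drift", ncol(drift)), "constant"),
    condition = c(conds, rep(NA_integer_, ncol(drift) + 1L)),
    stringsAsFactors = FALSE
  )
  colnames(X) <- labels$column
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  structure(list(X = X, labels = labels, task_cols = seq_along(conds),
                 tr = tr), class = "design_matrix")
}
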