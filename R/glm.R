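#' Estimate a trial-wise beta series by OLS
#'
#' Fits the design to every in-mask voxel time course by ordinary least
#' squares and returns the coefficients of the task (trial) regressors only;
#' drift and constant columns are estimated jointly but discarded. A
#' rank-deficient design falls back to the Moore-Penrose pseudoinverse with a
#' warning.
#'
#' @param vol A \code{"volume_series"} (one run) from [simulate_bold()] or
#'   assembled from data.
#' @param design A \code{"design_matrix"} for the same run.
#' @return A list of class \code{"beta_series"}: \code{betas} (trials x
#'   voxels), \code{labels} (condition/run/modality/block per trial),
#'   \code{mask}.
#' @export
fit_betas <- function(vol, design) {
  stopifnot(inherits(design, "design_matrix"))
  Y <- vol$data
  X <- design$X
  if (nrow(Y) != nrow(X)) stop("design and volume series disagree on scans")
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    warning("singular normal equations; using pseudoinverse")
    coef <- MASS::ginv(X) %*% Y
  } else {
    coef <- qr.coef(qr_x, Y)
  }
  task <- design$task_cols
  lab <- design$labels[task, c("condition", "run", "modality", "block")]
  rownames(lab) <- NULL
  structure(list(betas = coef[task, , drop = FALSE], labels = lab,
                 mask = vol$mask),
            class = "beta_series")
}

#' Combine beta series across runs
#'
#' Stacks per-run trial-wise beta series (same mask) into a single
#' trials x voxels matrix with concatenated labels, the input expected by the
#' searchlight cross-validation routines.
#'
#' @param ... \code{"beta_series"} objects, or a single list of them.
#' @return A \code{"beta_series"}.
#' @export
bind_betas <- function(...) {
  args <- list(...)
  if (length(args) == 1L && !inherits(args[[1]], "beta_series")) {
    args <- args[[1]]
  }
  stopifnot(all(vapply(args, inherits, logical(1), "beta_series")))
  structure(list(
    betas = do.call(rbind, lapply(args, `[[`, "betas")),
    labels = do.call(rbind, lapply(args, `[[`, "labels")),
    mask = args[[1]]$mask
  ), class = "beta_series")
}

#' Fit a whole session end to end
#'
#' Convenience wrapper: given a phantom and a trial table, simulates all runs,
#' fits the trial-wise GLM run by run, and returns the stacked beta series
#' split by modality.
#'
#' @inheritParams simulate_bold
#' @param hp_cutoff High-pass cutoff (s).
#' @return A list with elements \code{tactile} and \code{visual} (each a
#'   \code{"beta_series"}, or NULL when that modality is absent) and
#'   \code{all}.
#' @export
simulate_subject_betas <- function(phantom, trials, tr = 1.52,
                                   hrf = hrf_params(), hp_cutoff = 128,
                                   n_scans = NULL, seed = NULL) {
  vols <- simulate_bold(phantom, trials, tr, hrf, n_scans, seed)
  per_run <- lapply(vols, function(v) {
    des <- build_trial_design(v$trials, v$n_scans, v$tr, hrf, hp_cutoff)
    fit_betas(v, des)
  })
  all <- bind_betas(per_run)
  pick <- function(mod) {
    sel <- all$labels$modality == mod
    if (!any(sel)) return(NULL)
    structure(list(betas = all$betas[sel, , drop = FALSE],
                   labels = all$labels[sel, , drop = FALSE],
                   mask = all$mask), class = "beta_series")
  }
  list(tactile = pick("tactile"), visual = pick("visual"), all = all)
}

#' Condition-versus-rest t statistics for one subject
#'
#' Fits a condition-wise GLM (one regressor per roughness intensity, box-car
#' convolved with the HRF, plus per-run drift and constant columns) across
#' all runs of one modality in a single stacked design, and returns
#' per-condition contrast estimates and t statistics against rest.
#'
#' @param vols List of \code{"volume_series"} (the runs to model).
#' @param tr Repetition time (s).
#' @param hrf [hrf_params()].
#' @param hp_cutoff High-pass cutoff (s).
#' @return List with \code{beta} (5 x voxels contrast estimates), \code{t}
#'   (5 x voxels), \code{df} (scans minus design rank), \code{mask}.
#' @export
condition_vs_rest_tstats <- function(vols, tr = 1.52, hrf = hrf_params(),
                                     hp_cutoff = 128) {
  stopifnot(length(vols) >= 1)
  designs <- lapply(vols, function(v) {
    build_condition_design(v$trials, v$n_scans, v$tr, hrf, hp_cutoff)
  })
  conds <- designs[[1]]$labels$condition[designs[[1]]$task_cols]
  n_task <- length(conds)
  # stacked design: shared condition columns, per-run nuisance blocks
  nuis_cols <- vapply(designs, function(d) ncol(d$X) - n_task, integer(1))
  total_rows <- sum(vapply(vols, function(v) nrow(v$data), integer(1)))
  X <- matrix(0, total_rows, n_task + sum(nuis_cols))
  Y <- do.call(rbind, lapply(vols, `[[`, "data"))
  row0 <- 0L; col0 <- n_task
  for (i in seq_along(vols)) {
    d <- designs[[i]]
    nr <- nrow(d$X)
    X[row0 + seq_len(nr), seq_len(n_task)] <- d$X[, d$task_cols, drop = FALSE]
    nn <- nuis_cols[i]
    X[row0 + seq_len(nr), col0 + seq_len(nn)] <-
      d$X[, -d$task_cols, drop = FALSE]
    row0 <- row0 + nr; col0 <- col0 + nn
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stop("stacked design is rank deficient")
  coef <- qr.coef(qr_x, Y)
  res <- Y - X %*% coef
  df <- nrow(X) - qr_x$rank
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(chol(crossprod(X)))
  beta <- coef[seq_len(n_task), , drop = FALSE]
  se <- sqrt(outer(diag(xtx_inv)[seq_len(n_task)], sigma2))
  tmat <- beta / se
  list(beta = beta, t = tmat, df = df, mask = vols[[1]]$mask,
       conditions = conds)
}

#' Conjunction of thresholded activation maps
#'
#' A voxel belongs to the conjunction iff it is suprathreshold in every map.
#' Connected components of the conjunction are reported with their sizes.
#'
#' @param maps List of logical 3-D arrays (already thresholded), all on the
#'   same grid.
#' @param connectivity Component connectivity (6, 18 or 26; default 18).
#' @return List with \code{mask} (logical array) and \code{components}
#'   (data frame of component id and voxel count, largest first).
#' @export
conjunction_mask <- function(maps, connectivity = 18) {
  stopifnot(length(maps) >= 1)
  dims <- dim(maps[[1]])
  if (!all(vapply(maps, function(m) identical(dim(m), dims), logical(1)))) {
    stop("maps are not on the same grid")
  }
  conj <- Reduce(`&`, maps)
  comp <- label_components(which(conj), dims, connectivity)
  sizes <- if (length(comp)) {
    data.frame(component = seq_along(comp),
               size = vapply(comp, length, integer(1)))
  } else {
    data.frame(component = integer(0), size = integer(0))
  }
  sizes <- sizes[order(-sizes$size), , drop = FALSE]
  rownames(sizes) <- NULL
  list(mask = conj, components = sizes)
}
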