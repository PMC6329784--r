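#' Searchlight specification
#'
#' A cube searchlight of half-width \code{cube_half_width} (1 gives the
#' 3 x 3 x 3 cube, up to 27 voxels) slides over every in-mask voxel; the
#' neighborhood is clipped to the mask, and centers whose clipped
#' neighborhood holds fewer than \code{min_voxels} voxels are skipped and
#' recorded.
#'
#' @param mask Logical 3-D array.
#' @param cube_half_width Chebyshev radius of the cube (default 1).
#' @param min_voxels Minimum neighborhood size for a center to be analysed.
#' @return A list of class \code{"searchlight_spec"}.
#' @export
searchlight_spec <- function(mask, cube_half_width = 1, min_voxels = 10) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L,
            cube_half_width >= 1, min_voxels >= 1)
  structure(list(mask = mask, cube_half_width = as.integer(cube_half_width),
                 min_voxels = as.integer(min_voxels)),
            class = "searchlight_spec")
}

#' Neighborhood of one searchlight center
#'
#' All in-mask voxels within Chebyshev distance \code{cube_half_width} of the
#' center (the center itself included).
#'
#' @param center Voxel coordinate (3-vector); must be inside the mask.
#' @param spec [searchlight_spec()].
#' @return Integer matrix of neighbor coordinates (columns x, y, z).
#' @export
cube_neighborhood <- function(center, spec) {
  dims <- dim(spec$mask)
  center <- as.integer(center)
  if (!spec$mask[center[1], center[2], center[3]]) {
    stop("center voxel is outside the mask")
  }
  hw <- spec$cube_half_width
  rng <- lapply(1:3, function(a) {
    max(1L, center[a] - hw):min(dims[a], center[a] + hw)
  })
  g <- as.matrix(expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]]))
  g[spec$mask[g], , drop = FALSE]
}

## Sparse voxel-by-center incidence matrix of all searchlight neighborhoods.
## Column j holds the in-mask neighbors of the j-th in-mask voxel taken as
## center. Returns the matrix, the linear grid index of every center, and
## which centers pass the min_voxels rule.
build_neighborhoods <- function(spec) {
  dims <- dim(spec$mask)
  mask_idx <- which(spec$mask)
  V <- length(mask_idx)
  slot <- integer(prod(dims))
  slot[mask_idx] <- seq_len(V)
  coords <- index_to_coords(mask_idx, dims)
  hw <- spec$cube_half_width
  offs <- as.matrix(expand.grid(dx = -hw:hw, dy = -hw:hw, dz = -hw:hw))
  ii <- jj <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    nc <- sweep(coords, 2, offs[k, ], `+`)
    ok <- nc[, 1] >= 1 & nc[, 1] <= dims[1] &
      nc[, 2] >= 1 & nc[, 2] <= dims[2] &
      nc[, 3] >= 1 & nc[, 3] <= dims[3]
    lin <- coords_to_index(nc[ok, , drop = FALSE], dims)
    s <- slot[lin]
    keep <- s > 0L
    jj[[k]] <- which(ok)[keep]   # center slot
    ii[[k]] <- s[keep]           # neighbor slot
  }
  nbr <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = 1,
                              dims = c(V, V))
  size <- Matrix::colSums(nbr)
  list(nbr = nbr, centers = mask_idx, size = size,
       valid = size >= spec$min_voxels)
}

#' Fit a pooled-variance Gaussian Naive Bayes model
#'
#' Class-conditional Gaussian densities with independent features: the model
#' keeps per-feature class means and a single pooled within-class variance
#' per feature shared across classes (stabler than per-class variances at the
#' small example counts of run-wise folds). Variances are floored at
#' \code{var_floor_frac} times the mean pooled variance. Priors are the
#' training class frequencies (uniform for balanced designs).
#'
#' @param x Examples x features matrix.
#' @param y Integer class labels (1--5); every class needs at least 2
#'   examples.
#' @param var_floor_frac Relative variance floor (default 1e-12).
#' @return A list of class \code{"gnb_model"}: \code{class_means}
#'   (classes x features), \code{pooled_var}, \code{class_priors},
#'   \code{classes}.
#' @export
gnb_fit <- function(x, y, var_floor_frac = 1e-12) {
  x <- as.matrix(x)
  y <- as.integer(y)
  classes <- sort(unique(y))
  counts <- tabulate(match(y, classes))
  if (any(counts < 2)) stop("every class needs at least 2 training examples")
  n <- nrow(x)
  means <- rowsum(x, y) / counts
  ss <- colSums(x^2) - colSums(counts * means^2)
  pooled <- ss / (n - length(classes))
  floor_val <- var_floor_frac * max(mean(pooled), .Machine$double.xmin)
  pooled <- pmax(pooled, floor_val)
  structure(list(class_means = means, pooled_var = pooled,
                 class_priors = counts / n, classes = classes),
            class = "gnb_model")
}

#' Predict with a Gaussian Naive Bayes model
#'
#' Sums per-feature Gaussian log-likelihoods and the log prior; the predicted
#' class is the argmax, with ties broken toward the lowest class index.
#'
#' @param model A \code{"gnb_model"}.
#' @param x Examples x features matrix (same feature count as the model).
#' @return List with \code{labels} (predicted classes) and \code{log_posterior}
#'   (examples x classes, normalized so each row's exponentials sum to 1).
#' @export
gnb_predict <- function(model, x) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite values in prediction input")
  if (ncol(x) != ncol(model$class_means)) {
    stop("feature count does not match the model")
  }
  v <- model$pooled_var
  const <- -0.5 * sum(log(2 * pi * v))
  ll <- vapply(seq_along(model$classes), function(ci) {
    dev <- sweep(x, 2, model$class_means[ci, ], `-`)
    const - rowSums(sweep(dev^2, 2, 2 * v, `/`)) +
      log(model$class_priors[ci])
  }, numeric(nrow(x)))
  ll <- matrix(ll, nrow = nrow(x))
  norm <- apply(ll, 1, function(r) {
    m <- max(r); m + log(sum(exp(r - m)))
  })
  list(labels = model$classes[max.col(ll, ties.method = "first")],
       log_posterior = ll - norm)
}

## Vectorized searchlight GNB: fits sufficient statistics for every voxel at
## once, sums per-voxel log-likelihood terms over each neighborhood by one
## sparse matrix product per class, and returns the predicted label of every
## (test example, center) pair. Equivalent to running gnb_fit/gnb_predict per
## searchlight, but hundreds of times faster.
gnb_searchlight_predict <- function(train_x, train_y, test_x, nbr,
                                    var_floor_frac = 1e-12) {
  classes <- 1:5
  counts <- tabulate(train_y, 5L)
  if (any(counts < 2)) stop("a class is missing from a training fold")
  n <- nrow(train_x)
  means <- rowsum(train_x, factor(train_y, classes)) / counts
  ss <- colSums(train_x^2) - colSums(counts * means^2)
  pooled <- ss / (n - 5)
  floor_val <- var_floor_frac * max(mean(pooled), .Machine$double.xmin)
  pooled <- pmax(pooled, floor_val)
  const <- -0.5 * log(2 * pi * pooled)
  log_prior <- log(counts / n)
  n_test <- nrow(test_x)
  V <- ncol(test_x)
  scores <- matrix(0, n_test * V, 5)
  for (ci in classes) {
    dev2 <- sweep(test_x, 2, means[ci, ], `-`)^2
    L <- sweep(-dev2, 2, 2 * pooled, `/`)
    L <- sweep(L, 2, const, `+`)
    scores[, ci] <- as.numeric(as.matrix(L %*% nbr)) + log_prior[ci]
  }
  matrix(max.col(scores, ties.method = "first"), n_test, V)
}

## Accumulate per-center confusion counts from a prediction matrix.
accumulate_confusion <- function(conf, pred, truth) {
  for (ct in 1:5) {
    rows <- which(truth == ct)
    if (!length(rows)) next
    for (cp in 1:5) {
      conf[ct, cp, ] <- conf[ct, cp, ] +
        colSums(pred[rows, , drop = FALSE] == cp)
    }
  }
  conf
}

finalize_searchlight <- function(conf, n_test, valid, centers, mask, chance,
                                 scheme, extra = list()) {
  correct <- vapply(1:5, function(c) conf[c, c, ], numeric(dim(conf)[3]))
  acc <- rowSums(matrix(correct, ncol = 5)) / n_test
  acc[!valid] <- NA_real_
  structure(c(list(acc_raw = acc, acc = acc - chance, chance = chance,
                   scheme = scheme, confusion_counts = conf,
                   centers = centers, valid = valid, mask = mask,
                   n_test = n_test), extra),
            class = "searchlight_result")
}

#' Run-wise cross-validated searchlight decoding
#'
#' For every searchlight center, a 5-class pooled-variance Gaussian Naive
#' Bayes classifier is trained on all runs but one and tested on the held-out
#' run, cycling over runs (leave-one-run-out; 3-fold for the default three
#' runs per modality). The accuracy over all folds is stored at the center
#' voxel and chance level (0.2) is subtracted; per-center confusion counts
#' are accumulated over folds.
#'
#' @param betas A \code{"beta_series"} for one modality (trial-wise examples).
#' @param spec [searchlight_spec()]; defaults to a 3 x 3 x 3 cube over the
#'   beta-series mask.
#' @param scheme Label stored with the result (defaults to the modality).
#' @return A \code{"searchlight_result"}: \code{acc_raw} and chance-subtracted
#'   \code{acc} (vectors over in-mask voxels, NA at skipped centers),
#'   \code{confusion_counts} (5 x 5 x voxels), \code{chance}, \code{valid},
#'   \code{centers}, \code{mask}.
#' @export
runwise_cv <- function(betas, spec = NULL, scheme = NULL) {
  stopifnot(inherits(betas, "beta_series"))
  spec <- spec %||% searchlight_spec(betas$mask)
  runs <- sort(unique(betas$labels$run))
  if (length(runs) < 2) stop("run-wise cross-validation needs at least 2 runs")
  nb <- build_neighborhoods(spec)
  V <- length(nb$centers)
  conf <- array(0, c(5, 5, V))
  n_test <- 0L
  for (r in runs) {
    test_sel <- betas$labels$run == r
    pred <- gnb_searchlight_predict(
      betas$betas[!test_sel, , drop = FALSE],
      betas$labels$condition[!test_sel],
      betas$betas[test_sel, , drop = FALSE], nb$nbr
    )
    conf <- accumulate_confusion(conf, pred, betas$labels$condition[test_sel])
    n_test <- n_test + sum(test_sel)
  }
  finalize_searchlight(conf, n_test, nb$valid, nb$centers, spec$mask, 0.2,
                       scheme %||% betas$labels$modality[1])
}

#' Cross-modal searchlight decoding
#'
#' Trains the classifier on all examples of one modality and tests on all
#' examples of the other, in both directions; the stored map is the mean of
#' the two directional accuracies (each retained separately). Above-chance
#' cross-modal accuracy at a center requires a pattern-to-class mapping
#' common to both modalities.
#'
#' @param betas_tactile,betas_visual \code{"beta_series"} objects on the same
#'   mask.
#' @param spec [searchlight_spec()].
#' @return A \code{"searchlight_result"} with additional fields
#'   \code{acc_raw_t2v} and \code{acc_raw_v2t} (per-direction raw accuracy
#'   vectors).
#' @export
crossmodal_cv <- function(betas_tactile, betas_visual, spec = NULL) {
  stopifnot(inherits(betas_tactile, "beta_series"),
            inherits(betas_visual, "beta_series"))
  if (!identical(dim(betas_tactile$mask), dim(betas_visual$mask)) ||
      !identical(which(betas_tactile$mask), which(betas_visual$mask))) {
    stop("beta series are not on the same grid/mask")
  }
  spec <- spec %||% searchlight_spec(betas_tactile$mask)
  nb <- build_neighborhoods(spec)
  V <- length(nb$centers)
  conf <- array(0, c(5, 5, V))
  dir_acc <- list()
  pairs <- list(t2v = list(betas_tactile, betas_visual),
                v2t = list(betas_visual, betas_tactile))
  n_test <- 0L
  for (nm in names(pairs)) {
    tr <- pairs[[nm]][[1]]; te <- pairs[[nm]][[2]]
    pred <- gnb_searchlight_predict(tr$betas, tr$labels$condition,
                                    te$betas, nb$nbr)
    correct <- colMeans(pred == te$labels$condition)
    correct[!nb$valid] <- NA_real_
    dir_acc[[nm]] <- correct
    conf <- accumulate_confusion(conf, pred, te$labels$condition)
    n_test <- n_test + nrow(te$betas)
  }
  res <- finalize_searchlight(conf, n_test, nb$valid, nb$centers, spec$mask,
                              0.2, "crossmodal",
                              extra = list(acc_raw_t2v = dir_acc$t2v,
                                           acc_raw_v2t = dir_acc$v2t))
  # stored map = mean of the two directional accuracies (equal test counts)
  res$acc_raw <- (dir_acc$t2v + dir_acc$v2t) / 2
  res$acc <- res$acc_raw - res$chance
  res
}

#' Assemble a 3-D accuracy map from a searchlight result
#'
#' @param result \code{"searchlight_result"}.
#' @param chance_subtracted Return chance-subtracted values (default TRUE).
#' @return 3-D array (NA outside valid centers).
#' @export
accuracy_map <- function(result, chance_subtracted = TRUE) {
  out <- array(NA_real_, dim(result$mask))
  out[result$centers] <- if (chance_subtracted) result$acc else result$acc_raw
  out
}

#' Cluster-level confusion matrix
#'
#' Pools the test predictions of every searchlight center lying inside a
#' cluster and row-normalizes the pooled counts into a 5 x 5 confusion
#' matrix (row = presented intensity, column = predicted).
#'
#' @param result \code{"searchlight_result"} (one subject).
#' @param cluster Integer vector of linear grid indices (e.g. a
#'   \code{cluster$voxels} from [extract_clusters()]).
#' @return A [square_matrix5()] with role \code{"confusion"}.
#' @export
cluster_confusion <- function(result, cluster) {
  if (!length(cluster)) stop("empty cluster")
  sel <- which(result$centers %in% cluster & result$valid)
  if (!length(sel)) stop("cluster contains no valid searchlight centers")
  counts <- apply(result$confusion_counts[, , sel, drop = FALSE], c(1, 2), sum)
  square_matrix5(counts / rowSums(counts), "confusion")
}

#' Group-average cluster confusion matrix
#'
#' Per-subject cluster confusion matrices averaged entrywise across subjects.
#'
#' @param results List of \code{"searchlight_result"} objects (one per
#'   subject, same mask).
#' @param cluster Linear grid indices of the cluster.
#' @return List with \code{group} (a confusion [square_matrix5()]) and
#'   \code{subjects} (list of per-subject matrices).
#' @export
group_cluster_confusion <- function(results, cluster) {
  subj <- lapply(results, cluster_confusion, cluster = cluster)
  avg <- Reduce(`+`, lapply(subj, unclass)) / length(subj)
  list(group = square_matrix5(matrix(avg, 5, 5), "confusion"),
       subjects = subj)
}
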