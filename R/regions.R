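#' Correlate a neural confusion matrix with behavioral similarity
#'
#' Pearson correlation over the 20 off-diagonal entries of a cluster's
#' (row-stochastic) decoding confusion matrix and the behaviorally derived
#' similarity matrix, with permutation significance from the shared
#' condition-relabeling null of [mantel_test()] (this function delegates to
#' that machinery, so the two are one code path). Runs at the group level or,
#' fed per-subject confusion matrices, at the single-subject level.
#'
#' @param neural 5 x 5 confusion matrix (row-stochastic).
#' @param behavioral 5 x 5 similarity matrix.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param tail \code{"one"} (default) or \code{"two"}.
#' @param method \code{"sampled"} or \code{"exhaustive"}.
#' @return As [mantel_test()]: list with \code{r} and \code{p}.
#' @export
confusion_behavior_corr <- function(neural, behavioral, n_perm = 10000,
                                    seed = NULL, tail = c("one", "two"),
                                    method = c("sampled", "exhaustive")) {
  nv <- as.matrix(neural)
  if (any(abs(rowSums(nv) - 1) > 1e-6)) {
    stop("neural confusion matrix must be row-stochastic")
  }
  mantel_test(behavioral, nv, n_perm = n_perm, seed = seed,
              tail = match.arg(tail), method = match.arg(method))
}

#' Correlate regional activation levels with a stimulus property
#'
#' For every voxel of a cluster and each of the five condition-versus-rest
#' group t maps, pairs the voxel's t value with the condition's property
#' value (particle size or luminance) and computes the Pearson correlation
#' over the pooled \code{5 * |cluster|} pairs (\code{method = "pooled"},
#' default). The low-power alternative \code{"cluster_mean"} first averages t
#' over the cluster, leaving 5 pairs. Significance is parametric by default;
#' a property-relabeling permutation p is available.
#'
#' @param cluster Linear grid indices of the cluster voxels.
#' @param condition_tmaps List of five \code{"group_tmap"} objects, in
#'   condition order.
#' @param prop Numeric 5-vector of property values (condition order), e.g.
#'   \code{stimulus_set()$particle_size}.
#' @param method \code{"pooled"} or \code{"cluster_mean"}.
#' @param p_method \code{"parametric"} or \code{"permutation"}.
#' @param n_perm Permutations for \code{p_method = "permutation"}.
#' @param seed Integer seed for the permutation p.
#' @return List with \code{r}, \code{p}, \code{n} (number of pairs).
#' @export
tvalue_property_corr <- function(cluster, condition_tmaps, prop,
                                 method = c("pooled", "cluster_mean"),
                                 p_method = c("parametric", "permutation"),
                                 n_perm = 10000, seed = NULL) {
  method <- match.arg(method)
  p_method <- match.arg(p_method)
  stopifnot(length(condition_tmaps) == 5, length(prop) == 5,
            all(is.finite(prop)))
  if (!length(cluster)) stop("empty cluster")
  if (stats::sd(prop) == 0) {
    stop("undefined correlation: property vector is constant")
  }
  tvals <- vapply(condition_tmaps, function(tm) {
    lookup <- rep(NA_real_, prod(dim(tm$mask)))
    lookup[tm$centers] <- tm$t
    v <- lookup[cluster]
    if (anyNA(v)) stop("cluster extends outside the map")
    v
  }, numeric(length(cluster)))           # |cluster| x 5
  if (method == "cluster_mean") tvals <- matrix(colMeans(tvals), 1)
  x <- as.numeric(tvals)                 # voxel-major, condition blocks
  y <- rep(prop, each = nrow(tvals))
  r <- stats::cor(x, y)
  n <- length(x)
  if (p_method == "parametric") {
    p <- stats::cor.test(x, y)$p.value
  } else {
    r_null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      stats::cor(x, rep(prop[sample.int(5)], each = nrow(tvals)))
    }, numeric(1)))
    p <- (1 + sum(abs(r_null) >= abs(r) - 1e-12)) / (n_perm + 1)
  }
  list(r = r, p = p, n = n, method = method)
}

#' Condition with the highest decoding accuracy
#'
#' Index of the largest diagonal entry of a confusion matrix (the intensity
#' decoded best); ties resolve to the lowest index.
#'
#' @param confusion 5 x 5 confusion matrix.
#' @return Integer condition index (1--5).
#' @export
highest_row_accuracy <- function(confusion) {
  d <- diag(as.matrix(confusion))
  unname(which.max(d))
}
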