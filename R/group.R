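## Neighbor offsets for 6-, 18- or 26-connectivity in 3-D.
connectivity_offsets <- function(connectivity) {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(offs))
  keep <- switch(as.character(connectivity),
    "6" = nz == 1,
    "18" = nz >= 1 & nz <= 2,
    "26" = nz >= 1,
    stop("connectivity must be 6, 18 or 26")
  )
  offs[keep, , drop = FALSE]
}

#' Label connected components of a voxel set
#'
#' Partitions a set of suprathreshold voxels into connected components under
#' 6-, 18- or 26-connectivity. Adjacencies are enumerated by vectorized
#' offset shifts and the components resolved by graph connectivity
#' (\pkg{igraph}), which keeps the per-permutation cost of the sign-flip
#' null low.
#'
#' @param idx Linear grid indices of the voxels to label.
#' @param dims Grid dimensions.
#' @param connectivity 6, 18 or 26 (default 18).
#' @return List of integer vectors, one per component (linear grid indices).
#' @export
label_components <- function(idx, dims, connectivity = 18) {
  m <- length(idx)
  if (!m) return(list())
  idx <- as.integer(idx)
  offs <- connectivity_offsets(connectivity)
  # half set: each undirected adjacency enumerated once
  offs <- offs[offs[, 1] + 3 * offs[, 2] + 9 * offs[, 3] > 0, , drop = FALSE]
  coords <- index_to_coords(idx, dims)
  lookup <- integer(prod(dims))
  lookup[idx] <- seq_len(m)
  ei <- ej <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    nc <- sweep(coords, 2, offs[k, ], `+`)
    ok <- nc[, 1] >= 1 & nc[, 1] <= dims[1] &
      nc[, 2] >= 1 & nc[, 2] <= dims[2] &
      nc[, 3] >= 1 & nc[, 3] <= dims[3]
    if (!any(ok)) next
    j <- lookup[coords_to_index(nc[ok, , drop = FALSE], dims)]
    keep <- j > 0L
    ei[[k]] <- which(ok)[keep]
    ej[[k]] <- j[keep]
  }
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  edges <- rbind(unlist(ei), unlist(ej))
  if (length(edges)) g <- igraph::add_edges(g, as.integer(edges))
  membership <- igraph::components(g)$membership
  unname(lapply(split(idx, membership), sort))
}

#' Stack subject accuracy maps for group inference
#'
#' @param maps List of per-subject vectors over the in-mask voxels (e.g.
#'   \code{result$acc} from [runwise_cv()]), or a subjects x voxels matrix.
#' @param mask Logical 3-D array the vectors are aligned to.
#' @param scheme Optional scheme label.
#' @return A list of class \code{"group_stack"} with \code{data}
#'   (subjects x voxels; columns with any NA are dropped from inference via
#'   the \code{valid} flag), \code{mask}, \code{centers}, \code{valid}.
#' @export
group_stack <- function(maps, mask, scheme = NULL) {
  data <- if (is.matrix(maps)) maps else do.call(rbind, maps)
  centers <- which(mask)
  stopifnot(ncol(data) == length(centers), nrow(data) >= 2)
  valid <- colSums(is.na(data)) == 0
  structure(list(data = data, mask = mask, centers = centers,
                 valid = valid, scheme = scheme), class = "group_stack")
}

#' Random-effects one-sample t map
#'
#' Voxel-wise one-sample t test of the subject maps against zero (one-tailed:
#' above-chance decoding is the hypothesis), with z equivalents obtained by
#' mapping the t-derived p through the standard-normal quantile. Voxels with
#' zero between-subject variance get a +Inf/-Inf sentinel with a warning.
#'
#' @param stack A \code{"group_stack"}.
#' @return A list of class \code{"group_tmap"}: \code{t}, \code{p}
#'   (one-tailed), \code{z}, \code{df}, \code{mask}, \code{centers},
#'   \code{valid}.
#' @export
onesample_tmap <- function(stack) {
  stopifnot(inherits(stack, "group_stack"))
  X <- stack$data
  n <- nrow(X)
  m <- colMeans(X)
  s <- sqrt(pmax((colSums(X^2) - n * m^2) / (n - 1), 0))
  t <- rep(NA_real_, ncol(X))
  zero_var <- stack$valid & s < .Machine$double.eps^0.5
  if (any(zero_var)) {
    warning(sum(zero_var), " voxel(s) with zero variance; t set to +/-Inf")
  }
  ok <- stack$valid & !zero_var
  t[ok] <- m[ok] / (s[ok] / sqrt(n))
  t[zero_var] <- sign(m[zero_var]) * Inf
  df <- n - 1
  logp <- stats::pt(t, df, lower.tail = FALSE, log.p = TRUE)
  p <- exp(logp)
  z <- stats::qnorm(logp, lower.tail = FALSE, log.p = TRUE)
  structure(list(t = t, p = p, z = z, df = df, mask = stack$mask,
                 centers = stack$centers, valid = stack$valid,
                 scheme = stack$scheme),
            class = "group_tmap")
}

#' Extract suprathreshold clusters
#'
#' Thresholds the group t map at the one-tailed voxel-level p threshold,
#' labels the suprathreshold voxels into connected components, and keeps the
#' components larger than the extent threshold (strictly greater), sorted by
#' size.
#'
#' @param tmap A \code{"group_tmap"}.
#' @param p_thresh Voxel-level p threshold (default 0.001, uncorrected).
#' @param extent Extent threshold in voxels (default 50; a cluster survives
#'   when its size exceeds this).
#' @param connectivity 6, 18 or 26 (default 18).
#' @return A list of clusters, each with \code{voxels} (linear grid indices),
#'   \code{size}, \code{peak_t}, \code{peak_z}, \code{peak} (grid
#'   coordinates); empty list when nothing survives. The threshold t value is
#'   attached as attribute \code{"t_thresh"}.
#' @export
extract_clusters <- function(tmap, p_thresh = 0.001, extent = 50,
                             connectivity = 18) {
  stopifnot(inherits(tmap, "group_tmap"), p_thresh > 0, p_thresh < 1)
  dims <- dim(tmap$mask)
  t_thresh <- stats::qt(1 - p_thresh, tmap$df)
  supra <- which(!is.na(tmap$t) & tmap$t > t_thresh)
  comps <- label_components(tmap$centers[supra], dims, connectivity)
  comps <- comps[vapply(comps, length, integer(1)) > extent]
  lookup <- rep(NA_real_, prod(dims))
  lookup[tmap$centers] <- tmap$t
  zlook <- rep(NA_real_, prod(dims))
  zlook[tmap$centers] <- tmap$z
  out <- lapply(comps, function(vox) {
    tv <- lookup[vox]
    pk <- vox[which.max(tv)]
    list(voxels = vox, size = length(vox), peak_t = max(tv),
         peak_z = zlook[pk], peak = drop(index_to_coords(pk, dims)))
  })
  out <- out[order(-vapply(out, `[[`, integer(1), "size"))]
  attr(out, "t_thresh") <- t_thresh
  out
}

#' Sign-flip permutation null for cluster extent
#'
#' Calibrates a corrected cluster-extent threshold by the sign-flipping
#' permutation: in each permutation every subject's whole accuracy map is
#' flipped in sign independently with probability \code{flip_prob}, the group
#' t map is recomputed, thresholded at the voxel-level p threshold, and the
#' size of the largest suprathreshold component recorded. The corrected
#' extent threshold is the 95th percentile (or \code{percentile}) of this
#' max-cluster-size null; observed clusters are significant when their size
#' exceeds it.
#'
#' The default \code{flip_prob = 0.5} is the standard exchangeable null; the
#' asymmetric 80/20 variant (flip with probability 0.2, mirroring the
#' marginal sign probabilities of chance-subtracted accuracies bounded in
#' [-0.2, 0.8]) is available via \code{flip_prob = 0.2}.
#'
#' @param stack A \code{"group_stack"}.
#' @param p_thresh Voxel-level p threshold.
#' @param connectivity 6, 18 or 26.
#' @param n_perm Number of permutations (default 1000).
#' @param flip_prob Per-subject flip probability.
#' @param percentile Upper-tail percentile defining the corrected threshold.
#' @param extent Extent threshold used for the observed clusters.
#' @param seed Integer seed.
#' @return A list: \code{max_sizes} (length \code{n_perm}),
#'   \code{threshold} (corrected extent threshold), \code{clusters} (observed
#'   clusters, each annotated with \code{significant}), \code{tmap}.
#' @export
signflip_null <- function(stack, p_thresh = 0.001, connectivity = 18,
                          n_perm = 1000, flip_prob = 0.5, percentile = 0.95,
                          extent = 50, seed = NULL) {
  stopifnot(inherits(stack, "group_stack"), n_perm >= 1,
            flip_prob >= 0, flip_prob <= 1)
  X <- stack$data[, stack$valid, drop = FALSE]
  centers <- stack$centers[stack$valid]
  dims <- dim(stack$mask)
  n <- nrow(X)
  ss <- colSums(X^2)
  df <- n - 1
  t_thresh <- stats::qt(1 - p_thresh, df)
  max_sizes <- integer(n_perm)
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      s <- 1 - 2 * stats::rbinom(n, 1, flip_prob)
      m <- as.numeric(crossprod(s, X)) / n
      v <- (ss - n * m^2) / df
      v[v < .Machine$double.xmin] <- .Machine$double.xmin
      t <- m / sqrt(v / n)
      supra <- centers[t > t_thresh]
      if (!length(supra)) next
      comps <- label_components(supra, dims, connectivity)
      max_sizes[i] <- max(vapply(comps, length, integer(1)))
    }
  })
  threshold <- as.numeric(stats::quantile(max_sizes, percentile, type = 1))
  tm <- onesample_tmap(stack)
  clusters <- extract_clusters(tm, p_thresh, extent, connectivity)
  clusters[] <- lapply(clusters, function(cl) {
    cl$significant <- cl$size > threshold
    cl
  })
  list(max_sizes = max_sizes, threshold = threshold, clusters = clusters,
       tmap = tm, percentile = percentile, flip_prob = flip_prob)
}

#' Tabulate clusters
#'
#' Flattens a cluster list into the conventional report table: one row per
#' cluster with peak coordinate, size, peak t and z, and (when present) the
#' corrected-significance flag.
#'
#' @param clusters List of clusters from [extract_clusters()] or
#'   [signflip_null()].
#' @return Data frame.
#' @export
cluster_table <- function(clusters) {
  if (!length(clusters)) {
    return(data.frame(cluster = integer(0), x = integer(0), y = integer(0),
                      z = integer(0), size = integer(0), peak_t = numeric(0),
                      peak_z = numeric(0), significant = logical(0)))
  }
  do.call(rbind, lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    data.frame(cluster = i, x = cl$peak[1], y = cl$peak[2], z = cl$peak[3],
               size = cl$size, peak_t = cl$peak_t, peak_z = cl$peak_z,
               significant = cl$significant %||% NA)
  }))
}
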