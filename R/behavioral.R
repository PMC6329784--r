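#' Two-step normalization of free-modulus ratings
#'
#' Free-modulus magnitude estimates live on participant-specific scales. They
#' are normalized in two steps. Step 1: each participant's ratings are
#' multiplied by the scale factor \eqn{M_n = M_g / M_p}, where \eqn{M_p} is
#' the participant's geometric mean response and \eqn{M_g} the grand
#' geometric mean over all participants. Step 2: each participant's rescaled
#' ratings are mapped onto \code{[0, 1]} by subtracting their minimum and
#' dividing by the resulting maximum. The combination is invariant to any
#' positive rescaling of a participant's raw ratings (the free-modulus
#' property).
#'
#' Zero ratings are incompatible with a geometric mean. With
#' \code{zero_policy = "omit"} (default) \eqn{M_p} and \eqn{M_g} are computed
#' over strictly positive responses only; with \code{"epsilon"} zeros are
#' replaced by half the smallest positive rating before any computation.
#'
#' @param raw Data frame with columns \code{participant}, \code{block},
#'   \code{stimulus_first}, \code{stimulus_second}, \code{rating}
#'   (all ratings nonnegative, at least one positive per participant).
#' @param zero_policy How to treat zero ratings; see Details.
#' @return A list with \code{ratings} (the input with \code{rating} replaced
#'   by its normalized value) and \code{factors} (per-participant
#'   \code{m_p}, \code{m_g}, \code{m_n}, for audit).
#' @export
normalize_ratings <- function(raw, zero_policy = c("omit", "epsilon")) {
  zero_policy <- match.arg(zero_policy)
  need <- c("participant", "block", "stimulus_first", "stimulus_second",
            "rating")
  stopifnot(all(need %in% names(raw)))
  if (any(raw$rating < 0)) stop("ratings must be nonnegative")
  x <- raw$rating
  if (zero_policy == "epsilon" && any(x == 0)) {
    pos <- x[x > 0]
    if (!length(pos)) stop("all ratings are zero")
    x[x == 0] <- min(pos) / 2
  }
  use <- x > 0
  if (!all(tapply(use, raw$participant, any))) {
    stop("every participant needs at least one positive rating")
  }
  m_p <- tapply(x[use], raw$participant[use], geometric_mean)
  m_g <- geometric_mean(x[use])
  m_n <- m_g / m_p
  pid <- as.character(raw$participant)
  scaled <- x * m_n[pid]
  out <- raw
  out$rating <- NA_real_
  for (p in names(m_p)) {
    sel <- pid == p
    v <- scaled[sel]
    if (max(v) == min(v)) {
      stop("degenerate ratings for participant ", p, ": all values equal")
    }
    out$rating[sel] <- (v - min(v)) / (max(v) - min(v))
  }
  factors <- data.frame(participant = names(m_p), m_p = as.numeric(m_p),
                        m_g = m_g, m_n = as.numeric(m_n),
                        stringsAsFactors = FALSE)
  list(ratings = out, factors = factors)
}

#' Ordered-pair square matrix constructor
#'
#' Light container for the 5 x 5 matrices used throughout: behavioral
#' dissimilarity, similarity, and decoding confusion. Matrices are
#' ordered-pair (row = first/presented stimulus) and are not forced
#' symmetric. Role-specific invariants are validated: dissimilarities have a
#' zero diagonal and entries in \code{[0, 1]}; similarities are
#' \code{1 - dissimilarity}; confusion rows sum to 1.
#'
#' @param values 5 x 5 numeric matrix.
#' @param role One of \code{"dissimilarity"}, \code{"similarity"},
#'   \code{"confusion"}.
#' @param labels Condition labels in fixed intensity order.
#' @return The matrix with attributes \code{role} and \code{labels}, class
#'   \code{"square_matrix5"}.
#' @export
square_matrix5 <- function(values, role = c("dissimilarity", "similarity",
                                            "confusion"),
                           labels = stimulus_set()$particle_size) {
  role <- match.arg(role)
  stopifnot(is.matrix(values), all(dim(values) == 5L), all(is.finite(values)))
  if (role == "dissimilarity") {
    if (any(abs(diag(values)) > 1e-12)) stop("dissimilarity diagonal must be 0")
    if (any(values < -1e-12 | values > 1 + 1e-12)) {
      stop("dissimilarity entries must lie in [0, 1]")
    }
  } else if (role == "similarity") {
    if (any(values < -1e-12 | values > 1 + 1e-12)) {
      stop("similarity entries must lie in [0, 1]")
    }
  } else {
    if (any(values < -1e-12) || any(abs(rowSums(values) - 1) > 1e-9)) {
      stop("confusion matrix rows must be nonnegative and sum to 1")
    }
  }
  dimnames(values) <- list(labels, labels)
  structure(values, role = role, labels = labels, class = "square_matrix5")
}

#' @export
as.matrix.square_matrix5 <- function(x, ...) {
  v <- unclass(x)
  attr(v, "role") <- NULL
  attr(v, "labels") <- NULL
  v
}

#' Group-level dissimilarity matrix
#'
#' Averages normalized pairwise ratings into a 5 x 5 ordered-pair
#' dissimilarity matrix: entry (j, k) is the mean (over participants, of the
#' mean over repetitions) normalized rating when intensity j was presented
#' first and k second. The first block is conventionally a practice block and
#' dropped. The diagonal is zero.
#'
#' @param normalized Normalized ratings data frame (see
#'   [normalize_ratings()]).
#' @param drop_first_block Drop block 1 before averaging (default TRUE).
#' @return A [square_matrix5()] with role \code{"dissimilarity"}.
#' @export
group_dissimilarity <- function(normalized, drop_first_block = TRUE) {
  if (is.list(normalized) && !is.data.frame(normalized) &&
      !is.null(normalized$ratings)) {
    normalized <- normalized$ratings
  }
  d <- normalized
  if (drop_first_block) d <- d[d$block != min(d$block), , drop = FALSE]
  if (!nrow(d)) stop("no ratings left after block filtering")
  participants <- unique(d$participant)
  acc <- matrix(0, 5, 5)
  for (p in participants) {
    dp <- d[d$participant == p, , drop = FALSE]
    m <- tapply(dp$rating, list(factor(dp$stimulus_first, 1:5),
                                factor(dp$stimulus_second, 1:5)), mean)
    m <- matrix(as.numeric(m), 5, 5)
    diag(m) <- 0
    if (anyNA(m)) {
      stop("incomplete design: participant ", p,
           " is missing ordered pairs after filtering")
    }
    acc <- acc + m
  }
  vals <- acc / length(participants)
  vals <- pmin(pmax(vals, 0), 1)
  square_matrix5(vals, "dissimilarity")
}

#' Similarity from dissimilarity
#'
#' Entrywise complement \code{1 - d}; the diagonal (self-similarity)
#' becomes 1.
#'
#' @param d Dissimilarity matrix with entries in \code{[0, 1]}.
#' @return A [square_matrix5()] with role \code{"similarity"}.
#' @export
similarity_from_dissimilarity <- function(d) {
  v <- unclass(d)
  attributes(v) <- list(dim = dim(v))
  if (any(v < -1e-12 | v > 1 + 1e-12)) {
    stop("dissimilarity entries must lie in [0, 1]")
  }
  square_matrix5(1 - v, "similarity",
                 labels = attr(d, "labels") %||% stimulus_set()$particle_size)
}

#' Nonmetric multidimensional scaling with random restarts
#'
#' Embeds a 5 x 5 dissimilarity matrix in \code{n_dims} dimensions by
#' Kruskal's nonmetric MDS (isotonic regression of configuration distances on
#' dissimilarity ranks), minimizing stress-1
#' \deqn{\sqrt{\sum (\hat d_{ij} - f(d_{ij}))^2 / \sum \hat d_{ij}^2}.}
#' The ordered-pair input is symmetrized as \eqn{(d + d^T)/2} before
#' embedding. The optimizer is run from a classical-scaling start plus
#' \code{n_restarts - 1} random starts, and the best configuration is kept.
#' Stress is reported as a fraction in \code{[0, 1]} (Kruskal's verbal scale:
#' 0.20 poor, 0.10 fair, 0.05 good, 0.025 excellent, 0 perfect).
#'
#' @param d 5 x 5 dissimilarity matrix (or any square dissimilarity matrix).
#' @param n_dims Embedding dimension (1--3).
#' @param n_restarts Number of starts (default 50).
#' @param seed Integer seed for the random starts.
#' @return List with \code{coords} (points x n_dims) and \code{stress}.
#' @export
nonmetric_mds <- function(d, n_dims = 2, n_restarts = 50, seed = NULL) {
  stopifnot(n_dims %in% 1:3, n_restarts >= 1)
  v <- unclass(as.matrix(d))
  attributes(v) <- list(dim = dim(v))
  v <- (v + t(v)) / 2
  n <- nrow(v)
  if (all(v == 0)) stop("degenerate input: all dissimilarities are zero")
  if (any(v[row(v) != col(v)] <= 0)) {
    stop("off-diagonal dissimilarities must be positive for nonmetric MDS")
  }
  dd <- stats::as.dist(v)
  with_seed(seed, {
    starts <- vector("list", n_restarts)
    cs <- suppressWarnings(stats::cmdscale(dd, k = n_dims))
    if (ncol(cs) < n_dims) {
      cs <- cbind(cs, matrix(stats::rnorm(n * (n_dims - ncol(cs)), 0, 1e-4),
                             n))
    }
    starts[[1]] <- cs
    if (n_restarts > 1) {
      for (i in 2:n_restarts) {
        starts[[i]] <- matrix(stats::rnorm(n * n_dims), n, n_dims)
      }
    }
    best <- NULL
    for (s in starts) {
      fit <- tryCatch(
        MASS::isoMDS(dd, y = s, k = n_dims, maxit = 200, trace = FALSE,
                     tol = 1e-7),
        error = function(e) NULL
      )
      if (!is.null(fit) && (is.null(best) || fit$stress < best$stress)) {
        best <- fit
      }
    }
    if (is.null(best)) stop("nonmetric MDS failed for all starts")
    list(coords = best$points, stress = best$stress / 100)
  })
}

#' Mantel permutation test for ordered-pair matrices
#'
#' Pearson correlation between the 20 off-diagonal entries of two 5 x 5
#' ordered-pair matrices, with significance from a permutation null in which
#' the five condition labels of the second matrix are relabelled jointly on
#' rows and columns. With \code{method = "sampled"} the null is Monte-Carlo
#' (the observed statistic is included in the count, so
#' \eqn{p \ge 1/(n_{perm}+1)}); with \code{method = "exhaustive"} all 120
#' relabelings are enumerated and the p-value is exact.
#'
#' @param a,b Square matrices of identical size (typically 5 x 5).
#' @param n_perm Number of Monte-Carlo permutations (default 10000).
#' @param seed Integer seed.
#' @param tail \code{"one"} (positive correspondence, default) or
#'   \code{"two"}.
#' @param method \code{"sampled"} or \code{"exhaustive"}.
#' @return List with \code{r}, \code{p}, \code{n_perm}, \code{tail},
#'   \code{method}.
#' @export
mantel_test <- function(a, b, n_perm = 10000, seed = NULL,
                        tail = c("one", "two"),
                        method = c("sampled", "exhaustive")) {
  tail <- match.arg(tail)
  method <- match.arg(method)
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(all(dim(a) == dim(b)), nrow(a) == ncol(a), n_perm >= 1)
  va <- offdiag(a)
  stat <- function(m) {
    vb <- offdiag(m)
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
      stop("undefined correlation: zero variance in off-diagonal entries")
    }
    stats::cor(va, vb)
  }
  r_obs <- stat(b)
  score <- if (tail == "one") identity else abs
  n <- nrow(a)
  if (method == "exhaustive") {
    perms <- all_permutations(n)
    r_null <- vapply(seq_len(nrow(perms)), function(i) {
      p <- perms[i, ]
      stat(b[p, p, drop = FALSE])
    }, numeric(1))
    p_val <- mean(score(r_null) >= score(r_obs) - 1e-12)
    n_used <- nrow(perms)
  } else {
    r_null <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        p <- sample.int(n)
        stat(b[p, p, drop = FALSE])
      }, numeric(1))
    })
    p_val <- (1 + sum(score(r_null) >= score(r_obs) - 1e-12)) / (n_perm + 1)
    n_used <- n_perm
  }
  list(r = r_obs, p = p_val, n_perm = n_used, tail = tail, method = method)
}
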