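#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{code} with the random number generator seeded at \code{seed},
#' then restores the caller's RNG state, so that seeded package functions do
#' not perturb user-level random streams. A \code{NULL} seed evaluates the
#' expression under the current RNG state.
#'
#' @param seed Integer seed or \code{NULL}.
#' @param code Expression to evaluate.
#' @return The value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Off-diagonal entries of a square matrix
#'
#' Returns the entries off the main diagonal in column-major order; for the
#' 5 x 5 ordered-pair matrices used throughout this package this is the
#' 20-vector the Mantel-type correlations operate on.
#'
#' @param m Square numeric matrix.
#' @return Numeric vector of length \code{nrow(m) * (nrow(m) - 1)}.
#' @export
offdiag <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  m[row(m) != col(m)]
}

## All permutations of 1..n as an n! x n matrix (lexicographic-ish order,
## identity first). Only ever called with n = 5 (120 rows).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- seq_len(n)[-first]
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

## Geometric mean of strictly positive values.
geometric_mean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a

## Map 3-column voxel coordinates to linear indices of a 3-D array.
coords_to_index <- function(coords, dims) {
  coords <- matrix(as.integer(coords), ncol = 3L)
  stopifnot(all(coords >= 1L), all(t(coords) <= dims))
  (coords[, 3L] - 1L) * dims[1L] * dims[2L] +
    (coords[, 2L] - 1L) * dims[1L] + coords[, 1L]
}

## Inverse of coords_to_index.
index_to_coords <- function(idx, dims) {
  idx0 <- as.integer(idx) - 1L
  x <- idx0 %% dims[1L]
  y <- (idx0 %/% dims[1L]) %% dims[2L]
  z <- idx0 %/% (dims[1L] * dims[2L])
  cbind(x = x + 1L, y = y + 1L, z = z + 1L)
}
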