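# Independent oracles and small fixture builders shared across the suite.

# Flood-fill connected components by breadth-first search: the independent
# oracle for cluster labeling. Deliberately simple and slow.
bfs_components <- function(idx, dims, connectivity = 18) {
  if (!length(idx)) return(list())
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  nz <- rowSums(abs(offs))
  offs <- offs[switch(as.character(connectivity),
                      "6" = nz == 1, "18" = nz >= 1 & nz <= 2,
                      "26" = nz >= 1), ]
  to_c <- function(i) {
    i0 <- i - 1L
    c(i0 %% dims[1] + 1L, (i0 %/% dims[1]) %% dims[2] + 1L,
      i0 %/% (dims[1] * dims[2]) + 1L)
  }
  to_i <- function(cc) {
    (cc[3] - 1L) * dims[1] * dims[2] + (cc[2] - 1L) * dims[1] + cc[1]
  }
  member <- logical(prod(dims)); member[idx] <- TRUE
  seen <- logical(prod(dims))
  comps <- list()
  for (start in idx) {
    if (seen[start]) next
    queue <- start; seen[start] <- TRUE; comp <- integer(0)
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      comp <- c(comp, cur)
      cc <- to_c(cur)
      for (k in seq_len(nrow(offs))) {
        nc <- cc + as.integer(offs[k, ])
        if (any(nc < 1) || any(nc > dims)) next
        ni <- to_i(nc)
        if (member[ni] && !seen[ni]) {
          seen[ni] <- TRUE
          queue <- c(queue, ni)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# Canonical partition form for comparing component labelings.
partition_key <- function(comps) {
  sort(vapply(comps, function(v) paste(sort(v), collapse = ","), character(1)))
}

# Brute-force Gaussian Bayes posterior: direct density evaluation with
# dnorm(), the oracle for the vectorized GNB implementation.
bayes_posterior_oracle <- function(means, vars, priors, x) {
  post <- t(apply(x, 1, function(row) {
    like <- vapply(seq_len(nrow(means)), function(c) {
      prod(stats::dnorm(row, means[c, ], sqrt(vars))) * priors[c]
    }, numeric(1))
    like / sum(like)
  }))
  post
}

# Trial-wise beta series built directly (no GLM), with balanced labels:
# n_runs runs x 5 blocks x 5 conditions.
make_betas <- function(values, mask, n_runs = 3, modality = "tactile",
                       conditions = NULL) {
  n <- n_runs * 25
  labels <- do.call(rbind, lapply(seq_len(n_runs), function(r) {
    data.frame(condition = conditions %||% rep(1:5, 5), run = r,
               modality = modality, block = rep(1:5, each = 5))
  }))
  structure(list(betas = values, labels = labels, mask = mask),
            class = "beta_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal group_tmap constructed from a plain t vector (df known), used to
# exercise cluster extraction on crafted maps.
fake_tmap <- function(tvals, mask, df = 14) {
  logp <- stats::pt(tvals, df, lower.tail = FALSE, log.p = TRUE)
  structure(list(t = tvals, p = exp(logp),
                 z = stats::qnorm(logp, lower.tail = FALSE, log.p = TRUE),
                 df = df, mask = mask, centers = which(mask),
                 valid = rep(TRUE, sum(mask)), scheme = "test"),
            class = "group_tmap")
}
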