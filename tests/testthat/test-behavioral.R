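ratings_df <- function(participant, ratings) {
  pairs <- cbind(first = c(1, 1, 1), second = c(2, 3, 4))
  data.frame(participant = participant, block = 1,
             stimulus_first = pairs[, 1], stimulus_second = pairs[, 2],
             rating = ratings)
}

test_that("normalization equalizes multiplicatively scaled participants", {
  raw <- rbind(ratings_df("A", c(1, 2, 4)), ratings_df("B", c(2, 4, 8)))
  out <- normalize_ratings(raw)
  # hand computation: m_p = 2 and 4, m_g = sqrt(2*4) = 2.828
  expect_equal(out$factors$m_p, c(2, 4))
  expect_equal(out$factors$m_g, rep(sqrt(8), 2))
  expect_equal(out$factors$m_n * out$factors$m_p, rep(sqrt(8), 2))
  a <- out$ratings$rating[out$ratings$participant == "A"]
  b <- out$ratings$rating[out$ratings$participant == "B"]
  expect_equal(a, c(0, 1 / 3, 1))
  expect_equal(a, b)
})

test_that("normalized range is exactly [0, 1] per participant", {
  set.seed(1)
  raw <- generate_ratings(n_participants = 4, seed = 2)
  out <- normalize_ratings(raw)$ratings
  for (p in unique(out$participant)) {
    v <- out$rating[out$participant == p]
    expect_equal(range(v), c(0, 1))
  }
})

test_that("normalization is invariant to per-participant rescaling", {
  raw <- generate_ratings(n_participants = 5, seed = 3)
  scaled <- raw
  mult <- c(0.2, 1, 3, 10, 40)[match(raw$participant, 1:5)]
  scaled$rating <- raw$rating * mult
  expect_equal(normalize_ratings(raw)$ratings$rating,
               normalize_ratings(scaled)$ratings$rating, tolerance = 1e-12)
})

test_that("degenerate and zero ratings are handled per policy", {
  raw <- ratings_df("A", c(2, 2, 2))
  expect_error(normalize_ratings(raw), "degenerate")
  rz <- rbind(ratings_df("A", c(0, 2, 4)), ratings_df("B", c(1, 2, 4)))
  om <- normalize_ratings(rz, zero_policy = "omit")
  expect_equal(om$factors$m_p[1], sqrt(8))  # geometric mean over positives
  ep <- normalize_ratings(rz, zero_policy = "epsilon")
  expect_equal(ep$factors$m_p[1], (0.5 * 2 * 4)^(1 / 3))
})

test_that("group dissimilarity averages repetitions and participants", {
  # single participant, single block: matrix is the ratings rearranged
  r1 <- generate_ratings(n_participants = 1, n_blocks = 1, scale_spread = 0,
                         noise_cv = 0, seed = 4)
  n1 <- normalize_ratings(r1)$ratings
  m <- group_dissimilarity(n1, drop_first_block = FALSE)
  for (i in seq_len(nrow(n1))) {
    expect_equal(m[n1$stimulus_first[i], n1$stimulus_second[i]],
                 n1$rating[i])
  }
  expect_equal(unname(diag(as.matrix(m))), rep(0, 5))

  # five blocks, first dropped: mean of the remaining four repetitions
  r5 <- generate_ratings(n_participants = 2, n_blocks = 5, seed = 5)
  n5 <- normalize_ratings(r5)$ratings
  m5 <- group_dissimilarity(n5, drop_first_block = TRUE)
  keep <- n5[n5$block != 1, ]
  manual <- tapply(keep$rating,
                   list(keep$participant, keep$stimulus_first,
                        keep$stimulus_second), mean)
  byhand <- apply(manual, c(2, 3), mean)
  byhand[is.na(byhand)] <- 0
  expect_equal(unname(as.matrix(m5)), unname(byhand), tolerance = 1e-12)

  # a missing ordered pair is an incomplete design
  broken <- n5[!(n5$stimulus_first == 2 & n5$stimulus_second == 3), ]
  expect_error(group_dissimilarity(broken), "incomplete")
})

test_that("noiseless group matrix is an affine image of latent distances", {
  r <- generate_ratings(n_participants = 6, scale_spread = 0.8,
                        noise_cv = 0, seed = 6)
  latent <- attr(r, "latent")
  m <- group_dissimilarity(normalize_ratings(r)$ratings)
  dl <- abs(outer(latent, latent, `-`))
  off <- row(dl) != col(dl)
  expect_gt(cor(as.matrix(m)[off], dl[off]), 1 - 1e-12)
  # exact affine relation (min-max maps the smallest pair distance to 0)
  fit <- lm(as.matrix(m)[off] ~ dl[off])
  expect_lt(max(abs(residuals(fit))), 1e-10)
})

test_that("similarity complement and round trip", {
  set.seed(11)
  v <- matrix(runif(25), 5, 5); diag(v) <- 0
  d <- square_matrix5(v, "dissimilarity")
  s <- similarity_from_dissimilarity(d)
  expect_equal(unname(diag(as.matrix(s))), rep(1, 5))
  expect_equal(as.matrix(s), 1 - as.matrix(d), ignore_attr = TRUE)
  off <- row(s) != col(s)
  expect_equal(which.max(as.matrix(d)[off]), which.min(as.matrix(s)[off]))
  bad <- matrix(2, 5, 5)
  expect_error(similarity_from_dissimilarity(bad), "\\[0, 1\\]")
  d0 <- square_matrix5(matrix(0, 5, 5), "dissimilarity")
  expect_true(all(as.matrix(similarity_from_dissimilarity(d0)) == 1))
})

test_that("nonmetric MDS recovers exactly embeddable configurations", {
  pts <- matrix(c(0, 0, 4, 0, 4, 3, 0, 3, 2, 1.5), 5, 2, byrow = TRUE)
  d <- as.matrix(dist(pts))
  fit <- nonmetric_mds(d, n_dims = 2, n_restarts = 5, seed = 1)
  expect_lt(fit$stress, 1e-4)
  rec <- as.matrix(dist(fit$coords))
  off <- row(d) != col(d)
  ratio <- rec[off] / d[off]
  expect_lt(sd(ratio) / mean(ratio), 1e-3)   # distances proportional
})

test_that("MDS stress is non-increasing in dimension and seeded", {
  set.seed(2)
  m <- matrix(runif(25, 0.2, 1), 5, 5); diag(m) <- 0
  s <- vapply(1:3, function(k) {
    nonmetric_mds(m, n_dims = k, n_restarts = 10, seed = 3)$stress
  }, numeric(1))
  expect_true(all(diff(s) <= 1e-8))
  a <- nonmetric_mds(m, seed = 4); b <- nonmetric_mds(m, seed = 4)
  expect_identical(a, b)
  expect_error(nonmetric_mds(matrix(0, 5, 5)), "degenerate")
})

test_that("roughest stimulus sits farthest from the smoothest in the map", {
  r <- generate_ratings(n_participants = 10, seed = 7)
  m <- group_dissimilarity(normalize_ratings(r)$ratings)
  fit <- nonmetric_mds(m, seed = 8)
  d_from_1 <- sqrt(rowSums(sweep(fit$coords, 2, fit$coords[1, ])^2))
  expect_equal(which.max(d_from_1), 5)
})

test_that("Mantel statistic and null behave as specified", {
  set.seed(3)
  a <- matrix(runif(25), 5, 5); diag(a) <- 0
  self <- mantel_test(a, a, n_perm = 200, seed = 1)
  expect_equal(self$r, 1)
  b <- matrix(runif(25), 5, 5); diag(b) <- 0
  ex <- mantel_test(a, b, method = "exhaustive")
  expect_equal(ex$n_perm, 120)
  expect_gte(ex$p, 1 / 120)
  # Monte-Carlo agrees with exhaustive enumeration within binomial error
  mc <- mantel_test(a, b, n_perm = 3000, seed = 2)
  se <- sqrt(ex$p * (1 - ex$p) / 3000)
  expect_lt(abs(mc$p - ex$p), 4 * se + 1 / 3000)
  # point estimate independent of permutation count; p-values seeded
  expect_equal(mantel_test(a, b, n_perm = 50, seed = 5)$r, mc$r)
  expect_identical(mantel_test(a, b, n_perm = 500, seed = 6),
                   mantel_test(a, b, n_perm = 500, seed = 6))
  expect_error(mantel_test(a, matrix(1, 5, 5)), "zero variance")
})

test_that("Mantel r matches vegan on symmetric matrices", {
  skip_if_not_installed("vegan")
  set.seed(4)
  a <- matrix(runif(25), 5, 5); a <- (a + t(a)) / 2; diag(a) <- 0
  b <- matrix(runif(25), 5, 5); b <- (b + t(b)) / 2; diag(b) <- 0
  mine <- mantel_test(a, b, n_perm = 100, seed = 1)
  ref <- vegan::mantel(as.dist(a), as.dist(b), permutations = 99)
  expect_equal(mine$r, unname(ref$statistic), tolerance = 1e-12)
})
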