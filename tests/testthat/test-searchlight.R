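test_that("cube neighborhoods clip to the mask and cover it", {
  dims <- c(5, 5, 5)
  mask <- array(TRUE, dims)
  spec <- searchlight_spec(mask, min_voxels = 1)
  expect_equal(nrow(cube_neighborhood(c(3, 3, 3), spec)), 27)
  expect_equal(nrow(cube_neighborhood(c(1, 1, 1), spec)), 8)
  expect_equal(nrow(cube_neighborhood(c(1, 3, 3), spec)), 18)
  nb <- roughmvpa:::build_neighborhoods(spec)
  expect_equal(length(nb$centers), sum(mask))   # one center per mask voxel
  expect_true(all(nb$valid))
  m2 <- mask; m2[1, 1, 1] <- FALSE
  expect_error(cube_neighborhood(c(1, 1, 1), searchlight_spec(m2)),
               "outside")
})

test_that("GNB matches the brute-force Gaussian Bayes oracle", {
  set.seed(1)
  x <- matrix(rnorm(50 * 3), 50, 3) +
    matrix(rep(seq(0, 4), each = 10), 50, 3)
  y <- rep(1:5, each = 10)
  model <- gnb_fit(x, y)
  xt <- matrix(rnorm(40 * 3), 40, 3) + 2
  got <- gnb_predict(model, xt)
  oracle <- bayes_posterior_oracle(model$class_means, model$pooled_var,
                                   model$class_priors, xt)
  expect_lt(max(abs(exp(got$log_posterior) - oracle)), 1e-10)
  expect_equal(got$labels, apply(oracle, 1, which.max))
})

test_that("GNB sufficient statistics and tie rule", {
  x <- matrix(c(-1, -1.2, -0.8, 1, 1.2, 0.8), ncol = 1)
  y <- c(1, 1, 1, 2, 2, 2)
  m <- gnb_fit(x, y)
  # symmetric means, equal priors: boundary at zero
  expect_equal(gnb_predict(m, matrix(c(-0.1, 0.1), ncol = 1))$labels, c(1, 2))
  expect_equal(gnb_predict(m, matrix(0, 1, 1))$labels, 1)  # tie -> lowest
  # duplicating the training set leaves means, priors and decisions unchanged
  m2 <- gnb_fit(rbind(x, x), c(y, y))
  expect_equal(m$class_means, m2$class_means)
  expect_equal(m$class_priors, m2$class_priors)
  probe <- matrix(seq(-2, 2, by = 0.5), ncol = 1)
  expect_equal(gnb_predict(m, probe)$labels, gnb_predict(m2, probe)$labels)
  expect_error(gnb_fit(x, c(1, 1, 1, 2, 2, 3)), "at least 2")
  # constant feature is floored, not NaN
  mf <- gnb_fit(cbind(x, 1), y)
  expect_true(all(is.finite(gnb_predict(mf, cbind(x, 1))$log_posterior)))
})

test_that("GNB labels agree with an independent naive Bayes reference", {
  skip_if_not_installed("e1071")
  set.seed(2)
  n_per <- 200
  means <- matrix(rnorm(5 * 4, sd = 10), 5, 4)
  x <- do.call(rbind, lapply(1:5, function(c) {
    matrix(rnorm(n_per * 4), n_per, 4) + matrix(means[c, ], n_per, 4,
                                                byrow = TRUE)
  }))
  y <- rep(1:5, each = n_per)
  xt <- do.call(rbind, lapply(1:5, function(c) {
    matrix(rnorm(200 * 4), 200, 4) + matrix(means[c, ], 200, 4, byrow = TRUE)
  }))
  mine <- gnb_predict(gnb_fit(x, y), xt)$labels
  ref <- as.integer(predict(e1071::naiveBayes(x, factor(y)),
                            as.data.frame(xt)))
  expect_gte(mean(mine == ref), 0.999)
})

test_that("run-wise CV is perfect for a separable voxel and bounded", {
  dims <- c(4, 4, 4)
  mask <- array(TRUE, dims)
  set.seed(3)
  V <- prod(dims)
  vals <- matrix(rnorm(75 * V, sd = 0.1), 75, V)
  enc <- 22                       # this voxel encodes the label exactly
  labels <- rep(rep(1:5, 5), 3)
  vals[, enc] <- labels * 10
  bs <- make_betas(vals, mask, conditions = NULL)
  bs$labels$condition <- labels
  res <- runwise_cv(bs, searchlight_spec(mask, min_voxels = 1))
  enc_xyz <- roughmvpa:::index_to_coords(enc, dims)
  near <- which(apply(roughmvpa:::index_to_coords(res$centers, dims), 1,
                      function(cc) max(abs(cc - enc_xyz)) <= 1))
  expect_true(all(res$acc_raw[near] == 1))
  expect_true(all(res$acc[near] == 0.8))
  expect_true(all(res$acc >= -0.2 & res$acc <= 0.8, na.rm = TRUE))
})

test_that("run order does not change run-wise CV results", {
  dims <- c(4, 4, 4)
  set.seed(4)
  vals <- matrix(rnorm(75 * prod(dims)), 75)
  bs <- make_betas(vals, array(TRUE, dims))
  res1 <- runwise_cv(bs)
  perm <- order(match(bs$labels$run, c(3, 1, 2)))
  bs2 <- bs
  bs2$betas <- bs$betas[perm, ]
  bs2$labels <- bs$labels[perm, ]
  res2 <- runwise_cv(bs2)
  expect_equal(res1$acc_raw, res2$acc_raw)
  expect_equal(res1$confusion_counts, res2$confusion_counts)
})

test_that("shuffling labels within runs destroys decodable signal", {
  dims <- c(4, 4, 4)
  set.seed(5)
  labels <- rep(rep(1:5, 5), 3)
  vals <- matrix(rnorm(75 * prod(dims), sd = 1), 75) + labels  # univariate code
  bs <- make_betas(vals, array(TRUE, dims))
  bs$labels$condition <- labels
  strong <- runwise_cv(bs)
  expect_gt(mean(strong$acc_raw, na.rm = TRUE), 0.5)
  shuf <- bs
  for (r in 1:3) {
    sel <- which(shuf$labels$run == r)
    shuf$labels$condition[sel] <- sample(shuf$labels$condition[sel])
  }
  null <- runwise_cv(shuf)
  expect_lt(abs(mean(null$acc_raw, na.rm = TRUE) - 0.2), 0.06)
})

test_that("cross-modal CV averages its two directions", {
  dims <- c(4, 4, 4)
  mask <- array(TRUE, dims)
  set.seed(6)
  bt <- make_betas(matrix(rnorm(75 * prod(dims)), 75) +
                     rep(rep(1:5, 5), 3) * 0.5, mask)
  bv <- make_betas(matrix(rnorm(75 * prod(dims)), 75) +
                     rep(rep(1:5, 5), 3) * 0.5, mask, modality = "visual")
  res <- crossmodal_cv(bt, bv)
  expect_equal(res$acc_raw, (res$acc_raw_t2v + res$acc_raw_v2t) / 2)
  # identical beta series in both modalities: both directions equal
  # resubstitution accuracy
  res_id <- crossmodal_cv(bt, bt)
  nb <- roughmvpa:::build_neighborhoods(searchlight_spec(mask))
  pred <- roughmvpa:::gnb_searchlight_predict(bt$betas, bt$labels$condition,
                                              bt$betas, nb$nbr)
  resub <- colMeans(pred == bt$labels$condition)
  resub[!nb$valid] <- NA_real_
  expect_equal(res_id$acc_raw, resub)
  bad <- bv; bad$mask <- array(TRUE, c(5, 5, 5))
  expect_error(crossmodal_cv(bt, bad), "grid")
})

test_that("cluster confusion matrices are row-stochastic and sensible", {
  dims <- c(4, 4, 4)
  mask <- array(TRUE, dims)
  set.seed(7)
  labels <- rep(rep(1:5, 5), 3)
  # perfectly separable everywhere
  vals <- matrix(rnorm(75 * prod(dims), sd = 0.01), 75) + labels * 5
  bs <- make_betas(vals, mask); bs$labels$condition <- labels
  res <- runwise_cv(bs)
  cl <- which(mask)[1:20]
  conf <- cluster_confusion(res, cl)
  expect_equal(unname(as.matrix(conf)), diag(5))
  expect_equal(highest_row_accuracy(conf), 1)
  # pure noise: flat confusion
  bs0 <- make_betas(matrix(rnorm(75 * prod(dims)), 75), mask)
  conf0 <- cluster_confusion(runwise_cv(bs0), which(mask))
  expect_equal(rowSums(as.matrix(conf0)), rep(1, 5), ignore_attr = TRUE)
  expect_lt(max(abs(as.matrix(conf0) - 0.2)), 0.15)
  expect_error(cluster_confusion(res, integer(0)), "empty")
  # group average of per-subject matrices stays a confusion matrix
  g <- group_cluster_confusion(list(res, runwise_cv(bs0)), cl)
  expect_equal(rowSums(as.matrix(g$group)), rep(1, 5), ignore_attr = TRUE)
})
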