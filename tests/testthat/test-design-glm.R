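test_that("canonical HRF has the expected shape", {
  h <- canonical_hrf(hrf_params(), tr = 1.52, dt = 0.01)
  expect_equal(max(h$kernel), 1)           # unit-peak convention
  expect_equal(h$kernel[1], 0)             # zero at t = 0
  # dense-grid oracle: difference of gamma densities peaks near the peak
  # delay, followed by a smaller negative undershoot
  t <- h$time
  oracle <- dgamma(t, 6, 1) - dgamma(t, 16, 1) / 6
  expect_equal(which.max(h$kernel), which.max(oracle))
  expect_lt(abs(t[which.max(h$kernel)] - 6), 1.52)
  post_peak <- h$kernel[t > 10]
  expect_lt(min(post_peak), 0)
  expect_gt(min(post_peak), -0.25)
})

test_that("discrete-cosine drift basis matches the closed-form count", {
  n_scans <- 204; tr <- 1.52                         # a 310 s run
  drift <- dct_basis(n_scans, tr, 128)
  expect_equal(ncol(drift), floor(2 * n_scans * tr / 128))
  expect_equal(ncol(drift), 4)
  expect_equal(ncol(dct_basis(n_scans, tr, Inf)), 0)
  g <- crossprod(drift)
  expect_lt(max(abs(g[row(g) != col(g)])), 1e-8)     # mutually orthogonal
})

test_that("trial-wise session design has 150 task regressors", {
  tt <- generate_trial_table(3, seed = 1)
  n_task <- 0
  for (r in unique(tt$run)) {
    d <- build_trial_design(tt[tt$run == r, ], n_scans = 204, tr = 1.52)
    n_task <- n_task + length(d$task_cols)
    expect_equal(length(d$task_cols), 25)
    expect_true("constant" %in% d$labels$column)
    expect_equal(qr(d$X)$rank, ncol(d$X))
  }
  expect_equal(n_task, 150)
  # trial extending past the run is a design error
  bad <- tt[tt$run == 1, ]
  expect_error(build_trial_design(bad, n_scans = 100, tr = 1.52), "past")
})

test_that("OLS betas recover noiseless amplitudes and ignore offsets", {
  ph <- demo_phantom(seed = 1, noise_sd = 0, grid_shape = c(24, 24, 24))
  ph$drift_amp <- 0
  tt <- generate_trial_table(1, seed = 2)
  v <- simulate_bold(ph, tt, seed = 3)[[1]]
  des <- build_trial_design(v$trials, v$n_scans, v$tr)
  bs <- fit_betas(v, des)
  # ground truth amplitudes in the shared ROI
  roi <- ph$rois[[which(vapply(ph$rois, `[[`, character(1), "id") == "shared")]]
  pat <- roughmvpa:::phantom_patterns(ph)[[3]]$tactile
  slots <- match(roughmvpa:::coords_to_index(roi$voxels, dim(ph$mask)),
                 which(ph$mask))
  truth <- roi$intensity_gain * v$trials$condition +
    roi$pattern_amp * pat[v$trials$condition, ]
  est <- bs$betas[, slots]
  expect_lt(max(abs(est - truth)) / max(abs(truth)), 1e-6)
  # constant offsets are absorbed by the constant column
  v2 <- v; v2$data <- v$data + 7
  expect_equal(fit_betas(v2, des)$betas, bs$betas, tolerance = 1e-9)
})

test_that("high-pass drift model removes modelled drift and bounds leakage", {
  ph <- phantom_spec(c(10, 10, 10), mask = array(TRUE, c(10, 10, 10)),
                     rois = list(roi_spec("r", cube_roi(c(5, 5, 5), 3),
                                          "shared", pattern_amp = 0,
                                          intensity_gain = 1)),
                     noise_sd = 0, drift_amp = 0, seed = 1)
  tt <- generate_trial_table(1, seed = 2, modalities = "visual")
  v <- simulate_bold(ph, tt, seed = 3)[[1]]
  des <- build_trial_design(v$trials, v$n_scans, v$tr, hp_cutoff = 128)
  clean <- fit_betas(v, des)$betas
  ref <- max(abs(clean))
  # drift inside the span of the modelled drift basis is removed exactly
  drift_cols <- dct_basis(v$n_scans, v$tr, 128)
  v1 <- v
  v1$data <- v$data + outer(3 * drift_cols[, 1] - 2 * drift_cols[, 3] + 4,
                            rep(1, ncol(v$data)))
  expect_lt(max(abs(fit_betas(v1, des)$betas - clean)) / ref, 1e-8)
  # an off-harmonic slow cosine (period above the cutoff) is only
  # approximately spanned; its leakage into task betas stays bounded even at
  # an amplitude matching the peak signal
  t_sec <- (seq_len(v$n_scans) - 1) * v$tr
  v2 <- v
  v2$data <- v$data + ref * cos(2 * pi * t_sec / 200 + 0.7)
  expect_lt(max(abs(fit_betas(v2, des)$betas - clean)) / ref, 0.2)
})

test_that("beta estimates are unbiased under AR(1) noise", {
  dims <- c(3, 3, 3)
  roi <- roi_spec("r", cube_roi(c(2, 2, 2), 1), "shared", pattern_amp = 0,
                  intensity_gain = 1)
  tt <- generate_trial_table(1, seed = 1, n_blocks = 2,
                             modalities = "tactile")
  ph <- phantom_spec(dims, mask = array(TRUE, dims), rois = list(roi),
                     noise_sd = 4, drift_amp = 0, ar1_rho = 0.4, seed = 1)
  slot <- match(roughmvpa:::coords_to_index(matrix(c(2, 2, 2), 1), dims),
                which(ph$mask))
  est <- sapply(1:200, function(i) {
    v <- simulate_bold(ph, tt, seed = 100 + i)[[1]]
    fit_betas(v, build_trial_design(v$trials, v$n_scans, v$tr))$betas[, slot]
  })
  truth <- tt$condition
  err <- rowMeans(est) - truth
  se <- apply(est, 1, sd) / sqrt(ncol(est))
  expect_true(all(abs(err) < 3 * se + 1e-8))
})

test_that("condition-versus-rest t statistics behave", {
  dims <- c(12, 12, 12)
  ph <- phantom_spec(dims, mask = array(TRUE, dims),
                     rois = list(roi_spec("r", cube_roi(c(6, 6, 6), 3),
                                          "shared", pattern_amp = 0,
                                          intensity_gain = 1)),
                     noise_sd = 2, drift_amp = 0.5, seed = 1)
  tt <- generate_trial_table(2, seed = 2, modalities = "visual")
  vols <- simulate_bold(ph, tt, seed = 3)
  ts <- condition_vs_rest_tstats(vols, tr = 1.52)
  n_scans_total <- sum(vapply(vols, function(v) nrow(v$data), integer(1)))
  expect_equal(ts$df, n_scans_total - (5 + 2 * 5))  # 5 task + per-run 4 drift + const
  slots <- match(roughmvpa:::coords_to_index(ph$rois[[1]]$voxels, dims),
                 which(ph$mask))
  expect_gt(min(ts$t[5, slots]), 10)                # strong effect in ROI
  out <- setdiff(seq_len(sum(ph$mask)), slots)
  expect_lt(abs(mean(ts$t[, out])), 0.15)           # null voxels centred on 0
})

test_that("conjunction is an intersection with component bookkeeping", {
  dims <- c(10, 10, 10)
  block <- array(FALSE, dims); block[3:6, 3:6, 3:6] <- TRUE
  expect_equal(conjunction_mask(list(block, block, block))$mask, block)
  empty <- array(FALSE, dims)
  cj <- conjunction_mask(list(block, empty))
  expect_false(any(cj$mask))
  expect_equal(nrow(cj$components), 0)
  two <- block; two[8:9, 8:9, 8:9] <- TRUE
  cj2 <- conjunction_mask(list(two, two))
  expect_equal(cj2$components$size, c(64, 8))
  expect_error(conjunction_mask(list(block, array(FALSE, c(9, 9, 9)))),
               "grid")
})

test_that("conjunction of per-condition maps recovers a responsive region", {
  dims <- c(12, 12, 12)
  ph <- phantom_spec(dims, mask = array(TRUE, dims),
                     rois = list(roi_spec("r", cube_roi(c(6, 6, 6), 5),
                                          "shared", pattern_amp = 0,
                                          intensity_gain = 3)),
                     noise_sd = 2, drift_amp = 1, seed = 1)
  subj <- lapply(1:6, function(s) {
    tt <- generate_trial_table(2, seed = 10 + s, modalities = "visual")
    vols <- simulate_bold(ph, tt, seed = 20 + s)
    condition_vs_rest_tstats(vols, tr = 1.52)
  })
  thresholded <- lapply(1:5, function(cc) {
    st <- group_stack(lapply(subj, function(x) x$beta[cc, ]), ph$mask)
    tm <- onesample_tmap(st)
    arr <- array(FALSE, dims)
    arr[tm$centers] <- tm$p < 0.001
    arr
  })
  cj <- conjunction_mask(thresholded)
  roi_idx <- roughmvpa:::coords_to_index(ph$rois[[1]]$voxels, dims)
  got <- which(cj$mask)
  jac <- length(intersect(got, roi_idx)) / length(union(got, roi_idx))
  expect_gt(jac, 0.8)
})
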