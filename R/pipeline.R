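#' Default pipeline configuration
#'
#' The declarative document driving [run_pipeline()]. Defaults reproduce the
#' study conditions: 15 subjects, 3 runs per modality of 25 trials, TR
#' 1.52 s, 128 s high-pass, 3 x 3 x 3 searchlight, voxel p < 0.001 with
#' extent > 50, 1000 sign-flip permutations, 10000 Mantel permutations, on
#' the four-region recovery phantom.
#'
#' @param ... Named overrides of any default entry.
#' @return A named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1,
    n_subjects = 15,
    n_runs_per_modality = 3,
    tr = 1.52,
    hp_cutoff = 128,
    grid_shape = c(24, 24, 24),
    phantom = "demo",            # "demo" or "null"
    noise_sd = 14,
    pattern_amp = 1,
    intensity_gain = 0.5,
    cube_half_width = 1,
    min_voxels = 10,
    p_thresh = 0.001,
    extent = 50,
    connectivity = 18,
    n_perm_cluster = 1000,
    flip_prob = 0.5,
    n_perm_mantel = 10000,
    behavioral_n_participants = 15,
    behavioral_noise_cv = 0.2,
    behavioral_scale_spread = 0.5,
    write_volumes = FALSE
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

pipeline_phantom <- function(cfg, subject_seed) {
  if (identical(cfg$phantom, "null")) {
    demo_phantom(seed = subject_seed, pattern_amp = 0, intensity_gain = 0,
                 noise_sd = cfg$noise_sd, grid_shape = cfg$grid_shape)
  } else {
    demo_phantom(seed = subject_seed, pattern_amp = cfg$pattern_amp,
                 intensity_gain = cfg$intensity_gain,
                 noise_sd = cfg$noise_sd, grid_shape = cfg$grid_shape)
  }
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage end to end on synthetic data and writes all
#' artifacts under \code{out_dir}: behavioral matrices, MDS coordinates and
#' Mantel test (stage \code{behavioral}); per-subject simulated sessions,
#' trial-wise GLM beta series and the three searchlight schemes (tactile,
#' visual, cross-modal); group t maps, cluster tables and the sign-flip
#' null; per-cluster confusion matrices, confusion-behavior correlations and
#' t-versus-property correlations; and a manifest recording the
#' configuration, every seed consumed, and an MD5 hash of each artifact.
#'
#' @param config A configuration list from [default_config()], or a path to
#'   a JSON file of overrides.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config)) {
    config <- do.call(default_config, jsonlite::read_json(config,
                                                          simplifyVector = TRUE))
  }
  cfg <- config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("behavioral", "subjects", "group", "regions")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  seeds <- list(base = cfg$seed)

  ## ---- behavioral stage -------------------------------------------------
  seeds$ratings_tactile <- cfg$seed + 11
  seeds$ratings_learning <- cfg$seed + 12
  rt <- generate_ratings(n_participants = cfg$behavioral_n_participants,
                         noise_cv = cfg$behavioral_noise_cv,
                         scale_spread = cfg$behavioral_scale_spread,
                         seed = seeds$ratings_tactile)
  rl <- generate_ratings(n_participants = cfg$behavioral_n_participants,
                         noise_cv = cfg$behavioral_noise_cv,
                         scale_spread = cfg$behavioral_scale_spread,
                         seed = seeds$ratings_learning)
  bdir <- file.path(out_dir, "behavioral")
  utils::write.csv(rt, file.path(bdir, "ratings_tactile.csv"),
                   row.names = FALSE)
  utils::write.csv(rl, file.path(bdir, "ratings_learning.csv"),
                   row.names = FALSE)
  d_t <- group_dissimilarity(normalize_ratings(rt)$ratings)
  d_l <- group_dissimilarity(normalize_ratings(rl)$ratings)
  write_matrix_csv(d_t, file.path(bdir, "dissimilarity_tactile.csv"))
  write_matrix_csv(d_l, file.path(bdir, "dissimilarity_learning.csv"))
  sim <- similarity_from_dissimilarity(d_t)
  write_matrix_csv(sim, file.path(bdir, "similarity_tactile.csv"))
  seeds$mds <- cfg$seed + 13
  mds <- nonmetric_mds(d_t, n_dims = 2, seed = seeds$mds)
  utils::write.csv(
    data.frame(condition = 1:5, stimulus_set()[, c("particle_size", "color")],
               dim1 = mds$coords[, 1], dim2 = mds$coords[, 2],
               stress = mds$stress),
    file.path(bdir, "mds_coords.csv"), row.names = FALSE)
  seeds$mantel_behavior <- cfg$seed + 14
  mt <- mantel_test(similarity_from_dissimilarity(d_t),
                    similarity_from_dissimilarity(d_l),
                    n_perm = cfg$n_perm_mantel, seed = seeds$mantel_behavior)
  jsonlite::write_json(mt, file.path(bdir, "mantel_tactile_vs_learning.json"),
                       auto_unbox = TRUE, digits = NA)

  ## ---- subject stage: simulate, GLM, searchlight ------------------------
  schemes <- c("tactile", "visual", "crossmodal")
  results <- stats::setNames(lapply(schemes, function(s) list()), schemes)
  cond_betas <- list()
  spec <- NULL
  roi_reference <- NULL
  for (s in seq_len(cfg$n_subjects)) {
    sdir <- file.path(out_dir, "subjects", sprintf("sub-%02d", s))
    dir.create(sdir, showWarnings = FALSE)
    seeds[[sprintf("subject_%02d", s)]] <- list(
      pattern = cfg$seed + 1000 + s, trials = cfg$seed + 2000 + s,
      noise = cfg$seed + 3000 + s)
    phantom <- pipeline_phantom(cfg, cfg$seed + 1000 + s)
    if (is.null(roi_reference)) roi_reference <- phantom
    trials <- generate_trial_table(cfg$n_runs_per_modality,
                                   seed = cfg$seed + 2000 + s)
    write_events_tsv(trials, file.path(sdir, "events.tsv"))
    vols <- simulate_bold(phantom, trials, tr = cfg$tr,
                          seed = cfg$seed + 3000 + s)
    if (isTRUE(cfg$write_volumes)) {
      for (v in vols) {
        write_volume_nifti(v, file.path(sdir, sprintf("run-%02d_bold.nii.gz",
                                                      v$run)))
      }
    }
    per_run <- lapply(vols, function(v) {
      fit_betas(v, build_trial_design(v$trials, v$n_scans, v$tr,
                                      hp_cutoff = cfg$hp_cutoff))
    })
    all <- bind_betas(per_run)
    betas <- lapply(c(tactile = "tactile", visual = "visual"), function(m) {
      sel <- all$labels$modality == m
      structure(list(betas = all$betas[sel, , drop = FALSE],
                     labels = all$labels[sel, , drop = FALSE],
                     mask = all$mask), class = "beta_series")
    })
    if (is.null(spec)) {
      spec <- searchlight_spec(phantom$mask, cfg$cube_half_width,
                               cfg$min_voxels)
    }
    res <- list(
      tactile = runwise_cv(betas$tactile, spec),
      visual = runwise_cv(betas$visual, spec),
      crossmodal = crossmodal_cv(betas$tactile, betas$visual, spec)
    )
    for (sc in schemes) {
      results[[sc]][[s]] <- res[[sc]]
      write_map_nifti(accuracy_map(res[[sc]]),
                      file.path(sdir, sprintf("acc_%s.nii.gz", sc)))
    }
    cond_betas[[s]] <- condition_vs_rest_tstats(
      Filter(function(v) v$modality == "visual", vols),
      tr = cfg$tr, hp_cutoff = cfg$hp_cutoff)
  }

  ## ---- group stage ------------------------------------------------------
  gdir <- file.path(out_dir, "group")
  group_out <- list()
  for (sc in schemes) {
    seeds[[paste0("signflip_", sc)]] <- cfg$seed + 4000 + match(sc, schemes)
    stack <- group_stack(lapply(results[[sc]], `[[`, "acc"),
                         spec$mask, scheme = sc)
    gi <- signflip_null(stack, p_thresh = cfg$p_thresh,
                        connectivity = cfg$connectivity,
                        n_perm = cfg$n_perm_cluster,
                        flip_prob = cfg$flip_prob, extent = cfg$extent,
                        seed = cfg$seed + 4000 + match(sc, schemes))
    group_out[[sc]] <- gi
    tarr <- array(NA_real_, dim(spec$mask))
    tarr[gi$tmap$centers] <- gi$tmap$t
    tarr[is.na(tarr)] <- 0
    write_map_nifti(tarr, file.path(gdir, sprintf("tmap_%s.nii.gz", sc)))
    utils::write.csv(cluster_table(gi$clusters),
                     file.path(gdir, sprintf("clusters_%s.csv", sc)),
                     row.names = FALSE)
    utils::write.csv(data.frame(perm = seq_along(gi$max_sizes),
                                max_size = gi$max_sizes),
                     file.path(gdir, sprintf("null_max_sizes_%s.csv", sc)),
                     row.names = FALSE)
  }

  ## ---- region stage -----------------------------------------------------
  rdir <- file.path(out_dir, "regions")
  group_cond_tmaps <- lapply(1:5, function(cc) {
    onesample_tmap(group_stack(
      lapply(cond_betas, function(cb) cb$beta[cc, ]), spec$mask))
  })
  report <- list()
  for (sc in schemes) {
    cls <- group_out[[sc]]$clusters
    for (k in seq_along(cls)) {
      conf <- group_cluster_confusion(results[[sc]], cls[[k]]$voxels)
      write_matrix_csv(conf$group,
                       file.path(rdir, sprintf("confusion_%s_cluster%d.csv",
                                               sc, k)))
      seeds[[sprintf("confcorr_%s_%d", sc, k)]] <-
        cfg$seed + 5000 + 10 * match(sc, schemes) + k
      cb <- confusion_behavior_corr(conf$group, sim,
                                    n_perm = cfg$n_perm_mantel,
                                    seed = cfg$seed + 5000 +
                                      10 * match(sc, schemes) + k)
      tp_size <- tvalue_property_corr(cls[[k]]$voxels, group_cond_tmaps,
                                      stimulus_set()$particle_size)
      tp_lum <- tvalue_property_corr(cls[[k]]$voxels, group_cond_tmaps,
                                     stimulus_set()$luminance)
      report[[length(report) + 1L]] <- data.frame(
        scheme = sc, cluster = k, size = cls[[k]]$size,
        significant = isTRUE(cls[[k]]$significant),
        confusion_r = cb$r, confusion_p = cb$p,
        particle_size_r = tp_size$r, particle_size_p = tp_size$p,
        luminance_r = tp_lum$r, luminance_p = tp_lum$p,
        best_decoded = highest_row_accuracy(conf$group))
    }
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(scheme = character(0))
  utils::write.csv(report, file.path(rdir, "correlation_report.csv"),
                   row.names = FALSE)

  ## ---- manifest ---------------------------------------------------------
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("roughmvpa")),
    config = cfg,
    seeds = seeds,
    files = data.frame(
      path = sub(paste0("^", out_dir, "/?"), "", files),
      md5 = unname(tools::md5sum(files)), stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
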