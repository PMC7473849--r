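# End-to-end orchestration: simulate -> GLM -> searchlight -> ROIs ->
# regional evidence tests -> temporal decoding and generalization.

#' Pipeline configuration
#'
#' All randomness is governed by explicit per-stage seeds derived from
#' `seed`; the configuration round-trips losslessly through JSON.
#'
#' @param n_subjects Cohort size (even).
#' @param grid_dims Voxel grid dimensions.
#' @param tr_s Repetition time (seconds).
#' @param n_categories Stimulus categories (controls trials/runs).
#' @param amplitude Planted pattern amplitude.
#' @param site_voxels Voxels per planted pattern site (scale down with
#'   the grid).
#' @param white_sd,ar1,drift_order,drift_sd Noise model parameters.
#' @param radius Searchlight radius (voxels).
#' @param fraction Balanced subsampling fraction for searchlight decoding.
#' @param alpha FDR level for accuracy maps.
#' @param min_cluster Minimum cluster extent (voxels); scale down with the
#'   grid.
#' @param k_select ANOVA-selected features for regional/temporal stages.
#' @param folds Within-subject fold count.
#' @param n_frames Temporal epoch length.
#' @param label_sets Label sets to map with the searchlight.
#' @param seed Master seed.
#' @param output_dir Optional directory for NIfTI/TSV/JSON outputs.
#' @return A `run_config` list.
#' @export
run_config <- function(n_subjects = 24, grid_dims = c(20, 20, 20),
                       tr_s = DEFAULT_TR_S, n_categories = 60,
                       amplitude = 1, site_voxels = 33,
                       white_sd = 1, ar1 = 0.3,
                       drift_order = 2, drift_sd = 0.5, radius = 3,
                       fraction = 0.5, alpha = 0.01, min_cluster = 50,
                       k_select = 50, folds = 7, n_frames = 7,
                       label_sets = c("choice", "response", "image_type",
                                      "target_side"),
                       seed = 1, output_dir = NULL) {
  cfg <- as.list(environment())
  stopifnot(n_subjects %% 2 == 0, length(grid_dims) == 3, radius >= 0,
            alpha > 0, alpha < 1)
  structure(cfg, class = "run_config")
}

# Map a label-set name to the schedule column it decodes.
label_column <- function(label_set) {
  switch(label_set, choice = "choice", status = "memory_status",
         memory_status = "memory_status", response = "response",
         image_type = "image_type", target_side = "target_side",
         stop("unknown label set: ", label_set))
}

#' Run the full analysis pipeline
#'
#' Stages: cohort simulation; per-subject condition GLM,
#' execution-phase residualization and single-trial betas; between-subject
#' searchlight per label set; group t map, FDR and cluster thresholding
#' into ROIs; regional decoding by evidence with the mixed-model slope
#' test; temporal decoding and within-subject temporal generalization on
#' the largest choice ROI. Fully deterministic given the configuration.
#'
#' @param config A `run_config`.
#' @return A result bundle (list) with elements `cohort`, `betas`,
#'   `residuals`, `maps`, `rois`, `regional`, `temporal` and `manifest`
#'   (stage seeds and result hashes).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seeds <- child_seeds(config$seed, 8)
  names(seeds) <- c("cohort", "patterns", "subsample", "regional",
                    "temporal", "unused1", "unused2", "unused3")
  grid <- volume_grid(config$grid_dims)
  hrf <- make_hrf(dt_s = config$tr_s)
  specs <- default_pattern_suite(grid, seed = seeds[["patterns"]],
                                 site_voxels = config$site_voxels,
                                 amplitude = config$amplitude)
  noise <- noise_model(config$white_sd, config$ar1, config$drift_order,
                       config$drift_sd)
  cohort <- simulate_cohort(config$n_subjects, grid, specs, noise, hrf,
                            config$n_categories, tr_s = config$tr_s,
                            seed = seeds[["cohort"]])
  betas <- vector("list", config$n_subjects)
  residuals <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    sub <- cohort$subjects[[i]]
    design <- build_condition_design(sub$schedule, hrf, config$tr_s)
    residuals[[i]] <- residualize_execution(sub, design)
    betas[[i]] <- single_trial_betas(sub, sub$schedule, hrf,
                                     config$tr_s)
  }
  maps <- list(); rois <- list()
  for (ls in config$label_sets) {
    map <- run_searchlight(betas, label_column(ls), grid,
                           radius = config$radius,
                           fraction = config$fraction,
                           seed = seeds[["subsample"]])
    gt <- group_test_vs_chance(map)
    sig <- fdr_mask(gt$p, config$alpha)
    maps[[ls]] <- list(map = map, t = gt$t, p = gt$p, sig = sig)
    rois[[ls]] <- cluster_rois(sig, grid, min_size = config$min_cluster,
                               stat = rowMeans(map$acc))
  }
  # regional evidence analysis on every surviving ROI
  regional <- list()
  for (ls in config$label_sets) {
    tab <- rois[[ls]]$table
    for (lb in tab$label) {
      roi <- which(rois[[ls]]$labels == lb)
      rows <- regional_decode(betas, roi, label_set = label_column(ls),
                              k_select = config$k_select,
                              seed = seeds[["regional"]],
                              roi_name = paste0(ls, "_", lb))
      regional[[paste0(ls, "_", lb)]] <-
        list(rows = rows, slope = evidence_slope_test(rows))
    }
  }
  # temporal decoding on the largest choice ROI (if any)
  temporal <- NULL
  if (!is.null(rois$choice) && nrow(rois$choice$table)) {
    roi <- which(rois$choice$labels == rois$choice$table$label[1])
    epochs_list <- lapply(seq_len(config$n_subjects), function(i) {
      ep <- extract_epochs(residuals[[i]], cohort$subjects[[i]]$schedule,
                           roi, config$n_frames)
      ep$meta$subject <- i
      ep
    })
    epochs <- merge_epochs(epochs_list)
    n_rois <- nrow(rois$choice$table)
    temporal <- list(
      between = temporal_decode(epochs, epochs$meta$choice,
        cv_scheme("leave_one_subject_out"), k_select = config$k_select,
        n_rois = n_rois, fraction = config$fraction,
        seed = seeds[["temporal"]]),
      within = temporal_decode(epochs, epochs$meta$choice,
        cv_scheme("k_fold_within", k = config$folds),
        k_select = config$k_select, n_rois = n_rois,
        seed = seeds[["temporal"]]),
      generalization = temporal_generalization(epochs,
        epochs$meta$choice, cv_scheme("k_fold_within", k = config$folds),
        k_select = config$k_select, n_rois = n_rois,
        seed = seeds[["temporal"]]))
  }
  bundle <- list(cohort = cohort, betas = betas, residuals = residuals,
                 maps = maps, rois = rois, regional = regional,
                 temporal = temporal)
  bundle$manifest <- list(
    seeds = as.list(seeds[1:5]), config = unclass(config)[
      setdiff(names(config), "output_dir")],
    hashes = list(
      betas = rlang::hash(lapply(betas, `[[`, "beta")),
      maps = rlang::hash(lapply(maps, function(m) m$map$acc)),
      rois = rlang::hash(lapply(rois, `[[`, "labels"))))
  if (!is.null(config$output_dir)) write_bundle(bundle, config)
  bundle
}

# Concatenate per-subject epoch tensors (same ROI and frame count).
merge_epochs <- function(epochs_list) {
  datas <- lapply(epochs_list, `[[`, "data")
  nt <- vapply(datas, function(d) dim(d)[1], 1L)
  d1 <- dim(datas[[1]])
  arr <- array(NA_real_, c(sum(nt), d1[2], d1[3]))
  at <- 0
  for (d in datas) { arr[at + seq_len(dim(d)[1]), , ] <- d; at <- at + dim(d)[1] }
  structure(list(data = arr,
                 meta = do.call(rbind, lapply(epochs_list, `[[`, "meta")),
                 frame_times_s = epochs_list[[1]]$frame_times_s,
                 tr_s = epochs_list[[1]]$tr_s),
            class = "epoch_tensor")
}

# Persist the bundle's file outputs (NIfTI maps, ROI tables, manifest).
write_bundle <- function(bundle, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- bundle$cohort$grid
  for (ls in names(bundle$maps)) {
    m <- bundle$maps[[ls]]
    acc_mean <- rowMeans(m$map$acc)
    RNifti::writeNifti(RNifti::asNifti(unmask(acc_mean, grid)),
      file.path(config$output_dir, paste0("accuracy_", ls, ".nii.gz")))
    RNifti::writeNifti(RNifti::asNifti(unmask(m$t, grid)),
      file.path(config$output_dir, paste0("tmap_", ls, ".nii.gz")))
    RNifti::writeNifti(RNifti::asNifti(
      unmask(bundle$rois[[ls]]$labels, grid)),
      file.path(config$output_dir, paste0("rois_", ls, ".nii.gz")))
    write.table(bundle$rois[[ls]]$table,
      file.path(config$output_dir, paste0("rois_", ls, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(bundle$regional)) {
    rows <- do.call(rbind, lapply(bundle$regional, `[[`, "rows"))
    write.table(rows, file.path(config$output_dir, "regional_accuracy.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(lapply(bundle$regional, `[[`, "slope"),
                         file.path(config$output_dir,
                                   "regional_stats.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(bundle$temporal)) {
    tc <- rbind(cbind(scheme = "between", bundle$temporal$between$summary),
                cbind(scheme = "within", bundle$temporal$within$summary))
    write.table(tc, file.path(config$output_dir, "temporal_decoding.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(bundle$temporal$generalization$matrix,
                file.path(config$output_dir,
                          "temporal_generalization.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = paste0("test_f", seq_len(ncol(
                  bundle$temporal$generalization$matrix))))
  }
  write_cohort_json(bundle$cohort$designs, bundle$cohort$seed,
                    file.path(config$output_dir, "cohort.json"))
  jsonlite::write_json(bundle$manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(config$output_dir)
}
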