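# Shared fixtures: tiny grids, cohorts and noiseless forward models used
# across the test files. Everything is generated in code under fixed seeds.

tiny_grid <- function(dims = c(12, 12, 12)) volume_grid(dims)

tiny_suite <- function(grid, seed = 5, site_voxels = 20, amplitude = 3)
  default_pattern_suite(grid, seed = seed, site_voxels = site_voxels,
                        amplitude = amplitude)

noiseless <- function() noise_model(white_sd = 0, ar1 = 0, drift_order = 0)

# A small observed schedule (n trials = 6 * n_categories).
tiny_schedule <- function(n_categories = 10, seed = 9, observe = TRUE,
                          p_correct = default_p_correct()) {
  sc <- build_retrieval_schedule(n_categories, seed = seed)
  if (observe)
    sc <- simulate_observer(sc, assign_groups(2, seed = 1)[1, ],
                            p_correct, seed = seed + 1)
  sc
}

# Simulate a cohort and return single-trial beta series per subject.
cohort_betas <- function(cohort) {
  hrf <- make_hrf(dt_s = cohort$subjects[[1]]$tr_s)
  lapply(cohort$subjects, function(s)
    single_trial_betas(s, s$schedule, hrf))
}

# Residual datasets (execution phase projected out) per subject.
cohort_residuals <- function(cohort) {
  hrf <- make_hrf(dt_s = cohort$subjects[[1]]$tr_s)
  lapply(cohort$subjects, function(s) {
    d <- suppressWarnings(build_condition_design(s$schedule, hrf, s$tr_s))
    residualize_execution(s, d)
  })
}

# Merge per-subject epochs over an ROI into one labeled tensor.
cohort_epochs <- function(cohort, residuals, roi, n_frames = 7) {
  el <- lapply(seq_along(residuals), function(i) {
    e <- extract_epochs(residuals[[i]], cohort$subjects[[i]]$schedule,
                        roi, n_frames)
    e$meta$subject <- i
    e
  })
  bolddecode:::merge_epochs(el)
}

# Pooled labeled patterns over given voxels from per-subject beta series,
# with the standard searchlight preprocessing.
pooled_patterns <- function(betas, voxels, label) {
  X <- do.call(rbind, lapply(betas, function(b)
    detrend_zscore_trials(spatial_zscore(b$beta))[, voxels, drop = FALSE]))
  y <- unlist(lapply(betas, function(b) b$meta[[label]]))
  subject <- rep(seq_along(betas), vapply(betas, function(b)
    nrow(b$beta), 1L))
  meta <- do.call(rbind, lapply(betas, function(b) b$meta))
  labeled_patterns(X, y, subject, meta)
}
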