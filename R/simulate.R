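# Synthetic BOLD: planted condition-dependent patterns, noise, cohorts.

# Trial-level drivers: +1/-1 sign per trial for each decodable variable.
DRIVER_POSITIVE <- c(choice = "old", status = "old", response = "eye",
                     image_type = "indoor", target_side = "left")

driver_sign <- function(schedule, driver) {
  col <- switch(driver, choice = "choice", status = "memory_status",
                response = "response", image_type = "image_type",
                target_side = "target_side",
                stop("unknown driver: ", driver))
  if (is.null(schedule[[col]]))
    stop("schedule lacks column `", col, "` required by driver `",
         driver, "`")
  ifelse(schedule[[col]] == DRIVER_POSITIVE[[driver]], 1, -1)
}

#' Specify a planted activity pattern
#'
#' A pattern is a fixed set of in-mask voxels with unit-norm weights whose
#' common time course is an HRF-convolved boxcar placed `onset_lag_s` after
#' image onset, multiplied per trial by the driver sign (e.g. +1 for "old"
#' choices, -1 for "new"), an evidence-dependent gain and a group-dependent
#' sign.
#'
#' @param name Label.
#' @param voxels In-mask voxel column indices.
#' @param weights Numeric weights, one per voxel (normalized to unit norm).
#' @param driver One of `"choice"`, `"status"`, `"response"`,
#'   `"image_type"`, `"target_side"`.
#' @param amplitude Base amplitude in signal units.
#' @param evidence_gain Named multipliers for `low`, `middle`, `high`
#'   (default all 1).
#' @param onset_lag_s Lag of the boxcar after image onset (seconds).
#' @param duration_s Boxcar duration (seconds, positive).
#' @param group_sign Named signs for groups `A1`, `A2` (default both +1;
#'   association-dependent patterns flip one group to -1).
#' @param idiosyncratic If `TRUE`, the spatial weights are re-drawn
#'   deterministically for every subject: the signal stays decodable
#'   within subject but its spatial code does not generalize across
#'   subjects (the signature of activity tied to the subject's own
#'   choice-response association).
#' @return A `pattern_spec`.
#' @export
pattern_spec <- function(name, voxels, weights = NULL, driver = "choice",
                         amplitude = 1,
                         evidence_gain = c(low = 1, middle = 1, high = 1),
                         onset_lag_s = 0, duration_s = 1.5,
                         group_sign = c(A1 = 1, A2 = 1),
                         idiosyncratic = FALSE) {
  if (duration_s <= 0) stop("`duration_s` must be positive")
  if (is.null(weights)) weights <- rep(1, length(voxels))
  stopifnot(length(weights) == length(voxels))
  weights <- weights / sqrt(sum(weights^2))
  stopifnot(all(EVIDENCE_LEVELS %in% names(evidence_gain)),
            all(c("A1", "A2") %in% names(group_sign)))
  structure(list(name = name, voxels = as.integer(voxels),
                 weights = weights, driver = driver, amplitude = amplitude,
                 evidence_gain = evidence_gain[EVIDENCE_LEVELS],
                 onset_lag_s = onset_lag_s, duration_s = duration_s,
                 group_sign = group_sign[c("A1", "A2")],
                 idiosyncratic = isTRUE(idiosyncratic)),
            class = "pattern_spec")
}

#' Default suite of planted patterns
#'
#' Five mutually disjoint sites reproducing the qualitative signal
#' taxonomy under study:
#' * `choice` — early (no lag), transient (2 s), shared across groups,
#'   amplitude scaled by decision evidence (low < middle < high);
#' * `action` — driven by the motor response, late (6 s lag) and sustained
#'   to the go-signal, shared, evidence-insensitive;
#' * `association` — driven by the choice, late, with its sign tied to
#'   the subject's choice-response group (A1 = +1, A2 = -1) and a
#'   subject-idiosyncratic spatial code, so it is decodable within but
#'   not between subjects;
#' * `image_type` and `target_side` — early stimulus-locked controls.
#'
#' @param grid A `volume_grid`.
#' @param seed Integer seed for site placement and weights.
#' @param site_voxels Voxels per site.
#' @param amplitude Base amplitude applied to every pattern (signal units,
#'   relative to unit-variance noise).
#' @return List of five `pattern_spec` objects named by pattern.
#' @export
default_pattern_suite <- function(grid, seed = 1, site_voxels = 33,
                                  amplitude = 1) {
  V <- n_voxels(grid)
  if (V < 5 * site_voxels)
    stop("mask has ", V, " voxels; too small for 5 disjoint sites of ",
         site_voxels)
  with_seed(seed, {
    # greedy seeded placement; relax the between-site gap if the mask is
    # tight, but never below the site radius (sites stay disjoint via the
    # nearest-voxel assignment check below)
    site_r <- (3 * site_voxels / (4 * pi))^(1 / 3)
    cand <- sample(V)
    centers <- integer(0)
    for (min_gap in seq(ceiling(2 * site_r + 4), 2)) {
      centers <- integer(0)
      for (v in cand) {
        if (length(centers) == 5) break
        if (!length(centers)) { centers <- v; next }
        gap <- sqrt(rowSums((grid$coords[centers, , drop = FALSE] -
          matrix(grid$coords[v, ], length(centers), 3, byrow = TRUE))^2))
        if (all(gap >= min_gap)) centers <- c(centers, v)
      }
      if (length(centers) == 5) break
    }
    if (length(centers) < 5)
      stop("could not place 5 disjoint pattern sites; enlarge the grid")
    # nearest-center assignment guarantees the sites are disjoint even
    # when the mask squeezes two sites together
    D <- sapply(centers, function(v) sqrt(rowSums((grid$coords -
      matrix(grid$coords[v, ], V, 3, byrow = TRUE))^2)))
    nearest <- max.col(-D, ties.method = "first")
    sites <- lapply(seq_along(centers), function(i) {
      own <- which(nearest == i)
      if (length(own) < site_voxels)
        stop("could not place 5 disjoint pattern sites; enlarge the grid")
      own[order(D[own, i])][seq_len(site_voxels)]
    })
    w <- lapply(1:5, function(i) rnorm(site_voxels))
  })
  list(
    choice = pattern_spec("choice", sites[[1]], w[[1]], driver = "choice",
      amplitude = amplitude,
      evidence_gain = c(low = 0.5, middle = 1, high = 1.5),
      onset_lag_s = 0, duration_s = 2),
    action = pattern_spec("action", sites[[2]], w[[2]],
      driver = "response", amplitude = amplitude, onset_lag_s = 6,
      duration_s = 4.5),
    association = pattern_spec("association", sites[[3]], w[[3]],
      driver = "choice", amplitude = amplitude, onset_lag_s = 6,
      duration_s = 3, group_sign = c(A1 = 1, A2 = -1),
      idiosyncratic = TRUE),
    image_type = pattern_spec("image_type", sites[[4]], w[[4]],
      driver = "image_type", amplitude = amplitude, onset_lag_s = 0,
      duration_s = 1.5),
    target_side = pattern_spec("target_side", sites[[5]], w[[5]],
      driver = "target_side", amplitude = amplitude, onset_lag_s = 0,
      duration_s = 1.5))
}

#' Noise model for synthetic BOLD
#'
#' @param white_sd Marginal standard deviation of the AR(1) noise process
#'   (signal units).
#' @param ar1 Lag-1 autocorrelation coefficient in `[0, 1)`.
#' @param drift_order Polynomial drift order per run (0 disables drift).
#' @param drift_sd Per-frame standard deviation contributed by the drift.
#' @return A `noise_model` list.
#' @export
noise_model <- function(white_sd = 1, ar1 = 0.3, drift_order = 2,
                        drift_sd = 0.5) {
  if (ar1 < 0 || ar1 >= 1) stop("`ar1` must lie in [0, 1)")
  if (white_sd < 0) stop("`white_sd` must be non-negative")
  structure(list(white_sd = white_sd, ar1 = ar1,
                 drift_order = drift_order, drift_sd = drift_sd),
            class = "noise_model")
}

#' Simulate one subject's BOLD runs
#'
#' Per voxel the noiseless signal is the sum over patterns of
#' `weight * amplitude * evidence_gain * group_sign * driver_sign`
#' HRF-convolved boxcars; AR(1)-plus-white noise and polynomial drift are
#' added per run. Deterministic under a fixed seed.
#'
#' @param design One row of [assign_groups()].
#' @param schedule Observed retrieval `trial_schedule` for this subject.
#' @param specs List of `pattern_spec` objects.
#' @param noise A `noise_model`.
#' @param hrf HRF kernel sampled at the repetition time.
#' @param grid A `volume_grid`.
#' @param seed Integer seed.
#' @return A `subject_dataset`: list with `design`, `grid`, `runs` (list of
#'   frames x in-mask-voxels matrices), `tr_s`, `schedule`.
#' @export
simulate_subject <- function(design, schedule, specs, noise, hrf, grid,
                             seed = 1) {
  tr_s <- attr(schedule, "tr_s")
  run_frames <- attr(schedule, "run_frames")
  V <- n_voxels(grid)
  for (sp in specs)
    if (any(sp$voxels < 1 | sp$voxels > V))
      stop("pattern `", sp$name, "` has out-of-mask voxels")
  runs <- sort(unique(schedule$run))
  out <- vector("list", length(runs))
  # idiosyncratic patterns: redraw unit-norm weights per subject (stable
  # across this subject's runs and seeds derived from the subject id)
  specs <- lapply(specs, function(sp) {
    if (sp$idiosyncratic) {
      w <- with_seed(design$subject_id * 7919 + length(sp$voxels),
                     rnorm(length(sp$voxels)))
      sp$weights <- w / sqrt(sum(w^2))
    }
    sp
  })
  with_seed(seed, {
    for (ri in seq_along(runs)) {
      nf <- run_frames[ri]
      sc <- schedule[schedule$run == runs[ri], , drop = FALSE]
      sig <- matrix(0, nf, V)
      for (sp in specs) {
        amp <- sp$amplitude * sp$evidence_gain[sc$evidence] *
          sp$group_sign[[design$group]] * driver_sign(sc, sp$driver)
        reg <- hrf_regressor(sc$onset + sp$onset_lag_s,
                             rep(sp$duration_s, nrow(sc)), amp, nf, tr_s,
                             hrf)
        sig[, sp$voxels] <- sig[, sp$voxels] + outer(reg, sp$weights)
      }
      if (noise$white_sd > 0) {
        innov <- matrix(rnorm(nf * V,
                              sd = noise$white_sd * sqrt(1 - noise$ar1^2)),
                        nf, V)
        e <- if (noise$ar1 > 0)
          apply(innov, 2, function(x)
            as.numeric(filter(x, noise$ar1, method = "recursive")))
        else innov
        sig <- sig + e
      }
      if (noise$drift_order > 0 && noise$drift_sd > 0) {
        P <- poly(seq_len(nf), noise$drift_order)
        cf <- matrix(rnorm(noise$drift_order * V,
                           sd = noise$drift_sd * sqrt(nf)),
                     noise$drift_order, V)
        sig <- sig + P %*% cf
      }
      out[[ri]] <- sig
    }
  })
  structure(list(design = design, grid = grid, runs = out, tr_s = tr_s,
                 schedule = schedule),
            class = "subject_dataset")
}

#' Simulate a counterbalanced cohort
#'
#' Assigns groups, draws an independent randomized schedule and observer
#' per subject, and generates each subject's BOLD runs.
#'
#' @param n_subjects Even cohort size.
#' @param grid A `volume_grid`.
#' @param specs Pattern suite (default [default_pattern_suite()] on `grid`).
#' @param noise A `noise_model`.
#' @param hrf HRF kernel (default [make_hrf()] at `tr_s`).
#' @param n_categories Categories for the retrieval schedule (default 60:
#'   360 trials in 12 runs).
#' @param p_correct Observer accuracy table.
#' @param tr_s Repetition time (seconds).
#' @param seed Master seed; per-subject seeds are derived from it.
#' @return A `cohort`: list with `subjects` (list of `subject_dataset`),
#'   `designs`, `specs`, `grid`, `seed`.
#' @export
simulate_cohort <- function(n_subjects = 24, grid = volume_grid(),
                            specs = NULL, noise = noise_model(),
                            hrf = NULL, n_categories = 60,
                            p_correct = default_p_correct(),
                            tr_s = DEFAULT_TR_S, seed = 1) {
  if (is.null(hrf)) hrf <- make_hrf(dt_s = tr_s)
  if (is.null(specs)) specs <- default_pattern_suite(grid, seed = seed)
  designs <- assign_groups(n_subjects, seed = seed)
  seeds <- child_seeds(seed, 3 * n_subjects)
  subjects <- lapply(seq_len(n_subjects), function(i) {
    sc <- build_retrieval_schedule(n_categories, seed = seeds[3 * i - 2],
                                   tr_s = tr_s)
    sc <- simulate_observer(sc, designs[i, ], p_correct,
                            seed = seeds[3 * i - 1])
    simulate_subject(designs[i, ], sc, specs, noise, hrf, grid,
                     seed = seeds[3 * i])
  })
  structure(list(subjects = subjects, designs = designs, specs = specs,
                 grid = grid, seed = seed),
            class = "cohort")
}
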