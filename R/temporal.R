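# Frame-wise temporal decoding, temporal generalization, peak detection.

#' Extract per-trial frame epochs from a residual dataset
#'
#' Collects, for every trial, the ROI activity of the first `n_frames` MR
#' frames from image onset (frame 1 = first acquisition at or after the
#' onset). With the default timing, 7 frames span the image, the delay and
#' one frame of the execution phase. Trials too close to the end of their
#' run are dropped with a message.
#'
#' @param residual A `residual_dataset`.
#' @param schedule The matching observed `trial_schedule`.
#' @param roi In-mask voxel indices.
#' @param n_frames Epoch length in frames (default 7).
#' @return An `epoch_tensor`: list with `data` (trials x frames x voxels
#'   array), `meta` (schedule rows kept), `frame_times_s` (frame offsets
#'   from epoch start, seconds), `tr_s`.
#' @export
extract_epochs <- function(residual, schedule, roi, n_frames = 7) {
  tr <- residual$tr_s
  run_frames <- residual$run_frames
  runs <- sort(unique(schedule$run))
  offsets <- c(0, cumsum(run_frames))[seq_along(runs)]
  names(offsets) <- runs
  f0 <- ceiling(schedule$onset / tr - 1e-9) + 1  # first frame >= onset
  nf_run <- run_frames[match(schedule$run, runs)]
  keep <- f0 + n_frames - 1 <= nf_run
  if (any(!keep))
    message("dropping ", sum(!keep), " trial(s) with fewer than ",
            n_frames, " frames before run end")
  sc <- schedule[keep, , drop = FALSE]
  f0 <- f0[keep]
  arr <- array(NA_real_, c(nrow(sc), n_frames, length(roi)))
  for (i in seq_len(nrow(sc))) {
    rows <- offsets[[as.character(sc$run[i])]] + f0[i] + 0:(n_frames - 1)
    arr[i, , ] <- residual$data[rows, roi, drop = FALSE]
  }
  structure(list(data = arr, meta = as.data.frame(sc),
                 frame_times_s = (seq_len(n_frames) - 1) * tr, tr_s = tr),
            class = "epoch_tensor")
}

# Shared engine: per fold, train at frame i, test at frames `test_frames`.
# Returns accuracy array [train_frame, test_frame, fold] plus fold info.
frame_cv_engine <- function(epochs, labels, scheme, train_frames,
                            test_frames_of, k_select, C, fraction, seed) {
  n_frames <- dim(epochs$data)[2]
  y <- factor(labels)
  subject <- epochs$meta$subject
  if (is.null(subject)) stop("epoch metadata must carry a `subject` column")
  pat0 <- labeled_patterns(matrix(0, length(y), 1), y, subject,
                           epochs$meta)
  keep <- seq_along(y)
  if (fraction < 1) {
    sub <- balanced_subsample(
      labeled_patterns(matrix(seq_along(y)), y, subject, epochs$meta),
      fraction, seed = seed)
    keep <- drop(sub$X)
    pat0 <- labeled_patterns(matrix(0, length(keep), 1), sub$y,
                             sub$subject, sub$meta)
  }
  dat <- epochs$data[keep, , , drop = FALSE]
  folds <- make_folds(pat0, scheme)
  acc <- array(NA_real_, c(n_frames, n_frames, length(folds)))
  for (fi in seq_along(folds)) {
    fd <- folds[[fi]]
    for (i in train_frames) {
      Xtr <- dat[fd$train, i, , drop = TRUE]
      if (is.null(dim(Xtr))) Xtr <- matrix(Xtr, nrow = length(fd$train))
      ytr <- pat0$y[fd$train]
      cols <- seq_len(ncol(Xtr))
      if (!is.null(k_select))
        cols <- anova_select(Xtr, ytr, min(k_select, ncol(Xtr)))
      m <- fit_linear_classifier(Xtr[, cols, drop = FALSE], ytr, C = C)
      for (j in test_frames_of(i)) {
        Xte <- dat[fd$test, j, , drop = TRUE]
        if (is.null(dim(Xte))) Xte <- matrix(Xte, nrow = length(fd$test))
        pred <- predict(m, Xte[, cols, drop = FALSE])
        acc[i, j, fi] <- mean(pred == pat0$y[fd$test])
      }
    }
  }
  list(acc = acc, folds = folds)
}

#' Frame-wise temporal decoding
#'
#' Trains and tests an independent classifier (linear SVM with ANOVA
#' feature selection on the training fold) at every epoch frame.
#' Significance per frame is a one-sample t test of fold accuracies
#' against 0.5, Bonferroni-corrected by `n_frames * n_rois`.
#'
#' @param epochs An `epoch_tensor`.
#' @param labels Binary label per trial (e.g. `epochs$meta$choice`).
#' @param scheme A `cv_scheme` (LOSO for between-subject, `k_fold_within`
#'   for within-subject decoding).
#' @param k_select ANOVA-selected feature count (`NULL` disables).
#' @param C SVM regularization parameter.
#' @param n_rois ROI count entering the Bonferroni family.
#' @param fraction Balanced per-subject subsampling fraction.
#' @param seed Integer seed for subsampling.
#' @param alpha Significance level applied to the Bonferroni-corrected p
#'   values.
#' @return List with `accuracy` (data frame: `frame`, `time_s`, `fold`,
#'   `subject`, `accuracy`) and `summary` (per frame: mean accuracy, `t`,
#'   `p`, `p_bonf`, `significant`).
#' @export
temporal_decode <- function(epochs, labels,
                            scheme = cv_scheme("leave_one_subject_out"),
                            k_select = 50, C = 1, n_rois = 1,
                            fraction = 1, seed = 1, alpha = 0.05) {
  n_frames <- dim(epochs$data)[2]
  eng <- frame_cv_engine(epochs, labels, scheme, seq_len(n_frames),
                         function(i) i, k_select, C, fraction, seed)
  rows <- do.call(rbind, lapply(seq_along(eng$folds), function(fi)
    data.frame(frame = seq_len(n_frames),
               time_s = epochs$frame_times_s,
               fold = eng$folds[[fi]]$fold,
               subject = eng$folds[[fi]]$subject,
               accuracy = eng$acc[cbind(seq_len(n_frames),
                                        seq_len(n_frames), fi)],
               stringsAsFactors = FALSE)))
  summ <- do.call(rbind, lapply(seq_len(n_frames), function(f) {
    a <- rows$accuracy[rows$frame == f]
    tt <- tryCatch(t.test(a, mu = 0.5),
                   error = function(e) list(statistic = 0, p.value = 1))
    data.frame(frame = f, time_s = epochs$frame_times_s[f],
               mean_accuracy = mean(a), t = unname(tt$statistic),
               p = tt$p.value,
               p_bonf = bonferroni(tt$p.value, n_frames * n_rois))
  }))
  summ$significant <- summ$p_bonf < alpha
  list(accuracy = rows, summary = summ)
}

#' Temporal generalization matrix
#'
#' Trains at every frame and tests at every frame of the held-out fold,
#' yielding a `n_frames x n_frames` accuracy matrix whose diagonal equals
#' frame-wise decoding under the same folds and seed. Cell significance is
#' a one-sample t test against 0.5 with a Bonferroni factor of
#' `n_frames^2 * n_rois` (49 cells per matrix at the default 7 frames).
#'
#' @inheritParams temporal_decode
#' @return List with `matrix` (mean accuracy, train x test), `per_fold`
#'   (train x test x fold array), `p`, `p_bonf`, `significant` matrices
#'   and `folds`.
#' @export
temporal_generalization <- function(epochs, labels,
                                    scheme = cv_scheme("k_fold_within"),
                                    k_select = 50, C = 1, n_rois = 1,
                                    fraction = 1, seed = 1,
                                    alpha = 0.05) {
  n_frames <- dim(epochs$data)[2]
  eng <- frame_cv_engine(epochs, labels, scheme, seq_len(n_frames),
                         function(i) seq_len(n_frames), k_select, C,
                         fraction, seed)
  M <- apply(eng$acc, c(1, 2), mean)
  tmat <- apply(eng$acc, c(1, 2), function(a) {
    if (sd(a) == 0) return(c(0, 1))
    tt <- t.test(a, mu = 0.5)
    c(unname(tt$statistic), tt$p.value)
  })
  p <- matrix(tmat[2, , ], n_frames, n_frames)
  p_bonf <- bonferroni(p, n_frames^2 * n_rois)
  list(matrix = M, per_fold = eng$acc, t = matrix(tmat[1, , ], n_frames),
       p = p, p_bonf = p_bonf, significant = p_bonf < alpha,
       frame_times_s = epochs$frame_times_s)
}

#' Local maxima of a decoding time course
#'
#' A frame is a peak when its value exceeds both neighbors; plateaus
#' report their first frame; endpoints are never peaks.
#'
#' @param x Numeric vector (length >= 3).
#' @return Integer indices of the peaks (1-based).
#' @export
find_peaks <- function(x) {
  if (length(x) < 3) stop("need at least 3 points")
  r <- rle(as.numeric(x))
  k <- length(r$values)
  if (k < 3) return(integer(0))
  starts <- c(1, cumsum(r$lengths)[-k] + 1)
  inner <- 2:(k - 1)
  is_peak <- r$values[inner] > r$values[inner - 1] &
    r$values[inner] > r$values[inner + 1]
  starts[inner][is_peak]
}
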