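# Condition-level GLM, execution-phase residualization, single-trial betas.

#' Build the condition design matrix for a retrieval run set
#'
#' Task regressors are HRF-convolved boxcars: up to 12 decision regressors
#' (memory status x evidence x accuracy; 1.5 s boxcar at image onset) and 4
#' execution regressors (motor response x accuracy; 1 s boxcar at the
#' go-signal). Per-run nuisance columns (intercept and linear drift) are
#' appended. Cells with no trials yield all-zero columns and are dropped
#' with a warning.
#'
#' @param schedule Observed retrieval `trial_schedule` (with `choice`,
#'   `response`, `correct`).
#' @param hrf An [make_hrf()] kernel sampled at the repetition time.
#' @param tr_s Repetition time in seconds.
#' @param run_frames Integer vector of frames per run; defaults to the
#'   schedule attribute.
#' @return A `design_matrix`: list with `X` (frames x regressors), `labels`,
#'   `role` (`"decision"`, `"execution"` or `"nuisance"`), `run_frames`,
#'   `tr_s`.
#' @export
build_condition_design <- function(schedule, hrf, tr_s = attr(schedule, "tr_s"),
                                   run_frames = attr(schedule, "run_frames")) {
  if (is.null(schedule$onset)) stop("schedule has no `onset` column")
  if (is.null(schedule$choice) || is.null(schedule$correct))
    stop("schedule has no observed choices; run simulate_observer() first")
  acc <- ifelse(schedule$correct, "correct", "incorrect")
  dec_cell <- paste("dec", schedule$memory_status, schedule$evidence, acc,
                    sep = "_")
  exe_cell <- paste("exe", schedule$response, acc, sep = "_")
  dec_levels <- as.vector(outer(
    as.vector(outer(c("old", "new"), EVIDENCE_LEVELS, paste, sep = "_")),
    c("correct", "incorrect"), paste, sep = "_"))
  dec_levels <- paste0("dec_", dec_levels)
  exe_levels <- paste0("exe_", as.vector(outer(c("eye", "hand"),
    c("correct", "incorrect"), paste, sep = "_")))
  runs <- sort(unique(schedule$run))
  stopifnot(length(run_frames) == length(runs))
  task_labels <- c(dec_levels, exe_levels)
  blocks <- lapply(seq_along(runs), function(ri) {
    sc <- schedule[schedule$run == runs[ri], , drop = FALSE]
    nf <- run_frames[ri]
    cols <- sapply(task_labels, function(lb) {
      if (startsWith(lb, "dec_")) {
        sel <- dec_cell[schedule$run == runs[ri]] == lb
        if (!any(sel)) return(numeric(nf))
        hrf_regressor(sc$onset[sel], rep(IMAGE_DURATION_S, sum(sel)),
                      rep(1, sum(sel)), nf, tr_s, hrf)
      } else {
        sel <- exe_cell[schedule$run == runs[ri]] == lb
        if (!any(sel)) return(numeric(nf))
        hrf_regressor(sc$go_onset[sel], rep(GO_DURATION_S, sum(sel)),
                      rep(1, sum(sel)), nf, tr_s, hrf)
      }
    })
    cols
  })
  task <- do.call(rbind, blocks)
  empty <- colSums(abs(task)) == 0
  if (any(empty)) {
    warning("dropping empty condition regressor(s): ",
            paste(task_labels[empty], collapse = ", "))
    task <- task[, !empty, drop = FALSE]
    task_labels <- task_labels[!empty]
  }
  nuis <- nuisance_columns(run_frames)
  X <- cbind(task, nuis$X)
  role <- c(ifelse(startsWith(task_labels, "dec_"), "decision",
                   "execution"), nuis$role)
  labels <- c(task_labels, nuis$labels)
  colnames(X) <- labels
  structure(list(X = X, labels = labels, role = role,
                 run_frames = run_frames, tr_s = tr_s),
            class = "design_matrix")
}

# Per-run intercept + linear drift, block diagonal across runs.
nuisance_columns <- function(run_frames) {
  n_runs <- length(run_frames)
  total <- sum(run_frames)
  X <- matrix(0, total, 2 * n_runs)
  labels <- character(2 * n_runs)
  offset <- 0L
  for (r in seq_len(n_runs)) {
    idx <- offset + seq_len(run_frames[r])
    X[idx, 2 * r - 1] <- 1
    X[idx, 2 * r] <- seq(-1, 1, length.out = run_frames[r])
    labels[2 * r - 1] <- sprintf("run%02d_intercept", r)
    labels[2 * r] <- sprintf("run%02d_drift", r)
    offset <- offset + run_frames[r]
  }
  list(X = X, labels = labels, role = rep("nuisance", 2 * n_runs))
}

# Stack a subject's runs into one frames x voxels matrix.
stack_runs <- function(data) {
  if (is.list(data) && !is.null(data$runs)) data <- data$runs
  if (is.list(data)) do.call(rbind, data) else data
}

#' Fit an ordinary least squares GLM
#'
#' @param data Frames x voxels matrix (or a `subject_dataset`, whose runs
#'   are stacked in order).
#' @param design A `design_matrix`.
#' @return List with `beta` (regressors x voxels), `labels`, `role`,
#'   `sigma2` (residual variance per voxel) and `df_residual`.
#' @export
fit_glm <- function(data, design) {
  Y <- stack_runs(data)
  X <- design$X
  if (nrow(Y) != nrow(X))
    stop("data has ", nrow(Y), " frames but design has ", nrow(X))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- design$labels[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, Y)
  res <- Y - X %*% beta
  dfr <- nrow(X) - ncol(X)
  list(beta = beta, labels = design$labels, role = design$role,
       sigma2 = colSums(res^2) / dfr, df_residual = dfr)
}

#' Remove execution-phase and nuisance activity from BOLD data
#'
#' Projects the data onto the orthogonal complement of the span of the
#' execution-phase and nuisance regressors, retaining decision-phase
#' activity (fitted and unfitted). The operation is an orthogonal
#' projection: it is idempotent and the residuals are exactly orthogonal
#' to every execution and nuisance column.
#'
#' @param data Frames x voxels matrix or `subject_dataset`.
#' @param design A `design_matrix` containing execution-labeled columns.
#' @return A `residual_dataset`: list with `data` (frames x voxels),
#'   `run_frames`, `tr_s`.
#' @export
residualize_execution <- function(data, design) {
  Y <- stack_runs(data)
  sel <- design$role %in% c("execution", "nuisance")
  if (!any(design$role == "execution"))
    stop("design has no execution-phase regressors")
  Q <- qr.Q(qr(design$X[, sel, drop = FALSE]))
  R <- Y - Q %*% (t(Q) %*% Y)
  structure(list(data = R, run_frames = design$run_frames,
                 tr_s = design$tr_s),
            class = "residual_dataset")
}

#' Single-trial (beta-series) estimation
#'
#' Least-squares-all: each trial receives its own HRF-convolved 1.5 s
#' boxcar regressor at image onset; execution regressors and per-run
#' nuisance columns enter as covariates; all regressors of a run are
#' estimated jointly. `method = "lss"` instead fits one model per trial
#' (target trial + a single regressor carrying all other trials).
#'
#' @param data Frames x voxels matrix or `subject_dataset`.
#' @param schedule Observed retrieval `trial_schedule`.
#' @param hrf HRF kernel sampled at the repetition time.
#' @param tr_s Repetition time (seconds).
#' @param run_frames Frames per run.
#' @param method `"lsa"` (default, all trials jointly) or `"lss"`.
#' @return A `beta_series`: list with `beta` (trials x voxels, ordered as
#'   the schedule) and `meta` (the schedule rows).
#' @export
single_trial_betas <- function(data, schedule, hrf,
                               tr_s = attr(schedule, "tr_s"),
                               run_frames = attr(schedule, "run_frames"),
                               method = c("lsa", "lss")) {
  method <- match.arg(method)
  Y <- stack_runs(data)
  runs <- sort(unique(schedule$run))
  stopifnot(length(run_frames) == length(runs))
  beta <- matrix(NA_real_, nrow(schedule), ncol(Y))
  offset <- 0L
  for (ri in seq_along(runs)) {
    nf <- run_frames[ri]
    rows <- offset + seq_len(nf)
    sel <- which(schedule$run == runs[ri])
    sc <- schedule[sel, , drop = FALSE]
    trialX <- sapply(seq_along(sel), function(i)
      hrf_regressor(sc$onset[i], IMAGE_DURATION_S, 1, nf, tr_s, hrf))
    exeX <- run_execution_columns(sc, nf, tr_s, hrf)
    nuisX <- cbind(1, seq(-1, 1, length.out = nf))
    if (method == "lsa") {
      X <- cbind(trialX, exeX, nuisX)
      qx <- qr(X)
      if (qx$rank < ncol(X))
        stop("single-trial design for run ", runs[ri], " is rank ",
             "deficient (overlapping trial regressors); consider a ridge ",
             "penalty or longer inter-trial intervals")
      b <- qr.coef(qx, Y[rows, , drop = FALSE])
      beta[sel, ] <- b[seq_along(sel), , drop = FALSE]
    } else {
      for (i in seq_along(sel)) {
        others <- rowSums(trialX[, -i, drop = FALSE])
        X <- cbind(trialX[, i], others, exeX, nuisX)
        qx <- qr(X)
        if (qx$rank < ncol(X))
          stop("single-trial design for run ", runs[ri],
               " is rank deficient")
        b <- qr.coef(qx, Y[rows, , drop = FALSE])
        beta[sel[i], ] <- b[1, ]
      }
    }
    offset <- offset + nf
  }
  structure(list(beta = beta, meta = as.data.frame(schedule),
                 tr_s = tr_s),
            class = "beta_series")
}

# Execution regressors (response x accuracy) for the trials of one run.
run_execution_columns <- function(sc, nf, tr_s, hrf) {
  if (is.null(sc$response)) return(NULL)
  acc <- ifelse(sc$correct, "correct", "incorrect")
  cells <- paste(sc$response, acc, sep = "_")
  cols <- sapply(unique(cells), function(cl) {
    sel <- cells == cl
    hrf_regressor(sc$go_onset[sel], rep(GO_DURATION_S, sum(sel)),
                  rep(1, sum(sel)), nf, tr_s, hrf)
  })
  matrix(cols, nrow = nf)
}
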