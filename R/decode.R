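# Normalization, feature selection, linear SVM, cross-validation engines.

#' Bundle patterns, labels and metadata for classification
#'
#' @param X Samples x features numeric matrix.
#' @param y Binary labels (factor or coercible; exactly two levels).
#' @param subject Subject identifier per sample.
#' @param meta Optional data frame of per-sample metadata (evidence, run,
#'   frame, ...), row-aligned with `X`.
#' @return A `labeled_patterns` list.
#' @export
labeled_patterns <- function(X, y, subject, meta = NULL) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) != 2) stop("`y` must have exactly two classes")
  stopifnot(nrow(X) == length(y), length(subject) == length(y))
  if (!is.null(meta)) stopifnot(nrow(meta) == nrow(X))
  structure(list(X = X, y = y, subject = subject, meta = meta),
            class = "labeled_patterns")
}

#' Z-score each pattern map across features
#'
#' Removes the overall activity level of every sample so that
#' classification rests on the spatial distribution of activity rather than
#' its mean amplitude: each row is centered and scaled to unit standard
#' deviation across in-mask features.
#'
#' @param X Samples x features matrix (at least two features).
#' @return Matrix of the same shape; each row has mean 0 and sd 1.
#' @export
spatial_zscore <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least 2 features to z-score a map")
  mu <- rowMeans(X)
  s <- sqrt(rowSums((X - mu)^2) / (ncol(X) - 1))
  if (any(s == 0)) stop("zero-variance pattern map; cannot z-score")
  (X - mu) / s
}

#' Detrend and z-score voxel activity across trials
#'
#' Per voxel (column): removes a linear trend over the trial sequence, then
#' scales to zero mean and unit variance. Constant voxels are set to zero
#' with a warning.
#'
#' @param B Trials x voxels matrix (at least 3 trials) or a `beta_series`.
#' @return Matrix (or `beta_series`) of the same shape.
#' @export
detrend_zscore_trials <- function(B) {
  bs <- NULL
  if (inherits(B, "beta_series")) { bs <- B; B <- B$beta }
  B <- as.matrix(B)
  n <- nrow(B)
  if (n < 3) stop("need at least 3 trials to detrend")
  t <- seq_len(n) - (n + 1) / 2
  slope <- crossprod(t, B) / sum(t^2)
  D <- B - outer(t, drop(slope))
  D <- sweep(D, 2, colMeans(D))
  s <- sqrt(colSums(D^2) / (n - 1))
  # constant (or perfectly linear) voxels leave only float dust behind
  const <- s <= 1e-10 * max(s, sqrt(mean(B^2)), 1)
  if (any(const)) {
    warning(sum(const), " constant voxel(s) set to zero")
    s[const] <- Inf
  }
  D <- sweep(D, 2, s, "/")
  if (!is.null(bs)) { bs$beta <- D; return(bs) }
  D
}

#' ANOVA (F-score) feature selection
#'
#' Ranks features by the two-class one-way ANOVA F statistic computed on
#' the training rows only and returns the indices of the `k` largest. Ties
#' break deterministically toward the lowest index. Apply only to training
#' folds: selection on held-out data biases the classification error.
#'
#' @param X_train Training samples x features.
#' @param y_train Training labels (two classes).
#' @param k Number of features to keep (`k <= ncol(X_train)`).
#' @return Integer vector of `k` feature indices, in rank order.
#' @export
anova_select <- function(X_train, y_train, k) {
  X_train <- as.matrix(X_train)
  y_train <- factor(y_train)
  if (k > ncol(X_train))
    stop("k = ", k, " exceeds the ", ncol(X_train), " available features")
  f <- f_score(X_train, y_train)
  order(-f, seq_along(f))[seq_len(k)]
}

# Vectorized per-feature one-way ANOVA F statistic (any number of groups).
f_score <- function(X, y) {
  y <- factor(y)
  n <- nrow(X)
  g <- nlevels(y)
  gm <- colMeans(X)
  ss_b <- numeric(ncol(X))
  ss_w <- numeric(ncol(X))
  for (lv in levels(y)) {
    rows <- y == lv
    m <- colMeans(X[rows, , drop = FALSE])
    ss_b <- ss_b + sum(rows) * (m - gm)^2
    ss_w <- ss_w + colSums((X[rows, , drop = FALSE] -
                              matrix(m, sum(rows), ncol(X),
                                     byrow = TRUE))^2)
  }
  (ss_b / (g - 1)) / (ss_w / (n - g))
}

#' Fit a soft-margin linear support vector machine
#'
#' Minimizes `0.5 ||w||^2 + C * sum_i hinge(1 - y_i f(x_i))` with
#' `f(x) = <w, x> + b` (intercept absorbed as a constant feature), solved
#' by deterministic dual coordinate descent. Prediction is the sign of the
#' decision value; an exact zero is assigned to the first factor level.
#'
#' @param X Samples x features matrix.
#' @param y Binary labels; the first factor level is the positive class.
#' @param C Regularization parameter (default 1).
#' @param tol Stopping tolerance on the projected-gradient gap over one
#'   epoch (the LIBLINEAR criterion). The default gives held-out
#'   accuracies indistinguishable from full convergence; tighten it (with
#'   a higher `max_epochs`) when exact weights matter.
#' @param max_epochs Maximum passes over the dual variables.
#' @return A `linear_svm`: list with `w`, `b`, `levels`, `C`, `epochs`.
#' @export
fit_linear_classifier <- function(X, y, C = 1, tol = 0.01,
                                  max_epochs = 500) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) != 2 || any(tabulate(y, 2) == 0))
    stop("training data must contain both classes")
  ypm <- ifelse(as.integer(y) == 1L, 1, -1)
  fit <- .dcd_svm_fit(X, ypm, C, 1, tol, as.integer(max_epochs))
  p <- ncol(X)
  structure(list(w = fit[seq_len(p)], b = fit[p + 1], levels = levels(y),
                 C = C, epochs = fit[p + 2]),
            class = "linear_svm")
}

#' @export
predict.linear_svm <- function(object, newdata, type = c("class",
                                                         "decision"), ...) {
  type <- match.arg(type)
  d <- drop(as.matrix(newdata) %*% object$w) + object$b
  if (type == "decision") return(d)
  factor(ifelse(d >= 0, object$levels[1], object$levels[2]),
         levels = object$levels)
}

#' Cross-validation scheme
#'
#' @param kind `"leave_one_subject_out"` (folds are whole subjects; trains
#'   on the remaining subjects) or `"k_fold_within"` (per-subject k-fold
#'   with folds grouped by contiguous runs; trains within subject).
#' @param k Fold count for the within-subject scheme (default 7).
#' @param seed Integer seed (used by subsampling when requested).
#' @export
cv_scheme <- function(kind = c("leave_one_subject_out", "k_fold_within"),
                      k = 7, seed = 1) {
  kind <- match.arg(kind)
  structure(list(kind = kind, k = k, seed = seed), class = "cv_scheme")
}

# Build folds: list of list(train = idx, test = idx, subject, fold).
make_folds <- function(patterns, scheme) {
  subj <- patterns$subject
  if (scheme$kind == "leave_one_subject_out") {
    us <- unique(subj)
    lapply(us, function(s)
      list(train = which(subj != s), test = which(subj == s),
           subject = s, fold = paste0("loso_", s)))
  } else {
    us <- unique(subj)
    out <- list()
    for (s in us) {
      idx <- which(subj == s)
      blocks <- if (!is.null(patterns$meta$run))
        patterns$meta$run[idx] else cut(seq_along(idx), scheme$k,
                                        labels = FALSE)
      ub <- sort(unique(blocks))
      if (length(ub) < scheme$k)
        stop("subject ", s, " has ", length(ub),
             " run blocks; cannot form ", scheme$k, " grouped folds")
      grp <- cut(match(blocks, ub), scheme$k, labels = FALSE)
      for (f in seq_len(scheme$k))
        out[[length(out) + 1]] <-
          list(train = idx[grp != f], test = idx[grp == f], subject = s,
               fold = paste0("s", s, "_f", f))
    }
    out
  }
}

#' Cross-validated decoding accuracy
#'
#' Per fold: optional ANOVA feature selection on the training rows, linear
#' SVM fit, accuracy on the held-out fold. No statistic ever touches the
#' test rows before prediction.
#'
#' @param patterns A `labeled_patterns`.
#' @param scheme A `cv_scheme`.
#' @param k_select Features kept by [anova_select()] per fold (`NULL`
#'   disables selection; values above the feature count select all).
#' @param C SVM regularization parameter.
#' @return Data frame (`fold`, `subject`, `n_test`, `accuracy`) with the
#'   grand mean in `attr(, "mean_accuracy")`.
#' @export
cross_validate <- function(patterns, scheme, k_select = NULL, C = 1) {
  folds <- make_folds(patterns, scheme)
  rows <- lapply(folds, function(fd) {
    ytr <- patterns$y[fd$train]
    if (length(unique(ytr)) < 2)
      stop("fold ", fd$fold, " has single-class training data")
    cols <- seq_len(ncol(patterns$X))
    if (!is.null(k_select))
      cols <- anova_select(patterns$X[fd$train, , drop = FALSE], ytr,
                           min(k_select, ncol(patterns$X)))
    m <- fit_linear_classifier(patterns$X[fd$train, cols, drop = FALSE],
                               ytr, C = C)
    pred <- predict(m, patterns$X[fd$test, cols, drop = FALSE])
    data.frame(fold = fd$fold, subject = fd$subject,
               n_test = length(fd$test),
               accuracy = mean(pred == patterns$y[fd$test]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_accuracy") <- mean(out$accuracy)
  out
}

#' Balanced per-subject trial subsampling
#'
#' Retains, independently within every subject, `fraction` of the trials
#' with exactly equal counts per class (the device used to keep
#' leave-one-subject-out searchlights tractable while balancing
#' conditions).
#'
#' @param patterns A `labeled_patterns`.
#' @param fraction Fraction of per-class trials to keep, in `(0, 1]`.
#' @param seed Integer seed.
#' @return A `labeled_patterns` restricted to the sampled rows.
#' @export
balanced_subsample <- function(patterns, fraction, seed = 1) {
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]")
  if (fraction == 1) return(patterns)
  keep <- with_seed(seed, {
    unlist(lapply(unique(patterns$subject), function(s) {
      idx <- which(patterns$subject == s)
      per_class <- split(idx, patterns$y[idx])
      n_keep <- floor(fraction * min(lengths(per_class)))
      if (n_keep < 1)
        stop("subject ", s, ": classes too small to retain a balanced ",
             "subsample at fraction ", fraction)
      unlist(lapply(per_class, function(ix) sort(sample(ix, n_keep))))
    }))
  })
  keep <- sort(keep)
  labeled_patterns(patterns$X[keep, , drop = FALSE], patterns$y[keep],
                   patterns$subject[keep],
                   if (!is.null(patterns$meta))
                     patterns$meta[keep, , drop = FALSE])
}
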