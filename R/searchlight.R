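# Searchlight decoding, group-level maps, FDR and cluster thresholding.

#' Integer voxel offsets of a searchlight sphere
#'
#' All integer offsets with Euclidean norm at most `radius`; radius 3
#' yields 123 offsets (hence "up to 123 voxels per sphere" once clipped at
#' mask edges). Includes the origin and is symmetric under negation.
#'
#' @param radius Sphere radius in voxels (non-negative).
#' @return Integer matrix, offsets x 3.
#' @export
sphere_offsets <- function(radius) {
  if (radius < 0) stop("`radius` must be non-negative")
  r <- floor(radius)
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  g[rowSums(g^2) <= radius^2, , drop = FALSE]
}

#' Between-subject searchlight decoding
#'
#' For every in-mask center, decodes the trial labels from the sphere's
#' in-mask voxels with a linear SVM under leave-one-subject-out
#' cross-validation and writes the held-out accuracy of each subject at the
#' center. Input beta series are first z-scored per trial map across all
#' in-mask voxels, then detrended and z-scored per voxel across trials;
#' each subject's trials are then subsampled to a balanced fraction. No
#' feature selection is applied at the searchlight stage.
#'
#' @param betas List (one per subject) of `beta_series` or trials x voxels
#'   matrices over the in-mask voxels of `grid`.
#' @param labels List of per-subject binary label vectors (or the name of a
#'   metadata column when `betas` are `beta_series`).
#' @param grid A `volume_grid` shared by all subjects.
#' @param radius Sphere radius in voxels.
#' @param fraction Balanced per-subject subsampling fraction.
#' @param seed Integer seed for the subsampling.
#' @param C SVM regularization parameter.
#' @param centers Optional subset of in-mask voxel indices to evaluate
#'   (default all).
#' @return An `accuracy_map`: list with `acc` (centers x subjects, `NA` at
#'   unevaluated centers), `centers`, `subjects`, `grid`.
#' @export
run_searchlight <- function(betas, labels, grid, radius = 3,
                            fraction = 0.5, seed = 1, C = 1,
                            centers = NULL) {
  V <- n_voxels(grid)
  n_sub <- length(betas)
  mats <- lapply(betas, function(b) if (inherits(b, "beta_series"))
    b$beta else as.matrix(b))
  if (is.character(labels) && length(labels) == 1) {
    col <- labels
    labels <- lapply(betas, function(b) b$meta[[col]])
  }
  stopifnot(length(labels) == n_sub,
            all(vapply(mats, ncol, 1L) == V))
  # preprocessing: map-wise z-score, then trial-wise detrend + z-score
  mats <- lapply(mats, function(m)
    detrend_zscore_trials(spatial_zscore(m)))
  X <- do.call(rbind, mats)
  y <- factor(unlist(lapply(labels, as.character)))
  subject <- rep(seq_len(n_sub), vapply(mats, nrow, 1L))
  pat <- labeled_patterns(X, y, subject)
  pat <- balanced_subsample(pat, fraction, seed = seed)
  if (is.null(centers)) centers <- seq_len(V)
  off <- sphere_offsets(radius)
  acc <- matrix(NA_real_, V, n_sub)
  folds <- make_folds(pat, cv_scheme("leave_one_subject_out"))
  for (v in centers) {
    pts <- grid$coords[rep(v, nrow(off)), , drop = FALSE] + off
    ok <- pts[, 1] >= 1 & pts[, 1] <= grid$dims[1] &
      pts[, 2] >= 1 & pts[, 2] <= grid$dims[2] &
      pts[, 3] >= 1 & pts[, 3] <= grid$dims[3]
    feat <- grid$vol_index[pts[ok, , drop = FALSE]]
    feat <- feat[feat > 0]
    if (!length(feat)) {
      message("empty sphere at center ", v, "; skipped")
      next
    }
    Xs <- pat$X[, feat, drop = FALSE]
    for (fi in seq_along(folds)) {
      fd <- folds[[fi]]
      m <- fit_linear_classifier(Xs[fd$train, , drop = FALSE],
                                 pat$y[fd$train], C = C)
      pred <- predict(m, Xs[fd$test, , drop = FALSE])
      acc[v, fd$subject] <- mean(pred == pat$y[fd$test])
    }
  }
  structure(list(acc = acc, centers = centers,
                 subjects = seq_len(n_sub), grid = grid),
            class = "accuracy_map")
}

#' Dilate a voxel set to the searchlight's spatial resolution
#'
#' All in-mask voxels within `radius` (Euclidean, voxels) of the set. A
#' searchlight map localizes signal at sphere-radius resolution: every
#' center whose sphere touches an informative site can decode, so a
#' recovered cluster is expected to match the site's dilated footprint.
#'
#' @param voxels In-mask voxel indices.
#' @param grid A `volume_grid`.
#' @param radius Dilation radius in voxels.
#' @return Integer in-mask voxel indices of the dilated set.
#' @export
dilate_voxels <- function(voxels, grid, radius) {
  off <- sphere_offsets(radius)
  pts <- grid$coords[rep(voxels, each = nrow(off)), , drop = FALSE] +
    off[rep(seq_len(nrow(off)), length(voxels)), , drop = FALSE]
  ok <- pts[, 1] >= 1 & pts[, 1] <= grid$dims[1] &
    pts[, 2] >= 1 & pts[, 2] <= grid$dims[2] &
    pts[, 3] >= 1 & pts[, 3] <= grid$dims[3]
  idx <- grid$vol_index[pts[ok, , drop = FALSE]]
  sort(unique(idx[idx > 0]))
}

#' Voxelwise t test of decoding accuracy against chance
#'
#' One-sample t statistic of the per-subject accuracies against 0.5 at
#' every evaluated center, with two-sided p values. Zero-variance voxels
#' get `t = 0`, `p = 1` and are flagged.
#'
#' @param map An `accuracy_map` (needs at least 3 subjects).
#' @return List with vectors `t`, `p`, `flag_zero_var` over in-mask voxels
#'   (`NA` at unevaluated centers).
#' @export
group_test_vs_chance <- function(map) {
  A <- map$acc
  n <- ncol(A)
  if (n < 3) stop("need at least 3 subjects")
  m <- rowMeans(A)
  s <- apply(A, 1, sd)
  t <- (m - 0.5) / (s / sqrt(n))
  p <- 2 * pt(-abs(t), n - 1)
  zero <- !is.na(s) & s == 0
  t[zero] <- 0
  p[zero] <- 1
  list(t = t, p = p, df = n - 1, flag_zero_var = zero)
}

#' Benjamini-Hochberg FDR mask
#'
#' Step-up false-discovery-rate control at level `alpha` over the supplied
#' p values (`NA`s excluded from the family and never selected).
#'
#' @param p Vector of p values in `[0, 1]`.
#' @param alpha FDR level (default 0.01).
#' @return Logical vector: `TRUE` where the voxel survives.
#' @export
fdr_mask <- function(p, alpha = 0.01) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p values must lie in [0, 1]")
  out <- rep(FALSE, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH") <= alpha
  out
}

#' Cluster a significance mask into ROIs
#'
#' Labels connected components (6-connectivity by default) of the mask and
#' retains clusters of at least `min_size` voxels, sorted by size
#' descending.
#'
#' @param mask Logical vector over in-mask voxels (or logical array of the
#'   grid's dimensions).
#' @param grid A `volume_grid`.
#' @param min_size Minimum cluster extent in voxels.
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (full cube).
#' @param stat Optional statistic per in-mask voxel (e.g. mean accuracy)
#'   used to report each cluster's peak.
#' @return A `roi_set`: list with `labels` (integer per in-mask voxel, 0
#'   outside any ROI) and `table` (`label`, `size`, `peak_voxel`,
#'   `peak_value`).
#' @export
cluster_rois <- function(mask, grid, min_size = 50, connectivity = 6,
                         stat = NULL) {
  if (is.array(mask)) mask <- mask[grid$in_mask]
  mask[is.na(mask)] <- FALSE
  V <- n_voxels(grid)
  stopifnot(length(mask) == V)
  labels <- integer(V)
  tab <- data.frame(label = integer(0), size = integer(0),
                    peak_voxel = integer(0), peak_value = numeric(0))
  on_idx <- which(mask)
  if (length(on_idx)) {
    off <- switch(as.character(connectivity),
      "6" = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1)),
      "18" = { o <- sphere_offsets(sqrt(2)); o[rowSums(o^2) > 0, ] },
      "26" = { o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
               o[rowSums(o^2) > 0, ] },
      stop("`connectivity` must be 6, 18 or 26"))
    # adjacency among active voxels via the voxel-index volume
    active <- array(0L, grid$dims)
    active[grid$in_mask[on_idx]] <- seq_along(on_idx)
    edges <- NULL
    co <- grid$coords[on_idx, , drop = FALSE]
    for (k in seq_len(nrow(off))) {
      nb <- co + matrix(off[k, ], nrow(co), 3, byrow = TRUE)
      ok <- nb[, 1] >= 1 & nb[, 1] <= grid$dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= grid$dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= grid$dims[3]
      tgt <- integer(nrow(co))
      tgt[ok] <- active[nb[ok, , drop = FALSE]]
      has <- which(tgt > 0 & seq_along(tgt) < tgt)
      if (length(has)) edges <- rbind(edges, cbind(has, tgt[has]))
    }
    g <- igraph::make_empty_graph(n = length(on_idx), directed = FALSE)
    if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
    comp <- igraph::components(g)
    sizes <- tabulate(comp$membership)
    keep <- which(sizes >= min_size)
    keep <- keep[order(sizes[keep], decreasing = TRUE)]
    for (i in seq_along(keep)) {
      vox <- on_idx[comp$membership == keep[i]]
      labels[vox] <- i
      pk_v <- NA_integer_; pk_x <- NA_real_
      if (!is.null(stat)) {
        pk_v <- vox[which.max(stat[vox])]
        pk_x <- max(stat[vox], na.rm = TRUE)
      }
      tab <- rbind(tab, data.frame(label = i, size = length(vox),
                                   peak_voxel = pk_v, peak_value = pk_x))
    }
  }
  structure(list(labels = labels, table = tab, grid = grid),
            class = "roi_set")
}
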