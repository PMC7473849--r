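# Independent brute-force oracles shared across test files. Each one is
# deliberately written against the mathematical definition, not the
# package's algorithmic path.

# Projected-gradient solver for the dual of the soft-margin linear SVM
# with the intercept absorbed as a constant feature.
qp_svm_oracle <- function(X, y, C, iters = 2e5) {
  Xa <- cbind(X, 1)
  ypm <- ifelse(y == levels(factor(y))[1], 1, -1)
  K <- (Xa %*% t(Xa)) * (ypm %o% ypm)
  n <- nrow(Xa)
  alpha <- rep(0, n)
  eta <- 1 / max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  for (i in seq_len(iters)) {
    grad <- K %*% alpha - 1
    alpha <- pmin(pmax(alpha - eta * grad, 0), C)
  }
  w <- drop(t(Xa) %*% (alpha * ypm))
  list(w = w[-length(w)], b = w[length(w)])
}

# Benjamini-Hochberg step-up by direct definition: sort, compare each
# p(i) with i * alpha / m, keep everything up to the largest passer.
bh_brute <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  passing <- which(p[o] <= seq_len(m) * alpha / m)
  keep <- rep(FALSE, m)
  if (length(passing)) keep[o[seq_len(max(passing))]] <- TRUE
  keep
}

# Recursive flood-fill 6-connectivity component labeling over in-mask
# voxels, using a coordinate hash.
floodfill_oracle <- function(mask, grid) {
  lab <- integer(length(mask))
  nxt <- 0L
  coord_of <- grid$coords
  key <- function(p) paste(p, collapse = ",")
  idx_by_key <- new.env()
  for (i in which(mask)) assign(key(coord_of[i, ]), i, envir = idx_by_key)
  for (i in which(mask)) {
    if (lab[i] > 0) next
    nxt <- nxt + 1L
    stack <- i
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[v] > 0) next
      lab[v] <- nxt
      for (d in 1:3) for (s in c(-1L, 1L)) {
        p <- coord_of[v, ]; p[d] <- p[d] + s
        k <- key(p)
        if (exists(k, envir = idx_by_key, inherits = FALSE)) {
          nb <- get(k, envir = idx_by_key)
          if (lab[nb] == 0) stack <- c(stack, nb)
        }
      }
    }
  }
  lab
}

# Exhaustive neighbor-comparison peak finder (plateau -> first index).
peaks_brute <- function(x) {
  out <- integer(0)
  for (i in 2:(length(x) - 1)) {
    l <- i - 1
    while (l > 1 && x[l] == x[i]) l <- l - 1
    r <- i + 1
    while (r < length(x) && x[r] == x[i]) r <- r + 1
    if (x[i] > x[l] && x[i] > x[r] && x[i - 1] != x[i])
      out <- c(out, i)
  }
  out
}

# Simulate a regional-accuracy table with known per-level means, subject
# random intercepts and binomial measurement noise at n_test trials.
sim_accuracy_rows <- function(level_means, n_subjects = 24,
                              subject_sd = 0.04, n_test = 60, seed = 1) {
  withr::with_seed(seed, {
    u <- rnorm(n_subjects, 0, subject_sd)
    do.call(rbind, lapply(seq_along(level_means), function(l) {
      p <- pmin(pmax(level_means[l] + u, 0.02), 0.98)
      data.frame(roi = "r", label_set = "choice",
                 evidence = c("low", "middle", "high")[l],
                 subject = seq_len(n_subjects),
                 accuracy = rbinom(n_subjects, n_test, p) / n_test)
    }))
  })
}
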