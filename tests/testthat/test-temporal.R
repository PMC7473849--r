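# Epoch extraction, frame-wise decoding, generalization, peak finding.

test_that("epochs have the requested shape, carry HRF-lagged signal at
           frames 3-4, and shift with onsets", {
  g <- volume_grid(c(8, 8, 8))
  sc <- tiny_schedule(10, seed = 51)
  tr <- attr(sc, "tr_s")
  hrf <- make_hrf(dt_s = tr)
  design <- assign_groups(2, seed = 1)[1, ]
  sp <- pattern_spec("p", voxels = 1:4, weights = rep(1, 4),
                     driver = "choice", amplitude = 1, duration_s = 2)
  sub <- simulate_subject(design, sc, list(sp), noiseless(), hrf, g,
                          seed = 1)
  d <- suppressWarnings(build_condition_design(sc, hrf))
  res <- residualize_execution(sub, d)
  ep <- extract_epochs(res, sc, 1:4, n_frames = 7)
  expect_equal(dim(ep$data), c(60, 7, 4))
  expect_equal(ep$frame_times_s, (0:6) * tr)
  # signed mean epoch peaks where the HRF-convolved boxcar peaks
  # (~4-6 s after onset, i.e. frame 3 or 4 at this TR)
  signed <- ep$data[, , 1] * ifelse(ep$meta$choice == "old", 1, -1)
  expect_true(which.max(colMeans(signed)) %in% 3:4)
  # shifting every onset one TR later shifts the epoch content one frame
  sc2 <- sc
  sc2$onset <- sc$onset + tr
  sc2$go_onset <- sc$go_onset + tr
  ep2 <- extract_epochs(res, sc2, 1:4, n_frames = 6)
  expect_equal(ep2$data[, 1:6, ], ep$data[, 2:7, ], tolerance = 1e-12)
})

test_that("trials without enough frames before run end are dropped", {
  g <- volume_grid(c(8, 8, 8))
  sc <- tiny_schedule(10, seed = 52)
  res <- structure(list(
    data = matrix(0, sum(attr(sc, "run_frames")), n_voxels(g)),
    run_frames = attr(sc, "run_frames"), tr_s = attr(sc, "tr_s")),
    class = "residual_dataset")
  expect_message(ep <- extract_epochs(res, sc, 1:3, n_frames = 20),
                 "dropping")
  expect_lt(dim(ep$data)[1], nrow(sc))
})

test_that("temporal decoding is flat at chance on noise epochs with no
           significant frames", {
  set.seed(53)
  n_tr <- 40; n_sub <- 6
  meta <- data.frame(subject = rep(seq_len(n_sub), each = n_tr),
                     run = rep(rep(1:4, each = 10), n_sub))
  ep <- structure(list(
    data = array(rnorm(n_sub * n_tr * 7 * 10),
                 c(n_sub * n_tr, 7, 10)),
    meta = meta, frame_times_s = (0:6) * 1.914, tr_s = 1.914),
    class = "epoch_tensor")
  y <- factor(rep(rep(c("old", "new"), n_tr / 2), n_sub))
  td <- temporal_decode(ep, y, cv_scheme("leave_one_subject_out"),
                        k_select = 5)
  expect_true(all(abs(td$summary$mean_accuracy - 0.5) < 0.15))
  expect_false(any(td$summary$significant))
})

test_that("planted early choice and late action patterns dissociate in
           between-subject frame-wise decoding", {
  g <- volume_grid(c(10, 10, 10))
  specs <- tiny_suite(g, site_voxels = 12)
  co <- simulate_cohort(6, g, specs, noise_model(), n_categories = 10,
                        seed = 61)
  residuals <- cohort_residuals(co)
  ep_c <- cohort_epochs(co, residuals, specs$choice$voxels)
  ep_a <- cohort_epochs(co, residuals, specs$action$voxels)
  td_c <- temporal_decode(ep_c, ep_c$meta$choice,
                          cv_scheme("leave_one_subject_out"),
                          k_select = 12)
  td_a <- temporal_decode(ep_a, ep_a$meta$response,
                          cv_scheme("leave_one_subject_out"),
                          k_select = 12)
  peak_c <- which.max(td_c$summary$mean_accuracy)
  peak_a <- which.max(td_a$summary$mean_accuracy)
  expect_lt(peak_c, peak_a)      # choice peaks before action
  expect_gt(td_c$summary$mean_accuracy[peak_c], 0.75)
  expect_gt(td_a$summary$mean_accuracy[peak_a], 0.75)
  # choice is transient: decays well below peak by the last frame
  expect_lt(td_c$summary$mean_accuracy[7],
            td_c$summary$mean_accuracy[peak_c] - 0.15)
  # action rises only late: near chance over the early frames
  expect_lt(max(td_a$summary$mean_accuracy[1:3]), 0.65)
})

test_that("within-subject decoding shows the late association elevation
           that both between-subject label sets lack", {
  g <- volume_grid(c(10, 10, 10))
  specs <- tiny_suite(g, site_voxels = 12)
  late <- 6:7
  # aggregate per-subject late accuracies over three small cohorts: a
  # single 6-subject draw is dominated by random code alignments
  win <- NULL; ch <- NULL; rs <- NULL
  for (sd0 in 1:3) {
    co <- simulate_cohort(6, g, specs, noise_model(),
                          n_categories = 10, seed = 620 + sd0)
    residuals <- cohort_residuals(co)
    ep <- cohort_epochs(co, residuals, specs$association$voxels)
    per_sub_late <- function(td) {
      a <- td$accuracy[td$accuracy$frame %in% late, ]
      tapply(a$accuracy, a$subject, mean)
    }
    win <- c(win, per_sub_late(temporal_decode(ep, ep$meta$choice,
      cv_scheme("k_fold_within", k = 2), k_select = 12)))
    ch <- c(ch, per_sub_late(temporal_decode(ep, ep$meta$choice,
      cv_scheme("leave_one_subject_out"), k_select = 12)))
    rs <- c(rs, per_sub_late(temporal_decode(ep, ep$meta$response,
      cv_scheme("leave_one_subject_out"), k_select = 12)))
  }
  expect_gt(mean(win), 0.8)
  # neither between-subject decoder generalizes positively: the subject
  # mean stays within 3 subject-level SEs of chance (idiosyncratic codes
  # scatter per-subject accuracies around or below 0.5)
  for (acc in list(ch, rs)) {
    expect_lt(mean(acc), 0.5 + 3 * sd(acc) / sqrt(length(acc)))
    expect_gt(mean(win), mean(acc) + 0.2)
  }
})

test_that("choice decodability emerges before action decodability in
           nearly all seeded cohorts", {
  g <- volume_grid(c(10, 10, 10))
  specs <- tiny_suite(g, site_voxels = 12, amplitude = 1)
  first_decodable <- function(acc) {
    hit <- which(acc > 0.55)
    if (length(hit)) hit[1] else Inf
  }
  ordered <- vapply(1:20, function(i) {
    co <- simulate_cohort(6, g, specs, noise_model(), n_categories = 10,
                          seed = 800 + i)
    residuals <- cohort_residuals(co)
    ep_c <- cohort_epochs(co, residuals, specs$choice$voxels)
    ep_a <- cohort_epochs(co, residuals, specs$action$voxels)
    loso <- cv_scheme("leave_one_subject_out")
    f_c <- first_decodable(temporal_decode(ep_c, ep_c$meta$choice, loso,
      k_select = 12)$summary$mean_accuracy)
    f_a <- first_decodable(temporal_decode(ep_a, ep_a$meta$response,
      loso, k_select = 12)$summary$mean_accuracy)
    f_c < f_a
  }, logical(1))
  expect_gte(mean(ordered), 0.9)
})

test_that("the generalization matrix is square with a diagonal identical
           to frame-wise decoding under shared folds", {
  set.seed(63)
  n_tr <- 28; n_sub <- 4
  meta <- data.frame(subject = rep(seq_len(n_sub), each = n_tr),
                     run = rep(rep(1:7, each = 4), n_sub))
  y <- factor(rep(rep(c("old", "new"), n_tr / 2), n_sub))
  sig <- ifelse(y == "old", 1, -1)
  dat <- array(rnorm(n_sub * n_tr * 7 * 6, sd = 0.7),
               c(n_sub * n_tr, 7, 6))
  # orthogonal codes active at frames 2-3 vs 5-6
  dat[, 2:3, 1] <- dat[, 2:3, 1] + sig
  dat[, 5:6, 2] <- dat[, 5:6, 2] + sig
  ep <- structure(list(data = dat, meta = meta,
                       frame_times_s = (0:6) * 1.914, tr_s = 1.914),
                  class = "epoch_tensor")
  sch <- cv_scheme("k_fold_within", k = 7)
  tg <- temporal_generalization(ep, y, sch, k_select = 6)
  td <- temporal_decode(ep, y, sch, k_select = 6)
  expect_equal(dim(tg$matrix), c(7, 7))
  expect_equal(diag(tg$matrix), td$summary$mean_accuracy,
               tolerance = 1e-12)
  # on-block high, off-block generalization at chance
  expect_gt(mean(tg$matrix[cbind(c(2, 3, 5, 6), c(2, 3, 5, 6))]), 0.75)
  off <- c(tg$matrix[2, 5], tg$matrix[2, 6], tg$matrix[3, 5],
           tg$matrix[3, 6], tg$matrix[5, 2], tg$matrix[6, 3])
  expect_lt(max(abs(off - 0.5)), 0.15)
})

test_that("peak finding matches exhaustive neighbor comparison and the
           documented conventions", {
  expect_equal(find_peaks(c(.5, .7, .5, .5, .6, .8, .6)), c(2, 6))
  expect_equal(find_peaks(1:10), integer(0))
  expect_equal(find_peaks(10:1), integer(0))
  # plateau reports its first index
  expect_equal(find_peaks(c(0, 1, 1, 0)), 2)
  expect_error(find_peaks(c(1, 2)), "3 points")
  set.seed(64)
  for (i in 1:25) {
    x <- sample(1:5, 12, replace = TRUE)
    expect_equal(find_peaks(x), peaks_brute(x))
  }
})
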