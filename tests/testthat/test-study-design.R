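# Trial schedules, counterbalancing, observer and behavioral ANOVA.

test_that("encoding schedule has exact repetition structure", {
  sc <- build_encoding_schedule(60, 15, seed = 4)
  expect_equal(nrow(sc), 600)
  expect_equal(length(unique(sc$image_id)), 240)
  reps <- table(sc$image_id)
  role <- sub(".*_", "", names(reps))
  expect_true(all(reps[role == "1x"] == 1))
  expect_true(all(reps[role == "EO"] == 1))
  expect_true(all(reps[role == "3x"] == 3))
  expect_true(all(reps[role == "5x"] == 5))
  comp <- table(sc$block, sc$stimulus_type)
  expect_true(all(comp[, "1x"] == 4) && all(comp[, "EO"] == 4) &&
                all(comp[, "3x"] == 12) && all(comp[, "5x"] == 20))
})

test_that("encoding schedule scales, is seeded, rejects bad block counts", {
  sc <- build_encoding_schedule(2, 1, seed = 0)
  expect_equal(nrow(sc), 20)  # 2 categories x (1 + 1 + 3 + 5)
  expect_equal(as.vector(table(sc$stimulus_type)[c("1x", "EO", "3x", "5x")]),
               c(2, 2, 6, 10))
  expect_identical(sc, build_encoding_schedule(2, 1, seed = 0))
  expect_false(identical(sc$image_id,
                         build_encoding_schedule(2, 1, seed = 1)$image_id))
  expect_error(build_encoding_schedule(60, 14), "divide")
  expect_error(build_encoding_schedule(59, 1), "even")
})

test_that("retrieval schedule has the exact factor and run structure", {
  sc <- build_retrieval_schedule(60, seed = 2)
  expect_equal(nrow(sc), 360)
  expect_equal(sum(sc$memory_status == "old"), 180)
  expect_equal(sum(sc$memory_status == "new"), 180)
  expect_equal(length(unique(sc$run)), 12)
  expect_true(all(table(sc$run) == 30))
  expect_true(all(table(sc$run, sc$stimulus_type) == 5))
  # 60 trials per status x evidence cell
  expect_true(all(table(sc$memory_status, sc$evidence) == 60))
  # stimulus type -> (status, evidence) map is fixed
  map <- unique(sc[, c("stimulus_type", "memory_status", "evidence")])
  map <- map[order(map$stimulus_type), ]
  expect_equal(map$memory_status[map$stimulus_type %in%
                                   c("1x", "3x", "5x")], rep("old", 3))
  expect_equal(map$evidence[match(c("1x", "3x", "5x", "SPR", "SR", "U"),
                                  map$stimulus_type)],
               c("low", "middle", "high", "low", "middle", "high"))
  # target side balanced within run; ITIs within 2-4 frames
  expect_true(all(table(sc$run, sc$target_side) == 15))
  expect_true(all(sc$iti_frames %in% 2:4))
  # timing: onsets increment by image + delay + go + ITI
  r1 <- sc[sc$run == 1, ]
  expect_equal(diff(r1$onset),
               (10.5 + r1$iti_frames * attr(sc, "tr_s"))[-nrow(r1)])
  expect_identical(sc, build_retrieval_schedule(60, seed = 2))
  expect_error(build_retrieval_schedule(12), "multiple of 10")
})

test_that("group assignment is balanced with exactly reversed mappings", {
  d <- assign_groups(24, seed = 7)
  expect_equal(sum(d$group == "A1"), 12)
  expect_equal(sum(d$group == "A2"), 12)
  a1 <- d[d$group == "A1", ]; a2 <- d[d$group == "A2", ]
  expect_true(all(a1$old_response == "eye" & a1$new_response == "hand"))
  expect_true(all(a2$old_response == "hand" & a2$new_response == "eye"))
  expect_true(all(d$old_response != d$new_response))
  d2 <- assign_groups(2, seed = 1)
  expect_setequal(d2$group, c("A1", "A2"))
  expect_error(assign_groups(7), "even")
})

test_that("within a subject choice and response are collinear, but pooled
           across the counterbalanced cohort they are independent", {
  designs <- assign_groups(8, seed = 3)
  schedules <- lapply(1:8, function(i)
    simulate_observer(build_retrieval_schedule(10, seed = i),
                      designs[i, ], seed = 100 + i))
  for (sc in schedules)
    expect_true(all(table(sc$choice, sc$response) %in%
                      c(0, table(sc$choice))))
  pooled <- do.call(rbind, lapply(schedules, as.data.frame))
  ch <- as.integer(pooled$choice == "old")
  rs <- as.integer(pooled$response == "eye")
  # exact independence by construction: each group contributes the
  # opposite mapping with equal weight
  tab <- table(pooled$choice, pooled$response)
  expect_lt(abs(cor(ch, rs)), 0.1)
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.001)
})

test_that("observer converges to its generating accuracy table", {
  design <- assign_groups(2, seed = 1)[1, ]
  # deterministic extremes
  sc <- build_retrieval_schedule(10, seed = 5)
  all_right <- simulate_observer(sc, design,
    matrix(1, 2, 3, dimnames = dimnames(default_p_correct())), seed = 1)
  expect_true(all(all_right$choice == all_right$memory_status))
  expect_true(all(all_right$correct))
  # Monte-Carlo recovery of the default table at >= 1e4 trials
  p <- default_p_correct()
  big <- do.call(rbind, lapply(1:30, function(i)
    as.data.frame(simulate_observer(build_retrieval_schedule(10, seed = i),
                                    design, p, seed = 1000 + i))))
  acc <- tapply(big$correct, list(big$memory_status, big$evidence), mean)
  n_cell <- table(big$memory_status, big$evidence)
  for (st in rownames(p)) for (ev in colnames(p)) {
    se <- sqrt(p[st, ev] * (1 - p[st, ev]) / n_cell[st, ev])
    expect_lt(abs(acc[st, ev] - p[st, ev]), 3 * se + 1e-12)
  }
  expect_error(simulate_observer(sc, design, p * 2), "\\[0, 1\\]")
})

# Brute-force split-plot ANOVA oracle: balanced means-based sums of
# squares for a 2 (between, group) x 2 (status) x 3 (evidence) design
# with n subjects, computed directly from cell means.
splitplot_oracle <- function(tab) {
  n <- length(unique(tab$subject_id))
  m <- function(...) tapply(tab$accuracy, list(...), mean)
  mu <- mean(tab$accuracy)
  a <- m(tab$group); b <- m(tab$memory_status); cc <- m(tab$evidence)
  ms <- m(tab$subject_id)
  gs <- tapply(as.character(tab$group), tab$subject_id, `[`, 1)
  ab <- m(tab$group, tab$memory_status)
  ac <- m(tab$group, tab$evidence)
  bc <- m(tab$memory_status, tab$evidence)
  sb <- m(tab$subject_id, tab$memory_status)
  sc <- m(tab$subject_id, tab$evidence)
  ss_a <- 3 * n * sum((a - mu)^2)
  ss_sub_a <- 6 * sum((ms - a[gs])^2)
  ss_b <- 3 * n * sum((b - mu)^2)
  ss_ab <- (3 * n / 2) * sum((sweep(sweep(ab, 1, a), 2, b) + mu)^2)
  ss_b_err <- 3 * sum((sb - ms %o% rep(1, 2) -
                         ab[gs, ] + a[gs] %o% rep(1, 2))^2)
  ss_c <- 2 * n * sum((cc - mu)^2)
  ss_ac <- n * sum((sweep(sweep(ac, 1, a), 2, cc) + mu)^2)
  ss_c_err <- 2 * sum((sc - ms %o% rep(1, 3) -
                         ac[gs, ] + a[gs] %o% rep(1, 3))^2)
  ss_bc <- n * sum((sweep(sweep(bc, 1, b), 2, cc) + mu)^2)
  abc <- m(tab$group, tab$memory_status, tab$evidence)
  r3 <- abc
  for (i in 1:2) for (j in 1:2) for (k in 1:3)
    r3[i, j, k] <- abc[i, j, k] - ab[i, j] - ac[i, k] -
      bc[dimnames(abc)[[2]][j], dimnames(abc)[[3]][k]] +
      a[i] + b[j] + cc[k] - mu
  ss_abc <- (n / 2) * sum(r3^2)
  ss_tot <- sum((tab$accuracy - mu)^2)
  ss_bc_err <- ss_tot - ss_a - ss_sub_a - ss_b - ss_ab - ss_b_err -
    ss_c - ss_ac - ss_c_err - ss_bc - ss_abc
  list(
    F_group = (ss_a / 1) / (ss_sub_a / (n - 2)),
    F_status = (ss_b / 1) / (ss_b_err / (n - 2)),
    F_evidence = (ss_c / 2) / (ss_c_err / (2 * (n - 2))),
    F_status_evidence = (ss_bc / 2) / (ss_bc_err / (2 * (n - 2))))
}

test_that("mixed ANOVA matches a brute-force split-plot oracle and
           recovers planted effects", {
  set.seed(42)
  # 4-subject toy, arbitrary values
  toy <- expand.grid(subject_id = 1:4, memory_status = c("old", "new"),
                     evidence = c("low", "middle", "high"))
  toy$group <- ifelse(toy$subject_id <= 2, "A1", "A2")
  toy$accuracy <- round(runif(nrow(toy)), 3)
  res <- mixed_anova(toy)
  orc <- splitplot_oracle(toy)
  expect_equal(res$F[res$effect == "group"], orc$F_group, tolerance = 1e-8)
  expect_equal(res$F[res$effect == "status"], orc$F_status,
               tolerance = 1e-8)
  expect_equal(res$F[res$effect == "evidence"], orc$F_evidence,
               tolerance = 1e-8)
  expect_equal(res$F[res$effect == "status:evidence"],
               orc$F_status_evidence, tolerance = 1e-8)
  # planted pure evidence effect, no group effect, n = 24
  designs <- assign_groups(24, seed = 11)
  schedules <- lapply(1:24, function(i)
    simulate_observer(build_retrieval_schedule(10, seed = i),
                      designs[i, ], seed = 500 + i))
  tab <- behavioral_table(schedules, designs)
  res2 <- mixed_anova(tab)
  expect_gt(res2$F[res2$effect == "evidence"], 10)
  expect_lt(res2$p[res2$effect == "evidence"], 0.001)
  expect_gt(res2$p[res2$effect == "group"], 0.05)
  # unbalanced tables are rejected
  expect_error(mixed_anova(tab[-1, ]), "balanced")
  # all cells identical: every effect F collapses to 0
  const <- toy
  const$accuracy <- 0.7
  res_const <- mixed_anova(const)
  expect_true(all(res_const$F == 0))
})
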