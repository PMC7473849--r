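# Trial schedules, group counterbalancing, behavioral observer and ANOVA.

# Fixed mapping from retrieval stimulus type to memory status and evidence
# level. Old items gain evidence with encoding repetitions (1x < 3x < 5x);
# new items gain evidence with lure distinctiveness (SPR < SR < U).
STIMULUS_MAP <- data.frame(
  stimulus_type = c("1x", "3x", "5x", "SPR", "SR", "U"),
  memory_status = c("old", "old", "old", "new", "new", "new"),
  evidence      = c("low", "middle", "high", "low", "middle", "high"),
  stringsAsFactors = FALSE
)

EVIDENCE_LEVELS <- c("low", "middle", "high")

# Timing constants (seconds unless noted): image presentation, pre-go delay,
# go-signal/execution window, and the default repetition time.
IMAGE_DURATION_S <- 1.5
DELAY_S <- 8
GO_DURATION_S <- 1
DEFAULT_TR_S <- 1.914
ITI_FRAMES <- 2:4           # inter-trial interval, uniform over 2-4 frames
RUN_TAIL_S <- 12            # post-trial padding so the HRF can decay

new_trial_schedule <- function(df, session, tr_s = DEFAULT_TR_S,
                               run_frames = NULL) {
  structure(df, class = c("trial_schedule", "data.frame"),
            session = session, tr_s = tr_s, run_frames = run_frames)
}

#' Build an encoding-session schedule
#'
#' Each stimulus category contributes four images with fixed repetition
#' roles: one shown once (`1x`), one shown once and used only to create
#' perceptually similar retrieval lures (`EO`), one shown three times (`3x`)
#' and one shown five times (`5x`). Presentations are dealt into blocks of
#' fixed composition (per block: `n_categories/n_blocks` each of `1x` and
#' `EO`, three and five times that many `3x` and `5x` presentations) and
#' shuffled within block.
#'
#' @param n_categories Number of scene categories (even; half indoor, half
#'   outdoor). The default 60 yields 240 distinct images and 600
#'   presentations.
#' @param n_blocks Number of encoding blocks; must divide `n_categories`.
#' @param seed Integer seed controlling the dealing and within-block order.
#' @return A `trial_schedule` data frame with one row per presentation.
#' @export
build_encoding_schedule <- function(n_categories = 60, n_blocks = 15,
                                    seed = 1) {
  if (n_categories < 2 || n_categories %% 2 != 0)
    stop("`n_categories` must be even (half indoor, half outdoor)")
  if (n_blocks < 1 || n_categories %% n_blocks != 0)
    stop("`n_blocks` must divide `n_categories` so that the ",
         "per-block composition is constant; got ", n_categories,
         " categories and ", n_blocks, " blocks")
  roles <- c("1x" = 1L, "EO" = 1L, "3x" = 3L, "5x" = 5L)
  image_type <- ifelse(seq_len(n_categories) <= n_categories / 2,
                       "indoor", "outdoor")
  with_seed(seed, {
    per_block <- lapply(seq_len(n_blocks), function(b) NULL)
    for (role in names(roles)) {
      pres <- rep(seq_len(n_categories), roles[[role]])
      pres <- sample(pres)
      quota <- length(pres) / n_blocks
      for (b in seq_len(n_blocks)) {
        cats <- pres[((b - 1) * quota + 1):(b * quota)]
        per_block[[b]] <- rbind(per_block[[b]],
          data.frame(category = cats, stimulus_type = role,
                     stringsAsFactors = FALSE))
      }
    }
    rows <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
      blk <- per_block[[b]][sample(nrow(per_block[[b]])), , drop = FALSE]
      blk$block <- b
      blk
    }))
  })
  rows$image_id <- sprintf("cat%03d_%s", rows$category,
                           rows$stimulus_type)
  rows$image_type <- image_type[rows$category]
  rows$trial <- seq_len(nrow(rows))
  # encoding trials are self-paced within a 4.5 s envelope (warning cross,
  # 1 s image, response window); onsets are nominal within block
  rows$onset <- stats::ave(rows$trial, rows$block,
                           FUN = function(i) (seq_along(i) - 1) * 4.5)
  rownames(rows) <- NULL
  new_trial_schedule(
    rows[, c("trial", "block", "onset", "category", "image_id",
             "stimulus_type", "image_type")],
    session = "encoding")
}

#' Build a retrieval-session schedule
#'
#' Old items are all `1x`/`3x`/`5x` encoding images; new items are unrelated
#' (`U`), semantically related (`SR`) and semantically-plus-perceptually
#' related (`SPR`) lures, one per category per type. Trials are dealt into
#' runs of 30 with five trials per stimulus type per run; target side is
#' balanced within run. Each trial presents the image for 1.5 s, holds an
#' 8 s delay, issues a 1 s go-signal and waits a jittered 2-4 frame
#' inter-trial interval.
#'
#' @param n_categories Number of encoding categories (multiple of 10 so
#'   that runs and image types balance). Default 60 gives 360 trials in 12
#'   runs.
#' @param seed Integer seed for dealing, trial order, target side and ITIs.
#' @param tr_s Repetition time in seconds.
#' @return A `trial_schedule` with one row per trial. `onset` is in seconds
#'   relative to the start of the trial's run; the per-run frame counts are
#'   stored in `attr(, "run_frames")`.
#' @export
build_retrieval_schedule <- function(n_categories = 60, seed = 1,
                                     tr_s = DEFAULT_TR_S) {
  if (n_categories < 10 || n_categories %% 10 != 0)
    stop("`n_categories` must be a positive multiple of 10 so that runs ",
         "of 30 trials and indoor/outdoor types balance")
  n_runs <- n_categories / 5
  types <- STIMULUS_MAP$stimulus_type
  image_type <- ifelse(seq_len(n_categories) <= n_categories / 2,
                       "indoor", "outdoor")
  with_seed(seed, {
    # one image of each type per category (new-item categories mirror the
    # encoding categories for SR/SPR and are fresh for U)
    pool <- do.call(rbind, lapply(types, function(tp) {
      data.frame(category = seq_len(n_categories), stimulus_type = tp,
                 image_id = sprintf("cat%03d_%s", seq_len(n_categories), tp),
                 image_type = image_type, stringsAsFactors = FALSE)
    }))
    pool <- merge(pool, STIMULUS_MAP, by = "stimulus_type", sort = FALSE)
    # deal 5 images of each type to each run
    pool$run <- NA_integer_
    for (tp in types) {
      idx <- sample(which(pool$stimulus_type == tp))
      pool$run[idx] <- rep(seq_len(n_runs), each = 5)
    }
    rows <- do.call(rbind, lapply(seq_len(n_runs), function(r) {
      blk <- pool[pool$run == r, , drop = FALSE]
      blk <- blk[sample(nrow(blk)), , drop = FALSE]
      blk$target_side <- sample(rep(c("left", "right"), nrow(blk) / 2))
      blk$iti_frames <- sample(ITI_FRAMES, nrow(blk), replace = TRUE)
      blk
    }))
  })
  # trial timing within run
  span <- IMAGE_DURATION_S + DELAY_S + GO_DURATION_S +
    rows$iti_frames * tr_s
  rows$onset <- stats::ave(span, rows$run,
                           FUN = function(s) c(0, cumsum(s)[-length(s)]))
  rows$go_onset <- rows$onset + IMAGE_DURATION_S + DELAY_S
  rows$duration <- IMAGE_DURATION_S
  rows$trial <- seq_len(nrow(rows))
  rownames(rows) <- NULL
  run_end <- tapply(rows$onset + span, rows$run, max)
  run_frames <- as.integer(ceiling((run_end + RUN_TAIL_S) / tr_s))
  new_trial_schedule(
    rows[, c("trial", "run", "onset", "duration", "go_onset", "iti_frames",
             "category", "image_id", "stimulus_type", "memory_status",
             "evidence", "image_type", "target_side")],
    session = "retrieval", tr_s = tr_s, run_frames = run_frames)
}

#' Assign subjects to counterbalanced choice-response groups
#'
#' Half of the cohort (group A1) responds "old" with an eye movement and
#' "new" with a hand movement; group A2 uses the exact reverse mapping. The
#' reversal makes choice and response collinear within every subject but
#' independent across the pooled cohort.
#'
#' @param n_subjects Even cohort size.
#' @param seed Integer seed for the (balanced) random group assignment.
#' @return A data frame with columns `subject_id`, `group`, `old_response`,
#'   `new_response`.
#' @export
assign_groups <- function(n_subjects = 24, seed = 1) {
  if (n_subjects < 2 || n_subjects %% 2 != 0)
    stop("`n_subjects` must be even so the two groups balance")
  a1 <- with_seed(seed, sample(n_subjects, n_subjects / 2))
  group <- ifelse(seq_len(n_subjects) %in% a1, "A1", "A2")
  data.frame(
    subject_id = seq_len(n_subjects),
    group = group,
    old_response = ifelse(group == "A1", "eye", "hand"),
    new_response = ifelse(group == "A1", "hand", "eye"),
    stringsAsFactors = FALSE)
}

#' Default observer accuracy table
#'
#' Probability of a correct choice per memory status and evidence level.
#' The defaults place low-evidence old items at chance and reproduce the
#' graded increase of recognition accuracy with evidence.
#' @return A 2 x 3 matrix (rows `old`, `new`; columns `low`, `middle`,
#'   `high`) of correct-choice probabilities.
#' @export
default_p_correct <- function() {
  matrix(c(0.50, 0.75, 0.87,
           0.65, 0.75, 0.87),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("old", "new"), EVIDENCE_LEVELS))
}

#' Simulate a behavioral observer on a retrieval schedule
#'
#' Samples a choice per trial: with probability `p_correct[status, evidence]`
#' the choice equals the true memory status, otherwise it is flipped. The
#' motor response follows the subject's choice-response mapping.
#'
#' @param schedule A retrieval `trial_schedule`.
#' @param design One row of [assign_groups()] (the subject's mapping).
#' @param p_correct Status x evidence matrix of correct-choice
#'   probabilities, as [default_p_correct()].
#' @param seed Integer seed.
#' @return The schedule with `choice`, `response` and `correct` columns.
#' @export
simulate_observer <- function(schedule, design,
                              p_correct = default_p_correct(), seed = 1) {
  if (any(p_correct < 0 | p_correct > 1))
    stop("`p_correct` entries must lie in [0, 1]")
  p <- p_correct[cbind(schedule$memory_status, schedule$evidence)]
  hit <- with_seed(seed, runif(nrow(schedule)) < p)
  other <- c(old = "new", new = "old")
  schedule$choice <- ifelse(hit, schedule$memory_status,
                            other[schedule$memory_status])
  mapping <- c(old = design$old_response, new = design$new_response)
  schedule$response <- unname(mapping[schedule$choice])
  schedule$correct <- schedule$choice == schedule$memory_status
  schedule
}

#' Aggregate per-cell recognition accuracy across a cohort
#'
#' @param schedules List of observed retrieval schedules, one per subject.
#' @param designs Data frame from [assign_groups()].
#' @return A behavioral table with one row per subject x memory status x
#'   evidence cell (columns `subject_id`, `group`, `memory_status`,
#'   `evidence`, `accuracy`).
#' @export
behavioral_table <- function(schedules, designs) {
  stopifnot(length(schedules) == nrow(designs))
  do.call(rbind, lapply(seq_along(schedules), function(i) {
    sc <- schedules[[i]]
    agg <- stats::aggregate(correct ~ memory_status + evidence, data = sc,
                            FUN = mean)
    data.frame(subject_id = designs$subject_id[i], group = designs$group[i],
               memory_status = agg$memory_status, evidence = agg$evidence,
               accuracy = agg$correct, stringsAsFactors = FALSE)
  }))
}

#' Mixed-design ANOVA on recognition accuracy
#'
#' Split-plot ANOVA with memory status (old/new) and evidence (low, middle,
#' high) as within-subject factors and choice-response association group
#' (A1/A2) as the between-subject factor. Within-subject error strata are
#' subject-by-factor interactions, as in the standard balanced
#' repeated-measures decomposition.
#'
#' @param table A behavioral table from [behavioral_table()]: one accuracy
#'   per subject x status x evidence cell, balanced.
#' @return Data frame with columns `effect`, `df1`, `df2`, `F`, `p`.
#' @export
mixed_anova <- function(table) {
  required <- c("subject_id", "group", "memory_status", "evidence",
                "accuracy")
  missing <- setdiff(required, names(table))
  if (length(missing))
    stop("behavioral table lacks column(s): ",
         paste(missing, collapse = ", "))
  counts <- table(table$subject_id, table$memory_status, table$evidence)
  if (any(counts != 1))
    stop("design must be balanced with exactly one observation per ",
         "subject x memory status x evidence cell")
  d <- data.frame(
    subject = factor(table$subject_id),
    group = factor(table$group),
    status = factor(table$memory_status),
    evidence = factor(table$evidence, levels = EVIDENCE_LEVELS),
    accuracy = table$accuracy)
  fit <- aov(accuracy ~ group * status * evidence +
               Error(subject / (status * evidence)), data = d)
  out <- do.call(rbind, lapply(summary(fit), function(stratum) {
    tab <- stratum[[1]]
    eff <- trimws(rownames(tab))
    keep <- eff != "Residuals"
    if (!any(keep)) return(NULL)
    data.frame(effect = eff[keep],
               df1 = tab[keep, "Df"],
               df2 = tab[eff == "Residuals", "Df"],
               ss = tab[keep, "Sum Sq"],
               F = tab[keep, "F value"],
               p = tab[keep, "Pr(>F)"],
               stringsAsFactors = FALSE)
  }))
  # a zero effect sum of squares is no effect even when the error stratum
  # is also empty (all cells identical): report F = 0, not 0/0 or a
  # float-dust ratio
  degenerate <- out$ss < 1e-12 * max(1, sum(table$accuracy^2))
  out$F[degenerate] <- 0
  out$p[degenerate] <- 1
  out$ss <- NULL
  rownames(out) <- NULL
  out
}
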