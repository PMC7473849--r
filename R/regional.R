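# Regional (ROI) decoding by evidence level and its statistics.

#' ROI decoding per evidence level
#'
#' Runs the decoding pipeline restricted to an ROI's voxels, separately for
#' each decision-evidence level, with ANOVA feature selection (`k = 50` by
#' default) applied on training folds only. When the ROI holds fewer than
#' `k_select` voxels all are used, with a warning.
#'
#' @param betas List (one per subject) of `beta_series` over the in-mask
#'   voxels.
#' @param roi Integer in-mask voxel indices of the ROI (non-empty).
#' @param label_set Metadata column to decode: `"choice"`,
#'   `"memory_status"`, `"response"`, `"image_type"` or `"target_side"`.
#' @param scheme A `cv_scheme` (between-subject LOSO by default).
#' @param evidence Evidence levels to analyse (default all three).
#' @param k_select ANOVA-selected feature count.
#' @param C SVM regularization parameter.
#' @param fraction Balanced per-subject subsampling fraction (1 = keep
#'   all).
#' @param seed Integer seed for subsampling.
#' @param roi_name Label written into the output rows.
#' @return A `regional_accuracy` data frame: `roi`, `label_set`,
#'   `evidence`, `fold`, `subject`, `accuracy`.
#' @export
regional_decode <- function(betas, roi, label_set = "choice",
                            scheme = cv_scheme("leave_one_subject_out"),
                            evidence = EVIDENCE_LEVELS, k_select = 50,
                            C = 1, fraction = 1, seed = 1,
                            roi_name = "roi") {
  if (!length(roi)) stop("ROI is empty")
  if (k_select > length(roi)) {
    warning("ROI has ", length(roi), " voxels < k_select = ", k_select,
            "; selecting all")
    k_select <- length(roi)
  }
  mats <- lapply(betas, function(b)
    detrend_zscore_trials(spatial_zscore(b$beta)))
  rows <- lapply(evidence, function(ev) {
    Xl <- list(); yl <- list(); sl <- list(); ml <- list()
    for (i in seq_along(betas)) {
      meta <- betas[[i]]$meta
      sel <- meta$evidence == ev
      Xl[[i]] <- mats[[i]][sel, roi, drop = FALSE]
      yl[[i]] <- meta[[label_set]][sel]
      sl[[i]] <- rep(i, sum(sel))
      ml[[i]] <- meta[sel, , drop = FALSE]
    }
    pat <- labeled_patterns(do.call(rbind, Xl), unlist(yl), unlist(sl),
                            do.call(rbind, ml))
    pat <- balanced_subsample(pat, fraction, seed = seed)
    cv <- cross_validate(pat, scheme, k_select = k_select, C = C)
    data.frame(roi = roi_name, label_set = label_set, evidence = ev,
               fold = cv$fold, subject = cv$subject,
               accuracy = cv$accuracy, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("regional_accuracy", "data.frame")
  out
}

#' Linear mixed-model test of an evidence effect on decoding accuracy
#'
#' Fits `accuracy ~ evidence_code + (1 | subject)` with evidence coded
#' -1/0/+1 (low/middle/high) by REML and tests the fixed slope (Wald-type
#' t with Satterthwaite degrees of freedom). If the random-intercept fit
#' is singular, falls back to a one-sample t test of the per-subject OLS
#' slopes, flagged in `method`.
#'
#' @param rows A `regional_accuracy` data frame with at least two evidence
#'   levels and three subjects.
#' @return List with `slope`, `se`, `statistic`, `df`, `p`, `method`.
#' @export
evidence_slope_test <- function(rows) {
  rows <- as.data.frame(rows)
  if (length(unique(rows$evidence)) < 2)
    stop("need at least two evidence levels")
  if (length(unique(rows$subject)) < 3)
    stop("need at least three subjects")
  code <- c(low = -1, middle = 0, high = 1)
  d <- data.frame(accuracy = rows$accuracy,
                  evidence_code = code[rows$evidence],
                  subject = factor(rows$subject))
  fit <- suppressMessages(lmerTest::lmer(
    accuracy ~ evidence_code + (1 | subject), data = d, REML = TRUE))
  if (lme4::isSingular(fit, tol = 1e-5)) {
    slopes <- sapply(split(d, d$subject), function(s)
      coef(lm(accuracy ~ evidence_code, data = s))[2])
    tt <- t.test(slopes)
    return(list(slope = unname(mean(slopes)),
                se = unname(sd(slopes) / sqrt(length(slopes))),
                statistic = unname(tt$statistic),
                df = unname(tt$parameter), p = tt$p.value,
                method = "subject_slopes_t"))
  }
  cf <- coef(summary(fit))["evidence_code", ]
  list(slope = unname(cf["Estimate"]), se = unname(cf["Std. Error"]),
       statistic = unname(cf["t value"]), df = unname(cf["df"]),
       p = unname(cf["Pr(>|t|)"]), method = "lmer_wald")
}

#' Low-evidence choice decoding tests
#'
#' On the lowest-evidence trials — where subjective choice and objective
#' memory status diverge most — tests (a) choice-decoding accuracy against
#' chance (one-sample t vs 0.5) and (b) choice versus memory-status
#' decoding (two-tailed paired t across subjects).
#'
#' @param choice_rows,status_rows `regional_accuracy` rows for the choice
#'   and memory-status label sets on the same subjects (one accuracy per
#'   subject each).
#' @return List of two `htest`-like lists: `vs_chance` and
#'   `choice_vs_status`.
#' @export
low_evidence_tests <- function(choice_rows, status_rows) {
  ch <- as.data.frame(choice_rows)
  st <- as.data.frame(status_rows)
  ch <- ch[order(ch$subject), ]
  st <- st[order(st$subject), ]
  if (!identical(as.character(ch$subject), as.character(st$subject)))
    stop("choice and status rows must cover the same subjects")
  one_t <- function(x, mu) {
    n <- length(x)
    if (sd(x) == 0)  # zero spread: no evidence against mu, or infinite
      return(list(statistic = if (mean(x) == mu) 0 else
                    Inf * sign(mean(x) - mu), df = n - 1,
                  p = if (mean(x) == mu) 1 else 0, mean = mean(x)))
    tt <- t.test(x, mu = mu)
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, mean = unname(tt$estimate))
  }
  t1 <- one_t(ch$accuracy, 0.5)
  t2 <- one_t(ch$accuracy - st$accuracy, 0)
  names(t2)[names(t2) == "mean"] <- "mean_diff"
  list(vs_chance = t1, choice_vs_status = t2)
}

#' Bonferroni correction
#'
#' @param p P values.
#' @param m Family size (number of comparisons).
#' @return `min(1, p * m)` elementwise.
#' @export
bonferroni <- function(p, m) pmin(1, p * m)
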