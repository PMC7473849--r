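# File interfaces: BIDS-style events TSV, NIfTI volumes, JSON sidecars.

EVENTS_COLUMNS <- c("onset", "duration", "run", "stimulus_type",
                    "memory_status", "evidence", "image_type",
                    "target_side", "choice", "response", "correct")

#' Write a retrieval schedule as a BIDS-style events file
#'
#' Tab-separated with columns onset, duration, run, stimulus_type,
#' memory_status, evidence, image_type, target_side, choice, response,
#' correct (plus go_onset and iti_frames to make the file self-contained).
#'
#' @param schedule Observed retrieval `trial_schedule`.
#' @param path Output path (`.tsv`).
#' @export
write_events_tsv <- function(schedule, path) {
  df <- as.data.frame(schedule)
  for (col in c("choice", "response", "correct"))
    if (is.null(df[[col]])) df[[col]] <- NA
  df <- df[, c(EVENTS_COLUMNS, "go_onset", "iti_frames")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an events file written by [write_events_tsv()]
#'
#' @param path Path to the `.tsv` file.
#' @param tr_s Repetition time used to reconstruct run frame counts.
#' @return A retrieval `trial_schedule`.
#' @export
read_events_tsv <- function(path, tr_s = DEFAULT_TR_S) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(EVENTS_COLUMNS, names(df))
  if (length(missing))
    stop("events file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  df$trial <- seq_len(nrow(df))
  span <- IMAGE_DURATION_S + DELAY_S + GO_DURATION_S +
    df$iti_frames * tr_s
  run_end <- tapply(df$onset + span, df$run, max)
  run_frames <- as.integer(ceiling((run_end + RUN_TAIL_S) / tr_s))
  new_trial_schedule(df, session = "retrieval", tr_s = tr_s,
                     run_frames = run_frames)
}

#' Write a subject's runs as 4D NIfTI volumes
#'
#' One file per run (`sub-XX_run-YY_bold.nii.gz`), values placed back into
#' the full grid (zero outside the mask), plus the events file and a JSON
#' sidecar with grid, group and timing metadata.
#'
#' @param subject A `subject_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_subject_nifti <- function(subject, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- subject$grid
  sid <- subject$design$subject_id
  paths <- character(0)
  for (ri in seq_along(subject$runs)) {
    m <- subject$runs[[ri]]
    vol <- array(0, c(g$dims, nrow(m)))
    for (f in seq_len(nrow(m)))
      vol[, , , f][g$in_mask] <- m[f, ]
    p <- file.path(dir, sprintf("sub-%02d_run-%02d_bold.nii.gz", sid, ri))
    img <- RNifti::asNifti(vol)
    RNifti::pixdim(img) <- c(rep(g$voxel_size_mm, 3), subject$tr_s)
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  ev <- file.path(dir, sprintf("sub-%02d_events.tsv", sid))
  write_events_tsv(subject$schedule, ev)
  side <- file.path(dir, sprintf("sub-%02d_sidecar.json", sid))
  jsonlite::write_json(list(
    subject_id = sid, group = subject$design$group,
    old_response = subject$design$old_response,
    new_response = subject$design$new_response,
    tr_s = subject$tr_s, dims = g$dims,
    voxel_size_mm = g$voxel_size_mm), side, auto_unbox = TRUE,
    digits = NA)
  invisible(c(paths, ev, side))
}

#' Read a subject written by [write_subject_nifti()]
#'
#' @param dir Directory holding the subject's files.
#' @param subject_id Integer id.
#' @param grid The `volume_grid` used when writing (masking is applied on
#'   read).
#' @return A `subject_dataset`.
#' @export
read_subject_nifti <- function(dir, subject_id, grid) {
  side <- jsonlite::read_json(
    file.path(dir, sprintf("sub-%02d_sidecar.json", subject_id)),
    simplifyVector = TRUE)
  schedule <- read_events_tsv(
    file.path(dir, sprintf("sub-%02d_events.tsv", subject_id)),
    tr_s = side$tr_s)
  files <- sort(list.files(dir, sprintf(
    "sub-%02d_run-[0-9]+_bold\\.nii\\.gz", subject_id),
    full.names = TRUE))
  runs <- lapply(files, function(p) {
    vol <- RNifti::readNifti(p)
    t(apply(vol, 4, function(v) v)[grid$in_mask, , drop = FALSE])
  })
  design <- data.frame(subject_id = side$subject_id, group = side$group,
                       old_response = side$old_response,
                       new_response = side$new_response,
                       stringsAsFactors = FALSE)
  structure(list(design = design, grid = grid, runs = runs,
                 tr_s = side$tr_s, schedule = schedule),
            class = "subject_dataset")
}

#' Write the cohort description sidecar
#'
#' @param designs Output of [assign_groups()].
#' @param seed Cohort master seed.
#' @param path JSON output path.
#' @export
write_cohort_json <- function(designs, seed, path) {
  jsonlite::write_json(list(seed = seed, groups = designs),
                       path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
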