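# Session bundle file format: tab-separated trials, per-subject samples and
# events tables, plus a minimal reader for an ASC-like eye-tracker export.
# All timestamps are integer milliseconds on the session clock; missing
# pupil samples are written as empty fields with valid = 0.

trials_columns <- c(
  "subject", "block_index", "scheme_id", "trial_index", "choice", "rt_ms",
  "outcome", "outcome_points", "position", "t_fixation_on", "t_stimulus_on",
  "t_button_press", "t_feedback_on"
)
event_labels <- c("FIXATION_ON", "STIM_ON", "BUTTON_PRESS", "FEEDBACK_ON",
                  "BLOCK_START", "BLOCK_END")

#' Write a session bundle to a directory of TSV files
#'
#' Produces `trials.tsv` (all subjects), and per subject
#' `samples_<subject>.tsv` (`time_ms`, `pupil`, `valid`) and
#' `events_<subject>.tsv` (`timestamp`, `label`, `block`, `trial`).
#' Numeric values keep full precision so that a write/read cycle is
#' lossless.
#'
#' @param bundle A `session_bundle`.
#' @param directory Target directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_session <- function(bundle, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  tr <- data.table::as.data.table(bundle$trials)
  keep <- intersect(trials_columns, names(tr))
  data.table::fwrite(tr[, keep, with = FALSE],
                     file.path(directory, "trials.tsv"), sep = "\t")
  for (sid in names(bundle$samples)) {
    sm <- data.table::as.data.table(bundle$samples[[sid]])
    out <- data.table::data.table(
      time_ms = sm$time_ms,
      pupil = ifelse(sm$valid, sm$pupil, NA_real_),
      valid = as.integer(sm$valid)
    )
    data.table::fwrite(out, file.path(directory,
                                      sprintf("samples_%s.tsv", sid)),
                       sep = "\t", na = "")
  }
  for (sid in names(bundle$events)) {
    data.table::fwrite(bundle$events[[sid]],
                       file.path(directory, sprintf("events_%s.tsv", sid)),
                       sep = "\t", na = "")
  }
  invisible(directory)
}

validation_error <- function(...) {
  stop(structure(class = c("session_validation_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Read a session bundle from a directory of TSV files
#'
#' Validates the bundle while reading: required columns must be present,
#' each subject's sample grid must be a strictly increasing 1-ms grid
#' without duplicates, and every trial's four event timestamps must appear
#' in the subject's events table. Violations raise a typed
#' `session_validation_error` naming the offending row or timestamp.
#'
#' @param directory Directory written by [write_session()].
#' @return A `session_bundle` (without generator ground-truth columns).
#' @export
read_session <- function(directory) {
  tf <- file.path(directory, "trials.tsv")
  if (!file.exists(tf)) validation_error("missing trials.tsv in ", directory)
  trials <- data.table::fread(tf, sep = "\t")
  missing_cols <- setdiff(trials_columns, names(trials))
  if (length(missing_cols))
    validation_error("trials.tsv lacks columns: ",
                     paste(missing_cols, collapse = ", "))
  samples <- list()
  events <- list()
  sample_files <- list.files(directory, pattern = "^samples_.*\\.tsv$")
  for (f in sample_files) {
    sid <- sub("^samples_(.*)\\.tsv$", "\\1", f)
    sm <- data.table::fread(file.path(directory, f), sep = "\t",
                            na.strings = "")
    if (!all(c("time_ms", "pupil", "valid") %in% names(sm)))
      validation_error(f, " lacks required columns")
    if (nrow(sm) > 1) {
      d <- diff(sm$time_ms)
      if (any(d == 0)) {
        at <- sm$time_ms[which(d == 0)[1]]
        validation_error("duplicated sample timestamp ", at, " in ", f)
      }
      if (any(d != 1)) {
        at <- which(d != 1)[1]
        validation_error("sample time grid not a 1-ms grid in ", f,
                         " at row ", at + 1L, " (time ", sm$time_ms[at + 1L],
                         ")")
      }
    }
    sm$valid <- sm$valid == 1
    samples[[sid]] <- sm
  }
  event_files <- list.files(directory, pattern = "^events_.*\\.tsv$")
  for (f in event_files) {
    sid <- sub("^events_(.*)\\.tsv$", "\\1", f)
    ev <- data.table::fread(file.path(directory, f), sep = "\t",
                            na.strings = "")
    if (!all(c("timestamp", "label", "block", "trial") %in% names(ev)))
      validation_error(f, " lacks required columns")
    bad <- setdiff(unique(ev$label), event_labels)
    if (length(bad))
      validation_error("unknown event label '", bad[1], "' in ", f)
    tr <- trials[trials$subject == sid, ]
    orphan <- ev[!is.na(ev$trial) &
                   !paste(ev$block, ev$trial) %in%
                   paste(tr$block_index, tr$trial_index), ]
    if (nrow(orphan))
      validation_error("orphan event (block ", orphan$block[1], ", trial ",
                       orphan$trial[1], ") in ", f)
    map <- c(FIXATION_ON = "t_fixation_on", STIM_ON = "t_stimulus_on",
             BUTTON_PRESS = "t_button_press", FEEDBACK_ON = "t_feedback_on")
    for (i in seq_along(map)) {
      lab <- names(map)[i]
      evl <- ev[ev$label == lab, ]
      found <- paste(evl$block, evl$trial, evl$timestamp)
      want <- paste(tr$block_index, tr$trial_index, tr[[map[[i]]]])
      miss <- which(!want %in% found)
      if (length(miss) && nrow(tr))
        validation_error("missing ", lab, " event for subject ", sid,
                         ", block ", tr$block_index[miss[1]], ", trial ",
                         tr$trial_index[miss[1]])
    }
    events[[sid]] <- ev
  }
  structure(
    list(trials = trials, samples = samples, events = events,
         artifact_log = list(), config = list()),
    class = "session_bundle"
  )
}

#' Parse a minimal ASC-like eye-tracker export
#'
#' Understands two row kinds of the text dialect that 1,000-Hz infrared
#' trackers export: sample rows `<timestamp> <x> <y> <pupil>` and message
#' rows `MSG <timestamp> <label>`. Sample rows whose pupil field is missing
#' or unparseable become invalid samples at that timestamp (the blink
#' convention); rows without a parseable timestamp are ignored. Lines with
#' no parseable content at all raise a format error.
#'
#' @param lines Character vector of file lines.
#' @return list with `samples` (time_ms, pupil, valid) and `events`
#'   (timestamp, label).
#' @export
parse_asc_minimal <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  is_msg <- grepl("^MSG\\b", lines)
  samples <- list()
  events <- list()
  for (ln in lines[is_msg]) {
    parts <- strsplit(ln, "[ \t]+")[[1]]
    ts <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(ts) || length(parts) < 3) next
    events[[length(events) + 1L]] <- data.table::data.table(
      timestamp = ts, label = paste(parts[-(1:2)], collapse = " "))
  }
  for (ln in lines[!is_msg]) {
    parts <- strsplit(ln, "[ \t]+")[[1]]
    ts <- suppressWarnings(as.numeric(parts[1]))
    if (is.na(ts)) next
    pupil <- if (length(parts) >= 4)
      suppressWarnings(as.numeric(parts[4])) else NA_real_
    samples[[length(samples) + 1L]] <- data.table::data.table(
      time_ms = ts, pupil = pupil, valid = !is.na(pupil))
  }
  if (!length(samples) && !length(events))
    stop("parse_asc_minimal: no parseable rows")
  list(
    samples = if (length(samples)) data.table::rbindlist(samples) else
      data.table::data.table(time_ms = numeric(0), pupil = numeric(0),
                             valid = logical(0)),
    events = if (length(events)) data.table::rbindlist(events) else
      data.table::data.table(timestamp = numeric(0), label = character(0))
  )
}
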