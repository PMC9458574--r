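# Pupil preprocessing: derivative-based artifact detection, interpolation or
# epoch-level flagging, 50-ms binning, session-wide within-subject
# z-scoring, response-locked epoch extraction and exclusion, pretrial
# baselines and interval means.

#' Detect pupil artifacts on the 1-ms grid
#'
#' A sample is artifactual when it is missing (invalid) or belongs to an
#' adjacent pair whose absolute first difference exceeds `deriv_thresh`
#' pixels (strictly; both members of a violating pair are flagged).
#' Contiguous flagged samples are merged into runs; runs separated by fewer
#' than `merge_gap` valid samples are merged before classification, which
#' prevents later interpolation across flickering gaps. Runs are classed
#' `short` when their duration is at most `short_max_ms`, `long` otherwise.
#'
#' @param samples data.table with `time_ms` (contiguous 1-ms grid), `pupil`,
#'   `valid`.
#' @param deriv_thresh Derivative threshold (pixels per sample).
#' @param short_max_ms Boundary between short and long runs (ms).
#' @param merge_gap Runs separated by fewer than this many valid samples are
#'   merged.
#' @return data.table of runs: `start_ms`, `end_ms`, `class`.
#' @export
detect_artifacts <- function(samples, deriv_thresh = 10, short_max_ms = 350,
                             merge_gap = 2) {
  n <- nrow(samples)
  empty <- data.table::data.table(start_ms = integer(0), end_ms = integer(0),
                                  class = character(0))
  if (n == 0) return(empty)
  flag <- !samples$valid | is.na(samples$pupil)
  if (n >= 2) {
    d <- diff(samples$pupil)
    viol <- which(abs(d) > deriv_thresh) # which() drops NA comparisons
    flag[viol] <- TRUE
    flag[viol + 1L] <- TRUE
  }
  idx <- which(flag)
  if (length(idx) == 0) return(empty)
  # runs from gaps in the flagged-index list (cheap: operates on the flagged
  # samples only), then merge runs separated by < merge_gap valid samples
  brk <- which(diff(idx) > 1L)
  starts <- idx[c(1L, brk + 1L)]
  ends <- idx[c(brk, length(idx))]
  if (length(starts) > 1) {
    gap <- starts[-1] - ends[-length(ends)] - 1L
    keep_start <- c(TRUE, gap >= merge_gap)
    starts <- starts[keep_start]
    ends <- ends[c(keep_start[-1], TRUE)]
  }
  runs <- data.table::data.table(
    start_ms = samples$time_ms[starts],
    end_ms = samples$time_ms[ends]
  )
  dur <- runs$end_ms - runs$start_ms + 1L
  runs$class <- ifelse(dur <= short_max_ms, "short", "long")
  runs
}

#' Interpolate short artifact runs, flag long ones
#'
#' Short runs are replaced by linear interpolation between the nearest valid
#' neighbors on both sides and marked valid again. Long runs, and any run
#' touching a series boundary (no anchor on one side), are left invalid and
#' returned for epoch-level exclusion.
#'
#' @param samples data.table with `time_ms`, `pupil`, `valid`.
#' @param mask Runs from [detect_artifacts()].
#' @return list with `samples` (cleaned) and `long_runs` (data.table
#'   `start_ms`, `end_ms`, `reason` in `long`/`boundary`).
#' @export
repair_or_flag <- function(samples, mask) {
  no_runs <- data.table::data.table(start_ms = integer(0),
                                    end_ms = integer(0),
                                    reason = character(0))
  if (nrow(mask) == 0) {
    return(list(samples = data.table::as.data.table(samples),
                long_runs = no_runs))
  }
  time_ms <- samples$time_ms
  pupil <- as.numeric(samples$pupil)
  valid <- as.logical(samples$valid)
  t0 <- time_ms[1]
  n <- length(pupil)
  long_runs <- list()
  for (i in seq_len(nrow(mask))) {
    i1 <- mask$start_ms[i] - t0 + 1L
    i2 <- mask$end_ms[i] - t0 + 1L
    at_edge <- i1 <= 1L || i2 >= n
    if (at_edge || mask$class[i] == "long") {
      valid[i1:i2] <- FALSE
      long_runs[[length(long_runs) + 1L]] <- data.table::data.table(
        start_ms = mask$start_ms[i], end_ms = mask$end_ms[i],
        reason = if (at_edge) "boundary" else "long"
      )
    } else {
      a <- i1 - 1L
      b <- i2 + 1L
      ya <- pupil[a]
      yb <- pupil[b]
      pupil[i1:i2] <- ya + (yb - ya) * (seq.int(i1, i2) - a) / (b - a)
      valid[i1:i2] <- TRUE
    }
  }
  long_runs <- if (length(long_runs)) data.table::rbindlist(long_runs) else
    no_runs
  list(samples = data.table::data.table(time_ms = time_ms, pupil = pupil,
                                        valid = valid),
       long_runs = long_runs)
}

#' Downsample a pupil series into consecutive 50-ms bins
#'
#' Each bin is the arithmetic mean of its `bin_ms` consecutive 1-ms samples.
#' Bins containing any remaining invalid sample are marked invalid and carry
#' no value; a trailing partial bin is dropped.
#'
#' @param samples Cleaned series from [repair_or_flag()].
#' @param bin_ms Bin width (ms).
#' @return data.table with `bin_start_ms`, `pupil` (bin mean), `valid`.
#' @export
bin_50ms <- function(samples, bin_ms = 50L) {
  n_bins <- nrow(samples) %/% bin_ms
  if (n_bins == 0) {
    return(data.table::data.table(bin_start_ms = integer(0),
                                  pupil = numeric(0), valid = logical(0)))
  }
  m <- n_bins * bin_ms
  vals <- matrix(samples$pupil[seq_len(m)], nrow = bin_ms)
  ok <- matrix(samples$valid[seq_len(m)], nrow = bin_ms)
  bin_valid <- .colSums(ok, bin_ms, n_bins) == bin_ms
  means <- .colMeans(vals, bin_ms, n_bins)
  means[!bin_valid] <- NA_real_
  data.table::data.table(
    bin_start_ms = samples$time_ms[1] + (seq_len(n_bins) - 1L) * bin_ms,
    pupil = means,
    valid = bin_valid
  )
}

#' Z-transform a subject's binned pupil series session-wide
#'
#' The mean and standard deviation are computed over all retained (valid)
#' bins of the whole session -- all blocks jointly -- so the session-wide
#' average acts as one common reference for every condition and time point.
#' Samples lost to long artifacts are excluded from the reference by
#' default because their bins are invalid.
#'
#' @param binned Output of [bin_50ms()] for one subject's full session.
#' @return The table with a `z` column; attributes `subject_mean` and
#'   `subject_sd` store the reference values.
#' @export
zscore_pupil <- function(binned) {
  x <- binned$pupil[binned$valid]
  if (length(x) < 2) stop("zscore_pupil: need >= 2 valid bins")
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) stop("zscore_pupil: zero variance (degenerate subject)")
  out <- data.table::copy(data.table::as.data.table(binned))
  data.table::set(out, j = "z", value = (out$pupil - m) / s)
  data.table::setattr(out, "subject_mean", m)
  data.table::setattr(out, "subject_sd", s)
  out
}

bin_index_range <- function(press, t0, bin_ms, window) {
  # first bin whose center (bin_start + bin_ms/2) is >= press + window[1]
  half <- bin_ms / 2
  k_first <- ceiling((press + window[1] - t0 - half) / bin_ms) + 1L
  n_bins <- as.integer((window[2] - window[1]) / bin_ms)
  c(k_first, k_first + n_bins - 1L)
}

#' Extract response-locked epochs on the common 70-bin grid
#'
#' For every trial the bins whose centers fall within `window` (half-open,
#' relative to the button press) form the analysis epoch -- 70 bins for the
#' default -1,000 to 2,500 ms window. An epoch is excluded with reason
#' `long_artifact` when any long artifact run overlaps the wider
#' `excl_window` (-2,000 to 3,000 ms) around the press, and with reason
#' `boundary` when the press sits too close to the recording edge for the
#' grid to be complete.
#'
#' @param zbinned Z-scored bins from [zscore_pupil()].
#' @param trials One subject's trials (needs `block_index`, `trial_index`,
#'   `t_button_press`).
#' @param long_runs Long-run table from [repair_or_flag()].
#' @param window Analysis window (ms, relative to press).
#' @param excl_window Exclusion window for long artifacts (ms).
#' @param bin_ms Bin width (ms).
#' @return list with `epochs` (long table: block_index, trial_index, bin,
#'   rel_ms = nominal bin start relative to the press, z) and `meta`
#'   (per trial: included, reason in none/long_artifact/boundary).
#' @export
extract_epochs <- function(zbinned, trials, long_runs,
                           window = c(-1000, 2500),
                           excl_window = c(-2000, 3000),
                           bin_ms = 50L) {
  t0 <- zbinned$bin_start_ms[1]
  K <- nrow(zbinned)
  n_bins <- as.integer((window[2] - window[1]) / bin_ms)
  press <- trials$t_button_press
  nt <- length(press)
  half <- bin_ms / 2
  k_first <- ceiling((press + window[1] - t0 - half) / bin_ms) + 1L
  k_last <- k_first + n_bins - 1L

  hit_long <- rep(FALSE, nt)
  if (nrow(long_runs) > 0) {
    for (j in seq_len(nrow(long_runs))) {
      hit_long <- hit_long |
        (long_runs$start_ms[j] <= press + excl_window[2] &
           long_runs$end_ms[j] >= press + excl_window[1])
    }
  }
  out_of_range <- k_first < 1L | k_last > K
  meta <- data.table::data.table(
    block_index = trials$block_index,
    trial_index = trials$trial_index,
    included = !(hit_long | out_of_range),
    reason = ifelse(hit_long, "long_artifact",
                    ifelse(out_of_range, "boundary", "none"))
  )
  ok <- which(meta$included)
  if (length(ok)) {
    offs <- 0:(n_bins - 1L)
    idx <- rep(k_first[ok], each = n_bins) + offs
    epochs <- data.table::data.table(
      block_index = rep(trials$block_index[ok], each = n_bins),
      trial_index = rep(trials$trial_index[ok], each = n_bins),
      bin = rep(seq_len(n_bins), length(ok)),
      rel_ms = rep(window[1] + offs * bin_ms, length(ok)),
      z = zbinned$z[idx]
    )
  } else {
    epochs <- data.table::data.table(block_index = integer(0),
                                     trial_index = integer(0), bin = integer(0),
                                     rel_ms = numeric(0), z = numeric(0))
  }
  list(epochs = epochs, meta = meta)
}

#' Exclude epochs with extreme z values
#'
#' An included epoch is excluded with reason `extreme_z` when any of its
#' bins deviates from zero by strictly more than `z_max` standard
#' deviations (rule `"any_bin"`, the default); the `"epoch_mean"` variant
#' applies the rule to the epoch's mean instead. A bin of exactly `z_max`
#' is kept.
#'
#' @param epochs,meta Output of [extract_epochs()].
#' @param z_max Exclusion threshold in SD units.
#' @param rule `"any_bin"` or `"epoch_mean"`.
#' @return Updated `meta`.
#' @export
exclude_extreme_epochs <- function(epochs, meta, z_max = 3,
                                   rule = c("any_bin", "epoch_mean")) {
  rule <- match.arg(rule)
  meta <- data.table::copy(meta)
  if (nrow(epochs) == 0) return(meta)
  z <- block_index <- trial_index <- NULL
  stat <- epochs[, list(
    extreme = if (rule == "any_bin") any(abs(z) > z_max, na.rm = TRUE)
              else abs(mean(z, na.rm = TRUE)) > z_max
  ), by = c("block_index", "trial_index")]
  bad <- stat[stat$extreme == TRUE]
  if (nrow(bad)) {
    key <- paste(meta$block_index, meta$trial_index)
    hit <- key %in% paste(bad$block_index, bad$trial_index) & meta$included
    meta$included[hit] <- FALSE
    meta$reason[hit] <- "extreme_z"
  }
  meta
}

#' Pretrial pupil baseline
#'
#' Mean z over the (up to `window` width / bin width) bins whose centers
#' fall within `window` relative to the fixation cross onset; bins lost to
#' artifacts are skipped and an all-missing window yields NA.
#'
#' @param zbinned Z-scored bins from [zscore_pupil()].
#' @param trials One subject's trials (needs `t_fixation_on`).
#' @param window Baseline window (ms, relative to fixation onset).
#' @param bin_ms Bin width (ms).
#' @return data.table: block_index, trial_index, baseline.
#' @export
pretrial_baseline <- function(zbinned, trials, window = c(-300, 0),
                              bin_ms = 50L) {
  t0 <- zbinned$bin_start_ms[1]
  K <- nrow(zbinned)
  n_bins <- as.integer((window[2] - window[1]) / bin_ms)
  half <- bin_ms / 2
  k_first <- ceiling((trials$t_fixation_on + window[1] - t0 - half) /
                       bin_ms) + 1L
  offs <- 0:(n_bins - 1L)
  idx <- rep(k_first, each = n_bins) + offs
  vals <- rep(NA_real_, length(idx))
  inside <- idx >= 1L & idx <= K
  vals[inside] <- zbinned$z[idx[inside]]
  m <- matrix(vals, nrow = n_bins)
  n_ok <- .colSums(!is.na(m), n_bins, ncol(m))
  bl <- .colSums(ifelse(is.na(m), 0, m), n_bins, ncol(m)) / pmax(n_ok, 1L)
  bl[n_ok == 0] <- NA_real_
  data.table::data.table(
    block_index = trials$block_index,
    trial_index = trials$trial_index,
    baseline = bl
  )
}

#' Subtract the pretrial baseline from each epoch
#'
#' @param epochs Epoch table from [extract_epochs()].
#' @param baselines Output of [pretrial_baseline()].
#' @return list with `epochs` (z replaced by z minus the trial's baseline)
#'   and `dropped` (trials without a baseline, removed from this corrected
#'   variant only).
#' @export
baseline_correct <- function(epochs, baselines) {
  epochs <- data.table::as.data.table(epochs)
  merged <- merge(epochs, baselines, by = c("block_index", "trial_index"),
                  all.x = TRUE, sort = FALSE)
  dropped <- unique(merged[is.na(merged$baseline),
                           c("block_index", "trial_index")])
  kept <- merged[!is.na(merged$baseline)]
  kept$z <- kept$z - kept$baseline
  kept$baseline <- NULL
  list(epochs = kept, dropped = dropped)
}

#' Per-trial interval means of the epoch z series
#'
#' For every included epoch: the mean z over the main analysis window and
#' over the three functional subintervals (decision/action initiation,
#' outcome anticipation, feedback processing), the pretrial baseline, and
#' the baseline-corrected main-window mean. Windows are half-open
#' `[start, end)` on nominal bin centers; the main window is configurable
#' because it is normally chosen from the pointwise analysis.
#'
#' @param epochs,meta Output of [extract_epochs()] (after exclusions).
#' @param baselines Output of [pretrial_baseline()].
#' @param main_window Main averaging window (ms relative to press).
#' @param subintervals Named list of subinterval windows.
#' @param bin_ms Bin width (ms).
#' @return data.table, one row per included trial, with columns
#'   `pupil_main`, one per subinterval (`pupil_<name>`), `baseline`,
#'   `pupil_main_bc`.
#' @export
interval_means <- function(epochs, meta, baselines,
                           main_window = c(-400, 2200),
                           subintervals = list(decision = c(-400, 0),
                                               anticipation = c(0, 1000),
                                               feedback = c(1000, 2200)),
                           bin_ms = 50L) {
  included <- meta[meta$included == TRUE, c("block_index", "trial_index")]
  if (nrow(included) == 0 || nrow(epochs) == 0) {
    cols <- c("block_index", "trial_index", "pupil_main",
              paste0("pupil_", names(subintervals)), "baseline",
              "pupil_main_bc")
    out <- data.table::as.data.table(
      stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    out$block_index <- integer(0)
    out$trial_index <- integer(0)
    return(out)
  }
  epochs <- merge(epochs, included, by = c("block_index", "trial_index"),
                  sort = FALSE)
  centers <- epochs$rel_ms + bin_ms / 2
  z <- NULL
  windows <- c(list(main = main_window), subintervals)
  out <- NULL
  for (nm in names(windows)) {
    w <- windows[[nm]]
    g <- epochs[centers >= w[1] & centers < w[2],
                list(v = mean(z, na.rm = TRUE)),
                by = c("block_index", "trial_index")]
    data.table::setnames(g, "v", paste0("pupil_", nm))
    out <- if (is.null(out)) g else
      merge(out, g, by = c("block_index", "trial_index"), all = TRUE,
            sort = FALSE)
  }
  out <- merge(out, baselines, by = c("block_index", "trial_index"),
               all.x = TRUE, sort = FALSE)
  out$pupil_main_bc <- out$pupil_main - out$baseline
  out[]
}

#' Run the full pupil preprocessing chain for a session bundle
#'
#' Per subject: artifact detection, interpolation/flagging, 50-ms binning,
#' session-wide z-scoring, epoch extraction, extreme-z exclusion, pretrial
#' baselines and interval means. Returns trial-level measures merged with
#' the trials table, the long epoch table (for pointwise analyses) and a
#' preprocessing report.
#'
#' @param bundle A `session_bundle` with pupil samples.
#' @param main_window Main averaging window (ms relative to press).
#' @param extreme_rule Passed to [exclude_extreme_epochs()].
#' @param epoch_window,excl_window,baseline_window Window settings (ms).
#' @return list with `measures` (trials + pupil columns), `epochs`
#'   (subject, block_index, trial_index, bin, rel_ms, z; included trials
#'   only), `meta` (per-trial inclusion), `report`.
#' @export
preprocess_pupil <- function(bundle,
                             main_window = c(-400, 2200),
                             extreme_rule = "any_bin",
                             epoch_window = c(-1000, 2500),
                             excl_window = c(-2000, 3000),
                             baseline_window = c(-300, 0)) {
  stopifnot(length(bundle$samples) > 0)
  subjects <- names(bundle$samples)
  meas <- list()
  eps <- list()
  metas <- list()
  report <- list()
  for (sid in subjects) {
    tr <- bundle$trials[bundle$trials$subject == sid, ]
    sm <- bundle$samples[[sid]]
    mask <- detect_artifacts(sm)
    rep_ <- repair_or_flag(sm, mask)
    binned <- bin_50ms(rep_$samples)
    zb <- zscore_pupil(binned)
    ex <- extract_epochs(zb, tr, rep_$long_runs, epoch_window, excl_window)
    meta <- exclude_extreme_epochs(ex$epochs, ex$meta, rule = extreme_rule)
    bl <- pretrial_baseline(zb, tr, baseline_window)
    im <- interval_means(ex$epochs, meta, bl, main_window = main_window)
    im$subject <- sid
    meas[[sid]] <- im
    keep <- meta[meta$included == TRUE, c("block_index", "trial_index")]
    ep <- merge(ex$epochs, keep, by = c("block_index", "trial_index"),
                sort = FALSE)
    ep$subject <- sid
    eps[[sid]] <- ep
    meta$subject <- sid
    metas[[sid]] <- meta
    report[[sid]] <- data.table::data.table(
      subject = sid,
      n_runs_short = sum(mask$class == "short"),
      n_runs_long = sum(mask$class == "long"),
      pct_interpolated = 100 * sum(rep_$samples$valid & !sm$valid) / nrow(sm),
      n_epochs = nrow(meta),
      n_excluded_long = sum(meta$reason == "long_artifact"),
      n_excluded_boundary = sum(meta$reason == "boundary"),
      n_excluded_extreme = sum(meta$reason == "extreme_z"),
      subject_mean = attr(zb, "subject_mean"),
      subject_sd = attr(zb, "subject_sd")
    )
  }
  measures <- merge(bundle$trials, data.table::rbindlist(meas),
                    by = c("subject", "block_index", "trial_index"),
                    all.x = TRUE, sort = FALSE)
  list(
    measures = measures,
    epochs = data.table::rbindlist(eps),
    meta = data.table::rbindlist(metas),
    report = data.table::rbindlist(report)
  )
}
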