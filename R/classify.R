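# Trial classification: RT cleaning, learning criteria, choice-type triplets,
# restricted subsets and per-subject behavioral summaries.

#' Filter trials with extreme response times
#'
#' Trials with RT below 300 ms or above 4,000 ms are excluded; trials exactly
#' at either printed cutoff are retained (the rule is strict on both
#' inequalities).
#'
#' @param trials A data.frame/data.table with an `rt_ms` column.
#' @param min_ms,max_ms Exclusion cutoffs (ms).
#' @return A list with `trials` (retained rows) and `excluded_fraction`.
#' @export
filter_rt <- function(trials, min_ms = 300, max_ms = 4000) {
  trials <- data.table::as.data.table(trials)
  keep <- trials$rt_ms >= min_ms & trials$rt_ms <= max_ms
  list(
    trials = trials[keep],
    excluded_fraction = mean(!keep)
  )
}

#' Z-transform response times within subject
#'
#' Standardizes `rt_ms` within each subject over all retained trials of all
#' blocks jointly, adding an `rt_z` column.
#'
#' @param trials Retained trials with `subject` and `rt_ms` columns.
#' @return The table with an `rt_z` column added.
#' @export
zscore_rt <- function(trials) {
  trials <- data.table::as.data.table(trials)
  rt_ms <- NULL # NSE note
  zfun <- function(x) {
    if (length(x) < 2) stop("zscore_rt: need >= 2 retained trials per subject")
    s <- stats::sd(x)
    if (s == 0) stop("zscore_rt: zero RT variance for a subject")
    (x - mean(x)) / s
  }
  trials[, rt_z := zfun(rt_ms), by = "subject"]
  trials[]
}

#' Detect the learning criterion within one block
#'
#' A block counts as learned when (i) there is a run of four consecutive
#' advantageous choices and (ii) the fraction of advantageous choices in all
#' trials strictly after that run is at least 65%. The sequence is scanned
#' left to right; the earliest run whose subsequent period satisfies (ii)
#' defines the criterion point (later runs are consulted only when earlier
#' ones fail). A run of four ending on the last trial leaves an empty
#' subsequent period, which satisfies (ii) vacuously.
#'
#' @param choices Character vector (`"advantageous"`/`"disadvantageous"`) or
#'   logical vector (TRUE = advantageous) of the block's choices in order.
#' @param run_length Length of the required advantageous run.
#' @param threshold Minimum advantageous fraction after the run.
#' @return A list with `learned` (flag) and `criterion_index` (index of the
#'   last trial of the qualifying run; NA when not learned). The
#'   after-learning period is `criterion_index + 1` to the end of the block.
#' @export
find_learning_criterion <- function(choices, run_length = 4, threshold = 0.65) {
  adv <- as_advantageous(choices)
  n <- length(adv)
  if (n >= run_length) {
    for (t in run_length:n) {
      if (all(adv[(t - run_length + 1):t])) {
        after <- if (t < n) adv[(t + 1):n] else logical(0)
        ok <- length(after) == 0 || mean(after) >= threshold
        if (ok) {
          return(list(learned = TRUE, criterion_index = as.integer(t)))
        }
      }
    }
  }
  list(learned = FALSE, criterion_index = NA_integer_)
}

as_advantageous <- function(choices) {
  if (is.logical(choices)) return(choices)
  if (is.character(choices) || is.factor(choices)) {
    ch <- as.character(choices)
    bad <- !ch %in% c("advantageous", "disadvantageous")
    if (any(bad)) stop("unknown choice label: ", ch[which(bad)[1]])
    return(ch == "advantageous")
  }
  stop("choices must be logical or advantageous/disadvantageous labels")
}

#' Classify trials into choice-type triplets
#'
#' Each interior trial is labeled by the (previous, current, next) choice
#' triplet: `HP` for A-A-A, `preLP` for A-A-DA, `LP` for A-DA-A and `postLP`
#' for DA-A-A (A = advantageous, DA = disadvantageous); every other pattern
#' and the block-edge trials are `unclassified`. In a learned block only
#' trials strictly after the criterion run receive labels (their triplet may
#' reach back to the run itself); in an unlearned block all interior trials
#' are labeled.
#'
#' @param choices Block choice sequence (see [find_learning_criterion()]).
#' @param learned Did this block reach the learning criterion?
#' @param criterion_index Criterion index when learned.
#' @return Character vector of labels, one per trial.
#' @export
classify_choice_types <- function(choices, learned = FALSE,
                                  criterion_index = NA_integer_) {
  adv <- as_advantageous(choices)
  n <- length(adv)
  labels <- rep("unclassified", n)
  if (n < 3) return(labels)
  eligible_from <- if (isTRUE(learned)) criterion_index + 1L else 1L
  for (t in 2:(n - 1)) {
    if (t < eligible_from) next
    trip <- adv[(t - 1):(t + 1)]
    labels[t] <-
      if (trip[1] && trip[2] && trip[3]) "HP"
      else if (trip[1] && trip[2] && !trip[3]) "preLP"
      else if (trip[1] && !trip[2] && trip[3]) "LP"
      else if (!trip[1] && trip[2] && trip[3]) "postLP"
      else "unclassified"
  }
  labels
}

#' Flag the restricted pre-LP/LP/post-LP subset
#'
#' A pre-LP, LP, post-LP trio is flagged when the three trials are in direct
#' succession and the pre-LP trial's outcome was a gain. The restricted
#' subset guards the main contrasts against purely loss-driven switches.
#'
#' @param labels Per-trial labels from [classify_choice_types()].
#' @param outcomes Per-trial outcomes (`"gain"`/`"loss"`).
#' @return Logical vector marking members of qualifying trios.
#' @export
restricted_subset <- function(labels, outcomes) {
  n <- length(labels)
  stopifnot(length(outcomes) == n)
  flag <- rep(FALSE, n)
  if (n < 3) return(flag)
  for (t in 2:(n - 1)) {
    if (labels[t] == "LP" &&
        labels[t - 1] == "preLP" &&
        labels[t + 1] == "postLP" &&
        outcomes[t - 1] == "gain") {
      flag[(t - 1):(t + 1)] <- TRUE
    }
  }
  flag
}

#' Label all trials of a session bundle
#'
#' Applies the learning criterion per block and the triplet classification,
#' and derives the factors used by the mixed models: `learning`
#' (`"after"` for post-criterion trials of learned blocks, `"none"` for all
#' trials of unlearned blocks, `"pre"` for pre-criterion trials of learned
#' blocks, which the analyses ignore), `choice_type`, the `restricted` flag,
#' and `previous_feedback` / `current_feedback`.
#'
#' @param trials Trials table with `subject`, `block_index`, `trial_index`,
#'   `choice`, `outcome` columns.
#' @param run_length,threshold Learning-criterion settings.
#' @return The table with classification columns added, plus a
#'   `block_status` attribute (per subject x block: learned, criterion_index).
#' @export
classify_trials <- function(trials, run_length = 4, threshold = 0.65) {
  trials <- data.table::as.data.table(trials)
  data.table::setorderv(trials, c("subject", "block_index", "trial_index"))
  learning <- choice_type <- restricted <- NULL
  previous_feedback <- current_feedback <- choice <- outcome <- NULL

  status <- list()
  trials[, c("learning", "choice_type", "restricted") := {
    st <- find_learning_criterion(choice, run_length, threshold)
    labs <- classify_choice_types(choice, st$learned, st$criterion_index)
    res <- restricted_subset(labs, outcome)
    lrn <- if (st$learned) {
      ifelse(seq_along(choice) > st$criterion_index, "after", "pre")
    } else rep("none", length(choice))
    status[[length(status) + 1L]] <<- data.table::data.table(
      subject = .BY$subject, block_index = .BY$block_index,
      learned = st$learned, criterion_index = st$criterion_index
    )
    list(lrn, labs, res)
  }, by = c("subject", "block_index")]

  trials[, current_feedback := outcome]
  trials[, previous_feedback := data.table::shift(outcome),
         by = c("subject", "block_index")]
  out <- trials[]
  data.table::setattr(out, "block_status", data.table::rbindlist(status))
  out
}

#' Summarize advantageous-to-disadvantageous transitions
#'
#' Counts, per subject and learning condition, the transitions from an
#' advantageous to a disadvantageous choice on the next trial, and the
#' percentage of those transitions that immediately followed a loss (the
#' count of all transitions is taken as 100%). Group-level one-sample
#' t-tests compare the subject percentages to 100% (all switches triggered
#' by losses) and to the advantageous option's loss rate expressed in
#' percent (switches independent of feedback); subjects with zero
#' transitions in a condition are omitted from that condition's test.
#'
#' @param trials Labeled trials from [classify_trials()].
#' @param p_loss_pct Reference percentage for the feedback-independence test.
#' @return A list with `per_subject` (subject, condition, n_transitions,
#'   pct_after_loss) and `tests` (condition, reference, t, df, p, n).
#' @export
transition_summary <- function(trials, p_loss_pct = 30) {
  trials <- data.table::as.data.table(trials)
  data.table::setorderv(trials, c("subject", "block_index", "trial_index"))
  learning <- choice <- outcome <- NULL

  per <- trials[learning %in% c("after", "none"), {
    adv <- choice == "advantageous"
    nxt <- data.table::shift(adv, type = "lead")
    same_run <- data.table::shift(trial_index, type = "lead") == trial_index + 1L
    trans <- which(adv & !nxt & !is.na(nxt) & same_run)
    list(n_transitions = length(trans),
         n_after_loss = sum(outcome[trans] == "loss"))
  }, by = c("subject", "learning", "block_index")]
  per <- per[, list(n_transitions = sum(n_transitions),
                    n_after_loss = sum(n_after_loss)),
             by = c("subject", "learning")]
  n_transitions <- n_after_loss <- NULL
  per[, "pct_after_loss" := ifelse(n_transitions > 0,
                                   100 * n_after_loss / n_transitions, NA_real_)]
  data.table::setnames(per, "learning", "condition")

  tests <- data.table::rbindlist(lapply(split(per, per$condition), function(d) {
    x <- d$pct_after_loss[d$n_transitions > 0]
    mk <- function(mu) {
      if (length(x) < 2 || stats::sd(x) == 0) {
        data.table::data.table(condition = d$condition[1], reference = mu,
                               t = NA_real_, df = NA_real_, p = NA_real_,
                               n = length(x))
      } else {
        tt <- one_sample_t(x, mu)
        data.table::data.table(condition = d$condition[1], reference = mu,
                               t = tt$t, df = tt$df, p = tt$p, n = length(x))
      }
    }
    rbind(mk(100), mk(p_loss_pct))
  }))
  list(per_subject = per[], tests = tests)
}

#' Per-subject behavioral summary for the correlational analyses
#'
#' Within the after-learning condition of each subject: the counts of
#' disadvantageous (`n_da`) and advantageous (`n_a`) choices, the proportion
#' `p_da = n_da / (n_da + n_a)`, the number of gains, the LP-minus-HP
#' difference in mean standardized RT, the LP-minus-HP difference in the
#' late-window pupil measure, and the correlation-eligibility flag
#' (more than one LP choice).
#'
#' @param trials Labeled trials including `rt_z`; optionally a pupil-measure
#'   column named by `pupil_col` (z units, e.g. the 1,000--2,200-ms window
#'   mean).
#' @param pupil_col Name of the pupil-measure column, or NULL to skip.
#' @return A data.table, one row per subject.
#' @export
behavior_summary <- function(trials, pupil_col = NULL) {
  trials <- data.table::as.data.table(trials)
  learning <- choice <- outcome <- choice_type <- rt_z <- NULL
  after <- trials[learning == "after"]
  out <- after[, {
    n_da <- sum(choice == "disadvantageous")
    n_a <- sum(choice == "advantageous")
    n_lp <- sum(choice_type == "LP")
    rt_lp <- mean(rt_z[choice_type == "LP"])
    rt_hp <- mean(rt_z[choice_type == "HP"])
    pup <- NA_real_
    if (!is.null(pupil_col)) {
      pv <- .SD[[pupil_col]]
      pup <- mean(pv[choice_type == "LP"], na.rm = TRUE) -
        mean(pv[choice_type == "HP"], na.rm = TRUE)
    }
    list(
      n_da = n_da, n_a = n_a,
      p_da = if (n_da + n_a > 0) n_da / (n_da + n_a) else NA_real_,
      n_gains = sum(outcome == "gain"),
      n_lp = n_lp,
      rt_slowing_lp_minus_hp = rt_lp - rt_hp,
      pupil_lp_minus_hp = pup,
      corr_eligible = n_lp > 1
    )
  }, by = "subject"]
  out[]
}
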