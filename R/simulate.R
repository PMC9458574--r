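# Synthetic session generation: outcome schedules, a value-learning agent
# with deliberate exploration, lognormal response times, and a continuous
# 1 kHz pupil signal with injectable condition effects and artifacts.

condition_levels <- c("HP", "preLP", "LP", "postLP", "no_learning", "other")

restore_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
}

#' Build per-block gain/loss outcome schedules
#'
#' Assigns one gain/loss label per option per trial. Under the default
#' `"exact"` method each block carries exactly `round(p * trials_per_block)`
#' gains for each option in shuffled order, so the printed 70/30 contingency
#' is realized exactly; `"bernoulli"` draws labels independently instead.
#'
#' @param design A [task_design()].
#' @param seed Integer seed, or NULL to use the current RNG state.
#' @param method `"exact"` (default) or `"bernoulli"`.
#' @return A data.table with `block_slot`, `trial_index`, `adv_outcome`,
#'   `dis_outcome`; attribute `realized_p` stores the realized gain
#'   proportions per option.
#' @export
build_outcome_schedule <- function(design, seed = NULL,
                                   method = c("exact", "bernoulli")) {
  method <- match.arg(method)
  restore_seed(seed)
  n <- design$trials_per_block
  draw <- function(p) {
    if (method == "exact") {
      k <- round(p * n)
      sample(rep(c("gain", "loss"), c(k, n - k)))
    } else {
      ifelse(stats::runif(n) < p, "gain", "loss")
    }
  }
  out <- data.table::rbindlist(lapply(seq_len(design$n_blocks), function(b) {
    data.table::data.table(
      block_slot = b,
      trial_index = seq_len(n),
      adv_outcome = draw(design$p_gain_advantageous),
      dis_outcome = draw(design$p_gain_disadvantageous)
    )
  }))
  adv_outcome <- dis_outcome <- NULL
  data.table::setattr(out, "realized_p", c(
    advantageous = mean(out$adv_outcome == "gain"),
    disadvantageous = mean(out$dis_outcome == "gain")
  ))
  out
}

#' Simulate the learning agent's choices for one block
#'
#' A delta-rule value learner (reward coded +1 for gain, -1 for loss) with
#' softmax choice, blended with a win-stay/lose-shift tendency. Once the
#' internal preference `q_adv - q_dis` exceeds the agent's threshold, a
#' deliberate disadvantageous choice is emitted with probability
#' `directed_explore_rate`; these trials are flagged so that recovery tests
#' can rely on ground truth rather than on the agent's realism.
#'
#' @param design A [task_design()].
#' @param agent An [agent_params()].
#' @param block_schedule One block of [build_outcome_schedule()] output.
#' @param seed Integer seed, or NULL.
#' @return A data.table with `trial_index`, `choice`, `outcome`,
#'   `deliberate_explore` and the internal `preference` trajectory
#'   (value difference before the trial's update).
#' @export
simulate_agent_choices <- function(design, agent, block_schedule, seed = NULL) {
  restore_seed(seed)
  n <- nrow(block_schedule)
  stopifnot(n == design$trials_per_block)
  q <- c(adv = 0, dis = 0)
  choice <- character(n)
  outcome <- character(n)
  deliberate <- logical(n)
  pref <- numeric(n)
  prev_adv <- NA
  prev_gain <- NA
  for (t in seq_len(n)) {
    pref[t] <- q[["adv"]] - q[["dis"]]
    p_soft <- 1 / (1 + exp(-agent$inverse_temperature * pref[t]))
    p_wsls <- if (is.na(prev_adv)) 0.5 else if (prev_gain) {
      if (prev_adv) 1 else 0
    } else {
      if (prev_adv) 0 else 1
    }
    p_adv <- (1 - agent$wsls_weight) * p_soft + agent$wsls_weight * p_wsls
    if (pref[t] > agent$preference_threshold &&
        stats::runif(1) < agent$directed_explore_rate) {
      adv <- FALSE
      deliberate[t] <- TRUE
    } else {
      adv <- stats::runif(1) < p_adv
    }
    out_t <- if (adv) block_schedule$adv_outcome[t] else block_schedule$dis_outcome[t]
    r <- if (out_t == "gain") 1 else -1
    arm <- if (adv) "adv" else "dis"
    q[[arm]] <- q[[arm]] + agent$learning_rate * (r - q[[arm]])
    choice[t] <- if (adv) "advantageous" else "disadvantageous"
    outcome[t] <- out_t
    prev_adv <- adv
    prev_gain <- out_t == "gain"
  }
  data.table::data.table(
    trial_index = seq_len(n), choice = choice, outcome = outcome,
    deliberate_explore = deliberate, preference = pref
  )
}

#' Simulate response times for a vector of trial conditions
#'
#' `rt = rt_base_ms * multiplier[condition] * Lognormal(0, sigma)`, rounded
#' to the 1-ms clock.
#'
#' @param conditions Character vector of condition keys (`HP`, `preLP`, `LP`,
#'   `postLP`, `no_learning`, `other`).
#' @param agent An [agent_params()].
#' @param seed Integer seed, or NULL.
#' @return Integer RTs in ms (always >= 1).
#' @export
simulate_rt <- function(conditions, agent, seed = NULL) {
  restore_seed(seed)
  mult <- agent$rt_condition_multipliers[conditions]
  if (anyNA(mult)) stop("unknown condition key in simulate_rt")
  rt <- agent$rt_base_ms * mult *
    stats::rlnorm(length(conditions), 0, agent$rt_lognorm_sigma)
  pmax(1L, as.integer(round(rt)))
}

condition_key <- function(choice_type, learning) {
  ifelse(
    learning == "after" & choice_type %in% c("HP", "preLP", "LP", "postLP"),
    choice_type,
    ifelse(learning == "none" &
             choice_type %in% c("HP", "preLP", "LP", "postLP"),
           "no_learning", "other")
  )
}

# Linear interpolation from a regular knot grid (spacing h, first knot at
# sample 1) to the 1-ms grid; cheaper than stats::approx for this case.
lerp_regular <- function(vals, h, n_ms) {
  nb <- ceiling(n_ms / h)
  i <- rep.int(seq_len(nb), rep.int(h, nb))[seq_len(n_ms)]
  frac <- rep.int(seq.int(0, h - 1) / h, nb)[seq_len(n_ms)]
  vals[i] + (vals[i + 1L] - vals[i]) * frac
}

# Continuous background of the pupil signal, evaluated on a common 16-ms
# knot grid and linearly interpolated to 1 ms in a single pass: slow tonic
# drift (three low-frequency sinusoids, random phases), the hippus-like
# oscillation, and smooth measurement noise (white at `noise_cut_ms` knots,
# so adjacent 1-ms differences stay far below the artifact threshold).
pupil_background <- function(n_ms, params) {
  h <- 16L
  kt <- seq(0, n_ms + 2L * h, by = h)
  bg <- numeric(length(kt))
  if (params$tonic_drift_amp > 0) {
    periods <- c(293e3, 127e3, 61e3)
    w <- c(0.5, 0.3, 0.2)
    ph <- stats::runif(3, 0, 2 * pi)
    for (i in 1:3)
      bg <- bg + params$tonic_drift_amp * w[i] *
        sin(2 * pi * kt / periods[i] + ph[i])
  }
  if (params$hippus_amp > 0) {
    bg <- bg + params$hippus_amp *
      sin(2 * pi * params$hippus_freq_hz * kt / 1000 +
            stats::runif(1, 0, 2 * pi))
  }
  if (params$noise_sd > 0) {
    nk <- seq(0, n_ms + 2 * (h + params$noise_cut_ms),
              by = params$noise_cut_ms)
    nv <- stats::rnorm(length(nk), 0, params$noise_sd)
    bg <- bg + stats::approx(nk, nv, xout = kt)$y
  }
  lerp_regular(bg, h, n_ms)
}

# Accumulate scaled kernels at event onsets into a preallocated signal.
# Modifies `sig` by reference semantics within the caller's loop (no copies).
accumulate_kernels <- function(n, onsets_ms, kernel, scales) {
  out <- numeric(n)
  klen <- length(kernel)
  for (i in seq_along(onsets_ms)) {
    if (scales[i] == 0) next
    i0 <- onsets_ms[i] + 1L
    if (i0 > n) next
    len <- min(klen, n - i0 + 1L)
    idx <- i0:(i0 + len - 1L)
    out[idx] <- out[idx] + scales[i] * kernel[seq_len(len)]
  }
  out
}

#' Synthesize a continuous 1 kHz pupil signal for one subject
#'
#' Additive model: constant baseline + slow tonic drift + stimulus-locked
#' light-reflex dip + response-locked phasic kernel scaled by the trial
#' condition's amplitude + smooth measurement noise. Because the phasic
#' kernel outlasts the intertrial interval, adjacent trials superpose and
#' carryover into the next pretrial baseline arises naturally.
#'
#' @param trials One subject's trials (needs `t_stimulus_on`,
#'   `t_button_press` and `gt_condition` columns), time-ordered.
#' @param params A [pupil_gen_params()].
#' @param t_end_ms Length of the recording (ms); defaults to the last
#'   feedback onset plus the kernel length.
#' @param seed Integer seed, or NULL.
#' @return A data.table with `time_ms` (0-based 1-ms grid), `pupil`
#'   (camera pixels) and `valid` (all TRUE here).
#' @export
synthesize_pupil <- function(trials, params, t_end_ms = NULL, seed = NULL) {
  restore_seed(seed)
  stopifnot(!is.unsorted(trials$t_button_press))
  if (is.null(t_end_ms))
    t_end_ms <- max(trials$t_feedback_on) + params$kernel_len_ms
  n <- as.integer(t_end_ms) + 1L
  kt <- seq(0, params$kernel_len_ms - 1)
  phasic_kernel <- pupil_kernel(kt, params$kernel_shape, params$kernel_tmax_ms)
  reflex_kernel <- -pupil_kernel(seq(0, 1499), shape = 5, tmax_ms = 400)

  amps <- params$amplitude_map[trials$gt_condition]
  sig <- params$baseline_px + pupil_background(n, params) +
    accumulate_kernels(n, trials$t_stimulus_on, reflex_kernel,
                       rep(params$light_reflex_dip, nrow(trials))) +
    accumulate_kernels(n, trials$t_button_press, phasic_kernel, amps)
  data.table::data.table(time_ms = 0:(n - 1L), pupil = sig, valid = TRUE)
}

#' Inject blink and spike artifacts into a clean pupil signal
#'
#' Blinks are contiguous runs of missing samples (durations drawn from
#' `blink_dur_ms_range`); spikes are short (1--3 sample) jumps of more than
#' 10 pixels against the neighboring samples. A ground-truth log is
#' returned so that downstream artifact detection can be tested against the
#' construction.
#'
#' @param samples Clean output of [synthesize_pupil()].
#' @param params A [pupil_gen_params()].
#' @param seed Integer seed, or NULL.
#' @return A list with `samples` (modified) and `log` (data.table:
#'   `kind`, `start_ms`, `end_ms`).
#' @export
inject_artifacts <- function(samples, params, seed = NULL) {
  restore_seed(seed)
  time_ms <- samples$time_ms
  pupil <- as.numeric(samples$pupil)
  valid <- as.logical(samples$valid)
  n <- length(pupil)
  dur_s <- n / params$fs_hz
  log <- list()

  place_runs <- function(n_events, durs, margin, min_sep) {
    # uniformly placed, mutually separated runs away from the boundaries
    starts <- integer(0)
    ends <- integer(0)
    tries <- 0
    k <- 0
    while (k < n_events && tries < n_events * 50) {
      tries <- tries + 1
      d <- durs[(tries - 1L) %% length(durs) + 1L]
      s <- sample.int(n - 2L * margin - d, 1) + margin
      e <- s + d - 1L
      if (k == 0 || all(s > ends + min_sep | e < starts - min_sep)) {
        k <- k + 1
        starts[k] <- s
        ends[k] <- e
      }
    }
    o <- order(starts)
    list(start = starts[o], end = ends[o])
  }

  n_blinks <- stats::rpois(1, params$blink_rate_hz * dur_s)
  blinks <- place_runs(
    n_blinks,
    if (n_blinks) as.integer(round(stats::runif(
      n_blinks * 50, params$blink_dur_ms_range[1],
      params$blink_dur_ms_range[2]))) else 1L,
    margin = 1000L, min_sep = 500L
  )
  n_spikes <- stats::rpois(1, params$spike_rate_hz * dur_s)
  spikes <- place_runs(
    n_spikes,
    if (n_spikes) sample(1:3, n_spikes * 50, replace = TRUE) else 1L,
    margin = 1000L, min_sep = 500L
  )
  # keep spikes clear of blinks so the ground-truth log stays unambiguous
  if (length(spikes$start) && length(blinks$start)) {
    keep <- vapply(seq_along(spikes$start), function(i) {
      all(spikes$start[i] > blinks$end + 500 |
            spikes$end[i] < blinks$start - 500)
    }, logical(1))
    spikes <- list(start = spikes$start[keep], end = spikes$end[keep])
  }

  if (length(blinks$start)) {
    idx <- sequence(blinks$end - blinks$start + 1L, from = blinks$start)
    pupil[idx] <- NA_real_
    valid[idx] <- FALSE
    log$blinks <- data.table::data.table(
      kind = "blink",
      start_ms = time_ms[blinks$start],
      end_ms = time_ms[blinks$end]
    )
  }
  if (length(spikes$start)) {
    for (i in seq_along(spikes$start)) {
      idx <- spikes$start[i]:spikes$end[i]
      delta <- sample(c(-1, 1), 1) * stats::runif(1, 15, 40)
      pupil[idx] <- pupil[idx] + delta
    }
    log$spikes <- data.table::data.table(
      kind = "spike",
      start_ms = time_ms[spikes$start],
      end_ms = time_ms[spikes$end]
    )
  }
  log <- if (length(log)) data.table::rbindlist(log) else
    data.table::data.table(kind = character(0), start_ms = integer(0),
                           end_ms = integer(0))
  data.table::setorderv(log, "start_ms")
  list(samples = data.table::data.table(time_ms = time_ms, pupil = pupil,
                                        valid = valid),
       log = log)
}

#' Simulate a complete multi-subject session
#'
#' For each subject: a reinforcement-scheme order is drawn from the design's
#' permissible orders, per-block outcome schedules are built, the agent
#' produces choices, trials receive event timestamps that respect the task
#' durations (fixation, feedback delay, feedback duration, flat intertrial
#' interval), response times are drawn from the condition-dependent
#' lognormal model, and (optionally) a continuous pupil signal with
#' artifacts is synthesized. Ground-truth columns (`gt_learning`,
#' `gt_choice_type`, `gt_condition`, `deliberate_explore`, `preference`)
#' record the generating condition of every trial.
#'
#' @param design A [task_design()].
#' @param agent An [agent_params()].
#' @param pupil A [pupil_gen_params()].
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer seed for the whole session.
#' @param pupil_signal Generate the 1 kHz pupil stream? (behavior-only
#'   simulations are much faster).
#' @param schedule_method Passed to [build_outcome_schedule()].
#' @return A `session_bundle`: list with `trials` (one table, all subjects),
#'   `samples`, `events`, `artifact_log` (per-subject lists keyed by subject
#'   id) and `config`.
#' @export
simulate_session <- function(design = task_design(),
                             agent = agent_params(),
                             pupil = pupil_gen_params(),
                             n_subjects = 1L,
                             seed = 1L,
                             pupil_signal = TRUE,
                             schedule_method = "exact") {
  stopifnot(n_subjects >= 1)
  set.seed(seed)
  block_gap_ms <- 5000
  all_trials <- vector("list", n_subjects)
  samples <- list()
  events <- list()
  artifact_log <- list()

  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%03d", s)
    agent_s <- agent
    if (agent$subject_sigma > 0) {
      agent_s$inverse_temperature <- agent$inverse_temperature *
        stats::rlnorm(1, 0, agent$subject_sigma)
    }
    p_disengage <- if (agent$disengage_rate > 0) {
      a_shape <- 0.5
      stats::rbeta(1, a_shape,
                   a_shape * (1 - agent$disengage_rate) /
                     agent$disengage_rate)
    } else 0
    order_idx <- sample.int(length(design$scheme_orders), 1)
    scheme_order <- design$scheme_orders[[order_idx]]
    schedule <- build_outcome_schedule(design, seed = NULL,
                                       method = schedule_method)
    sub_trials <- vector("list", design$n_blocks)
    t_clock <- 1000
    ev <- list()
    for (b in seq_len(design$n_blocks)) {
      scheme_id <- scheme_order[b]
      scheme <- design$reinforcement_schemes[[scheme_id]]
      agent_b <- agent_s
      if (stats::runif(1) < p_disengage)
        agent_b$inverse_temperature <- agent$disengaged_beta
      beh <- simulate_agent_choices(design, agent_b,
                                    schedule[schedule$block_slot == b, ])
      st <- find_learning_criterion(beh$choice)
      labs <- classify_choice_types(beh$choice, st$learned, st$criterion_index)
      lrn <- if (st$learned) {
        ifelse(seq_len(nrow(beh)) > st$criterion_index, "after", "pre")
      } else rep("none", nrow(beh))
      cond <- condition_key(labs, lrn)
      rt <- simulate_rt(cond, agent)

      nb <- nrow(beh)
      t_fix <- t_stim <- t_press <- t_fb <- integer(nb)
      ev[[length(ev) + 1L]] <- data.table::data.table(
        timestamp = as.integer(t_clock), label = "BLOCK_START",
        block = b, trial = NA_integer_)
      for (t in seq_len(nb)) {
        t_fix[t] <- t_clock
        t_stim[t] <- t_fix[t] + design$fixation_ms
        t_press[t] <- t_stim[t] + rt[t]
        t_fb[t] <- t_press[t] + design$feedback_delay_ms
        iti <- round(stats::runif(1, design$iti_range_ms[1],
                                  design$iti_range_ms[2]))
        t_clock <- t_fb[t] + design$feedback_dur_ms + iti
      }
      ev[[length(ev) + 1L]] <- data.table::data.table(
        timestamp = as.integer(t_fb[nb] + design$feedback_dur_ms),
        label = "BLOCK_END", block = b, trial = NA_integer_)
      t_clock <- t_clock + block_gap_ms

      sub_trials[[b]] <- data.table::data.table(
        subject = sid,
        block_index = b,
        scheme_id = scheme_id,
        trial_index = beh$trial_index,
        choice = beh$choice,
        rt_ms = rt,
        outcome = beh$outcome,
        outcome_points = ifelse(beh$outcome == "gain",
                                scheme[["gain"]], scheme[["loss"]]),
        position = sample(c("left", "right"), nb, replace = TRUE),
        t_fixation_on = as.integer(t_fix),
        t_stimulus_on = as.integer(t_stim),
        t_button_press = as.integer(t_press),
        t_feedback_on = as.integer(t_fb),
        deliberate_explore = beh$deliberate_explore,
        preference = beh$preference,
        gt_learning = lrn,
        gt_choice_type = labs,
        gt_condition = cond
      )
    }
    tr <- data.table::rbindlist(sub_trials)
    all_trials[[s]] <- tr

    trial_ev <- data.table::rbindlist(lapply(
      c(FIXATION_ON = "t_fixation_on", STIM_ON = "t_stimulus_on",
        BUTTON_PRESS = "t_button_press", FEEDBACK_ON = "t_feedback_on"),
      function(col) data.table::data.table(
        timestamp = tr[[col]], block = tr$block_index, trial = tr$trial_index)
    ), idcol = "label")
    trial_ev <- trial_ev[, c("timestamp", "label", "block", "trial")]
    ev_all <- rbind(data.table::rbindlist(ev), trial_ev)
    data.table::setorderv(ev_all, c("timestamp", "label"))
    events[[sid]] <- ev_all

    if (pupil_signal) {
      clean <- synthesize_pupil(tr, pupil)
      art <- inject_artifacts(clean, pupil)
      samples[[sid]] <- art$samples
      artifact_log[[sid]] <- art$log
    }
  }

  structure(
    list(
      trials = data.table::rbindlist(all_trials),
      samples = samples,
      events = events,
      artifact_log = artifact_log,
      config = list(design = design, agent = agent, pupil = pupil,
                    n_subjects = n_subjects, seed = seed,
                    schedule_method = schedule_method)
    ),
    class = "session_bundle"
  )
}

#' @export
print.session_bundle <- function(x, ...) {
  cat("<session_bundle>\n")
  cat("  subjects:", length(unique(x$trials$subject)), "\n")
  cat("  trials:  ", nrow(x$trials), "\n")
  cat("  pupil:   ", if (length(x$samples)) "1 kHz signal present" else "none",
      "\n")
  invisible(x)
}

#' Calibrate phasic amplitudes to target epoch z-score differences
#'
#' Converts desired condition differences on the z scale (relative to the HP
#' condition) into pixel amplitudes. The conversion uses the closed-form
#' mean of the unit phasic kernel over the analysis window and an empirical
#' estimate of the session-wide standard deviation of the binned signal
#' obtained from a short calibration simulation with condition-free
#' amplitudes, so that a requested LP-minus-HP difference of, say, 0.15 z
#' is realized (up to carryover) by the full preprocessing chain.
#'
#' @param z_effects Named numeric: target z differences vs `HP` for
#'   conditions among `preLP`, `LP`, `postLP` (after learning).
#' @param design,agent,pupil Generator settings to calibrate under.
#' @param window Analysis window (ms relative to the button press) over
#'   which the kernel mean is taken.
#' @param n_cal_subjects,seed Calibration-simulation size and seed.
#' @return A [pupil_gen_params()] whose `amplitude_map` realizes the
#'   requested differences; attribute `calibration` stores the session SD
#'   and kernel window mean used.
#' @export
calibrate_amplitude_map <- function(z_effects,
                                    design = task_design(),
                                    agent = agent_params(),
                                    pupil = pupil_gen_params(),
                                    window = c(-400, 2200),
                                    n_cal_subjects = 2L,
                                    seed = 20260101L) {
  flat <- pupil
  base_amp <- mean(pupil$amplitude_map)
  flat$amplitude_map[] <- base_amp
  flat$blink_rate_hz <- 0
  flat$spike_rate_hz <- 0
  cal <- simulate_session(design, agent, flat, n_subjects = n_cal_subjects,
                          seed = seed, pupil_signal = TRUE)
  sds <- vapply(cal$samples, function(sm) {
    b <- bin_50ms(sm)
    stats::sd(b$pupil[b$valid])
  }, numeric(1))
  sd_hat <- mean(sds)

  tt <- seq(max(window[1], 0), window[2] - 1)
  km <- sum(pupil_kernel(tt, pupil$kernel_shape, pupil$kernel_tmax_ms)) /
    (window[2] - window[1])

  out <- pupil
  hp <- out$amplitude_map[["HP"]]
  for (cond in names(z_effects)) {
    out$amplitude_map[[cond]] <- hp + z_effects[[cond]] * sd_hat / km
  }
  attr(out, "calibration") <- list(sd_binned = sd_hat, kernel_window_mean = km)
  out
}
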