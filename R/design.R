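#' Task design for the two-alternative probabilistic learning task
#'
#' Describes the experimental schedule: five blocks of forty trials in which
#' one option (the advantageous one) is rewarded on 70% of trials and the
#' other (disadvantageous) on 30%, under one of five reinforcement schemes
#' (gain/loss point magnitudes). Event timing follows the task procedure:
#' a 150-ms fixation cross, a stimulus that stays on screen until the button
#' press, feedback shown for 500 ms after a 1,000-ms delay, and a flat
#' 700--1,400-ms intertrial interval.
#'
#' @param n_blocks Number of experimental blocks.
#' @param trials_per_block Trials per block.
#' @param p_gain_advantageous Gain probability of the advantageous option.
#' @param p_gain_disadvantageous Gain probability of the disadvantageous option.
#' @param reinforcement_schemes Named list of `c(gain_points, loss_points)`
#'   integer pairs, one per scheme.
#' @param scheme_orders List of permutations of scheme names; each simulated
#'   subject is assigned one of these block orders at random.
#' @param fixation_ms,feedback_delay_ms,feedback_dur_ms Event durations (ms).
#' @param iti_range_ms Length-2 numeric, the flat intertrial-interval range (ms).
#'
#' @return An object of class `task_design`.
#' @export
task_design <- function(n_blocks = 5L,
                        trials_per_block = 40L,
                        p_gain_advantageous = 0.7,
                        p_gain_disadvantageous = 0.3,
                        reinforcement_schemes = list(
                          I   = c(gain =  20, loss =   0),
                          II  = c(gain =   0, loss = -20),
                          III = c(gain =  50, loss =  20),
                          IV  = c(gain = -20, loss = -50),
                          V   = c(gain =  20, loss = -20)
                        ),
                        scheme_orders = list(
                          c("I", "II", "III", "IV", "V"),
                          c("V", "III", "II", "IV", "I"),
                          c("V", "III", "II", "I", "IV")
                        ),
                        fixation_ms = 150,
                        feedback_delay_ms = 1000,
                        feedback_dur_ms = 500,
                        iti_range_ms = c(700, 1400)) {
  stopifnot(
    n_blocks >= 1, trials_per_block >= 1,
    p_gain_advantageous >= 0, p_gain_advantageous <= 1,
    p_gain_disadvantageous >= 0, p_gain_disadvantageous <= 1,
    p_gain_advantageous > p_gain_disadvantageous,
    fixation_ms > 0, feedback_delay_ms > 0, feedback_dur_ms > 0,
    length(iti_range_ms) == 2, all(iti_range_ms > 0),
    iti_range_ms[1] <= iti_range_ms[2]
  )
  scheme_names <- names(reinforcement_schemes)
  if (is.null(scheme_names) || anyDuplicated(scheme_names))
    stop("reinforcement_schemes must be a uniquely named list")
  for (ord in scheme_orders) {
    if (!setequal(ord, scheme_names) || length(ord) != length(scheme_names))
      stop("every scheme order must be a permutation of the scheme names")
  }
  if (n_blocks != length(scheme_names))
    stop("n_blocks must equal the number of reinforcement schemes")
  structure(
    list(
      n_blocks = as.integer(n_blocks),
      trials_per_block = as.integer(trials_per_block),
      p_gain_advantageous = p_gain_advantageous,
      p_gain_disadvantageous = p_gain_disadvantageous,
      reinforcement_schemes = reinforcement_schemes,
      scheme_orders = scheme_orders,
      fixation_ms = fixation_ms,
      feedback_delay_ms = feedback_delay_ms,
      feedback_dur_ms = feedback_dur_ms,
      iti_range_ms = iti_range_ms
    ),
    class = "task_design"
  )
}

#' Parameters of the simulated learning agent
#'
#' The agent is a deliberately simple stand-in for human behaviour: an
#' incremental value learner (delta rule on a +1/-1 reward code) choosing by
#' softmax, blended with a win-stay/lose-shift tendency. Once its internal
#' preference for the advantageous option exceeds `preference_threshold`, it
#' occasionally (with probability `directed_explore_rate`) emits a deliberate
#' disadvantageous choice -- the simulated analogue of directed exploration.
#' Response times are lognormal around `rt_base_ms` with a multiplicative
#' slowing per choice-type condition; the defaults mirror the qualitative
#' ordering seen in this task (low-payoff choices slowest, high-payoff
#' fastest, both only after learning).
#'
#' @param learning_rate Delta-rule learning rate in (0, 1].
#' @param inverse_temperature Softmax inverse temperature (>= 0).
#' @param directed_explore_rate Probability of a deliberate disadvantageous
#'   choice once the internal preference has formed.
#' @param wsls_weight Weight in `[0, 1]` of the win-stay/lose-shift component.
#' @param preference_threshold Internal value difference above which the
#'   preference is considered formed.
#' @param subject_sigma Between-subject heterogeneity: each simulated
#'   subject's inverse temperature is multiplied by a lognormal factor with
#'   this sigma.
#' @param disengage_rate Mean probability that a block is played in a
#'   disengaged state (inverse temperature replaced by `disengaged_beta`).
#'   The per-subject propensity is drawn from a Beta distribution with this
#'   mean, so most subjects disengage rarely while a few disengage in most
#'   blocks -- reproducing both the share of unlearned ("no learning")
#'   blocks and the occasional subject who never meets the criterion.
#' @param disengaged_beta Inverse temperature used in disengaged blocks.
#' @param rt_base_ms Baseline median response time (ms).
#' @param rt_lognorm_sigma Lognormal sigma of the response-time noise.
#' @param rt_condition_multipliers Named multipliers for conditions
#'   `HP`, `preLP`, `LP`, `postLP` (after learning), `no_learning`
#'   (any classified choice in an unlearned block) and `other`
#'   (unclassified trials).
#'
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(learning_rate = 0.25,
                         inverse_temperature = 7,
                         directed_explore_rate = 0.08,
                         wsls_weight = 0.1,
                         preference_threshold = 0.5,
                         subject_sigma = 0.3,
                         disengage_rate = 0.25,
                         disengaged_beta = 0.5,
                         rt_base_ms = 1200,
                         rt_lognorm_sigma = 0.4,
                         rt_condition_multipliers = c(
                           HP = 1.0, preLP = 1.18, LP = 1.4, postLP = 1.24,
                           no_learning = 1.33, other = 1.25
                         )) {
  stopifnot(
    learning_rate > 0, learning_rate <= 1,
    inverse_temperature >= 0,
    directed_explore_rate >= 0, directed_explore_rate <= 1,
    wsls_weight >= 0, wsls_weight <= 1,
    preference_threshold >= 0, subject_sigma >= 0,
    disengage_rate >= 0, disengage_rate <= 1, disengaged_beta >= 0,
    rt_base_ms > 0, rt_lognorm_sigma >= 0,
    all(rt_condition_multipliers > 0)
  )
  need <- c("HP", "preLP", "LP", "postLP", "no_learning", "other")
  if (!all(need %in% names(rt_condition_multipliers)))
    stop("rt_condition_multipliers must name: ", paste(need, collapse = ", "))
  structure(
    list(
      learning_rate = learning_rate,
      inverse_temperature = inverse_temperature,
      directed_explore_rate = directed_explore_rate,
      wsls_weight = wsls_weight,
      preference_threshold = preference_threshold,
      subject_sigma = subject_sigma,
      disengage_rate = disengage_rate,
      disengaged_beta = disengaged_beta,
      rt_base_ms = rt_base_ms,
      rt_lognorm_sigma = rt_lognorm_sigma,
      rt_condition_multipliers = rt_condition_multipliers[need]
    ),
    class = "agent_params"
  )
}

#' Parameters of the synthetic 1 kHz pupil signal
#'
#' The generated signal is additive: a constant baseline level, a slow tonic
#' drift (sum of low-frequency sinusoids with random phases), a transient
#' pupillary light-reflex dip locked to each stimulus onset, a phasic
#' response kernel locked to each button press and scaled by the trial's
#' condition amplitude, and smooth low-pass measurement noise. The phasic
#' kernel is the canonical unimodal pupil impulse response
#' `h(t) = (t/tmax)^s * exp(s * (1 - t/tmax))`, unit peak at `t = tmax`.
#' Because the kernel outlasts the intertrial interval, responses from
#' adjacent trials superpose and carryover into the next pretrial baseline
#' emerges naturally.
#'
#' @param fs_hz Sampling rate; the analysis chain assumes 1000.
#' @param kernel_shape Shape parameter `s` of the phasic kernel.
#' @param kernel_tmax_ms Peak latency of the phasic kernel (ms).
#' @param kernel_len_ms Length at which the kernel is truncated (ms).
#' @param amplitude_map Named phasic amplitudes (camera pixels) for
#'   conditions `HP`, `preLP`, `LP`, `postLP`, `no_learning`, `other`.
#' @param baseline_px Constant pupil-area baseline (camera pixels).
#' @param hippus_amp Amplitude of the quasi-periodic pupillary oscillation
#'   (hippus-like component, pixels). This bounded oscillation dominates the
#'   session variance, which keeps the z-scored signal's excursions well
#'   inside the 3-SD epoch-exclusion bound on artifact-free data; its period
#'   is much shorter than the epoch averaging windows, so it contributes
#'   little to trial-level measures.
#' @param hippus_freq_hz Frequency of the hippus-like oscillation.
#' @param tonic_drift_amp Total amplitude of the slow drift (pixels).
#' @param light_reflex_dip Depth of the stimulus-locked constriction (pixels).
#' @param noise_sd Standard deviation of the smooth measurement noise (pixels).
#' @param noise_cut_ms Knot spacing of the low-pass noise (ms); noise is
#'   white at this grid and linearly interpolated to 1 ms, so adjacent-sample
#'   derivatives stay far below the artifact threshold.
#' @param blink_rate_hz Expected blink rate (events per second).
#' @param blink_dur_ms_range Length-2 range of blink durations (ms).
#' @param spike_rate_hz Expected rate of short spike artifacts (per second).
#'
#' @return An object of class `pupil_gen_params`.
#' @export
pupil_gen_params <- function(fs_hz = 1000,
                             kernel_shape = 10.1,
                             kernel_tmax_ms = 930,
                             kernel_len_ms = 4000,
                             amplitude_map = c(
                               HP = 25, preLP = 30, LP = 35, postLP = 30,
                               no_learning = 30, other = 28
                             ),
                             baseline_px = 2000,
                             hippus_amp = 60,
                             hippus_freq_hz = 0.47,
                             tonic_drift_amp = 15,
                             light_reflex_dip = 30,
                             noise_sd = 3,
                             noise_cut_ms = 40,
                             blink_rate_hz = 0.15,
                             blink_dur_ms_range = c(80, 300),
                             spike_rate_hz = 0.03) {
  stopifnot(
    fs_hz > 0, kernel_shape > 0, kernel_tmax_ms > 0, kernel_len_ms > 0,
    all(is.finite(amplitude_map)),
    baseline_px > 0, hippus_amp >= 0, hippus_freq_hz > 0,
    tonic_drift_amp >= 0, light_reflex_dip >= 0,
    noise_sd >= 0, noise_cut_ms >= 1,
    blink_rate_hz >= 0, spike_rate_hz >= 0,
    length(blink_dur_ms_range) == 2, all(blink_dur_ms_range > 0),
    blink_dur_ms_range[1] <= blink_dur_ms_range[2]
  )
  need <- c("HP", "preLP", "LP", "postLP", "no_learning", "other")
  if (!all(need %in% names(amplitude_map)))
    stop("amplitude_map must name: ", paste(need, collapse = ", "))
  structure(
    list(
      fs_hz = fs_hz,
      kernel_shape = kernel_shape,
      kernel_tmax_ms = kernel_tmax_ms,
      kernel_len_ms = kernel_len_ms,
      amplitude_map = amplitude_map[need],
      baseline_px = baseline_px,
      hippus_amp = hippus_amp,
      hippus_freq_hz = hippus_freq_hz,
      tonic_drift_amp = tonic_drift_amp,
      light_reflex_dip = light_reflex_dip,
      noise_sd = noise_sd,
      noise_cut_ms = noise_cut_ms,
      blink_rate_hz = blink_rate_hz,
      blink_dur_ms_range = blink_dur_ms_range,
      spike_rate_hz = spike_rate_hz
    ),
    class = "pupil_gen_params"
  )
}

#' Evaluate the unit-peak phasic pupil response kernel
#'
#' @param t_ms Times (ms) at which to evaluate, relative to the event.
#' @param shape Shape parameter `s`.
#' @param tmax_ms Peak latency (ms).
#' @return Kernel values; 0 for `t_ms < 0`, peak value 1 at `t_ms == tmax_ms`.
#' @export
pupil_kernel <- function(t_ms, shape = 10.1, tmax_ms = 930) {
  out <- numeric(length(t_ms))
  pos <- t_ms >= 0
  tt <- t_ms[pos] / tmax_ms
  out[pos] <- tt^shape * exp(shape * (1 - tt))
  out
}
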