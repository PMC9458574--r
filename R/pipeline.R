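# End-to-end orchestration: simulate -> preprocess -> classify -> analyze
# -> report, as one seeded, configured, logged run.

#' Build a run configuration
#'
#' Every switch defaults to the documented analysis decision; the full
#' configuration is serialized into the report so each output is
#' self-describing.
#'
#' @param n_subjects Number of simulated subjects.
#' @param seed Master seed for the run.
#' @param design,agent,pupil Generator settings.
#' @param extreme_rule Epoch exclusion rule (`"any_bin"` or `"epoch_mean"`).
#' @param df_method Denominator-df approximation for the main contrast
#'   tables (`"satterthwaite"` or the large-sample `"asymptotic"` fallback).
#' @param fdr FDR flavor for the pointwise analysis (`"BH"` or `"BY"`).
#' @param window_fallback Analysis window (ms) used when the pointwise
#'   window selection fails.
#' @param use_selected_window Average pupil size over the window selected
#'   from the pointwise analysis (otherwise over `window_fallback`).
#' @param pointwise Run the per-bin analysis (the slowest stage)?
#' @param n_perm Permutations for the correlation tests.
#' @param alpha Significance level for model selection and tests.
#' @param q FDR level for the pointwise analysis.
#' @param rt_limits_ms RT exclusion cutoffs.
#' @param exclude_never_learners Drop subjects that reached the learning
#'   criterion in no block (they contribute no after-learning condition).
#' @param pupil_signal Simulate and analyze the pupil stream?
#' @return list of class `run_config`.
#' @export
run_config <- function(n_subjects = 94L,
                       seed = 1L,
                       design = task_design(),
                       agent = agent_params(),
                       pupil = pupil_gen_params(),
                       extreme_rule = "any_bin",
                       df_method = "satterthwaite",
                       fdr = "BH",
                       window_fallback = c(-400, 2200),
                       use_selected_window = TRUE,
                       pointwise = TRUE,
                       n_perm = 20000L,
                       alpha = 0.05,
                       q = 0.05,
                       rt_limits_ms = c(300, 4000),
                       exclude_never_learners = TRUE,
                       pupil_signal = TRUE) {
  structure(
    list(n_subjects = n_subjects, seed = seed, design = design,
         agent = agent, pupil = pupil, extreme_rule = extreme_rule,
         df_method = df_method,
         fdr = fdr, window_fallback = window_fallback,
         use_selected_window = use_selected_window, pointwise = pointwise,
         n_perm = n_perm, alpha = alpha, q = q,
         rt_limits_ms = rt_limits_ms,
         exclude_never_learners = exclude_never_learners,
         pupil_signal = pupil_signal),
    class = "run_config"
  )
}

#' Read/write a run configuration as YAML
#'
#' The file has sections `task`, `agent`, `pupil` and `run`; every omitted
#' key keeps its default.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  design <- do.call(task_design, as.list(y$task))
  agent_args <- as.list(y$agent)
  if (!is.null(agent_args$rt_condition_multipliers))
    agent_args$rt_condition_multipliers <-
      unlist(agent_args$rt_condition_multipliers)
  agent <- do.call(agent_params, agent_args)
  pupil_args <- as.list(y$pupil)
  if (!is.null(pupil_args$amplitude_map))
    pupil_args$amplitude_map <- unlist(pupil_args$amplitude_map)
  pupil <- do.call(pupil_gen_params, pupil_args)
  run_args <- as.list(y$run)
  do.call(run_config, c(list(design = design, agent = agent, pupil = pupil),
                        run_args))
}

#' @rdname read_run_config
#' @param config A `run_config` to serialize.
#' @export
write_run_config <- function(config, path) {
  y <- list(
    task = config$design[setdiff(names(config$design),
                                 c("reinforcement_schemes", "scheme_orders"))],
    agent = unclass(config$agent),
    pupil = unclass(config$pupil),
    run = config[setdiff(names(config), c("design", "agent", "pupil"))]
  )
  y$agent$rt_condition_multipliers <- as.list(config$agent$rt_condition_multipliers)
  y$pupil$amplitude_map <- as.list(config$pupil$amplitude_map)
  yaml::write_yaml(y, path)
  invisible(path)
}

safe_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

log_stage <- function(stage, msg, verbose) {
  if (verbose) message(sprintf("[%s] %s", stage, msg))
}

main_factor_levels <- function(d) {
  d$choice_type <- factor(d$choice_type,
                          levels = c("HP", "preLP", "LP", "postLP"))
  d$learning <- factor(d$learning, levels = c("after", "none"))
  d$previous_feedback <- factor(d$previous_feedback,
                                levels = c("gain", "loss"))
  d$current_feedback <- factor(d$current_feedback,
                               levels = c("gain", "loss"))
  d
}

analysis_subset <- function(trials) {
  d <- trials[trials$learning %in% c("after", "none") &
                trials$choice_type %in% c("HP", "preLP", "LP", "postLP"), ]
  main_factor_levels(as.data.frame(d))
}

fit_main_model <- function(d, response, alpha, df_method = "satterthwaite") {
  # factors without two observed levels (tiny runs) cannot enter the model
  want <- c("choice_type", "previous_feedback", "learning")
  ok <- vapply(want, function(v) {
    length(unique(d[[v]][!is.na(d[[v]]) & !is.na(d[[response]])])) >= 2
  }, logical(1))
  if (!any(ok)) stop("no testable fixed factor for response ", response)
  sel <- step_down(d, response, paste(want[ok], collapse = " * "),
                   alpha = alpha)
  anova_tab <- if (length(sel$fixed)) anova_type3(sel$fit) else
    data.frame(term = character(0), F = numeric(0), df_num = numeric(0),
               df_den = numeric(0), p = numeric(0))
  has_ct <- any(grepl("choice_type", sel$fixed))
  contrasts_ct <- if (has_ct)
    marginal_mean_contrasts(sel$fit, "choice_type",
                            df_method = df_method) else NULL
  by_learning <- if (has_ct && any(grepl("learning", sel$fixed)))
    marginal_mean_contrasts(sel$fit, "choice_type", by = "learning",
                            df_method = df_method) else NULL
  learning_by_ct <- if (has_ct && any(grepl("learning", sel$fixed)))
    marginal_mean_contrasts(sel$fit, "learning", by = "choice_type",
                            df_method = df_method) else NULL
  list(selection = sel[c("fixed", "random", "history")],
       anova = anova_tab, contrasts = contrasts_ct,
       contrasts_by_learning = by_learning,
       learning_by_choice_type = learning_by_ct)
}

#' Run the full analysis pipeline on a simulated session
#'
#' Stages: simulate -> RT cleaning and z-scoring -> learning/choice-type
#' classification -> pupil preprocessing -> behavioral statistics ->
#' pointwise window selection -> main mixed models on RT and pupil size ->
#' pretrial and baseline-corrected variants -> permutation correlations ->
#' condition summary tables. Deterministic under a fixed configuration and
#' seed.
#'
#' @param config A [run_config()].
#' @param verbose Log one line per stage?
#' @return A report list; see the elements of the returned object.
#' @export
run_pipeline <- function(config = run_config(), verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  report <- list(config = config)

  bundle <- safe_stage("simulate", simulate_session(
    config$design, config$agent, config$pupil,
    n_subjects = config$n_subjects, seed = config$seed,
    pupil_signal = config$pupil_signal))
  log_stage("simulate", sprintf("%d trials, %d subjects",
                                nrow(bundle$trials), config$n_subjects),
            verbose)

  fr <- safe_stage("filter_rt",
                   filter_rt(bundle$trials, config$rt_limits_ms[1],
                             config$rt_limits_ms[2]))
  trials <- safe_stage("zscore_rt", zscore_rt(fr$trials))
  trials <- safe_stage("classify", classify_trials(trials))
  block_status <- attr(trials, "block_status")

  dropped_subjects <- character(0)
  if (config$exclude_never_learners) {
    learned_any <- tapply(block_status$learned, block_status$subject, any)
    dropped_subjects <- names(learned_any)[!learned_any]
    trials <- trials[!trials$subject %in% dropped_subjects, ]
  }
  report$block_status <- block_status
  report$counts <- list(
    n_trials_simulated = nrow(bundle$trials),
    rt_excluded_fraction = fr$excluded_fraction,
    n_trials_analyzed = nrow(trials),
    dropped_subjects = dropped_subjects,
    blocks_learned = sum(block_status$learned),
    blocks_total = nrow(block_status)
  )
  log_stage("classify", sprintf(
    "%d/%d blocks learned; %d subjects never learned",
    sum(block_status$learned), nrow(block_status),
    length(dropped_subjects)), verbose)

  pp <- NULL
  window_used <- config$window_fallback
  if (config$pupil_signal) {
    bundle_kept <- bundle
    bundle_kept$samples <- bundle$samples[
      setdiff(names(bundle$samples), dropped_subjects)]
    pp <- safe_stage("preprocess", preprocess_pupil(
      bundle_kept, main_window = config$window_fallback,
      extreme_rule = config$extreme_rule))
    report$preprocessing <- pp$report
    log_stage("preprocess", sprintf(
      "%d epochs, %d excluded", nrow(pp$meta),
      sum(!pp$meta$included)), verbose)
  }

  # pointwise analysis and window selection (after-learning trials)
  if (config$pupil_signal && config$pointwise) {
    labels <- trials[, c("subject", "block_index", "trial_index",
                         "scheme_id", "choice_type", "learning")]
    epo <- merge(pp$epochs, labels,
                 by = c("subject", "block_index", "trial_index"),
                 sort = FALSE)
    epo <- epo[epo$learning == "after" &
                 epo$choice_type %in% c("HP", "preLP", "LP", "postLP"), ]
    pw <- safe_stage("pointwise", pointwise_contrasts(
      epo, q = config$q, fdr = config$fdr))
    report$pointwise <- pw
    ws <- tryCatch(select_window(pw), window_error = function(e) {
      log_stage("window", paste("fallback:", conditionMessage(e)), verbose)
      NULL
    })
    report$window <- ws
    if (!is.null(ws) && config$use_selected_window)
      window_used <- unname(ws$overlap)
  }
  report$window_used <- window_used

  # per-trial pupil measures on the selected window
  measures <- trials
  if (config$pupil_signal) {
    im2 <- safe_stage("interval_means", {
      ms <- list()
      for (sid in unique(trials$subject)) {
        tr_s <- bundle$trials[bundle$trials$subject == sid, ]
        ep_s <- pp$epochs[pp$epochs$subject == sid, ]
        meta_s <- pp$meta[pp$meta$subject == sid, ]
        bl_s <- pp$measures[pp$measures$subject == sid,
                            c("block_index", "trial_index", "baseline")]
        m <- interval_means(ep_s, meta_s, bl_s, main_window = window_used)
        m$subject <- sid
        ms[[sid]] <- m
      }
      data.table::rbindlist(ms)
    })
    measures <- merge(trials, im2,
                      by = c("subject", "block_index", "trial_index"),
                      all.x = TRUE, sort = FALSE)
  }

  # behavioral statistics
  report$transitions <- safe_stage(
    "transitions",
    transition_summary(trials,
                       p_loss_pct = 100 * (1 - config$design$p_gain_advantageous)))
  pupil_col <- if (config$pupil_signal) "pupil_feedback" else NULL
  report$behavior <- safe_stage("behavior",
                                behavior_summary(measures, pupil_col))
  lp_shares <- trials[trials$learning %in% c("after", "none"), ]
  lp_by <- tapply(lp_shares$choice == "disadvantageous",
                  list(factor(lp_shares$subject),
                       factor(lp_shares$learning,
                              levels = c("after", "none"))), mean)
  report$p_da_by_condition <- data.frame(
    condition = c("after", "none"),
    mean_pct = c(mean(lp_by[, "after"], na.rm = TRUE) * 100,
                 mean(lp_by[, "none"], na.rm = TRUE) * 100),
    sd_pct = c(stats::sd(lp_by[, "after"], na.rm = TRUE) * 100,
               stats::sd(lp_by[, "none"], na.rm = TRUE) * 100)
  )
  both <- stats::complete.cases(lp_by)
  report$p_da_paired_t <- if (sum(both) >= 2 &&
                              stats::sd(lp_by[both, "after"] -
                                        lp_by[both, "none"]) > 0) {
    tt <- stats::t.test(lp_by[both, "none"] * 100, lp_by[both, "after"] * 100,
                        paired = TRUE)
    list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
  } else NULL

  # main mixed models
  d_main <- analysis_subset(measures)
  report$rt_model <- safe_stage("rt_model",
                                fit_main_model(d_main, "rt_z", config$alpha, config$df_method))
  if (config$pupil_signal) {
    report$pupil_model <- safe_stage(
      "pupil_model", fit_main_model(d_main, "pupil_main", config$alpha, config$df_method))
    report$pretrial_model <- safe_stage(
      "pretrial_model", fit_main_model(d_main, "baseline", config$alpha, config$df_method))
    report$baseline_corrected_model <- safe_stage(
      "bc_model", fit_main_model(d_main, "pupil_main_bc", config$alpha, config$df_method))
    restricted <- d_main[d_main$restricted | d_main$choice_type == "HP", ]
    report$restricted_models <- tryCatch(list(
      rt = fit_main_model(restricted, "rt_z", config$alpha, config$df_method),
      pupil = fit_main_model(restricted, "pupil_main", config$alpha, config$df_method)
    ), error = function(e) paste("restricted subset untestable:",
                                 conditionMessage(e)))
  }

  # permutation correlations
  beh <- report$behavior
  elig <- beh[beh$corr_eligible == TRUE, ]
  corr_seed <- function(k) (config$seed %% 1000L) * 1000L + k
  mk_corr <- function(x, y, k) {
    tryCatch(perm_corr(x, y, n_perm = config$n_perm, seed = corr_seed(k)),
             error = function(e) paste("untestable:", conditionMessage(e)))
  }
  report$correlations <- list(
    gains_vs_p_da = mk_corr(100 * beh$p_da, beh$n_gains, 1L),
    rt_slowing_vs_p_da = mk_corr(100 * elig$p_da,
                                 elig$rt_slowing_lp_minus_hp, 2L),
    pupil_vs_p_da = if (config$pupil_signal)
      mk_corr(100 * elig$p_da, elig$pupil_lp_minus_hp, 3L) else NULL,
    n_eligible = nrow(elig)
  )

  report$summary_tables <- safe_stage("summary",
                                      make_summary_tables(measures))
  report$trials <- measures
  class(report) <- "pupilexplore_report"
  report
}

#' Condition summary tables (mean, SEM, counts)
#'
#' Per ChoiceType x Learning x PreviousFeedback cell: trial count and mean
#' with standard error for standardized RT and each pupil measure present.
#' Empty cells are emitted with a count of zero and no mean.
#'
#' @param measures Labeled trial table with `rt_z` and optional pupil
#'   measure columns.
#' @return data.table, one row per condition cell and measure.
#' @export
make_summary_tables <- function(measures) {
  measures <- data.table::as.data.table(measures)
  d <- measures[measures$learning %in% c("after", "none") &
                  measures$choice_type %in%
                  c("HP", "preLP", "LP", "postLP"), ]
  value_cols <- intersect(c("rt_z", "rt_ms", "pupil_main", "pupil_decision",
                            "pupil_anticipation", "pupil_feedback",
                            "baseline", "pupil_main_bc"), names(d))
  cells <- data.table::CJ(choice_type = c("HP", "preLP", "LP", "postLP"),
                          learning = c("after", "none"),
                          previous_feedback = c("gain", "loss"))
  out <- list()
  for (vc in value_cols) {
    g <- d[!is.na(d[[vc]]) & !is.na(d$previous_feedback),
           list(n = .N, mean = mean(.SD[[1]]),
                sem = stats::sd(.SD[[1]]) / sqrt(.N)),
           by = c("choice_type", "learning", "previous_feedback"),
           .SDcols = vc]
    g <- merge(cells, g,
               by = c("choice_type", "learning", "previous_feedback"),
               all.x = TRUE)
    g$n[is.na(g$n)] <- 0L
    g$measure <- vc
    out[[vc]] <- g
  }
  data.table::rbindlist(out)
}

#' Write a pipeline report to disk
#'
#' Emits the tabular sections as TSV and the scalar sections as JSON; the
#' configuration is serialized alongside so every output is reproducible.
#'
#' @param report Output of [run_pipeline()].
#' @param directory Target directory.
#' @return The directory, invisibly.
#' @export
write_report <- function(report, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, name) {
    if (!is.null(x))
      data.table::fwrite(data.table::as.data.table(x),
                         file.path(directory, name), sep = "\t")
  }
  wt(report$trials, "labeled_trials.tsv")
  wt(report$summary_tables, "summary_tables.tsv")
  wt(report$preprocessing, "preprocessing_report.tsv")
  wt(report$pointwise, "pointwise_qvalues.tsv")
  wt(report$behavior, "behavior_summary.tsv")
  wt(report$transitions$per_subject, "transitions_per_subject.tsv")
  wt(report$transitions$tests, "transition_tests.tsv")
  wt(report$rt_model$anova, "rt_anova.tsv")
  if (!is.null(report$pupil_model)) {
    wt(report$pupil_model$anova, "pupil_anova.tsv")
  }
  scalars <- list(
    window_used = report$window_used,
    counts = report$counts[c("n_trials_simulated", "rt_excluded_fraction",
                             "n_trials_analyzed", "blocks_learned",
                             "blocks_total")],
    p_da_by_condition = report$p_da_by_condition,
    correlations = lapply(
      Filter(function(x) is.list(x), report$correlations),
      function(cr) cr[c("r", "p_perm", "n_perm", "n")]),
    seed = report$config$seed,
    fdr = report$config$fdr
  )
  jsonlite::write_json(scalars, file.path(directory, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_run_config(report$config, file.path(directory, "config.yaml"))
  invisible(directory)
}
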