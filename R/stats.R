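# Mixed-effects statistics: crossed random-intercept models, step-down
# selection, type-III tests with Satterthwaite denominator df,
# Tukey-adjusted marginal-mean contrasts, pointwise epoch analysis with FDR
# window selection, permutation correlations and criterion-calibration
# helpers.

default_random <- c("subject", "block_index", "scheme_id")

build_formula <- function(response, fixed, random) {
  fx <- if (length(fixed) == 0) "1" else paste(fixed, collapse = " + ")
  rnd <- if (length(random)) {
    paste(sprintf("(1 | %s)", random), collapse = " + ")
  } else NULL
  stats::as.formula(paste(response, "~",
                          paste(c(fx, rnd), collapse = " + ")))
}

#' Fit a linear mixed model with crossed random intercepts
#'
#' REML fit of `response ~ fixed terms + (1|subject) + (1|block_index) +
#' (1|scheme_id)` (or any subset of random grouping factors). When no
#' random factors remain the model collapses to ordinary least squares.
#' Singular fits (a variance component estimated at the zero boundary) are
#' reported by lme4 as messages and returned as-is, never silently dropped.
#'
#' @param data Trial-level data; grouping columns are converted to factors.
#' @param response Response column name (`rt_z`, `pupil_main`, ...).
#' @param fixed Character vector of fixed-effect terms, e.g.
#'   `"choice_type * previous_feedback * learning"`.
#' @param random Character vector of random-intercept grouping columns.
#' @return An `lmerModLmerTest` fit (or `lm` when `random` is empty) with
#'   attribute `spec` recording the request.
#' @export
fit_lmm <- function(data, response, fixed, random = default_random) {
  data <- as.data.frame(data)
  fvars <- all.vars(stats::as.formula(paste("~", paste(
    c(fixed, "1"), collapse = "+"))))
  for (v in intersect(c(fvars, random), names(data))) {
    if (is.character(data[[v]]) || is.logical(data[[v]]))
      data[[v]] <- factor(data[[v]])
  }
  data <- data[stats::complete.cases(data[, c(response, fvars[fvars %in% names(data)], random), drop = FALSE]), ]
  for (v in fvars[fvars %in% names(data)]) {
    if (is.factor(data[[v]]) && nlevels(droplevels(data[[v]])) < 2)
      stop("fixed factor '", v, "' has fewer than 2 observed levels")
  }
  fml <- build_formula(response, fixed, random)
  fit <- if (length(random)) {
    lmerTest::lmer(fml, data = data, REML = TRUE)
  } else {
    stats::lm(fml, data = data)
  }
  attr(fit, "spec") <- list(response = response, fixed = fixed,
                            random = random)
  fit
}

#' Type III ANOVA with Satterthwaite denominator degrees of freedom
#'
#' @param fit A fit from [fit_lmm()].
#' @return data.frame with one row per fixed term: F, numerator and
#'   denominator df, p. For an `lm` fit the marginality-respecting
#'   `drop1` F tests are returned instead.
#' @export
anova_type3 <- function(fit) {
  if (inherits(fit, "lmerModLmerTest")) {
    tab <- as.data.frame(stats::anova(fit, type = 3, ddf = "Satterthwaite"))
    data.frame(term = rownames(tab), F = tab$`F value`,
               df_num = tab$NumDF, df_den = tab$DenDF,
               p = tab$`Pr(>F)`, row.names = NULL)
  } else if (inherits(fit, "lm")) {
    tab <- stats::drop1(fit, scope = stats::formula(fit), test = "F")
    tab <- tab[-1, , drop = FALSE]
    data.frame(term = rownames(tab), F = tab$`F value`,
               df_num = tab$Df, df_den = stats::df.residual(fit),
               p = tab$`Pr(>F)`, row.names = NULL)
  } else {
    stop("unsupported fit class")
  }
}

term_factors <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

removable_terms <- function(terms_vec) {
  # a term is removable when its factor set is not a proper subset of
  # another surviving term's factor set (marginality)
  keep <- vapply(terms_vec, function(a) {
    fa <- term_factors(a)
    !any(vapply(terms_vec, function(b) {
      if (identical(a, b)) return(FALSE)
      fb <- term_factors(b)
      all(fa %in% fb)
    }, logical(1)))
  }, logical(1))
  terms_vec[keep]
}

expand_terms <- function(fixed) {
  attr(stats::terms(stats::as.formula(paste("~", paste(fixed, collapse = "+")))),
       "term.labels")
}

random_lrt <- function(data, response, fixed, random, drop) {
  full <- fit_lmm(data, response, fixed, random)
  reduced_random <- setdiff(random, drop)
  ll_full <- as.numeric(stats::logLik(full))
  ll_red <- if (length(reduced_random)) {
    as.numeric(stats::logLik(fit_lmm(data, response, fixed, reduced_random)))
  } else {
    fml <- build_formula(response, fixed, character(0))
    as.numeric(stats::logLik(stats::lm(fml, data = as.data.frame(data)),
                             REML = TRUE))
  }
  stat <- 2 * (ll_full - ll_red)
  # boundary mixture 1/2 chi^2_0 + 1/2 chi^2_1 for a variance component
  p <- if (stat <= 0) 1 else 0.5 * stats::pchisq(stat, df = 1,
                                                 lower.tail = FALSE)
  list(stat = stat, p = p)
}

#' Backward (step-down) model selection
#'
#' Stage 1 removes, one at a time, the random intercept with the largest
#' nonsignificant restricted-likelihood-ratio p-value (boundary mixture
#' 1/2 chi-squared(0) + 1/2 chi-squared(1)). Stage 2 iteratively removes
#' the nonsignificant fixed term with the highest type-III Satterthwaite
#' p-value, respecting marginality: a term is only removable while no
#' surviving interaction contains it. Elimination stops when every
#' remaining term is significant at `alpha`; an intercept-only model is a
#' legitimate outcome.
#'
#' @param data,response,fixed,random As in [fit_lmm()].
#' @param alpha Significance level for retention.
#' @return list with `fixed` and `random` (surviving terms), `fit` (final
#'   model) and `history` (data.frame of eliminated terms with p-values).
#' @export
step_down <- function(data, response, fixed, random = default_random,
                      alpha = 0.05) {
  history <- list()
  random_cur <- random
  fixed_cur <- expand_terms(fixed)

  repeat {
    if (length(random_cur) == 0) break
    ps <- vapply(random_cur, function(r) {
      random_lrt(data, response, fixed_cur, random_cur, r)$p
    }, numeric(1))
    worst <- which.max(ps)
    if (ps[worst] > alpha) {
      history[[length(history) + 1L]] <- data.frame(
        stage = "random", term = random_cur[worst], p = ps[worst])
      random_cur <- random_cur[-worst]
    } else break
  }

  repeat {
    if (length(fixed_cur) == 0) break
    fit <- fit_lmm(data, response, fixed_cur, random_cur)
    tab <- anova_type3(fit)
    cand <- removable_terms(fixed_cur)
    sub <- tab[tab$term %in% cand, , drop = FALSE]
    if (nrow(sub) == 0) break
    worst <- which.max(sub$p)
    if (is.na(sub$p[worst]) || sub$p[worst] > alpha) {
      history[[length(history) + 1L]] <- data.frame(
        stage = "fixed", term = sub$term[worst], p = sub$p[worst])
      fixed_cur <- setdiff(fixed_cur, sub$term[worst])
    } else break
  }

  final <- fit_lmm(data, response,
                   if (length(fixed_cur)) fixed_cur else character(0),
                   random_cur)
  list(
    fixed = fixed_cur,
    random = random_cur,
    fit = final,
    history = if (length(history)) do.call(rbind, history) else
      data.frame(stage = character(0), term = character(0), p = numeric(0))
  )
}

#' Tukey-adjusted pairwise marginal-mean contrasts
#'
#' Estimated marginal means average over the other factors with equal
#' weights; all pairwise differences within `factor` (optionally split by
#' the levels of `by`) are adjusted with the studentized-range (Tukey)
#' method, using Satterthwaite degrees of freedom.
#'
#' @param fit A fit from [fit_lmm()].
#' @param factor Factor whose levels are compared.
#' @param by Optional split factor.
#' @param df_method `"satterthwaite"` (default) or `"asymptotic"`: the
#'   denominator-df approximation for the contrasts. The asymptotic
#'   (infinite-df) setting is a fallback for large samples, where the two
#'   coincide numerically but the Satterthwaite computation is costly.
#' @return list with `emmeans` and `contrasts` data.frames.
#' @export
marginal_mean_contrasts <- function(fit, factor, by = NULL,
                                    df_method = c("satterthwaite",
                                                  "asymptotic")) {
  df_method <- match.arg(df_method)
  spec <- if (is.null(by)) {
    stats::as.formula(paste("~", factor))
  } else {
    stats::as.formula(paste("~", factor, "|", by))
  }
  em <- if (inherits(fit, "lmerMod") && df_method == "asymptotic") {
    emmeans::emmeans(fit, spec, lmer.df = "asymptotic")
  } else {
    emmeans::emmeans(fit, spec, lmer.df = "satterthwaite",
                     lmerTest.limit = 50000)
  }
  prs <- emmeans::contrast(em, method = "pairwise", adjust = "tukey")
  list(emmeans = as.data.frame(em), contrasts = as.data.frame(prs))
}

#' Pointwise epoch analysis with FDR correction
#'
#' Fits, independently for each 50-ms bin of the response-locked epoch, the
#' model `z ~ choice_type + (1|subject) + (1|block_index) + (1|scheme_id)`,
#' computes the Tukey-adjusted contrasts of pre-LP, LP and post-LP against
#' HP, and then corrects each contrast's p-values across the bins with the
#' false discovery rate at level `q`. Bins where a model cannot be fitted
#' (missing factor levels) are marked untestable and excluded from the FDR
#' family; the realized family size is reported.
#'
#' @param epoch_data Long table with columns `z`, `bin`, `rel_ms`,
#'   `choice_type`, `subject`, `block_index`, `scheme_id` (typically the
#'   after-learning subset).
#' @param q FDR level.
#' @param fdr `"BH"` (Benjamini-Hochberg, default) or `"BY"`
#'   (Benjamini-Yekutieli).
#' @param random Random grouping factors for the per-bin model.
#' @param df_method Denominator-df approximation for the per-bin contrasts;
#'   defaults to the large-sample (asymptotic) setting because each bin's
#'   model is fitted on thousands of epochs, where the Satterthwaite df are
#'   effectively infinite.
#' @return data.table with one row per bin x contrast: `estimate`, `p`,
#'   `q_value`, `sig`, `testable`; attributes `fdr`, `family_size`.
#' @export
pointwise_contrasts <- function(epoch_data, q = 0.05, fdr = c("BH", "BY"),
                                random = default_random,
                                df_method = "asymptotic") {
  fdr <- match.arg(fdr)
  epoch_data <- data.table::as.data.table(epoch_data)
  bins <- sort(unique(epoch_data$bin))
  rows <- list()
  for (b in bins) {
    d <- epoch_data[epoch_data$bin == b & !is.na(epoch_data$z), ]
    rel <- d$rel_ms[1]
    ok <- length(unique(d$choice_type)) ==
      length(unique(epoch_data$choice_type)) && nrow(d) > 8
    res <- NULL
    if (ok) {
      res <- tryCatch({
        fit <- fit_lmm(d, "z", "choice_type", random)
        mm <- marginal_mean_contrasts(fit, "choice_type",
                                      df_method = df_method)
        ct <- mm$contrasts
        ct[grepl("HP", ct$contrast), , drop = FALSE]
      }, error = function(e) NULL)
    }
    if (is.null(res)) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        bin = b, rel_ms = rel,
        contrast = c("preLP-HP", "LP-HP", "postLP-HP"),
        estimate = NA_real_, p = NA_real_, testable = FALSE)
    } else {
      out <- lapply(c("preLP", "LP", "postLP"), function(lv) {
        i <- which(res$contrast == paste("HP -", lv))
        j <- which(res$contrast == paste(lv, "- HP"))
        if (length(i)) {
          data.table::data.table(contrast = paste0(lv, "-HP"),
                                 estimate = -res$estimate[i],
                                 p = res$p.value[i])
        } else if (length(j)) {
          data.table::data.table(contrast = paste0(lv, "-HP"),
                                 estimate = res$estimate[j],
                                 p = res$p.value[j])
        } else {
          data.table::data.table(contrast = paste0(lv, "-HP"),
                                 estimate = NA_real_, p = NA_real_)
        }
      })
      out <- data.table::rbindlist(out)
      out$bin <- b
      out$rel_ms <- rel
      out$testable <- !is.na(out$p)
      rows[[length(rows) + 1L]] <- out
    }
  }
  pw <- data.table::rbindlist(rows, use.names = TRUE, fill = TRUE)
  pw$q_value <- NA_real_
  fam <- integer(0)
  for (ctr in unique(pw$contrast)) {
    idx <- which(pw$contrast == ctr & pw$testable)
    fam[ctr] <- length(idx)
    if (length(idx))
      pw$q_value[idx] <- stats::p.adjust(pw$p[idx], method = fdr)
  }
  pw$sig <- !is.na(pw$q_value) & pw$q_value <= q
  data.table::setorderv(pw, c("contrast", "bin"))
  data.table::setattr(pw, "fdr", fdr)
  data.table::setattr(pw, "family_size", fam)
  pw[]
}

spans_from_mask <- function(rel_ms, sig, bin_ms = 50) {
  o <- order(rel_ms)
  rel_ms <- rel_ms[o]
  sig <- sig[o]
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.table::data.table(
    start_ms = rel_ms[starts[keep]],
    end_ms = rel_ms[ends[keep]] + bin_ms
  )
}

#' Select the analysis window from pointwise significance masks
#'
#' For each contrast, the maximal contiguous significant span containing
#' the response time point (the bin covering 0 ms); the selected window is
#' the intersection (overlap) of the three spans. A contrast without a
#' significant span at the response raises an error of class
#' `window_error`, prompting the configured fallback window.
#'
#' @param pw Output of [pointwise_contrasts()], or any table with columns
#'   `contrast`, `rel_ms`, `sig`.
#' @param bin_ms Bin width (ms).
#' @return list with `spans` (per contrast) and `overlap = c(start, end)`.
#' @export
select_window <- function(pw, bin_ms = 50) {
  pw <- data.table::as.data.table(pw)
  spans <- list()
  for (ctr in unique(pw$contrast)) {
    d <- pw[pw$contrast == ctr, ]
    sp <- spans_from_mask(d$rel_ms, d$sig, bin_ms)
    hit <- sp[sp$start_ms <= 0 & sp$end_ms > 0, ]
    if (nrow(hit) == 0) {
      stop(structure(class = c("window_error", "error", "condition"),
                     list(message = paste0(
                       "no significant span containing the response for ",
                       "contrast ", ctr, "; use the fallback window"),
                       call = NULL)))
    }
    spans[[ctr]] <- c(start_ms = hit$start_ms[1], end_ms = hit$end_ms[1])
  }
  lo <- max(vapply(spans, `[[`, numeric(1), "start_ms"))
  hi <- min(vapply(spans, `[[`, numeric(1), "end_ms"))
  if (lo >= hi) {
    stop(structure(class = c("window_error", "error", "condition"),
                   list(message = "empty overlap of significant spans",
                        call = NULL)))
  }
  list(spans = spans, overlap = c(start_ms = lo, end_ms = hi))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  r <- 0L
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out[r + seq_len(nrow(block)), ] <- block
    r <- r + nrow(block)
  }
  out
}

#' Permutation test for a Pearson correlation
#'
#' Reshuffles one variable, recomputes the correlation each time, and
#' estimates the two-sided p-value as
#' `(1 + #(|r*| >= |r|)) / (1 + n_perm)`. When the sample is small enough
#' that all `n!` orderings fit within `n_perm`, the test enumerates them
#' exhaustively and the p-value is exact.
#'
#' @param x,y Paired numeric vectors (length >= 3, nonzero variance).
#' @param n_perm Number of random permutations (default 20,000).
#' @param seed Integer seed, or NULL for the current RNG state.
#' @return list with `r`, `p_perm`, `n_perm`, `exhaustive`, `n`.
#' @export
perm_corr <- function(x, y, n_perm = 20000, seed = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("perm_corr: need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("perm_corr: zero variance")
  restore_seed(seed)
  r <- stats::cor(x, y)
  xs <- (x - mean(x)) / stats::sd(x)
  ys <- (y - mean(y)) / stats::sd(y)
  tol <- 1e-12
  if (factorial(n) <= n_perm) {
    P <- all_permutations(n)
    rstar <- (matrix(xs[P], nrow(P), n) %*% ys) / (n - 1)
    p <- mean(abs(rstar) >= abs(r) - tol)
    return(list(r = r, p_perm = p, n_perm = nrow(P), exhaustive = TRUE,
                n = n))
  }
  idx <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  rstar <- as.numeric(crossprod(matrix(xs[idx], n, n_perm), ys)) / (n - 1)
  p <- (1 + sum(abs(rstar) >= abs(r) - tol)) / (1 + n_perm)
  list(r = r, p_perm = p, n_perm = n_perm, exhaustive = FALSE, n = n)
}

#' Probability of a run of consecutive advantageous choices under chance
#'
#' `0.5^k`: the chance probability that `k` further advantageous choices
#' immediately follow a first one, the argument behind the run-of-four
#' learning criterion.
#'
#' @param k Run length beyond the first choice.
#' @return Probability.
#' @export
run_probability <- function(k) {
  stopifnot(k >= 0)
  0.5^k
}

#' Exact upper binomial tail for the post-criterion threshold
#'
#' `P(X >= ceiling(frac * n))` for `X ~ Binomial(n, p0)`, by exact
#' summation. With `n = 30`, `frac = 0.65` and `p0 = 0.5` this is the
#' margin-of-significance calculation behind the 65% criterion.
#'
#' @param n Number of trials.
#' @param frac Required advantageous fraction.
#' @param p0 Null success probability.
#' @return Tail probability.
#' @export
binomial_tail <- function(n, frac, p0) {
  stopifnot(n >= 1, frac >= 0, frac <= 1, p0 >= 0, p0 <= 1)
  k0 <- ceiling(frac * n)
  if (k0 <= 0) return(1)
  sum(stats::dbinom(k0:n, n, p0))
}

#' Calibration helpers behind the learning criterion
#'
#' @return list with the [run_probability()] and [binomial_tail()]
#'   functions.
#' @export
criterion_calibration <- function() {
  list(run_probability = run_probability, binomial_tail = binomial_tail)
}

#' Classical one-sample t-test (two-sided)
#'
#' @param values Numeric sample (n >= 2, nonzero variance).
#' @param mu Null mean.
#' @return list with `t`, `df`, `p`.
#' @export
one_sample_t <- function(values, mu) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("one_sample_t: need n >= 2")
  if (stats::sd(values) == 0) stop("one_sample_t: zero variance")
  tt <- stats::t.test(values, mu = mu)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
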