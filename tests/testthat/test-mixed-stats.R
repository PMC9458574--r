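suppressMessages({
  library(lme4)
})

quiet_fit <- function(...) suppressMessages(fit_lmm(...))

make_lmm_data <- function(n_sub = 10, n_per = 20, sub_sd = 0.5, res_sd = 0.5,
                          effects = c(HP = 0, preLP = 0, LP = 0, postLP = 0),
                          seed = 1) {
  set.seed(seed)
  d <- expand.grid(subject = sprintf("S%02d", seq_len(n_sub)),
                   rep = seq_len(n_per), stringsAsFactors = FALSE)
  d$choice_type <- sample(names(effects), nrow(d), replace = TRUE)
  d$previous_feedback <- sample(c("gain", "loss"), nrow(d), replace = TRUE)
  d$block_index <- sample(1:5, nrow(d), replace = TRUE)
  d$scheme_id <- sample(c("I", "II", "III", "IV", "V"), nrow(d),
                        replace = TRUE)
  sub_eff <- rnorm(n_sub, 0, sub_sd)
  d$y <- effects[d$choice_type] + sub_eff[match(d$subject,
                                                unique(d$subject))] +
    rnorm(nrow(d), 0, res_sd)
  d
}

test_that("with no grouping variance the mixed model collapses to group means", {
  set.seed(2)
  d <- data.frame(
    subject = rep(sprintf("S%02d", 1:8), each = 10),
    g = rep(rep(c("a", "b"), each = 5), 8),
    block_index = 1, scheme_id = "I"
  )
  d$y <- ifelse(d$g == "a", 0, 1) + rnorm(nrow(d), 0, 0.3)
  fit <- quiet_fit(d, "y", "g", random = "subject")
  est <- lme4::fixef(fit)[["gb"]]
  expect_equal(est, mean(d$y[d$g == "b"]) - mean(d$y[d$g == "a"]),
               tolerance = 1e-6)
})

test_that("variance components are recovered from a known generating model", {
  set.seed(7)
  n_sub <- 50
  n_per <- 40
  d <- data.frame(subject = rep(sprintf("S%02d", 1:n_sub), each = n_per))
  d$y <- rep(rnorm(n_sub, 0, 1), each = n_per) + rnorm(nrow(d), 0, 1)
  fit <- quiet_fit(d, "y", character(0), random = "subject")
  vc <- as.data.frame(lme4::VarCorr(fit))
  expect_equal(vc$vcov[vc$grp == "subject"], 1, tolerance = 0.35)
  expect_equal(vc$vcov[vc$grp == "Residual"], 1, tolerance = 0.1)
})

test_that("fixed effects equal the closed-form GLS solution on a tiny balanced set", {
  # with a known compound-symmetric covariance, GLS is computable by hand
  set.seed(8)
  n_sub <- 6
  n_per <- 8
  d <- data.frame(subject = rep(letters[1:n_sub], each = n_per),
                  g = rep(rep(c("a", "b"), each = n_per / 2), n_sub))
  d$y <- ifelse(d$g == "b", 0.8, 0) + rep(rnorm(n_sub, 0, 0.7), each = n_per) +
    rnorm(nrow(d), 0, 0.4)
  fit <- quiet_fit(d, "y", "g", random = "subject")
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2_u <- vc$vcov[vc$grp == "subject"]
  s2_e <- vc$vcov[vc$grp == "Residual"]
  X <- model.matrix(~g, d)
  V <- diag(s2_e, nrow(d)) +
    s2_u * outer(d$subject, d$subject, "==") * 1
  Vi <- solve(V)
  beta_gls <- solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi %*% d$y
  expect_equal(unname(lme4::fixef(fit)), as.numeric(beta_gls),
               tolerance = 1e-6)
})

test_that("type III tests agree with the sequential ANOVA on balanced data", {
  set.seed(9)
  d <- expand.grid(subject = sprintf("S%02d", 1:8),
                   g = c("a", "b"), h = c("x", "y"), rep = 1:5,
                   stringsAsFactors = FALSE)
  d$y <- (d$g == "b") * 0.5 + (d$h == "y") * 0.3 + rnorm(nrow(d), 0, 0.5)
  fit <- quiet_fit(d, "y", "g * h", random = "subject")
  t3 <- anova_type3(fit)
  seq_tab <- as.data.frame(suppressMessages(
    stats::anova(fit, type = 1, ddf = "Satterthwaite")))
  expect_equal(t3$F, seq_tab$`F value`, tolerance = 1e-6)
})

test_that("large-sample p-values match the F reference without random effects", {
  set.seed(10)
  n <- 4000
  d <- data.frame(g = sample(c("a", "b", "c"), n, replace = TRUE))
  d$y <- (d$g == "b") * 0.1 + rnorm(n)
  fit <- quiet_fit(d, "y", "g", random = character(0))
  t3 <- anova_type3(fit)
  ref <- anova(lm(y ~ g, d))
  expect_equal(t3$F, ref$`F value`[1], tolerance = 1e-9)
  expect_equal(t3$p, ref$`Pr(>F)`[1], tolerance = 1e-9)
})

test_that("step-down keeps strongly significant terms and removes pure noise", {
  d <- make_lmm_data(n_sub = 16, n_per = 40, sub_sd = 0.8, res_sd = 0.4,
                     effects = c(HP = 0, preLP = 0.1, LP = 0.7, postLP = 0.1),
                     seed = 11)
  d$noise_factor <- sample(c("u", "v"), nrow(d), replace = TRUE)
  sel <- suppressMessages(step_down(d, "y", "choice_type + noise_factor",
                                    random = c("subject", "block_index",
                                               "scheme_id")))
  expect_true("choice_type" %in% sel$fixed)
  expect_false("noise_factor" %in% sel$fixed)
  expect_true("subject" %in% sel$random)
  # the null grouping factors fall away
  expect_false("block_index" %in% sel$random)
  expect_false("scheme_id" %in% sel$random)
  # noise was eliminated before anything significant
  fixed_hist <- sel$history[sel$history$stage == "fixed", ]
  expect_equal(fixed_hist$term, "noise_factor")
})

test_that("step-down elimination matches an exhaustive re-fit oracle", {
  d <- make_lmm_data(n_sub = 10, n_per = 24, sub_sd = 0.6, res_sd = 0.5,
                     effects = c(HP = 0, preLP = 0, LP = 0.6, postLP = 0),
                     seed = 12)
  sel <- suppressMessages(
    step_down(d, "y", "choice_type * previous_feedback",
              random = c("subject", "block_index")))

  # oracle: independently re-run both stages, recomputing every candidate
  # model at each step
  oracle_random <- c("subject", "block_index")
  repeat {
    ps <- vapply(oracle_random, function(r) {
      full <- suppressMessages(
        fit_lmm(d, "y", c("choice_type", "previous_feedback",
                          "choice_type:previous_feedback"), oracle_random))
      red_random <- setdiff(oracle_random, r)
      red <- if (length(red_random)) {
        suppressMessages(fit_lmm(d, "y",
                                 c("choice_type", "previous_feedback",
                                   "choice_type:previous_feedback"),
                                 red_random))
      } else {
        lm(y ~ choice_type * previous_feedback, d)
      }
      ll_red <- if (inherits(red, "lm")) as.numeric(logLik(red, REML = TRUE))
                else as.numeric(logLik(red))
      stat <- 2 * (as.numeric(logLik(full)) - ll_red)
      if (stat <= 0) 1 else 0.5 * pchisq(stat, 1, lower.tail = FALSE)
    }, numeric(1))
    if (max(ps) > 0.05) {
      oracle_random <- oracle_random[-which.max(ps)]
    } else break
    if (!length(oracle_random)) break
  }
  oracle_fixed <- c("choice_type", "previous_feedback",
                    "choice_type:previous_feedback")
  repeat {
    fit <- suppressMessages(fit_lmm(d, "y", oracle_fixed, oracle_random))
    tab <- anova_type3(fit)
    has_inter <- "choice_type:previous_feedback" %in% oracle_fixed
    cand <- if (has_inter) "choice_type:previous_feedback" else oracle_fixed
    sub <- tab[tab$term %in% cand, ]
    worst <- which.max(sub$p)
    if (sub$p[worst] > 0.05) {
      oracle_fixed <- setdiff(oracle_fixed, sub$term[worst])
    } else break
    if (!length(oracle_fixed)) break
  }
  expect_setequal(sel$fixed, oracle_fixed)
  expect_setequal(sel$random, oracle_random)
})

test_that("a two-level factor's Tukey-adjusted p equals the unadjusted t-based p", {
  set.seed(13)
  d <- data.frame(subject = rep(sprintf("S%02d", 1:10), each = 12),
                  g = sample(c("a", "b"), 120, replace = TRUE))
  d$y <- (d$g == "b") * 0.3 + rep(rnorm(10, 0, 0.4), each = 12) +
    rnorm(120, 0, 0.5)
  fit <- quiet_fit(d, "y", "g", random = "subject")
  mm <- marginal_mean_contrasts(fit, "g")
  ct <- mm$contrasts
  expect_equal(ct$p.value, 2 * pt(-abs(ct$t.ratio), ct$df), tolerance = 1e-9)
})

test_that("Tukey adjustment matches the studentized-range distribution for k = 4", {
  # balanced one-way layout, no random effects: classical Tukey HSD
  set.seed(14)
  k <- 4
  n_per <- 12
  d <- data.frame(g = rep(letters[1:k], each = n_per))
  d$y <- (d$g == "c") * 0.6 + rnorm(k * n_per)
  fit <- quiet_fit(d, "y", "g", random = character(0))
  mm <- marginal_mean_contrasts(fit, "g")
  ct <- mm$contrasts
  df_err <- k * n_per - k
  for (i in seq_len(nrow(ct))) {
    q_obs <- sqrt(2) * abs(ct$t.ratio[i])
    p_oracle <- stats::ptukey(q_obs, nmeans = k, df = df_err,
                              lower.tail = FALSE)
    expect_equal(ct$p.value[i], p_oracle, tolerance = 1e-6)
  }
})

test_that("contrasts of identical populations center on zero across replicates", {
  set.seed(15)
  ests <- replicate(40, {
    d <- data.frame(subject = rep(sprintf("S%02d", 1:8), each = 10),
                    g = sample(c("a", "b"), 80, replace = TRUE))
    d$y <- rep(rnorm(8, 0, 0.5), each = 10) + rnorm(80)
    fit <- quiet_fit(d, "y", "g", random = "subject")
    mm <- marginal_mean_contrasts(fit, "g")
    mm$contrasts$estimate
  })
  expect_lt(abs(mean(ests)), 3 * sd(ests) / sqrt(length(ests)))
})

test_that("FDR q-values equal an independent step-up implementation", {
  set.seed(16)
  for (i in 1:20) {
    p <- runif(70)^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
  # the two printed degenerate patterns
  expect_true(all(p.adjust(rep(0.001, 70), "BH") <= 0.05))
  expect_true(all(p.adjust(runif(70, 0.9, 1), "BH") > 0.05))
})

test_that("pointwise analysis flags injected bins and reports the FDR family", {
  set.seed(17)
  n_sub <- 8
  trials_per <- 30
  bins <- 1:70
  rel <- seq(-1000, 2450, by = 50)
  rows <- list()
  for (s in seq_len(n_sub)) {
    for (tr in seq_len(trials_per)) {
      ct <- sample(c("HP", "preLP", "LP", "postLP"), 1,
                   prob = c(0.6, 0.13, 0.14, 0.13))
      eff <- ifelse(bins >= 30 & bins <= 50 & ct == "LP", 0.8, 0)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        subject = sprintf("S%02d", s), block_index = sample(1:5, 1),
        scheme_id = sample(c("I", "II", "III", "IV", "V"), 1),
        trial_index = tr, choice_type = ct, bin = bins, rel_ms = rel,
        z = eff + rnorm(70, 0, 0.5)
      )
    }
  }
  epo <- data.table::rbindlist(rows)
  pw <- suppressMessages(pointwise_contrasts(epo))
  expect_equal(attr(pw, "fdr"), "BH")
  expect_equal(unname(attr(pw, "family_size")["LP-HP"]), 70L)
  lp <- pw[pw$contrast == "LP-HP", ]
  expect_true(all(lp$sig[lp$bin >= 32 & lp$bin <= 48]))
  expect_true(all(!lp$sig[lp$bin < 25 | lp$bin > 55]))
  # q-values dominate raw p-values
  expect_true(all(pw$q_value >= pw$p - 1e-12, na.rm = TRUE))
})

test_that("window selection intersects the three spans and handles failures", {
  rel <- seq(-1000, 2450, by = 50)
  mask_from_span <- function(lo, hi) rel >= lo & rel < hi
  pw <- data.table::rbindlist(lapply(
    list(c("preLP-HP", -400, 2200), c("LP-HP", -400, 2200),
         c("postLP-HP", -1000, 2200)),
    function(x) data.table::data.table(
      contrast = x[1], rel_ms = rel,
      sig = mask_from_span(as.numeric(x[2]), as.numeric(x[3])))
  ))
  ws <- select_window(pw)
  expect_equal(unname(ws$overlap), c(-400, 2200))
  expect_equal(unname(ws$spans[["postLP-HP"]]), c(-1000, 2200))

  # a contrast whose significant span misses the response bin -> error
  pw3 <- data.table::data.table(contrast = "a", rel_ms = rel,
                                sig = mask_from_span(500, 1000))
  expect_error(select_window(pw3), class = "window_error")

  # random masks equal a bitwise-AND oracle on the shared span
  set.seed(18)
  for (i in 1:20) {
    m1 <- rel >= -500 & rel < sample(seq(100, 2450, 50), 1)
    m2 <- rel >= -sample(seq(100, 1000, 50), 1) & rel < 2000
    pw4 <- data.table::rbindlist(list(
      data.table::data.table(contrast = "a", rel_ms = rel, sig = m1),
      data.table::data.table(contrast = "b", rel_ms = rel, sig = m2)
    ))
    ws4 <- select_window(pw4)
    both <- m1 & m2
    runs <- rle(both)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    k <- which(runs$values & rel[starts] <= 0 & rel[ends] + 50 > 0)
    expect_equal(unname(ws4$overlap),
                 c(rel[starts[k]], rel[ends[k]] + 50))
  }
})

test_that("permutation correlation is exact for n = 4 and seeded for larger n", {
  x <- c(1, 2, 3, 4)
  y <- c(2, 1, 4, 3)
  got <- perm_corr(x, y, n_perm = 20000, seed = 1)
  expect_true(got$exhaustive)
  expect_equal(got$n_perm, 24)
  expect_equal(got$p_perm, oracle_perm_corr_p(x, y), tolerance = 1e-12)

  set.seed(19)
  for (i in 1:5) {
    x4 <- rnorm(4)
    y4 <- rnorm(4)
    expect_equal(perm_corr(x4, y4)$p_perm, oracle_perm_corr_p(x4, y4),
                 tolerance = 1e-12)
  }

  # an identical pair of vectors with distinct values is maximally correlated
  x10 <- 1:10
  big <- perm_corr(x10, x10, n_perm = 9999, seed = 2)
  expect_equal(big$r, 1)
  expect_lte(big$p_perm, 0.001)
  # seeded reproducibility
  x30 <- rnorm(30); y30 <- rnorm(30)
  expect_identical(perm_corr(x30, y30, n_perm = 500, seed = 7),
                   perm_corr(x30, y30, n_perm = 500, seed = 7))
  expect_error(perm_corr(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("criterion calibration helpers implement the stated formulas", {
  expect_equal(run_probability(3), 0.125)
  expect_equal(run_probability(0), 1)
  expect_equal(binomial_tail(30, 0, 0.5), 1)
  # exact tail: sum over k = 20..30 of C(30, k) / 2^30
  k0 <- ceiling(0.65 * 30)
  expect_equal(k0, 20)
  expect_equal(binomial_tail(30, 0.65, 0.5),
               sum(choose(30, 20:30)) / 2^30, tolerance = 1e-12)
  cc <- criterion_calibration()
  expect_equal(cc$run_probability(3), 0.125)
  expect_error(binomial_tail(30, 1.5, 0.5))
})

test_that("one-sample t shifts linearly in the null mean", {
  x <- c(12, 15, 11, 14, 18, 13)
  t0 <- one_sample_t(x, 14)$t
  t1 <- one_sample_t(x, 15)$t
  expect_equal(t1 - t0, -1 * sqrt(6) / sd(x), tolerance = 1e-10)
  expect_error(one_sample_t(c(3, 3, 3), 3), "zero variance")
  expect_error(one_sample_t(5, 3), "n >= 2")
})
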