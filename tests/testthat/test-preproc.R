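test_that("the derivative rule flags both members of a violating pair", {
  sm <- make_samples(c(500, 505, 520, 522))
  mask <- detect_artifacts(sm)
  expect_equal(nrow(mask), 1L)
  expect_equal(mask$start_ms, 1L) # samples at 1 and 2 ms (0-based grid)
  expect_equal(mask$end_ms, 2L)
  expect_equal(mask$class, "short")

  # a jump of exactly 10 pixels is not an artifact (strict threshold)
  expect_equal(nrow(detect_artifacts(make_samples(c(500, 510, 500)))), 0L)
  expect_equal(nrow(detect_artifacts(make_samples(rep(7, 100)))), 0L)
  expect_equal(nrow(detect_artifacts(make_samples(numeric(0)))), 0L)
})

test_that("runs are classed by the 350-ms boundary and merged across tiny gaps", {
  # 351 missing samples -> long
  p <- rep(600, 1000)
  v <- rep(TRUE, 1000)
  v[100:450] <- FALSE
  mask <- detect_artifacts(make_samples(p, v))
  expect_equal(mask$class, "long")
  v2 <- rep(TRUE, 1000)
  v2[100:449] <- FALSE # 350 samples -> short
  expect_equal(detect_artifacts(make_samples(p, v2))$class, "short")

  # two flagged stretches separated by a single valid sample merge
  v3 <- rep(TRUE, 100)
  v3[10:20] <- FALSE
  v3[22:30] <- FALSE
  mask3 <- detect_artifacts(make_samples(rep(5, 100), v3))
  expect_equal(nrow(mask3), 1L)
  expect_equal(c(mask3$start_ms, mask3$end_ms), c(9L, 29L))
})

test_that("detector matches the brute-force oracle on random series", {
  set.seed(1234)
  for (rep in 1:60) {
    n <- sample(20:200, 1)
    pupil <- sample(c(500, 505, 512, 530), n, replace = TRUE)
    valid <- runif(n) > 0.1
    pupil[!valid] <- NA
    mask <- detect_artifacts(make_samples(pupil, valid))
    oracle <- oracle_runs(oracle_artifact_flags(pupil, valid))
    expect_equal(nrow(mask), nrow(oracle))
    if (nrow(oracle)) {
      expect_equal(mask$start_ms, oracle$start)
      expect_equal(mask$end_ms, oracle$end)
      expect_equal(mask$class, oracle$class)
    }
  }
})

test_that("short gaps are linearly interpolated, long and edge runs left invalid", {
  # 100-ms missing gap between anchors 400 and 500 -> exact linear ramp
  p <- c(rep(400, 50), rep(NA, 100), rep(500, 50))
  v <- !is.na(p)
  sm <- make_samples(p, v)
  rep_ <- repair_or_flag(sm, detect_artifacts(sm))
  filled <- rep_$samples$pupil[50:151]
  expect_equal(filled, seq(400, 500, length.out = 102), tolerance = 1e-9)
  expect_true(all(rep_$samples$valid))
  expect_equal(nrow(rep_$long_runs), 0L)

  # interpolation never changes valid samples; values lie between anchors
  expect_equal(rep_$samples$pupil[v], p[v])
  expect_true(all(filled >= 400 & filled <= 500))

  # no artifacts -> identity
  sm2 <- make_samples(rep(450, 200))
  rep2 <- repair_or_flag(sm2, detect_artifacts(sm2))
  expect_equal(rep2$samples$pupil, sm2$pupil)

  # 400-ms gap -> untouched and reported
  p3 <- c(rep(400, 100), rep(NA, 400), rep(500, 100))
  sm3 <- make_samples(p3, !is.na(p3))
  rep3 <- repair_or_flag(sm3, detect_artifacts(sm3))
  expect_true(all(is.na(rep3$samples$pupil[101:500])))
  expect_equal(rep3$long_runs$reason, "long")
  expect_equal(c(rep3$long_runs$start_ms, rep3$long_runs$end_ms),
               c(100L, 499L))

  # run touching the series boundary stays invalid regardless of length
  p4 <- c(rep(NA, 50), rep(500, 200))
  sm4 <- make_samples(p4, !is.na(p4))
  rep4 <- repair_or_flag(sm4, detect_artifacts(sm4))
  expect_true(all(is.na(rep4$samples$pupil[1:50])))
  expect_equal(rep4$long_runs$reason, "boundary")
})

test_that("50-ms binning is the block mean and propagates invalid samples", {
  expect_equal(bin_50ms(make_samples(rep(7, 500)))$pupil, rep(7, 10))
  expect_equal(bin_50ms(make_samples(1:50))$pupil, 25.5)

  set.seed(5)
  x <- rnorm(1000)
  b <- bin_50ms(make_samples(x))
  oracle <- colMeans(matrix(x, nrow = 50))
  expect_equal(b$pupil, oracle, tolerance = 1e-12)
  expect_equal(b$bin_start_ms, seq(0, 950, by = 50))

  v <- rep(TRUE, 1000)
  v[75] <- FALSE
  b2 <- bin_50ms(make_samples(x, v))
  expect_false(b2$valid[2])
  expect_true(is.na(b2$pupil[2]))
  expect_equal(b2$pupil[-2], oracle[-2], tolerance = 1e-12)
})

test_that("session-wide z-scoring matches the direct formula and is affine-invariant", {
  set.seed(6)
  x <- rnorm(400, 2000, 30)
  b <- bin_50ms(make_samples(rep(x, each = 50)))
  z <- zscore_pupil(b)
  expect_equal(mean(z$z), 0, tolerance = 1e-10)
  expect_equal(sd(z$z), 1, tolerance = 1e-10)
  expect_equal(z$z, (x - mean(x)) / sd(x), tolerance = 1e-9)

  b2 <- data.table::copy(b)
  b2$pupil <- 3.7 * b2$pupil + 250
  expect_equal(zscore_pupil(b2)$z, z$z, tolerance = 1e-9)

  bc <- data.table::copy(b)
  bc$pupil <- rep(5, nrow(bc))
  expect_error(zscore_pupil(bc), "zero variance")
})

test_that("epoch extraction yields the 70-bin grid and matches a slicing oracle", {
  # a pure ramp signal: epoch values are predictable from the press time
  n_ms <- 60000
  ramp <- seq(0, 1, length.out = n_ms)
  zb <- zscore_pupil(bin_50ms(make_samples(ramp)))
  trials <- data.table::data.table(block_index = 1L, trial_index = 1:3,
                                   t_button_press = c(5000L, 20033L, 40988L))
  no_runs <- data.table::data.table(start_ms = integer(0),
                                    end_ms = integer(0),
                                    reason = character(0))
  ex <- extract_epochs(zb, trials, no_runs)
  expect_true(all(ex$meta$included))
  expect_equal(nrow(ex$epochs), 3L * 70L)
  for (i in 1:3) {
    ep <- ex$epochs[ex$epochs$trial_index == i, ]
    expect_equal(nrow(ep), 70L)
    expect_equal(ep$rel_ms, seq(-1000, 2450, by = 50))
    # slicing oracle: bins whose centers lie in [-1000, 2500) around press
    press <- trials$t_button_press[i]
    centers <- zb$bin_start_ms + 25
    keep <- centers >= press - 1000 & centers < press + 2500
    expect_equal(ep$z, zb$z[keep], tolerance = 1e-12)
  }
})

test_that("epochs near long artifacts or recording edges are excluded with one reason", {
  n_ms <- 30000
  zb <- zscore_pupil(bin_50ms(make_samples(rnorm(n_ms, 2000, 5))))
  runs <- data.table::data.table(start_ms = 12800L, end_ms = 13300L,
                                 reason = "long")
  trials <- data.table::data.table(
    block_index = 1L, trial_index = 1:4,
    # press 2: long run sits at press+2,900 ms (outside the analysis window
    # but inside the exclusion window); press 4: too close to the start
    t_button_press = c(5000L, 9900L, 20000L, 800L))
  ex <- extract_epochs(zb, trials, runs)
  expect_equal(ex$meta$included, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(ex$meta$reason, c("none", "long_artifact", "none", "boundary"))
})

test_that("the extreme-z rule excludes on any bin beyond 3 SD, strictly", {
  base <- data.table::data.table(
    block_index = 1L,
    trial_index = rep(1:3, each = 70),
    bin = rep(1:70, 3),
    rel_ms = rep(seq(-1000, 2450, 50), 3),
    z = rep(0.5, 210)
  )
  base$z[base$trial_index == 2 & base$bin == 35] <- 3.5
  base$z[base$trial_index == 3 & base$bin == 10] <- 3.0 # boundary: kept
  meta <- data.table::data.table(block_index = 1L, trial_index = 1:3,
                                 included = TRUE, reason = "none")
  out <- exclude_extreme_epochs(base, meta)
  expect_equal(out$included, c(TRUE, FALSE, TRUE))
  expect_equal(out$reason[2], "extreme_z")

  # epoch-mean variant keeps the single-bin outlier
  out2 <- exclude_extreme_epochs(base, meta, rule = "epoch_mean")
  expect_true(all(out2$included))
})

test_that("pretrial baselines average the fixation-locked window", {
  zb <- zscore_pupil(bin_50ms(make_samples(rnorm(20000, 2000, 10))))
  zb$z <- rep(0.2, nrow(zb)) # overwrite with a constant for the first check
  trials <- data.table::data.table(block_index = 1L, trial_index = 1L,
                                   t_fixation_on = 5000L)
  bl <- pretrial_baseline(zb, trials)
  expect_equal(bl$baseline, 0.2)

  # direct-mean oracle on random values
  set.seed(8)
  zb$z <- rnorm(nrow(zb))
  bl2 <- pretrial_baseline(zb, trials)
  centers <- zb$bin_start_ms + 25
  keep <- centers >= 5000 - 300 & centers < 5000
  expect_equal(sum(keep), 6L)
  expect_equal(bl2$baseline, mean(zb$z[keep]), tolerance = 1e-12)

  # missing bins are skipped; an all-missing window yields NA
  zb$z[keep][1:2] <- NA
  expect_equal(pretrial_baseline(zb, trials)$baseline,
               mean(zb$z[keep], na.rm = TRUE), tolerance = 1e-12)
  zb$z[keep] <- NA
  expect_true(is.na(pretrial_baseline(zb, trials)$baseline))
})

test_that("baseline correction subtracts per-trial baselines and drops orphans", {
  epochs <- data.table::data.table(
    block_index = 1L, trial_index = rep(1:2, each = 70),
    bin = rep(1:70, 2), rel_ms = rep(seq(-1000, 2450, 50), 2),
    z = rep(c(0.4, 1.0), each = 70)
  )
  baselines <- data.table::data.table(block_index = 1L, trial_index = 1L,
                                      baseline = 0.4)
  out <- baseline_correct(epochs, baselines)
  expect_equal(unique(out$epochs$trial_index), 1L)
  expect_equal(out$epochs$z, rep(0, 70))
  expect_equal(out$dropped$trial_index, 2L)

  # zero baseline is the identity
  baselines0 <- data.table::data.table(block_index = 1L, trial_index = 1:2,
                                       baseline = 0)
  out0 <- baseline_correct(epochs, baselines0)
  expect_equal(out0$epochs$z, epochs$z)
})

test_that("interval means decompose into bin-count-weighted subinterval means", {
  set.seed(9)
  epochs <- data.table::data.table(
    block_index = 1L, trial_index = rep(1:5, each = 70),
    bin = rep(1:70, 5), rel_ms = rep(seq(-1000, 2450, 50), 5),
    z = rnorm(350)
  )
  meta <- data.table::data.table(block_index = 1L, trial_index = 1:5,
                                 included = TRUE, reason = "none")
  baselines <- data.table::data.table(block_index = 1L, trial_index = 1:5,
                                      baseline = rnorm(5))
  im <- interval_means(epochs, meta, baselines)
  # the default main window covers 52 bins: (2200 - (-400)) / 50
  centers <- seq(-975, 2475, by = 50)
  expect_equal(sum(centers >= -400 & centers < 2200), 52L)
  for (i in 1:5) {
    zz <- epochs$z[epochs$trial_index == i]
    main <- mean(zz[centers >= -400 & centers < 2200])
    expect_equal(im$pupil_main[im$trial_index == i], main, tolerance = 1e-12)
    # decomposition: main = weighted mean of the three subintervals
    w <- c(8, 20, 24)
    subs <- c(im$pupil_decision[im$trial_index == i],
              im$pupil_anticipation[im$trial_index == i],
              im$pupil_feedback[im$trial_index == i])
    expect_equal(sum(w * subs) / sum(w), main, tolerance = 1e-12)
    expect_equal(im$pupil_main_bc[im$trial_index == i],
                 main - baselines$baseline[i], tolerance = 1e-12)
  }

  # constant epoch -> every mean equals the constant
  epochs$z <- 0.77
  imc <- interval_means(epochs, meta, baselines)
  expect_equal(imc$pupil_main, rep(0.77, 5))
  expect_equal(imc$pupil_decision, rep(0.77, 5))
})

test_that("binning then z-scoring commutes with affine transforms end to end", {
  b <- simulate_session(n_subjects = 1, seed = 77)
  sm <- b$samples$S001
  sm2 <- data.table::copy(sm)
  sm2$pupil <- 2.5 * sm2$pupil + 100
  run <- function(s) {
    rep_ <- repair_or_flag(s, detect_artifacts(s))
    zscore_pupil(bin_50ms(rep_$samples))$z
  }
  # affine scaling changes the derivative, so compare on the artifact-free
  # configuration where the detector finds nothing to interpolate
  p0 <- pupil_gen_params(blink_rate_hz = 0, spike_rate_hz = 0)
  b0 <- simulate_session(pupil = p0, n_subjects = 1, seed = 78)
  s0 <- b0$samples$S001
  s1 <- data.table::copy(s0)
  s1$pupil <- 2.5 * s1$pupil + 100
  expect_equal(run(s0), run(s1), tolerance = 1e-9)
})

test_that("planted artifacts are recovered and drive the documented exclusions", {
  b <- simulate_session(n_subjects = 1, seed = 91)
  sm <- b$samples$S001
  truth <- b$artifact_log$S001
  mask <- detect_artifacts(sm)
  # every planted run is matched by a detected run within 1 ms
  for (i in seq_len(nrow(truth))) {
    hit <- which(abs(mask$start_ms - truth$start_ms[i]) <= 1 &
                   abs(mask$end_ms - truth$end_ms[i]) <= 1)
    expect_equal(length(hit), 1L)
  }
  expect_equal(nrow(mask), nrow(truth))
})
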