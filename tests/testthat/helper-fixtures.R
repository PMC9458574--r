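# Shared fixture builders; everything is generated in code at test time.

# a plain 1-ms sample series starting at t = 0
make_samples <- function(pupil, valid = rep(TRUE, length(pupil))) {
  data.table::data.table(
    time_ms = seq_along(pupil) - 1L,
    pupil = as.numeric(pupil),
    valid = valid
  )
}

# brute-force per-sample artifact scan: the independent oracle for
# detect_artifacts (no run logic; marks every artifactual sample)
oracle_artifact_flags <- function(pupil, valid, thresh = 10) {
  n <- length(pupil)
  flag <- !valid | is.na(pupil)
  for (i in seq_len(n - 1)) {
    if (!is.na(pupil[i]) && !is.na(pupil[i + 1]) &&
        abs(pupil[i + 1] - pupil[i]) > thresh) {
      flag[i] <- TRUE
      flag[i + 1] <- TRUE
    }
  }
  flag
}

# merge oracle flags into runs with the same < merge_gap rule, then class
oracle_runs <- function(flag, merge_gap = 2, short_max = 350) {
  n <- length(flag)
  # merge: a gap of fewer than merge_gap unflagged samples between two
  # flagged stretches is flagged too
  i <- 1
  repeat {
    idx <- which(flag)
    if (!length(idx)) return(data.frame(start = integer(0), end = integer(0),
                                        class = character(0)))
    changed <- FALSE
    for (j in seq_len(n)) {
      if (!flag[j]) {
        before <- j > 1 && flag[j - 1]
        # count unflagged run starting at j
        k <- j
        while (k <= n && !flag[k]) k <- k + 1
        after <- k <= n
        if (before && after && (k - j) < merge_gap) {
          flag[j:(k - 1)] <- TRUE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  idx <- which(flag)
  brk <- which(diff(idx) > 1)
  starts <- idx[c(1, brk + 1)]
  ends <- idx[c(brk, length(idx))]
  data.frame(
    start = starts - 1L, end = ends - 1L, # 0-based times
    class = ifelse(ends - starts + 1 <= short_max, "short", "long")
  )
}

# independent learning-criterion enumerator: tries every trial at which a
# run of `k` consecutive advantageous choices ends, in order, and applies
# the after-period threshold rule directly
oracle_learning <- function(adv, k = 4, thr = 0.65) {
  n <- length(adv)
  ends <- which(vapply(seq_len(n), function(t) {
    t >= k && all(adv[(t - k + 1):t])
  }, logical(1)))
  for (t in ends) {
    after <- if (t < n) adv[(t + 1):n] else logical(0)
    if (length(after) == 0 || mean(after) >= thr) {
      return(list(learned = TRUE, criterion_index = t))
    }
  }
  list(learned = FALSE, criterion_index = NA_integer_)
}

# independent triplet pattern matcher for choice types
oracle_choice_types <- function(adv, learned = FALSE, crit = NA) {
  n <- length(adv)
  out <- rep("unclassified", n)
  from <- if (isTRUE(learned)) crit + 1 else 1
  pat <- list(HP = c(TRUE, TRUE, TRUE), preLP = c(TRUE, TRUE, FALSE),
              LP = c(TRUE, FALSE, TRUE), postLP = c(FALSE, TRUE, TRUE))
  for (t in seq_len(n)) {
    if (t < max(2, from) || t > n - 1) next
    trip <- adv[(t - 1):(t + 1)]
    for (nm in names(pat)) {
      if (identical(trip, pat[[nm]])) out[t] <- nm
    }
  }
  out
}

# Benjamini-Hochberg step-up q-values, written from the defining formula
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  q[o] <- p[o] * m / seq_len(m)
  # enforce step-up monotonicity from the largest p downwards
  for (i in (m - 1):1) q[o[i]] <- min(q[o[i]], q[o[i + 1]])
  pmin(q, 1)
}

# exhaustive permutation p-value for a Pearson correlation (two-sided)
oracle_perm_corr_p <- function(x, y) {
  perms <- matrix(NA_integer_, 0, length(x))
  gen <- function(v, acc) {
    if (!length(v)) {
      perms <<- rbind(perms, acc)
      return(invisible())
    }
    for (i in seq_along(v)) gen(v[-i], c(acc, v[i]))
  }
  gen(seq_along(x), integer(0))
  r0 <- abs(cor(x, y))
  rs <- apply(perms, 1, function(ix) abs(cor(x[ix], y)))
  mean(rs >= r0 - 1e-12)
}

# recovery / detection conditions used by the power study: flat amplitudes
# plus calibrated after-learning effects, RT multipliers restricted to the
# after-learning conditions
recovery_agent <- function() {
  agent_params(rt_condition_multipliers = c(
    HP = 1, preLP = 1.2, LP = 1.4, postLP = 1.2,
    no_learning = 1, other = 1))
}

recovery_pupil <- function() {
  base <- pupil_gen_params(amplitude_map = c(
    HP = 25, preLP = 25, LP = 25, postLP = 25,
    no_learning = 25, other = 25))
  calibrate_amplitude_map(c(preLP = 0.075, LP = 0.15, postLP = 0.075),
                          agent = recovery_agent(), pupil = base)
}
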