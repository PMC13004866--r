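test_that("dF/F extraction normalizes by the per-trial baseline", {
  d <- make_it_dataset(n_roi = 5, n_per_cs = 6, noise_sd = 0)
  # constant (non-responsive, noiseless) ROI: dff identically zero
  silent <- which(!d$traces$ground_truth$responsive)[1]
  expect_true(all(d$dff$dff[, silent, ] == 0))
  expect_equal(length(d$dff$baseline_frames), 30)   # 1 s at 30 Hz
  expect_equal(length(d$dff$analysis_frames), 45)   # 1.5 s at 30 Hz

  # doubling fluorescence from baseline gives dff = 1 exactly
  tr <- d$traces
  tr$F[] <- 100
  tr$F[1, tr$trial_frames[1] + 0:10] <- 200
  dff <- compute_dff(tr, d$table)
  expect_equal(dff$dff[1, 1, dff$onset_frame + 0:10], rep(1, 11))

  tr$F[2, ] <- 0
  expect_error(compute_dff(tr, d$table), "non-positive baseline")
})

test_that("moving-average smoothing is a truncated centered boxcar", {
  x <- c(0, 0, 1, 0, 0)
  expect_equal(smooth_trace(x, 1), x)
  expect_equal(smooth_trace(rep(2, 10), 7), rep(2, 10))
  expect_equal(smooth_trace(x, 3), c(0, 1 / 3, 1 / 3, 1 / 3, 0))
  expect_error(smooth_trace(x, 4), "odd")
})

test_that("responsiveness requires both the Wilcoxon test and the amplitude criterion", {
  d <- make_it_dataset(n_roi = 60, n_per_cs = 25, noise_sd = 0.1, seed = 3)
  cls <- classify_responsive(d$dff, "CSplus")
  gt <- d$traces$ground_truth
  truth <- gt$responsive & gt$tuning %in% c("both", "plus")
  # strong responses (amp 0.3, noise 0.1, 25 trials) are detected
  expect_gt(mean(cls$responsive == truth), 0.9)

  # all-zero dff is never responsive
  zero <- d$dff
  zero$dff[] <- 0
  expect_true(all(!classify_responsive(zero, "CSplus")$responsive))

  # significant but sub-threshold amplitude (0.04 < 0.05) is rejected
  small <- d$dff
  small$dff[] <- 0
  small$dff[, 1, small$analysis_frames] <- 0.04
  out <- classify_responsive(small, "CSplus")
  expect_lt(out$p_value[1], 0.01)
  expect_false(out$responsive[1])
  expect_equal(out$amplitude[1], 0.04, tolerance = 1e-9)

  # too few trials: unclassified
  few <- make_it_dataset(n_roi = 4, n_per_cs = 4, seed = 5)
  expect_true(all(is.na(classify_responsive(few$dff, "CSplus")$responsive)))
})

test_that("selectivity index is the rescaled ROC area with symmetric sign", {
  expect_equal(selectivity_index(c(1, 1), c(1, 1)), 0)        # AUC 0.5
  expect_equal(selectivity_index(c(2, 3), c(0, 1)), 1)        # AUC 1
  expect_equal(selectivity_index(c(0, 1), c(2, 3)), -1)       # AUC 0
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(selectivity_index(a, b), -selectivity_index(b, a))
  expect_equal(selectivity_index(a, b, si_sign = -1), -selectivity_index(a, b))
  # shared ROC core: SI == 2 * auROC - 1 on the same inputs
  expect_equal(selectivity_index(a, b), 2 * auroc(a, b) - 1, tolerance = 1e-12)
})

test_that("response classes follow the two responsiveness flags", {
  expect_equal(as.character(response_class(TRUE, TRUE)), "non_selective")
  expect_equal(as.character(response_class(TRUE, FALSE)), "selective")
  expect_equal(as.character(response_class(FALSE, TRUE)), "selective")
  expect_equal(as.character(response_class(FALSE, FALSE)), "non_responsive")
})

test_that("transition fractions contrast stable and reorganizing populations", {
  cls <- response_class(c(TRUE, TRUE, FALSE), c(FALSE, TRUE, FALSE))
  same <- transition_fractions(cls, cls)
  expect_equal(same$maintained, 1)
  flipped <- response_class(c(FALSE, FALSE, TRUE), c(FALSE, FALSE, FALSE))
  flip <- transition_fractions(cls, flipped)
  expect_equal(flip$changed, 1)
  expect_equal(same$maintained + same$changed, 1)
  expect_error(transition_fractions(response_class(FALSE, FALSE),
                                    response_class(FALSE, FALSE)),
               "no tracked responsive")

  # IT-like (no turnover) maintains more than ET-like with turnover 0.4
  tts <- lapply(1:2, function(d) generate_trial_table(25, day = d, seed = 50 + d))
  day_classes <- function(spec, seed) {
    trs <- generate_roi_traces(tts, spec, seed = seed)
    lapply(seq_along(trs), function(d) {
      dff <- compute_dff(trs[[d]], tts[[d]])
      response_class(classify_responsive(dff, "CSplus")$responsive,
                     classify_responsive(dff, "CSminus")$responsive)
    })
  }
  it <- day_classes(population_spec(60, "IT_like", noise_sd = 0.05), 51)
  et <- day_classes(population_spec(
    60, "ET_like", ramp_gain_by_day = rep(0.3, 5),
    identity_turnover_by_day = rep(0.4, 4), reliability = 1,
    noise_sd = 0.05), 52)
  expect_gt(transition_fractions(it[[1]], it[[2]])$maintained,
            transition_fractions(et[[1]], et[[2]])$maintained)
})

test_that("stability matrices average ROI-wise correlations over a 3 s window", {
  set.seed(8)
  base <- matrix(rnorm(10 * 90), 10, 90)
  ident <- stability_matrix(list(base, base, base))
  expect_equal(ident, matrix(1, 3, 3), ignore_attr = TRUE)
  expect_equal(diag(ident), rep(1, 3))

  # independent noise across days: off-diagonal mean ~ 0 within 3 s.e.
  days <- lapply(1:2, function(d) matrix(rnorm(100 * 90), 100, 90))
  M <- stability_matrix(days)
  expect_lt(abs(M[1, 2]), 3 * (1 / sqrt(89)) / sqrt(100) + 0.02)

  # window is 90 frames: frames beyond 3 s cannot affect the result
  longer <- lapply(days, function(m) cbind(m, matrix(1e3, 100, 30)))
  expect_equal(stability_matrix(longer), M, ignore_attr = TRUE)

  # zero-variance ROI excluded from the pair
  days[[1]][1, ] <- 5
  M2 <- stability_matrix(days)
  expect_equal(attr(M2, "n_excluded"), 1L)
  expect_true(is.finite(M2[1, 2]))
})

test_that("chi-squared fraction comparison reproduces the hand formula", {
  hand_chi2 <- function(k1, n1, k2, n2) {
    O <- c(k1, n1 - k1, k2, n2 - k2)
    p <- (k1 + k2) / (n1 + n2)
    E <- c(n1 * p, n1 * (1 - p), n2 * p, n2 * (1 - p))
    sum((O - E)^2 / E)
  }
  set.seed(3)
  for (i in 1:1000) {
    n1 <- sample(5:300, 1); n2 <- sample(5:300, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    if ((k1 + k2) %in% c(0, n1 + n2)) next  # degenerate margin
    expect_equal(compare_fractions(k1, n1, k2, n2)$chi2,
                 hand_chi2(k1, n1, k2, n2), tolerance = 1e-10)
  }
  expect_equal(compare_fractions(10, 100, 10, 100)$chi2, 0)
  expect_true(compare_fractions(1, 40, 0, 40)$low_expected)
  expect_error(compare_fractions(5, 4, 1, 10), "k <= n")
})

test_that("Ward clustering on correlation distances recovers planted templates", {
  set.seed(9)
  t1 <- sin(seq(0, 2 * pi, length.out = 60))
  t2 <- cos(seq(0, 4 * pi, length.out = 60))
  traces <- rbind(
    t(replicate(20, t1 * runif(1, 0.5, 2) + rnorm(60, 0, 0.05))),
    t(replicate(20, t2 * runif(1, 0.5, 2) + rnorm(60, 0, 0.05)))
  )
  res <- cluster_responses(traces, k = 2)
  truth <- rep(1:2, each = 20)
  agree <- max(mean(res$labels == truth), mean(res$labels == 3 - truth))
  expect_gte(agree, 0.95)

  # z-scoring: per-ROI mean 0, sd 1; identical traces at distance 0
  z <- t(scale(t(traces)))
  expect_equal(unname(rowMeans(z)), rep(0, 40), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 40), tolerance = 1e-12)

  # permutation invariance of the partition
  perm <- sample(40)
  res_p <- cluster_responses(traces[perm, ], k = 2)
  expect_true(all(outer(res$labels[perm], res$labels[perm], "==") ==
                  outer(res_p$labels, res_p$labels, "==")))

  # zero-variance ROI excluded
  traces[1, ] <- 0
  res_z <- cluster_responses(traces, k = 2)
  expect_equal(res_z$excluded, 1L)
  expect_true(is.na(res_z$labels[1]))
})

test_that("event alignment distinguishes event-locked from stimulus-locked activity", {
  n_trial <- 40
  n_roi <- 5
  n_frame <- 135
  fr <- 30
  kernel_resp <- function(onset, n_frame) {
    x <- rep(0, n_frame)
    idx <- onset:min(onset + 20, n_frame)
    x[idx] <- 1
    x
  }
  make_dff <- function(onsets) {
    arr <- array(rnorm(n_trial * n_roi * n_frame, 0, 0.01),
                 c(n_trial, n_roi, n_frame))
    for (i in seq_len(n_trial)) for (r in seq_len(n_roi))
      arr[i, r, ] <- arr[i, r, ] + kernel_resp(onsets[i], n_frame)
    structure(list(dff = arr, cs_type = rep("CSplus", n_trial),
                   frame_rate = fr, onset_frame = 31,
                   baseline_frames = 1:30, analysis_frames = 31:75,
                   reward_frame = 76), class = "dff_tensor")
  }
  set.seed(10)
  events <- sample(50:70, n_trial, replace = TRUE)

  # activity locked to the event: latency variance is ~ 0
  locked <- align_to_event(make_dff(events), events)
  expect_equal(locked$n_used, n_trial)
  expect_lt(locked$latency_var, 0.01)

  # activity locked to the stimulus while events jitter: variance ~ event jitter
  fixed <- align_to_event(make_dff(rep(60, n_trial)), events)
  expect_equal(fixed$latency_var, var((60 - events) / fr), tolerance = 0.25)
  expect_gt(fixed$latency_var, 5 * locked$latency_var)

  # no qualifying trials
  none <- align_to_event(make_dff(events), rep(NA_real_, n_trial))
  expect_equal(none$n_used, 0L)
  expect_equal(none$n_skipped, n_trial)
})
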