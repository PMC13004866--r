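#' Extract trial-aligned dF/F
#'
#' Cuts the continuous fluorescence matrix into trial windows and converts to
#' relative fluorescence change `(F - F0) / F0`, where `F0` is that trial's
#' mean fluorescence over the 1 s (30 frame) baseline preceding stimulus
#' onset, computed per ROI and per trial.
#'
#' @param traces A `roi_traces` object.
#' @param table The matching `trial_table`.
#' @param n_pre Baseline frames before onset (30 = 1 s at 30 Hz).
#' @param n_post Frames from onset kept for analysis (default 105 = 3.5 s,
#'   covering the 1.5 s analysis window, the reward response and the 3 s
#'   stability window).
#' @return A `dff_tensor`: list with `dff` (trial x ROI x frame array),
#'   `cs_type`, `frame_rate`, `onset_frame` (index of the stimulus-onset
#'   frame within the window), `baseline_frames`, `analysis_frames` (1.5 s
#'   from onset) and `reward_frame`.
#' @export
compute_dff <- function(traces, table, n_pre = 30L, n_post = 105L) {
  stopifnot(inherits(traces, "roi_traces"))
  if (nrow(table) != length(traces$trial_frames))
    stop_invalid("trial table (%d trials) does not match traces (%d trials)",
                 nrow(table), length(traces$trial_frames))
  if (any(traces$trial_frames - n_pre < 1))
    stop_invalid("every trial needs >= %d baseline frames before onset", n_pre)
  n_trial <- nrow(table)
  n_roi <- nrow(traces$F)
  win <- n_pre + n_post
  dff <- array(NA_real_, c(n_trial, n_roi, win))
  for (i in seq_len(n_trial)) {
    f0i <- traces$trial_frames[i]
    idx <- (f0i - n_pre):(f0i + n_post - 1L)
    seg <- traces$F[, idx, drop = FALSE]
    F0 <- rowMeans(seg[, seq_len(n_pre), drop = FALSE])
    if (any(F0 <= 0))
      stop_invalid("non-positive baseline fluorescence for ROI(s) %s on trial %d",
                   paste(which(F0 <= 0), collapse = ", "), i)
    dff[i, , ] <- sweep(sweep(seg, 1, F0), 1, F0, "/")
  }
  fr <- traces$frame_rate
  onset <- n_pre + 1L
  structure(list(
    dff = dff,
    cs_type = table$cs_type,
    frame_rate = fr,
    onset_frame = onset,
    baseline_frames = seq_len(n_pre),
    analysis_frames = onset:(onset + round(REWARD_DELAY_S * fr) - 1L),
    reward_frame = onset + round(REWARD_DELAY_S * fr)
  ), class = "dff_tensor")
}

#' @export
print.dff_tensor <- function(x, ...) {
  d <- dim(x$dff)
  cat(sprintf("dF/F tensor: %d trials x %d ROIs x %d frames (%d baseline)\n",
              d[1], d[2], d[3], length(x$baseline_frames)))
  invisible(x)
}

#' Moving-average smoothing
#'
#' Centered boxcar average of odd width `k`; windows are truncated at the
#' edges. Trial-averaged traces are conventionally displayed with `k = 3`
#' and single trials with `k = 7`.
#'
#' @param trace Numeric frame series.
#' @param k Odd window width in frames.
#' @return Smoothed series of the same length.
#' @export
smooth_trace <- function(trace, k = 3L) {
  if (k %% 2 == 0) stop_invalid("`k` must be odd, got %d", k)
  if (k == 1) return(trace)
  n <- length(trace)
  half <- (k - 1L) / 2L
  cs <- cumsum(c(0, trace))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Classify ROIs as responsive to a stimulus or reward condition
#'
#' For each ROI the time-averaged dF/F over the 1.5 s after stimulus onset
#' (after reward delivery for `condition = "reward"`) is compared against the
#' time-averaged 1 s baseline across trials of the condition with a paired
#' two-sided Wilcoxon signed-rank test. An ROI is responsive iff the test
#' gives p < `alpha` with a greater post-window mean, and the
#' baseline-subtracted mean response exceeds `amp_threshold` (default 0.05
#' dF/F). ROIs with fewer than `min_trials` condition trials are left
#' unclassified (`NA`).
#'
#' @param dff A [compute_dff()] tensor.
#' @param condition `"CSplus"`, `"CSminus"` or `"reward"`.
#' @param alpha Significance level of the Wilcoxon test (0.01).
#' @param amp_threshold Minimum baseline-subtracted mean dF/F (0.05).
#' @param min_trials Minimum trials required to classify (10).
#' @return Data frame with one row per ROI: `roi`, `responsive` (logical,
#'   `NA` when unclassified), `amplitude` (baseline-subtracted mean dF/F over
#'   the window), `p_value`.
#' @export
classify_responsive <- function(dff, condition = c("CSplus", "CSminus", "reward"),
                                alpha = 0.01, amp_threshold = 0.05,
                                min_trials = 10L) {
  condition <- match.arg(condition)
  trials <- if (condition == "reward") which(dff$cs_type == "CSplus")
            else which(dff$cs_type == condition)
  frames <- if (condition == "reward") {
    fr <- dff$frame_rate
    dff$reward_frame:min(dff$reward_frame + round(REWARD_DELAY_S * fr) - 1L,
                         dim(dff$dff)[3])
  } else dff$analysis_frames
  n_roi <- dim(dff$dff)[2]
  out <- data.frame(roi = seq_len(n_roi), responsive = NA,
                    amplitude = NA_real_, p_value = NA_real_)
  if (length(trials) < min_trials) return(out)
  for (r in seq_len(n_roi)) {
    post <- apply(dff$dff[trials, r, frames, drop = FALSE], 1, mean)
    base <- apply(dff$dff[trials, r, dff$baseline_frames, drop = FALSE], 1, mean)
    amp <- mean(post - base)
    d <- post - base
    p <- if (all(d == 0)) 1 else
      suppressWarnings(stats::wilcox.test(post, base, paired = TRUE,
                                          exact = length(post) <= 25))$p.value
    out$responsive[r] <- is.finite(p) && p < alpha && amp > 0 &&
      amp > amp_threshold
    out$amplitude[r] <- amp
    out$p_value[r] <- p
  }
  out
}

#' ROC selectivity index between CS+ and CS- responses
#'
#' `SI = (AUC - 0.5) * 2`, where AUC is the ROC area between the per-trial
#' response distributions with CS+ as the positive class (same rank-sum
#' construction as [auroc()]). With the default sign, SI > 0 indicates a
#' CS+ preference; `si_sign = -1` flips the convention.
#'
#' @param resp_plus,resp_minus Per-trial responses (e.g. window-averaged
#'   dF/F) on CS+ and CS- trials.
#' @param si_sign `1` (SI > 0 means CS+ preference) or `-1`.
#' @return SI in \[-1, 1\].
#' @export
selectivity_index <- function(resp_plus, resp_minus, si_sign = 1) {
  si_sign * (auroc(resp_plus, resp_minus) - 0.5) * 2
}

#' Response class from the two stimulus-responsiveness flags
#'
#' Non-selective ROIs are active in both CS+ and CS- trials, selective ROIs
#' in exactly one, non-responsive ROIs in neither.
#'
#' @param responsive_plus,responsive_minus Logical vectors.
#' @return Factor with levels `non_selective`, `selective`, `non_responsive`.
#' @export
response_class <- function(responsive_plus, responsive_minus) {
  cls <- ifelse(responsive_plus & responsive_minus, "non_selective",
         ifelse(responsive_plus | responsive_minus, "selective",
                "non_responsive"))
  cls[is.na(responsive_plus) | is.na(responsive_minus)] <- NA
  factor(cls, levels = c("non_selective", "selective", "non_responsive"))
}

#' Day-to-day response-type transitions of tracked ROIs
#'
#' Among ROIs responsive (non-selective or selective) on day `d`, the
#' fraction whose response class is identical on day `d + 1` (maintained)
#' versus different (changed).
#'
#' @param class_d,class_d1 Response classes (from [response_class()]) of the
#'   same tracked ROIs on consecutive days.
#' @return List with `maintained`, `changed` (fractions summing to 1) and
#'   `n_responsive` (denominator).
#' @export
transition_fractions <- function(class_d, class_d1) {
  if (length(class_d) != length(class_d1))
    stop_invalid("tracked ROI vectors must have equal length")
  resp <- !is.na(class_d) & class_d != "non_responsive" & !is.na(class_d1)
  n <- sum(resp)
  if (n == 0)
    stop_invalid("no tracked responsive ROIs on the reference day")
  maintained <- sum(class_d[resp] == class_d1[resp]) / n
  list(maintained = maintained, changed = 1 - maintained, n_responsive = n)
}

#' Across-day stability of trial-averaged responses
#'
#' For every pair of training days, the Pearson correlation between each
#' tracked ROI's trial-averaged dF/F traces over the 3 s (90 frame) window
#' from stimulus onset, averaged across ROIs within each mouse and then
#' across mice. ROIs with a zero-variance trace on either day of a pair are
#' excluded from that pair.
#'
#' @param day_traces List over days; each element an ROI x frame matrix of
#'   trial-averaged dF/F starting at stimulus onset, same tracked ROIs in
#'   the same order on every day. Frames beyond the window are ignored.
#' @param mouse Optional per-ROI mouse identifier (single cohort if omitted).
#' @param window_s Correlation window in seconds (3).
#' @param frame_rate Sampling rate (30 Hz).
#' @return A `n_day` x `n_day` symmetric matrix of mean Pearson r with unit
#'   diagonal; attribute `n_excluded` counts zero-variance ROI-pair
#'   exclusions.
#' @export
stability_matrix <- function(day_traces, mouse = NULL, window_s = 3,
                             frame_rate = FRAME_RATE) {
  n_day <- length(day_traces)
  n_roi <- nrow(day_traces[[1]])
  if (is.null(mouse)) mouse <- rep(1L, n_roi)
  nf <- min(round(window_s * frame_rate),
            min(vapply(day_traces, ncol, integer(1))))
  M <- diag(1, n_day)
  excluded <- 0L
  for (a in seq_len(n_day - 1)) for (b in (a + 1):n_day) {
    r_roi <- rep(NA_real_, n_roi)
    for (r in seq_len(n_roi)) {
      x <- day_traces[[a]][r, seq_len(nf)]
      y <- day_traces[[b]][r, seq_len(nf)]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) { excluded <- excluded + 1L; next }
      r_roi[r] <- stats::cor(x, y)
    }
    per_mouse <- tapply(r_roi, mouse, mean, na.rm = TRUE)
    M[a, b] <- M[b, a] <- mean(per_mouse, na.rm = TRUE)
  }
  attr(M, "n_excluded") <- excluded
  M
}

#' Chi-squared comparison of two responsive fractions
#'
#' Pearson chi-squared test (1 d.f., no continuity correction) on the 2x2
#' table of responsive vs non-responsive counts in two populations.
#'
#' @param k1,n1 Responsive count and total in population 1.
#' @param k2,n2 Responsive count and total in population 2.
#' @return List with `chi2`, `p_value`, `df` and `low_expected` (TRUE when
#'   any expected cell is below 1, attached as a warning flag).
#' @examples
#' compare_fractions(154, 273, 57, 159)$chi2  # 17.00
#' @export
compare_fractions <- function(k1, n1, k2, n2) {
  if (any(c(k1, k2) < 0) || k1 > n1 || k2 > n2 || any(c(n1, n2) < 1))
    stop_invalid("counts must satisfy 0 <= k <= n, n >= 1")
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2, byrow = TRUE)
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(res$statistic), p_value = res$p.value, df = 1L,
       low_expected = any(res$expected < 1))
}

#' Ward clustering of trial-averaged ROI responses
#'
#' Traces are z-scored per ROI, pairwise correlation distances
#' `1 - Pearson r` computed, and agglomerative hierarchical clustering
#' performed with Ward's linkage. Zero-variance ROIs cannot be z-scored and
#' are excluded (reported in the result).
#'
#' @param traces ROI x frame matrix of trial-averaged responses.
#' @param k Number of clusters to cut the tree into.
#' @return List with `labels` (per input ROI; `NA` for excluded ROIs),
#'   `hclust` (the dendrogram), and `excluded` (ROI indices).
#' @export
cluster_responses <- function(traces, k = 2) {
  if (nrow(traces) < 2) stop_invalid("need >= 2 ROIs to cluster")
  sds <- apply(traces, 1, stats::sd)
  excluded <- which(sds == 0)
  keep <- which(sds > 0)
  if (length(keep) < 2) stop_invalid("fewer than 2 ROIs with non-zero variance")
  z <- t(scale(t(traces[keep, , drop = FALSE])))
  d <- stats::as.dist(1 - stats::cor(t(z)))
  hc <- stats::hclust(d, method = "ward.D2")
  lab <- rep(NA_integer_, nrow(traces))
  lab[keep] <- stats::cutree(hc, k = k)
  list(labels = lab, hclust = hc, excluded = excluded)
}

#' Event-triggered average and onset-locking statistic
#'
#' Re-references single-trial dF/F to a per-trial behavioural event (e.g.
#' the first anticipatory lick), averages across qualifying trials, and
#' quantifies how tightly activity onset is locked to the event as the
#' variance across trials of the activity-onset latency relative to the
#' event. Activity onset on a trial is the first frame at which the
#' ROI-averaged trace reaches `onset_frac` of that trial's maximum.
#'
#' @param dff A [compute_dff()] tensor.
#' @param event_frames Per-trial event frame index within the trial window
#'   (`NA` = no event; such trials are skipped and counted).
#' @param pre,post Frames kept before/after the event in the triggered
#'   average.
#' @param onset_frac Fraction of the trial maximum defining activity onset.
#' @return List with `eta` (ROI x frame event-triggered average),
#'   `latencies` (seconds, per used trial), `latency_var` (s^2),
#'   `n_used`, `n_skipped`.
#' @export
align_to_event <- function(dff, event_frames, pre = 15L, post = 45L,
                           onset_frac = 0.5) {
  n_trial <- dim(dff$dff)[1]
  n_roi <- dim(dff$dff)[2]
  n_frame <- dim(dff$dff)[3]
  if (length(event_frames) != n_trial)
    stop_invalid("`event_frames` must have one entry per trial")
  usable <- which(!is.na(event_frames) &
                  event_frames - pre >= 1 & event_frames + post <= n_frame)
  n_skipped <- n_trial - length(usable)
  if (length(usable) == 0)
    return(list(eta = NULL, latencies = numeric(0), latency_var = NA_real_,
                n_used = 0L, n_skipped = n_skipped))
  eta <- array(0, c(n_roi, pre + post + 1L))
  latencies <- numeric(length(usable))
  for (j in seq_along(usable)) {
    i <- usable[j]
    e <- event_frames[i]
    eta <- eta + dff$dff[i, , (e - pre):(e + post), drop = TRUE]
    pop <- colMeans(matrix(dff$dff[i, , ], n_roi, n_frame))
    thresh <- onset_frac * max(pop)
    onset <- which(pop >= thresh)[1]
    latencies[j] <- (onset - e) / dff$frame_rate
  }
  list(eta = eta / length(usable), latencies = latencies,
       latency_var = stats::var(latencies),
       n_used = length(usable), n_skipped = n_skipped)
}
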