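#' Bin trial-aligned activity into 500-ms windows
#'
#' Averages dF/F within consecutive non-overlapping bins tiling the stored
#' trial window; decoding is performed separately per bin.
#'
#' @param dff A [compute_dff()] tensor.
#' @param bin_s Bin width in seconds (0.5 = 15 frames at 30 Hz).
#' @return A `binned_activity`: list with `X` (trial x ROI x bin array),
#'   `bin_starts_s`/`bin_ends_s` (edges relative to stimulus onset),
#'   `cs_type`.
#' @export
bin_activity <- function(dff, bin_s = 0.5) {
  fpb <- dff$frame_rate * bin_s
  if (abs(fpb - round(fpb)) > 1e-9)
    stop_invalid("bin width of %g s is not an integer number of frames at %g Hz",
                 bin_s, dff$frame_rate)
  fpb <- as.integer(round(fpb))
  n_frame <- dim(dff$dff)[3]
  n_bin <- n_frame %/% fpb
  n_trial <- dim(dff$dff)[1]
  n_roi <- dim(dff$dff)[2]
  X <- array(NA_real_, c(n_trial, n_roi, n_bin))
  for (b in seq_len(n_bin)) {
    idx <- ((b - 1L) * fpb + 1L):(b * fpb)
    X[, , b] <- apply(dff$dff[, , idx, drop = FALSE], c(1, 2), mean)
  }
  start_frame <- (seq_len(n_bin) - 1L) * fpb + 1L
  structure(list(
    X = X,
    bin_starts_s = (start_frame - dff$onset_frame) / dff$frame_rate,
    bin_ends_s = (start_frame + fpb - 1L - dff$onset_frame + 1L) / dff$frame_rate,
    cs_type = dff$cs_type
  ), class = "binned_activity")
}

## Stratified fold assignment: each class is split evenly across folds.
stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

## z-score columns using training-set statistics only.
train_scaler <- function(Xtr) {
  mu <- colMeans(Xtr)
  sd <- apply(Xtr, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(apply = function(X) sweep(sweep(X, 2, mu), 2, sd, "/"))
}

#' Decode stimulus identity from time-binned population activity
#'
#' For each bin independently, a linear support vector machine is trained to
#' classify CS+ vs CS- trials from the ROI population vector, with
#' stratified `folds`-fold cross-validation; the random fold assignment is
#' resampled `repeats` times and accuracy averaged across repeats. Features
#' are z-scored using training-fold statistics only. Chance level is 0.5
#' for the balanced 50/50 design.
#'
#' @param binned A [bin_activity()] object.
#' @param y Trial class labels (defaults to the stored CS type).
#' @param folds Cross-validation folds (5).
#' @param repeats Random resamplings of the fold assignment per bin (100).
#' @param cost SVM regularization parameter C (1).
#' @param seed Integer seed.
#' @return Data frame with one row per bin: `bin`, `time_s` (bin start
#'   relative to stimulus onset), `accuracy` (mean over repeats), `se`
#'   (standard error over repeats).
#' @export
decode_stimulus <- function(binned, y = NULL, folds = 5L, repeats = 100L,
                            cost = 1, seed = NULL) {
  if (is.null(y)) y <- binned$cs_type
  y <- factor(y)
  if (nlevels(y) < 2)
    stop_invalid("both trial classes must be present to decode")
  if (min(table(y)) < folds)
    stop_invalid("need at least `folds` trials per class")
  n_bin <- dim(binned$X)[3]
  with_seed(seed, {
    acc <- matrix(NA_real_, repeats, n_bin)
    for (rep_i in seq_len(repeats)) {
      for (b in seq_len(n_bin)) {
        fold <- stratified_folds(y, folds)
        correct <- 0L
        for (f in seq_len(folds)) {
          tr <- fold != f
          Xtr <- binned$X[tr, , b, drop = FALSE][, , 1, drop = TRUE]
          Xte <- binned$X[!tr, , b, drop = FALSE][, , 1, drop = TRUE]
          Xtr <- matrix(Xtr, sum(tr)); Xte <- matrix(Xte, sum(!tr))
          sc <- train_scaler(Xtr)
          fit <- e1071::svm(sc$apply(Xtr), y[tr], kernel = "linear",
                            cost = cost, scale = FALSE)
          correct <- correct + sum(stats::predict(fit, sc$apply(Xte)) == y[!tr])
        }
        acc[rep_i, b] <- correct / length(y)
      }
    }
    data.frame(
      bin = seq_len(n_bin),
      time_s = binned$bin_starts_s,
      accuracy = colMeans(acc),
      se = apply(acc, 2, stats::sd) / sqrt(repeats)
    )
  })
}

#' Decode lick counts from time-binned population activity
#'
#' Linear epsilon-insensitive SVM regression predicting per-trial lick counts
#' from the population vector, scored by `folds`-fold cross-validated R^2
#' (which ranges from infinitely negative to 1). With the default
#' `train_epoch = test_epoch = NULL` a separate decoder is fit and scored per
#' bin. When distinct epochs are given (sets of bin indices, e.g. the
#' anticipatory vs consummatory windows), one decoder is fit on the training
#' epoch's trial-bin samples and scored on the held-out trials of the test
#' epoch, quantifying cross-epoch generalization.
#'
#' @param binned A [bin_activity()] object.
#' @param lick_counts Trial x bin matrix of lick counts aligned with the bins.
#' @param folds Cross-validation folds (5).
#' @param cost,epsilon SVM regression parameters (C = 1, epsilon = 0.1).
#' @param train_epoch,test_epoch Optional bin-index vectors for cross-epoch
#'   decoding.
#' @param seed Integer seed.
#' @return Per-bin data frame (`bin`, `time_s`, `r2`, `n_folds_excluded`) or,
#'   for cross-epoch decoding, a list with overall `r2` and
#'   `n_folds_excluded`. Folds whose test target is constant have undefined
#'   R^2 and are excluded and counted.
#' @export
decode_licks <- function(binned, lick_counts, folds = 5L, cost = 1,
                         epsilon = 0.1, train_epoch = NULL, test_epoch = NULL,
                         seed = NULL) {
  n_trial <- dim(binned$X)[1]
  if (nrow(lick_counts) != n_trial)
    stop_invalid("`lick_counts` must have one row per trial")
  if (n_trial < folds) stop_invalid("need at least `folds` trials")
  cross <- !is.null(train_epoch) && !is.null(test_epoch)
  with_seed(seed, {
    if (!cross) {
      n_bin <- dim(binned$X)[3]
      out <- data.frame(bin = seq_len(n_bin), time_s = binned$bin_starts_s,
                        r2 = NA_real_, n_folds_excluded = 0L)
      for (b in seq_len(n_bin)) {
        cv <- cv_svr_r2(matrix(binned$X[, , b], n_trial), lick_counts[, b],
                        folds, cost, epsilon)
        out$r2[b] <- cv$r2
        out$n_folds_excluded[b] <- cv$excluded
      }
      out
    } else {
      ## stack trial x bin samples within each epoch; folds split trials so
      ## no trial contributes to both training and testing
      fold <- rep_len(seq_len(folds), n_trial)[sample.int(n_trial)]
      r2s <- c(); excluded <- 0L
      for (f in seq_len(folds)) {
        tr <- which(fold != f); te <- which(fold == f)
        Xtr <- do.call(rbind, lapply(train_epoch, function(b)
          matrix(binned$X[tr, , b], length(tr))))
        ytr <- unlist(lapply(train_epoch, function(b) lick_counts[tr, b]))
        Xte <- do.call(rbind, lapply(test_epoch, function(b)
          matrix(binned$X[te, , b], length(te))))
        yte <- unlist(lapply(test_epoch, function(b) lick_counts[te, b]))
        r2 <- fit_score_svr(Xtr, ytr, Xte, yte, cost, epsilon)
        if (is.na(r2)) excluded <- excluded + 1L else r2s <- c(r2s, r2)
      }
      list(r2 = if (length(r2s)) mean(r2s) else NA_real_,
           n_folds_excluded = excluded)
    }
  })
}

fit_score_svr <- function(Xtr, ytr, Xte, yte, cost, epsilon) {
  if (stats::var(yte) == 0) return(NA_real_)
  sc <- train_scaler(Xtr)
  fit <- e1071::svm(sc$apply(Xtr), ytr, type = "eps-regression",
                    kernel = "linear", cost = cost, epsilon = epsilon,
                    scale = FALSE)
  pred <- stats::predict(fit, sc$apply(Xte))
  1 - sum((yte - pred)^2) / sum((yte - mean(yte))^2)
}

cv_svr_r2 <- function(X, y, folds, cost, epsilon) {
  fold <- rep_len(seq_len(folds), length(y))[sample.int(length(y))]
  r2s <- c(); excluded <- 0L
  for (f in seq_len(folds)) {
    tr <- fold != f
    r2 <- fit_score_svr(X[tr, , drop = FALSE], y[tr],
                        X[!tr, , drop = FALSE], y[!tr], cost, epsilon)
    if (is.na(r2)) excluded <- excluded + 1L else r2s <- c(r2s, r2)
  }
  list(r2 = if (length(r2s)) mean(r2s) else NA_real_, excluded = excluded)
}

#' Count licks per trial in each activity bin
#'
#' Convenience helper aligning behavioural licks with [bin_activity()] bins.
#'
#' @param table A `trial_table` with licks.
#' @param binned A [bin_activity()] object.
#' @return Trial x bin matrix of lick counts.
#' @export
bin_lick_counts <- function(table, binned) {
  n_bin <- length(binned$bin_starts_s)
  out <- matrix(0L, nrow(table), n_bin)
  for (i in seq_len(nrow(table))) {
    on <- table$stim_onset[i]
    licks <- table$lick_times[[i]]
    for (b in seq_len(n_bin)) {
      out[i, b] <- sum(licks >= on + binned$bin_starts_s[b] &
                       licks < on + binned$bin_ends_s[b])
    }
  }
  out
}
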