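#' Count anticipatory licks on one trial
#'
#' Licks in the half-open window from stimulus onset up to (but excluding)
#' the reward time, i.e. `[stim_onset, stim_onset + 1.5)`; the same window is
#' applied on CS+ and CS- trials. The half-open convention avoids counting a
#' lick at reward onset as both anticipatory and consummatory.
#'
#' @param lick_times Sorted numeric vector of lick timestamps (session clock).
#' @param stim_onset Stimulus onset time (seconds).
#' @param window Anticipatory window length in seconds (1.5 = stimulus +
#'   trace interval).
#' @return Integer lick count.
#' @export
anticipatory_lick_count <- function(lick_times, stim_onset,
                                    window = REWARD_DELAY_S) {
  if (length(lick_times) == 0) return(0L)
  sum(lick_times >= stim_onset & lick_times < stim_onset + window)
}

#' Area under the ROC curve between two count distributions
#'
#' Computed by the rank-sum (Mann-Whitney) identity: the fraction of
#' CS+/CS- trial pairs in which the CS+ count exceeds the CS- count, with
#' ties credited 0.5. Equivalent to trapezoidal integration of the empirical
#' ROC curve and exact on tied count data. Values above 0.5 indicate more
#' anticipatory licking on CS+ trials.
#'
#' @param counts_plus,counts_minus Per-trial anticipatory lick counts (or any
#'   per-trial responses) for the positive (CS+) and negative (CS-) class.
#' @return auROC in \[0, 1\].
#' @examples
#' auroc(c(3, 4, 5), c(0, 1, 2))  # complete separation -> 1
#' @export
auroc <- function(counts_plus, counts_minus) {
  if (length(counts_plus) == 0 || length(counts_minus) == 0)
    stop_invalid("`auroc` requires non-empty count vectors for both classes")
  n1 <- length(counts_plus)
  n2 <- length(counts_minus)
  r <- rank(c(counts_plus, counts_minus))   # midranks give the 0.5 tie credit
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Score behavioural performance across training sessions
#'
#' For each session: the initial 10% of trials (floor of `0.1 * n`) are
#' discarded to exclude impulsive licking at session start, anticipatory lick
#' counts are extracted per remaining trial, the session auROC between
#' CS+ and CS- counts is computed, and the session is flagged proficient when
#' auROC exceeds 0.7.
#'
#' @param sessions A `trial_table` or list of trial tables ordered by day.
#' @param proficiency_threshold auROC above which a session counts as
#'   proficient (0.7).
#' @param min_trials Minimum analyzable trials after the discard; smaller
#'   sessions get `NA` auROC and are flagged in `too_few_trials`.
#' @return A `learning_curve` data frame with one row per session: `day`,
#'   `n_analyzed`, `n_discarded`, `auROC`, `rate_plus`, `rate_minus` (mean
#'   anticipatory lick rate in Hz, counts / 1.5 s), `proficient`,
#'   `too_few_trials`.
#' @export
learning_curve <- function(sessions, proficiency_threshold = 0.7,
                           min_trials = 10) {
  if (inherits(sessions, "trial_table")) sessions <- list(sessions)
  rows <- lapply(sessions, function(tab) {
    n <- nrow(tab)
    n_drop <- floor(0.1 * n)
    keep <- tab[seq_len(n) > n_drop, , drop = FALSE]
    counts <- mapply(anticipatory_lick_count, keep$lick_times, keep$stim_onset)
    plus <- counts[keep$cs_type == "CSplus"]
    minus <- counts[keep$cs_type == "CSminus"]
    too_few <- nrow(keep) < min_trials || length(plus) == 0 || length(minus) == 0
    a <- if (too_few) NA_real_ else auroc(plus, minus)
    data.frame(
      day = tab$day[1], n_analyzed = nrow(keep), n_discarded = n_drop,
      auROC = a,
      rate_plus = mean(plus) / REWARD_DELAY_S,
      rate_minus = mean(minus) / REWARD_DELAY_S,
      proficient = !is.na(a) && a > proficiency_threshold,
      too_few_trials = too_few
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("learning_curve", "data.frame")
  out
}
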