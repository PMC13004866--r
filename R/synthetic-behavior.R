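#' Generate a trial table for one conditioning session
#'
#' Builds the trial structure of a Pavlovian trace-conditioning session:
#' `n_per_cs` CS+ and `n_per_cs` CS- trials in random order (each trial type
#' is equiprobable at every position), a 1 s whisker stimulus, a 0.5 s trace
#' interval, reward delivered 1.5 s after stimulus onset on CS+ trials only,
#' and inter-trial intervals drawn uniformly from 6-8 s.
#'
#' @param n_per_cs Number of trials of each CS type (the experiment used 100,
#'   i.e. 200 trials per session).
#' @param day Session day (1-5).
#' @param seed Integer seed; fixed seed gives an identical table.
#' @param iti_range Inter-trial interval range in seconds.
#' @param session_start Time of the first stimulus onset (seconds).
#' @return A `trial_table`: a data frame with one row per trial and columns
#'   `trial_id`, `day`, `cs_type` (`"CSplus"`/`"CSminus"`), `stim_onset`,
#'   `stim_offset`, `reward_time` (`NA` on CS- trials) and a list column
#'   `lick_times` (empty until [generate_licks()] fills it).
#' @seealso [generate_licks()], [learning_curve()]
#' @examples
#' tt <- generate_trial_table(10, day = 1, seed = 1)
#' table(tt$cs_type)
#' @export
generate_trial_table <- function(n_per_cs, day = 1L, seed = NULL,
                                 iti_range = c(6, 8), session_start = 10) {
  if (!is.numeric(n_per_cs) || length(n_per_cs) != 1L || n_per_cs < 1)
    stop_invalid("`n_per_cs` must be a positive count, got %s", format(n_per_cs)[1])
  n_per_cs <- as.integer(n_per_cs)
  n <- 2L * n_per_cs
  with_seed(seed, {
    cs <- sample(rep(c("CSplus", "CSminus"), each = n_per_cs))
    iti <- stats::runif(n - 1L, iti_range[1], iti_range[2])
    ## ITI measured from end of the trial epoch (reward time + consummatory
    ## allowance is irrelevant for onset spacing; spec defines ITI between
    ## trials, applied onset-to-onset after the 1.5 s trial epoch).
    onset <- session_start + c(0, cumsum(iti + REWARD_DELAY_S))
    tab <- data.frame(
      trial_id = seq_len(n),
      day = as.integer(day),
      cs_type = cs,
      stim_onset = onset,
      stim_offset = onset + STIM_DUR_S,
      reward_time = ifelse(cs == "CSplus", onset + REWARD_DELAY_S, NA_real_),
      stringsAsFactors = FALSE
    )
    tab$lick_times <- rep(list(numeric(0)), n)
    class(tab) <- c("trial_table", "data.frame")
    tab
  })
}

#' Populate a trial table with simulated licking
#'
#' Draws lick timestamps from an inhomogeneous Poisson process: a baseline
#' rate throughout the trial epoch, a CS-specific anticipatory rate in the
#' window from stimulus onset to reward time (1.5 s), and a consummatory
#' rate for a bounded window after reward delivery on CS+ trials.
#'
#' @param table A `trial_table`.
#' @param rate_plus,rate_minus Anticipatory lick rate (Hz) on CS+ / CS- trials.
#' @param rate_baseline Baseline lick rate (Hz) outside the special windows.
#' @param rate_consummatory Lick rate (Hz) in the consummatory window.
#' @param consummatory_dur Duration (s) of the consummatory window after
#'   reward; the burst is bounded so anticipatory and consummatory licking
#'   can be decoded separately.
#' @param seed Integer seed.
#' @return The trial table with `lick_times` filled (sorted, session clock).
#' @export
generate_licks <- function(table, rate_plus, rate_minus,
                           rate_baseline = 0.5, rate_consummatory = 6,
                           consummatory_dur = 2, seed = NULL) {
  rates <- c(rate_plus, rate_minus, rate_baseline, rate_consummatory)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop_invalid("lick rates must be finite and non-negative")
  with_seed(seed, {
    table$lick_times <- lapply(seq_len(nrow(table)), function(i) {
      on <- table$stim_onset[i]
      plus <- table$cs_type[i] == "CSplus"
      ## piecewise-constant rate over [onset - 3, onset + 5] s
      segs <- rbind(
        c(on - 3, on, rate_baseline),
        c(on, on + REWARD_DELAY_S, if (plus) rate_plus else rate_minus),
        if (plus) c(on + REWARD_DELAY_S, on + REWARD_DELAY_S + consummatory_dur,
                    rate_consummatory)
        else c(on + REWARD_DELAY_S, on + REWARD_DELAY_S + consummatory_dur,
               rate_baseline),
        c(on + REWARD_DELAY_S + consummatory_dur, on + 5, rate_baseline)
      )
      licks <- unlist(lapply(seq_len(nrow(segs)), function(j) {
        len <- segs[j, 2] - segs[j, 1]
        k <- stats::rpois(1, segs[j, 3] * len)
        if (k == 0) numeric(0) else stats::runif(k, segs[j, 1], segs[j, 2])
      }))
      sort(licks)
    })
    table
  })
}

#' @export
print.trial_table <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("Trial table: %d trials (%d CS+, %d CS-), day %d\n",
              n, sum(x$cs_type == "CSplus"), sum(x$cs_type == "CSminus"),
              x$day[1]))
  cat(sprintf("  total licks: %d\n", sum(lengths(x$lick_times))))
  invisible(x)
}

#' Write / read a trial table as CSV
#'
#' One row per trial; `lick_times` is serialized as a semicolon-joined
#' numeric list so the file is plain text.
#'
#' @param table A `trial_table`.
#' @param path File path.
#' @return `read_trial_table` returns a `trial_table`.
#' @export
write_trial_table <- function(table, path) {
  out <- as.data.frame(table[setdiff(names(table), "lick_times")])
  out$lick_times <- vapply(table$lick_times,
                           function(l) paste(format(l, digits = 10, trim = TRUE),
                                             collapse = ";"),
                           character(1))
  out$lick_times[lengths(table$lick_times) == 0] <- ""
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$lick_times <- lapply(tab$lick_times, function(s) {
    if (is.na(s) || !nzchar(s)) numeric(0)
    else as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
  class(tab) <- c("trial_table", "data.frame")
  tab
}
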