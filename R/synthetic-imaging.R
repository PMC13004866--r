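#' Specify a synthetic ROI population
#'
#' Describes the statistical structure of a simulated layer-5 population.
#' IT-like populations are stimulus-locked, highly reliable and stable
#' across days (zero ramp gain, zero identity turnover); ET-like populations
#' carry a learning-dependent ramp toward the expected reward time, respond
#' non-selectively and unreliably at the single-trial level, and reassign
#' which ROIs are responsive from day to day.
#'
#' @param n_roi Number of ROIs.
#' @param subtype `"IT_like"` or `"ET_like"`.
#' @param frac_responsive Fraction of ROIs responsive in the naive state
#'   (defaults: 0.56 IT-like, 0.36 ET-like, matching the naive-population
#'   fractions the analyses contrast).
#' @param transient_kernel Calcium transient kernel `c(rise, decay)` in
#'   seconds (jGCaMP8m-like default 0.05 / 0.7).
#' @param ramp_gain_by_day Length-5 nondecreasing ramp amplitude (dF/F) of the
#'   reward-expectation ramp; must be all zero for IT-like.
#' @param identity_turnover_by_day Length-4 day-to-day probabilities that a
#'   responsive ROI hands its role to a previously silent ROI; must be zero
#'   for IT-like, and typically decreases with learning for ET-like.
#' @param amp Transient amplitude (dF/F) of a stimulus-locked response.
#' @param reliability Per-trial probability that a responsive ROI actually
#'   emits its response (IT-like default 1; ET-like default 0.5, making
#'   single-trial ET activity sparse and unreliable).
#' @param tuning_probs Probabilities that a responsive IT-like ROI responds to
#'   both CSs, CS+ only, or CS- only. ET-like ROIs are always non-selective.
#' @param noise_sd Additive Gaussian noise s.d. in dF/F units.
#' @param baseline_F Baseline fluorescence (arbitrary units).
#' @return A `population_spec` list.
#' @export
population_spec <- function(n_roi,
                            subtype = c("IT_like", "ET_like"),
                            frac_responsive = NULL,
                            transient_kernel = c(0.05, 0.7),
                            ramp_gain_by_day = NULL,
                            identity_turnover_by_day = NULL,
                            amp = 0.3,
                            reliability = NULL,
                            tuning_probs = c(both = 0.5, plus = 0.25, minus = 0.25),
                            noise_sd = 0.05,
                            baseline_F = 100) {
  subtype <- match.arg(subtype)
  it <- subtype == "IT_like"
  if (is.null(frac_responsive)) frac_responsive <- if (it) 0.56 else 0.36
  if (is.null(ramp_gain_by_day))
    ramp_gain_by_day <- if (it) rep(0, 5) else c(0.05, 0.1, 0.2, 0.3, 0.4)
  if (is.null(identity_turnover_by_day))
    identity_turnover_by_day <- if (it) rep(0, 4) else c(0.4, 0.3, 0.2, 0.1)
  if (is.null(reliability)) reliability <- if (it) 1 else 0.5
  if (frac_responsive < 0 || frac_responsive > 1)
    stop_invalid("`frac_responsive` must lie in [0, 1]")
  if (any(identity_turnover_by_day < 0 | identity_turnover_by_day > 1))
    stop_invalid("turnover probabilities must lie in [0, 1]")
  if (it && (any(ramp_gain_by_day != 0) || any(identity_turnover_by_day != 0)))
    stop_invalid("IT-like populations have zero ramp gain and zero turnover")
  if (!it && is.unsorted(ramp_gain_by_day))
    stop_invalid("ET-like ramp gain must be nondecreasing over days")
  structure(list(
    n_roi = as.integer(n_roi), subtype = subtype,
    frac_responsive = frac_responsive,
    transient_kernel = transient_kernel,
    ramp_gain_by_day = ramp_gain_by_day,
    identity_turnover_by_day = identity_turnover_by_day,
    amp = amp, reliability = reliability,
    tuning_probs = tuning_probs,
    noise_sd = noise_sd, baseline_F = baseline_F
  ), class = "population_spec")
}

## Double-exponential calcium transient, peak-normalized to 1.
calcium_kernel <- function(rise, decay, frame_rate = FRAME_RATE, dur = 4) {
  t <- seq(0, dur, by = 1 / frame_rate)
  h <- (1 - exp(-t / rise)) * exp(-t / decay)
  h / max(h)
}

## Initial ground-truth role assignment for a population.
init_roles <- function(spec) {
  n_resp <- round(spec$frac_responsive * spec$n_roi)
  responsive <- rep(FALSE, spec$n_roi)
  responsive[seq_len(n_resp)] <- TRUE
  tuning <- rep(NA_character_, spec$n_roi)
  if (n_resp > 0) {
    tuning[responsive] <- if (spec$subtype == "ET_like") "both"
    else sample(names(spec$tuning_probs), n_resp, replace = TRUE,
                prob = spec$tuning_probs)
  }
  data.frame(roi_id = seq_len(spec$n_roi), responsive = responsive,
             tuning = tuning, stringsAsFactors = FALSE)
}

## Day-to-day identity reassignment: with probability p each responsive ROI
## hands its role (and tuning) to an ROI drawn from the day's silent pool,
## conserving the responsive fraction.
turnover_roles <- function(roles, p) {
  if (p <= 0) return(roles)
  resp <- which(roles$responsive)
  movers <- resp[stats::runif(length(resp)) < p]
  silent <- which(!roles$responsive)
  k <- min(length(movers), length(silent))
  if (k == 0) return(roles)
  movers <- movers[seq_len(k)]
  new <- if (length(silent) == 1) silent else sample(silent, k)
  roles$responsive[new] <- TRUE
  roles$tuning[new] <- roles$tuning[movers]
  roles$responsive[movers] <- FALSE
  roles$tuning[movers] <- NA_character_
  roles
}

#' Generate ROI fluorescence traces for one or more sessions
#'
#' Simulates a continuous fluorescence matrix (ROI x frame, 30 Hz) for each
#' supplied trial table. Responsive IT-like ROIs emit stimulus-locked calcium
#' transients (double-exponential kernel) on trials of their preferred CS,
#' with identical tuning on every day. Responsive ET-like ROIs emit a linear
#' ramp from stimulus onset to the expected reward time (1.5 s), scaled by
#' the day's ramp gain, with ROI identity reassigned between days according
#' to the turnover schedule. Fluorescence is
#' `F = baseline_F * (1 + signal + noise)` with `noise ~ N(0, noise_sd)` per
#' frame in dF/F units.
#'
#' @param tables A `trial_table` or a list of them (one per day, ordered).
#' @param spec A [population_spec()].
#' @param seed Integer seed.
#' @return For a single table, a `roi_traces` object: list with `F`
#'   (ROI x frame matrix), `frame_rate`, `trial_frames` (stimulus-onset frame
#'   per trial), `roi_ids`, `subtype`, `day`, and `ground_truth` (per-ROI
#'   responsive flag and tuning for that day). For a list of tables, a list
#'   of `roi_traces` sharing `roi_ids` across days.
#' @export
generate_roi_traces <- function(tables, spec, seed = NULL) {
  if (inherits(tables, "trial_table")) return(
    generate_roi_traces(list(tables), spec, seed)[[1]])
  stopifnot(all(vapply(tables, inherits, logical(1), "trial_table")))
  days <- vapply(tables, function(t) t$day[1], numeric(1))
  if (length(tables) > 1 && any(diff(days) <= 0))
    stop_invalid("trial tables must be ordered by increasing day")
  with_seed(seed, {
    roles <- init_roles(spec)
    out <- vector("list", length(tables))
    for (d in seq_along(tables)) {
      if (d > 1) {
        p <- spec$identity_turnover_by_day[min(d - 1, length(spec$identity_turnover_by_day))]
        roles <- turnover_roles(roles, p)
      }
      out[[d]] <- simulate_session_traces(tables[[d]], spec, roles)
    }
    names(out) <- paste0("day", days)
    out
  })
}

simulate_session_traces <- function(table, spec, roles) {
  fr <- FRAME_RATE
  day <- table$day[1]
  day_idx <- min(max(day, 1L), length(spec$ramp_gain_by_day))
  t_end <- max(table$stim_onset) + 6
  n_frames <- ceiling(t_end * fr)
  onset_frames <- round(table$stim_onset * fr) + 1L
  kern <- calcium_kernel(spec$transient_kernel[1], spec$transient_kernel[2], fr)
  ramp_len <- round(REWARD_DELAY_S * fr)
  ramp <- seq_len(ramp_len) / ramp_len   # linear rise to 1 at reward time
  gain <- spec$ramp_gain_by_day[day_idx]

  sig <- matrix(0, spec$n_roi, n_frames)
  for (r in which(roles$responsive)) {
    tun <- roles$tuning[r]
    resp_trials <- switch(tun,
      both = seq_len(nrow(table)),
      plus = which(table$cs_type == "CSplus"),
      minus = which(table$cs_type == "CSminus"))
    if (spec$reliability < 1)
      resp_trials <- resp_trials[stats::runif(length(resp_trials)) < spec$reliability]
    for (i in resp_trials) {
      f0 <- onset_frames[i]
      if (spec$subtype == "IT_like") {
        idx <- f0:min(f0 + length(kern) - 1L, n_frames)
        sig[r, idx] <- sig[r, idx] + spec$amp * kern[seq_along(idx)]
      } else {
        idx <- f0:min(f0 + ramp_len - 1L, n_frames)
        sig[r, idx] <- sig[r, idx] + gain * ramp[seq_along(idx)]
      }
    }
  }
  noise <- if (spec$noise_sd > 0)
    matrix(stats::rnorm(length(sig), 0, spec$noise_sd), nrow(sig)) else 0
  F <- spec$baseline_F * (1 + sig + noise)
  structure(list(
    F = F, frame_rate = fr, trial_frames = onset_frames,
    roi_ids = roles$roi_id, subtype = spec$subtype, day = day,
    ground_truth = roles
  ), class = "roi_traces")
}

#' @export
print.roi_traces <- function(x, ...) {
  cat(sprintf("ROI traces (%s, day %d): %d ROIs x %d frames at %g Hz, %d trials\n",
              x$subtype, x$day, nrow(x$F), ncol(x$F), x$frame_rate,
              length(x$trial_frames)))
  invisible(x)
}

#' Generate the artificial stimulus bank for the network model
#'
#' Eight stimulus classes, each a 20-dimensional Gaussian with a distinct
#' random mean and equal isotropic covariance `sigma^2 I`; two distinct
#' classes are randomly designated CS+ and CS-.
#'
#' @param n_classes Number of stimulus classes (default 8).
#' @param dim Stimulus dimensionality (default 20).
#' @param sigma Isotropic within-class s.d. (default 0.5, relative to
#'   unit-scale class means).
#' @param seed Integer seed.
#' @return A `stimulus_bank`: list with `means` (n_classes x dim matrix),
#'   `sigma`, `cs_plus_class`, `cs_minus_class`.
#' @export
generate_model_stimuli <- function(n_classes = 8, dim = 20, sigma = 0.5,
                                   seed = NULL) {
  if (n_classes < 2) stop_invalid("`n_classes` must be >= 2")
  if (!is.numeric(sigma) || sigma <= 0) stop_invalid("`sigma` must be > 0")
  with_seed(seed, {
    means <- matrix(stats::rnorm(n_classes * dim), n_classes, dim)
    ## unit-scale means: random directions of unit norm, so the within-class
    ## noise sigma is expressed relative to the stimulus scale
    means <- means / sqrt(rowSums(means^2))
    pair <- sample.int(n_classes, 2)
    structure(list(means = means, sigma = sigma,
                   cs_plus_class = pair[1], cs_minus_class = pair[2]),
              class = "stimulus_bank")
  })
}

#' Draw noisy stimulus samples from a bank class
#'
#' @param bank A [generate_model_stimuli()] bank.
#' @param class Class index.
#' @param n Number of samples.
#' @return An `n` x `dim` matrix of samples from `N(mean_class, sigma^2 I)`.
#' @export
sample_stimuli <- function(bank, class, n = 1) {
  if (class < 1 || class > nrow(bank$means))
    stop_invalid("class index out of range")
  mu <- bank$means[class, ]
  matrix(stats::rnorm(n * length(mu), 0, bank$sigma), n, length(mu),
         byrow = FALSE) + matrix(mu, n, length(mu), byrow = TRUE)
}
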