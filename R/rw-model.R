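#' Pretrain the IT autoencoder on the stimulus bank
#'
#' The IT channel is a feedforward autoencoder (two 50-unit encoder layers,
#' a 15-unit bottleneck, two 50-unit decoder layers; tanh hidden
#' activations, linear reconstruction) trained by full-batch gradient
#' descent on the L2 reconstruction loss over samples drawn from all
#' stimulus classes. Once pretrained the network is frozen: its weights do
#' not change during the association task.
#'
#' @param bank A [generate_model_stimuli()] bank.
#' @param epochs Gradient steps (full batch).
#' @param lr Learning rate.
#' @param n_train,n_holdout Training / held-out samples (drawn evenly
#'   across classes).
#' @param seed Integer seed.
#' @return An `it_network`: list with `layers`, `frozen = TRUE`,
#'   `loss_initial`, `loss_final` (held-out L2 loss before/after training)
#'   and `loss_history`.
#' @export
pretrain_it_network <- function(bank, epochs = 400L, lr = 0.05,
                                n_train = 800L, n_holdout = 200L,
                                seed = NULL) {
  n_cls <- nrow(bank$means)
  with_seed(seed, {
    draw <- function(n_per) do.call(rbind, lapply(seq_len(n_cls), function(k)
      sample_stimuli(bank, k, n_per)))
    Xtr <- draw(ceiling(n_train / n_cls))
    Xho <- draw(ceiling(n_holdout / n_cls))
    dim_x <- ncol(bank$means)
    layers <- mlp_init(c(dim_x, 50, 50, 15, 50, 50, dim_x),
                       c(rep("tanh", 5), "linear"))
    holdout_loss <- function(ls) {
      A <- mlp_forward(ls, Xho)
      mean((A[[length(A)]] - Xho)^2)
    }
    loss0 <- holdout_loss(layers)
    fit <- mlp_train(layers, Xtr, Xtr, epochs, lr)
    structure(list(layers = fit$layers, frozen = TRUE,
                   loss_initial = loss0,
                   loss_final = holdout_loss(fit$layers),
                   loss_history = fit$history),
              class = "it_network")
  })
}

#' IT representation of a stimulus
#'
#' The output of the second (50-unit) encoder layer of the frozen
#' autoencoder, expressed as a nonnegative rate: the tanh activation `a` of
#' each unit is mapped to `h = (1 + a) / 2` in (0, 1), since the relayed
#' population signal is a firing rate. Deterministic given the network and
#' the stimulus. The shared positive baseline of these rates is what lets
#' value updates for one stimulus generalize to similar ones.
#'
#' @param net An [pretrain_it_network()] result.
#' @param x A 20-dim stimulus vector or an n x 20 matrix.
#' @return A 50-dim vector (or n x 50 matrix) with entries in (0, 1).
#' @export
encode_it <- function(net, x) {
  d_in <- ncol(net$layers[[1]]$W)
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, 1)
  if (ncol(x) != d_in)
    stop_invalid("stimulus dimension %d does not match network input %d",
                 ncol(x), d_in)
  A <- mlp_forward(net$layers[1:2], x)
  h <- (A[[3]] + 1) / 2
  if (vec) drop(h) else h
}

#' Anticipatory lick-rate readout of an association strength
#'
#' The model's predicted lick rate is a linear scaling of the value:
#' `rate = r_min + (r_max - r_min) * V`. The endpoints are a display
#' calibration mapping V = 0 to baseline licking and V = 1 to the asymptotic
#' CS+ anticipatory rate.
#'
#' @param V Association strength(s) in (0, 1).
#' @param r_min,r_max Rate (Hz) at V = 0 and V = 1.
#' @return Lick rate(s) in Hz.
#' @export
predict_lick_rate <- function(V, r_min = 0.5, r_max = 6) {
  r_min + (r_max - r_min) * V
}

#' Run the two-channel Rescorla-Wagner conditioning simulation
#'
#' Trains the value-encoding network over interleaved CS+/CS- trials. Each
#' trial: a stimulus is sampled from its class Gaussian, encoded by the
#' frozen IT network (`h_it`) and passed raw through the non-S1 channel
#' (`h_non_s1 = x`); the network predicts `V`, the reward prediction error
#' `delta = R - V` is computed (R = 1 on CS+, 0 on CS-), and every weight is
#' updated by `alpha * delta * dV/dw`. Concurrently a transfer sub-network
#' receiving only the non-S1 channel is trained by squared loss toward the
#' relayed value prediction, supporting S1-independent expert performance.
#'
#' Silencing conditions: `IT_silenced` replaces `h_it` with zero-mean
#' isotropic Gaussian noise on every trial (the prediction can no longer use
#' IT stimulus representations); `ET_silenced` replaces the value prediction
#' used inside the prediction error with zero-mean Gaussian noise (RPEs can
#' no longer be estimated correctly; the recorded association strengths are
#' still the network's true predictions); `expert_S1_silenced` trains as
#' control but reports the transfer sub-network's predictions, emulating
#' expert performance after S1 removal.
#'
#' @param bank Stimulus bank (generated from a sub-seed if `NULL`).
#' @param it_net Pretrained IT network (pretrained here if `NULL`).
#' @param sessions Number of training sessions (5).
#' @param n_per_cs Trials of each CS per session (100).
#' @param alpha Rescorla-Wagner learning rate (0.2; together with the small
#'   weight initialization this paces acquisition over the five sessions and
#'   routes early learning through the shared network components, producing
#'   the generalized early rise before stimulus-specific divergence).
#' @param condition `"control"`, `"IT_silenced"`, `"ET_silenced"` or
#'   `"expert_S1_silenced"`.
#' @param n_sims Number of independent simulations (seed-derived).
#' @param it_gain Gain applied to the IT representation where it enters the
#'   value network (4). The IT channel conveys the richer stimulus
#'   representation, so its effective separations are made to dominate the
#'   coarse raw channel; silencing noise is matched to the scaled signal.
#' @param it_noise_sd S.d. of IT-silencing noise; `NULL` matches the
#'   empirical s.d. of the replaced (scaled) IT representations.
#' @param et_noise_sd S.d. of ET-silencing noise replacing the relayed value.
#' @param lr_subnet Learning rate of the transfer sub-network.
#' @param pretrain_args List of arguments passed to [pretrain_it_network()].
#' @param seed Master seed; each simulation draws its own sub-seed.
#' @return A `sim_result`: list with `trials` (per-sim per-trial `sim`,
#'   `session`, `trial`, `cs_type`, `V`, `V_subnet`, `delta`), `sessions`
#'   (per-sim per-session mean association strengths `V_plus`, `V_minus`,
#'   `V_plus_subnet`, `V_minus_subnet` and predicted lick rates),
#'   `condition`, `alpha`, `n_sims`, `seeds`.
#' @export
run_conditioning <- function(bank = NULL, it_net = NULL, sessions = 5L,
                             n_per_cs = 100L, alpha = 0.1,
                             condition = c("control", "IT_silenced",
                                           "ET_silenced", "expert_S1_silenced"),
                             n_sims = 1L, it_gain = 4, it_noise_sd = NULL,
                             et_noise_sd = 0.25, lr_subnet = 0.2,
                             vnet_args = list(), pretrain_args = list(),
                             seed = NULL) {
  condition <- match.arg(condition)
  seeds <- derive_seeds(seed, n_sims)
  sims <- lapply(seq_len(n_sims), function(s) {
    run_conditioning_once(bank, it_net, sessions, n_per_cs, alpha, condition,
                          it_gain, it_noise_sd, et_noise_sd, lr_subnet,
                          vnet_args, pretrain_args, seeds[s], sim_id = s)
  })
  trials <- do.call(rbind, lapply(sims, `[[`, "trials"))
  sess <- do.call(rbind, lapply(sims, `[[`, "sessions"))
  structure(list(trials = trials, sessions = sess, condition = condition,
                 alpha = alpha, lr_subnet = lr_subnet, n_sims = n_sims,
                 seeds = seeds),
            class = "sim_result")
}

run_conditioning_once <- function(bank, it_net, sessions, n_per_cs, alpha,
                                  condition, it_gain, it_noise_sd,
                                  et_noise_sd, lr_subnet, vnet_args,
                                  pretrain_args, seed, sim_id) {
  sub <- derive_seeds(seed, 4)
  if (is.null(bank)) bank <- generate_model_stimuli(seed = sub[1])
  if (is.null(it_net))
    it_net <- do.call(pretrain_it_network,
                      c(list(bank = bank, seed = sub[2]), pretrain_args))
  d_x <- ncol(bank$means)
  d_it <- nrow(it_net$layers[[2]]$W)
  with_seed(sub[3], {
    vnet <- do.call(value_network, c(list(input_dim = d_it + d_x), vnet_args))
    subnet <- do.call(value_network, c(list(input_dim = d_x), vnet_args))
    if (is.null(it_noise_sd)) {
      ## match the silencing noise to the replaced signal's empirical spread
      samp <- do.call(rbind, lapply(seq_len(nrow(bank$means)), function(k)
        sample_stimuli(bank, k, 25)))
      it_noise_sd <- stats::sd(it_gain * encode_it(it_net, samp))
    }
    n_trials <- 2L * n_per_cs
    rows <- vector("list", sessions)
    for (ss in seq_len(sessions)) {
      cs <- sample(rep(c("CSplus", "CSminus"), each = n_per_cs))
      V <- Vs <- delta <- numeric(n_trials)
      for (i in seq_len(n_trials)) {
        cls <- if (cs[i] == "CSplus") bank$cs_plus_class else bank$cs_minus_class
        x <- drop(sample_stimuli(bank, cls, 1))
        h_it <- if (condition == "IT_silenced")
          stats::rnorm(d_it, 0, it_noise_sd) else it_gain * encode_it(it_net, x)
        V[i] <- predict_value(vnet, h_it, x)
        R <- if (cs[i] == "CSplus") 1 else 0
        relayed <- if (condition == "ET_silenced")
          stats::rnorm(1, 0, et_noise_sd) else V[i]
        delta[i] <- R - relayed
        vnet <- rw_update(vnet, alpha, delta[i], h_it, x)
        subnet <- subnet_mse_update(subnet, lr_subnet, V[i], x)
        Vs[i] <- predict_value(subnet, x)
      }
      rows[[ss]] <- data.frame(sim = sim_id, session = ss,
                               trial = seq_len(n_trials), cs_type = cs,
                               V = V, V_subnet = Vs, delta = delta)
    }
    trials <- do.call(rbind, rows)
    report <- if (condition == "expert_S1_silenced") trials$V_subnet else trials$V
    agg <- function(col, sess, cs)
      mean(col[trials$session == sess & trials$cs_type == cs])
    sess_df <- do.call(rbind, lapply(seq_len(sessions), function(ss) data.frame(
      sim = sim_id, session = ss,
      V_plus = agg(report, ss, "CSplus"),
      V_minus = agg(report, ss, "CSminus"),
      V_plus_subnet = agg(trials$V_subnet, ss, "CSplus"),
      V_minus_subnet = agg(trials$V_subnet, ss, "CSminus")
    )))
    sess_df$lick_rate_plus <- predict_lick_rate(sess_df$V_plus)
    sess_df$lick_rate_minus <- predict_lick_rate(sess_df$V_minus)
    list(trials = trials, sessions = sess_df)
  })
}

#' Run matched conditioning simulations across silencing conditions
#'
#' Repeats the full conditioning protocol for several independent
#' simulations, each with its own stimulus bank and pretrained IT network,
#' and runs every requested condition on the *same* bank/network/seed per
#' simulation, so conditions are seed-matched and differences between them
#' reflect the silencing manipulation alone.
#'
#' @param n_sims Number of independent simulations (10 in the reference
#'   protocol).
#' @param conditions Conditions to run (all four by default).
#' @param seed Master seed.
#' @param ... Further arguments passed to [run_conditioning()].
#' @return Named list of `sim_result` objects, one per condition.
#' @export
run_all_conditions <- function(n_sims = 10L,
                               conditions = c("control", "IT_silenced",
                                              "ET_silenced",
                                              "expert_S1_silenced"),
                               seed = NULL, ...) {
  seeds <- derive_seeds(seed, 2L * n_sims)
  prep <- lapply(seq_len(n_sims), function(s) {
    bank <- generate_model_stimuli(seed = seeds[s])
    list(bank = bank,
         net = pretrain_it_network(bank, seed = seeds[n_sims + s]))
  })
  out <- lapply(conditions, function(cond) {
    sims <- lapply(seq_len(n_sims), function(s) {
      r <- run_conditioning(prep[[s]]$bank, prep[[s]]$net, condition = cond,
                            n_sims = 1L, seed = seeds[s], ...)
      r$trials$sim <- s
      r$sessions$sim <- s
      r
    })
    structure(list(
      trials = do.call(rbind, lapply(sims, `[[`, "trials")),
      sessions = do.call(rbind, lapply(sims, `[[`, "sessions")),
      condition = cond, alpha = sims[[1]]$alpha,
      lr_subnet = sims[[1]]$lr_subnet, n_sims = n_sims,
      seeds = seeds[seq_len(n_sims)]
    ), class = "sim_result")
  })
  names(out) <- conditions
  out
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("RW conditioning simulation: %s, %d sim(s), alpha = %g\n",
              x$condition, x$n_sims, x$alpha))
  last <- max(x$sessions$session)
  vp <- mean(x$sessions$V_plus[x$sessions$session == last])
  vm <- mean(x$sessions$V_minus[x$sessions$session == last])
  cat(sprintf("  terminal association: V(CS+) = %.3f, V(CS-) = %.3f, diff = %.3f\n",
              vp, vm, vp - vm))
  invisible(x)
}

#' Expert performance before and after S1 removal
#'
#' Discrimination (terminal-session `V(CS+) - V(CS-)`) of the full
#' two-channel model versus the transfer sub-network alone (i.e. with the
#' S1 channels removed), per simulation, with their paired difference. The
#' test only reads the stored simulation result.
#'
#' @param result A control-condition [run_conditioning()] result.
#' @return List with per-sim `full` and `subnet` discrimination vectors,
#'   `paired_diff`, `retention` (mean subnet / mean full discrimination) and
#'   `p_value` of a two-sided paired t-test (NA for a single simulation).
#' @export
expert_transfer_test <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  if (result$condition != "control")
    stop_invalid("expert transfer is evaluated on a control run (got '%s')",
                 result$condition)
  last <- max(result$sessions$session)
  sess <- result$sessions[result$sessions$session == last, ]
  full <- sess$V_plus - sess$V_minus
  subnet <- sess$V_plus_subnet - sess$V_minus_subnet
  if (!is.null(result$lr_subnet) && result$lr_subnet == 0)
    stop("transfer sub-network is untrained (lr_subnet = 0)", call. = FALSE)
  p <- if (length(full) > 1 && stats::sd(full - subnet) > 0)
    stats::t.test(full, subnet, paired = TRUE)$p.value else NA_real_
  list(full = full, subnet = subnet, paired_diff = full - subnet,
       retention = mean(subnet) / mean(full), p_value = p)
}

#' Representational overlap versus learning performance
#'
#' For random CS+/CS- pairs drawn from the stimulus classes, measures the
#' mean Euclidean distance between the IT representations of the two
#' classes and the learning performance on that pair, defined as the
#' difference in association strength `V(CS+) - V(CS-)` after Session 2 of
#' a conditioning run. The relationship is summarized by a saturating
#' exponential fit `delta = a * (1 - exp(-b * distance))` (deltas are
#' bounded, so the saturating form is used) and Spearman's rank correlation.
#'
#' @param bank Stimulus bank.
#' @param it_net Pretrained IT network for the bank.
#' @param n_pairs Number of random class pairs (>= 3).
#' @param n_per_cs Trials per CS per session in each conditioning run.
#' @param alpha Learning rate.
#' @param n_dist_samples Samples per class for the distance estimate.
#' @param n_reps Conditioning runs averaged per pair (trial ordering and
#'   stimulus sampling make a single two-session run noisy).
#' @param seed Integer seed.
#' @return List with `pairs` (data frame: `cs_plus`, `cs_minus`, `distance`,
#'   `delta`), `fit` (coefficients `a`, `b`, or `NULL` if the fit failed)
#'   and `spearman_rho`.
#' @export
representational_overlap <- function(bank, it_net, n_pairs = 20L,
                                     n_per_cs = 100L, alpha = 0.1,
                                     n_dist_samples = 100L, n_reps = 3L,
                                     seed = NULL) {
  if (n_pairs < 3) stop_invalid("need at least 3 pairs")
  seeds <- derive_seeds(seed, n_pairs * (n_reps + 1L) + 1L)
  n_cls <- nrow(bank$means)
  pairs <- with_seed(seeds[length(seeds)], t(replicate(n_pairs,
    sample.int(n_cls, 2))))
  res <- lapply(seq_len(n_pairs), function(i) {
    b2 <- bank
    b2$cs_plus_class <- pairs[i, 1]
    b2$cs_minus_class <- pairs[i, 2]
    si <- seeds[((i - 1L) * (n_reps + 1L) + 1L):(i * (n_reps + 1L))]
    d <- with_seed(si[1], {
      ha <- encode_it(it_net, sample_stimuli(b2, b2$cs_plus_class, n_dist_samples))
      hb <- encode_it(it_net, sample_stimuli(b2, b2$cs_minus_class, n_dist_samples))
      ## distance between the class centroids in IT space; averaging the
      ## per-sample representations first removes the within-class noise
      ## floor that would otherwise swamp the between-class separation
      sqrt(sum((colMeans(ha) - colMeans(hb))^2))
    })
    delta <- mean(vapply(seq_len(n_reps), function(rep_i) {
      run <- run_conditioning(bank = b2, it_net = it_net, sessions = 2L,
                              n_per_cs = n_per_cs, alpha = alpha,
                              condition = "control", seed = si[rep_i + 1L])
      s2 <- run$sessions[run$sessions$session == 2, ]
      s2$V_plus - s2$V_minus
    }, numeric(1)))
    data.frame(cs_plus = pairs[i, 1], cs_minus = pairs[i, 2],
               distance = d, delta = delta)
  })
  tab <- do.call(rbind, res)
  fit <- tryCatch({
    f <- suppressWarnings(minpack.lm::nlsLM(
      delta ~ a * (1 - exp(-b * distance)), data = tab,
      start = list(a = max(tab$delta), b = 1 / mean(tab$distance)),
      control = minpack.lm::nls.lm.control(maxiter = 500)))
    as.list(stats::coef(f))
  }, error = function(e) NULL)
  rho <- stats::cor(tab$distance, tab$delta, method = "spearman")
  list(pairs = tab, fit = fit, spearman_rho = rho)
}
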