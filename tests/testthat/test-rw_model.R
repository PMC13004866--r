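test_that("autoencoder pretraining reduces held-out reconstruction loss and freezes", {
  bank <- generate_model_stimuli(seed = 1)
  net <- pretrain_it_network(bank, epochs = 150, seed = 2)
  expect_lt(net$loss_final, net$loss_initial)
  expect_true(net$frozen)
  # architecture: 20 -> 50 -> 50 -> 15 -> 50 -> 50 -> 20
  dims <- vapply(net$layers, function(l) nrow(l$W), integer(1))
  expect_equal(dims, c(50L, 50L, 15L, 50L, 50L, 20L))

  # frozen contract: a conditioning run leaves the weights byte-identical
  before <- net$layers
  invisible(run_conditioning(bank, net, sessions = 1, n_per_cs = 5, seed = 3))
  expect_identical(net$layers, before)
})

test_that("the IT representation is the deterministic 50-unit encoder output", {
  bank <- generate_model_stimuli(seed = 4)
  net <- pretrain_it_network(bank, epochs = 150, seed = 5)
  x <- sample_stimuli(bank, 1, 1)
  h <- encode_it(net, drop(x))
  expect_length(h, 50)
  expect_identical(h, encode_it(net, drop(x)))
  expect_error(encode_it(net, rnorm(7)), "dimension")

  # same-class samples are closer than different-class samples in expectation
  h1 <- encode_it(net, sample_stimuli(bank, 1, 300))
  h1b <- encode_it(net, sample_stimuli(bank, 1, 300))
  h2 <- encode_it(net, sample_stimuli(bank, 2, 300))
  d_within <- mean(sqrt(rowSums((h1 - h1b)^2)))
  d_between <- mean(sqrt(rowSums((h1 - h2)^2)))
  expect_lt(d_within, d_between)
})

test_that("value predictions respect the sigmoid architecture", {
  vnet <- value_network(70, seed = 6)
  expect_length(vnet$w2, 116)           # hidden width
  v <- predict_value(vnet, rnorm(50), rnorm(20))
  expect_true(v > 0 && v < 1)
  expect_error(predict_value(vnet, rnorm(10)), "dimension")

  # all-zero weights and bias: V = sigmoid(0) = 0.5
  zero <- value_network(10, init_sd = 0, v0 = 0.5, seed = 7)
  expect_equal(predict_value(zero, rnorm(10)), 0.5)
})

test_that("the prediction error is reward minus value", {
  expect_equal(rpe(1, 0.3), 0.7)
  expect_equal(rpe(0, 0.4), -0.4)
  expect_equal(rpe(1, 1), 0)
  expect_error(rpe(0.5, 0.2), "0 or 1")
})

test_that("rw_update moves weights along alpha * delta * grad V", {
  vnet <- value_network(12, hidden_units = 8, seed = 8)
  u <- rnorm(12)
  expect_identical(rw_update(vnet, 0.1, 0, u), vnet)   # delta = 0: no change

  # analytic gradients match central finite differences on random networks
  flatten <- function(v) c(v$w2, v$b2, as.vector(v$W1), v$b1)
  unflatten <- function(v, p) {
    n2 <- length(v$w2)
    v$w2 <- p[1:n2]; v$b2 <- p[n2 + 1]
    nW <- length(v$W1)
    v$W1 <- matrix(p[(n2 + 2):(n2 + 1 + nW)], nrow(v$W1))
    v$b1 <- p[(n2 + 2 + nW):length(p)]
    v
  }
  for (s in 1:20) {
    v <- value_network(5, hidden_units = 4, init_sd = 1, seed = s)
    u <- rnorm(5)
    g <- corticond:::vnet_grad(v, u)$grads
    ga <- c(g$w2, g$b2, as.vector(g$W1), g$b1)
    p0 <- flatten(v)
    eps <- 1e-6
    gn <- vapply(seq_along(p0), function(i) {
      pp <- p0; pp[i] <- pp[i] + eps
      pm <- p0; pm[i] <- pm[i] - eps
      (predict_value(unflatten(v, pp), u) -
         predict_value(unflatten(v, pm), u)) / (2 * eps)
    }, numeric(1))
    expect_equal(ga, gn, tolerance = 1e-5)
  }
})

test_that("the one-hot linear limit recovers tabular Rescorla-Wagner exactly", {
  for (alpha in c(0.1, 0.5)) {
    vnet <- value_network(1, hidden_units = 0, output = "linear",
                          bias = FALSE, init_sd = 0)
    V <- numeric(10)
    for (t in 1:10) {
      v_now <- predict_value(vnet, 1)
      vnet <- rw_update(vnet, alpha, rpe(1, v_now), 1)
      V[t] <- predict_value(vnet, 1)
    }
    expect_equal(V, 1 - (1 - alpha)^(1:10), tolerance = 1e-10)
  }
})

test_that("conditioning runs are deterministic and respect reward structure", {
  bank <- generate_model_stimuli(seed = 9)
  net <- pretrain_it_network(bank, epochs = 100, seed = 10)
  r1 <- run_conditioning(bank, net, sessions = 2, n_per_cs = 10, seed = 11)
  r2 <- run_conditioning(bank, net, sessions = 2, n_per_cs = 10, seed = 11)
  expect_identical(r1, r2)
  # R = V + delta recovers exactly 1 on CS+ and 0 on CS- for every trial
  R <- r1$trials$V + r1$trials$delta
  expect_equal(R[r1$trials$cs_type == "CSplus"],
               rep(1, sum(r1$trials$cs_type == "CSplus")))
  expect_equal(R[r1$trials$cs_type == "CSminus"],
               rep(0, sum(r1$trials$cs_type == "CSminus")))
  expect_true(all(r1$sessions$V_plus > 0 & r1$sessions$V_plus < 1))
  expect_error(run_conditioning(bank, net, condition = "nope"), "arg")
})

test_that("control learning curves rise jointly before diverging", {
  r <- run_conditioning(n_sims = 3, seed = 12)
  s <- aggregate(cbind(V_plus, V_minus) ~ session, r$sessions, mean)
  v0 <- 0.1   # initial association of a naive network
  expect_gt(s$V_plus[1], v0)
  expect_gt(s$V_minus[1], v0)          # early generalized rise
  peak <- which.max(s$V_minus)
  expect_lt(peak, 5)                   # CS- declines from its peak session
  expect_lt(s$V_minus[5], s$V_minus[peak])
  expect_gt(s$V_plus[5], s$V_plus[1])  # CS+ keeps rising
})

test_that("expert transfer evaluates the sub-network without mutating the run", {
  bank <- generate_model_stimuli(seed = 13)
  net <- pretrain_it_network(bank, epochs = 100, seed = 14)
  r <- run_conditioning(bank, net, n_sims = 2, seed = 15)
  snapshot <- r
  et <- expert_transfer_test(r)
  expect_identical(r, snapshot)        # read-only evaluation
  expect_gte(et$retention, 0.8)
  expect_length(et$paired_diff, 2)

  # an untrained sub-network (zero transfer steps) carries no discrimination
  r0 <- run_conditioning(bank, net, n_sims = 1, lr_subnet = 0, seed = 16)
  expect_error(expert_transfer_test(r0), "untrained")
  its <- run_conditioning(bank, net, condition = "IT_silenced",
                          sessions = 1, n_per_cs = 5, seed = 17)
  expect_error(expert_transfer_test(its), "control")
})

test_that("representational overlap predicts learning performance", {
  bank <- generate_model_stimuli(seed = 18)
  net <- pretrain_it_network(bank, epochs = 150, seed = 19)
  expect_error(representational_overlap(bank, net, n_pairs = 2), "3 pairs")
  ov <- representational_overlap(bank, net, n_pairs = 20, n_per_cs = 60,
                                 seed = 20)
  expect_equal(nrow(ov$pairs), 20)
  expect_true(all(ov$pairs$distance > 0))
  # learning improves with representational separation: positive monotone
  # association, and clearly larger deltas for distant than for close pairs
  expect_gt(ov$spearman_rho, 0.4)
  ord <- order(ov$pairs$distance)
  far <- tail(ord, 5); near <- head(ord, 5)
  expect_gt(mean(ov$pairs$delta[far]), mean(ov$pairs$delta[near]))
  if (!is.null(ov$fit)) expect_gt(ov$fit$a, 0)
  # identical pair: tiny representational distance, near-zero learning delta
  same <- bank
  same$cs_minus_class <- same$cs_plus_class <- 1
  run <- run_conditioning(same, net, sessions = 2, n_per_cs = 40, seed = 21)
  s2 <- run$sessions[run$sessions$session == 2, ]
  expect_lt(abs(s2$V_plus - s2$V_minus), 0.1)
})
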