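# Inference and learning dynamics: forward initialization, analytic gradients
# against hand derivations and finite differences, the inference loop,
# equilibrium propagation, the backprop baseline, and the training loop.

scalar_chain <- function(weights, act = "identity", T_steps = 1) {
  L <- length(weights)
  nodes <- list(node_spec(0, 1, "input", act = "identity"))
  for (m in seq_len(L - 1))
    nodes[[m + 1]] <- node_spec(m, 1, "hidden", act = act)
  nodes[[L + 1]] <- node_spec(L, 1, "output", act = "identity")
  edges <- lapply(seq_len(L), function(m)
    edge_spec(m - 1, m, "feedforward", fn_fc(1), params_id = sprintf("w%d", m)))
  g <- network_graph(nodes, edges, T_steps)
  p <- init_params(g, seed = 0)
  for (m in seq_len(L)) {
    p$tensors[[sprintf("w%d", m)]]$W[] <- weights[m]
    p$tensors[[sprintf("w%d", m)]]$b[] <- 0
  }
  list(g = g, p = p)
}

test_that("forward initialization populates states and zeroes internal errors", {
  # scalar chain theta = 2 per layer, x = 1 -> states (1, 2, 4)
  sc <- scalar_chain(c(2, 2))
  tr <- init_states(sc$g, sc$p, matrix(1, 1, 1))
  expect_equal(sapply(1:3, function(u) as.numeric(tr$v[[u]][[1]])), c(1, 2, 4))

  # on any static graph the internal hpc energy is exactly zero after init
  for (g in list(build_graph("toy_chain", depth = 3, width = 4, n_classes = 2,
                             input_shape = 3, skip = TRUE),
                 build_graph("toy_conv", n_classes = 2, input_shape = c(4, 4, 1),
                             channels = c(2, 3)))) {
    p <- init_params(g, seed = 1)
    x <- if (length(g$nodes[[1]]$shape) == 3)
      array(rnorm(2 * 16), c(2, 4, 4, 1)) else matrix(rnorm(2 * 3), 2, 3)
    tr <- init_states(g, p, x)
    expect_equal(hpc_energy(g, p, tr)$E_internal, 0)
  }

  # temporal net: the recursion matches a hand-rolled time-unrolled loop
  g <- build_graph("toy_chain", depth = 2, width = 2, n_classes = 2,
                   input_shape = 2, T_steps = 3)
  p <- init_params(g, seed = 4)
  x <- matrix(rnorm(3 * 2), 3, 2)
  tr <- init_states(g, p, x)
  W <- function(id) p$tensors[[id]]$W
  bvec <- function(id) matrix(p$tensors[[id]]$b, nrow(x), length(p$tensors[[id]]$b), byrow = TRUE)
  v <- list()   # v[[m+1]][[t+1]]
  v[[1]] <- lapply(1:4, function(s) x)
  for (m in 1:2) v[[m + 1]] <- c(list(matrix(0, nrow(x), 2)), vector("list", 3))
  v[[4]] <- c(list(matrix(0, nrow(x), 2)), vector("list", 3))
  for (t in 1:3) {
    for (m in 1:2) {
      ss <- v[[m]][[t]] %*% W(sprintf("e%d_%d_ff", m - 1, m)) +
        bvec(sprintf("e%d_%d_ff", m - 1, m)) + v[[m + 1]][[t]]
      pre <- ss %*% W(sprintf("e%d_%d_rec", m, m)) + bvec(sprintf("e%d_%d_rec", m, m))
      v[[m + 1]][[t + 1]] <- tanh(pre)
    }
    v[[4]][[t + 1]] <- v[[3]][[t]] %*% W("e2_3_ff") + bvec("e2_3_ff")
  }
  for (m in 1:3) for (s in 1:4)
    expect_equal(tr$v[[m + 1]][[s]], v[[m + 1]][[s]], tolerance = 1e-12)
})

test_that("state gradients match hand derivations and finite differences", {
  # chain v0 = 1, theta1 = 2, v1 = 3, theta2 = 1, v2 = 3:
  # F = (v1 - 2)^2 + (v2 - v1)^2, dF/dv1 = 2
  sc <- scalar_chain(c(2, 1))
  tr <- init_states(sc$g, sc$p, matrix(1, 1, 1))
  tr$v[[2]][[1]][] <- 3
  tr$v[[3]][[1]][] <- 3
  sg <- state_gradients(sc$g, sc$p, tr, method = "hpc")
  expect_equal(as.numeric(sg[["n1.t0"]]$grad), 2)
  expect_equal(as.numeric(sg[["n2.t0"]]$grad), 0)

  # at an exact equilibrium (all errors zero, no loss) every gradient is 0
  tr0 <- init_states(sc$g, sc$p, matrix(1, 1, 1))
  sg0 <- state_gradients(sc$g, sc$p, tr0, method = "hpc")
  for (rec in sg0) expect_equal(max(abs(rec$grad)), 0)

  blob <- make_blob_batch(3, 3, 2)
  for (setup in list(list(T_steps = 1, skip = TRUE), list(T_steps = 3, skip = TRUE))) {
    g <- build_graph("toy_chain", depth = 3, width = 3, n_classes = 2,
                     input_shape = 3, T_steps = setup$T_steps, skip = setup$skip)
    p <- init_params(g, seed = 6)
    tr <- perturbed_traj(g, p, blob$x, seed = 8)
    for (m in c("hpc", "bipc_additive", "bipc_combined"))
      expect_lt(fd_state_check(g, p, tr, blob$y, m, max_coords = 12), 1e-4)
  }
})

test_that("parameter gradients match hand derivations and finite differences", {
  # single layer v0 = 2, theta = 1, v1 = 5: F = (5 - 2)^2, dF/dW = -2*3*2
  sc <- scalar_chain(1)
  tr <- init_states(sc$g, sc$p, matrix(2, 1, 1))
  tr$v[[2]][[1]][] <- 5
  pg <- param_gradients(sc$g, sc$p, tr, method = "hpc")
  expect_equal(as.numeric(pg$w1$W), -12)

  # all-zero errors and no loss: all parameter gradients vanish
  tr0 <- init_states(sc$g, sc$p, matrix(2, 1, 1))
  pg0 <- param_gradients(sc$g, sc$p, tr0, method = "hpc")
  expect_equal(max(abs(th_flatten(pg0))), 0)

  blob <- make_blob_batch(3, 3, 2)
  g <- build_graph("toy_chain", depth = 3, width = 3, n_classes = 2,
                   input_shape = 3, T_steps = 3, skip = TRUE)
  p <- init_params(g, seed = 6)
  tr <- perturbed_traj(g, p, blob$x, seed = 8)
  for (m in c("hpc", "bipc_additive", "bipc_combined"))
    expect_lt(fd_param_check(g, p, tr, blob$y, m, max_coords = 10), 1e-4)

  # convolutional graph, including tied transposed-conv feedback routing
  gc_ <- build_graph("toy_conv", n_classes = 2, input_shape = c(4, 4, 1),
                     channels = c(2, 2))
  pc_ <- init_params(gc_, seed = 7)
  xc <- array(rnorm(2 * 16), c(2, 4, 4, 1))
  trc <- perturbed_traj(gc_, pc_, xc, seed = 9)
  expect_lt(fd_param_check(gc_, pc_, trc, c(0L, 1L), "bipc_combined",
                           max_coords = 10), 1e-4)
})

test_that("two-state (complex-variant) gradients match finite differences", {
  g <- build_graph("skip_recurrent_complex", n_classes = 2,
                   input_shape = c(8, 8, 1), channels = rep(2L, 6))
  p <- init_params(g, seed = 5)
  x <- array(rnorm(64), c(1, 8, 8, 1))
  tr <- perturbed_traj(g, p, x, seed = 10)
  expect_lt(fd_state_check(g, p, tr, 0L, "bipc_combined", max_coords = 3), 1e-4)
  expect_lt(fd_param_check(g, p, tr, 0L, "bipc_combined", max_coords = 2), 1e-4)
})

test_that("inference converges immediately at equilibrium and geometrically on a quadratic", {
  # start at equilibrium: one convergence check, states unchanged
  sc <- scalar_chain(c(2, 2))
  tr <- init_states(sc$g, sc$p, matrix(1, 1, 1))
  inf <- run_inference(sc$g, sc$p, tr, method = "hpc")
  expect_true(inf$trace$converged)
  expect_equal(inf$trace$iterations_used, 1L)
  expect_equal(length(inf$trace$F_history), inf$trace$iterations_used + 1L)
  expect_equal(inf$traj$v[[2]][[1]], tr$v[[2]][[1]])

  # quadratic toy F = (v - 3)^2 via an identity edge from clamped input 3:
  # with eta_v = 0.1 the error contracts by 0.8 per step
  g <- network_graph(list(node_spec(0, 1, "input", act = "identity"),
                          node_spec(1, 1, "output", act = "identity")),
                     list(edge_spec(0, 1, "feedforward", fn_identity())), 1)
  p <- init_params(g, seed = 0)
  tr <- init_states(g, p, matrix(3, 1, 1))
  tr$v[[2]][[1]][] <- 0
  inf <- run_inference(g, p, tr, method = "hpc",
                       cfg = inference_config(eta_v = 0.1, N = 30, threshold = 1e-300))
  Fh <- inf$trace$F_history
  expect_equal(Fh[1], 9)
  expect_equal(Fh[-1] / Fh[-length(Fh)], rep(0.64, length(Fh) - 1), tolerance = 1e-10)
})

test_that("inference descends the energy monotonically and flags divergence", {
  set.seed(21)
  g <- build_graph("toy_chain", depth = 2, width = 4, n_classes = 2, input_shape = 3)
  p <- init_params(g, seed = 3)
  x <- matrix(rnorm(8 * 3), 8, 3); y <- sample(0:1, 8, TRUE)
  for (m in c("hpc", "bipc_combined")) {
    tr <- init_states(g, p, x)
    inf <- run_inference(g, p, tr, y = y, method = m,
                         cfg = inference_config(eta_v = 1e-3, N = 200))
    expect_true(all(diff(inf$trace$F_history) <= 1e-8))
    expect_false(inf$trace$diverged)
  }
  # a absurdly large step explodes; the loop aborts with a report, not NaNs
  p_hot <- init_params(g, seed = 3, weight_scale = 4)
  tr <- init_states(g, p_hot, x)
  inf <- run_inference(g, p_hot, tr, y = y, method = "hpc",
                       cfg = inference_config(eta_v = 5, N = 200,
                                              divergence_factor = 1e6))
  expect_true(inf$trace$diverged)
  expect_true(all(is.finite(inf$trace$F_history)))
})

test_that("equilibrium propagation matches the implicit loss gradient", {
  set.seed(2)
  n <- 5
  w <- matrix(rnorm(n * n, sd = 0.3), n, n); w <- (w + t(w)) / 2; diag(w) <- 0
  hp <- hopfield_params(w, b = rnorm(n, sd = 0.1), rho = "tanh",
                        input_units = 1:2, output_units = 4:5)
  x <- matrix(rnorm(4), 2, 2)
  y <- matrix(c(0.5, -0.3, 0.2, 0.8), 2, 2)
  cfg <- inference_config(eta_v = 0.05, N = 5000, threshold = 1e-14)
  res <- ep_two_phase(hp, x, y, beta = 1e-3, cfg = cfg)
  expect_true(res$free_converged && res$nudged_converged)

  # numerical oracle: central differences of C at the free equilibrium
  Cstar <- function(hp) {
    v0 <- matrix(0, nrow(x), n); v0[, hp$input_units] <- x
    fr <- ebll:::ep_relax(v0, hp, cfg = cfg)
    external_loss(fr$v[, hp$output_units, drop = FALSE], y, "mse")
  }
  h <- 1e-5
  gW <- matrix(0, n, n); gb <- numeric(n)
  for (i in 1:n) for (j in 1:n) {
    if (i >= j) next
    hp1 <- hp; hp1$w[i, j] <- hp1$w[i, j] + h; hp1$w[j, i] <- hp1$w[j, i] + h
    hp2 <- hp; hp2$w[i, j] <- hp2$w[i, j] - h; hp2$w[j, i] <- hp2$w[j, i] - h
    gW[i, j] <- gW[j, i] <- (Cstar(hp1) - Cstar(hp2)) / (2 * h)
  }
  for (i in 1:n) {
    hp1 <- hp; hp1$b[i] <- hp1$b[i] + h
    hp2 <- hp; hp2$b[i] <- hp2$b[i] - h
    gb[i] <- (Cstar(hp1) - Cstar(hp2)) / (2 * h)
  }
  a <- c(res$contrastive_grads$w[upper.tri(gW)], res$contrastive_grads$b)
  b <- c(gW[upper.tri(gW)], gb)
  expect_gt(sum(a * b) / sqrt(sum(a^2) * sum(b^2)), 0.99)

  # target equal to the free-phase output: nudging changes nothing
  yfree <- res$free_states[, hp$output_units, drop = FALSE]
  res2 <- ep_two_phase(hp, x, yfree, beta = 0.1, cfg = cfg)
  expect_lt(sqrt(sum(th_flatten(res2$contrastive_grads)^2)), 1e-5)

  # determinism: identical inputs give identical gradients
  res3 <- ep_two_phase(hp, x, y, beta = 1e-3, cfg = cfg)
  expect_identical(res3$contrastive_grads, res$contrastive_grads)
})

test_that("converged hierarchical updates align with the backprop gradient", {
  set.seed(1)
  g <- build_graph("toy_chain", depth = 3, width = 8, n_classes = 2, input_shape = 6)
  p <- init_params(g, seed = 1)
  x <- matrix(rnorm(16 * 6), 16, 6)
  ytg <- matrix(rnorm(16 * 2), 16, 2)
  bp <- backprop_gradients(g, p, x, ytg, loss = "mse")
  tr <- init_states(g, p, x)
  inf <- run_inference(g, p, tr, y = ytg, method = "hpc",
                       cfg = inference_config(eta_v = 0.05, N = 4000,
                                              threshold = 1e-12, beta = 0.05),
                       loss_f = "mse")
  pg <- param_gradients(g, p, inf$traj, y = ytg, method = "hpc",
                        beta = 0.05, loss_f = "mse")
  a <- th_flatten(pg); b <- th_flatten(bp$dth)
  expect_gt(sum(a * b) / sqrt(sum(a^2) * sum(b^2)), 0.9)
})

test_that("backprop gradients match finite differences through the forward sweep", {
  set.seed(14)
  g <- build_graph("toy_chain", depth = 2, width = 3, n_classes = 2,
                   input_shape = 3, T_steps = 3)
  p <- init_params(g, seed = 14)
  x <- matrix(rnorm(2 * 3), 2, 3); y <- c(0L, 1L)
  bp <- backprop_gradients(g, p, x, y, loss = "cross_entropy")
  h <- 1e-5; worst <- 0
  for (id in names(p$tensors)) {
    flat <- th_flatten(bp$dth[[id]])
    for (i in seq_len(min(6, length(flat)))) {
      p1 <- p; p2 <- p
      p1$tensors[[id]] <- th_perturb(p$tensors[[id]], i, h)
      p2$tensors[[id]] <- th_perturb(p$tensors[[id]], i, -h)
      fd <- (backprop_gradients(g, p1, x, y)$loss -
             backprop_gradients(g, p2, x, y)$loss) / (2 * h)
      worst <- max(worst, abs(flat[i] - fd) / max(abs(fd), 1e-6))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("the training loop runs every method and honours epochs = 0", {
  ds <- make_synthetic(synthetic_spec("blobs", n_samples = 120, n_classes = 2, seed = 1))
  g <- build_graph("toy_chain", depth = 2, width = 6, n_classes = 2, input_shape = 2)
  cfg0 <- run_config(epochs = 0, seed = 1)
  fit0 <- ebll_train(g, ds, cfg0)
  expect_equal(nrow(fit0$metrics), 0L)
  p_init <- init_params(g, seed = 1)
  expect_equal(fit0$params$tensors, p_init$tensors)

  for (m in c("hpc", "bipc_additive", "bipc_combined", "backprop", "ep")) {
    cfg <- run_config(method = m, optimizer = "sgd", epochs = 2, seed = 1,
                      batch_size = 32, N = 15, eta_theta = 0.02)
    fit <- ebll_train(g, ds, cfg)
    expect_equal(nrow(fit$metrics), 2L)
    expect_true(all(is.finite(fit$metrics$loss)))
    expect_true(all(fit$metrics$accuracy >= 0 & fit$metrics$accuracy <= 1))
    pr <- predict(fit, ds$test$x)
    expect_true(all(pr %in% 0:1))
  }
})

test_that("identical configurations reproduce identical metrics logs", {
  ds <- make_synthetic(synthetic_spec("blobs", n_samples = 160, n_classes = 2, seed = 5))
  g <- build_graph("toy_chain", depth = 2, width = 6, n_classes = 2, input_shape = 2)
  cfg <- run_config(method = "bipc_combined", optimizer = "lalr", epochs = 3,
                    seed = 9, batch_size = 64, N = 20)
  f1 <- ebll_train(g, ds, cfg)
  f2 <- ebll_train(g, ds, cfg)
  expect_equal(f1$metrics, f2$metrics, tolerance = 1e-12)
  expect_equal(f1$grad_norms$grad_norm, f2$grad_norms$grad_norm, tolerance = 1e-12)
  expect_equal(f1$params$tensors, f2$params$tensors, tolerance = 1e-12)
})
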