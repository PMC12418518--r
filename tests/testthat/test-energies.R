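# Energy functions: hand-worked examples, reductions, invariant properties,
# and equivalence with explicit-loop oracles.

linear_chain <- function(depth, width, n_classes = 2, input_shape = width,
                         T_steps = 1, skip = FALSE, seed = 1) {
  g <- build_graph("toy_chain", depth = depth, width = width,
                   n_classes = n_classes, input_shape = input_shape,
                   T_steps = T_steps, skip = skip, act = "identity")
  list(g = g, p = init_params(g, seed = seed))
}

set_scalar_weight <- function(p, id, w) {
  p$tensors[[id]]$W[] <- w
  p$tensors[[id]]$b[] <- 0
  p
}

test_that("feedforward predictions follow the branch-sum composition", {
  # scalar net: weights 1, identity recurrent transform, linear activation;
  # bottom-up 1 + skip 2 + self 3 -> prediction 6
  nodes <- list(node_spec(0, 1, "input", act = "identity"),
                node_spec(1, 1, "hidden", act = "identity"),
                node_spec(2, 1, "hidden", act = "identity"),
                node_spec(3, 1, "output", act = "identity"))
  edges <- list(
    edge_spec(0, 1, "feedforward", fn_fc(1), params_id = "f1"),
    edge_spec(1, 2, "feedforward", fn_fc(1), params_id = "f2"),
    edge_spec(0, 2, "skip", fn_fc(1), params_id = "s2"),
    edge_spec(2, 2, "recurrent", fn_identity()),
    edge_spec(2, 3, "feedforward", fn_fc(1), params_id = "f3"))
  g <- network_graph(nodes, edges, T_steps = 2)
  p <- init_params(g, seed = 0)
  for (id in c("f1", "f2", "s2", "f3")) p <- set_scalar_weight(p, id, 1)
  traj <- init_states(g, p, matrix(2, 1, 1))   # input = skip source = 2
  traj$v[[2]][[1]][] <- 1                      # v_{m-1, t-1} = 1
  traj$v[[3]][[1]][] <- 3                      # v_{m, t-1}   = 3
  preds <- forward_predictions(g, p, traj)
  expect_equal(as.numeric(preds[["n2.t1"]]$vhat), 6)

  # T = 1 chain, theta = 2: prediction = 2 * v_{m-1}
  lc <- linear_chain(1, 1, n_classes = 1, input_shape = 1)
  lc$p <- set_scalar_weight(lc$p, "e0_1_ff", 2)
  tr <- init_states(lc$g, lc$p, matrix(1, 1, 1))
  pr <- forward_predictions(lc$g, lc$p, tr)
  expect_equal(as.numeric(pr[["n1.t0"]]$vhat), 2)

  # a node without a skip source: prediction = bottom-up + self only
  g3 <- build_graph("toy_chain", depth = 3, width = 2, n_classes = 2,
                    skip = TRUE, act = "identity")
  p3 <- init_params(g3, seed = 3)
  tr3 <- init_states(g3, p3, matrix(rnorm(2), 1, 2))
  pr3 <- forward_predictions(g3, p3, tr3)
  manual <- tr3$v[[1]][[1]] %*% p3$tensors$e0_1_ff$W +
    matrix(p3$tensors$e0_1_ff$b, 1, 2, byrow = TRUE)
  expect_equal(pr3[["n1.t0"]]$vhat, manual)
})

test_that("feedback predictions apply half-weighted transposed branches", {
  # scalars: theta_td = 2 applied to 1, theta_rec = 4 applied to 0.5
  nodes <- list(node_spec(0, 1, "input", act = "identity"),
                node_spec(1, 1, "hidden", act = "identity"),
                node_spec(2, 1, "output", act = "identity"))
  edges <- list(
    edge_spec(0, 1, "feedforward", fn_fc(1), params_id = "f1"),
    edge_spec(1, 1, "recurrent", fn_fc(1), params_id = "r1"),
    edge_spec(1, 2, "feedforward", fn_fc(1), params_id = "f2"))
  edges <- c(edges, ebll:::mirror_feedback(edges))
  g <- network_graph(nodes, edges, T_steps = 2)
  p <- init_params(g, seed = 0)
  p <- set_scalar_weight(p, "f2", 2)
  p <- set_scalar_weight(p, "r1", 4)
  p <- set_scalar_weight(p, "f1", 1)
  traj <- init_states(g, p, matrix(0, 1, 1))
  traj$v[[3]][[2]][] <- 1       # v_{m+1, t+1}
  traj$v[[2]][[2]][] <- 0.5     # v_{m, t+1}
  preds <- backward_predictions(g, p, traj)
  expect_equal(as.numeric(preds[["n1.t0"]]$vhat), 0.5 * 2 * 1 + 0.5 * 4 * 0.5)

  # the top node has no feedback source at all (no node above, no recurrent
  # edge), so no feedback prediction exists there -- dropped, not zero-filled
  expect_null(preds[["n2.t0"]])
  expect_null(preds[["n2.t1"]])

  # a hidden node with only the recurrent feedback branch keeps the literal
  # 1/2 factor (no renormalization by default)
  g1 <- network_graph(list(node_spec(0, 1, "input", act = "identity"),
                           node_spec(1, 1, "hidden", act = "identity"),
                           node_spec(2, 1, "output", act = "identity")),
                      c(list(edge_spec(0, 1, "feedforward", fn_fc(1), params_id = "f1"),
                             edge_spec(1, 1, "recurrent", fn_fc(1), params_id = "r1")),
                        ebll:::mirror_feedback(list(
                          edge_spec(1, 1, "recurrent", fn_fc(1), params_id = "r1")))),
                      T_steps = 2)
  p1 <- init_params(g1, seed = 0)
  p1 <- set_scalar_weight(p1, "r1", 4)
  p1 <- set_scalar_weight(p1, "f1", 1)
  tr1 <- init_states(g1, p1, matrix(0, 1, 1))
  tr1$v[[2]][[2]][] <- 0.5
  pr1 <- backward_predictions(g1, p1, tr1)
  expect_equal(as.numeric(pr1[["n1.t0"]]$vhat), 0.5 * 4 * 0.5)
  # with renormalization the single branch carries full weight
  pr1r <- backward_predictions(g1, p1, tr1, renorm = TRUE)
  expect_equal(as.numeric(pr1r[["n1.t0"]]$vhat), 4 * 0.5)
})

test_that("hpc energy matches hand-computed sums and zeroes out after init", {
  # scalar chain v0 = 1, theta = 2, v1 = 3, no output loss: F = (3 - 2)^2
  lc <- linear_chain(1, 1, n_classes = 1, input_shape = 1)
  lc$p <- set_scalar_weight(lc$p, "e0_1_ff", 2)
  lc$p <- set_scalar_weight(lc$p, "e1_2_ff", 1)
  tr <- init_states(lc$g, lc$p, matrix(1, 1, 1))
  tr$v[[2]][[1]][] <- 3
  tr$v[[3]][[1]][] <- 3        # equals its prediction, contributes 0
  bd <- hpc_energy(lc$g, lc$p, tr)
  expect_equal(bd$F_total, 1)

  # after forward-pass initialization every internal error is 0, so F = C
  blob <- make_blob_batch(6, 4, 2)
  g <- build_graph("toy_chain", depth = 3, width = 5, n_classes = 2,
                   input_shape = 4)
  p <- init_params(g, seed = 5)
  tr2 <- init_states(g, p, blob$x)
  bd2 <- hpc_energy(g, p, tr2, target = blob$y, loss_kind = "cross_entropy")
  expect_equal(bd2$E_internal, 0)
  expect_equal(bd2$F_total, bd2$C_f)
  expect_gt(bd2$C_f, 0)

  # seeded random states match a brute-force recomputation
  tr3 <- perturbed_traj(g, p, blob$x)
  bd3 <- hpc_energy(g, p, tr3, target = blob$y, loss_kind = "cross_entropy")
  expect_equal(bd3$F_total,
               chain_energy_oracle(g, p, tr3, blob$y, "hpc"),
               tolerance = 1e-10)
})

test_that("combined and additive energies differ exactly by cancellation", {
  # a node with eps_f = 0.5 and eps_b = -0.5: combined term 0, additive 0.5
  lc <- linear_chain(2, 1, n_classes = 1, input_shape = 1)
  # engineer states: v1 = vhat_f + 0.5 and v1 = vhat_b - 0.5
  p <- lc$p
  p <- set_scalar_weight(p, "e0_1_ff", 1)
  p <- set_scalar_weight(p, "e1_2_ff", 1)
  p <- set_scalar_weight(p, "e2_3_ff", 1)
  tr <- init_states(lc$g, p, matrix(1, 1, 1))
  # with all weights 1 and identity act: vhat_f(n1) = v0 = 1.
  # choose v1 = 1.5 so eps_f = +0.5; then pick v2 so that
  # vhat_b(n1) = 0.5 * v2 = 2, i.e. v2 = 4, giving eps_b = 1.5 - 2 = -0.5
  tr$v[[2]][[1]][] <- 1.5
  tr$v[[3]][[1]][] <- 4
  add <- bipc_energy(lc$g, p, tr, variant = "additive")
  com <- bipc_energy(lc$g, p, tr, variant = "combined")
  n1_add <- add$per_term[add$per_term$node == 1, ]
  expect_equal(sum(n1_add$value), 0.5)
  n1_com <- com$per_term[com$per_term$node == 1, ]
  expect_equal(sum(n1_com$value), 0)
})

test_that("bidirectional energies match the explicit-loop oracle", {
  blob <- make_blob_batch(5, 3, 2)
  for (setup in list(list(T_steps = 1, skip = FALSE),
                     list(T_steps = 1, skip = TRUE),
                     list(T_steps = 3, skip = TRUE))) {
    g <- build_graph("toy_chain", depth = 3, width = 3, n_classes = 2,
                     input_shape = 3, T_steps = setup$T_steps,
                     skip = setup$skip)
    p <- init_params(g, seed = 9)
    tr <- perturbed_traj(g, p, blob$x)
    for (m in c("hpc", "bipc_additive", "bipc_combined")) {
      got <- energy_of(g, p, tr, blob$y, m)
      expect_equal(got, chain_energy_oracle(g, p, tr, blob$y, m),
                   tolerance = 1e-8)
    }
  }
})

test_that("energy terms are non-negative and combined <= 2 x additive", {
  blob <- make_blob_batch(4, 3, 2)
  for (seed in 1:5) {
    g <- build_graph("toy_chain", depth = 3, width = 3, n_classes = 2,
                     input_shape = 3, T_steps = 2, skip = TRUE)
    p <- init_params(g, seed = seed)
    tr <- perturbed_traj(g, p, blob$x, sd = 0.5, seed = seed + 100)
    add <- bipc_energy(g, p, tr, y = blob$y, variant = "additive")
    com <- bipc_energy(g, p, tr, y = blob$y, variant = "combined")
    expect_true(all(add$per_term$value >= 0))
    expect_true(all(com$per_term$value >= 0))
    expect_lte(com$E_internal, 2 * add$E_internal + 1e-12)
    expect_gte(com$E_internal, 0)
  }
})

test_that("combined energy with feedback clamped to states reduces to hpc", {
  # when every feedback prediction equals the actual state, eps_b = 0 and the
  # combined residual collapses onto the feedforward error alone
  blob <- make_blob_batch(4, 3, 2)
  g <- build_graph("toy_chain", depth = 2, width = 3, n_classes = 2,
                   input_shape = 3)
  p <- init_params(g, seed = 2)
  tr <- perturbed_traj(g, p, blob$x)
  com0 <- bipc_energy(g, p, tr, y = blob$y, variant = "combined",
                      zero_feedback_errors = TRUE)
  hpc0 <- hpc_energy(g, p, tr, target = blob$y, loss_kind = "cross_entropy")
  expect_equal(com0$E_internal, hpc0$E_internal, tolerance = 1e-10)
  expect_equal(com0$F_total, hpc0$E_internal + com0$C_f + com0$C_b,
               tolerance = 1e-10)
})

test_that("hopfield energy matches its formula and a double-loop oracle", {
  hp <- hopfield_params(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(hopfield_energy(c(1, 1), hp), 0)      # 1 - 1 - 0
  expect_equal(hopfield_energy(c(1, 0), hp), 0.5)    # no interaction active
  expect_error(hopfield_params(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")

  set.seed(13)
  n <- 5
  w <- matrix(rnorm(n * n), n, n); w <- (w + t(w)) / 2; diag(w) <- 0
  b <- rnorm(n)
  hp2 <- hopfield_params(w, b, rho = "tanh")
  v <- rnorm(n)
  r <- tanh(v)
  ora <- 0.5 * sum(v^2)
  for (i in 1:n) {
    ora <- ora - b[i] * r[i]
    for (j in 1:n) if (i != j) ora <- ora - 0.5 * r[i] * w[i, j] * r[j]
  }
  expect_equal(hopfield_energy(v, hp2), ora, tolerance = 1e-12)

  # invariance under simultaneous permutation of units and weight rows/cols
  perm <- sample(n)
  hp3 <- hopfield_params(w[perm, perm], b[perm], rho = "tanh")
  expect_equal(hopfield_energy(v[perm], hp3), hopfield_energy(v, hp2),
               tolerance = 1e-12)
})

test_that("total energy and external losses follow their definitions", {
  expect_equal(total_energy(2, 3, 0), 2)
  expect_equal(total_energy(2, 3, 1), 5)
  expect_equal(total_energy(2, 3, 0.5), 3.5)
  expect_error(total_energy(1, 1, 1.5), "beta")

  expect_equal(external_loss(c(1, 2), c(1, 2), "mse"), 0)
  expect_equal(external_loss(c(1, 2), c(0, 0), "mse"), 2.5)
  expect_equal(external_loss(matrix(0, 1, 2), 0L, "cross_entropy"), log(2))
  expect_equal(external_loss(matrix(0, 1, 2), 1L, "cross_entropy"), log(2))
  expect_error(external_loss(matrix(0, 1, 2), 5L, "cross_entropy"), "labels")
})
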