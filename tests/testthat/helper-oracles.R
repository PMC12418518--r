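# Independent oracles: finite-difference gradients, explicit-loop energies,
# and a naive direct convolution, all written without the package's
# plan/prediction machinery so they can stand as cross-checks.

# -- pytree utilities for perturbing parameter stores ------------------------

th_flatten <- function(th) ebll:::th_unlist(th)

th_refill <- function(th, flat) {
  if (is.null(th)) return(list(NULL, flat))
  if (is.numeric(th)) {
    n <- length(th)
    v <- flat[seq_len(n)]
    attributes(v) <- attributes(th)
    return(list(v, flat[-seq_len(n)]))
  }
  out <- th
  for (j in seq_along(th)) {
    r <- th_refill(th[[j]], flat)
    out[j] <- list(r[[1]])
    flat <- r[[2]]
  }
  list(out, flat)
}

th_perturb <- function(th, i, delta) {
  flat <- th_flatten(th)
  flat[i] <- flat[i] + delta
  th_refill(th, flat)[[1]]
}

# -- scalar energy used by all finite-difference oracles ---------------------

energy_of <- function(graph, params, traj, y, method, beta = 1,
                      loss_f = "cross_entropy") {
  bd <- switch(method,
    hpc = hpc_energy(graph, params, traj, target = y, loss_kind = loss_f,
                     beta = beta),
    bipc_additive = bipc_energy(graph, params, traj, y = y,
                                variant = "additive", beta = beta,
                                loss_f = loss_f),
    bipc_combined = bipc_energy(graph, params, traj, y = y,
                                variant = "combined", beta = beta,
                                loss_f = loss_f))
  bd$F_total
}

# central finite differences over a (possibly subsampled) set of state
# coordinates; returns max relative error against the analytic gradient
fd_state_check <- function(graph, params, traj, y, method, beta = 1,
                           loss_f = "cross_entropy", h = 1e-5,
                           max_coords = Inf, seed = 1) {
  sg <- state_gradients(graph, params, traj, y = y, method = method,
                        beta = beta, loss_f = loss_f)
  plan <- ebll:::compile_plan(graph)
  set.seed(seed)
  worst <- 0
  for (rec in sg) {
    g <- rec$grad
    coords <- seq_along(g)
    if (length(coords) > max_coords) coords <- sort(sample(coords, max_coords))
    u <- which(vapply(plan$units, function(un)
      un$m == rec$m && un$slot == rec$slot, TRUE))
    s <- rec$t + 1L
    for (i in coords) {
      t1 <- traj; t2 <- traj
      if (t1$clamp[u, s]) next
      t1$v[[u]][[s]][i] <- t1$v[[u]][[s]][i] + h
      t2$v[[u]][[s]][i] <- t2$v[[u]][[s]][i] - h
      fd <- (energy_of(graph, params, t1, y, method, beta, loss_f) -
             energy_of(graph, params, t2, y, method, beta, loss_f)) / (2 * h)
      worst <- max(worst, abs(g[i] - fd) / max(abs(fd), 1e-6))
    }
  }
  worst
}

fd_param_check <- function(graph, params, traj, y, method, beta = 1,
                           loss_f = "cross_entropy", h = 1e-5,
                           max_coords = Inf, seed = 1) {
  pg <- param_gradients(graph, params, traj, y = y, method = method,
                        beta = beta, loss_f = loss_f)
  set.seed(seed)
  worst <- 0
  for (id in names(pg)) {
    g <- th_flatten(pg[[id]])
    coords <- seq_along(g)
    if (length(coords) > max_coords) coords <- sort(sample(coords, max_coords))
    for (i in coords) {
      p1 <- params; p2 <- params
      p1$tensors[[id]] <- th_perturb(params$tensors[[id]], i, h)
      p2$tensors[[id]] <- th_perturb(params$tensors[[id]], i, -h)
      fd <- (energy_of(graph, p1, traj, y, method, beta, loss_f) -
             energy_of(graph, p2, traj, y, method, beta, loss_f)) / (2 * h)
      worst <- max(worst, abs(g[i] - fd) / max(abs(fd), 1e-6))
    }
  }
  worst
}

# -- randomized trajectories (so prediction errors are nonzero) --------------

perturbed_traj <- function(graph, params, x, sd = 0.3, seed = 7) {
  traj <- init_states(graph, params, x)
  set.seed(seed)
  for (u in seq_along(traj$v)) for (s in seq_along(traj$v[[u]]))
    if (!traj$clamp[u, s])
      traj$v[[u]][[s]] <- traj$v[[u]][[s]] +
        matrix(rnorm(length(traj$v[[u]][[s]]), sd = sd),
               nrow(traj$v[[u]][[s]]))
  traj
}

# -- explicit-loop energy oracle for fully connected chains ------------------
# Recomputes the bidirectional energy of a toy_chain graph (static or
# temporal, with or without skip edges) directly from the weight matrices,
# looping over nodes and time steps.

chain_energy_oracle <- function(graph, params, traj, y, method,
                                beta = 1, loss_f = "cross_entropy") {
  D <- length(graph$nodes) - 2L            # hidden nodes
  S <- traj$S
  act <- function(m, x) {
    a <- graph$nodes[[m + 1L]]$act
    if (a == "tanh") tanh(x) else x
  }
  W <- function(id) params$tensors[[id]]$W
  bb <- function(id) params$tensors[[id]]$b
  has <- function(id) !is.null(params$tensors[[id]])
  v <- function(m, s) traj$v[[m + 1L]][[s]]
  lin <- function(x, id) sweep(x %*% W(id), 2, -bb(id))
  n_nodes <- D + 2L
  E <- 0; Cb <- 0
  for (m in 1:(n_nodes - 1L)) {
    for (s in seq_len(S)) {
      # feedforward prediction
      ef <- NULL
      if (S == 1L || s >= 2L) {
        sl <- if (S == 1L) s else s - 1L
        ss <- lin(v(m - 1L, sl), sprintf("e%d_%d_ff", m - 1L, m))
        if (m >= 2L && has(sprintf("e%d_%d_skip", m - 2L, m)))
          ss <- ss + lin(v(m - 2L, sl), sprintf("e%d_%d_skip", m - 2L, m))
        if (has(sprintf("e%d_%d_rec", m, m))) {
          ss <- ss + v(m, s - 1L)
          ss <- lin(ss, sprintf("e%d_%d_rec", m, m))
        }
        ef <- v(m, s) - act(m, ss)
      }
      # feedback prediction
      eb <- NULL
      if (method != "hpc" && (S == 1L || s <= S - 1L)) {
        sh <- if (S == 1L) s else s + 1L
        pb <- NULL
        if (m + 1L <= n_nodes - 1L)
          pb <- 0.5 * v(m + 1L, sh) %*% t(W(sprintf("e%d_%d_ff", m, m + 1L)))
        if (has(sprintf("e%d_%d_rec", m, m))) {
          rb <- 0.5 * v(m, sh) %*% t(W(sprintf("e%d_%d_rec", m, m)))
          pb <- if (is.null(pb)) rb else pb + rb
        }
        if (!is.null(pb)) eb <- v(m, s) - act(m, pb)
      }
      if (is.null(ef) && is.null(eb)) next
      if (method == "bipc_combined" && !is.null(ef) && !is.null(eb)) {
        E <- E + mean(rowSums((ef + eb)^2))
      } else {
        if (!is.null(ef)) E <- E + mean(rowSums(ef^2))
        if (!is.null(eb)) E <- E + mean(rowSums(eb^2))
      }
    }
  }
  if (method != "hpc") {
    for (s in seq_len(S)) {
      if (S > 1L && s > S - 1L) next
      sh <- if (S == 1L) s else s + 1L
      pb <- 0.5 * v(1L, sh) %*% t(W("e0_1_ff"))
      Cb <- Cb + mean((v(0L, s) - pb)^2)     # input node act is identity
    }
  }
  Cf <- if (!is.null(y)) external_loss(v(n_nodes - 1L, S), y, loss_f) else 0
  E + beta * (Cf + Cb)
}

# -- naive direct 2-D convolution (triple loop) ------------------------------

naive_conv <- function(x_arr, W, b) {
  d <- dim(x_arr); k <- dim(W)[1]; co <- dim(W)[4]; p <- (k - 1) / 2
  out <- array(0, c(d[1], d[2], d[3], co))
  for (n in seq_len(d[1])) for (i in seq_len(d[2])) for (j in seq_len(d[3]))
    for (o in seq_len(co)) {
      acc <- b[o]
      for (a in seq_len(k)) for (bb in seq_len(k)) for (ci in seq_len(d[4])) {
        ii <- i + a - 1 - p; jj <- j + bb - 1 - p
        if (ii >= 1 && ii <= d[2] && jj >= 1 && jj <= d[3])
          acc <- acc + x_arr[n, ii, jj, ci] * W[a, bb, ci, o]
      }
      out[n, i, j, o] <- acc
    }
  out
}

make_blob_batch <- function(n = 8, d = 4, K = 2, seed = 3) {
  set.seed(seed)
  list(x = matrix(rnorm(n * d), n, d), y = sample(0:(K - 1), n, TRUE))
}

zero_bias <- function(th) {
  if (is.null(th)) return(NULL)
  if (!is.null(th$W)) { th$b <- 0 * th$b; return(th) }
  lapply(th, zero_bias)
}

fn_has_maxpool <- function(fn) {
  if (fn$type == "maxpool") return(TRUE)
  if (fn$type == "seq") return(any(vapply(fn$stages, fn_has_maxpool, TRUE)))
  FALSE
}
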