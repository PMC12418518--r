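# Equilibrium propagation over the Hopfield energy: a free phase relaxes the
# states under the internal energy alone (beta = 0); a nudged phase adds the
# external loss (beta > 0) and relaxes again from the free equilibrium; the
# weight update is the scaled difference of the internal-energy gradients at
# the two equilibria.

ep_relax <- function(v, hp, x = NULL, y = NULL, beta = 0, cfg = inference_config()) {
  B <- nrow(v)
  n_out <- length(hp$output_units)
  F_hist <- numeric(0); converged <- FALSE; it <- 0L
  repeat {
    E <- hopfield_energy(v, hp)
    C <- if (beta > 0 && !is.null(y))
      external_loss(v[, hp$output_units, drop = FALSE], y, "mse") else 0
    F_hist <- c(F_hist, E + beta * C)
    k <- length(F_hist)
    if (!is.finite(F_hist[k])) break
    if (k > 1L && abs(F_hist[k] - F_hist[k - 1L]) < cfg$threshold) {
      converged <- TRUE; break
    }
    if (it >= cfg$N) break
    it <- it + 1L
    g <- B * hopfield_state_grad(v, hp)      # per-sample energy gradient
    if (beta > 0 && !is.null(y)) {
      gc_ <- 2 * (v[, hp$output_units, drop = FALSE] - y) / n_out
      g[, hp$output_units] <- g[, hp$output_units] + beta * gc_
    }
    if (!is.null(hp$input_units)) g[, hp$input_units] <- 0
    v <- v - cfg$eta_v * g
  }
  list(v = v, F_history = F_hist, converged = converged, iterations_used = it)
}

#' Two-phase equilibrium-propagation update
#'
#' Phase 1 relaxes the unit states to a free equilibrium of the Hopfield
#' energy alone; phase 2 adds the external loss scaled by `beta` and relaxes
#' again starting from the free equilibrium.  The contrastive parameter
#' gradient is `(1/beta) * (dE/dtheta at the nudged equilibrium - dE/dtheta
#' at the free equilibrium)`, which for small `beta` approximates the
#' gradient of the external loss at the free fixed point.
#'
#' @param hp A [hopfield_params()] with `input_units` and `output_units` set.
#' @param x Input batch clamped onto `hp$input_units` (matrix or vector).
#' @param y Target for the mean-squared external loss on `hp$output_units`.
#' @param beta Nudging strength (> 0).
#' @param cfg An [inference_config()] controlling both relaxations.
#' @return An `ep_phase_result`: `free_states`, `nudged_states`,
#'   `contrastive_grads` (list `w`, `b`), per-phase traces and convergence
#'   flags.
#' @export
ep_two_phase <- function(hp, x, y, beta = 0.1, cfg = inference_config()) {
  stopifnot(beta > 0)
  x <- as_batch_matrix(x); y <- as_batch_matrix(y)
  n <- nrow(hp$w)
  v0 <- matrix(0, nrow(x), n)
  v0[, hp$input_units] <- x
  free <- ep_relax(v0, hp, beta = 0, cfg = cfg)
  nudged <- ep_relax(free$v, hp, y = y, beta = beta, cfg = cfg)
  g_free <- hopfield_param_grad(free$v, hp)
  g_nudged <- hopfield_param_grad(nudged$v, hp)
  structure(list(
    free_states = free$v, nudged_states = nudged$v,
    contrastive_grads = list(w = (g_nudged$w - g_free$w) / beta,
                             b = (g_nudged$b - g_free$b) / beta),
    free_converged = free$converged, nudged_converged = nudged$converged,
    free_trace = free$F_history, nudged_trace = nudged$F_history),
    class = "ep_phase_result")
}

#' @export
print.ep_phase_result <- function(x, ...) {
  cat(sprintf("<ep_phase_result> free: %d F-evals (converged %s); nudged: %d (converged %s)\n",
              length(x$free_trace), x$free_converged,
              length(x$nudged_trace), x$nudged_converged))
  invisible(x)
}

# ---- EP on layered (chain) architectures -----------------------------------

#' Build a layered Hopfield network matching a chain of widths
#'
#' Units are the concatenation of all layer states; symmetric weights are
#' nonzero only between consecutive layers (the Hopfield analogue of a fully
#' connected chain).  The first layer is clamped to the input, the last one
#' is read out by the external loss.
#'
#' @param sizes Integer vector of layer widths (input, hidden..., output).
#' @param seed Integer seed for the fan-in-scaled block initialization.
#' @param rho Pointwise activation.
#' @param weight_scale Multiplier on the 1/sqrt(fan_in) block sd.
#' @return List with `hp` (a [hopfield_params()]), `blocks` (the per-layer
#'   weight blocks as a named parameter list) and `layer_index` (unit ranges).
#' @export
hopfield_chain <- function(sizes, seed = 0L, rho = "tanh", weight_scale = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  L <- length(sizes)
  offs <- cumsum(c(0L, sizes))
  idx <- lapply(seq_len(L), function(l) offs[l] + seq_len(sizes[l]))
  blocks <- list()
  for (l in seq_len(L - 1L))
    blocks[[sprintf("w%d_%d", l - 1L, l)]] <-
      matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                          sd = weight_scale / sqrt(sizes[l])),
             sizes[l], sizes[l + 1L])
  hp <- hopfield_assemble(blocks, sizes, idx, rho)
  list(hp = hp, blocks = blocks, layer_index = idx, sizes = sizes)
}

hopfield_assemble <- function(blocks, sizes, idx, rho) {
  n <- sum(sizes)
  w <- matrix(0, n, n)
  L <- length(sizes)
  for (l in seq_len(L - 1L)) {
    B <- blocks[[sprintf("w%d_%d", l - 1L, l)]]
    w[idx[[l]], idx[[l + 1L]]] <- B
    w[idx[[l + 1L]], idx[[l]]] <- t(B)
  }
  hopfield_params(w, rho = rho, input_units = idx[[1]], output_units = idx[[L]])
}

ep_block_grads <- function(res, net) {
  g <- list()
  L <- length(net$sizes)
  for (l in seq_len(L - 1L)) {
    id <- sprintf("w%d_%d", l - 1L, l)
    g[[id]] <- res$contrastive_grads$w[net$layer_index[[l]],
                                       net$layer_index[[l + 1L]], drop = FALSE]
  }
  g
}

one_hot <- function(y, K) {
  oh <- matrix(0, length(y), K)
  oh[cbind(seq_along(y), as.integer(y) + 1L)] <- 1
  oh
}

# free-phase readout: relax under the internal energy with the input clamped
# and read the output units
ep_predict <- function(net, x, cfg) {
  x <- as_batch_matrix(x)
  v0 <- matrix(0, nrow(x), nrow(net$hp$w))
  v0[, net$hp$input_units] <- x
  free <- ep_relax(v0, net$hp, cfg = cfg)
  free$v[, net$hp$output_units, drop = FALSE]
}

# Equilibrium-propagation training loop over the layered Hopfield net.
# Returns the pieces ebll_train() wraps into an ebll_fit.
ep_train_loop <- function(net, data, config, icfg) {
  K <- net$sizes[length(net$sizes)]
  n <- nrow(data$train$x)
  opt_state <- NULL
  metrics <- list(); gnorm_rows <- list()
  beta <- max(config$beta, 1e-3)
  store <- list(tensors = net$blocks)   # optimizer operates on the blocks
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(n)
    ep_loss <- 0; nb <- 0L; gn_acc <- NULL
    for (b0 in seq(1L, n, by = config$batch_size)) {
      i <- ord[b0:min(b0 + config$batch_size - 1L, n)]
      xb <- data$train$x[i, , drop = FALSE]
      yb <- one_hot(data$train$y[i], K)
      res <- ep_two_phase(net$hp, xb, yb, beta = beta, cfg = icfg)
      grads <- ep_block_grads(res, net)
      ep_loss <- ep_loss +
        external_loss(res$nudged_states[, net$hp$output_units, drop = FALSE], yb, "mse")
      gn <- vapply(grads, th_l2, 0)
      gn_acc <- if (is.null(gn_acc)) gn else gn_acc + gn
      upd <- apply_update(store, grads, opt_state, rule = config$optimizer,
                          eta = config$eta_theta)
      store <- upd$params; opt_state <- upd$state
      net$blocks <- store$tensors
      net$hp <- hopfield_assemble(net$blocks, net$sizes, net$layer_index, net$hp$rho)
      nb <- nb + 1L
    }
    out <- ep_predict(net, data$test$x, icfg)
    acc <- accuracy_of(out, data$test$y)
    metrics[[epoch]] <- data.frame(
      epoch = epoch, loss = ep_loss / nb, accuracy = acc, mean_F = NA_real_,
      mean_inference_iters = NA_real_, n_batches = nb, n_diverged = 0L)
    for (id in names(gn_acc))
      gnorm_rows[[length(gnorm_rows) + 1L]] <-
        data.frame(epoch = epoch, params_id = id, grad_norm = gn_acc[[id]] / nb)
  }
  list(net = net, metrics = metrics, gnorm_rows = gnorm_rows)
}
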