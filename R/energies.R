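# Energy functions: prediction-error energies (hierarchical and bidirectional
# predictive coding), Hopfield energy, and the unified internal/external
# decomposition F = E + beta * C.
#
# Conventions: energy terms are sums over features and nodes/time steps and
# means over the batch dimension, so state and parameter step sizes do not
# depend on the batch size.

#' External (supervised) loss
#'
#' @param output_state Output-node state, matrix (batch x units) or vector.
#' @param target For `"cross_entropy"`: integer class labels, 0-based.
#'   For `"mse"`: a numeric target with the shape of `output_state`.
#' @param kind `"cross_entropy"` (softmax + negative log-likelihood, averaged
#'   over the batch) or `"mse"` (mean squared difference).
#' @return Scalar loss.
#' @export
external_loss <- function(output_state, target, kind = c("cross_entropy", "mse")) {
  kind <- match.arg(kind)
  v <- as_batch_matrix(output_state)
  if (kind == "mse") {
    tg <- as_batch_matrix(target)
    return(mean((v - tg)^2))
  }
  lab <- as.integer(target)
  if (any(lab < 0L) || any(lab >= ncol(v)))
    stop("class labels must lie in [0, n_classes)")
  lse <- log(rowSums(exp(v - apply(v, 1, max)))) + apply(v, 1, max)
  mean(lse - v[cbind(seq_len(nrow(v)), lab + 1L)])
}

loss_grad <- function(output_state, target, kind) {
  v <- output_state
  B <- nrow(v)
  if (kind == "mse") return(2 * (v - as_batch_matrix(target)) / (B * ncol(v)))
  p <- exp(v - apply(v, 1, max))
  p <- p / rowSums(p)
  oh <- matrix(0, B, ncol(v))
  oh[cbind(seq_len(B), as.integer(target) + 1L)] <- 1
  (p - oh) / B
}

#' Total energy from its internal and external parts
#'
#' `F = E + beta * C`: at `beta = 0` the external loss has no influence (the
#' free phase of equilibrium propagation); at `beta = 1` internal and external
#' energy are weighted equally.
#'
#' @param E_internal Internal energy (prediction errors or Hopfield terms).
#' @param C_external External (supervised) loss.
#' @param beta Scaling factor in `[0, 1]`.
#' @return Scalar total energy.
#' @export
total_energy <- function(E_internal, C_external, beta) {
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]")
  E_internal + beta * C_external
}

new_energy_breakdown <- function(per_term, E, Cf, Cb, beta, method) {
  structure(list(per_term = per_term, E_internal = E, C_f = Cf, C_b = Cb,
                 beta = beta, F_total = total_energy(E, Cf + Cb, beta),
                 method = method),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("<energy_breakdown> %s: F = %.6g (E = %.6g, Cf = %.6g, Cb = %.6g, beta = %g)\n",
              x$method, x$F_total, x$E_internal, x$C_f, x$C_b, x$beta))
  invisible(x)
}

#' Export an energy breakdown as a CSV-ready data frame
#' @param breakdown An `energy_breakdown`.
#' @param path Optional CSV file to write.
#' @return Data frame with columns node, slot, time, term, value.
#' @export
energy_to_csv <- function(breakdown, path = NULL) {
  df <- breakdown$per_term
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

# residual bookkeeping shared by the energy and gradient code.  For each unit
# and slice with at least one defined prediction this returns the residuals
# and the energy term under the requested variant:
#   additive:   (eps_f)^2 + (eps_b)^2          -- two squared terms
#   combined:   (eps_f + eps_b)^2              -- one squared summed residual
# where only one prediction exists, that residual is used alone under both.
residual_terms <- function(v, f, b, combined, zero_fb = FALSE) {
  ef <- if (!is.null(f)) v - f$vhat
  eb <- if (!is.null(b)) { if (zero_fb) 0 * v else v - b$vhat }
  if (combined && !is.null(ef) && !is.null(eb)) {
    r <- ef + eb
    list(terms = list(list(type = "combined", r = r)),
         value = mean(rowSums(r * r)))
  } else {
    terms <- list()
    val <- 0
    if (!is.null(ef)) { terms <- c(terms, list(list(type = "ff", r = ef))); val <- val + mean(rowSums(ef * ef)) }
    if (!is.null(eb)) { terms <- c(terms, list(list(type = "fb", r = eb))); val <- val + mean(rowSums(eb * eb)) }
    list(terms = terms, value = val)
  }
}

# Core prediction-error energy over a graph.  method selects the variant:
# "hpc" uses only feedforward errors; "bipc_additive" and "bipc_combined" add
# weight-tied feedback errors, squared separately or inside one square.
pc_energy <- function(graph, params, traj, y = NULL, method = "bipc_combined",
                      beta = 1, loss_f = "cross_entropy", renorm = FALSE,
                      plan = NULL, preds = NULL, zero_feedback_errors = FALSE) {
  if (is.null(plan)) plan <- compile_plan(graph)
  feedback <- method != "hpc"
  if (is.null(preds))
    preds <- compute_predictions(plan, graph, params, traj, feedback = feedback,
                                 renorm = renorm, with_cache = FALSE)
  combined <- method == "bipc_combined"
  rows <- list(); E <- 0; Cb <- 0
  for (u in seq_along(plan$units)) {
    unit <- plan$units[[u]]
    for (s in seq_len(plan$S)) {
      f <- if (!is.null(preds$fwd[[u]])) preds$fwd[[u]][[s]]
      b <- if (!is.null(preds$bwd[[u]])) preds$bwd[[u]][[s]]
      if (is.null(f) && is.null(b)) next
      if (unit$m == 0L) {
        # the input node is clamped: its feedback reconstruction error is the
        # external feedback loss Cb, not part of the internal energy
        if (!is.null(b)) Cb <- Cb + mean((traj$v[[u]][[s]] - b$vhat)^2)
        next
      }
      rt <- residual_terms(traj$v[[u]][[s]], f, b, combined,
                           zero_fb = zero_feedback_errors)
      E <- E + rt$value
      for (tm in rt$terms)
        rows[[length(rows) + 1L]] <- data.frame(
          node = unit$m, slot = unit$slot, time = slice_to_t(s),
          term = tm$type, value = mean(rowSums(tm$r * tm$r)))
    }
  }
  Cf <- if (!is.null(y)) {
    external_loss(traj$v[[plan$output_uid]][[plan$S]], y, loss_f)
  } else 0
  per_term <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node = integer(0), slot = integer(0), time = integer(0),
               term = character(0), value = numeric(0))
  new_energy_breakdown(per_term, E, Cf, if (feedback) Cb else 0, beta, method)
}

#' Hierarchical predictive-coding energy
#'
#' The classical supervised formulation: squared feedforward prediction
#' errors summed over all non-input nodes, plus the external loss on the
#' free output state, `F = sum_i eps_i^2 + beta * C`.
#'
#' @param graph An `ebll_graph`.
#' @param params A `param_store`.
#' @param traj A `state_trajectory`.
#' @param target Supervised target (labels for cross-entropy, numeric for
#'   mse); `NULL` for no external loss.
#' @param loss_kind `"mse"` (the classical choice) or `"cross_entropy"`.
#' @param beta External-energy scale in `[0, 1]`.
#' @return An `energy_breakdown`.
#' @export
hpc_energy <- function(graph, params, traj, target = NULL,
                       loss_kind = "mse", beta = 1) {
  pc_energy(graph, params, traj, y = target, method = "hpc", beta = beta,
            loss_f = loss_kind)
}

#' Bidirectional predictive-coding energy
#'
#' Adds weight-tied feedback prediction errors to the feedforward ones.  The
#' `additive` variant squares both error directions separately,
#' `F = sum (eps_f)^2 + (eps_b)^2 + Cf + Cb`; the `combined` variant sums the
#' two residuals inside one square, `F = sum (eps_f + eps_b)^2 + Cf + Cb`, so
#' errors of opposite sign cancel -- the mechanism that stabilizes inference
#' gradients in deep networks.  `Cf` is the supervised loss at the output
#' (cross-entropy by default), `Cb` the mean-squared reconstruction error of
#' the feedback pathway at the clamped input.
#'
#' @inheritParams hpc_energy
#' @param x Unused: the input reconstruction target is the clamped input
#'   state already held by `traj` (argument kept for call-signature symmetry).
#' @param y Supervised target.
#' @param variant `"combined"` (default) or `"additive"`.
#' @param loss_f Output loss kind.
#' @param renorm Renormalize 1/2 feedback-branch weights at boundary nodes.
#' @param zero_feedback_errors Clamp every feedback prediction to the actual
#'   state (so `eps_b = 0`); the combined energy then reduces to the
#'   hierarchical internal terms plus `Cf + Cb`.
#' @return An `energy_breakdown`.
#' @export
bipc_energy <- function(graph, params, traj, x = NULL, y = NULL,
                        variant = c("combined", "additive"),
                        beta = 1, loss_f = "cross_entropy", renorm = FALSE,
                        zero_feedback_errors = FALSE) {
  variant <- match.arg(variant)
  pc_energy(graph, params, traj, y = y,
            method = paste0("bipc_", variant), beta = beta,
            loss_f = loss_f, renorm = renorm,
            zero_feedback_errors = zero_feedback_errors)
}

# ---- Hopfield energy -------------------------------------------------------

#' Hopfield network parameters
#'
#' @param w Symmetric weight matrix with zero diagonal.
#' @param b Bias vector.
#' @param rho Pointwise activation: `"identity"` or `"tanh"`.
#' @param input_units,output_units Indices (1-based) of the clamped input
#'   units and of the units read out by the external loss, used by
#'   [ep_two_phase()].
#' @return A `hopfield_params` list.
#' @export
hopfield_params <- function(w, b = numeric(nrow(w)), rho = c("identity", "tanh"),
                            input_units = NULL, output_units = NULL) {
  rho <- match.arg(rho)
  w <- as.matrix(w)
  if (!isTRUE(all.equal(w, t(w), tolerance = 1e-12)))
    stop("Hopfield weights must be symmetric")
  diag(w) <- 0
  structure(list(w = w, b = as.numeric(b), rho = rho,
                 input_units = input_units, output_units = output_units),
            class = "hopfield_params")
}

rho_apply <- function(x, rho) if (rho == "tanh") tanh(x) else x
rho_deriv <- function(x, rho) if (rho == "tanh") 1 - tanh(x)^2 else 1

#' Hopfield energy of a state
#'
#' `E = 1/2 sum_i ||v_i||^2 - 1/2 sum_{i != j} rho(v_i) w_ij rho(v_j)
#'  - sum_i b_i rho(v_i)`, averaged over the batch when `v` is a matrix.
#'
#' @param v State vector (length n) or matrix (batch x n).
#' @param hp A `hopfield_params`.
#' @return Scalar energy.
#' @export
hopfield_energy <- function(v, hp) {
  v <- as_batch_matrix(v)
  if (ncol(v) != nrow(hp$w)) stop("state length does not match the weight matrix")
  r <- rho_apply(v, hp$rho)
  mean(0.5 * rowSums(v * v) - 0.5 * rowSums((r %*% hp$w) * r) - r %*% hp$b)
}

# gradient of the (batch-mean) Hopfield energy
hopfield_state_grad <- function(v, hp) {
  r <- rho_apply(v, hp$rho)
  (v - rho_deriv(v, hp$rho) * (r %*% hp$w + matrix(hp$b, nrow(v), ncol(v), byrow = TRUE))) / nrow(v)
}

hopfield_param_grad <- function(v, hp) {
  r <- rho_apply(v, hp$rho)
  gW <- -crossprod(r) / nrow(v)
  diag(gW) <- 0
  list(w = gW, b = -colMeans(r))
}
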