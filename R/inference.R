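# The inference phase: gradient descent on the energy over unclamped states
# until the energy change falls below a convergence threshold.

#' Inference-phase configuration
#'
#' Defaults follow the reference hyperparameter table: step size 0.01, at
#' most 200 iterations, energy-change threshold 1e-7, beta = 1.
#'
#' @param eta_v State step size (per sample; > 0).
#' @param N Maximum number of inference iterations.
#' @param threshold Energy-change convergence tolerance (> 0).
#' @param beta External-energy scale in `[0, 1]`.
#' @param divergence_factor Abort the loop (with a gradient-explosion report)
#'   if the energy exceeds this multiple of its starting value.
#' @param relative Use `|dF| / max(|F|, 1)` instead of the absolute energy
#'   change as the convergence criterion.
#' @param renorm Feedback 1/2-weight renormalization flag.
#' @return An `inference_config` list.
#' @export
inference_config <- function(eta_v = 0.01, N = 200L, threshold = 1e-7,
                             beta = 1, divergence_factor = 1e6,
                             relative = FALSE, renorm = FALSE) {
  stopifnot(eta_v > 0, N >= 1, threshold > 0, beta >= 0, beta <= 1)
  structure(list(eta_v = eta_v, N = as.integer(N), threshold = threshold,
                 beta = beta, divergence_factor = divergence_factor,
                 relative = relative, renorm = renorm),
            class = "inference_config")
}

#' Run the inference phase on a state trajectory
#'
#' Iterates `v <- v - eta_v * dF/dv` over all unclamped unit states
#' simultaneously until the change in total energy falls below
#' `cfg$threshold` or `cfg$N` iterations are reached.  `eta_v` is defined per
#' sample: state updates descend each sample's own energy, so the dynamics do
#' not depend on the batch size.  If the energy grows beyond
#' `cfg$divergence_factor` times its starting value (or becomes non-finite)
#' the run aborts with a gradient-explosion flag instead of producing NaNs.
#'
#' @param graph An `ebll_graph`.
#' @param params A `param_store`.
#' @param traj A `state_trajectory` (typically from [init_states()]).
#' @param y Supervised target, or `NULL`.
#' @param method Energy variant: `"hpc"`, `"bipc_additive"`, `"bipc_combined"`.
#' @param cfg An [inference_config()].
#' @param loss_f Output loss kind.
#' @return List with `traj` (the equilibrium states) and `trace`, an
#'   `inference_trace` holding `F_history`, per-node gradient-norm histories,
#'   `converged`, `diverged` and `iterations_used`.
#' @export
run_inference <- function(graph, params, traj, y = NULL,
                          method = "bipc_combined",
                          cfg = inference_config(), loss_f = "cross_entropy") {
  B <- traj$batch_size
  F_hist <- numeric(0)
  gn <- list()
  converged <- FALSE; diverged <- FALSE; it <- 0L
  plan <- NULL
  repeat {
    res <- energy_gradients(graph, params, traj, y, method, cfg$beta,
                            loss_f, cfg$renorm, wrt = "states")
    plan <- res$plan
    F_hist <- c(F_hist, res$F)
    gn[[length(gn) + 1L]] <- vapply(seq_along(plan$units), function(u)
      sqrt(sum(vapply(res$dv[[u]], function(g) sum(g * g), 0))), 0)
    k <- length(F_hist)
    if (!is.finite(res$F) ||
        (k > 1L && res$F > cfg$divergence_factor * max(abs(F_hist[1]), .Machine$double.xmin))) {
      diverged <- TRUE
      break
    }
    if (k > 1L) {
      dF <- abs(F_hist[k] - F_hist[k - 1L])
      if (cfg$relative) dF <- dF / max(abs(F_hist[k]), 1)
      if (dF < cfg$threshold) { converged <- TRUE; break }
    }
    if (it >= cfg$N) break
    it <- it + 1L
    for (u in seq_along(plan$units))
      for (s in seq_len(plan$S))
        if (!traj$clamp[u, s])
          traj$v[[u]][[s]] <- traj$v[[u]][[s]] - cfg$eta_v * B * res$dv[[u]][[s]]
  }
  gn_mat <- do.call(rbind, gn)
  colnames(gn_mat) <- vapply(plan$units, function(u) u$label, "")
  trace <- structure(
    list(F_history = F_hist, grad_norm_history = gn_mat,
         converged = converged, diverged = diverged, iterations_used = it),
    class = "inference_trace")
  list(traj = traj, trace = trace)
}

#' @export
print.inference_trace <- function(x, ...) {
  cat(sprintf("<inference_trace> %d iterations, F %.6g -> %.6g, converged: %s%s\n",
              x$iterations_used, x$F_history[1],
              x$F_history[length(x$F_history)], x$converged,
              if (x$diverged) " [DIVERGED: gradient explosion]" else ""))
  invisible(x)
}
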