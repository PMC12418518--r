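# Gradient-explosion / vanishing diagnostics: per-node state-gradient norm
# traces recorded along the inference loop, on chains with inflated weight
# scales where the instability of the purely feedforward energies shows.

#' Probe per-node state-gradient norms along the inference loop
#'
#' Builds a fully connected chain (optionally with two-level skip edges),
#' initializes its weights at `weight_scale` times the fan-in normalization,
#' runs `n_iter` inference iterations on a random batch for each seed, and
#' records the l2 norm of every node's state gradient at every iteration.
#' Gradient explosion appears as deep-node norms growing by orders of
#' magnitude; vanishing as shallow-node norms collapsing towards zero.
#'
#' @param method Energy variant to probe.
#' @param depth Number of hidden nodes (depth 6 gives an 8-node chain).
#' @param width Hidden width.
#' @param weight_scale Multiplier above the 1/sqrt(fan_in) weight sd.
#' @param skip Include skip connections.
#' @param n_iter Inference iterations to run (no early stopping).
#' @param seeds Integer vector of seeds (one probe run per seed).
#' @param eta_v State step size for the probe (see the methods vignette for
#'   how this is matched to the curvature regime of full-scale networks).
#' @param batch_size,n_classes Probe batch geometry.
#' @param csv Optional path to write the trace as CSV.
#' @return Data frame with columns `method`, `skip`, `seed`, `iter`, `node`,
#'   `grad_norm`.
#' @export
probe_gradient_norms <- function(method = c("hpc", "bipc_additive", "bipc_combined"),
                                 depth = 6L, width = 16L, weight_scale = 1.3,
                                 skip = TRUE, recurrent_T = 1L, n_iter = 50L,
                                 seeds = 0:4, eta_v = 0.1, batch_size = 16L,
                                 n_classes = 2L, csv = NULL) {
  method <- match.arg(method)
  rows <- list()
  for (seed in seeds) {
    graph <- build_graph("toy_chain", depth = depth, width = width,
                         T_steps = recurrent_T, skip = skip,
                         n_classes = n_classes, input_shape = width)
    params <- init_params(graph, seed = seed, weight_scale = weight_scale)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(seed + 1000L)
    x <- matrix(stats::rnorm(batch_size * width), batch_size, width)
    y <- sample(0:(n_classes - 1L), batch_size, replace = TRUE)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    traj <- init_states(graph, params, x)
    cfg <- inference_config(eta_v = eta_v, N = n_iter, threshold = 1e-300,
                            divergence_factor = Inf)
    inf <- run_inference(graph, params, traj, y = y, method = method, cfg = cfg)
    gh <- inf$trace$grad_norm_history
    for (it in seq_len(nrow(gh)))
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, skip = skip, seed = seed, iter = it - 1L,
        node = seq_len(ncol(gh)) - 1L, grad_norm = gh[it, ])
  }
  df <- do.call(rbind, rows)
  if (!is.null(csv)) utils::write.csv(df, csv, row.names = FALSE)
  df
}

#' Summarize a gradient-norm probe into growth ratios
#'
#' For each seed, the ratio of a node's gradient norm at the final recorded
#' iteration to its first nonzero value -- the quantity used to call an
#' explosion (ratio much greater than 1) or stability (ratio near 1).
#'
#' @param probe Output of [probe_gradient_norms()].
#' @param node 0-based node id to summarize.
#' @return Data frame with one growth ratio per seed.
#' @export
probe_growth_ratio <- function(probe, node) {
  out <- list()
  for (sd in unique(probe$seed)) {
    tr <- probe[probe$seed == sd & probe$node == node, ]
    tr <- tr[order(tr$iter), ]
    nz <- which(tr$grad_norm > 0)
    if (length(nz) == 0L) { ratio <- NA_real_ } else {
      first <- tr$grad_norm[nz[1]]
      last <- tr$grad_norm[nrow(tr)]
      ratio <- last / first
    }
    out[[length(out) + 1L]] <- data.frame(seed = sd, node = node, ratio = ratio)
  }
  do.call(rbind, out)
}
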