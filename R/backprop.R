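# Backpropagation baseline: trains the same node/edge graph end-to-end by
# direct differentiation of the output loss through the forward sweep (BPTT
# on temporal graphs).  Used as the reference the local energy-based rules
# are compared against.

#' Backpropagation gradients of the output loss through a graph
#'
#' Runs the forward initialization sweep (input clamped, every unit set to
#' its feedforward prediction) and backpropagates the loss at the output
#' node's final-slice state through activations, recurrent wraps and all
#' feedforward/skip/self branches, unrolled over time slices on temporal
#' graphs.
#'
#' @param graph An `ebll_graph`.
#' @param params A `param_store`.
#' @param x Input batch.
#' @param y Supervised target.
#' @param loss Output loss kind.
#' @return List with `loss` (scalar), `output` (output-state matrix) and
#'   `dth` (named list of parameter gradients).
#' @export
backprop_gradients <- function(graph, params, x, y, loss = "cross_entropy") {
  plan <- compile_plan(graph)
  x <- as_batch_matrix(x)
  traj <- new_trajectory(plan, nrow(x))
  for (s in seq_len(plan$S)) traj$v[[plan$input_uid]][[s]] <- x
  traj$clamp[plan$input_uid, ] <- TRUE
  caches <- vector("list", length(plan$units))
  for (u in seq_along(plan$units)) caches[[u]] <- vector("list", plan$S)
  for (s in seq_len(plan$S)) {
    for (u in seq_along(plan$units)) {
      f <- plan$fwd[[u]]
      if (is.null(f) || s < f$smin) next
      p <- fwd_prediction(plan, graph, params, traj, u, s, with_cache = TRUE)
      traj$v[[u]][[s]] <- p$vhat
      caches[[u]][[s]] <- p
    }
  }
  vout <- traj$v[[plan$output_uid]][[plan$S]]
  loss_val <- external_loss(vout, y, loss)
  dv <- lapply(plan$units, function(u)
    lapply(seq_len(plan$S), function(s) matrix(0, nrow(x), prod(u$shape))))
  dth <- lapply(params$tensors, th_zero)
  dv[[plan$output_uid]][[plan$S]] <- loss_grad(vout, y, loss)
  for (s in rev(seq_len(plan$S))) {
    for (u in rev(seq_along(plan$units))) {
      p <- caches[[u]][[s]]
      if (is.null(p)) next
      U <- dv[[u]][[s]]
      if (all(U == 0)) next
      fplan <- plan$fwd[[u]]
      u1 <- U * act_deriv_from_pre(p$pre, plan$units[[u]]$act)
      if (fplan$wrap > 0L) {
        e <- graph$edges[[fplan$wrap]]
        r <- fn_vjp(e$fn, edge_theta(e, params), p$wrap_cache, u1, e$src_shape)
        if (!is.na(e$params_id)) dth[[e$params_id]] <- th_add(dth[[e$params_id]], r$dth)
        u2 <- r$dx
      } else u2 <- u1
      for (i in seq_along(fplan$branches)) {
        br <- fplan$branches[[i]]
        e <- graph$edges[[br$eidx]]
        r <- fn_vjp(e$fn, edge_theta(e, params), p$caches[[i]], u2, e$src_shape)
        dv[[br$src_uid]][[s - br$dt]] <- dv[[br$src_uid]][[s - br$dt]] + r$dx
        if (!is.na(e$params_id)) dth[[e$params_id]] <- th_add(dth[[e$params_id]], r$dth)
      }
      if (fplan$self) dv[[u]][[s - 1L]] <- dv[[u]][[s - 1L]] + u2
    }
  }
  list(loss = loss_val, output = vout, dth = dth)
}
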