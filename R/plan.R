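# The prediction plan: graphs are compiled into "units" -- one per (node,
# internal-state slot) pair -- with explicit branch lists for the feedforward
# and feedback predictions of every unit.  Static graphs (T = 1) use a single
# time slice and same-slice sources; temporal graphs use T+1 slices with
# feedforward branches reading slice t-1 and feedback branches slice t+1.

unit_label <- function(m, slot) if (slot == 1L) sprintf("n%d", m) else sprintf("n%d.%d", m, slot)

compile_plan <- function(graph) {
  n <- length(graph$nodes)
  S <- if (graph$T <= 1L) 1L else graph$T + 1L
  units <- list(); uidx <- matrix(NA_integer_, n, 2L)
  for (m in 0:(n - 1L)) {
    nd <- graph$nodes[[m + 1L]]
    for (slot in seq_len(nd$n_states)) {
      units[[length(units) + 1L]] <-
        list(uid = length(units) + 1L, m = m, slot = slot,
             shape = node_slot_shape(graph, m, slot),
             act = nd$act, role = nd$role,
             label = unit_label(m, slot))
      uidx[m + 1L, slot] <- length(units)
    }
  }
  fwd <- vector("list", length(units))
  bwd <- vector("list", length(units))
  for (i in seq_along(graph$edges)) {
    e <- graph$edges[[i]]
    if (e$kind %in% c("feedforward", "skip")) {
      u <- uidx[e$dst + 1L, e$state_dst]
      src <- uidx[e$src + 1L, e$state_src]
      fwd[[u]]$branches <- c(fwd[[u]]$branches,
                             list(list(eidx = i, src_uid = src, dt = if (S > 1L) 1L else 0L)))
    } else if (e$kind == "recurrent") {
      if (e$state_src == e$state_dst) {
        # temporal self-edge: wraps the branch sum and contributes the raw
        # previous state as the self-excitation term
        u <- uidx[e$dst + 1L, e$state_dst]
        fwd[[u]]$wrap <- i
        fwd[[u]]$self <- TRUE
      } else {
        # internal state mapping (complex variant): same-slice branch
        u <- uidx[e$dst + 1L, e$state_dst]
        src <- uidx[e$src + 1L, e$state_src]
        fwd[[u]]$branches <- c(fwd[[u]]$branches,
                               list(list(eidx = i, src_uid = src, dt = 0L)))
      }
    } else if (e$kind == "feedback") {
      u <- uidx[e$dst + 1L, e$state_dst]
      src <- uidx[e$src + 1L, e$state_src]
      dt <- if (e$src == e$dst && e$state_src != e$state_dst) 0L     # internal mirror
            else if (S > 1L) -1L else 0L
      bwd[[u]]$branches <- c(bwd[[u]]$branches,
                             list(list(eidx = i, src_uid = src, dt = dt)))
    }
  }
  for (u in seq_along(units)) {
    if (!is.null(fwd[[u]])) {
      if (is.null(fwd[[u]]$branches)) fwd[[u]]$branches <- list()
      if (is.null(fwd[[u]]$wrap)) fwd[[u]]$wrap <- 0L
      if (is.null(fwd[[u]]$self)) fwd[[u]]$self <- FALSE
      if (length(fwd[[u]]$branches) == 0L && !fwd[[u]]$self) { fwd[u] <- list(NULL); next }
      dts <- vapply(fwd[[u]]$branches, function(b) b$dt, 0L)
      if (fwd[[u]]$self) dts <- c(dts, 1L)
      fwd[[u]]$smin <- if (S == 1L) 1L else if (any(dts == 1L)) 2L else 1L
    }
  }
  for (u in seq_along(units)) {
    if (!is.null(bwd[[u]])) {
      dts <- vapply(bwd[[u]]$branches, function(b) b$dt, 0L)
      bwd[[u]]$smax <- if (S == 1L) 1L else if (any(dts == -1L)) S - 1L else S
    }
  }
  out_m <- n - 1L
  list(units = units, uidx = uidx, fwd = fwd, bwd = bwd, S = S,
       input_uid = uidx[1L, 1L], output_uid = uidx[out_m + 1L, 1L])
}

# ---- state trajectories ----------------------------------------------------

new_trajectory <- function(plan, batch_size) {
  v <- lapply(plan$units, function(u)
    lapply(seq_len(plan$S), function(s) matrix(0, batch_size, prod(u$shape))))
  clamp <- matrix(FALSE, length(plan$units), plan$S)
  structure(list(v = v, clamp = clamp, batch_size = batch_size, S = plan$S),
            class = "state_trajectory")
}

#' @export
print.state_trajectory <- function(x, ...) {
  cat(sprintf("<state_trajectory> %d units x %d slices, batch %d\n",
              length(x$v), x$S, x$batch_size))
  invisible(x)
}

as_batch_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.array(x)) return(matrix(x, nrow = dim(x)[1]))
  matrix(x, nrow = 1L)
}

#' Initialize a state trajectory with a forward pass
#'
#' Runs one feedforward sweep (the feedforward predictions, without error
#' correction) to populate every unit state: the input node is clamped to `x`
#' at all time slices, hidden and output states are set to their feedforward
#' predictions, and -- on temporal graphs -- internal states at t = 0 start at
#' zero.  Immediately after initialization every feedforward prediction error
#' on a static graph is exactly zero, so the total energy reduces to the
#' external loss.
#'
#' @param graph An `ebll_graph`.
#' @param params A `param_store`.
#' @param x Input batch: matrix (batch x features) or array (batch, h, w, c).
#' @param y Unused (accepted so initialization and training share a call
#'   signature); the output node is left free, not clamped to the target.
#' @return A `state_trajectory`.
#' @export
init_states <- function(graph, params, x, y = NULL) {
  plan <- compile_plan(graph)
  x <- as_batch_matrix(x)
  in_d <- prod(plan$units[[plan$input_uid]]$shape)
  if (ncol(x) != in_d)
    stop(sprintf("input has %d features; the input node expects %d", ncol(x), in_d))
  traj <- new_trajectory(plan, nrow(x))
  for (s in seq_len(plan$S)) traj$v[[plan$input_uid]][[s]] <- x
  traj$clamp[plan$input_uid, ] <- TRUE
  for (s in seq_len(plan$S)) {
    for (u in seq_along(plan$units)) {
      f <- plan$fwd[[u]]
      if (is.null(f) || s < f$smin) next
      traj$v[[u]][[s]] <- fwd_prediction(plan, graph, params, traj, u, s, with_cache = FALSE)$vhat
    }
  }
  traj
}

act_apply <- function(x, act) if (act == "tanh") tanh(x) else x
act_deriv_from_pre <- function(pre, act) if (act == "tanh") 1 - tanh(pre)^2 else 1

# feedforward prediction of unit u at slice s (assumes s >= smin)
fwd_prediction <- function(plan, graph, params, traj, u, s, with_cache = TRUE) {
  f <- plan$fwd[[u]]
  unit <- plan$units[[u]]
  ssum <- NULL
  caches <- if (with_cache) vector("list", length(f$branches))
  for (i in seq_along(f$branches)) {
    br <- f$branches[[i]]
    e <- graph$edges[[br$eidx]]
    xb <- traj$v[[br$src_uid]][[s - br$dt]]
    r <- fn_forward(e$fn, edge_theta(e, params), xb, e$src_shape)
    if (with_cache) caches[i] <- list(r$cache)
    ssum <- if (is.null(ssum)) r$y else ssum + r$y
  }
  if (f$self) {
    xs <- traj$v[[u]][[s - 1L]]
    ssum <- if (is.null(ssum)) xs else ssum + xs
  }
  wrap_cache <- NULL
  if (f$wrap > 0L) {
    e <- graph$edges[[f$wrap]]
    r <- fn_forward(e$fn, edge_theta(e, params), ssum, e$src_shape)
    pre <- r$y
    if (with_cache) wrap_cache <- r$cache
  } else pre <- ssum
  list(vhat = act_apply(pre, unit$act), pre = pre, ssum = ssum,
       caches = caches, wrap_cache = wrap_cache)
}

# feedback prediction of unit u at slice s (assumes s <= smax).
# Each branch applies the transposed operator of its tied parameters, scaled
# by 1/2 (the literal reading of the feedback-prediction formula) or by
# 1/n_branches when `renorm` is set.
bwd_prediction <- function(plan, graph, params, traj, u, s, renorm = FALSE,
                           with_cache = TRUE) {
  b <- plan$bwd[[u]]
  unit <- plan$units[[u]]
  wgt <- if (renorm) 1 / length(b$branches) else 0.5
  pre <- NULL
  caches <- if (with_cache) vector("list", length(b$branches))
  for (i in seq_along(b$branches)) {
    br <- b$branches[[i]]
    e <- graph$edges[[br$eidx]]
    xb <- traj$v[[br$src_uid]][[s - br$dt]]
    r <- fn_feedback(e$fn[setdiff(names(e$fn), "transposed")],
                     edge_theta(e, params), xb, e$dst_shape)
    if (with_cache) caches[i] <- list(r$cache)
    pre <- if (is.null(pre)) wgt * r$y else pre + wgt * r$y
  }
  list(vhat = act_apply(pre, unit$act), pre = pre, caches = caches, wgt = wgt)
}

compute_predictions <- function(plan, graph, params, traj, feedback = TRUE,
                                renorm = FALSE, with_cache = TRUE) {
  nf <- vector("list", length(plan$units))
  nb <- vector("list", length(plan$units))
  for (u in seq_along(plan$units)) {
    f <- plan$fwd[[u]]
    if (!is.null(f)) {
      nf[[u]] <- vector("list", plan$S)
      for (s in f$smin:plan$S)
        nf[[u]][[s]] <- fwd_prediction(plan, graph, params, traj, u, s, with_cache)
    }
    if (feedback && !is.null(plan$bwd[[u]])) {
      nb[[u]] <- vector("list", plan$S)
      for (s in seq_len(plan$bwd[[u]]$smax))
        nb[[u]][[s]] <- bwd_prediction(plan, graph, params, traj, u, s, renorm, with_cache)
    }
  }
  list(fwd = nf, bwd = nb)
}

slice_to_t <- function(s) s - 1L

#' Feedforward predictions and errors for every unit and time step
#'
#' @param graph An `ebll_graph`.
#' @param params A `param_store`.
#' @param traj A `state_trajectory` (see [init_states()]).
#' @return A list of records, one per (node, slot, t) with a defined
#'   feedforward prediction: `m`, `slot`, `t`, `vhat` and `eps = v - vhat`.
#' @export
forward_predictions <- function(graph, params, traj) {
  plan <- compile_plan(graph)
  preds <- compute_predictions(plan, graph, params, traj, feedback = FALSE,
                               with_cache = FALSE)
  collect_predictions(plan, traj, preds$fwd)
}

#' Feedback predictions and errors for every unit and time step
#'
#' Feedback predictions apply the transposed operators of the weight-tied
#' feedforward/recurrent parameters, each branch scaled by 1/2.
#'
#' @inheritParams forward_predictions
#' @param renorm Rescale the 1/2 branch weights to sum to one where a
#'   boundary node has a single feedback branch.
#' @return As [forward_predictions()], for the feedback half.
#' @export
backward_predictions <- function(graph, params, traj, renorm = FALSE) {
  plan <- compile_plan(graph)
  nb <- vector("list", length(plan$units))
  for (u in seq_along(plan$units)) {
    if (is.null(plan$bwd[[u]])) next
    nb[[u]] <- vector("list", plan$S)
    for (s in seq_len(plan$bwd[[u]]$smax))
      nb[[u]][[s]] <- bwd_prediction(plan, graph, params, traj, u, s, renorm,
                                     with_cache = FALSE)
  }
  collect_predictions(plan, traj, nb)
}

collect_predictions <- function(plan, traj, pl) {
  out <- list()
  for (u in seq_along(plan$units)) {
    if (is.null(pl[[u]])) next
    for (s in seq_len(plan$S)) {
      p <- pl[[u]][[s]]
      if (is.null(p)) next
      unit <- plan$units[[u]]
      out[[paste0(unit$label, ".t", slice_to_t(s))]] <-
        list(m = unit$m, slot = unit$slot, t = slice_to_t(s),
             vhat = p$vhat, eps = traj$v[[u]][[s]] - p$vhat)
    }
  }
  out
}
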