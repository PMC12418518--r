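# Analytic gradients of the prediction-error energies with respect to states
# (inference phase) and parameters (learning phase).  Both phases descend the
# same scalar F; the gradients here are exact derivatives of the quantities
# computed in energies.R and are validated against central finite differences
# in the test suite.

# Accumulates state gradients dv (per unit/slice) and, optionally, parameter
# gradients dth (per params_id).  Returns the energy breakdown as well so the
# inference loop gets F and its gradients from one pass.
energy_gradients <- function(graph, params, traj, y = NULL,
                             method = "bipc_combined", beta = 1,
                             loss_f = "cross_entropy", renorm = FALSE,
                             wrt = c("states", "params")) {
  wrt <- match.arg(wrt, several.ok = TRUE)
  plan <- compile_plan(graph)
  feedback <- method != "hpc"
  preds <- compute_predictions(plan, graph, params, traj, feedback = feedback,
                               renorm = renorm, with_cache = TRUE)
  combined <- method == "bipc_combined"
  B <- traj$batch_size
  want_v <- "states" %in% wrt
  want_p <- "params" %in% wrt

  dv <- if (want_v) lapply(plan$units, function(u)
    lapply(seq_len(plan$S), function(s) matrix(0, B, prod(u$shape))))
  dth <- if (want_p) lapply(params$tensors, th_zero)

  add_dv <- function(u, s, g) {
    if (want_v) dv[[u]][[s]] <<- dv[[u]][[s]] + g
  }
  add_dth <- function(id, g) {
    if (want_p && !is.null(g) && !is.null(id) && !is.na(id))
      dth[[id]] <<- th_add(dth[[id]], g)
  }

  # push an upstream gradient U (w.r.t. the feedforward prediction vhat of
  # unit u at slice s) into the branch sources and edge parameters
  push_fwd <- function(u, s, f, U) {
    fplan <- plan$fwd[[u]]
    u1 <- U * act_deriv_from_pre(f$pre, plan$units[[u]]$act)
    if (fplan$wrap > 0L) {
      e <- graph$edges[[fplan$wrap]]
      r <- fn_vjp(e$fn, edge_theta(e, params), f$wrap_cache, u1, e$src_shape)
      add_dth(e$params_id, r$dth)
      u2 <- r$dx
    } else u2 <- u1
    for (i in seq_along(fplan$branches)) {
      br <- fplan$branches[[i]]
      e <- graph$edges[[br$eidx]]
      r <- fn_vjp(e$fn, edge_theta(e, params), f$caches[[i]], u2, e$src_shape)
      add_dv(br$src_uid, s - br$dt, r$dx)
      add_dth(e$params_id, r$dth)
    }
    if (fplan$self) add_dv(u, s - 1L, u2)
  }

  # as push_fwd, for a feedback prediction; parameter gradients are routed to
  # the tied feedforward/recurrent parameters
  push_bwd <- function(u, s, b, U) {
    bplan <- plan$bwd[[u]]
    u1 <- U * act_deriv_from_pre(b$pre, plan$units[[u]]$act)
    for (i in seq_along(bplan$branches)) {
      br <- bplan$branches[[i]]
      e <- graph$edges[[br$eidx]]
      fn <- e$fn[setdiff(names(e$fn), "transposed")]
      r <- fn_feedback_vjp(fn, edge_theta(e, params), b$caches[[i]],
                           b$wgt * u1, e$dst_shape)
      add_dv(br$src_uid, s - br$dt, r$dx)
      add_dth(e$tied_to, r$dth)
    }
  }

  E <- 0; Cb <- 0
  for (u in seq_along(plan$units)) {
    unit <- plan$units[[u]]
    for (s in seq_len(plan$S)) {
      f <- if (!is.null(preds$fwd[[u]])) preds$fwd[[u]][[s]]
      b <- if (!is.null(preds$bwd[[u]])) preds$bwd[[u]][[s]]
      if (is.null(f) && is.null(b)) next
      v <- traj$v[[u]][[s]]
      if (unit$m == 0L) {
        if (!is.null(b)) {      # input reconstruction -> external loss Cb
          eb <- v - b$vhat
          Cb <- Cb + mean(eb * eb)
          push_bwd(u, s, b, -beta * 2 * eb / (B * ncol(eb)))
        }
        next
      }
      ef <- if (!is.null(f)) v - f$vhat
      eb <- if (!is.null(b)) v - b$vhat
      if (combined && !is.null(ef) && !is.null(eb)) {
        r <- ef + eb
        E <- E + mean(rowSums(r * r))
        w <- 2 * r / B
        add_dv(u, s, 2 * w)     # v appears in both residuals of the square
        push_fwd(u, s, f, -w)
        push_bwd(u, s, b, -w)
      } else {
        if (!is.null(ef)) {
          E <- E + mean(rowSums(ef * ef))
          w <- 2 * ef / B
          add_dv(u, s, w)
          push_fwd(u, s, f, -w)
        }
        if (!is.null(eb)) {
          E <- E + mean(rowSums(eb * eb))
          w <- 2 * eb / B
          add_dv(u, s, w)
          push_bwd(u, s, b, -w)
        }
      }
    }
  }

  Cf <- 0
  if (!is.null(y)) {
    vout <- traj$v[[plan$output_uid]][[plan$S]]
    Cf <- external_loss(vout, y, loss_f)
    add_dv(plan$output_uid, plan$S, beta * loss_grad(vout, y, loss_f))
  }
  if (!feedback) Cb <- 0

  if (want_v) {     # clamped entries receive no gradient
    for (u in seq_along(plan$units))
      for (s in seq_len(plan$S))
        if (traj$clamp[u, s]) dv[[u]][[s]] <- matrix(0, B, ncol(dv[[u]][[s]]))
  }

  list(F = total_energy(E, Cf + Cb, beta), E = E, C_f = Cf, C_b = Cb,
       dv = dv, dth = dth, plan = plan)
}

#' State gradients of an energy function
#'
#' Returns the exact gradient of the total energy `F` (a batch mean) with
#' respect to every unclamped unit state at every time slice; clamped entries
#' get a zero gradient.  For the hierarchical variant on a static chain this
#' reduces to the classical local rule `dF/dv_i = 2 eps_i - 2 eps_{i+1}
#' dg_{i+1}/dv_i`.
#'
#' @param graph An `ebll_graph`.
#' @param params A `param_store`.
#' @param traj A `state_trajectory`.
#' @param y Supervised target (or `NULL` to drop the external loss).
#' @param method `"hpc"`, `"bipc_additive"` or `"bipc_combined"`.
#' @param beta External-energy scale.
#' @param loss_f Output loss kind.
#' @param renorm Feedback 1/2-weight renormalization flag.
#' @return List of records `(m, slot, t, grad)`, one per unit and time step.
#' @export
state_gradients <- function(graph, params, traj, y = NULL,
                            method = "bipc_combined", beta = 1,
                            loss_f = "cross_entropy", renorm = FALSE) {
  res <- energy_gradients(graph, params, traj, y, method, beta, loss_f,
                          renorm, wrt = "states")
  out <- list()
  for (u in seq_along(res$plan$units)) {
    unit <- res$plan$units[[u]]
    for (s in seq_len(res$plan$S))
      out[[paste0(unit$label, ".t", slice_to_t(s))]] <-
        list(m = unit$m, slot = unit$slot, t = slice_to_t(s),
             grad = res$dv[[u]][[s]])
  }
  out
}

#' Parameter gradients of an energy function at the inference equilibrium
#'
#' Returns `dF/dtheta` for every learnable parameter tensor; gradients of
#' weight-tied feedback edges are routed to their source parameters.  For the
#' hierarchical variant this is the local rule
#' `dF/dtheta_i = -2 eps_i dg_i/dtheta_i`.
#'
#' @inheritParams state_gradients
#' @return Named list (by params_id) of gradient tensors matching the
#'   parameter-store structure.
#' @export
param_gradients <- function(graph, params, traj, y = NULL,
                            method = "bipc_combined", beta = 1,
                            loss_f = "cross_entropy", renorm = FALSE) {
  res <- energy_gradients(graph, params, traj, y, method, beta, loss_f,
                          renorm, wrt = "params")
  res$dth
}
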