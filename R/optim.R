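# Optimizers for the learning phase: plain SGD, Adam, and the layer-adaptive
# learning rate (LALR).  LALR normalizes every layer's parameter update
# magnitude to a common budget: with per-layer gradient norms ||dtheta_i||_2
# and their harmonic mean S, the layer rate is
#     eta_i = eta * S / ||dtheta_i||_2,
# so each layer moves by the same l2 distance eta * S.  The harmonic mean is
# used because it is insensitive to the occasional exploding layer norm.
# "Layer" granularity is one rate per edge-parameter tensor (the weights and
# biases of one edge share a rate, with norms computed jointly).

#' Harmonic mean of non-negative gradient norms
#'
#' Entries are floored at `floor` before inversion, so a zero norm cannot
#' blow up the mean.
#'
#' @param norms Numeric vector (at least one entry).
#' @param floor Lower bound applied before taking reciprocals.
#' @return `n / sum(1 / pmax(norms, floor))`.
#' @export
harmonic_mean <- function(norms, floor = 1e-12) {
  if (length(norms) == 0L) stop("harmonic_mean of an empty vector")
  length(norms) / sum(1 / pmax(norms, floor))
}

#' Layer-adaptive learning rates from a set of parameter gradients
#'
#' @param eta_theta Global learning rate (> 0).
#' @param grads Named list (by params_id) of gradient tensors.
#' @param floor Gradient-norm floor; layers whose norm falls below it keep
#'   the unscaled global rate and are flagged in `floored`.
#' @return An `optim_state` with per-layer rates, gradient norms, the
#'   harmonic mean `S_value`, and the common update magnitude
#'   `delta_theta = eta_theta * S_value`.
#' @export
lalr_rates <- function(eta_theta, grads, floor = 1e-12) {
  stopifnot(eta_theta > 0, length(grads) > 0)
  norms <- vapply(grads, th_l2, 0)
  S <- harmonic_mean(norms, floor)
  floored <- norms < floor
  rates <- ifelse(floored, eta_theta, eta_theta * S / norms)
  names(rates) <- names(grads)
  structure(list(eta_theta = eta_theta, per_layer_rates = rates,
                 grad_norms = norms, S_value = S,
                 delta_theta = eta_theta * S, floored = floored,
                 step_count = 0L),
            class = "optim_state")
}

#' @export
print.optim_state <- function(x, ...) {
  cat(sprintf("<optim_state> eta = %g, S = %.6g, common update magnitude %.6g (%d layers, %d floored)\n",
              x$eta_theta, x$S_value, x$delta_theta,
              length(x$per_layer_rates), sum(x$floored)))
  invisible(x)
}

new_adam_state <- function(grads, eta, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(eta = eta, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(grads, th_zero), v = lapply(grads, th_zero))
}

#' Apply one optimizer step to the parameter store
#'
#' @param params A `param_store`.
#' @param grads Named list of parameter gradients (as from
#'   [param_gradients()]).
#' @param state Optimizer state: for `"lalr"` an [lalr_rates()] result is
#'   computed from `grads` when not supplied; for `"adam"` the moment state
#'   (created on first use); for `"sgd"` a list with `eta`.
#' @param rule `"sgd"`, `"adam"` or `"lalr"`.
#' @param eta Learning rate, used when `state` is `NULL`.
#' @param lalr_on_adam For `"lalr"`: first precondition the gradients with
#'   Adam's moment estimates, then apply the layer-wise rate normalization
#'   (exposes the alternative composition of the two rules).
#' @return List with the updated `params` and `state`.
#' @export
apply_update <- function(params, grads, state = NULL,
                         rule = c("sgd", "adam", "lalr"), eta = 0.01,
                         lalr_on_adam = FALSE) {
  rule <- match.arg(rule)
  if (rule == "sgd") {
    if (is.null(state)) state <- list(eta = eta, step_count = 0L)
    for (id in names(grads))
      params$tensors[[id]] <- th_map2(params$tensors[[id]], grads[[id]],
                                      function(th, g) th - state$eta * g)
    state$step_count <- state$step_count + 1L
    return(list(params = params, state = state))
  }
  if (rule == "adam" || (rule == "lalr" && lalr_on_adam)) {
    if (is.null(state$m))
      state <- c(new_adam_state(grads, state$eta %||% eta), state["eta_theta"])
    state$t <- state$t + 1L
    steps <- list()
    for (id in names(grads)) {
      state$m[[id]] <- th_map2(state$m[[id]], grads[[id]],
                               function(m, g) state$beta1 * m + (1 - state$beta1) * g)
      state$v[[id]] <- th_map2(state$v[[id]], grads[[id]],
                               function(v, g) state$beta2 * v + (1 - state$beta2) * g^2)
      mhat <- th_scale(state$m[[id]], 1 / (1 - state$beta1^state$t))
      vhat <- th_scale(state$v[[id]], 1 / (1 - state$beta2^state$t))
      steps[[id]] <- th_map2(mhat, vhat, function(m, v) m / (sqrt(v) + state$eps))
    }
    if (rule == "adam") {
      for (id in names(grads))
        params$tensors[[id]] <- th_map2(params$tensors[[id]], steps[[id]],
                                        function(th, s) th - state$eta * s)
      check_finite_params(params)
      return(list(params = params, state = state))
    }
    grads <- steps           # LALR on Adam-preconditioned steps
    eta_use <- if (!is.null(state$eta_theta)) state$eta_theta else state$eta
    ls <- lalr_rates(eta_use, grads)
    for (id in names(grads))
      params$tensors[[id]] <- th_map2(params$tensors[[id]], grads[[id]],
                                      function(th, g) th - ls$per_layer_rates[[id]] * g)
    state$last_lalr <- ls
    check_finite_params(params)
    return(list(params = params, state = state))
  }
  # plain LALR on raw gradients
  if (is.null(state) || is.null(state$eta_theta))
    state <- list(eta_theta = eta, step_count = 0L)
  ls <- lalr_rates(state$eta_theta, grads)
  for (id in names(grads))
    params$tensors[[id]] <- th_map2(params$tensors[[id]], grads[[id]],
                                    function(th, g) th - ls$per_layer_rates[[id]] * g)
  state$last_lalr <- ls
  state$step_count <- (state$step_count %||% 0L) + 1L
  check_finite_params(params)
  list(params = params, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_finite_params <- function(params) {
  for (id in names(params$tensors))
    if (!all(is.finite(th_unlist(params$tensors[[id]]))))
      stop("non-finite parameter update in tensor '", id,
           "' (gradient explosion during the learning phase)")
  invisible(TRUE)
}

#' Weight-to-gradient-update ratio per layer
#'
#' The divergence-risk diagnostic: `||w||_2 / (eta * ||dw||_2)` per parameter
#' tensor.  A ratio below 1 means a single step would move the layer further
#' than its current weight norm -- the regime where training tends to
#' diverge.  Layers with zero gradient report `Inf`.
#'
#' @param params A `param_store`.
#' @param grads Named list of parameter gradients.
#' @param eta Learning rate (global, or a named vector of per-layer rates).
#' @param epoch Optional epoch tag carried into the report.
#' @return A `ratio_report` data frame with columns `params_id`, `ratio`,
#'   `flagged` (ratio < 1).
#' @export
weight_grad_ratio <- function(params, grads, eta, epoch = NA_integer_) {
  ids <- names(grads)
  eta_i <- if (length(eta) == 1L) rep(eta, length(ids)) else eta[ids]
  ratio <- vapply(seq_along(ids), function(i) {
    gn <- th_l2(grads[[ids[i]]])
    wn <- th_l2(params$tensors[[ids[i]]])
    if (gn == 0) Inf else wn / (eta_i[i] * gn)
  }, 0)
  structure(data.frame(params_id = ids, ratio = ratio,
                       flagged = is.finite(ratio) & ratio < 1,
                       epoch = epoch, row.names = NULL),
            class = c("ratio_report", "data.frame"))
}

#' Per-layer gradient-norm time series from a training log
#'
#' @param log A metrics log: the `metrics` element of an `ebll_fit`, or a
#'   data frame with columns `epoch`, `params_id`, `grad_norm`.
#' @return Data frame ordered by layer and epoch, one gradient-norm series
#'   per params_id, ready for CSV export or plotting.
#' @export
grad_fluctuation_trace <- function(log) {
  df <- if (inherits(log, "ebll_fit")) log$grad_norms else log
  if (is.null(df) || nrow(df) == 0L) stop("empty training log")
  df[order(df$params_id, df$epoch), c("params_id", "epoch", "grad_norm")]
}
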