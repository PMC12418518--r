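# The full training loop: per batch, an inference phase relaxes the states
# to an energy minimum, then a learning phase updates the parameters from the
# local gradients at that minimum.  A backpropagation baseline trains the
# same graph by direct loss differentiation.

predict_graph <- function(graph, params, x) {
  plan <- compile_plan(graph)
  traj <- init_states(graph, params, x)
  traj$v[[plan$output_uid]][[plan$S]]
}

accuracy_of <- function(logits, y) mean(max.col(logits, ties.method = "first") - 1L == y)

#' Train a network graph with an energy-based local rule (or backprop)
#'
#' For the energy-based methods each batch runs the two-phase procedure:
#' states are initialized with a forward sweep, relaxed by gradient descent
#' on the energy (inference phase), and the parameter gradients at the energy
#' minimum drive the optimizer step (learning phase).  `method = "backprop"`
#' trains the identical graph end-to-end from the output loss as the
#' baseline.  Everything is deterministic given `config$seed`.
#'
#' @param graph An `ebll_graph`; built from `config$architecture` when `NULL`.
#' @param data List with `train` and `test` components (`x`, 0-based `y`),
#'   as returned by [make_synthetic()].
#' @param config A [run_config()].
#' @param params Optional initial `param_store` (defaults to a fresh
#'   fan-in-scaled initialization from `config$seed`).
#' @param track_energy Record the mean equilibrium energy per epoch.
#' @param verbose Print one line per epoch.
#' @return An `ebll_fit`: graph, trained parameters, per-epoch `metrics`
#'   (loss, accuracy, mean F, inference iterations), per-layer `grad_norms`,
#'   and flags for any diverged batches.
#' @export
ebll_train <- function(graph = NULL, data, config = run_config(),
                       params = NULL, track_energy = TRUE, verbose = FALSE) {
  if (is.null(graph)) graph <- build_graph(config$architecture)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed + 1L)

  icfg <- inference_config(eta_v = config$eta_v, N = config$N,
                           threshold = config$threshold, beta = config$beta)

  if (config$method == "ep") {
    # equilibrium propagation runs on the layered Hopfield analogue of the
    # graph: one unit block per node, symmetric weights between neighbours
    sizes <- vapply(graph$nodes, function(nd) prod(nd$shape), 0)
    net <- hopfield_chain(sizes, seed = config$seed)
    res <- ep_train_loop(net, data, config, icfg)
    return(structure(list(
      graph = graph, hopfield = res$net, params = list(tensors = res$net$blocks),
      config = config,
      metrics = if (length(res$metrics)) do.call(rbind, res$metrics) else
        empty_metrics(),
      grad_norms = if (length(res$gnorm_rows)) do.call(rbind, res$gnorm_rows) else
        empty_grad_norms(),
      diverged_batches = list()), class = "ebll_fit"))
  }

  if (is.null(params)) params <- init_params(graph, seed = config$seed)
  opt_state <- NULL
  n <- if (is.matrix(data$train$x)) nrow(data$train$x) else dim(data$train$x)[1]
  metrics <- list(); gnorm_rows <- list(); flagged <- list()

  for (epoch in seq_len(config$epochs)) {
    ord <- sample(n)
    batch_starts <- seq(1L, n, by = config$batch_size)
    ep_loss <- 0; ep_F <- 0; ep_iters <- 0; nb <- 0L
    gn_acc <- NULL
    for (b0 in batch_starts) {
      idx <- ord[b0:min(b0 + config$batch_size - 1L, n)]
      xb <- subset_x(data$train$x, idx)
      yb <- data$train$y[idx]
      if (config$method == "backprop") {
        bp <- backprop_gradients(graph, params, xb, yb, loss = config$loss_f)
        grads <- bp$dth
        ep_loss <- ep_loss + bp$loss; ep_F <- ep_F + bp$loss
      } else {
        traj <- init_states(graph, params, xb)
        inf <- run_inference(graph, params, traj, y = yb,
                             method = config$method, cfg = icfg,
                             loss_f = config$loss_f)
        if (inf$trace$diverged) {
          flagged[[length(flagged) + 1L]] <-
            list(epoch = epoch, batch = b0,
                 F_last = utils::tail(inf$trace$F_history, 1))
          next
        }
        grads <- param_gradients(graph, params, inf$traj, y = yb,
                                 method = config$method, beta = config$beta,
                                 loss_f = config$loss_f)
        Fh <- inf$trace$F_history
        ep_F <- ep_F + Fh[length(Fh)]
        ep_iters <- ep_iters + inf$trace$iterations_used
        vout <- inf$traj$v[[compile_plan(graph)$output_uid]][[inf$traj$S]]
        ep_loss <- ep_loss + external_loss(vout, yb, config$loss_f)
      }
      gn <- vapply(grads, th_l2, 0)
      gn_acc <- if (is.null(gn_acc)) gn else gn_acc + gn
      upd <- apply_update(params, grads, opt_state, rule = config$optimizer,
                          eta = config$eta_theta)
      params <- upd$params; opt_state <- upd$state
      nb <- nb + 1L
    }
    if (nb == 0L) stop("every batch in epoch ", epoch, " diverged")
    test_logits <- predict_graph(graph, params, data$test$x)
    acc <- accuracy_of(test_logits, data$test$y)
    metrics[[epoch]] <- data.frame(
      epoch = epoch, loss = ep_loss / nb, accuracy = acc,
      mean_F = if (track_energy) ep_F / nb else NA_real_,
      mean_inference_iters = ep_iters / nb, n_batches = nb,
      n_diverged = length(flagged))
    for (id in names(gn_acc))
      gnorm_rows[[length(gnorm_rows) + 1L]] <-
        data.frame(epoch = epoch, params_id = id, grad_norm = gn_acc[[id]] / nb)
    if (verbose)
      message(sprintf("epoch %d: loss %.4f, test accuracy %.3f", epoch,
                      ep_loss / nb, acc))
  }
  structure(list(
    graph = graph, params = params, config = config,
    metrics = if (length(metrics)) do.call(rbind, metrics) else empty_metrics(),
    grad_norms = if (length(gnorm_rows)) do.call(rbind, gnorm_rows) else
      empty_grad_norms(),
    diverged_batches = flagged),
    class = "ebll_fit")
}

empty_metrics <- function() {
  data.frame(epoch = integer(0), loss = numeric(0), accuracy = numeric(0),
             mean_F = numeric(0), mean_inference_iters = numeric(0),
             n_batches = integer(0), n_diverged = integer(0))
}

empty_grad_norms <- function() {
  data.frame(epoch = integer(0), params_id = character(0), grad_norm = numeric(0))
}

#' Write per-epoch training metrics as JSON lines
#'
#' One JSON record per epoch, suitable for appending across runs.
#'
#' @param fit An `ebll_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_metrics_jsonl <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(fit$metrics)))
    writeLines(jsonlite::toJSON(as.list(fit$metrics[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  invisible(path)
}

# ---- fitted-model methods --------------------------------------------------

#' @export
print.ebll_fit <- function(x, ...) {
  cat(sprintf("<ebll_fit> method %s, optimizer %s, %d epochs\n",
              x$config$method, x$config$optimizer, nrow(x$metrics)))
  if (nrow(x$metrics) > 0) {
    last <- x$metrics[nrow(x$metrics), ]
    cat(sprintf("  final loss %.4f, test accuracy %.3f\n", last$loss, last$accuracy))
  }
  invisible(x)
}

#' @export
summary.ebll_fit <- function(object, ...) {
  cat(sprintf("Energy-based local learning fit (%s, %s optimizer)\n",
              object$config$method, object$config$optimizer))
  print(object$graph)
  np <- sum(vapply(object$params$tensors, function(th) length(th_unlist(th)), 0))
  cat(sprintf("Parameters: %d across %d tensors (seed %d)\n",
              np, length(object$params$tensors), object$config$seed))
  if (nrow(object$metrics)) print(object$metrics)
  if (length(object$diverged_batches))
    cat(sprintf("Diverged batches flagged: %d\n", length(object$diverged_batches)))
  invisible(object)
}

#' @export
coef.ebll_fit <- function(object, ...) object$params$tensors

#' Predict class labels or logits from a fitted network
#'
#' @param object An `ebll_fit`.
#' @param newdata Input batch (matrix or image array).
#' @param type `"class"` (0-based labels), `"logits"` or `"prob"` (softmax).
#' @param ... Unused.
#' @return Labels, logit matrix, or probability matrix.
#' @export
predict.ebll_fit <- function(object, newdata, type = c("class", "logits", "prob"), ...) {
  type <- match.arg(type)
  logits <- if (!is.null(object$hopfield)) {
    ep_predict(object$hopfield, as_batch_matrix(newdata),
               inference_config(eta_v = object$config$eta_v, N = object$config$N,
                                threshold = object$config$threshold))
  } else predict_graph(object$graph, object$params, newdata)
  switch(type,
    class = max.col(logits, ties.method = "first") - 1L,
    logits = logits,
    prob = {
      p <- exp(logits - apply(logits, 1, max))
      p / rowSums(p)
    })
}

#' Plot training curves of a fitted network
#'
#' Loss and held-out accuracy per epoch, base graphics.
#'
#' @param x An `ebll_fit`.
#' @param ... Passed to `plot()`.
#' @export
plot.ebll_fit <- function(x, ...) {
  m <- x$metrics
  if (nrow(m) == 0) stop("no epochs to plot")
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  plot(m$epoch, m$loss, type = "b", xlab = "epoch", ylab = "training loss", ...)
  plot(m$epoch, m$accuracy, type = "b", xlab = "epoch",
       ylab = "held-out accuracy", ylim = c(0, 1), ...)
  invisible(x)
}

#' Equilibrium prediction errors of a fitted network on data
#'
#' Runs the inference phase on a batch and returns the per-node prediction
#' errors at the energy minimum -- the model's residuals.
#'
#' @param object An `ebll_fit`.
#' @param newdata List with `x` and `y` (defaults required).
#' @param ... Unused.
#' @return Data frame of per-node/time residual energy terms.
#' @export
residuals.ebll_fit <- function(object, newdata, ...) {
  cfg <- object$config
  method <- if (cfg$method %in% c("hpc", "bipc_additive", "bipc_combined"))
    cfg$method else "bipc_combined"
  traj <- init_states(object$graph, object$params, newdata$x)
  inf <- run_inference(object$graph, object$params, traj, y = newdata$y,
                       method = method,
                       cfg = inference_config(eta_v = cfg$eta_v, N = cfg$N,
                                              threshold = cfg$threshold,
                                              beta = cfg$beta),
                       loss_f = cfg$loss_f)
  bd <- pc_energy(object$graph, object$params, inf$traj, y = newdata$y,
                  method = method, beta = cfg$beta, loss_f = cfg$loss_f)
  bd$per_term
}
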