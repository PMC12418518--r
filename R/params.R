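# Parameter store: one tensor set per learnable edge, keyed by params_id.

#' Initialize parameters for every learnable edge of a graph
#'
#' Weights are fan-in-scaled Gaussians (sd = `weight_scale`/sqrt(fan_in)),
#' biases zero.  `weight_scale = 1` is the standard normalization; inflating
#' it is the knob used by the gradient-explosion diagnostics.
#'
#' @param graph An `ebll_graph`.
#' @param seed Integer seed; initialization is fully reproducible.
#' @param weight_scale Multiplier on the fan-in-normalized weight sd.
#' @return A `param_store`: list with `tensors` (named by params_id) and the
#'   `seed` used.
#' @export
init_params <- function(graph, seed = 0L, weight_scale = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  tensors <- list()
  for (e in graph$edges) {
    if (e$kind == "feedback" || is.na(e$params_id)) next
    in_sh <- node_slot_shape(graph, e$src, e$state_src)
    tensors[[e$params_id]] <- fn_init_params(e$fn, in_sh, weight_scale)
  }
  structure(list(tensors = tensors, seed = as.integer(seed),
                 weight_scale = weight_scale),
            class = "param_store")
}

#' @export
print.param_store <- function(x, ...) {
  n <- vapply(x$tensors, function(th) length(th_unlist(th)), 0)
  cat(sprintf("<param_store> %d tensors, %d parameters (seed %d)\n",
              length(n), sum(n), x$seed))
  invisible(x)
}

edge_theta <- function(edge, params) {
  id <- if (edge$kind == "feedback") edge$tied_to else edge$params_id
  if (is.na(id) || is.null(id)) NULL else params$tensors[[id]]
}

#' Apply one edge's mapping function to a state
#'
#' Feedforward, skip and recurrent edges apply their forward map; feedback
#' edges apply the transposed linear operator of the parameters they are tied
#' to (matrix transpose for fully connected edges, transposed convolution for
#' convolutional ones, nearest-neighbour upsampling for max-pool stages).
#'
#' @param edge An `edge_spec` (from `graph$edges`, so shape metadata is set).
#' @param params A `param_store`.
#' @param x State matrix (batch x features); a plain vector is treated as a
#'   single-row batch.
#' @return The mapped state, as a matrix with one row per batch element.
#' @export
edge_apply <- function(edge, params, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (!is.null(edge$src_shape) && ncol(x) != prod(edge$src_shape))
    stop(sprintf("shape mismatch: edge expects %d input features, got %d",
                 prod(edge$src_shape), ncol(x)))
  th <- edge_theta(edge, params)
  if (edge$kind == "feedback") {
    if (is.null(edge$tied_to)) stop("feedback edge has no tied parameters")
    if (!is.null(edge$tied_to) && is.null(th) &&
        !edge$fn$type %in% c("identity", "maxpool"))
      stop("tied parameters '", edge$tied_to, "' not found in the store")
    # the fn descriptor mirrors the tied forward edge; in_shape is the tied
    # edge's input shape, i.e. this feedback edge's destination state
    fn_feedback(edge$fn[setdiff(names(edge$fn), "transposed")], th, x,
                edge$dst_shape)$y
  } else {
    fn_forward(edge$fn, th, x, edge$src_shape)$y
  }
}
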