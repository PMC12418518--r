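# Edge (layer) functions: parameterized mappings carried by graph edges.
#
# States are stored as matrices (batch x prod(shape)); image-shaped states use
# channels-last shape vectors c(h, w, c) and are reshaped on demand.  Every
# primitive provides
#   * a forward map            y = f(x; theta)
#   * its vector-Jacobian product (for gradients and backprop)
#   * a feedback map           z = f^T(y; theta) -- the transposed linear
#     operator of the forward map (transposed convolution for conv edges,
#     matrix transpose for fully connected, nearest-neighbour upsampling for
#     max-pool), used by weight-tied feedback edges
#   * the feedback map's vector-Jacobian product, with parameter gradients
#     routed to the tied forward parameters.
# Feedback maps never add a bias: they transpose only the linear part.

#' Fully connected edge function descriptor
#'
#' @param units Output width (number of units). Inputs are flattened, so a
#'   fully connected edge can follow an image-shaped node directly.
#' @return An edge-function descriptor list.
#' @export
fn_fc <- function(units) {
  stopifnot(is.numeric(units), units >= 1)
  list(type = "fc", units = as.integer(units))
}

#' Convolution edge function descriptor
#'
#' Stride-1, zero-padded ("same") 2-D convolution with square kernels.
#'
#' @param kernel Odd kernel size (1 or 3 in the reference architectures).
#' @param channels Number of output channels.
#' @return An edge-function descriptor list.
#' @export
fn_conv <- function(kernel, channels) {
  stopifnot(kernel %% 2 == 1, channels >= 1)
  list(type = "conv", kernel = as.integer(kernel), channels = as.integer(channels))
}

#' Max-pooling edge function descriptor
#'
#' @param pool Pooling window (and stride). The feedback map is
#'   nearest-neighbour upsampling by the same factor.
#' @return An edge-function descriptor list.
#' @export
fn_maxpool <- function(pool) {
  stopifnot(pool >= 2)
  list(type = "maxpool", pool = as.integer(pool))
}

#' Identity edge function descriptor
#' @return An edge-function descriptor list.
#' @export
fn_identity <- function() list(type = "identity")

#' Pointwise tanh stage (for composite edges)
#' @return An edge-function descriptor list.
#' @export
fn_tanh <- function() list(type = "tanh")

#' Composite edge function: stages applied in sequence
#'
#' Used for Table-style rows that fold several operations into one edge,
#' e.g. convolution followed by max-pooling, or a flatten + two-layer
#' fully connected decoder.
#'
#' @param ... Edge-function descriptors, applied left to right.
#' @return An edge-function descriptor list.
#' @export
fn_seq <- function(...) {
  stages <- list(...)
  if (length(stages) == 1L && is.null(stages[[1]]$type)) stages <- stages[[1]]
  list(type = "seq", stages = stages)
}

# ---- shape bookkeeping -----------------------------------------------------

#' Output shape of an edge function
#'
#' @param fn Edge-function descriptor.
#' @param in_shape Input state shape (length 1 for feature vectors,
#'   c(h, w, c) for images).
#' @return Integer shape vector of the output state.
#' @export
fn_out_shape <- function(fn, in_shape) {
  in_shape <- as.integer(in_shape)
  switch(fn$type,
    fc = fn$units,
    conv = {
      if (length(in_shape) != 3L) stop("conv edge needs an image-shaped input")
      c(in_shape[1], in_shape[2], fn$channels)
    },
    maxpool = {
      if (length(in_shape) != 3L) stop("maxpool edge needs an image-shaped input")
      if (any(in_shape[1:2] %% fn$pool != 0L))
        stop("maxpool window must divide the spatial dimensions")
      c(in_shape[1] %/% fn$pool, in_shape[2] %/% fn$pool, in_shape[3])
    },
    identity = in_shape,
    tanh = in_shape,
    seq = {
      sh <- in_shape
      for (st in fn$stages) sh <- fn_out_shape(st, sh)
      sh
    },
    stop("unknown edge function type: ", fn$type)
  )
}

fn_n_params <- function(fn, in_shape) {
  switch(fn$type,
    fc = prod(in_shape) * fn$units + fn$units,
    conv = fn$kernel^2 * in_shape[3] * fn$channels + fn$channels,
    seq = {
      sh <- in_shape; n <- 0
      for (st in fn$stages) { n <- n + fn_n_params(st, sh); sh <- fn_out_shape(st, sh) }
      n
    },
    0
  )
}

# Fan-in-scaled Gaussian initialization.  `scale` is a multiplier on the
# 1/sqrt(fan_in) standard deviation; inflating it above 1 is the knob used by
# the gradient-explosion probes.
fn_init_params <- function(fn, in_shape, scale = 1) {
  switch(fn$type,
    fc = {
      d_in <- prod(in_shape)
      list(W = matrix(stats::rnorm(d_in * fn$units, sd = scale / sqrt(d_in)),
                      nrow = d_in, ncol = fn$units),
           b = numeric(fn$units))
    },
    conv = {
      fan_in <- fn$kernel^2 * in_shape[3]
      list(W = array(stats::rnorm(fn$kernel^2 * in_shape[3] * fn$channels,
                                  sd = scale / sqrt(fan_in)),
                     dim = c(fn$kernel, fn$kernel, in_shape[3], fn$channels)),
           b = numeric(fn$channels))
    },
    seq = {
      sh <- in_shape
      out <- vector("list", length(fn$stages))
      for (i in seq_along(fn$stages)) {
        out[i] <- list(fn_init_params(fn$stages[[i]], sh, scale))
        sh <- fn_out_shape(fn$stages[[i]], sh)
      }
      out
    },
    NULL
  )
}

to_arr <- function(x, shape) array(x, dim = c(nrow(x), shape))
to_mat <- function(a) matrix(a, nrow = dim(a)[1])

# ---- primitive forward / vjp / feedback ------------------------------------

conv_pad <- function(x_arr, p) {
  d <- dim(x_arr)
  if (p == 0L) return(x_arr)
  xp <- array(0, c(d[1], d[2] + 2 * p, d[3] + 2 * p, d[4]))
  xp[, p + seq_len(d[2]), p + seq_len(d[3]), ] <- x_arr
  xp
}

conv_fwd <- function(x_arr, W, b) {
  d <- dim(x_arr); bs <- d[1]; h <- d[2]; w <- d[3]; ci <- d[4]
  k <- dim(W)[1]; co <- dim(W)[4]; p <- (k - 1L) %/% 2L
  xp <- conv_pad(x_arr, p)
  y <- matrix(rep(b, each = bs * h * w), nrow = bs * h * w, ncol = co)
  for (a in seq_len(k)) for (bb in seq_len(k)) {
    xs <- xp[, (a - 1L) + seq_len(h), (bb - 1L) + seq_len(w), , drop = FALSE]
    y <- y + matrix(xs, nrow = bs * h * w) %*% matrix(W[a, bb, , ], nrow = ci)
  }
  array(y, c(bs, h, w, co))
}

conv_vjp <- function(x_arr, W, u_arr) {
  d <- dim(x_arr); bs <- d[1]; h <- d[2]; w <- d[3]; ci <- d[4]
  k <- dim(W)[1]; co <- dim(W)[4]; p <- (k - 1L) %/% 2L
  xp <- conv_pad(x_arr, p)
  Um <- matrix(u_arr, nrow = bs * h * w)
  dxp <- array(0, c(bs, h + 2 * p, w + 2 * p, ci))
  dW <- array(0, dim(W))
  for (a in seq_len(k)) for (bb in seq_len(k)) {
    ri <- (a - 1L) + seq_len(h); cj <- (bb - 1L) + seq_len(w)
    xs <- matrix(xp[, ri, cj, , drop = FALSE], nrow = bs * h * w)
    Wm <- matrix(W[a, bb, , ], nrow = ci)
    dxp[, ri, cj, ] <- dxp[, ri, cj, , drop = FALSE] +
      array(Um %*% t(Wm), c(bs, h, w, ci))
    dW[a, bb, , ] <- crossprod(xs, Um)
  }
  dx <- dxp[, p + seq_len(h), p + seq_len(w), , drop = FALSE]
  list(dx = dx, dW = dW, db = colSums(Um))
}

# adjoint of conv_fwd's linear part: maps output-shaped u to input-shaped dx
conv_adjoint <- function(u_arr, W, in_ch) {
  d <- dim(u_arr); bs <- d[1]; h <- d[2]; w <- d[3]
  k <- dim(W)[1]; p <- (k - 1L) %/% 2L
  Um <- matrix(u_arr, nrow = bs * h * w)
  dxp <- array(0, c(bs, h + 2 * p, w + 2 * p, in_ch))
  for (a in seq_len(k)) for (bb in seq_len(k)) {
    ri <- (a - 1L) + seq_len(h); cj <- (bb - 1L) + seq_len(w)
    Wm <- matrix(W[a, bb, , ], nrow = in_ch)
    dxp[, ri, cj, ] <- dxp[, ri, cj, , drop = FALSE] +
      array(Um %*% t(Wm), c(bs, h, w, in_ch))
  }
  dxp[, p + seq_len(h), p + seq_len(w), , drop = FALSE]
}

maxpool_fwd <- function(x_arr, p) {
  d <- dim(x_arr); h <- d[2]; w <- d[3]
  oh <- h %/% p; ow <- w %/% p
  y <- NULL
  for (dy in seq_len(p)) for (dx in seq_len(p)) {
    xs <- x_arr[, seq(dy, h, by = p), seq(dx, w, by = p), , drop = FALSE]
    y <- if (is.null(y)) xs else pmax(y, xs)
  }
  y
}

maxpool_vjp <- function(x_arr, p, y_arr, u_arr) {
  d <- dim(x_arr); h <- d[2]; w <- d[3]
  cnt <- array(0, dim(y_arr))
  for (dy in seq_len(p)) for (dx in seq_len(p)) {
    xs <- x_arr[, seq(dy, h, by = p), seq(dx, w, by = p), , drop = FALSE]
    cnt <- cnt + (xs == y_arr)
  }
  dx <- array(0, dim(x_arr))
  for (dy in seq_len(p)) for (dx_ in seq_len(p)) {
    ri <- seq(dy, h, by = p); cj <- seq(dx_, w, by = p)
    xs <- x_arr[, ri, cj, , drop = FALSE]
    dx[, ri, cj, ] <- (xs == y_arr) * u_arr / cnt
  }
  dx
}

upsample_nn <- function(x_arr, p) {
  d <- dim(x_arr)
  x_arr[, rep(seq_len(d[2]), each = p), rep(seq_len(d[3]), each = p), , drop = FALSE]
}

upsample_nn_adjoint <- function(u_arr, p) {
  d <- dim(u_arr); h <- d[2]; w <- d[3]
  acc <- NULL
  for (dy in seq_len(p)) for (dx in seq_len(p)) {
    us <- u_arr[, seq(dy, h, by = p), seq(dx, w, by = p), , drop = FALSE]
    acc <- if (is.null(acc)) us else acc + us
  }
  acc
}

# ---- generic dispatch ------------------------------------------------------

# forward: x matrix (batch x prod(in_shape)) -> list(y matrix, cache)
fn_forward <- function(fn, th, x, in_shape) {
  switch(fn$type,
    fc = list(y = x %*% th$W + matrix(th$b, nrow(x), length(th$b), byrow = TRUE),
              cache = list(x = x)),
    conv = {
      xa <- to_arr(x, in_shape)
      list(y = to_mat(conv_fwd(xa, th$W, th$b)), cache = list(xa = xa))
    },
    maxpool = {
      xa <- to_arr(x, in_shape)
      ya <- maxpool_fwd(xa, fn$pool)
      list(y = to_mat(ya), cache = list(xa = xa, ya = ya))
    },
    identity = list(y = x, cache = NULL),
    tanh = { y <- tanh(x); list(y = y, cache = list(y = y)) },
    seq = {
      sh <- in_shape; caches <- vector("list", length(fn$stages))
      for (i in seq_along(fn$stages)) {
        r <- fn_forward(fn$stages[[i]], th[[i]], x, sh)
        caches[[i]] <- list(cache = r$cache, in_shape = sh)
        x <- r$y; sh <- fn_out_shape(fn$stages[[i]], sh)
      }
      list(y = x, cache = caches)
    },
    stop("unknown edge function type: ", fn$type)
  )
}

# vjp of fn_forward: upstream u (matrix shaped like y) ->
#   list(dx matrix, dth same structure as th or NULL)
fn_vjp <- function(fn, th, cache, u, in_shape) {
  switch(fn$type,
    fc = list(dx = u %*% t(th$W),
              dth = list(W = crossprod(cache$x, u), b = colSums(u))),
    conv = {
      r <- conv_vjp(cache$xa, th$W, to_arr(u, fn_out_shape(fn, in_shape)))
      list(dx = to_mat(r$dx), dth = list(W = r$dW, b = r$db))
    },
    maxpool = {
      ua <- to_arr(u, fn_out_shape(fn, in_shape))
      list(dx = to_mat(maxpool_vjp(cache$xa, fn$pool, cache$ya, ua)), dth = NULL)
    },
    identity = list(dx = u, dth = NULL),
    tanh = list(dx = u * (1 - cache$y^2), dth = NULL),
    seq = {
      dth <- vector("list", length(fn$stages))
      for (i in rev(seq_along(fn$stages))) {
        r <- fn_vjp(fn$stages[[i]], th[[i]], cache[[i]]$cache, u, cache[[i]]$in_shape)
        u <- r$dx; dth[i] <- list(r$dth)
      }
      list(dx = u, dth = dth)
    },
    stop("unknown edge function type: ", fn$type)
  )
}

# feedback (transposed) map: x shaped like the forward OUTPUT ->
#   list(y matrix shaped like the forward INPUT, cache)
fn_feedback <- function(fn, th, x, in_shape) {
  switch(fn$type,
    fc = list(y = x %*% t(th$W), cache = list(x = x)),
    conv = {
      out_sh <- fn_out_shape(fn, in_shape)
      xa <- to_arr(x, out_sh)
      list(y = to_mat(conv_adjoint(xa, th$W, in_shape[3])), cache = list(xa = xa))
    },
    maxpool = {
      out_sh <- fn_out_shape(fn, in_shape)
      list(y = to_mat(upsample_nn(to_arr(x, out_sh), fn$pool)), cache = NULL)
    },
    identity = list(y = x, cache = NULL),
    tanh = { y <- tanh(x); list(y = y, cache = list(y = y)) },
    seq = {
      # reverse composition: the last forward stage's feedback runs first
      shapes <- vector("list", length(fn$stages))
      sh <- in_shape
      for (i in seq_along(fn$stages)) { shapes[[i]] <- sh; sh <- fn_out_shape(fn$stages[[i]], sh) }
      caches <- vector("list", length(fn$stages))
      for (i in rev(seq_along(fn$stages))) {
        r <- fn_feedback(fn$stages[[i]], th[[i]], x, shapes[[i]])
        caches[i] <- list(r$cache)
        x <- r$y
      }
      list(y = x, cache = caches)
    },
    stop("unknown edge function type: ", fn$type)
  )
}

# vjp of fn_feedback.  dth is the gradient routed to the TIED forward
# parameters; for linear maps it uses the adjoint-swap identity
# d/dW <u, x W^T> = u^T x.
fn_feedback_vjp <- function(fn, th, cache, u, in_shape) {
  switch(fn$type,
    fc = list(dx = u %*% th$W, dth = list(W = crossprod(u, cache$x), b = 0 * th$b)),
    conv = {
      # z = convT_W(x); <u, convT_W(x)> = <conv_W(u), x>, so dW equals the
      # forward-conv parameter gradient with input u and upstream x.
      r <- conv_vjp(to_arr(u, in_shape), th$W, cache$xa)
      list(dx = to_mat(conv_fwd(to_arr(u, in_shape), th$W, 0 * th$b)),
           dth = list(W = r$dW, b = 0 * th$b))
    },
    maxpool = {
      list(dx = to_mat(upsample_nn_adjoint(to_arr(u, in_shape), fn$pool)), dth = NULL)
    },
    identity = list(dx = u, dth = NULL),
    tanh = list(dx = u * (1 - cache$y^2), dth = NULL),
    seq = {
      shapes <- vector("list", length(fn$stages))
      sh <- in_shape
      for (i in seq_along(fn$stages)) { shapes[[i]] <- sh; sh <- fn_out_shape(fn$stages[[i]], sh) }
      dth <- vector("list", length(fn$stages))
      for (i in seq_along(fn$stages)) {   # forward order = reverse of feedback
        r <- fn_feedback_vjp(fn$stages[[i]], th[[i]], cache[[i]], u, shapes[[i]])
        u <- r$dx; dth[i] <- list(r$dth)
      }
      list(dx = u, dth = dth)
    },
    stop("unknown edge function type: ", fn$type)
  )
}

# Flatten every numeric leaf of a parameter (or gradient) pytree to one vector.
th_unlist <- function(th) {
  if (is.null(th)) return(numeric(0))
  if (is.numeric(th)) return(as.numeric(th))
  unlist(lapply(th, th_unlist), use.names = FALSE)
}

th_l2 <- function(th) sqrt(sum(th_unlist(th)^2))

# elementwise combination of two pytrees with identical structure
th_map2 <- function(a, b, f) {
  if (is.null(a)) return(NULL)
  if (is.numeric(a)) {
    out <- f(a, b)
    attributes(out) <- attributes(a)
    return(out)
  }
  out <- a
  for (i in seq_along(a)) out[i] <- list(th_map2(a[[i]], b[[i]], f))
  out
}

th_add <- function(a, b) if (is.null(a)) b else if (is.null(b)) a else th_map2(a, b, `+`)
th_scale <- function(a, s) if (is.null(a)) NULL else th_map2(a, a, function(x, y) s * x)
th_zero <- function(a) th_scale(a, 0)
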