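# Synthetic classification data and standard dataset file readers.
# Class labels are 0-based throughout, matching the 0-based node indexing.

#' Synthetic dataset specification
#'
#' @param kind `"blobs"` (Gaussian clusters in feature space) or
#'   `"toy_images"` (procedurally drawn class-distinct glyphs).
#' @param n_samples Total number of samples (before the 80/20 split).
#' @param n_classes Number of classes.
#' @param dims Feature dimension (blobs).
#' @param image_shape `c(h, w)` resolution (toy_images).
#' @param class_separation Distance scale between class centers (blobs).
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param seed Integer seed; identical specs yield identical data.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(kind = c("blobs", "toy_images"), n_samples = 1000L,
                           n_classes = 2L, dims = 2L, image_shape = c(8L, 8L),
                           class_separation = 4, noise_sd = 1, seed = 0L) {
  kind <- match.arg(kind)
  if (n_samples < n_classes) stop("need at least one sample per class")
  if (class_separation < 0) stop("class_separation must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(kind = kind, n_samples = as.integer(n_samples),
                 n_classes = as.integer(n_classes), dims = as.integer(dims),
                 image_shape = as.integer(image_shape),
                 class_separation = class_separation, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic train/test split
#'
#' Blobs place seeded class centers `class_separation` apart (for two
#' classes, exactly that Euclidean distance) with isotropic Gaussian noise;
#' toy images draw one glyph per class (horizontal bar, vertical bar, cross,
#' disc, ...) with pixel noise and one-pixel jitter, so convolutional
#' architectures can be exercised at desk scale.  The 80/20 train/test split
#' is deterministic given the seed.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `train` and `test`, each holding `x` (matrix for blobs,
#'   `(n, h, w, 1)` array for images) and 0-based integer labels `y`.
#' @export
make_synthetic <- function(spec) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  n <- spec$n_samples; K <- spec$n_classes
  y <- sample(rep_len(0:(K - 1L), n))
  if (spec$kind == "blobs") {
    # class centers: seeded random directions on a sphere of radius
    # separation/2, so two opposite centers sit `class_separation` apart
    dirs <- matrix(stats::rnorm(K * spec$dims), K, spec$dims)
    if (K == 2L) dirs[2, ] <- -dirs[1, ]
    dirs <- dirs / sqrt(rowSums(dirs^2))
    centers <- dirs * spec$class_separation / 2
    x <- centers[y + 1L, , drop = FALSE] +
      matrix(stats::rnorm(n * spec$dims, sd = spec$noise_sd), n, spec$dims)
  } else {
    hw <- spec$image_shape
    x <- array(stats::rnorm(n * hw[1] * hw[2], sd = spec$noise_sd),
               dim = c(n, hw[1], hw[2], 1L))
    jit <- cbind(sample(-1:1, n, replace = TRUE), sample(-1:1, n, replace = TRUE))
    for (i in seq_len(n))
      x[i, , , 1L] <- x[i, , , 1L] + glyph(y[i], hw, jit[i, ])
  }
  idx <- sample(n)
  n_tr <- floor(0.8 * n)
  list(train = list(x = subset_x(x, idx[seq_len(n_tr)]), y = y[idx[seq_len(n_tr)]]),
       test = list(x = subset_x(x, idx[(n_tr + 1L):n]), y = y[idx[(n_tr + 1L):n]]),
       spec = spec)
}

subset_x <- function(x, idx) {
  if (is.matrix(x)) x[idx, , drop = FALSE] else x[idx, , , , drop = FALSE]
}

# class-distinct glyphs on an h x w canvas, drawn with amplitude 2 so they
# stand clear of unit pixel noise
glyph <- function(class, hw, jitter = c(0L, 0L)) {
  h <- hw[1]; w <- hw[2]
  g <- matrix(0, h, w)
  cy <- max(2L, min(h - 1L, h %/% 2L + jitter[1]))
  cx <- max(2L, min(w - 1L, w %/% 2L + jitter[2]))
  amp <- 2
  switch((class %% 4L) + 1L,
    { g[cy, ] <- amp },                               # horizontal bar
    { g[, cx] <- amp },                               # vertical bar
    { g[cy, ] <- amp; g[, cx] <- amp },               # cross
    { for (i in seq_len(h)) for (j in seq_len(w))     # disc
        if ((i - cy)^2 + (j - cx)^2 <= (min(h, w) / 3)^2) g[i, j] <- amp })
  g
}

# ---- IDX reader ------------------------------------------------------------

#' Read an IDX-format array file (MNIST images or labels)
#'
#' Parses the big-endian IDX layout: a 4-byte magic number whose third byte
#' encodes the element type (0x08 unsigned byte, 0x0C int32, 0x0D float32,
#' 0x0E double) and whose fourth byte gives the number of dimensions,
#' followed by one big-endian int32 per dimension and the row-major payload.
#' Gzip-compressed files are accepted transparently.
#'
#' @param path Path to an IDX file (plain or gzipped).
#' @return An array with the dimensions declared in the header (a plain
#'   vector for 1-D label files); image files come back as `(n, 28, 28)`.
#' @export
read_idx <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 4L, size = 1L, signed = FALSE)
  if (magic[1] != 0L || magic[2] != 0L)
    stop(sprintf("bad IDX magic bytes: %02x %02x", magic[1], magic[2]))
  type <- magic[3]; ndim <- magic[4]
  if (ndim < 1L || ndim > 4L) stop("unsupported IDX dimensionality: ", ndim)
  dims <- readBin(con, "integer", n = ndim, size = 4L, endian = "big")
  n_el <- prod(dims)
  dat <- switch(as.character(type),
    "8" = readBin(con, "integer", n = n_el, size = 1L, signed = FALSE),
    "12" = readBin(con, "integer", n = n_el, size = 4L, endian = "big"),
    "13" = readBin(con, "double", n = n_el, size = 4L, endian = "big"),
    "14" = readBin(con, "double", n = n_el, size = 8L, endian = "big"),
    stop(sprintf("unsupported IDX element type 0x%02x", type)))
  if (length(dat) != n_el)
    stop(sprintf("truncated IDX payload: expected %d elements, got %d",
                 n_el, length(dat)))
  if (ndim == 1L) return(dat)
  # IDX payloads are row-major (last dimension fastest); R arrays are
  # column-major, so fill reversed then transpose back
  aperm(array(dat, dim = rev(dims)), rev(seq_len(ndim)))
}

# ---- CIFAR binary batches --------------------------------------------------

#' Read CIFAR-10/100 binary batch files
#'
#' Reads the standard binary batch distribution: per record one label byte
#' (CIFAR-10) or a coarse+fine label byte pair (CIFAR-100) followed by 3072
#' pixel bytes (1024 per channel, row-major).  Pixels are scaled to `[0, 1]`
#' and standardized with per-channel mean/sd computed on the training split
#' only.
#'
#' @param dir Directory holding the batch files.
#' @param variant `"cifar10"` (`data_batch_*.bin`, `test_batch.bin`) or
#'   `"cifar100"` (`train.bin`, `test.bin`).
#' @param normalize Apply the per-channel standardization.
#' @return List with `train` and `test` (`x`: `(n, 32, 32, 3)` arrays, `y`:
#'   0-based labels) and the normalization statistics used.
#' @export
read_cifar_batches <- function(dir, variant = c("cifar10", "cifar100"),
                               normalize = TRUE) {
  variant <- match.arg(variant)
  files <- if (variant == "cifar10") {
    list(train = file.path(dir, sprintf("data_batch_%d.bin", 1:5)),
         test = file.path(dir, "test_batch.bin"))
  } else {
    list(train = file.path(dir, "train.bin"), test = file.path(dir, "test.bin"))
  }
  files$train <- files$train[file.exists(files$train)]
  if (length(files$train) == 0L || !all(file.exists(files$test)))
    stop("missing CIFAR batch files in ", dir)
  read_split <- function(paths) {
    xs <- list(); ys <- list()
    rec <- 3072L + if (variant == "cifar100") 2L else 1L
    for (p in paths) {
      raw <- readBin(p, "integer", n = file.size(p), size = 1L, signed = FALSE)
      if (length(raw) %% rec != 0L) stop("corrupt CIFAR batch: ", p)
      n <- length(raw) %/% rec
      m <- matrix(raw, nrow = rec)
      ys[[length(ys) + 1L]] <- m[rec - 3072L, ]       # fine label
      px <- m[(rec - 3072L + 1L):rec, , drop = FALSE] / 255
      # layout per record: channel, then row, then column (row-major planes)
      a <- array(px, dim = c(32L, 32L, 3L, n))        # (col, row, ch, n)
      xs[[length(xs) + 1L]] <- aperm(a, c(4L, 2L, 1L, 3L))
    }
    list(x = do.call(abind1, xs), y = as.integer(unlist(ys)))
  }
  tr <- read_split(files$train); te <- read_split(files$test)
  stats <- NULL
  if (normalize) {
    stats <- lapply(1:3, function(ch) {
      v <- tr$x[, , , ch]
      list(mean = mean(v), sd = max(stats::sd(v), 1e-8))
    })
    for (ch in 1:3) {
      tr$x[, , , ch] <- (tr$x[, , , ch] - stats[[ch]]$mean) / stats[[ch]]$sd
      te$x[, , , ch] <- (te$x[, , , ch] - stats[[ch]]$mean) / stats[[ch]]$sd
    }
  }
  list(train = tr, test = te, stats = stats)
}

abind1 <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L) return(xs[[1]])
  d <- dim(xs[[1]])
  out <- array(0, dim = c(sum(vapply(xs, function(x) dim(x)[1], 0L)), d[-1]))
  at <- 0L
  for (x in xs) { out[at + seq_len(dim(x)[1]), , , ] <- x; at <- at + dim(x)[1] }
  out
}

#' Horizontal flip augmentation
#' @param x Image array `(n, h, w, c)`.
#' @return The horizontally mirrored array (an involution).
#' @export
augment_flip <- function(x) x[, , rev(seq_len(dim(x)[3])), , drop = FALSE]

#' Random-crop augmentation with zero padding
#'
#' Pads each image by `pad` pixels on every side and takes a seeded random
#' crop back to the original resolution.
#'
#' @param x Image array `(n, h, w, c)`.
#' @param pad Padding width in pixels.
#' @param seed Integer seed for the crop offsets.
#' @return Augmented array of the same shape.
#' @export
augment_crop <- function(x, pad = 4L, seed = 0L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  d <- dim(x)
  xp <- array(0, dim = c(d[1], d[2] + 2 * pad, d[3] + 2 * pad, d[4]))
  xp[, pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
  out <- array(0, dim = d)
  for (i in seq_len(d[1])) {
    oy <- sample.int(2 * pad + 1L, 1L) - 1L
    ox <- sample.int(2 * pad + 1L, 1L) - 1L
    out[i, , , ] <- xp[i, oy + seq_len(d[2]), ox + seq_len(d[3]), ]
  }
  out
}
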