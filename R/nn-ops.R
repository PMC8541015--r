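#' @useDynLib cascadeseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd aggregate
#' @importFrom utils write.table read.delim modifyList
NULL

# ---- tensor helpers ---------------------------------------------------------
# Feature tensors are numeric arrays with dim (H, W, C, N).

as_tensor <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("input must be a matrix or array")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("input must have 2..4 dimensions")
  storage.mode(x) <- "double"
  x
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

relu_bwd <- function(gy, pre) {
  gy * (pre > 0)
}

# softmax over the channel axis of an (H, W, C, N) tensor
softmax_channels <- function(logits) {
  d <- dim(logits)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  out <- logits
  for (n in seq_len(N)) {
    m <- matrix(logits[, , , n], H * W, C)
    m <- m - apply(m, 1L, max)
    e <- exp(m)
    out[, , , n] <- e / rowSums(e)
  }
  out
}

# ---- compiled-kernel wrappers ----------------------------------------------

conv2d <- function(x, w, b, dilation = 1L) {
  cpp_conv2d_fwd(x, w, b, as.integer(dilation))
}

conv2d_bwd <- function(x, w, gy, dilation = 1L) {
  cpp_conv2d_bwd(x, w, gy, as.integer(dilation))
}

upconv2 <- function(x, w, b) cpp_convt2_fwd(x, w, b)
upconv2_bwd <- function(x, w, gy) cpp_convt2_bwd(x, w, gy)

maxpool2 <- function(x) cpp_maxpool2_fwd(x)
maxpool2_bwd <- function(gy, idx, H, W) {
  cpp_maxpool2_bwd(gy, idx, as.integer(H), as.integer(W))
}

resize_bilinear <- function(x, h, w) {
  was_mat <- is.matrix(x)
  y <- cpp_resize_bilinear_fwd(as_tensor(x), as.integer(h), as.integer(w))
  if (was_mat) dim(y) <- c(h, w)
  y
}
resize_bilinear_bwd <- function(gy, h, w) {
  cpp_resize_bilinear_bwd(gy, as.integer(h), as.integer(w))
}

concat_channels <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1L]])
  C <- sum(vapply(xs, function(x) dim(x)[3L], integer(1)))
  out <- array(0, c(d[1L], d[2L], C, d[4L]))
  at <- 0L
  for (x in xs) {
    ci <- dim(x)[3L]
    out[, , at + seq_len(ci), ] <- x
    at <- at + ci
  }
  out
}

split_channels <- function(x, sizes) {
  at <- 0L
  lapply(sizes, function(ci) {
    s <- x[, , at + seq_len(ci), , drop = FALSE]
    at <<- at + ci
    s
  })
}

# ---- parameter initialisation ----------------------------------------------

init_conv <- function(k, cin, cout, gain = 2) {
  w <- array(rnorm(k * k * cin * cout, sd = sqrt(gain / (k * k * cin))),
             c(k, k, cin, cout))
  list(w = w, b = numeric(cout))
}

init_upconv <- function(cin, cout) {
  w <- array(rnorm(4 * cin * cout, sd = sqrt(2 / (4 * cin))),
             c(2L, 2L, cin, cout))
  list(w = w, b = numeric(cout))
}

# ---- parameter-tree utilities ----------------------------------------------

tree_map <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1L]])) {
    out <- lapply(seq_along(trees[[1L]]), function(i) {
      do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    })
    names(out) <- names(trees[[1L]])
    out
  } else {
    do.call(f, trees)
  }
}

tree_leaves <- function(tree) {
  if (!is.list(tree)) return(list(tree))
  unlist(lapply(tree, tree_leaves), recursive = FALSE)
}

n_parameters <- function(params) {
  sum(vapply(tree_leaves(params), length, numeric(1)))
}

zeros_like <- function(tree) tree_map(function(x) x * 0, tree)

# ---- Adam optimiser ---------------------------------------------------------

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g * g,
                      state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- tree_map(function(p, m, v) {
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}
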