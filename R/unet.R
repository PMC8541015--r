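#' Configuration of the coarse-stage U-Net
#'
#' The classic encoder-decoder: per encoder level two 3x3 convolutions with
#' rectification, then 2x2 max pooling with channel doubling; per decoder
#' level a 2x2 transposed convolution halving the channels, concatenation
#' with the same-level encoder features, and two 3x3 convolutions; a final
#' 1x1 convolution maps to the class logits. With the default depth 4 this
#' gives 23 convolutional layers (transposed and 1x1 included). All 3x3
#' convolutions use "same" padding so the output resolution equals the input
#' resolution. Softmax (not per-class sigmoid) is applied downstream because
#' the three classes are mutually exclusive.
#'
#' @param in_channels input channels (1 for a windowed CT slice).
#' @param base_width channels at the first level; doubled at each descent.
#' @param depth number of down-sampling steps (`>= 1`).
#' @param n_classes number of output classes.
#' @return an object of class `unet_config`.
#' @export
unet_config <- function(in_channels = 1L, base_width = 64L, depth = 4L,
                        n_classes = 3L) {
  stopifnot(depth >= 1L, base_width >= 1L)
  structure(list(in_channels = as.integer(in_channels),
                 base_width = as.integer(base_width),
                 depth = as.integer(depth),
                 n_classes = as.integer(n_classes)),
            class = "unet_config")
}

#' Channel widths down the contracting path
#' @param cfg a [unet_config()].
#' @return integer vector of length `depth + 1`.
#' @export
unet_channel_widths <- function(cfg) {
  cfg$base_width * 2L^(0:cfg$depth)
}

#' Number of convolutional layers in the network
#'
#' Counts every trainable convolution: two per encoder level, one transposed
#' plus two plain per decoder level, and the final 1x1 classifier.
#'
#' @param cfg a [unet_config()].
#' @return integer layer count (`5 * depth + 3`; 23 at the default depth 4).
#' @export
unet_conv_layer_count <- function(cfg) {
  length(build_unet(cfg, init = FALSE)$layout)
}

#' Build (initialise) a coarse U-Net
#'
#' @param cfg a [unet_config()].
#' @param init if `FALSE`, only the layer layout is returned (no weights).
#' @return list with `cfg`, `params` (nested weight arrays) and `layout`.
#' @export
build_unet <- function(cfg, init = TRUE) {
  stopifnot(inherits(cfg, "unet_config"))
  widths <- unet_channel_widths(cfg)
  layout <- list()
  params <- list(enc = list(), dec = list())
  for (l in seq_len(cfg$depth + 1L)) {
    cin <- if (l == 1L) cfg$in_channels else widths[l - 1L]
    layout <- c(layout, list(c(3, cin, widths[l]), c(3, widths[l], widths[l])))
    if (init) {
      params$enc[[l]] <- list(conv1 = init_conv(3L, cin, widths[l]),
                              conv2 = init_conv(3L, widths[l], widths[l]))
    }
  }
  for (l in rev(seq_len(cfg$depth))) {
    layout <- c(layout, list(c(2, widths[l + 1L], widths[l]),
                             c(3, 2L * widths[l], widths[l]),
                             c(3, widths[l], widths[l])))
    if (init) {
      params$dec[[l]] <- list(up = init_upconv(widths[l + 1L], widths[l]),
                              conv1 = init_conv(3L, 2L * widths[l], widths[l]),
                              conv2 = init_conv(3L, widths[l], widths[l]))
    }
  }
  layout <- c(layout, list(c(1, widths[1L], cfg$n_classes)))
  if (init) params$final <- init_conv(1L, widths[1L], cfg$n_classes, gain = 1)
  structure(list(cfg = cfg, params = if (init) params else NULL,
                 layout = layout),
            class = "unet")
}

check_unet_input <- function(net, x) {
  d <- dim(x)
  down <- 2L^net$cfg$depth
  if (d[1L] %% down != 0L || d[2L] %% down != 0L) {
    stop("input side ", d[1L], "x", d[2L], " is not divisible by 2^depth = ",
         down, "; pad or crop the slice, or reduce the network depth")
  }
  if (d[3L] != net$cfg$in_channels) {
    stop("input has ", d[3L], " channels, network expects ",
         net$cfg$in_channels)
  }
  if (!all(is.finite(x))) stop("non-finite values in network input")
  invisible(TRUE)
}

# double conv with relu; returns output and the cache needed for backprop
dconv_fwd <- function(p, x) {
  pre1 <- conv2d(x, p$conv1$w, p$conv1$b)
  a1 <- relu(pre1)
  pre2 <- conv2d(a1, p$conv2$w, p$conv2$b)
  list(y = relu(pre2), x = x, pre1 = pre1, a1 = a1, pre2 = pre2)
}

dconv_bwd <- function(p, cache, gy) {
  g2 <- relu_bwd(gy, cache$pre2)
  b2 <- conv2d_bwd(cache$a1, p$conv2$w, g2)
  g1 <- relu_bwd(b2$gx, cache$pre1)
  b1 <- conv2d_bwd(cache$x, p$conv1$w, g1)
  list(gx = b1$gx,
       gp = list(conv1 = list(w = b1$gw, b = b1$gb),
                 conv2 = list(w = b2$gw, b = b2$gb)))
}

#' Forward pass of the coarse U-Net
#'
#' @param net a [build_unet()] network.
#' @param x input tensor `(H, W, C, N)` (or matrix for one slice).
#' @param want_cache keep intermediate activations for a backward pass.
#' @return list with `logits` `(H, W, n_classes, N)` and optionally `cache`.
#' @export
unet_forward <- function(net, x, want_cache = FALSE) {
  x <- as_tensor(x)
  check_unet_input(net, x)
  depth <- net$cfg$depth
  cache <- list(enc = vector("list", depth + 1L),
                pool = vector("list", depth),
                dec = vector("list", depth))
  skips <- vector("list", depth + 1L)
  h <- x
  for (l in seq_len(depth + 1L)) {
    cc <- dconv_fwd(net$params$enc[[l]], h)
    cache$enc[[l]] <- cc
    skips[[l]] <- cc$y
    if (l <= depth) {
      mp <- maxpool2(cc$y)
      cache$pool[[l]] <- list(idx = mp$idx, H = dim(cc$y)[1L],
                              W = dim(cc$y)[2L])
      h <- mp$y
    } else {
      h <- cc$y
    }
  }
  for (l in rev(seq_len(depth))) {
    p <- net$params$dec[[l]]
    up <- upconv2(h, p$up$w, p$up$b)
    cat_in <- concat_channels(skips[[l]], up)
    cc <- dconv_fwd(p, cat_in)
    cache$dec[[l]] <- list(up_in = h, up = up, cat = cat_in, dc = cc)
    h <- cc$y
  }
  logits <- conv2d(h, net$params$final$w, net$params$final$b)
  cache$top <- h
  if (want_cache) list(logits = logits, cache = cache)
  else list(logits = logits)
}

# backward pass; returns parameter gradients with the same tree shape
unet_backward <- function(net, cache, glogits) {
  depth <- net$cfg$depth
  gp <- list(enc = vector("list", depth + 1L),
             dec = vector("list", depth))
  fb <- conv2d_bwd(cache$top, net$params$final$w, glogits)
  gp$final <- list(w = fb$gw, b = fb$gb)
  gh <- fb$gx
  gskips <- vector("list", depth + 1L)
  for (l in seq_len(depth)) {
    p <- net$params$dec[[l]]
    cc <- cache$dec[[l]]
    db <- dconv_bwd(p, cc$dc, gh)
    skip_c <- dim(cc$cat)[3L] %/% 2L
    parts <- split_channels(db$gx, c(skip_c, skip_c))
    gskips[[l]] <- parts[[1L]]
    ub <- upconv2_bwd(cc$up_in, p$up$w, parts[[2L]])
    # same element order as params$dec[[l]] so the optimizer trees line up
    gp$dec[[l]] <- list(up = list(w = ub$gw, b = ub$gb),
                        conv1 = db$gp$conv1, conv2 = db$gp$conv2)
    gh <- ub$gx
  }
  for (l in rev(seq_len(depth + 1L))) {
    if (l <= depth) {
      pl <- cache$pool[[l]]
      g <- maxpool2_bwd(gh, pl$idx, pl$H, pl$W) + gskips[[l]]
    } else {
      g <- gh
    }
    db <- dconv_bwd(net$params$enc[[l]], cache$enc[[l]], g)
    gp$enc[[l]] <- db$gp
    gh <- db$gx
  }
  gp
}

#' Coarse-stage prediction: probability map for one slice or batch
#'
#' @param net a [build_unet()] network.
#' @param image input slice matrix or `(H, W, C, N)` tensor.
#' @return probability tensor `(H, W, n_classes, N)`; per-pixel values lie on
#'   the unit simplex.
#' @export
coarse_forward <- function(net, image) {
  out <- unet_forward(net, image)
  softmax_channels(out$logits)
}
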