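#' Configuration of the fine-stage refinement network
#'
#' The fine stage processes the fused image-plus-prior at several resolutions.
#' Each resolution branch applies a 3x3 stem convolution, a densely connected
#' atrous spatial pyramid pooling block (the "ADense" block: every dilated
#' layer receives the block input concatenated with all previous layer
#' outputs), and multi-layered channel attention; branch features are
#' bilinearly up-sampled to full resolution, summed, and a final convolution
#' with softmax emits the refined 3-class probability map.
#'
#' @param width common channel width of the branches (stem output).
#' @param growth_rate channels added by each dense dilated layer.
#' @param dilation_rates dilation per dense layer; every rate must be below
#'   24, beyond which dilated convolution samples too sparsely to be
#'   effective.
#' @param attention_K odd length of the shared 1-D convolution applied across
#'   the channel axis of the pooled descriptors.
#' @param branch_kernels kernel sizes of the three attention input
#'   convolutions (three scales of local context).
#' @param resolutions down-scale factors of the input branches; factor 1 is
#'   the native resolution (512 -> 512, 256, 128 with the defaults).
#' @param use_attention disable to ablate the attention mechanism.
#' @param in_channels input channels of the fused map.
#' @param n_classes output classes.
#' @return an object of class `adense_config`.
#' @export
adense_config <- function(width = 32L, growth_rate = 32L,
                          dilation_rates = c(1L, 3L, 6L, 12L),
                          attention_K = 3L,
                          branch_kernels = c(1L, 3L, 5L),
                          resolutions = c(1L, 2L, 4L),
                          use_attention = TRUE,
                          in_channels = 1L, n_classes = 3L) {
  if (any(dilation_rates < 1L)) stop("dilation rates must be >= 1")
  if (any(dilation_rates >= 24L)) {
    stop("dilation rate >= 24: at such rates dilated convolution samples ",
         "too sparsely and becomes ineffective")
  }
  if (attention_K %% 2L == 0L) stop("attention_K must be odd")
  if (length(branch_kernels) != 3L) stop("exactly three branch kernels")
  if (use_attention && width < attention_K) {
    stop("channel width (", width, ") must be at least attention_K (",
         attention_K, ")")
  }
  structure(list(width = as.integer(width),
                 growth_rate = as.integer(growth_rate),
                 dilation_rates = as.integer(dilation_rates),
                 n_layers = length(dilation_rates),
                 attention_K = as.integer(attention_K),
                 branch_kernels = as.integer(branch_kernels),
                 resolutions = as.integer(resolutions),
                 use_attention = isTRUE(use_attention),
                 in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes)),
            class = "adense_config")
}

#' Fuse the coarse probability map with the input slice
#'
#' The input intensities are min-max normalised to `[0, 1]` and the summed
#' foreground probability (liver + tumor) is added elementwise, keeping a
#' single channel. A constant slice normalises to all zeros.
#'
#' @param prob coarse probability tensor `(H, W, 3[, 1])`.
#' @param image the corresponding input slice matrix.
#' @return fused single-channel matrix, same height/width as the slice.
#' @export
fuse_coarse <- function(prob, image) {
  prob <- as_tensor(prob)
  d <- dim(prob)
  if (d[1L] != nrow(image) || d[2L] != ncol(image)) {
    stop("probability map (", d[1L], "x", d[2L], ") and image (",
         nrow(image), "x", ncol(image), ") shapes differ")
  }
  norm01(image) + prob[, , 2L, 1L] + prob[, , 3L, 1L]
}

norm01 <- function(x) {
  rng <- range(x)
  if (rng[2] == rng[1]) return(x * 0)
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Build the multi-resolution branch inputs
#'
#' Factor 1 passes the fused map through; larger factors down-scale it
#' bilinearly (512 -> 256 and 128 with the default factors).
#'
#' @param fused fused single-channel matrix from [fuse_coarse()].
#' @param factors integer down-scale factors.
#' @return list of matrices, one per factor.
#' @export
build_multires_inputs <- function(fused, factors = c(1L, 2L, 4L)) {
  h <- nrow(fused); w <- ncol(fused)
  mf <- max(factors)
  if (h %% mf != 0L || w %% mf != 0L) {
    stop("input side ", h, "x", w, " is not divisible by the largest ",
         "down-scale factor ", mf)
  }
  lapply(factors, function(f) {
    if (f == 1L) fused else resize_bilinear(fused, h %/% f, w %/% f)
  })
}

# ---- ADense block -----------------------------------------------------------

#' Channel plan of an ADense block
#'
#' @param cin block input channels.
#' @param cfg an [adense_config()].
#' @return list with `layer_in` (input channels of each dilated layer) and
#'   `concat` (channels entering the 1x1 projection).
#' @export
adense_channel_plan <- function(cin, cfg) {
  g <- cfg$growth_rate
  list(layer_in = cin + (seq_len(cfg$n_layers) - 1L) * g,
       concat = cin + cfg$n_layers * g)
}

adense_init <- function(cin, cfg) {
  plan <- adense_channel_plan(cin, cfg)
  layers <- lapply(seq_len(cfg$n_layers), function(i) {
    init_conv(3L, plan$layer_in[i], cfg$growth_rate)
  })
  list(layers = layers, proj = init_conv(1L, plan$concat, cin))
}

#' Apply an ADense block
#'
#' Dilated layer `i` receives the concatenation of the block input and all
#' previous layer outputs, and produces `growth_rate` channels with a 3x3
#' convolution at `dilation_rates[i]` followed by rectification; the final
#' concatenation is projected back to the input channel count by a 1x1
#' convolution, also rectified. Spatial dimensions are preserved throughout.
#'
#' @param x input tensor `(H, W, C, N)`.
#' @param params block parameters from the network builder.
#' @param cfg an [adense_config()].
#' @param want_cache keep activations for the backward pass.
#' @return output tensor with the same shape as `x` (plus `cache` on request).
#' @export
adense_block <- function(x, params, cfg, want_cache = FALSE) {
  feats <- x
  cache <- list(inputs = vector("list", cfg$n_layers),
                pres = vector("list", cfg$n_layers))
  for (i in seq_len(cfg$n_layers)) {
    cache$inputs[[i]] <- feats
    pre <- conv2d(feats, params$layers[[i]]$w, params$layers[[i]]$b,
                  dilation = cfg$dilation_rates[i])
    cache$pres[[i]] <- pre
    feats <- concat_channels(feats, relu(pre))
  }
  cache$concat <- feats
  pre <- conv2d(feats, params$proj$w, params$proj$b)
  cache$pre_proj <- pre
  y <- relu(pre)
  if (want_cache) list(y = y, cache = cache) else y
}

adense_bwd <- function(params, cfg, cache, gy) {
  gy <- relu_bwd(gy, cache$pre_proj)
  pb <- conv2d_bwd(cache$concat, params$proj$w, gy)
  gp <- list(layers = vector("list", cfg$n_layers),
             proj = list(w = pb$gw, b = pb$gb))
  g <- cfg$growth_rate
  cin <- dim(cache$inputs[[1L]])[3L]
  gcat <- pb$gx  # gradient on [x, o_1, ..., o_L]
  for (i in rev(seq_len(cfg$n_layers))) {
    ci <- cin + (i - 1L) * g
    go <- gcat[, , ci + seq_len(g), , drop = FALSE]
    gfeats <- gcat[, , seq_len(ci), , drop = FALSE]
    gpre <- relu_bwd(go, cache$pres[[i]])
    cb <- conv2d_bwd(cache$inputs[[i]], params$layers[[i]]$w, gpre,
                     dilation = cfg$dilation_rates[i])
    gp$layers[[i]] <- list(w = cb$gw, b = cb$gb)
    gcat <- gfeats + cb$gx
  }
  list(gx = gcat, gp = gp)
}

# ---- multi-layered channel attention ---------------------------------------

attention_init <- function(cin, cfg) {
  convs <- lapply(cfg$branch_kernels, function(k) init_conv(k, cin, cin))
  list(convs = convs,
       kvec = rnorm(cfg$attention_K, sd = 1 / sqrt(cfg$attention_K)))
}

# 1-D convolution across the channel axis, zero ("same") padding.
# V: C x M matrix (one column per sample), k: length-K kernel.
conv1d_same <- function(V, k) {
  r <- (length(k) - 1L) %/% 2L
  C <- nrow(V)
  pad <- rbind(matrix(0, r, ncol(V)), V, matrix(0, r, ncol(V)))
  out <- V * 0
  for (t in seq_along(k)) {
    out <- out + k[t] * pad[(t - 1L) + seq_len(C), , drop = FALSE]
  }
  out
}

conv1d_bwd <- function(V, k, gs) {
  r <- (length(k) - 1L) %/% 2L
  C <- nrow(V)
  gV <- conv1d_same(gs, rev(k))
  pad <- rbind(matrix(0, r, ncol(V)), V, matrix(0, r, ncol(V)))
  gk <- vapply(seq_along(k), function(t) {
    sum(pad[(t - 1L) + seq_len(C), , drop = FALSE] * gs)
  }, numeric(1))
  list(gV = gV, gk = gk)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Apply multi-layered channel attention
#'
#' The input passes through three rectified convolutions of different kernel
#' sizes, forming three branches. Per branch, global max pooling and global average
#' pooling each yield a channel descriptor; both descriptors pass through one
#' shared K-length 1-D convolution across the channel axis, their sum is
#' squashed by the sigmoid into per-channel weights in `(0, 1)`, and the
#' branch features are rescaled channel-wise by those weights. The three
#' calibrated branches are summed elementwise.
#'
#' @param x input tensor `(H, W, C, N)` with `C >= attention_K`.
#' @param params attention parameters from the network builder.
#' @param cfg an [adense_config()].
#' @param want_cache keep activations for the backward pass.
#' @return tensor with the shape of `x` (plus `cache`/`weights` on request).
#' @export
channel_attention <- function(x, params, cfg, want_cache = FALSE) {
  d <- dim(x)
  C <- d[3L]; N <- d[4L]; HW <- d[1L] * d[2L]
  if (C < cfg$attention_K) {
    stop("channel count (", C, ") below attention kernel length (",
         cfg$attention_K, ")")
  }
  y <- 0
  cache <- list(branches = vector("list", 3L), x = x)
  weights <- vector("list", 3L)
  for (j in 1:3) {
    pre_u <- conv2d(x, params$convs[[j]]$w, params$convs[[j]]$b)
    u <- relu(pre_u)
    um <- matrix(u, HW, C * N)
    amax <- max.col(t(um), ties.method = "first")
    m <- matrix(um[cbind(amax, seq_len(C * N))], C, N)
    a <- matrix(colMeans(um), C, N)
    s <- conv1d_same(m, params$kvec) + conv1d_same(a, params$kvec)
    z <- sigmoid(s)
    zmap <- array(rep(as.numeric(z), each = HW), d)
    y <- y + u * zmap
    cache$branches[[j]] <- list(u = u, pre_u = pre_u, amax = amax, m = m,
                                a = a, z = z, zmap = zmap)
    weights[[j]] <- z
  }
  if (want_cache) list(y = y, cache = cache, weights = weights) else y
}

attention_bwd <- function(params, cfg, cache, gy) {
  x <- cache$x
  d <- dim(x)
  C <- d[3L]; N <- d[4L]; HW <- d[1L] * d[2L]
  gx <- 0
  gk <- params$kvec * 0
  gconvs <- vector("list", 3L)
  for (j in 1:3) {
    br <- cache$branches[[j]]
    gu <- gy * br$zmap
    gz <- matrix(colSums(matrix(gy * br$u, HW, C * N)), C, N)
    gs <- gz * br$z * (1 - br$z)
    bm <- conv1d_bwd(br$m, params$kvec, gs)
    ba <- conv1d_bwd(br$a, params$kvec, gs)
    gk <- gk + bm$gk + ba$gk
    # scatter the max-pool gradient to the argmax positions
    gum <- matrix(0, HW, C * N)
    gum[cbind(br$amax, seq_len(C * N))] <- as.numeric(bm$gV)
    gum <- gum + matrix(rep(as.numeric(ba$gV), each = HW) / HW, HW, C * N)
    gu <- gu + array(gum, d)
    gu <- relu_bwd(gu, br$pre_u)
    cb <- conv2d_bwd(x, params$convs[[j]]$w, gu)
    gconvs[[j]] <- list(w = cb$gw, b = cb$gb)
    gx <- gx + cb$gx
  }
  list(gx = gx, gp = list(convs = gconvs, kvec = gk))
}

# ---- full fine network ------------------------------------------------------

#' Build (initialise) the fine-stage network
#'
#' @param cfg an [adense_config()].
#' @return list with `cfg` and `params`.
#' @export
build_adensenet <- function(cfg) {
  stopifnot(inherits(cfg, "adense_config"))
  C <- cfg$width
  branches <- lapply(cfg$resolutions, function(f) {
    p <- list(stem = init_conv(3L, cfg$in_channels, C),
              dense = adense_init(C, cfg))
    if (cfg$use_attention) p$att <- attention_init(C, cfg)
    p
  })
  params <- list(branches = branches,
                 final = init_conv(3L, C, cfg$n_classes, gain = 1))
  structure(list(cfg = cfg, params = params), class = "adensenet")
}

#' Forward pass of the fine-stage network
#'
#' @param net a [build_adensenet()] network.
#' @param branch_inputs list of per-resolution inputs as produced by
#'   [build_multires_inputs()] (matrices or `(H, W, 1, N)` tensors).
#' @param want_cache keep activations for the backward pass.
#' @return list with `probs` (full-resolution probability tensor), `logits`,
#'   and optionally `cache`.
#' @export
fine_forward <- function(net, branch_inputs, want_cache = FALSE) {
  cfg <- net$cfg
  if (length(branch_inputs) != length(cfg$resolutions)) {
    stop("got ", length(branch_inputs), " branch inputs but the network is ",
         "configured for ", length(cfg$resolutions), " resolutions")
  }
  branch_inputs <- lapply(branch_inputs, as_tensor)
  full <- dim(branch_inputs[[1L]])
  H <- full[1L]; W <- full[2L]
  fused <- 0
  cache <- list(branches = vector("list", length(branch_inputs)))
  for (b in seq_along(branch_inputs)) {
    p <- net$params$branches[[b]]
    xb <- branch_inputs[[b]]
    pre_stem <- conv2d(xb, p$stem$w, p$stem$b)
    h <- relu(pre_stem)
    dc <- adense_block(h, p$dense, cfg, want_cache = TRUE)
    h2 <- dc$y
    if (cfg$use_attention) {
      at <- channel_attention(h2, p$att, cfg, want_cache = TRUE)
      h3 <- at$y
    } else {
      at <- NULL
      h3 <- h2
    }
    up <- if (all(dim(h3)[1:2] == c(H, W))) h3 else {
      cpp_resize_bilinear_fwd(h3, H, W)
    }
    fused <- fused + up
    cache$branches[[b]] <- list(x = xb, pre_stem = pre_stem, stem_out = h,
                                dense = dc$cache, att = at,
                                bdim = dim(h3))
  }
  logits <- conv2d(fused, net$params$final$w, net$params$final$b)
  cache$fused <- fused
  out <- list(logits = logits, probs = softmax_channels(logits))
  if (want_cache) out$cache <- cache
  out
}

fine_backward <- function(net, cache, glogits) {
  cfg <- net$cfg
  fb <- conv2d_bwd(cache$fused, net$params$final$w, glogits)
  gfused <- fb$gx
  gbranches <- vector("list", length(cache$branches))
  for (b in seq_along(cache$branches)) {
    cc <- cache$branches[[b]]
    p <- net$params$branches[[b]]
    bd <- cc$bdim
    gup <- if (all(bd[1:2] == dim(gfused)[1:2])) gfused else {
      cpp_resize_bilinear_bwd(gfused, bd[1L], bd[2L])
    }
    gp <- list()
    if (cfg$use_attention) {
      ab <- attention_bwd(p$att, cfg, cc$att$cache, gup)
      gp$att <- ab$gp
      g <- ab$gx
    } else {
      g <- gup
    }
    db <- adense_bwd(p$dense, cfg, cc$dense, g)
    gp$dense <- db$gp
    gstem <- relu_bwd(db$gx, cc$pre_stem)
    sb <- conv2d_bwd(cc$x, p$stem$w, gstem)
    gp$stem <- list(w = sb$gw, b = sb$gb)
    gbranches[[b]] <- gp[c("stem", "dense", if (cfg$use_attention) "att")]
  }
  list(branches = gbranches, final = list(w = fb$gw, b = fb$gb))
}
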