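test_that("coarse-prior fusion adds foreground probability to intensities", {
  img <- matrix(5, 4, 4)  # constant -> normalises to zero
  prob <- array(1 / 3, c(4, 4, 3, 1))
  fused <- fuse_coarse(prob, img)
  expect_equal(fused, matrix(2 / 3, 4, 4))

  img2 <- matrix(seq(0, 1, length.out = 16), 4, 4)
  zero_fg <- array(0, c(4, 4, 3, 1))
  zero_fg[, , 1, ] <- 1
  expect_equal(fuse_coarse(zero_fg, img2), img2)

  # localized prior: the fused minus normalized image is its indicator
  spot <- array(0, c(4, 4, 3, 1))
  spot[, , 1, ] <- 1
  spot[1:2, 1, 2, 1] <- 1
  spot[1:2, 1, 1, 1] <- 0
  delta <- fuse_coarse(spot, img2) - img2
  expect_equal(delta, matrix(c(1, 1, rep(0, 14)), 4, 4))

  expect_error(fuse_coarse(array(1 / 3, c(4, 4, 3, 1)), matrix(0, 8, 8)),
               "differ")
})

test_that("multi-resolution branches have the prescribed side lengths", {
  f512 <- matrix(0, 512, 512)
  sides <- vapply(build_multires_inputs(f512), nrow, integer(1))
  expect_equal(sides, c(512L, 256L, 128L))

  f128 <- matrix(rnorm(128 * 128), 128, 128)
  sides <- vapply(build_multires_inputs(f128), nrow, integer(1))
  expect_equal(sides, c(128L, 64L, 32L))

  # constant image stays constant on every branch
  const <- matrix(2.5, 16, 16)
  for (b in build_multires_inputs(const)) {
    expect_equal(unique(as.numeric(b)), 2.5)
  }
  expect_error(build_multires_inputs(matrix(0, 10, 10)), "divisible")
})

test_that("configuration validation enforces the dilation and kernel rules", {
  expect_error(adense_config(dilation_rates = c(1, 24)), "ineffective")
  expect_error(adense_config(dilation_rates = c(0, 2)), ">= 1")
  expect_error(adense_config(attention_K = 4L), "odd")
  expect_error(adense_config(width = 2L, attention_K = 5L), "at least")
})

test_that("ADense block channel arithmetic matches the dense closed form", {
  cfg <- adense_config(width = 8L, growth_rate = 4L,
                       dilation_rates = c(1L, 2L, 3L))
  plan <- adense_channel_plan(8L, cfg)
  expect_equal(plan$layer_in, c(8L, 12L, 16L))
  expect_equal(plan$concat, 20L)

  params <- ns$adense_init(8L, cfg)
  expect_length(params$layers, 3L)  # trainable convs = n_layers + 1 (proj)
  for (i in 1:3) {
    expect_equal(dim(params$layers[[i]]$w),
                 c(3L, 3L, plan$layer_in[i], 4L))
  }
  expect_equal(dim(params$proj$w), c(1L, 1L, 20L, 8L))

  # random configurations obey the closed form
  set.seed(3)
  for (i in 1:5) {
    g <- sample(2:6, 1)
    L <- sample(1:4, 1)
    cin <- sample(3:10, 1)
    p <- adense_channel_plan(cin, adense_config(
      width = cin, growth_rate = g, dilation_rates = sample(1:12, L)))
    expect_equal(p$layer_in, cin + (seq_len(L) - 1) * g)
    expect_equal(p$concat, cin + L * g)
  }
})

test_that("ADense block preserves shape and degenerates to a plain conv", {
  set.seed(8)
  cfg1 <- adense_config(width = 4L, growth_rate = 4L, dilation_rates = 1L)
  p1 <- ns$adense_init(4L, cfg1)
  x <- array(rnorm(10 * 10 * 4 * 2), c(10, 10, 4, 2))
  y <- adense_block(x, p1, cfg1)
  expect_equal(dim(y), dim(x))

  # one layer at dilation 1: conv3x3 -> relu -> 1x1 projection -> relu, by hand
  manual <- ns$relu(ns$conv2d(ns$concat_channels(
    x, ns$relu(ns$conv2d(x, p1$layers[[1]]$w, p1$layers[[1]]$b))),
    p1$proj$w, p1$proj$b))
  expect_equal(y, manual)
})

test_that("receptive field of the dense dilated stack grows as prescribed", {
  set.seed(10)
  cfg <- adense_config(width = 2L, growth_rate = 2L,
                       dilation_rates = c(1L, 3L, 6L, 12L),
                       attention_K = 1L, use_attention = FALSE)
  p <- ns$tree_map(function(a) abs(a) + 0.01, ns$adense_init(2L, cfg))
  side <- 51L
  ctr <- 26L
  x <- array(abs(rnorm(side * side * 2)) + 0.1, c(side, side, 2, 1))
  full <- adense_block(x, p, cfg)[ctr, ctr, , 1]
  # theoretical receptive radius: stacked dilations 1+3+6+12 = 22
  mask_radius <- function(r) {
    xm <- x
    d <- abs(row(matrix(0, side, side)) - ctr)
    e <- abs(col(matrix(0, side, side)) - ctr)
    outside <- pmax(d, e) > r
    for (c in 1:2) {
      sl <- xm[, , c, 1]
      sl[outside] <- 0
      xm[, , c, 1] <- sl
    }
    adense_block(xm, p, cfg)[ctr, ctr, , 1]
  }
  expect_equal(mask_radius(22L), full)        # no influence beyond radius 22
  expect_false(isTRUE(all.equal(mask_radius(5L), full)))  # inside: changes
})

test_that("channel attention calibrates channels within (0, 1)", {
  set.seed(13)
  cfg <- tiny_adense_cfg(width = 6L)
  p <- ns$attention_init(6L, cfg)
  x <- array(rnorm(8 * 8 * 6 * 2), c(8, 8, 6, 2))
  out <- channel_attention(x, p, cfg, want_cache = TRUE)
  expect_equal(dim(out$y), dim(x))
  for (z in out$weights) {
    expect_true(all(z > 0 & z < 1))
  }

  # constant channel scales exactly by its weight
  br <- out$cache$branches[[2]]
  uc <- br$u
  uc[, , 3, 1] <- 7  # overwrite one branch channel with a constant
  calibrated <- uc[, , 3, 1] * br$z[3, 1]
  expect_equal(unique(as.numeric(calibrated)), 7 * br$z[3, 1])

  # scale-aware, not scale-invariant: amplifying a channel moves weights
  x10 <- x
  x10[, , 2, ] <- 10 * x10[, , 2, ]
  out10 <- channel_attention(x10, p, cfg, want_cache = TRUE)
  expect_false(isTRUE(all.equal(out10$weights[[1]], out$weights[[1]])))

  expect_error(channel_attention(array(0, c(4, 4, 2, 1)), p,
                                 tiny_adense_cfg(width = 6L, attention_K = 3L)),
               "channel count")
})

test_that("fine forward emits a full-resolution simplex map", {
  set.seed(17)
  cfg <- tiny_adense_cfg()
  net <- build_adensenet(cfg)
  fused <- matrix(rnorm(128 * 128), 128, 128)
  binputs <- build_multires_inputs(fused, cfg$resolutions)
  out <- fine_forward(net, binputs)
  expect_equal(dim(out$probs), c(128L, 128L, 3L, 1L))
  sums <- apply(out$probs, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  expect_identical(fine_forward(net, binputs)$probs, out$probs)
  expect_error(fine_forward(net, binputs[1]), "branch inputs")
})

test_that("fine network gradients agree with finite differences", {
  set.seed(19)
  cfg <- tiny_adense_cfg()
  net <- build_adensenet(cfg)
  fused <- matrix(rnorm(64), 8, 8)
  binputs <- build_multires_inputs(fused, cfg$resolutions)
  truth <- array(sample(0:2, 64, TRUE), c(8, 8, 1))
  w <- c(1, 3, 10)
  out <- fine_forward(net, binputs, want_cache = TRUE)
  gr <- ns$fine_backward(net, out$cache,
                         ns$wce_logit_grad(out$probs, truth, w))
  leaves_p <- ns$tree_leaves(net$params)
  leaves_g <- ns$tree_leaves(gr)
  expect_equal(length(leaves_p), length(leaves_g))
  offs <- cumsum(c(0, vapply(leaves_p, length, numeric(1))))
  flat <- unlist(net$params)
  lossfn <- function(v) {
    net$params <- ns$tree_map(function(a, b) { dim(b) <- dim(a); b },
                              net$params, utils::relist(v, net$params))
    weighted_cross_entropy(fine_forward(net, binputs)$probs, truth, w)
  }
  for (rep in 1:12) {
    li <- sample(length(leaves_p), 1)
    ci <- sample(length(leaves_p[[li]]), 1)
    fi <- offs[li] + ci
    eps <- 1e-5
    up <- flat; up[fi] <- up[fi] + eps
    dn <- flat; dn[fi] <- dn[fi] - eps
    num <- (lossfn(up) - lossfn(dn)) / (2 * eps)
    expect_equal(leaves_g[[li]][ci], num, tolerance = 1e-4)
  }
})
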