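test_that("class proportions count pixels and normalise", {
  m <- matrix(c(0L, 0L, 1L, 2L), 2, 2)
  expect_equal(unname(class_proportions(m)), c(0.5, 0.25, 0.25))
  expect_equal(unname(class_proportions(matrix(1L, 3, 3))), c(0, 1, 0))
  set.seed(4)
  for (i in 1:10) {
    expect_equal(sum(class_proportions(random_mask())), 1)
  }
  expect_error(class_proportions(list()), "at least one")
})

test_that("adaptive weights follow 1/ln(t + P) with clamping", {
  # absent class: 1/ln(1.02) ~ 50.5 -> clamped to the upper bound 50
  expect_equal(unname(adaptive_weights(c(0, 0, 1))[1]), 50)
  # saturated class: 1/ln(2.02) inside the clamp
  expect_equal(unname(adaptive_weights(c(0, 0, 1))[3]), 1 / log(2.02),
               tolerance = 1e-12)
  expect_equal(1 / log(2.02), 1.422, tolerance = 1e-3)

  # monotone decreasing in the proportion, always inside the clamp
  P <- seq(0, 1, by = 0.05)
  w <- sapply(P, function(p) {
    unname(adaptive_weights(c(p, 1 - p, 0))[1])
  })
  expect_true(all(diff(w) <= 0))
  expect_true(all(w >= 1 & w <= 50))

  expect_error(adaptive_weights(c(0.5, 0.5, 0), t = 1), "exceed 1")
  expect_error(adaptive_weights(c(0.5, 0.6, 0)), "sum")
})

test_that("weighted cross-entropy matches its closed forms", {
  # perfect one-hot predictions -> zero loss
  truth <- matrix(c(0L, 1L, 2L, 1L), 2, 2)
  perfect <- ns$one_hot(truth)
  expect_equal(weighted_cross_entropy(perfect, truth), 0, tolerance = 1e-9)

  # uniform predictions with unit weights -> ln 3
  unif <- array(1 / 3, c(2, 2, 3, 1))
  expect_equal(weighted_cross_entropy(unif, truth), log(3), tolerance = 1e-12)

  # 1-pixel hand example: true liver, p = 0.5, w_liver = 2 -> 2 ln 2
  probs <- array(c(0.25, 0.5, 0.25), c(1, 1, 3, 1))
  expect_equal(weighted_cross_entropy(probs, matrix(1L, 1, 1), c(1, 2, 1)),
               2 * log(2), tolerance = 1e-12)

  # all-weights-1 equals plain cross-entropy
  set.seed(6)
  logits <- array(rnorm(8 * 8 * 3), c(8, 8, 3, 1))
  p <- cascadeseg:::softmax_channels(logits)
  t8 <- random_mask(8)
  plain <- -mean(log(p[cbind(as.vector(row(t8)), as.vector(col(t8)),
                             as.vector(t8) + 1, 1)]))
  expect_equal(weighted_cross_entropy(p, t8, c(1, 1, 1)), plain,
               tolerance = 1e-10)

  # degenerate zero probability stays finite via the epsilon floor
  zero <- array(rep(c(1, 0, 0), each = 1), c(1, 1, 3, 1))
  expect_true(is.finite(weighted_cross_entropy(zero, matrix(2L, 1, 1))))
})

test_that("the analytic loss gradient matches finite differences", {
  set.seed(9)
  logits <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  truth <- array(sample(0:2, 32, TRUE), c(4, 4, 2))
  w <- c(1.5, 2, 30)
  probs <- ns$softmax_channels(logits)
  g <- ns$wce_logit_grad(probs, truth, w)
  for (k in 1:10) {
    i <- sample(length(logits), 1)
    eps <- 1e-6
    l1 <- logits; l1[i] <- l1[i] + eps
    l2 <- logits; l2[i] <- l2[i] - eps
    num <- (weighted_cross_entropy(ns$softmax_channels(l1), truth, w) -
            weighted_cross_entropy(ns$softmax_channels(l2), truth, w)) /
      (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-5)
  }
})

test_that("confusion counts match brute-force pixel loops", {
  t1 <- random_mask(8)
  expect_equal(confusion(t1, t1, 1L)[c("fp", "fn")], list(fp = 0L, fn = 0L))

  pred0 <- matrix(0L, 8, 8)
  k <- sum(t1 == 2)
  cc <- confusion(pred0, t1, 2L)
  expect_equal(cc, list(tp = 0L, fp = 0L, fn = k))

  set.seed(14)
  for (i in 1:25) {
    p <- random_mask(8)
    t <- random_mask(8)
    for (cls in 1:2) {
      expect_identical(confusion(p, t, cls), brute_confusion(p, t, cls))
    }
  }
  expect_error(confusion(matrix(0L, 2, 2), matrix(0L, 3, 3), 1L), "differ")
})

test_that("dice, voe, rvd match their formulas and conventions", {
  m <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  expect_equal(dice(m, m, 1L), 1)
  disjoint <- matrix(c(0L, 0L, 1L, 1L), 2, 2)
  expect_equal(dice(m, disjoint, 1L), 0)
  # |A| = 4, |B| = 4, overlap 2 -> 0.5
  expect_equal(dice(list(tp = 2, fp = 2, fn = 2)), 0.5)

  expect_equal(voe(list(tp = 5, fp = 0, fn = 0)), 0)
  expect_equal(voe(list(tp = 3, fp = 1, fn = 1)), 0.4)
  expect_equal(voe(list(tp = 0, fp = 3, fn = 2)), 1)

  expect_equal(rvd(list(tp = 3, fp = 0, fn = 2), signed = FALSE), 0)
  expect_equal(rvd(list(tp = 3, fp = 1, fn = 1), signed = FALSE), 0.25)
  # signed form: prediction 4 px vs truth 5 px -> -0.2
  expect_equal(rvd(list(tp = 4, fp = 0, fn = 1), signed = TRUE), -0.2)

  # both-empty convention
  empty <- list(tp = 0, fp = 0, fn = 0)
  expect_equal(dice(empty), 1)
  expect_equal(voe(empty), 0)
  expect_equal(rvd(empty), 0)
})

test_that("metric identities hold against set-based brute force", {
  set.seed(23)
  for (i in 1:50) {
    p <- random_mask(16)
    t <- random_mask(16)
    cls <- sample(1:2, 1)
    A <- which(p == cls)
    B <- which(t == cls)
    cc <- confusion(p, t, cls)
    expect_equal(dice(cc), 2 * length(intersect(A, B)) /
                   (length(A) + length(B)))
    expect_equal(voe(cc), 1 - length(intersect(A, B)) /
                   length(union(A, B)))
    if (length(B) > 0) {
      expect_equal(rvd(cc, signed = TRUE),
                   (length(A) - length(B)) / length(B))
    }
    # permutation invariance: same shuffle of both grids
    perm <- sample(256)
    pp <- matrix(p[perm], 16, 16)
    tt <- matrix(t[perm], 16, 16)
    expect_equal(confusion(pp, tt, cls), cc)
  }
})

test_that("per-case metrics and aggregation behave", {
  t1 <- matrix(0L, 6, 6)
  t1[2:5, 2:5] <- 1L
  t1[3, 3] <- 2L
  cm <- case_metrics(t1, t1, case_id = "x")
  expect_equal(cm$dice, c(1, 1))
  expect_equal(cm$voe, c(0, 0))
  expect_equal(cm$rvd, c(0, 0))

  two <- rbind(
    data.frame(case = "a", class = "tumor", dice = 0.4, voe = 0.1, rvd = 0,
               rvd_ratio = 0, pattern = "large"),
    data.frame(case = "b", class = "tumor", dice = 0.6, voe = 0.3, rvd = 0,
               rvd_ratio = 0, pattern = "large"))
  agg <- aggregate_metrics(two, by = c("class", "pattern"))
  expect_equal(agg$dice, 0.5)
  expect_equal(agg$n, 2L)

  # grouping by pattern partitions the cases exactly
  many <- do.call(rbind, lapply(1:9, function(i) {
    data.frame(case = paste0("c", i), class = "liver", dice = 0.9, voe = 0.1,
               rvd = 0, rvd_ratio = 0,
               pattern = c("large", "small", "multiple")[1 + i %% 3])
  }))
  agg2 <- aggregate_metrics(many, by = c("class", "pattern"))
  expect_equal(sum(agg2$n), 9L)
  single <- aggregate_metrics(many[1, ], by = "class")
  expect_equal(single$dice, many$dice[1])
})
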