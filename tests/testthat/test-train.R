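test_that("training is deterministic and its loss decreases on a toy set", {
  pairs <- phantom_pairs(8, side = 32L, seed = 3L)
  prof <- cpu_test_profile(epochs = 3L, seed = 7L)
  cfg <- tiny_unet_cfg(depth = 2L, base_width = 4L)
  fcfg <- tiny_adense_cfg()

  m1 <- train_cascade(pairs, prof$train, cfg, fcfg)
  m2 <- train_cascade(pairs, prof$train, cfg, fcfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$coarse$params, m2$coarse$params)

  coarse_losses <- m1$history$loss[m1$history$phase == "coarse"]
  expect_lt(coarse_losses[3], coarse_losses[1])

  expect_error(train_cascade(list(), prof$train), "empty")
  empty_pair <- list(list(image = matrix(0, 32, 32),
                          mask = matrix(0L, 32, 32)))
  expect_error(train_cascade(empty_pair, prof$train), "foreground")
})

test_that("alpha = 1 sends zero gradient to the fine net in joint mode", {
  pairs <- phantom_pairs(4, side = 32L, seed = 9L)
  prof <- cpu_test_profile(epochs = 1L, seed = 2L)
  cfg_joint <- prof$train
  cfg_joint$alpha <- 1
  cfg_joint$joint_epochs <- 1L
  m <- train_cascade(pairs, cfg_joint, tiny_unet_cfg(depth = 2L, 4L),
                     tiny_adense_cfg())
  # rebuild the pre-joint fine net by rerunning without the joint phase
  cfg_nojoint <- cfg_joint
  cfg_nojoint$joint_epochs <- 0L
  m0 <- train_cascade(pairs, cfg_nojoint, tiny_unet_cfg(depth = 2L, 4L),
                      tiny_adense_cfg())
  expect_equal(m$fine$params, m0$fine$params, tolerance = 1e-12)
  expect_false(identical(m$coarse$params, m0$coarse$params))
})

test_that("predictions obey the label, shape and batching contracts", {
  pairs <- phantom_pairs(6, side = 32L, seed = 13L)
  prof <- cpu_test_profile(epochs = 2L, seed = 5L)
  m <- train_cascade(pairs[1:4], prof$train, tiny_unet_cfg(depth = 2L, 4L),
                     tiny_adense_cfg())
  imgs <- lapply(pairs[5:6], `[[`, "image")
  preds <- predict_cascade(m, imgs)
  for (p in preds) {
    expect_true(all(p %in% 0:2))
    expect_equal(dim(p), c(32L, 32L))
  }
  # batch-size invariance
  preds1 <- predict_cascade(m, imgs, batch_size = 1L)
  expect_identical(preds, preds1)

  # argmax ties resolve to the lowest class index
  tie <- array(1 / 3, c(2, 2, 3, 1))
  expect_true(all(ns$argmax_labels(tie) == 0L))
  tie2 <- array(c(0.4, 0.4, 0.2), c(1, 1, 3, 1))
  expect_equal(as.integer(ns$argmax_labels(tie2)), 0L)
})

test_that("checkpoints round-trip to identical predictions", {
  pairs <- phantom_pairs(4, side = 32L, seed = 17L)
  prof <- cpu_test_profile(epochs = 1L, seed = 3L)
  m <- train_cascade(pairs, prof$train, tiny_unet_cfg(depth = 2L, 4L),
                     tiny_adense_cfg())
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  img <- pairs[[1]]$image
  expect_identical(predict_cascade(m, img), predict_cascade(m2, img))
})

test_that("evaluation tables are exact for perfect predictions", {
  pairs <- phantom_pairs(5, side = 32L, seed = 19L)
  masks <- lapply(pairs, `[[`, "mask")
  ev <- evaluate_run(masks, masks)
  expect_true(all(ev$per_case$dice == 1))
  expect_true(all(ev$per_case$voe == 0))
  expect_true(all(ev$per_case$rvd == 0))
  expect_setequal(ev$by_class$class, c("liver", "tumor"))
  # pattern grouping partitions the cases
  expect_equal(sum(ev$by_pattern$n[ev$by_pattern$class == "liver"]),
               length(pairs))
})

test_that("the ablation suite emits one row per variant with shared stage 1", {
  pairs <- phantom_pairs(10, side = 32L, seed = 23L)
  prof <- cpu_test_profile(epochs = 1L, seed = 11L)
  ab <- ablation_suite(pairs[1:8], pairs[9:10], prof$train,
                       tiny_unet_cfg(depth = 2L, 4L), tiny_adense_cfg())
  expect_equal(nrow(ab$table), 4L)
  expect_setequal(ab$table$variant,
                  c("coarse_only", "multires_no_attention",
                    "attention_no_multires", "full_cascade"))
  # identical stage-1 checkpoints across variants
  expect_identical(ab$models$full_cascade$coarse$params,
                   ab$models$multires_no_attention$coarse$params)
  # toggling attention changes the fine-net parameter count
  expect_lt(ab$table$n_params[ab$table$variant == "multires_no_attention"],
            ab$table$n_params[ab$table$variant == "full_cascade"])
})

test_that("resumed training continues the epoch numbering", {
  pairs <- phantom_pairs(4, side = 32L, seed = 29L)
  prof <- cpu_test_profile(epochs = 2L, seed = 4L)
  m <- train_cascade(pairs, prof$train, tiny_unet_cfg(depth = 2L, 4L),
                     tiny_adense_cfg())
  prof1 <- cpu_test_profile(epochs = 1L, seed = 4L)
  m2 <- train_cascade(pairs, prof1$train, tiny_unet_cfg(depth = 2L, 4L),
                      tiny_adense_cfg(), init = m)
  expect_equal(max(m2$history$epoch), 3L)
  expect_equal(nrow(m2$history), nrow(m$history) + 2L)
})

test_that("the cascade can overfit a handful of slices (capacity sanity)", {
  # 8 phantom slices; training liver Dice should reach 0.95 within a couple
  # hundred optimiser steps in most seeds
  hits <- 0L
  for (seed in 1:5) {
    pairs <- phantom_pairs(8, side = 32L, seed = 40L + seed,
                           mix = c(large = 0.5, small = 0.5))
    cfg <- train_config(epochs = 50L, lr = 1e-3, batch_size = 2L,
                        seed = seed)  # 4 steps/epoch -> 200 optimiser steps
    m <- train_cascade(pairs, cfg, tiny_unet_cfg(depth = 2L, base_width = 8L),
                       tiny_adense_cfg(width = 8L))
    preds <- predict_cascade(m, lapply(pairs, `[[`, "image"))
    ev <- evaluate_run(preds, lapply(pairs, `[[`, "mask"))$by_class
    if (ev$dice[ev$class == "liver"] >= 0.95) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
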