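#' Training configuration for the two-stage cascade
#'
#' Defaults follow the reference training protocol: 300 epochs with a
#' constant learning rate of 1e-4 and a stage-1 loss weight `alpha` of 0.33
#' (used only when joint fine-tuning is enabled; the combined objective is
#' `alpha * L_coarse + (1 - alpha) * L_fine`). Training is sequential by
#' default: the coarse net is trained first, then frozen while its
#' probability outputs are fused with the inputs to train the fine net.
#'
#' @param epochs training epochs per stage.
#' @param lr constant Adam learning rate.
#' @param alpha stage-1 weight of the joint objective, in `[0, 1]`.
#' @param batch_size mini-batch size.
#' @param seed integer seed controlling initialisation and shuffling.
#' @param val_fraction held-out fraction when a split is requested.
#' @param joint_epochs additional joint fine-tuning epochs (0 disables).
#' @param weight_t hyper-parameter `t` of the adaptive class weights.
#' @param weight_clamp clamping interval of the adaptive class weights.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 300L, lr = 1e-4, alpha = 0.33,
                         batch_size = 4L, seed = 1L, val_fraction = 0.2,
                         joint_epochs = 0L, weight_t = 1.02,
                         weight_clamp = c(1.0, 50)) {
  stopifnot(epochs >= 1L, lr > 0, alpha >= 0, alpha <= 1)
  structure(list(epochs = as.integer(epochs), lr = lr, alpha = alpha,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 val_fraction = val_fraction,
                 joint_epochs = as.integer(joint_epochs),
                 weight_t = weight_t, weight_clamp = weight_clamp),
            class = "train_config")
}

#' Reduced desk-scale profile for CPU experiments
#'
#' Small widths and epoch counts for 64x64 phantom experiments on one CPU:
#' coarse depth 3 / base width 8, fine width 16 / growth 8, Adam at 1e-3.
#'
#' @param epochs epochs per stage.
#' @param seed RNG seed.
#' @return list with `train`, `coarse` and `fine` configurations.
#' @export
cpu_test_profile <- function(epochs = 10L, seed = 1L) {
  list(train = train_config(epochs = epochs, lr = 1e-3, batch_size = 8L,
                            seed = seed),
       coarse = unet_config(base_width = 8L, depth = 3L),
       fine = adense_config(width = 16L, growth_rate = 8L))
}

# stack a list of matrices into an (H, W, 1, N) tensor
stack_slices <- function(mats) {
  d <- dim(mats[[1L]])
  out <- array(0, c(d[1L], d[2L], 1L, length(mats)))
  for (i in seq_along(mats)) out[, , 1L, i] <- mats[[i]]
  out
}

stack_masks <- function(masks) {
  d <- dim(masks[[1L]])
  out <- array(0L, c(d[1L], d[2L], length(masks)))
  for (i in seq_along(masks)) out[, , i] <- masks[[i]]
  out
}

# per-pixel argmax over the channel axis; ties resolve to the lowest index
argmax_labels <- function(probs) {
  d <- dim(probs)
  out <- array(0L, c(d[1L], d[2L], d[4L]))
  for (n in seq_len(d[4L])) {
    best <- probs[, , 1L, n]
    lab <- matrix(0L, d[1L], d[2L])
    for (c in 2:d[3L]) {
      p <- probs[, , c, n]
      better <- p > best
      lab[better] <- c - 1L
      best[better] <- p[better]
    }
    out[, , n] <- lab
  }
  out
}

check_loss_finite <- function(loss, where) {
  if (!is.finite(loss)) {
    stop("non-finite loss (", loss, ") during ", where,
         "; reduce the learning rate or inspect the inputs")
  }
  loss
}

#' Train the two-stage coarse-to-fine cascade
#'
#' Phase A trains the coarse U-Net with the adaptive class-weighted
#' cross-entropy (weights computed once from the training masks). Phase B
#' freezes the coarse net, fuses its probability outputs with the normalised
#' inputs, and trains the fine net on the multi-resolution fused maps. An
#' optional joint phase continues training both nets under
#' `alpha * L_coarse + (1 - alpha) * L_fine` (the fused prior is treated as a
#' constant input of the fine stage, so no gradient crosses the stages).
#'
#' @param pairs list of training pairs, each `list(image = matrix of windowed
#'   HU values, mask = integer label matrix)`.
#' @param cfg a [train_config()].
#' @param coarse_cfg a [unet_config()].
#' @param fine_cfg an [adense_config()].
#' @param verbose print per-epoch losses.
#' @param init optional `cascade_model` to resume from; its weights seed both
#'   stages and epoch numbering continues from its history.
#' @return an object of class `cascade_model` with elements `coarse`, `fine`,
#'   `weights`, `history` (per-epoch losses by phase) and the configurations.
#' @export
train_cascade <- function(pairs, cfg = train_config(),
                          coarse_cfg = unet_config(),
                          fine_cfg = adense_config(),
                          verbose = FALSE, init = NULL) {
  if (length(pairs) == 0L) stop("empty training dataset")
  masks <- lapply(pairs, `[[`, "mask")
  if (!any(vapply(masks, function(m) any(m > 0), logical(1)))) {
    stop("training dataset contains no foreground pixels")
  }
  with_seed(cfg$seed, {
    images <- lapply(pairs, function(p) norm01(p$image))
    weights <- adaptive_weights(class_proportions(masks), t = cfg$weight_t,
                                clamp = cfg$weight_clamp)
    history <- list()
    epoch0 <- 0L
    if (!is.null(init)) {
      stopifnot(inherits(init, "cascade_model"))
      history[[1L]] <- init$history
      epoch0 <- max(init$history$epoch)
    }

    coarse <- if (is.null(init)) build_unet(coarse_cfg) else init$coarse
    opt_c <- adam_init(coarse$params)
    for (epoch in epoch0 + seq_len(cfg$epochs)) {
      res <- run_epoch_coarse(coarse, opt_c, images, masks, weights, cfg)
      coarse <- res$net; opt_c <- res$opt
      history[[length(history) + 1L]] <-
        data.frame(phase = "coarse", epoch = epoch, loss = res$loss)
      if (verbose) message(sprintf("coarse %3d  loss %.4f", epoch, res$loss))
    }

    branch_sets <- make_branch_inputs(coarse, images, fine_cfg, cfg$batch_size)
    fine <- if (is.null(init)) build_adensenet(fine_cfg) else init$fine
    opt_f <- adam_init(fine$params)
    for (epoch in epoch0 + seq_len(cfg$epochs)) {
      res <- run_epoch_fine(fine, opt_f, branch_sets, masks, weights, cfg)
      fine <- res$net; opt_f <- res$opt
      history[[length(history) + 1L]] <-
        data.frame(phase = "fine", epoch = epoch, loss = res$loss)
      if (verbose) message(sprintf("fine   %3d  loss %.4f", epoch, res$loss))
    }

    if (cfg$joint_epochs > 0L) {
      # fresh optimizer state: the joint objective is a new optimisation, and
      # stale momentum would move parameters whose gradient is exactly zero
      opt_c <- adam_init(coarse$params)
      opt_f <- adam_init(fine$params)
      for (epoch in seq_len(cfg$joint_epochs)) {
        res <- run_epoch_joint(coarse, fine, opt_c, opt_f, images, masks,
                               weights, cfg, fine_cfg)
        coarse <- res$coarse; fine <- res$fine
        opt_c <- res$opt_c; opt_f <- res$opt_f
        history[[length(history) + 1L]] <-
          data.frame(phase = "joint", epoch = epoch, loss = res$loss)
        if (verbose) message(sprintf("joint  %3d  loss %.4f", epoch, res$loss))
      }
    }

    structure(list(coarse = coarse, fine = fine, weights = weights,
                   history = do.call(rbind, history), cfg = cfg,
                   coarse_cfg = coarse_cfg, fine_cfg = fine_cfg),
              class = "cascade_model")
  })
}

batch_indices <- function(n, batch_size) {
  ord <- sample.int(n)
  split(ord, ceiling(seq_along(ord) / batch_size))
}

run_epoch_coarse <- function(net, opt, images, masks, weights, cfg) {
  losses <- c()
  for (idx in batch_indices(length(images), cfg$batch_size)) {
    x <- stack_slices(images[idx])
    truth <- stack_masks(masks[idx])
    out <- unet_forward(net, x, want_cache = TRUE)
    probs <- softmax_channels(out$logits)
    loss <- check_loss_finite(
      weighted_cross_entropy(probs, truth, weights), "coarse training")
    gr <- unet_backward(net, out$cache, wce_logit_grad(probs, truth, weights))
    st <- adam_step(net$params, gr, opt, cfg$lr)
    net$params <- st$params; opt <- st$state
    losses <- c(losses, loss)
  }
  list(net = net, opt = opt, loss = mean(losses))
}

# frozen-coarse priors: fused multi-resolution inputs for every slice
make_branch_inputs <- function(coarse, images, fine_cfg, batch_size) {
  n <- length(images)
  out <- vector("list", n)
  for (idx in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    probs <- coarse_forward(coarse, stack_slices(images[idx]))
    for (k in seq_along(idx)) {
      fused <- fuse_coarse(probs[, , , k, drop = FALSE], images[[idx[k]]])
      out[[idx[k]]] <- build_multires_inputs(fused, fine_cfg$resolutions)
    }
  }
  out
}

stack_branches <- function(branch_sets, idx) {
  nb <- length(branch_sets[[1L]])
  lapply(seq_len(nb), function(b) {
    stack_slices(lapply(branch_sets[idx], `[[`, b))
  })
}

run_epoch_fine <- function(net, opt, branch_sets, masks, weights, cfg) {
  losses <- c()
  for (idx in batch_indices(length(branch_sets), cfg$batch_size)) {
    binputs <- stack_branches(branch_sets, idx)
    truth <- stack_masks(masks[idx])
    out <- fine_forward(net, binputs, want_cache = TRUE)
    loss <- check_loss_finite(
      weighted_cross_entropy(out$probs, truth, weights), "fine training")
    gr <- fine_backward(net, out$cache,
                        wce_logit_grad(out$probs, truth, weights))
    st <- adam_step(net$params, gr, opt, cfg$lr)
    net$params <- st$params; opt <- st$state
    losses <- c(losses, loss)
  }
  list(net = net, opt = opt, loss = mean(losses))
}

run_epoch_joint <- function(coarse, fine, opt_c, opt_f, images, masks,
                            weights, cfg, fine_cfg) {
  losses <- c()
  for (idx in batch_indices(length(images), cfg$batch_size)) {
    x <- stack_slices(images[idx])
    truth <- stack_masks(masks[idx])
    cout <- unet_forward(coarse, x, want_cache = TRUE)
    cprobs <- softmax_channels(cout$logits)
    loss_c <- weighted_cross_entropy(cprobs, truth, weights)
    gr_c <- unet_backward(coarse, cout$cache,
                          cfg$alpha * wce_logit_grad(cprobs, truth, weights))
    binputs <- local({
      sets <- lapply(seq_along(idx), function(k) {
        fused <- fuse_coarse(cprobs[, , , k, drop = FALSE], images[[idx[k]]])
        build_multires_inputs(fused, fine_cfg$resolutions)
      })
      nb <- length(sets[[1L]])
      lapply(seq_len(nb), function(b) stack_slices(lapply(sets, `[[`, b)))
    })
    fout <- fine_forward(fine, binputs, want_cache = TRUE)
    loss_f <- weighted_cross_entropy(fout$probs, truth, weights)
    gr_f <- fine_backward(fine, fout$cache,
                          (1 - cfg$alpha) *
                            wce_logit_grad(fout$probs, truth, weights))
    loss <- check_loss_finite(cfg$alpha * loss_c + (1 - cfg$alpha) * loss_f,
                              "joint training")
    st <- adam_step(coarse$params, gr_c, opt_c, cfg$lr)
    coarse$params <- st$params; opt_c <- st$state
    st <- adam_step(fine$params, gr_f, opt_f, cfg$lr)
    fine$params <- st$params; opt_f <- st$state
    losses <- c(losses, loss)
  }
  list(coarse = coarse, fine = fine, opt_c = opt_c, opt_f = opt_f,
       loss = mean(losses))
}

#' Predict label masks with a trained cascade
#'
#' Per slice: coarse forward, fusion with the normalised input,
#' multi-resolution construction, fine forward, and per-pixel argmax (ties
#' resolve to the lowest class index). With `stage = "coarse"` the coarse
#' probabilities are argmaxed directly (the coarse-only ablation).
#'
#' @param model a [train_cascade()] model.
#' @param images list of windowed HU slice matrices.
#' @param batch_size inference batch size (the predictions are independent of
#'   it).
#' @param stage `"cascade"` (default) or `"coarse"`.
#' @return list of integer label matrices over \{0, 1, 2\}.
#' @export
predict_cascade <- function(model, images, batch_size = 8L,
                            stage = c("cascade", "coarse")) {
  stage <- match.arg(stage)
  if (is.matrix(images)) images <- list(images)
  images <- lapply(images, norm01)
  n <- length(images)
  preds <- vector("list", n)
  for (idx in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    probs <- coarse_forward(model$coarse, stack_slices(images[idx]))
    if (stage == "coarse") {
      labs <- argmax_labels(probs)
    } else {
      sets <- lapply(seq_along(idx), function(k) {
        fused <- fuse_coarse(probs[, , , k, drop = FALSE], images[[idx[k]]])
        build_multires_inputs(fused, model$fine_cfg$resolutions)
      })
      nb <- length(sets[[1L]])
      binputs <- lapply(seq_len(nb), function(b) {
        stack_slices(lapply(sets, `[[`, b))
      })
      labs <- argmax_labels(fine_forward(model$fine, binputs)$probs)
    }
    for (k in seq_along(idx)) preds[[idx[k]]] <- labs[, , k]
  }
  preds
}

#' Evaluate predictions against ground truth
#'
#' @param preds,truths lists of label matrices, paired by position.
#' @param case_ids optional case identifiers.
#' @param patterns optional tumor-pattern labels; inferred from each truth
#'   mask when `NULL`.
#' @return list with `per_case` (one row per case and class), `by_class`
#'   (overall means) and `by_pattern` (means within each pattern).
#' @export
evaluate_run <- function(preds, truths, case_ids = NULL, patterns = NULL) {
  stopifnot(length(preds) == length(truths))
  if (is.null(case_ids)) case_ids <- sprintf("case%04d", seq_along(preds))
  per_case <- do.call(rbind, lapply(seq_along(preds), function(i) {
    case_metrics(preds[[i]], truths[[i]], case_id = case_ids[i],
                 pattern = if (is.null(patterns)) NULL else patterns[i])
  }))
  list(per_case = per_case,
       by_class = aggregate_metrics(per_case, by = "class"),
       by_pattern = aggregate_metrics(per_case, by = c("class", "pattern")))
}

#' Ablation comparison of the cascade's components
#'
#' Trains the coarse stage once per configuration and seed, then three fine
#' variants on top of the shared stage-1 checkpoint: multi-resolution without
#' attention, attention without multi-resolution input, and the full model.
#' All variants are evaluated on the same held-out pairs.
#'
#' @param train_pairs,eval_pairs lists of `list(image, mask)` pairs.
#' @param cfg a [train_config()].
#' @param coarse_cfg a [unet_config()].
#' @param fine_cfg an [adense_config()] for the full variant.
#' @return list with `table` (one row per variant: mean liver/tumor Dice,
#'   VOE, RVD) and `models`.
#' @export
ablation_suite <- function(train_pairs, eval_pairs, cfg = train_config(),
                           coarse_cfg = unet_config(),
                           fine_cfg = adense_config()) {
  vary_cfg <- function(...) {
    fields <- modifyList(unclass(fine_cfg), list(...))
    do.call(adense_config, fields[setdiff(names(fields), "n_layers")])
  }
  eval_images <- lapply(eval_pairs, `[[`, "image")
  eval_masks <- lapply(eval_pairs, `[[`, "mask")
  base <- train_cascade(train_pairs, cfg, coarse_cfg, fine_cfg)
  variants <- list(
    coarse_only = base,
    multires_no_attention = retrain_fine(base, train_pairs, cfg,
                                         vary_cfg(use_attention = FALSE)),
    attention_no_multires = retrain_fine(base, train_pairs, cfg,
                                         vary_cfg(resolutions = 1L)),
    full_cascade = base
  )
  models <- variants
  rows <- list()
  for (v in names(variants)) {
    model <- variants[[v]]
    preds <- predict_cascade(model, eval_images,
                             stage = if (v == "coarse_only") "coarse"
                                     else "cascade")
    ev <- evaluate_run(preds, eval_masks)
    bc <- ev$by_class
    rows[[v]] <- data.frame(
      variant = v,
      liver_dice = bc$dice[bc$class == "liver"],
      liver_voe = bc$voe[bc$class == "liver"],
      liver_rvd = bc$rvd[bc$class == "liver"],
      tumor_dice = bc$dice[bc$class == "tumor"],
      tumor_voe = bc$voe[bc$class == "tumor"],
      tumor_rvd = bc$rvd[bc$class == "tumor"],
      n_params = n_parameters(model$fine$params))
  }
  list(table = do.call(rbind, rows), models = models)
}

# train a fine-stage variant on top of an existing (frozen) coarse net
retrain_fine <- function(model, pairs, cfg, fine_cfg) {
  masks <- lapply(pairs, `[[`, "mask")
  with_seed(cfg$seed + 1L, {
    images <- lapply(pairs, function(p) norm01(p$image))
    branch_sets <- make_branch_inputs(model$coarse, images, fine_cfg,
                                      cfg$batch_size)
    fine <- build_adensenet(fine_cfg)
    opt_f <- adam_init(fine$params)
    hist <- list()
    for (epoch in seq_len(cfg$epochs)) {
      res <- run_epoch_fine(fine, opt_f, branch_sets, masks, model$weights,
                            cfg)
      fine <- res$net; opt_f <- res$opt
      hist[[epoch]] <- data.frame(phase = "fine", epoch = epoch,
                                  loss = res$loss)
    }
    out <- model
    out$fine <- fine
    out$fine_cfg <- fine_cfg
    out$history <- rbind(model$history[model$history$phase != "fine", ],
                         do.call(rbind, hist))
    out
  })
}

#' Save / load a cascade checkpoint
#'
#' The checkpoint embeds both networks with their configurations; a load
#' followed by prediction reproduces the saved model's outputs exactly.
#'
#' @param model a `cascade_model`.
#' @param path file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "cascade_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "cascade_model"))
  model
}
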