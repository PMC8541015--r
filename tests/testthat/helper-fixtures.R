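# Shared fixtures and oracles for the test suite.

ns <- asNamespace("cascadeseg")

# tiny configurations that keep CPU time negligible
tiny_unet_cfg <- function(depth = 2L, base_width = 3L) {
  unet_config(in_channels = 1L, base_width = base_width, depth = depth)
}

tiny_adense_cfg <- function(...) {
  defaults <- list(width = 4L, growth_rate = 3L, dilation_rates = c(1L, 2L),
                   attention_K = 3L, resolutions = c(1L, 2L))
  do.call(adense_config, modifyList(defaults, list(...)))
}

random_mask <- function(side = 16L, p = c(0.6, 0.3, 0.1)) {
  matrix(sample(0:2, side * side, replace = TRUE, prob = p), side, side)
}

# brute-force confusion counts by explicit pixel loops (independent oracle)
brute_confusion <- function(pred, truth, class_id) {
  tp <- fp <- fn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j] == class_id
      t <- truth[i, j] == class_id
      if (p && t) tp <- tp + 1L
      if (p && !t) fp <- fp + 1L
      if (!p && t) fn <- fn + 1L
    }
  }
  list(tp = tp, fp = fp, fn = fn)
}

# brute-force 8-connected component count via union-find (independent oracle)
brute_components <- function(bin) {
  n <- sum(bin)
  if (n == 0L) return(0L)
  idx <- which(bin, arr.ind = TRUE)
  id <- seq_len(n)
  find <- function(i) {
    while (id[i] != i) {
      id[i] <<- id[id[i]]
      i <- id[i]
    }
    i
  }
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a < b && abs(idx[a, 1] - idx[b, 1]) <= 1 &&
          abs(idx[a, 2] - idx[b, 2]) <= 1) {
        id[find(a)] <- find(b)
      }
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# brute-force pattern rule: component count then pixel-ratio threshold
brute_pattern <- function(mask, threshold = 0.10) {
  tumor <- sum(mask == 2)
  if (tumor == 0) return("none")
  if (brute_components(mask == 2) >= 2) return("multiple")
  if (tumor / sum(mask > 0) > threshold) "large" else "small"
}

# a small deterministic batch of phantom training pairs
phantom_pairs <- function(n, side = 32L, seed = 5L,
                          mix = c(large = 0.3, small = 0.3, multiple = 0.2,
                                  none = 0.2)) {
  generate_dataset(n, mix, phantom_spec(image_side = side), seed = seed)$pairs
}
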