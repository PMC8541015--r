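#' Class proportions of a set of label masks
#'
#' @param masks a label matrix/array or a list of them.
#' @return numeric 3-vector `(background, liver, tumor)` summing to 1.
#' @export
class_proportions <- function(masks) {
  if (!is.list(masks)) masks <- list(masks)
  if (length(masks) == 0L || sum(lengths(masks)) == 0L) {
    stop("need at least one mask pixel to compute class proportions")
  }
  counts <- numeric(3)
  for (m in masks) {
    check_labels(m)
    counts <- counts + tabulate(as.integer(m) + 1L, nbins = 3L)
  }
  p <- counts / sum(counts)
  names(p) <- c("background", "liver", "tumor")
  p
}

#' Adaptive class weights for imbalanced cross-entropy
#'
#' Computes `w_c = 1 / ln(t + P_c)` from the class proportions and clips the
#' result into the closed interval `clamp`. Rare classes (small `P_c`) receive
#' large weights; with the default `t = 1.02` an absent class hits the upper
#' clamp of 50.
#'
#' @param P class proportions (non-negative, summing to 1).
#' @param t hyper-parameter `> 1` controlling the weight scale.
#' @param clamp closed clipping interval for the weights.
#' @return numeric weight vector, same length and names as `P`.
#' @export
adaptive_weights <- function(P, t = 1.02, clamp = c(1.0, 50)) {
  if (t <= 1) {
    stop("t must exceed 1 so that ln(t + P) is positive for every class")
  }
  if (any(P < 0) || abs(sum(P) - 1) > 1e-6) {
    stop("P must be non-negative proportions summing to 1")
  }
  w <- 1 / log(t + P)
  pmin(pmax(w, clamp[1]), clamp[2])
}

# one-hot truth tensor (H, W, C, N) from an (H, W, N) integer label array
one_hot <- function(truth, n_classes = 3L) {
  d <- dim(truth)
  if (length(d) == 2L) dim(truth) <- d <- c(d, 1L)
  out <- array(0, c(d[1L], d[2L], n_classes, d[3L]))
  for (c in seq_len(n_classes)) {
    out[, , c, ] <- (truth == c - 1L)
  }
  out
}

#' Class-weighted cross-entropy over a batch
#'
#' `L = -(1/N) * sum_i sum_c w_c * 1[truth_i = c] * log(p_ic)` with `N` the
#' number of pixels in the batch and a floor of `1e-12` inside the logarithm
#' so degenerate predictions give a finite loss.
#'
#' @param probs probability tensor `(H, W, C[, N])`, per-pixel simplex.
#' @param truth integer label matrix/array `(H, W[, N])`.
#' @param weights per-class weights (default all 1, i.e. plain cross-entropy).
#' @return scalar loss (non-negative).
#' @export
weighted_cross_entropy <- function(probs, truth, weights = c(1, 1, 1)) {
  probs <- as_tensor(probs)
  d <- dim(probs)
  y <- one_hot(truth, n_classes = d[3L])
  stopifnot(all(dim(y) == d))
  wmap <- array(rep(weights, each = d[1L] * d[2L]), d)
  npix <- d[1L] * d[2L] * d[4L]
  -sum(wmap * y * log(pmax(probs, 1e-12))) / npix
}

# gradient of the weighted cross-entropy w.r.t. the pre-softmax logits
wce_logit_grad <- function(probs, truth, weights = c(1, 1, 1)) {
  d <- dim(probs)
  y <- one_hot(truth, n_classes = d[3L])
  truth_w <- array(weights[as.integer(truth) + 1L], c(d[1L], d[2L], d[4L]))
  wmap <- array(0, d)
  for (c in seq_len(d[3L])) wmap[, , c, ] <- truth_w
  npix <- d[1L] * d[2L] * d[4L]
  wmap * (probs - y) / npix
}

#' Pixel confusion counts for one class
#'
#' @param pred,truth integer label grids of identical shape.
#' @param class_id the class evaluated (1 = liver, 2 = tumor).
#' @return list with `tp`, `fp`, `fn` pixel counts.
#' @export
confusion <- function(pred, truth, class_id) {
  if (!all(dim(pred) == dim(truth))) {
    stop("prediction and truth shapes differ")
  }
  p <- pred == class_id
  t <- truth == class_id
  list(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t))
}

as_counts <- function(x, truth = NULL, class_id = NULL) {
  if (is.list(x) && all(c("tp", "fp", "fn") %in% names(x))) return(x)
  confusion(x, truth, class_id)
}

#' Dice similarity coefficient
#'
#' `DSC = 2|A n B| / (|A| + |B|) = 2 TP / (2 TP + FP + FN)`. When both masks
#' are empty the prediction agrees perfectly with the truth and 1 is returned.
#'
#' @param x confusion counts from [confusion()], or a predicted label grid.
#' @param truth,class_id used when `x` is a label grid.
#' @return Dice score in `[0, 1]`.
#' @export
dice <- function(x, truth = NULL, class_id = NULL) {
  cc <- as_counts(x, truth, class_id)
  denom <- 2 * cc$tp + cc$fp + cc$fn
  if (denom == 0) return(1)
  2 * cc$tp / denom
}

#' Volumetric overlap error
#'
#' `VOE = 1 - TP / (TP + FP + FN)` (the Jaccard complement); 0 for a perfect
#' prediction, 0 by convention when both masks are empty.
#'
#' @inheritParams dice
#' @return VOE in `[0, 1]`.
#' @export
voe <- function(x, truth = NULL, class_id = NULL) {
  cc <- as_counts(x, truth, class_id)
  denom <- cc$tp + cc$fp + cc$fn
  if (denom == 0) return(0)
  1 - cc$tp / denom
}

#' Relative volume difference
#'
#' The literal ratio form is `FP / (TP + FN)` and is non-negative. The signed
#' form, `(|A| - |B|) / |B| = (TP + FP) / (TP + FN) - 1`, is negative for
#' under-segmentation and is the variant used in summary tables. Both return
#' 0 when both masks are empty.
#'
#' @inheritParams dice
#' @param signed if `TRUE` (default) return the signed volume difference.
#' @return RVD; unbounded, negative only in the signed form.
#' @export
rvd <- function(x, truth = NULL, class_id = NULL, signed = TRUE) {
  cc <- as_counts(x, truth, class_id)
  if (cc$tp + cc$fn == 0) {
    if (cc$fp == 0) return(0)
    return(Inf)
  }
  if (signed) (cc$tp + cc$fp) / (cc$tp + cc$fn) - 1
  else cc$fp / (cc$tp + cc$fn)
}

#' Per-case segmentation metrics for liver and tumor
#'
#' The liver region is evaluated as labels \{1, 2\} together (lesions lie
#' inside the liver), the tumor class as label 2 alone.
#'
#' @param pred,truth integer label grids.
#' @param case_id identifier carried into the output.
#' @param pattern optional tumor-pattern label; inferred from the truth mask
#'   when `NULL`.
#' @return data frame with one row per class (`liver`, `tumor`) and columns
#'   `case`, `class`, `dice`, `voe`, `rvd` (signed), `rvd_ratio` (literal
#'   form), `pattern`.
#' @export
case_metrics <- function(pred, truth, case_id = "case", pattern = NULL) {
  if (is.null(pattern)) pattern <- classify_pattern(truth)
  liver_cc <- confusion((pred > 0) * 1L, (truth > 0) * 1L, 1L)
  tumor_cc <- confusion(pred, truth, 2L)
  row <- function(cls, cc) {
    data.frame(case = case_id, class = cls, dice = dice(cc), voe = voe(cc),
               rvd = rvd(cc, signed = TRUE),
               rvd_ratio = rvd(cc, signed = FALSE), pattern = pattern)
  }
  rbind(row("liver", liver_cc), row("tumor", tumor_cc))
}

#' Aggregate per-case metrics
#'
#' Unweighted means of the per-case metrics within each group.
#'
#' @param metrics data frame from [case_metrics()] rows.
#' @param by grouping columns, e.g. `c("class")` or `c("class", "pattern")`.
#' @return data frame of group means with a case count column `n`.
#' @export
aggregate_metrics <- function(metrics, by = c("class", "pattern")) {
  metrics <- metrics[is.finite(metrics$rvd), , drop = FALSE]
  f <- metrics[, by, drop = FALSE]
  agg <- aggregate(metrics[, c("dice", "voe", "rvd")], by = f, FUN = mean)
  cnt <- aggregate(list(n = metrics$dice), by = f, FUN = length)
  merge(agg, cnt, by = by)
}
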