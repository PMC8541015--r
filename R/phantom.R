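#' Specification of a synthetic abdominal CT phantom slice
#'
#' The phantom emulates the structure of a contrast-enhanced axial abdominal
#' CT slice: a large, noisy-edged elliptical liver region (label 1) on a
#' darker background with elliptical clutter (other organs), and zero or more
#' darker circular tumor lesions (label 2) strictly inside the liver. Raw
#' voxel values are `(target HU - intercept) / slope` plus Gaussian noise, so
#' the full HU-conversion path is exercised.
#'
#' Default tissue values follow the usual contrast ordering of portal-venous
#' phase CT: liver parenchyma around 60 HU, hypodense lesions around 30 HU,
#' background soft tissue/air mixture well below.
#'
#' @param image_side slice side length in pixels (square slices).
#' @param pattern one of `"large"`, `"small"`, `"multiple"`, `"none"`, or
#'   `NULL` to control tumors via `n_tumors`/`tumor_radius_range` directly.
#'   Patterns follow the tumor-morphology stratification: a single lesion
#'   whose pixel ratio to the liver region exceeds 10\% (large), a single
#'   smaller lesion (small), or several disjoint lesions (multiple).
#' @param n_tumors number of lesions when `pattern` is `NULL`.
#' @param tumor_radius_range lesion radius range in pixels when `pattern`
#'   is `NULL`.
#' @param liver_axes_range liver semi-axis range as a fraction of the side.
#' @param liver_hu_mean,liver_hu_sd liver tissue HU mean and spread.
#' @param tumor_hu_mean,tumor_hu_sd lesion HU mean and spread.
#' @param background_hu_mean background HU.
#' @param noise_sd additive Gaussian noise, in HU.
#' @param slope,intercept scanner rescale parameters for the raw values.
#' @param n_clutter number of background clutter ellipses.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_side = 512L,
                         pattern = NULL,
                         n_tumors = 1L,
                         tumor_radius_range = NULL,
                         liver_axes_range = c(0.24, 0.36),
                         liver_hu_mean = 60, liver_hu_sd = 10,
                         tumor_hu_mean = 30, tumor_hu_sd = 8,
                         background_hu_mean = -100,
                         noise_sd = 15,
                         slope = 1, intercept = -1024,
                         n_clutter = 3L) {
  if (!is.null(pattern)) {
    pattern <- match.arg(pattern, c("large", "small", "multiple", "none"))
  }
  if (slope == 0) stop("slope must be nonzero")
  if (!is.null(tumor_radius_range) && any(tumor_radius_range <= 0)) {
    stop("tumor radii must be positive")
  }
  structure(list(image_side = as.integer(image_side), pattern = pattern,
                 n_tumors = as.integer(n_tumors),
                 tumor_radius_range = tumor_radius_range,
                 liver_axes_range = liver_axes_range,
                 liver_hu_mean = liver_hu_mean, liver_hu_sd = liver_hu_sd,
                 tumor_hu_mean = tumor_hu_mean, tumor_hu_sd = tumor_hu_sd,
                 background_hu_mean = background_hu_mean,
                 noise_sd = noise_sd, slope = slope, intercept = intercept,
                 n_clutter = as.integer(n_clutter)),
            class = "phantom_spec")
}

# run expr with a private RNG stream; the caller's RNG state is untouched
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# disk pixel offsets for radius r (8-connected blob)
disk_offsets <- function(r) {
  d <- expand.grid(dh = -ceiling(r):ceiling(r), dw = -ceiling(r):ceiling(r))
  d[d$dh^2 + d$dw^2 <= r^2, , drop = FALSE]
}

paint_ellipse <- function(mask, value, ch, cw, a, b, theta, wobble = NULL) {
  n <- nrow(mask)
  h <- matrix(seq_len(n), n, n) - ch
  w <- matrix(seq_len(n), n, n, byrow = TRUE) - cw
  hr <- cos(theta) * h + sin(theta) * w
  wr <- -sin(theta) * h + cos(theta) * w
  rad2 <- (hr / a)^2 + (wr / b)^2
  lim <- 1
  if (!is.null(wobble)) {
    ang <- atan2(wr, hr)
    lim <- 1
    for (m in seq_along(wobble$amp)) {
      lim <- lim + wobble$amp[m] * cos((m + 1) * ang + wobble$phase[m])
    }
    lim <- lim^2
  }
  mask[rad2 <= lim] <- value
  mask
}

#' Generate one labeled synthetic CT slice
#'
#' Deterministic for a fixed `(spec, seed)` pair. Lesions are placed fully
#' inside the liver with a 2-pixel separation between distinct lesions; if a
#' lesion cannot be placed after bounded retries, an error is raised.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed driving all randomness of this slice.
#' @return list with `volume` (a single-slice [ct_volume()]), `mask`
#'   (integer label matrix), and `tumor_ratio` (lesion pixels over liver
#'   region pixels, the region counting labels 1 and 2 together).
#' @export
generate_slice <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(seed, {
    n <- spec$image_side
    mask <- matrix(0L, n, n)

    # liver: noisy-edged ellipse near the image centre
    ax <- runif(2, spec$liver_axes_range[1], spec$liver_axes_range[2]) * n
    ctr <- n / 2 + runif(2, -0.05, 0.05) * n
    wob <- list(amp = runif(3, 0, 0.06), phase = runif(3, 0, 2 * pi))
    theta <- runif(1, 0, pi)
    mask <- paint_ellipse(mask, 1L, ctr[1], ctr[2], ax[1], ax[2], theta, wob)
    liver_px <- sum(mask == 1L)
    if (liver_px == 0) stop("degenerate phantom: empty liver region")

    # lesion sizes from the requested pattern
    radii <- phantom_radii(spec, liver_px)
    for (r in radii) mask <- place_tumor(mask, r)

    # HU image: clutter first, then liver and lesions overwrite
    hu <- matrix(spec$background_hu_mean, n, n)
    for (i in seq_len(spec$n_clutter)) {
      cl <- matrix(0L, n, n)
      cl <- paint_ellipse(cl, 1L, runif(1, 0, n), runif(1, 0, n),
                          runif(1, 0.03, 0.12) * n, runif(1, 0.03, 0.12) * n,
                          runif(1, 0, pi))
      hu[cl == 1L & mask == 0L] <- runif(1, -80, 200)
    }
    hu[mask == 1L] <- spec$liver_hu_mean +
      rnorm(sum(mask == 1L), 0, spec$liver_hu_sd)
    hu[mask == 2L] <- spec$tumor_hu_mean +
      rnorm(sum(mask == 2L), 0, spec$tumor_hu_sd)

    raw <- (hu - spec$intercept) / spec$slope + rnorm(n * n, 0, spec$noise_sd)
    vol <- ct_volume(raw, slope = spec$slope, intercept = spec$intercept,
                     case_id = sprintf("phantom%06d", seed %% 1000000L))
    ratio <- sum(mask == 2L) / sum(mask > 0L)
    list(volume = vol, mask = mask, tumor_ratio = ratio)
  })
}

# lesion radii consistent with the requested pattern (or the free-form spec)
phantom_radii <- function(spec, liver_px) {
  ratio_to_r <- function(ratio) sqrt(ratio * liver_px / pi)
  if (is.null(spec$pattern)) {
    if (spec$n_tumors == 0L) return(numeric(0))
    rng <- spec$tumor_radius_range
    if (is.null(rng)) rng <- c(2, ratio_to_r(0.08))
    return(runif(spec$n_tumors, rng[1], rng[2]))
  }
  switch(spec$pattern,
    none = numeric(0),
    large = ratio_to_r(runif(1, 0.13, 0.22)),
    small = ratio_to_r(runif(1, 0.02, 0.07)),
    multiple = {
      k <- sample(2:4, 1)
      pmax(2, ratio_to_r(runif(k, 0.012, 0.035)))
    }
  )
}

# place one circular lesion fully inside the liver, >= 2 px from other lesions
place_tumor <- function(mask, r, max_tries = 400L) {
  n <- nrow(mask)
  liver_idx <- which(mask == 1L)
  off <- disk_offsets(r)
  gap <- disk_offsets(r + 2)
  for (try in seq_len(max_tries)) {
    ctr <- liver_idx[sample.int(length(liver_idx), 1L)]
    ch <- (ctr - 1L) %% n + 1L
    cw <- (ctr - 1L) %/% n + 1L
    hh <- ch + off$dh
    ww <- cw + off$dw
    if (any(hh < 1L | hh > n | ww < 1L | ww > n)) next
    cells <- cbind(hh, ww)
    if (any(mask[cells] == 0L)) next              # leaves the liver
    gh <- pmin(pmax(ch + gap$dh, 1L), n)
    gw <- pmin(pmax(cw + gap$dw, 1L), n)
    if (any(mask[cbind(gh, gw)] == 2L)) next      # touches another lesion
    mask[cells] <- 2L
    return(mask)
  }
  stop("could not place a lesion of radius ", round(r, 1),
       " inside the liver after ", max_tries, " tries")
}

#' Classify the tumor-morphology pattern of a label mask
#'
#' `none` if there are no tumor pixels; `multiple` if the tumor pixels form
#' two or more 8-connected components; otherwise `large` when the pixel ratio
#' of tumor to liver region (labels 1 and 2 together) exceeds the threshold,
#' else `small`. A ratio exactly at the threshold counts as small.
#'
#' @param mask integer label matrix (or 3-d stack, classified as a whole
#'   with per-slice 8-connectivity).
#' @param threshold large/small pixel-ratio threshold (default 0.10).
#' @return one of `"large"`, `"small"`, `"multiple"`, `"none"`.
#' @export
classify_pattern <- function(mask, threshold = 0.10) {
  check_labels(mask)
  tumor_px <- sum(mask == 2L)
  if (tumor_px == 0L) return("none")
  liver_region <- sum(mask > 0L)
  if (liver_region == tumor_px && sum(mask == 1L) == 0L) {
    stop("degenerate mask: tumor pixels without any liver pixels")
  }
  slices <- if (length(dim(mask)) == 3L) slice_volume(mask) else list(mask)
  n_comp <- sum(vapply(slices, function(s) {
    max(cpp_label_components(s == 2L))
  }, numeric(1)))
  if (n_comp >= 2) return("multiple")
  if (tumor_px / liver_region > threshold) "large" else "small"
}

#' Generate a labeled phantom dataset
#'
#' Draws `n_cases` single-slice phantoms with the requested mix of tumor
#' patterns (largest-remainder rounding), re-drawing a slice if pixelation
#' pushes its realized pattern off the requested one, so that the manifest's
#' pattern labels always agree with [classify_pattern()].
#'
#' @param n_cases number of slices to generate.
#' @param pattern_mix named proportions over
#'   `c("large", "small", "multiple", "none")`; must sum to 1.
#' @param spec base [phantom_spec()]; its `pattern` field is overridden.
#' @param seed integer seed; fixed seed gives an identical dataset.
#' @param out_dir if non-NULL, windowed slices and masks are written there as
#'   PNG pairs plus a tab-separated `manifest.tsv`.
#' @param window HU window used for the exported intensity PNGs.
#' @return list with `pairs` (list of `image` = windowed HU matrix, `mask`,
#'   `pattern`, `case_id`) and `manifest` (data frame).
#' @export
generate_dataset <- function(n_cases, pattern_mix = c(large = 0.25,
                                                      small = 0.25,
                                                      multiple = 0.25,
                                                      none = 0.25),
                             spec = phantom_spec(), seed = 1L,
                             out_dir = NULL, window = c(-200, 250)) {
  stopifnot(n_cases >= 1)
  if (abs(sum(pattern_mix) - 1) > 1e-8) {
    stop("pattern_mix proportions must sum to 1")
  }
  counts <- largest_remainder(pattern_mix * n_cases)
  # deterministic interleaving so any contiguous split is pattern-balanced
  patterns <- with_seed(seed, sample(rep(names(pattern_mix), counts)))
  pairs <- vector("list", n_cases)
  rows <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    pat <- patterns[i]
    sp <- spec
    sp$pattern <- pat
    for (attempt in 0:19) {
      out <- generate_slice(sp, seed = (seed + 7919L * i + 1000003L * attempt)
                            %% .Machine$integer.max)
      realized <- classify_pattern(out$mask)
      if (realized == pat) break
    }
    if (realized != pat) {
      stop("could not realize pattern '", pat, "' for case ", i)
    }
    hu <- window_hu(to_hounsfield(out$volume)[, , 1L], window[1], window[2])
    case_id <- sprintf("case%04d", i)
    pairs[[i]] <- list(image = hu, mask = out$mask, pattern = pat,
                       case_id = case_id)
    rows[[i]] <- data.frame(case = case_id, slice = 0L, pattern = pat,
                            tumor_count = max(cpp_label_components(
                              out$mask == 2L)),
                            tumor_ratio = out$tumor_ratio)
    if (!is.null(out_dir)) {
      export_png(hu, out$mask, out_dir, case_id = case_id, slice_index = 0L,
                 window = window)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  list(pairs = pairs, manifest = manifest)
}

largest_remainder <- function(x) {
  base <- floor(x)
  rem <- x - base
  need <- round(sum(x)) - sum(base)
  if (need > 0) {
    ord <- order(rem, decreasing = TRUE)
    base[ord[seq_len(need)]] <- base[ord[seq_len(need)]] + 1
  }
  as.integer(base)
}
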