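#' CT volume container
#'
#' Holds a raw scanner voxel grid together with the rescale slope/intercept
#' needed for Hounsfield-unit (HU) conversion, `HU = pixel * slope + intercept`.
#' Slices are taken along the last axis of the stored array (the axial axis in
#' the LiTS storage convention); no reorientation is attempted.
#'
#' @param voxels numeric 3-d array (H x W x Z) of raw scanner values, or a
#'   matrix for a single slice.
#' @param slope HU per raw unit; must be nonzero.
#' @param intercept additive HU offset.
#' @param case_id identifier used in error messages and output file names.
#' @return an object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, slope = 1, intercept = 0, case_id = "case") {
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L)
  stopifnot(length(dim(voxels)) == 3L)
  if (!all(is.finite(voxels))) {
    stop("non-finite voxel values in case '", case_id, "'")
  }
  structure(list(voxels = voxels, slope = slope, intercept = intercept,
                 case_id = case_id),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("CT volume '%s': %d x %d x %d, slope %g, intercept %g\n",
              x$case_id, d[1], d[2], d[3], x$slope, x$intercept))
  invisible(x)
}

#' Read a CT volume from a NIfTI file
#'
#' Raw stored values are kept as read; the header's `scl_slope`/`scl_inter`
#' (0 meaning unset, i.e. slope 1 / intercept 0) populate the HU conversion
#' unless overridden.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param slope,intercept optional overrides for the header scaling.
#' @param case_id case identifier; defaults to the file name without extension.
#' @return a [ct_volume()].
#' @export
read_ct_nifti <- function(path, slope = NULL, intercept = NULL,
                          case_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  if (is.null(slope)) slope <- if (hdr$scl_slope == 0) 1 else hdr$scl_slope
  if (is.null(intercept)) {
    intercept <- if (hdr$scl_slope == 0) 0 else hdr$scl_inter
  }
  if (is.null(case_id)) {
    case_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  ct_volume(a, slope = slope, intercept = intercept, case_id = case_id)
}

#' Read a label volume from a NIfTI file
#'
#' @param path path to the segmentation NIfTI; values must be in \{0, 1, 2\}.
#' @return integer 3-d array of labels.
#' @export
read_labels_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  a <- as.array(RNifti::readNifti(path))
  attributes(a) <- list(dim = dim(a))
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  a <- round(a)
  check_labels(a)
  storage.mode(a) <- "integer"
  a
}

check_labels <- function(labels) {
  if (!all(labels %in% 0:2)) {
    stop("label values must be 0 (background), 1 (liver) or 2 (tumor)")
  }
  invisible(labels)
}

#' Convert raw scanner values to Hounsfield units
#'
#' Applies `HU = pixel * slope + intercept` elementwise.
#'
#' @param volume a [ct_volume()].
#' @return numeric array of HU values, same dimensions as the input voxels.
#' @export
to_hounsfield <- function(volume) {
  stopifnot(inherits(volume, "ct_volume"))
  if (is.null(volume$slope) || is.null(volume$intercept) ||
      is.na(volume$slope) || is.na(volume$intercept)) {
    stop("slope/intercept not set for case '", volume$case_id, "'")
  }
  if (volume$slope == 0) {
    stop("slope must be nonzero for case '", volume$case_id, "'")
  }
  volume$voxels * volume$slope + volume$intercept
}

#' Window an HU image to a tissue-relevant interval
#'
#' Values below `low` are set to `low`, values above `high` to `high`;
#' interior values pass through unchanged. The default (-200, 250) HU is a
#' standard liver window covering parenchyma and lesions while suppressing
#' air and bone.
#'
#' @param hu numeric matrix or array of HU values.
#' @param low,high window bounds in HU, `low < high`.
#' @return the windowed grid.
#' @export
window_hu <- function(hu, low = -200, high = 250) {
  if (low >= high) stop("window low must be smaller than window high")
  pmin(pmax(hu, low), high)
}

#' Gaussian denoising of a 2-d slice
#'
#' Separable convolution with a normalized Gaussian kernel truncated at radius
#' `ceiling(3*sigma)`; borders are handled by reflection, so the global image
#' mean is preserved. `sigma = 0` returns the input unchanged.
#'
#' @param x numeric matrix.
#' @param sigma kernel standard deviation in pixels, `>= 0`.
#' @return smoothed matrix of the same size.
#' @export
gaussian_smooth <- function(x, sigma = 1) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(x)
  r <- ceiling(3 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  smooth_axis <- function(m) {
    n <- nrow(m)
    # half-sample reflection (edge pixel repeated): the resulting smoothing
    # operator is doubly stochastic, so the global mean is preserved exactly
    idx <- function(i) {
      i <- ifelse(i < 1L, 1L - i, i)
      i <- ifelse(i > n, 2L * n + 1L - i, i)
      pmin(pmax(i, 1L), n)
    }
    out <- m * k[r + 1L]
    for (d in seq_len(r)) {
      out <- out + k[r + 1L + d] * m[idx(seq_len(n) + d), , drop = FALSE] +
        k[r + 1L - d] * m[idx(seq_len(n) - d), , drop = FALSE]
    }
    out
  }
  t(smooth_axis(t(smooth_axis(x))))
}

#' Split a 3-d grid into axial slices
#'
#' @param x 3-d array; slicing is along the last axis.
#' @return list of matrices.
#' @export
slice_volume <- function(x) {
  stopifnot(length(dim(x)) == 3L)
  lapply(seq_len(dim(x)[3L]), function(z) x[, , z])
}

#' Remove slice/mask pairs without any foreground
#'
#' A pair is retained iff its mask contains at least one liver or tumor pixel;
#' order is preserved. All-background slices carry no supervision signal for
#' the foreground classes and are removed from training sets.
#'
#' @param slices list of image matrices.
#' @param masks list of paired label matrices.
#' @return list with elements `slices` and `masks` (the retained pairs) and
#'   `kept` (logical vector over the input pairs).
#' @export
drop_empty_slices <- function(slices, masks) {
  if (length(slices) != length(masks)) {
    stop("slices and masks must pair one-to-one (", length(slices), " vs ",
         length(masks), ")")
  }
  kept <- vapply(masks, function(m) any(m > 0), logical(1))
  list(slices = slices[kept], masks = masks[kept], kept = kept)
}

#' Write a windowed slice and its mask as PNG files
#'
#' The intensity image maps the window range linearly to 8-bit `[0, 255]`;
#' the mask PNG stores the raw labels \{0, 1, 2\} so that a read round-trip
#' recovers them exactly.
#'
#' @param slice windowed HU matrix.
#' @param mask integer label matrix, same size.
#' @param out_dir output directory (created if needed).
#' @param case_id,slice_index used to form the file names
#'   `{case}_{slice:04d}_img.png` / `_mask.png`.
#' @param window the `(low, high)` window the slice was clipped to.
#' @return named character vector with the two file paths.
#' @export
export_png <- function(slice, mask, out_dir, case_id = "case",
                       slice_index = 0L, window = c(-200, 250)) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  stopifnot(all(dim(slice) == dim(mask)))
  check_labels(mask)
  stem <- sprintf("%s_%04d", case_id, slice_index)
  img_path <- file.path(out_dir, paste0(stem, "_img.png"))
  mask_path <- file.path(out_dir, paste0(stem, "_mask.png"))
  scaled <- (slice - window[1]) / (window[2] - window[1])
  scaled <- pmin(pmax(scaled, 0), 1)
  png::writePNG(round(scaled * 255) / 255, img_path)
  png::writePNG(mask / 255, mask_path)
  c(img = img_path, mask = mask_path)
}

#' Read an intensity PNG back to the `[0, 1]` scale
#' @param path PNG file path.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  x
}

#' Read a label-mask PNG written by [export_png()]
#' @param path PNG file path.
#' @return integer matrix over \{0, 1, 2\}.
#' @export
read_mask_png <- function(path) {
  m <- round(read_image_png(path) * 255)
  check_labels(m)
  storage.mode(m) <- "integer"
  m
}

#' Full preprocessing of one CT case
#'
#' HU conversion, windowing, Gaussian denoising, axial slicing, empty-slice
#' filtering, and optional PNG export.
#'
#' @param volume a [ct_volume()].
#' @param labels integer 3-d label array paired with the volume.
#' @param window HU window `(low, high)`.
#' @param sigma Gaussian sigma in pixels (0 disables denoising).
#' @param out_dir if non-NULL, retained pairs are written there as PNGs.
#' @return list with `slices`, `masks` (retained pairs), `kept`, and
#'   `n_total` / `n_kept` counts.
#' @export
preprocess_case <- function(volume, labels, window = c(-200, 250), sigma = 1,
                            out_dir = NULL) {
  stopifnot(all(dim(volume$voxels) == dim(labels)))
  hu <- to_hounsfield(volume)
  hu <- window_hu(hu, window[1], window[2])
  slices <- lapply(slice_volume(hu), gaussian_smooth, sigma = sigma)
  masks <- slice_volume(labels)
  filtered <- drop_empty_slices(slices, masks)
  if (!is.null(out_dir)) {
    keep_idx <- which(filtered$kept)
    for (i in seq_along(filtered$slices)) {
      export_png(filtered$slices[[i]], filtered$masks[[i]], out_dir,
                 case_id = volume$case_id, slice_index = keep_idx[i] - 1L,
                 window = window)
    }
  }
  c(filtered, list(n_total = length(slices), n_kept = length(filtered$slices)))
}
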