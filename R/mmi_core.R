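# Binarization and the Mask Matching Image (MMI): per-mask binary images
# whose set pixels mark where every reference point of the mask lands on a
# foreground pixel.

stop_if_not_binary <- function(f, arg = "f") {
  if (!is.matrix(f)) stop(sprintf("%s must be a matrix", arg))
  bad <- f[!(f == 0 | f == 1)]
  if (length(bad)) {
    stop(sprintf("%s must be binary (0/1); found value %s", arg,
                 format(bad[1])))
  }
  invisible(f)
}

#' Binarize a grayscale image
#'
#' Maps a grayscale matrix (intensities in 0..255) to a 0/1 matrix.
#' Foreground (1) is at-or-above threshold, i.e. the bright phase; pass
#' `invert = TRUE` when the structures of interest are dark (e.g. wood
#' pores imaged darker than the surrounding tissue).
#'
#' @param image Numeric matrix of intensities in \[0, 255\].
#' @param method `"otsu"` (default) selects the threshold maximizing the
#'   between-class variance over the 256 gray levels; `"fixed"` uses
#'   `threshold`; `"none"` asserts the input is already two-valued and maps
#'   its larger value to 1.
#' @param threshold Threshold in \[0, 255\] for `method = "fixed"`.
#' @param invert Logical; flip foreground and background after thresholding.
#' @return Integer 0/1 matrix with attributes `method` and `threshold`
#'   (the smallest intensity mapped to 1 before inversion).
#' @examples
#' g <- matrix(c(rep(40, 8), rep(200, 8)), 4, 4)
#' binarize(g)  # Otsu puts the cut between the two modes
#' @export
binarize <- function(image, method = c("otsu", "fixed", "none"),
                     threshold = NULL, invert = FALSE) {
  method <- match.arg(method)
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a numeric matrix")
  }
  if (method == "none") {
    vals <- sort(unique(as.vector(image)))
    if (length(vals) > 2L) {
      extra <- setdiff(vals, c(0, 1))
      stop(sprintf(
        "method 'none' requires a two-valued image; found value %s",
        format(extra[length(extra)])))
    }
    t <- max(vals)
  } else if (method == "fixed") {
    if (is.null(threshold) || threshold < 0 || threshold > 255) {
      stop("fixed binarization needs a threshold in [0, 255]")
    }
    t <- threshold
  } else {
    vals <- unique(as.vector(image))
    if (length(vals) == 1L) {
      t <- vals  # degenerate: constant image, everything is foreground
    } else {
      cut <- EBImage::otsu(EBImage::Image(image / 255),
                           range = c(0, 1), levels = 256L) * 255
      t <- ceiling(cut)  # smallest integer intensity mapped to foreground
    }
  }
  out <- matrix(as.integer(image >= t), nrow(image), ncol(image))
  if (invert) out <- 1L - out
  attr(out, "method") <- method
  attr(out, "threshold") <- t
  out
}

#' Compute the Mask Matching Image for one mask
#'
#' The MMI of a binary image `f` under mask `m` is the binary image whose
#' pixel (x, y) is 1 exactly when every offset of the mask, applied at
#' (x, y), lands inside `f` and on a set pixel (the product of `f` over the
#' mask's reference points). Positions where any offset falls outside the
#' image are 0: no padding is assumed, so the pixel sum of the MMI equals
#' the HLAC match count with no phantom matches at the border.
#'
#' @param f Binary (0/1) matrix.
#' @param mask An `mmi_mask` (see [enumerate_masks()]).
#' @return Integer 0/1 matrix with the dimensions of `f` and attribute
#'   `mask_index`.
#' @export
compute_mmi <- function(f, mask) {
  stop_if_not_binary(f)
  if (!inherits(mask, "mmi_mask")) stop("mask must be an 'mmi_mask'")
  h <- nrow(f); w <- ncol(f)
  pts <- mask$points
  out <- matrix(0L, h, w)
  r0 <- 1L - min(pts[, 1L]); r1 <- h - max(pts[, 1L])
  c0 <- 1L - min(pts[, 2L]); c1 <- w - max(pts[, 2L])
  if (r0 <= r1 && c0 <= c1) {
    acc <- matrix(TRUE, r1 - r0 + 1L, c1 - c0 + 1L)
    for (k in seq_len(nrow(pts))) {
      acc <- acc & (f[(r0:r1) + pts[k, 1L], (c0:c1) + pts[k, 2L],
                      drop = FALSE] == 1L)
    }
    out[r0:r1, c0:c1] <- as.integer(acc)
  }
  attr(out, "mask_index") <- mask$index
  out
}

#' HLAC match count for one mask
#'
#' The number of image positions where the mask matches: the pixel sum of
#' [compute_mmi()]. This single number per mask is the classical HLAC
#' feature.
#'
#' @inheritParams compute_mmi
#' @return Non-negative integer.
#' @export
hlac_count <- function(f, mask) {
  sum(compute_mmi(f, mask))
}

#' Compute the MMI for every mask of a bank
#'
#' @param f Binary (0/1) matrix.
#' @param bank An `mmi_mask_bank`.
#' @return List of MMI matrices, in bank order.
#' @export
compute_mmi_stack <- function(f, bank) {
  stopifnot(inherits(bank, "mmi_mask_bank"))
  stop_if_not_binary(f)
  lapply(bank$masks, function(m) compute_mmi(f, m))
}
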