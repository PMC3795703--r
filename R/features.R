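# Features derived from Mask Matching Images: connected-component
# statistics (SSMMI) and maximal-run-length width/height histograms (the
# length histogram, LH).

#' Areas of the connected subgraphs of a binary image
#'
#' Labels the maximal connected groups of set pixels and returns their
#' areas. The default 4-connectivity links horizontally and vertically
#' adjacent foreground pixels — the only adjacencies the MMI feature
#' definitions use; 8-connectivity additionally links diagonal neighbors.
#'
#' @param mmi Binary (0/1) matrix (typically an MMI).
#' @param connectivity 4 (default) or 8.
#' @return A list with `areas` (integer vector of component areas, sorted
#'   increasing) and `L` (the number of components). `L == 0` and empty
#'   `areas` for an all-zero image.
#' @export
component_areas <- function(mmi, connectivity = 4L) {
  stop_if_not_binary(mmi, "mmi")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  lab <- label_components(mmi, connectivity)
  areas <- tabulate(lab[lab > 0L])
  areas <- sort(areas[areas > 0L])
  list(areas = as.integer(areas), L = length(areas))
}

# Connected-component labels. EBImage::bwlabel provides 4-connectivity;
# 8-connectivity is obtained by merging 4-components that touch diagonally.
label_components <- function(f, connectivity = 4L) {
  lab <- matrix(as.integer(EBImage::bwlabel(f)), nrow(f), ncol(f))
  if (connectivity == 4L || max(lab) == 0L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  pairs <- NULL
  if (h > 1L && w > 1L) {
    dr <- cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1]))  # down-right
    dl <- cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w]))  # down-left
    pairs <- rbind(dr, dl)
    pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L, , drop = FALSE]
  }
  if (is.null(pairs) || nrow(pairs) == 0L) return(lab)
  parent <- seq_len(max(lab))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1L]); b <- find(pairs[k, 2L])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_along(parent), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  lab
}

#' Five simple statistical features of an MMI (one SSMMI block)
#'
#' From the multiset of connected-subgraph areas: the total area S (equal
#' to the HLAC match count), the number of subgraphs L, and the maximum,
#' minimum and mean area. All five are 0 for an empty MMI.
#'
#' @param areas Integer vector of component areas, or the list returned by
#'   [component_areas()].
#' @return Named numeric vector `c(S, L, max, min, mean)`.
#' @examples
#' ssmmi_stats(c(1, 3))  # S=4 L=2 max=3 min=1 mean=2
#' @export
ssmmi_stats <- function(areas) {
  if (is.list(areas)) areas <- areas$areas
  if (length(areas) == 0L) {
    return(c(S = 0, L = 0, max = 0, min = 0, mean = 0))
  }
  c(S = sum(areas), L = length(areas), max = max(areas),
    min = min(areas), mean = sum(areas) / length(areas))
}

#' Width histogram: maximal horizontal runs by length
#'
#' Counts the maximal horizontal line segments of foreground pixels —
#' runs that cannot be extended left or right — bucketed by length. Bin i
#' holds the number of segments of length i, for i in 1..W. Each row is
#' scanned once, so the cost is linear in the number of pixels.
#'
#' @param mmi Binary (0/1) matrix.
#' @return Integer vector of length `ncol(mmi)`; entry i counts the
#'   horizontal segments of length i.
#' @export
width_histogram <- function(mmi) {
  stop_if_not_binary(mmi, "mmi")
  w <- ncol(mmi)
  runs <- unlist(lapply(seq_len(nrow(mmi)), function(r) {
    z <- rle(mmi[r, ])
    z$lengths[z$values == 1L]
  }), use.names = FALSE)
  if (length(runs) == 0L) return(integer(w))
  tabulate(runs, nbins = w)
}

#' Height histogram: maximal vertical runs by length
#'
#' The vertical counterpart of [width_histogram()]: bin i (i in 1..H)
#' counts the maximal vertical line segments of length i. Equals the width
#' histogram of the transposed image.
#'
#' @param mmi Binary (0/1) matrix.
#' @return Integer vector of length `nrow(mmi)`.
#' @export
height_histogram <- function(mmi) {
  width_histogram(t(mmi))
}

#' Extract a per-image feature vector
#'
#' Binarizes the image, computes the MMI for every mask of the bank, and
#' concatenates one block per mask in bank order:
#' \describe{
#'   \item{`hlac`}{1 number per mask — the match count (classical HLAC).}
#'   \item{`ssmmi`}{5 numbers per mask — S, L, max, min, mean of the
#'     connected-subgraph areas.}
#'   \item{`lh`}{W + H numbers per mask — the width histogram (bins 1..W)
#'     followed by the height histogram (bins 1..H).}
#' }
#' Vector names encode the layout as `m<index>.<feature>`, e.g. `m2.L`,
#' `m2.w17`, `m7.h3`.
#'
#' @param image Numeric grayscale matrix (0..255), or an already binary
#'   matrix with `binarize_method = "none"`.
#' @param bank An `mmi_mask_bank`.
#' @param kind `"ssmmi"`, `"lh"` or `"hlac"`.
#' @param binarize_method,threshold,invert Passed to [binarize()].
#' @param connectivity Component connectivity for `kind = "ssmmi"`.
#' @return Named numeric vector; length `|bank|`, `5 |bank|` or
#'   `(W + H) |bank|` depending on `kind`.
#' @export
extract_features <- function(image, bank, kind = c("ssmmi", "lh", "hlac"),
                             binarize_method = "otsu", threshold = NULL,
                             invert = FALSE, connectivity = 4L) {
  kind <- match.arg(kind)
  stopifnot(inherits(bank, "mmi_mask_bank"))
  f <- binarize(image, binarize_method, threshold = threshold,
                invert = invert)
  h <- nrow(f); w <- ncol(f)
  blocks <- lapply(bank$masks, function(m) {
    g <- compute_mmi(f, m)
    val <- switch(kind,
      hlac = c(count = as.numeric(sum(g))),
      ssmmi = ssmmi_stats(component_areas(g, connectivity)),
      lh = stats::setNames(
        as.numeric(c(width_histogram(g), height_histogram(g))),
        c(paste0("w", seq_len(w)), paste0("h", seq_len(h)))))
    names(val) <- paste0("m", m$index, ".", names(val))
    val
  })
  unlist(blocks, use.names = TRUE)
}

#' Extract a feature table for a labeled image set
#'
#' Applies [extract_features()] to every image of a dataset (as produced by
#' [generate_dataset()] or [load_image_dataset()]) and assembles a data
#' frame with one row per image. All images must share the same dimensions
#' so length-histogram bins align across the dataset.
#'
#' @param dataset List with elements `images` (list of matrices), `labels`
#'   and optionally `ids`.
#' @inheritParams extract_features
#' @return Data frame with columns `label`, `id`, then one column per
#'   feature (named as in [extract_features()]).
#' @export
extract_feature_table <- function(dataset, bank,
                                  kind = c("ssmmi", "lh", "hlac"),
                                  binarize_method = "otsu", threshold = NULL,
                                  invert = FALSE, connectivity = 4L) {
  kind <- match.arg(kind)
  imgs <- dataset$images
  if (length(imgs) == 0L) stop("dataset contains no images")
  ids <- dataset$ids %||% as.character(seq_along(imgs))
  d0 <- dim(imgs[[1L]])
  for (i in seq_along(imgs)) {
    if (!identical(dim(imgs[[i]]), d0)) {
      stop(sprintf(
        "image '%s' is %dx%d but the first image is %dx%d; all images must share one size",
        ids[i], nrow(imgs[[i]]), ncol(imgs[[i]]), d0[1L], d0[2L]))
    }
  }
  feats <- lapply(imgs, extract_features, bank = bank, kind = kind,
                  binarize_method = binarize_method, threshold = threshold,
                  invert = invert, connectivity = connectivity)
  mat <- do.call(rbind, feats)
  out <- data.frame(label = as.character(dataset$labels), id = ids,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(mat, optional = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
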