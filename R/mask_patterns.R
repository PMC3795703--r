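# HLAC mask patterns: origin-rooted point sets inside the 3x3 displacement
# window, deduplicated up to translation.

#' Canonical translation key of a mask point set
#'
#' Translates a set of pixel offsets so the minimum corner of its bounding
#' box sits at (0,0) and serializes the points in lexicographic (row, col)
#' order. Two point sets are translates of each other if and only if their
#' canonical keys are equal; the key therefore identifies the
#' translation-equivalence class a mask belongs to.
#'
#' @param points Integer matrix with one row per point and two columns
#'   (row offset, column offset).
#' @return A single string, e.g. `"0,0;0,1"`.
#' @examples
#' canonical_key(rbind(c(0, 0), c(0, 1)))
#' canonical_key(rbind(c(0, -1), c(0, 0)))  # same class as above
#' @export
canonical_key <- function(points) {
  points <- as_points(points)
  if (nrow(points) == 0L) {
    stop("a mask must contain at least one point")
  }
  points[, 1L] <- points[, 1L] - min(points[, 1L])
  points[, 2L] <- points[, 2L] - min(points[, 2L])
  points <- points[order(points[, 1L], points[, 2L], method = "radix"), ,
                   drop = FALSE]
  paste(points[, 1L], points[, 2L], sep = ",", collapse = ";")
}

as_points <- function(points) {
  if (is.null(dim(points))) {
    points <- matrix(as.integer(points), ncol = 2L)
  }
  storage.mode(points) <- "integer"
  if (ncol(points) != 2L || anyNA(points)) {
    stop("mask points must be an integer matrix with two columns")
  }
  unique(points)
}

#' Construct a single mask pattern
#'
#' Builds an `mmi_mask` from explicit offsets, for use with
#' [compute_mmi()] and [hlac_count()] outside an enumerated bank. The
#' points must lie in the 3x3 window and include the origin.
#'
#' @param points Integer matrix of (row, col) offsets in \{-1, 0, 1\},
#'   one row per point.
#' @return An `mmi_mask`.
#' @examples
#' mask_pattern(rbind(c(0, 0), c(0, 1)))  # horizontal pair
#' @export
mask_pattern <- function(points) {
  points <- as_points(points)
  if (nrow(points) == 0L) stop("a mask must contain at least one point")
  if (any(points < -1L | points > 1L)) {
    stop("mask offsets must lie within the 3x3 window (components in -1..1)")
  }
  if (!any(points[, 1L] == 0L & points[, 2L] == 0L)) {
    stop("a mask must contain the origin (0,0)")
  }
  new_mask(points)
}

new_mask <- function(points, index = NA_integer_) {
  points <- as_points(points)
  structure(
    list(points = points,
         order = nrow(points) - 1L,
         index = index,
         key = canonical_key(points)),
    class = "mmi_mask")
}

#' Enumerate distinct HLAC mask patterns up to a given order
#'
#' Generates every subset of the 3x3 offset window that contains the origin
#' and has at most `max_order + 1` points, then merges subsets that are
#' translates of one another (the autocorrelation sum is shift-invariant, so
#' translated masks count exactly the same matches). The surviving classes
#' are sorted by (order, canonical key) and indexed from 1. The bank sizes
#' are 1, 5, 25, ... , 223 for `max_order` 0, 1, 2, ... , 8.
#'
#' Each retained mask keeps an origin-containing representative: the first
#' member of its class encountered while scanning subsets in a fixed binary
#' counting order over the eight non-origin cells.
#'
#' @param max_order Maximum autocorrelation order (number of displacement
#'   vectors), an integer in 0..8. Order 2 gives the classical 25-mask bank;
#'   order 8 gives the full 223-mask bank.
#' @return An object of class `mmi_mask_bank`: a list with elements
#'   `masks` (list of `mmi_mask`) and `max_order`.
#' @examples
#' length(enumerate_masks(2)$masks)  # 25
#' @export
enumerate_masks <- function(max_order = 2L) {
  max_order <- as.integer(max_order)
  if (length(max_order) != 1L || is.na(max_order) ||
      max_order < 0L || max_order > 8L) {
    stop("max_order must be a single integer in [0, 8]")
  }
  cells <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  cells <- cells[order(cells[, 1L], cells[, 2L], method = "radix"), ]
  non_origin <- cells[!(cells[, 1L] == 0L & cells[, 2L] == 0L), , drop = FALSE]

  seen <- new.env(parent = emptyenv())
  masks <- vector("list", 256L)
  n_kept <- 0L
  for (m in 0:255) {
    bits <- as.integer(intToBits(m))[1:8]
    if (sum(bits) + 1L > max_order + 1L) next
    pts <- rbind(c(0L, 0L), non_origin[bits == 1L, , drop = FALSE])
    key <- canonical_key(pts)
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      n_kept <- n_kept + 1L
      masks[[n_kept]] <- new_mask(pts)
    }
  }
  masks <- masks[seq_len(n_kept)]
  ord <- order(vapply(masks, `[[`, integer(1), "order"),
               vapply(masks, `[[`, character(1), "key"),
               method = "radix")
  masks <- masks[ord]
  for (i in seq_along(masks)) masks[[i]]$index <- i
  structure(list(masks = masks, max_order = max_order),
            class = "mmi_mask_bank")
}

#' @export
length.mmi_mask_bank <- function(x) length(x$masks)

#' Render a mask as a 3x3 grid
#'
#' @param mask An `mmi_mask`.
#' @return A 3x3 integer matrix of 0/1, the window centered on the origin.
#' @export
mask_grid <- function(mask) {
  g <- matrix(0L, 3L, 3L)
  g[cbind(mask$points[, 1L] + 2L, mask$points[, 2L] + 2L)] <- 1L
  g
}

#' @export
format.mmi_mask <- function(x, ...) {
  g <- mask_grid(x)
  paste(apply(g, 1L, paste, collapse = " "), collapse = "\n")
}

#' @export
print.mmi_mask <- function(x, ...) {
  cat(sprintf("mask %s (order %d)\n", x$index, x$order))
  cat(format(x), "\n")
  invisible(x)
}

#' @export
print.mmi_mask_bank <- function(x, ...) {
  cat(sprintf("HLAC mask bank: %d masks, max order %d\n",
              length(x), x$max_order))
  tab <- table(vapply(x$masks, `[[`, integer(1), "order"))
  cat("masks per order:",
      paste(sprintf("%s:%s", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Tabulate a mask bank
#'
#' @param x An `mmi_mask_bank`.
#' @param row.names,optional,... Ignored; present for the generic.
#' @return A data frame with columns `index`, `order` and `offsets`
#'   (the representative's offsets, serialized as `"dr,dc;..."`).
#' @export
as.data.frame.mmi_mask_bank <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(
    index = vapply(x$masks, `[[`, integer(1), "index"),
    order = vapply(x$masks, `[[`, integer(1), "order"),
    offsets = vapply(x$masks, function(m) {
      p <- m$points[order(m$points[, 1L], m$points[, 2L], method = "radix"), ,
                    drop = FALSE]
      paste(p[, 1L], p[, 2L], sep = ",", collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE)
}
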