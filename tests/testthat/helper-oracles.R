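# Independent brute-force oracles used to validate the vectorized
# implementations. These deliberately use naive per-pixel loops and
# explicit adjacency checks.

# Number of positions where every mask offset lands in-bounds on a set
# pixel: direct triple loop over positions x offsets.
brute_hlac <- function(f, pts) {
  h <- nrow(f); w <- ncol(f); n <- nrow(pts)
  cnt <- 0L
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      ok <- TRUE
      for (k in seq_len(n)) {
        rr <- r + pts[k, 1L]; cc <- c + pts[k, 2L]
        if (rr < 1L || rr > h || cc < 1L || cc > w || f[rr, cc] != 1L) {
          ok <- FALSE
          break
        }
      }
      if (ok) cnt <- cnt + 1L
    }
  }
  cnt
}

# Lengths of all maximal horizontal runs, found by explicit adjacency
# checking: a run starts where the left neighbor is background (or the
# border) and ends where the right neighbor is.
brute_width_runs <- function(f) {
  h <- nrow(f); w <- ncol(f)
  runs <- integer(0)
  for (r in seq_len(h)) {
    c <- 1L
    while (c <= w) {
      if (f[r, c] == 1L && (c == 1L || f[r, c - 1L] == 0L)) {
        len <- 0L
        while (c + len <= w && f[r, c + len] == 1L) len <- len + 1L
        runs <- c(runs, len)
        c <- c + len
      } else {
        c <- c + 1L
      }
    }
  }
  runs
}

brute_height_runs <- function(f) brute_width_runs(t(f))

brute_hist <- function(runs, nbins) {
  if (length(runs) == 0L) return(integer(nbins))
  tabulate(runs, nbins = nbins)
}

# Component areas by stack-based flood fill.
brute_component_areas <- function(f, connectivity = 4L) {
  h <- nrow(f); w <- ncol(f)
  if (connectivity == 4L) {
    nb <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else {
    nb <- as.matrix(expand.grid(-1:1, -1:1))
    nb <- nb[!(nb[, 1L] == 0L & nb[, 2L] == 0L), ]
  }
  seen <- matrix(FALSE, h, w)
  areas <- integer(0)
  for (r0 in seq_len(h)) {
    for (c0 in seq_len(w)) {
      if (f[r0, c0] != 1L || seen[r0, c0]) next
      stack <- list(c(r0, c0))
      seen[r0, c0] <- TRUE
      area <- 0L
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        area <- area + 1L
        for (k in seq_len(nrow(nb))) {
          rr <- p[1L] + nb[k, 1L]; cc <- p[2L] + nb[k, 2L]
          if (rr >= 1L && rr <= h && cc >= 1L && cc <= w &&
              f[rr, cc] == 1L && !seen[rr, cc]) {
            seen[rr, cc] <- TRUE
            stack[[length(stack) + 1L]] <- c(rr, cc)
          }
        }
      }
      areas <- c(areas, area)
    }
  }
  sort(areas)
}

rand_binary <- function(h, w, p = 0.5) {
  matrix(rbinom(h * w, 1L, p), h, w)
}

# All 512 binary 3x3 images.
all_3x3_images <- function() {
  lapply(0:511, function(m) {
    matrix(as.integer(intToBits(m))[1:9], 3L, 3L)
  })
}

# Component id for each set pixel of f (order of which(f == 1, arr.ind)),
# derived from the flood-fill oracle's traversal.
brute_component_label <- function(f, connectivity = 4L) {
  h <- nrow(f); w <- ncol(f)
  nb <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  lab <- matrix(0L, h, w)
  nextlab <- 0L
  for (c0 in seq_len(w)) {
    for (r0 in seq_len(h)) {
      if (f[r0, c0] != 1L || lab[r0, c0] > 0L) next
      nextlab <- nextlab + 1L
      stack <- list(c(r0, c0))
      lab[r0, c0] <- nextlab
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (k in seq_len(nrow(nb))) {
          rr <- p[1L] + nb[k, 1L]; cc <- p[2L] + nb[k, 2L]
          if (rr >= 1L && rr <= h && cc >= 1L && cc <= w &&
              f[rr, cc] == 1L && lab[rr, cc] == 0L) {
            lab[rr, cc] <- nextlab
            stack[[length(stack) + 1L]] <- c(rr, cc)
          }
        }
      }
    }
  }
  lab[which(f == 1L)]
}
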