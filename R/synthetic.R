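# Synthetic inputs: the canonical 16-pixel worked-example configurations,
# and a seeded generator of wood-cross-section-like textures (pore-like
# blobs, ray-like vertical streaks, background granularity) so the full
# pipeline is testable without any external dataset.

#' Canonical 16-pixel binary configurations
#'
#' Deterministic fixtures on a 12x12 canvas (1x16 for the bar), each with
#' exactly 16 set pixels but very different connectivity structure:
#' \describe{
#'   \item{`singletons16`}{16 isolated pixels on a spaced lattice
#'     (pairwise Chebyshev distance 3): L = 16 components of area 1.}
#'   \item{`blocks2x2`}{four solid 2x2 blocks: L = 4, areas 4.}
#'   \item{`blocks2x4`}{two solid 2x4 blocks: L = 2, areas 8.}
#'   \item{`block4x4`}{one solid 4x4 block: L = 1, area 16.}
#'   \item{`bar1x16`}{a single 1x16 horizontal bar: one maximal horizontal
#'     run of length 16.}
#' }
#' Groups are separated by at least 2 background pixels and sit at least 1
#' pixel from the border. All five have identical match count (16) under
#' the single-point mask, while their component counts, areas and run
#' lengths differ — the configurations that motivate the MMI features.
#'
#' @param name One of `"singletons16"`, `"blocks2x2"`, `"blocks2x4"`,
#'   `"block4x4"`, `"bar1x16"`.
#' @return Integer 0/1 matrix.
#' @export
make_configuration <- function(name = c("singletons16", "blocks2x2",
                                        "blocks2x4", "block4x4",
                                        "bar1x16")) {
  name <- match.arg(name)
  if (name == "bar1x16") {
    return(matrix(1L, 1L, 16L))
  }
  f <- matrix(0L, 12L, 12L)
  switch(name,
    singletons16 = {
      at <- c(2L, 5L, 8L, 11L)
      f[as.matrix(expand.grid(at, at))] <- 1L
    },
    blocks2x2 = {
      for (r in c(2L, 8L)) for (c in c(2L, 8L)) {
        f[r:(r + 1L), c:(c + 1L)] <- 1L
      }
    },
    blocks2x4 = {
      f[3:4, 4:7] <- 1L
      f[9:10, 4:7] <- 1L
    },
    block4x4 = {
      f[5:8, 5:8] <- 1L
    })
  f
}

#' Generate one wood-like grayscale texture
#'
#' Emulates the cross-section anatomy that differentiates wood species at
#' the texture level: bright elliptical pore-like blobs scattered over a
#' darker granular background, periodic bright vertical streaks standing in
#' for wood rays, and sparse salt noise. The blob count is Poisson with
#' mean `pore_density`; blob radii are uniform in `pore_radius`. Identical
#' seeds give identical images.
#'
#' @param height,width Image size in pixels (default 100x100, the size the
#'   pipeline targets).
#' @param pore_density Expected number of pore blobs per image.
#' @param pore_radius Length-2 range (pixels) for blob semi-axes.
#' @param ray_period Column spacing of the vertical ray streaks; 0 disables
#'   rays.
#' @param ray_width Streak width in pixels.
#' @param noise_level Per-pixel probability of salt noise (value 255).
#' @param background,background_sd Mean and s.d. of the background
#'   intensity.
#' @param pore_level,ray_level Foreground intensities of blobs and rays.
#' @param seed Optional integer seed; when given the current RNG state is
#'   left untouched.
#' @return Integer matrix with intensities in 0..255.
#' @export
generate_wood_texture <- function(height = 100L, width = 100L,
                                  pore_density = 12, pore_radius = c(2, 5),
                                  ray_period = 10, ray_width = 1L,
                                  noise_level = 0.005,
                                  background = 50, background_sd = 10,
                                  pore_level = 210, ray_level = 170,
                                  seed = NULL) {
  if (height < 1L || width < 1L) stop("degenerate image size")
  if (max(pore_radius) >= min(height, width) / 2) {
    stop("pore radii must be smaller than half the image size")
  }
  draw <- function() {
    img <- matrix(stats::rnorm(height * width, background, background_sd),
                  height, width)
    if (ray_period >= 1) {
      phase <- sample.int(max(1L, as.integer(round(ray_period))), 1L)
      for (c0 in seq(phase, width, by = ray_period)) {
        cc <- c0:min(width, c0 + ray_width - 1L)
        img[, cc] <- ray_level +
          stats::rnorm(height * length(cc), 0, background_sd / 2)
      }
    }
    n_pores <- stats::rpois(1L, pore_density)
    if (n_pores > 0L) {
      rows <- matrix(seq_len(height), height, width)
      cols <- matrix(seq_len(width), height, width, byrow = TRUE)
      for (i in seq_len(n_pores)) {
        cy <- stats::runif(1, 1, height)
        cx <- stats::runif(1, 1, width)
        ry <- stats::runif(1, pore_radius[1L], pore_radius[2L])
        rx <- stats::runif(1, pore_radius[1L], pore_radius[2L])
        inside <- ((rows - cy) / ry)^2 + ((cols - cx) / rx)^2 <= 1
        img[inside] <- pore_level + stats::rnorm(sum(inside), 0, 5)
      }
    }
    if (noise_level > 0) {
      img[stats::runif(height * width) < noise_level] <- 255
    }
    matrix(as.integer(pmin(255, pmax(0, round(img)))), height, width)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Parameter presets for distinguishable texture classes
#'
#' Class parameter sets that differ in pore density, pore size, and ray
#' spacing/width — the anatomical axes along which wood species differ.
#' The first four are the benchmark classes used throughout the package's
#' examples and tests; larger `n_classes` extends the grid with graded
#' variants.
#'
#' @param n_classes Number of classes (>= 2).
#' @return Named list of parameter lists accepted by
#'   [generate_wood_texture()].
#' @export
texture_presets <- function(n_classes = 4L) {
  if (n_classes < 2L) stop("need at least 2 classes")
  base <- list(
    dense_small  = list(pore_density = 25, pore_radius = c(2, 3),
                        ray_period = 7,  ray_width = 1L),
    sparse_large = list(pore_density = 6,  pore_radius = c(5, 7),
                        ray_period = 7,  ray_width = 1L),
    dense_wideray = list(pore_density = 25, pore_radius = c(2, 3),
                         ray_period = 15, ray_width = 3L),
    sparse_wideray = list(pore_density = 6, pore_radius = c(5, 7),
                          ray_period = 15, ray_width = 3L))
  if (n_classes <= 4L) return(base[seq_len(n_classes)])
  extra <- lapply(seq_len(n_classes - 4L), function(i) {
    list(pore_density = 4 + 3 * i,
         pore_radius = c(2, 3) + (i %% 4),
         ray_period = 6 + (i %% 5) * 3,
         ray_width = 1L + (i %% 3))
  })
  names(extra) <- sprintf("variant_%02d", seq_along(extra))
  c(base, extra)
}

#' Generate a labeled synthetic texture dataset
#'
#' Draws `n_per_class` images for each class parameter set. A master seed
#' spawns one sub-seed per image, so the whole dataset is reproducible and
#' individual images can be regenerated independently.
#'
#' @param class_params Named list of parameter lists (see
#'   [texture_presets()]); names become class labels.
#' @param n_per_class Images per class (the reference layout is 20, as in
#'   a 24-species x 20-stereogram collection).
#' @param seed Master seed.
#' @return List with `images` (list of grayscale matrices), `labels`
#'   (factor) and `ids`.
#' @export
generate_dataset <- function(class_params = texture_presets(4L),
                             n_per_class = 20L, seed = 1L) {
  if (length(class_params) < 2L) stop("need at least 2 classes")
  if (is.null(names(class_params))) {
    names(class_params) <- sprintf("class_%02d", seq_along(class_params))
  }
  n_total <- length(class_params) * n_per_class
  image_seeds <- withr::with_seed(
    seed, sample.int(.Machine$integer.max, n_total))
  images <- vector("list", n_total)
  labels <- character(n_total)
  ids <- character(n_total)
  k <- 0L
  for (cl in names(class_params)) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      images[[k]] <- do.call(generate_wood_texture,
                             c(class_params[[cl]],
                               list(seed = image_seeds[k])))
      labels[k] <- cl
      ids[k] <- sprintf("%s_%02d", cl, i)
    }
  }
  list(images = images, labels = factor(labels), ids = ids)
}
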