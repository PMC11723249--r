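#' Synthetic H&E-like image generation
#'
#' Every test in this package runs without downloading pathology data: a
#' generator emulates the two properties of H&E histology that the network
#' and the data pipeline actually exploit:
#'
#' * class-discriminative periodic texture — each class is assigned a
#'   dominant spatial frequency, so the frequency-domain operators are
#'   discriminative by construction;
#' * elliptical "nuclei" rendered in hematoxylin-like coloration on an
#'   eosin-pink background, with controlled counts and guaranteed
#'   separation, giving the nucleus-count filter an exact ground truth.
#'
#' Images are deterministic given the seed (byte-identical PNG output).
#'
#' @name synthetic
NULL

#' Specification of a synthetic dataset
#'
#' Defaults define the standing test-bed conditions of this package: two
#' texture classes (4 vs 16 cycles/image) of 16 images each at 64 px.
#'
#' @param classes number of classes.
#' @param per_class images per class.
#' @param size square image size in pixels.
#' @param frequencies dominant texture frequency per class in cycles/image;
#'   default doubles from 4 (4, 16, 32, ... capped at `size / 4`).
#' @param nuclei_range inclusive range of nuclei per image.
#' @param noise_sd gaussian stain-noise level on [0, 1] intensities.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(classes = 2L, per_class = 16L, size = 64L,
                           frequencies = NULL,
                           nuclei_range = c(3L, 8L), noise_sd = 0.05) {
  if (is.null(frequencies)) {
    if (classes > 8L) stop("supply frequencies explicitly for more than 8 classes")
    frequencies <- pmin(c(4L, 16L, 8L, 24L, 6L, 20L, 12L, 28L)[seq_len(classes)],
                        size %/% 4L)
  }
  stopifnot(length(frequencies) == classes, all(nuclei_range >= 0))
  structure(list(classes = as.integer(classes), per_class = as.integer(per_class),
                 size = as.integer(size), frequencies = frequencies,
                 nuclei_range = as.integer(nuclei_range), noise_sd = noise_sd),
            class = "synthetic_spec")
}

# Hematoxylin-ish nucleus color and eosin-pink background (RGB in [0, 1]).
.he_nucleus_rgb <- c(0.32, 0.22, 0.54)
.he_background_rgb <- c(0.93, 0.79, 0.88)

#' Render one H&E-like patch with a known number of nuclei
#'
#' Background is eosin-pink modulated by a sinusoidal grating at
#' `texture_freq` cycles/image (random orientation and phase); nuclei are
#' hematoxylin-colored ellipses placed by rejection sampling so that they
#' never touch, making the rendered count an exact ground truth for the
#' nucleus counter. Uses the current RNG state.
#'
#' @param height,width patch size in pixels.
#' @param n_nuclei number of ellipses to place.
#' @param texture_freq grating frequency in cycles per image (0 disables).
#' @param noise_sd gaussian noise level.
#' @param axis_range semi-axis range of the ellipses in pixels.
#' @return list with `img` (array `(height, width, 3)` in [0, 1]) and
#'   `centers` (n x 2 matrix of row/col centers; may have fewer rows than
#'   requested if the patch is too crowded, see `placed`).
#' @export
render_he_patch <- function(height, width, n_nuclei, texture_freq = 0,
                            noise_sd = 0.05, axis_range = c(4, 7)) {
  hh <- matrix(seq_len(height), height, width)
  ww <- matrix(seq_len(width), height, width, byrow = TRUE)
  img <- array(rep(.he_background_rgb, each = height * width),
               dim = c(height, width, 3))
  if (texture_freq > 0) {
    theta <- stats::runif(1, 0, pi)
    phase <- stats::runif(1, 0, 2 * pi)
    gr <- sin(2 * pi * texture_freq *
                (cos(theta) * hh / height + sin(theta) * ww / width) + phase)
    img[, , 1] <- img[, , 1] - 0.06 * gr
    img[, , 2] <- img[, , 2] - 0.12 * gr
    img[, , 3] <- img[, , 3] - 0.04 * gr
  }
  centers <- matrix(0, 0, 2)
  if (n_nuclei > 0) {
    amax <- max(axis_range)
    margin <- amax + 2
    mind <- 2 * amax + 3                    # guaranteed disjoint components
    tries <- 0L
    while (nrow(centers) < n_nuclei && tries < 4000L) {
      tries <- tries + 1L
      cand <- c(stats::runif(1, margin, height - margin),
                stats::runif(1, margin, width - margin))
      if (nrow(centers) == 0 ||
          min(sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)) > mind) {
        centers <- rbind(centers, cand)
      }
    }
    for (k in seq_len(nrow(centers))) {
      a <- stats::runif(1, axis_range[1], axis_range[2])
      b <- stats::runif(1, axis_range[1], axis_range[2])
      ang <- stats::runif(1, 0, pi)
      dy <- hh - centers[k, 1]
      dx <- ww - centers[k, 2]
      ry <- cos(ang) * dy + sin(ang) * dx
      rx <- -sin(ang) * dy + cos(ang) * dx
      inside <- (ry / a)^2 + (rx / b)^2 <= 1
      jitter <- stats::rnorm(3, 0, 0.03)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[inside] <- min(max(.he_nucleus_rgb[ch] + jitter[ch], 0), 1)
        img[, , ch] <- plane
      }
    }
  }
  if (noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, noise_sd), dim = dim(img))
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  list(img = img, centers = centers, placed = nrow(centers))
}

#' Generate a synthetic dataset on disk
#'
#' Writes one PNG per image under `out_dir/class_<k>/`, assigns stratified
#' train/val/test splits, and writes `manifest.csv`
#' (`path,label,magnification,split`). Byte-identical output under the same
#' seed.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @param split_fractions passed to [stratified_split()].
#' @return the dataset manifest (data.frame, see [scan_breakhis()] for the
#'   column contract).
#' @export
generate_synthetic_dataset <- function(spec, out_dir, seed = 1L,
                                       split_fractions = c(0.6, 0.2, 0.2)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory ", out_dir)
  }
  set.seed(seed)
  rows <- list()
  for (k in seq_len(spec$classes)) {
    cls <- sprintf("class_%d", k - 1L)
    cdir <- file.path(out_dir, cls)
    dir.create(cdir, showWarnings = FALSE)
    for (i in seq_len(spec$per_class)) {
      nn <- sample(seq(spec$nuclei_range[1], spec$nuclei_range[2]), 1L)
      p <- render_he_patch(spec$size, spec$size, nn,
                           texture_freq = spec$frequencies[k],
                           noise_sd = spec$noise_sd,
                           axis_range = c(3, 5.5))
      path <- file.path(cdir, sprintf("img_%03d.png", i))
      png::writePNG(p$img, path)
      rows[[length(rows) + 1L]] <- data.frame(
        path = path, label = cls, magnification = NA_integer_,
        split = NA_character_, stringsAsFactors = FALSE)
    }
  }
  man <- new_manifest(do.call(rbind, rows), source = "synthetic")
  stratified_split(man, fractions = split_fractions, seed = seed)
}

#' Render a BACH-sized synthetic slide tile with per-patch nucleus counts
#'
#' Builds a `height x width` image (default 1536 x 2048) as a grid of
#' 512 px cells; cell `(r, c)` is rendered with `counts[r, c]` nuclei.
#' This gives [extract_bach_patches()] an exact per-patch ground truth.
#'
#' @param counts integer matrix (rows x cols of 512-px cells) of nucleus
#'   counts; default 3 x 4.
#' @param texture_freq grating frequency per cell in cycles/cell.
#' @param noise_sd noise level.
#' @param seed integer seed.
#' @return list with `img` and the `counts` matrix used.
#' @export
render_synthetic_bach_image <- function(counts = matrix(25L, 3L, 4L),
                                        texture_freq = 8, noise_sd = 0.03,
                                        seed = 1L) {
  set.seed(seed)
  ps <- 512L
  H <- nrow(counts) * ps
  W <- ncol(counts) * ps
  img <- array(0, dim = c(H, W, 3))
  for (r in seq_len(nrow(counts))) {
    for (c in seq_len(ncol(counts))) {
      cell <- render_he_patch(ps, ps, counts[r, c], texture_freq = texture_freq,
                              noise_sd = noise_sd, axis_range = c(5, 8))
      img[(r - 1L) * ps + seq_len(ps), (c - 1L) * ps + seq_len(ps), ] <- cell$img
    }
  }
  list(img = img, counts = counts)
}
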