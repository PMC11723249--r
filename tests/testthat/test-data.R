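# Dataset manifests, splits, nucleus counting, patch extraction and the
# synthetic generator.

test_that("BreaKHis-style trees scan into labelled manifests", {
  root <- make_breakhis_tree(tempfile("bk"), magnifications = c(40L, 100L),
                             per_subtype = 2L)
  man <- scan_breakhis(root)
  expect_equal(nrow(man), 8 * 2 * 2)
  expect_setequal(unique(man$label), c("A", "F", "PT", "TA", "DC", "LC", "MC", "PC"))
  expect_setequal(unique(man$magnification), c(40L, 100L))

  man40 <- scan_breakhis(root, magnification = 40L)
  expect_equal(nrow(man40), 16)
  expect_true(all(man40$magnification == 40L))

  expect_warning(empty <- scan_breakhis(tempfile("nope")), "no images")
  expect_equal(nrow(empty), 0)

  # unknown subtype directory: warned and skipped, counted in the report
  d <- file.path(root, "benign", "SOB", "mystery_tumor", "s", "40X")
  dir.create(d, recursive = TRUE)
  png::writePNG(array(0.5, c(4, 4, 3)), file.path(d, "x.png"))
  expect_warning(man2 <- scan_breakhis(root), "unrecognised")
  expect_equal(attr(man2, "skipped"), 1L)
  expect_equal(nrow(man2), 32)
})

test_that("stratified splitting conserves counts at 0.6/0.2/0.2 per class", {
  df <- data.frame(path = sprintf("img%03d.png", 1:100), label = "a",
                   stringsAsFactors = FALSE)
  man <- affnet:::new_manifest(df, source = "synthetic")
  sp <- stratified_split(man, seed = 3)
  expect_equal(as.vector(table(sp$split)[c("train", "val", "test")]),
               c(60L, 20L, 20L))

  # conservation with several classes and awkward sizes
  df2 <- data.frame(path = sprintf("i%03d.png", 1:37),
                    label = rep(c("a", "b", "c"), times = c(13, 11, 13)),
                    stringsAsFactors = FALSE)
  man2 <- affnet:::new_manifest(df2, source = "synthetic")
  sp2 <- stratified_split(man2, seed = 1)
  expect_equal(sum(!is.na(sp2$split)), 37)
  for (cl in c("a", "b", "c")) {
    cnt <- table(factor(sp2$split[sp2$label == cl],
                        levels = c("train", "val", "test")))
    n <- sum(cnt)
    expect_lte(max(abs(cnt - n * c(0.6, 0.2, 0.2))), 1)
  }

  # deterministic under the seed
  expect_identical(stratified_split(man2, seed = 7)$split,
                   stratified_split(man2, seed = 7)$split)
  expect_false(identical(stratified_split(man2, seed = 7)$split,
                         stratified_split(man2, seed = 8)$split))

  # grouped rows never cross splits
  df3 <- data.frame(path = sprintf("p%03d.png", 1:60), label = "a",
                    group = rep(sprintf("slide%02d", 1:12), each = 5),
                    stringsAsFactors = FALSE)
  man3 <- affnet:::new_manifest(df3, source = "bach")
  sp3 <- stratified_split(man3, seed = 2)
  per_group <- tapply(sp3$split, sp3$group, function(s) length(unique(s)))
  expect_true(all(per_group == 1))

  tiny <- affnet:::new_manifest(
    data.frame(path = c("a.png", "b.png"), label = "rare",
               stringsAsFactors = FALSE), source = "synthetic")
  expect_error(stratified_split(tiny), "rare")
})

test_that("the nucleus counter recovers generator ground truth", {
  expect_equal(count_nuclei(array(1, c(64, 64, 3))), 0L)

  set.seed(50)
  for (k in c(3L, 10L, 25L)) {
    p <- render_he_patch(384, 384, k, texture_freq = 6, noise_sd = 0.03,
                         axis_range = c(5, 8))
    expect_equal(p$placed, k)
    expect_equal(count_nuclei(p$img), k)
  }

  # two overlapping nuclei merge into one connected component
  img <- array(rep(affnet:::.he_background_rgb, each = 64 * 64), c(64, 64, 3))
  hh <- matrix(1:64, 64, 64); ww <- t(hh)
  for (ctr in list(c(30, 30), c(30, 36))) {
    inside <- ((hh - ctr[1])^2 + (ww - ctr[2])^2) <= 36
    for (ch in 1:3) {
      pl <- img[, , ch]; pl[inside] <- affnet:::.he_nucleus_rgb[ch]
      img[, , ch] <- pl
    }
  }
  expect_equal(count_nuclei(img), 1L)

  # monotone in the rendered count for disjoint nuclei
  set.seed(51)
  counts <- vapply(c(2L, 6L, 12L), function(k) {
    count_nuclei(render_he_patch(320, 320, k, noise_sd = 0.03,
                                 axis_range = c(5, 7))$img)
  }, 0L)
  expect_true(all(diff(counts) > 0))

  expect_error(count_nuclei(matrix(0, 4, 4)), "RGB")
})

test_that("slide tiling yields the 12-patch grid and honours the filter", {
  counts <- matrix(25L, 3L, 4L)
  counts[1, 3] <- 5L; counts[2, 2] <- 5L; counts[3, 1] <- 5L
  bi <- render_synthetic_bach_image(counts, seed = 3L)
  expect_identical(dim(bi$img), c(1536L, 2048L, 3L))

  ex <- extract_bach_patches(bi$img)
  expect_equal(ex$n_candidates, 12L)
  expect_equal(nrow(ex$report), 12L)
  # patches rendered with 5 nuclei are excluded, 25-nucleus patches kept
  expect_equal(sum(ex$report$kept), 9L)
  expect_true(all(ex$report$n_nuclei[!ex$report$kept] < 20))
  expect_true(all(ex$report$n_nuclei[ex$report$kept] >= 20))
  expect_identical(dim(ex$patches[[1]]), c(224L, 224L, 3L))

  # disabling the filter keeps the full grid
  ex0 <- extract_bach_patches(bi$img, patch_spec(min_nuclei = 0L))
  expect_equal(length(ex0$patches), 12L)

  expect_error(extract_bach_patches(array(0, c(100, 100, 3))), "smaller")
  expect_error(patch_spec(stride = 256L), "non-overlapping")
})

test_that("the synthetic generator is deterministic and class-separable in frequency", {
  d1 <- tempfile("s1"); d2 <- tempfile("s2")
  sp <- synthetic_spec(classes = 2L, per_class = 6L, size = 64L)
  m1 <- generate_synthetic_dataset(sp, d1, seed = 5L)
  m2 <- generate_synthetic_dataset(sp, d2, seed = 5L)
  expect_equal(nrow(m1), 12L)
  expect_identical(unname(tools::md5sum(sort(m1$path))),
                   unname(tools::md5sum(sort(m2$path))))

  # every record gets exactly one split and fractions are conserved
  expect_true(all(m1$split %in% c("train", "val", "test")))

  # spectral class signature: the mean energy in the annulus around each
  # class's grating frequency (4 vs 16 cycles/image) dominates for that
  # class, so the frequency-domain operators are discriminative by design
  band_energy <- function(paths, r0, r1) {
    tot <- 0
    for (p in paths) {
      img <- png::readPNG(p)
      z <- Mod(real_fft2(array(img[, , 2], c(1, 64, 64)))$values[1, , ])^2
      u <- rep(0:63, times = 33); v <- rep(0:32, each = 64)
      r <- sqrt(pmin(u, 64 - u)^2 + v^2)
      tot <- tot + sum(z[r >= r0 & r <= r1])
    }
    tot / length(paths)
  }
  p0 <- m1$path[m1$label == "class_0"]
  p1 <- m1$path[m1$label == "class_1"]
  expect_gt(band_energy(p0, 3, 5), 1.5 * band_energy(p1, 3, 5))
  expect_gt(band_energy(p1, 14, 18), 3 * band_energy(p0, 14, 18))
})

test_that("manifest CSV round-trips", {
  df <- data.frame(path = c("x.png", "y.png"), label = c("a", "b"),
                   magnification = c(40L, NA), split = c("train", "test"),
                   stringsAsFactors = FALSE)
  man <- affnet:::new_manifest(df, source = "synthetic")
  f <- tempfile(fileext = ".csv")
  write_manifest(man, f)
  back <- read_manifest(f)
  expect_equal(back$path, df$path)
  expect_equal(back$split, df$split)
})
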