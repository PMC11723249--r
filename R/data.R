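#' Dataset manifests, directory scanners, splitting and patch extraction
#'
#' A manifest is a plain data.frame with columns `path`, `label`,
#' `magnification` (40/100/200/400 or NA), `split` (train/val/test or NA)
#' and optionally `group` (images sharing a group never cross splits, used
#' for patches cut from one parent slide). Attributes carry the ordered
#' class names and the source tag (`breakhis`, `bach`, `synthetic`).
#'
#' @name data-pipeline
NULL

#' @keywords internal
new_manifest <- function(df, source, class_names = NULL) {
  stopifnot(all(c("path", "label") %in% names(df)))
  if (is.null(df$magnification)) df$magnification <- NA_integer_
  if (is.null(df$split)) df$split <- NA_character_
  if (anyDuplicated(df$path)) stop("manifest contains duplicated paths")
  attr(df, "class_names") <- class_names %||% sort(unique(df$label))
  attr(df, "source") <- source
  class(df) <- c("affnet_manifest", "data.frame")
  df
}

#' @export
print.affnet_manifest <- function(x, ...) {
  cat(sprintf("dataset manifest (%s): %d images, %d classes\n",
              attr(x, "source") %||% "?", nrow(x),
              length(attr(x, "class_names"))))
  if (!all(is.na(x$split))) print(table(x$label, x$split))
  invisible(x)
}

#' Write / read a manifest CSV (`path,label,magnification,split`).
#' @param manifest a manifest data.frame; @param path CSV file.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest[, c("path", "label", "magnification", "split",
                                intersect("group", names(manifest)))],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @param source source tag recorded on the manifest.
#' @export
read_manifest <- function(path, source = "csv") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  new_manifest(df, source = source)
}

# BreaKHis subtype directory names -> standard codes
.breakhis_subtypes <- c(
  adenosis = "A", fibroadenoma = "F", phyllodes_tumor = "PT",
  tubular_adenoma = "TA", ductal_carcinoma = "DC", lobular_carcinoma = "LC",
  mucinous_carcinoma = "MC", papillary_carcinoma = "PC")

#' Scan a BreaKHis-style directory tree
#'
#' Expects the usual `benign|malignant / SOB / <subtype> / <slide> /
#' <magnification>X / image` layout (the scanner is lenient: subtype and
#' magnification are searched anywhere along each image's path).
#' Unrecognised subtype directories produce a warning and are skipped;
#' the number skipped is recorded in `attr(, "skipped")`.
#'
#' @param root dataset root directory.
#' @param magnification optional filter (40, 100, 200 or 400).
#' @return a manifest with subtype codes `A, F, PT, TA, DC, LC, MC, PC` as
#'   labels.
#' @export
scan_breakhis <- function(root, magnification = NULL) {
  files <- list.files(root, pattern = "\\.(png|PNG|jpe?g|JPE?G|tiff?|TIFF?)$",
                      recursive = TRUE, full.names = TRUE)
  if (length(files) == 0L) {
    warning("no images found under ", root)
    return(new_manifest(
      data.frame(path = character(), label = character(),
                 magnification = integer(), split = character(),
                 stringsAsFactors = FALSE),
      source = "breakhis", class_names = unname(.breakhis_subtypes)))
  }
  parse_one <- function(f) {
    parts <- strsplit(f, "/", fixed = TRUE)[[1]]
    sub <- .breakhis_subtypes[match(tolower(parts), names(.breakhis_subtypes))]
    sub <- sub[!is.na(sub)]
    mag <- sub("X$", "", grep("^(40|100|200|400)X$", parts, value = TRUE))
    if (length(sub) == 0L) {
      # fall back to SOB_B_A-style filename codes
      m <- regmatches(basename(f), regexpr("SOB_[BM]_(A|F|PT|TA|DC|LC|MC|PC)",
                                           basename(f)))
      if (length(m)) sub <- sub("SOB_[BM]_", "", m)
    }
    list(sub = if (length(sub)) sub[[1]] else NA_character_,
         mag = if (length(mag)) as.integer(mag[[1]]) else NA_integer_)
  }
  parsed <- lapply(files, parse_one)
  labs <- vapply(parsed, `[[`, "", "sub")
  mags <- vapply(parsed, `[[`, 0L, "mag")
  bad <- is.na(labs)
  if (any(bad)) {
    warning(sum(bad), " image(s) with unrecognised subtype skipped")
  }
  df <- data.frame(path = files[!bad], label = labs[!bad],
                   magnification = mags[!bad], split = NA_character_,
                   stringsAsFactors = FALSE)
  if (!is.null(magnification)) {
    df <- df[!is.na(df$magnification) & df$magnification == magnification, ,
             drop = FALSE]
  }
  man <- new_manifest(df, source = "breakhis",
                      class_names = unname(.breakhis_subtypes))
  attr(man, "skipped") <- sum(bad)
  man
}

#' Stratified train/val/test split
#'
#' Splits per class at the given fractions with largest-remainder rounding,
#' deterministically under `seed`. When the manifest has a `group` column
#' (e.g. patches cut from one parent slide) whole groups are assigned to a
#' single split, preventing leakage.
#'
#' @param manifest a manifest data.frame.
#' @param fractions train/val/test fractions summing to 1
#'   (default `c(0.6, 0.2, 0.2)`).
#' @param seed integer seed.
#' @param min_per_class minimum images (or groups) per class.
#' @return the manifest with its `split` column filled.
#' @export
stratified_split <- function(manifest, fractions = c(0.6, 0.2, 0.2),
                             seed = 1L, min_per_class = 5L) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-9)
  set.seed(seed)
  splits <- c("train", "val", "test")
  has_group <- "group" %in% names(manifest)
  for (cls in unique(manifest$label)) {
    rows <- which(manifest$label == cls)
    units <- if (has_group) unique(manifest$group[rows]) else rows
    n <- length(units)
    if (n < min_per_class) {
      stop("class '", cls, "' has only ", n,
           " unit(s); need at least ", min_per_class)
    }
    units <- sample(units)
    base <- floor(n * fractions)
    rem <- n - sum(base)
    if (rem > 0) {
      frac <- n * fractions - base
      base[order(-frac, seq_along(frac))[seq_len(rem)]] <-
        base[order(-frac, seq_along(frac))[seq_len(rem)]] + 1L
    }
    assign_vec <- rep(splits, times = base)
    for (j in seq_along(units)) {
      target <- if (has_group) rows[manifest$group[rows] == units[j]] else units[j]
      manifest$split[target] <- assign_vec[j]
    }
  }
  manifest
}

# ---- nucleus counting -------------------------------------------------------

# Ruifrok-Johnston H&E(+residual) optical-density stain vectors, row-normalised.
.stain_matrix <- function() {
  m <- rbind(h = c(0.650, 0.704, 0.286),
             e = c(0.072, 0.990, 0.105),
             r = c(0.268, 0.570, 0.776))
  m / sqrt(rowSums(m^2))
}

#' Count nuclei in an RGB patch
#'
#' A stain-separation proxy for the nucleus density of an H&E patch:
#' optical-density transform, hematoxylin channel by color deconvolution
#' with the standard stain matrix, Otsu threshold, then connected
#' components with area at least `min_area` px^2 are counted. Overlapping
#' nuclei merged into one component count as one — the documented
#' connected-component semantics.
#'
#' @param patch RGB array `(H, W, 3)` with intensities in [0, 1].
#' @param min_area minimum component area in pixels (default 40).
#' @param min_od minimum hematoxylin optical density for a patch to contain
#'   any nuclei at all (guards blank patches).
#' @return integer count.
#' @export
count_nuclei <- function(patch, min_area = 40L, min_od = 0.15) {
  d <- dim(patch)
  if (length(d) != 3L || d[3] != 3L) stop("patch must be an RGB (H, W, 3) array")
  od <- -log10(pmax(patch, 1 / 255))
  dim(od) <- c(d[1] * d[2], 3L)
  conc <- od %*% solve(.stain_matrix())
  h <- pmax(conc[, 1], 0)
  if (max(h) < min_od) return(0L)
  hn <- h / max(h)
  dim(hn) <- d[1:2]
  th <- EBImage::otsu(EBImage::Image(hn))
  bw <- EBImage::bwlabel(EBImage::Image(hn > th))
  sizes <- tabulate(as.integer(EBImage::imageData(bw)))
  sum(sizes >= min_area)
}

# ---- BACH-style patch extraction --------------------------------------------

#' Patch-extraction settings for BACH-style slides
#'
#' @param patch_size patch edge in pixels (default 512).
#' @param stride tiling stride; must equal `patch_size` (non-overlapping).
#' @param min_nuclei patches with fewer nuclei are excluded (default 20).
#' @param resize_to edge of the resized output patches (default 224).
#' @export
patch_spec <- function(patch_size = 512L, stride = 512L, min_nuclei = 20L,
                       resize_to = 224L) {
  if (stride != patch_size) stop("tiling is non-overlapping: stride must equal patch_size")
  if (min_nuclei < 0L) stop("min_nuclei must be non-negative")
  structure(list(patch_size = as.integer(patch_size), stride = as.integer(stride),
                 min_nuclei = as.integer(min_nuclei),
                 resize_to = as.integer(resize_to)),
            class = "patch_spec")
}

#' @keywords internal
resize_rgb <- function(img, size) {
  # EBImage works x-major; transpose in and out
  im <- EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(im, w = size, h = size)
  aperm(EBImage::imageData(out), c(2, 1, 3))
}

#' Tile a slide into patches and apply the nucleus-count filter
#'
#' Non-overlapping grid tiling (a 2048 x 1536 image yields exactly 12
#' candidate patches); each patch is kept if its nucleus count reaches
#' `spec$min_nuclei` and is then resized to `spec$resize_to`. Excluded
#' patches are recorded with their counts.
#'
#' @param image RGB array `(H, W, 3)`.
#' @param spec a [patch_spec()].
#' @return list with `patches` (list of resized kept patches), `report`
#'   (data.frame `row, col, n_nuclei, kept`) and `n_candidates`.
#' @export
extract_bach_patches <- function(image, spec = patch_spec()) {
  d <- dim(image)
  ps <- spec$patch_size
  if (d[1] < ps || d[2] < ps) {
    stop("image (", d[1], "x", d[2], ") is smaller than the patch size ", ps)
  }
  nR <- d[1] %/% ps
  nC <- d[2] %/% ps
  patches <- list()
  rep_rows <- list()
  for (r in seq_len(nR)) {
    for (c in seq_len(nC)) {
      p <- image[(r - 1L) * ps + seq_len(ps), (c - 1L) * ps + seq_len(ps), ,
                 drop = FALSE]
      n <- count_nuclei(p)
      kept <- n >= spec$min_nuclei
      rep_rows[[length(rep_rows) + 1L]] <-
        data.frame(row = r, col = c, n_nuclei = n, kept = kept)
      if (kept) patches[[length(patches) + 1L]] <- resize_rgb(p, spec$resize_to)
    }
  }
  list(patches = patches, report = do.call(rbind, rep_rows),
       n_candidates = nR * nC)
}

#' Prepare a directory of BACH-style slides into filtered patches
#'
#' Tiles every image under `root` (one subdirectory per class), applies the
#' nucleus filter, writes kept patches as PNG under `out_dir`, groups all
#' patches of one parent image so splits never separate them, and returns
#' the split manifest. The exclusion report is written as JSON next to the
#' manifest.
#'
#' @param root input directory (`<class>/<image>` layout).
#' @param out_dir output directory.
#' @param spec a [patch_spec()].
#' @param seed split seed.
#' @export
prepare_bach <- function(root, out_dir, spec = patch_spec(), seed = 1L) {
  classes <- list.dirs(root, recursive = FALSE)
  if (length(classes) == 0L) stop("no class directories under ", root)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  report <- list()
  for (cd in classes) {
    cls <- basename(cd)
    dir.create(file.path(out_dir, cls), showWarnings = FALSE)
    for (f in list.files(cd, pattern = "\\.(png|tiff?)$", ignore.case = TRUE,
                         full.names = TRUE)) {
      img <- read_image(f)
      ex <- extract_bach_patches(img, spec)
      stemn <- tools::file_path_sans_ext(basename(f))
      ex$report$image <- stemn
      report[[length(report) + 1L]] <- ex$report
      for (k in seq_along(ex$patches)) {
        path <- file.path(out_dir, cls, sprintf("%s_p%02d.png", stemn, k))
        png::writePNG(ex$patches[[k]], path)
        rows[[length(rows) + 1L]] <- data.frame(
          path = path, label = cls, magnification = NA_integer_,
          split = NA_character_, group = paste0(cls, "/", stemn),
          stringsAsFactors = FALSE)
      }
    }
  }
  man <- new_manifest(do.call(rbind, rows), source = "bach")
  man <- stratified_split(man, seed = seed, min_per_class = 1L)
  jsonlite::write_json(do.call(rbind, report),
                       file.path(out_dir, "exclusion_report.json"))
  write_manifest(man, file.path(out_dir, "manifest.csv"))
  man
}

#' Read an image file into an `(H, W, 3)` array in [0, 1]
#'
#' PNG via the png package, TIFF via the tiff package when installed,
#' anything else through EBImage.
#' @param path image file.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff") && requireNamespace("tiff", quietly = TRUE)) {
    tiff::readTIFF(path)
  } else {
    aperm(EBImage::imageData(EBImage::readImage(path)), c(2, 1, 3))
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}
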