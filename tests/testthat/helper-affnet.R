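# Shared helpers: finite-difference gradients, brute-force oracles and
# small fixture builders. Everything is generated in code; no stored data.

# central-difference gradient of scalar f at x (small arrays only)
num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force evaluation of the 2-D DCT coefficient (u, v)
# of a single-channel map, straight from the double-sum definition
naive_dct_coeff <- function(x, u, v) {
  H <- dim(x)[1]; W <- dim(x)[2]
  cs <- function(k, L) if (k == 0) sqrt(1 / L) else sqrt(2 / L)
  s <- 0
  for (h in 0:(H - 1)) for (w in 0:(W - 1)) {
    s <- s + x[h + 1, w + 1] * cs(u, H) * cs(v, W) *
      cos(pi * (2 * h + 1) * u / (2 * H)) * cos(pi * (2 * w + 1) * v / (2 * W))
  }
  s
}

# brute-force DFT of a real matrix at one (u, v) bin (0-based)
naive_dft_bin <- function(x, u, v) {
  H <- nrow(x); W <- ncol(x)
  s <- 0 + 0i
  for (h in 0:(H - 1)) for (w in 0:(W - 1)) {
    s <- s + x[h + 1, w + 1] * exp(-2i * pi * (u * h / H + v * w / W))
  }
  s
}

# tiny reference configuration used across model-level tests;
# named arguments override the reduced-width defaults
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(dims = c(16L, 32L, 64L, 128L), input_size = 64L, window = 4L,
         heads = c(1L, 2L, 4L, 8L), num_classes = 2L, seed = 7L),
    list(...))
  do.call(affnet_config, args)
}

# grab the flat parameter list of a model
model_params <- function(model) {
  affnet:::ag_collect_params(model[c("stem", "stages", "downsamples", "head")])
}

# run loss = sum(f(x)^2) forward+backward, return list(analytic grads env)
with_grads <- function(fwd) {
  tp <- affnet:::ag_tape_open()
  loss <- fwd()
  affnet:::ag_tape_close()
  affnet:::ag_backward(tp, loss)
  loss
}

# build a small BreaKHis-style directory tree with n images per subtype
make_breakhis_tree <- function(root, magnifications = c(40L),
                               per_subtype = 2L, size = 16L) {
  subtypes <- c(benign = "adenosis", benign = "fibroadenoma",
                benign = "phyllodes_tumor", benign = "tubular_adenoma",
                malignant = "ductal_carcinoma", malignant = "lobular_carcinoma",
                malignant = "mucinous_carcinoma", malignant = "papillary_carcinoma")
  for (i in seq_along(subtypes)) {
    for (mag in magnifications) {
      d <- file.path(root, names(subtypes)[i], "SOB", subtypes[i],
                     "slide_01", paste0(mag, "X"))
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      for (j in seq_len(per_subtype)) {
        img <- array(stats::runif(size * size * 3), c(size, size, 3))
        png::writePNG(img, file.path(d, sprintf("img_%02d.png", j)))
      }
    }
  }
  root
}
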