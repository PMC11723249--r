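#' Spectral primitives: 2-D DCT bases, real FFT round trips, frequency
#' partitioning and soft-thresholding
#'
#' These are the pure numerical kernels underneath the two frequency-domain
#' network operators (multi-spectral channel attention and the Fourier
#' filtering enhancement operator). All transforms use base R's FFT; the DCT
#' is evaluated directly from its separable cosine definition because only a
#' handful of selected frequencies are ever needed, not full transforms.
#'
#' @name spectral
NULL

#' Build an orthonormal 2-D DCT basis for selected frequency pairs
#'
#' Returns the separable cosine basis slices
#' `basis[k, h, w] = c(u) c(v) cos(pi (2h+1) u / 2H) cos(pi (2w+1) v / 2W)`
#' for each selected `(u, v)`, with orthonormal scale factors
#' `c(0) = sqrt(1/L)`, `c(k > 0) = sqrt(2/L)`. Under this normalisation every
#' slice has unit energy, so projections onto different frequencies are
#' directly comparable.
#'
#' @param H,W spatial dimensions in pixels (positive integers).
#' @param freq_pairs list (or n x 2 matrix) of 0-based `(u, v)` frequency
#'   index pairs, `0 <= u < H`, `0 <= v < W`.
#' @return object of class `dct_basis`: list with `H`, `W`, `n`,
#'   `freq_pairs` (n x 2 integer matrix) and `basis` (array `(n, H, W)`).
#' @examples
#' b <- build_dct_basis(2, 2, list(c(0, 0)))
#' b$basis[1, , ]           # constant 0.5 (the DC atom)
#' @export
build_dct_basis <- function(H, W, freq_pairs) {
  if (H < 1 || W < 1) stop("H and W must be positive")
  if (is.matrix(freq_pairs)) {
    fp <- freq_pairs
  } else {
    fp <- do.call(rbind, lapply(freq_pairs, function(p) as.integer(p[1:2])))
  }
  storage.mode(fp) <- "integer"
  if (any(fp[, 1] < 0L) || any(fp[, 1] >= H) || any(fp[, 2] < 0L) || any(fp[, 2] >= W)) {
    stop("frequency index (u, v) out of range for ", H, "x", W)
  }
  n <- nrow(fp)
  cs <- function(k, L) ifelse(k == 0, sqrt(1 / L), sqrt(2 / L))
  basis <- array(0, dim = c(n, H, W))
  h <- seq_len(H) - 1L
  w <- seq_len(W) - 1L
  for (k in seq_len(n)) {
    u <- fp[k, 1]; v <- fp[k, 2]
    bh <- cs(u, H) * cos(pi * (2 * h + 1) * u / (2 * H))
    bw <- cs(v, W) * cos(pi * (2 * w + 1) * v / (2 * W))
    basis[k, , ] <- outer(bh, bw)
  }
  structure(list(H = as.integer(H), W = as.integer(W), n = n,
                 freq_pairs = fp, basis = basis),
            class = "dct_basis")
}

#' Zigzag-ordered low-frequency pair selection
#'
#' The n attention frequencies are the n lowest pairs of a `grid x grid` DCT
#' plane in zigzag (anti-diagonal) order, the ordering under which DCT energy
#' of natural images concentrates first. Indices are rescaled to an `H x W`
#' map by `floor(u * H / grid)`.
#' @keywords internal
zigzag_freq_pairs <- function(n, H, W, grid = 7L) {
  uv <- expand.grid(u = 0:(grid - 1L), v = 0:(grid - 1L))
  uv <- uv[order(uv$u + uv$v, uv$u, uv$v), , drop = FALSE]
  uv <- uv[seq_len(n), , drop = FALSE]
  cbind(pmin(floor(uv$u * H / grid), H - 1L),
        pmin(floor(uv$v * W / grid), W - 1L))
}

#' Project channels of a feature map onto their part's DCT atom
#'
#' The map's `C` channels are divided into `n` contiguous parts; channel `c`
#' in part `i` receives the scalar descriptor
#' `sum_{h,w} x[c, h, w] * basis[i, h, w]`. Concatenated over parts this is
#' the multi-spectral frequency descriptor of the whole input.
#'
#' @param x real array `(C, H, W)`.
#' @param basis a [build_dct_basis()] object with `n` slices matching the
#'   spatial dimensions of `x`.
#' @param part_assignment optional integer vector mapping each channel to a
#'   part in `1..n`; defaults to contiguous blocks of `C / n` channels.
#' @return numeric vector of length `C`.
#' @export
dct_project <- function(x, basis, part_assignment = NULL) {
  d <- dim(x)
  stopifnot(length(d) == 3L)
  C <- d[1]
  if (d[2] != basis$H || d[3] != basis$W) {
    stop("spatial dimensions of x do not match the basis")
  }
  if (is.null(part_assignment)) {
    if (C %% basis$n != 0L) {
      stop("channel count ", C, " is not divisible by the number of parts ", basis$n)
    }
    part_assignment <- rep(seq_len(basis$n), each = C %/% basis$n)
  }
  stopifnot(length(part_assignment) == C)
  bm <- matrix(basis$basis, basis$n, basis$H * basis$W)
  xm <- matrix(x, C, d[2] * d[3])
  rowSums(xm * bm[part_assignment, , drop = FALSE])
}

# ---- real 2-D FFT -----------------------------------------------------------

#' FFT along one dimension of an arbitrary array (unnormalised).
#' @keywords internal
fft_dim <- function(a, dm, inverse = FALSE) {
  d <- dim(a)
  perm <- c(dm, setdiff(seq_along(d), dm))
  ap <- aperm(a, perm)
  dim(ap) <- c(d[dm], prod(d[-dm]))
  m <- stats::mvfft(ap, inverse = inverse)
  dim(m) <- d[perm]
  aperm(m, order(perm))
}

rfft2_raw <- function(x) {
  # x: (N, C, H, W) real -> (N, C, H, W/2 + 1) complex half-plane
  d <- dim(x)
  z <- fft_dim(fft_dim(x + 0i, 3L), 4L)
  Wr <- d[4] %/% 2L + 1L
  z[, , , seq_len(Wr), drop = FALSE]
}

irfft2_raw <- function(z, W) {
  d <- dim(z)
  H <- d[3]; Wr <- d[4]
  stopifnot(Wr == W %/% 2L + 1L)
  zf <- array(0 + 0i, dim = c(d[1], d[2], H, W))
  zf[, , , seq_len(Wr)] <- z
  if (W > Wr) {
    mu <- c(1L, if (H > 1L) seq.int(H, 2L))      # Hermitian mirror of the row index
    for (v in seq.int(Wr + 1L, W)) {
      zf[, , , v] <- Conj(z[, , mu, W - v + 2L, drop = FALSE])
    }
  }
  Re(fft_dim(fft_dim(zf, 3L, inverse = TRUE), 4L, inverse = TRUE)) / (H * W)
}

#' Half-plane weights: bins in self-conjugate columns appear once in the
#' half-plane layout, interior columns stand for a conjugate pair.
#' @keywords internal
rfft_col_weights <- function(W) {
  Wr <- W %/% 2L + 1L
  freq <- seq_len(Wr) - 1L
  ifelse(freq == 0L | 2L * freq == W, 1, 2)
}

#' Real 2-D FFT of a feature map (half-plane layout)
#'
#' Transforms a real `(C, H, W)` map to its complex spectrum stored on the
#' Hermitian half-plane `H x (W/2 + 1)`.
#'
#' @param x real array `(C, H, W)` with `H, W >= 2`.
#' @return object of class `spectral_grid`: list with `values` (complex array
#'   `(C, H, W/2 + 1)`), `H`, `W`, `half_width`.
#' @seealso [inverse_real_fft2()]
#' @export
real_fft2 <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 3L, d[2] >= 2L, d[3] >= 2L)
  x4 <- x; dim(x4) <- c(1L, d)
  z <- rfft2_raw(x4)
  dim(z) <- dim(z)[-1]
  structure(list(values = z, H = d[2], W = d[3],
                 half_width = d[3] %/% 2L + 1L),
            class = "spectral_grid")
}

#' Inverse real 2-D FFT
#'
#' Reconstructs the real `(C, H, W)` map from its half-plane spectrum;
#' `inverse_real_fft2(real_fft2(x), H, W)` recovers `x` to round-off.
#'
#' @param g a [real_fft2()] spectral grid (or bare complex array
#'   `(C, H, W/2+1)`).
#' @param H,W target spatial dimensions.
#' @return real array `(C, H, W)`.
#' @export
inverse_real_fft2 <- function(g, H, W) {
  z <- if (inherits(g, "spectral_grid")) g$values else g
  d <- dim(z)
  stopifnot(length(d) == 3L)
  if (d[2] != H || d[3] != W %/% 2L + 1L) {
    stop("spectrum shape (", d[2], ", ", d[3], ") does not match H = ", H,
         ", W = ", W, " (expected half width ", W %/% 2L + 1L, ")")
  }
  z4 <- z; dim(z4) <- c(1L, d)
  x <- irfft2_raw(z4, W)
  dim(x) <- dim(x)[-1]
  x
}

# ---- frequency partition ----------------------------------------------------

#' Split half-plane FFT bins into low- and high-pass halves
#'
#' All `H x (W/2 + 1)` bins are ordered by the radial key
#' `r(u, v) = sqrt(min(u, H - u)^2 + v^2)` (Hermitian-aware in the row
#' direction), ties broken row-major; the first half becomes the low-pass
#' set and the rest the high-pass set. With an even bin count the halves are
#' exactly `H (W/2 + 1) / 2` each; an odd count gives the low-pass side the
#' extra bin.
#'
#' @param H number of row bins; @param W spatial width in pixels (the column
#'   bins are `W/2 + 1`).
#' @return object of class `frequency_partition`: `lp_indices` and
#'   `hp_indices` (0-based `(u, v)` matrices), `low_freq_count`,
#'   `high_freq_count`, and 1-based flat bin indices `lp_bins`, `hp_bins`
#'   into the column-major `H x (W/2+1)` plane.
#' @export
partition_frequencies <- function(H, W) {
  Wr <- W %/% 2L + 1L
  u <- rep(seq_len(H) - 1L, times = Wr)
  v <- rep(seq_len(Wr) - 1L, each = H)
  r <- sqrt(pmin(u, H - u)^2 + v^2)
  ord <- order(r, u, v)
  nb <- H * Wr
  nlo <- (nb + 1L) %/% 2L          # odd count: extra bin goes low-pass
  lo <- ord[seq_len(nlo)]
  hi <- ord[seq.int(nlo + 1L, nb)]
  structure(list(
    lp_indices = cbind(u = u[lo], v = v[lo]),
    hp_indices = cbind(u = u[hi], v = v[hi]),
    low_freq_count = length(lo),
    high_freq_count = length(hi),
    lp_bins = lo,
    hp_bins = hi,
    H = as.integer(H), W = as.integer(W), half_width = Wr
  ), class = "frequency_partition")
}

#' Soft-thresholding operator
#'
#' `sign(x) * max(|x| - lam, 0)`, the classical sparsifying shrinkage.
#' Complex input is shrunk on its real and imaginary parts independently.
#'
#' @param x numeric or complex array.
#' @param lam non-negative threshold.
#' @export
softshrink <- function(x, lam) {
  if (!is.numeric(lam) || length(lam) != 1L || lam < 0) {
    stop("lam must be a single non-negative number")
  }
  if (is.complex(x)) {
    v <- complex(real = sign(Re(x)) * pmax(abs(Re(x)) - lam, 0),
                 imaginary = sign(Im(x)) * pmax(abs(Im(x)) - lam, 0))
    dim(v) <- dim(x)
    v
  } else {
    sign(x) * pmax(abs(x) - lam, 0)
  }
}

# ---- autograd wrappers ------------------------------------------------------

#' rfft2 as a differentiable op on (N, C, H, W) tensors.
#' The vjp is the adjoint DFT: zero-pad the half-plane cotangent to the full
#' grid and take the real part of the unnormalised inverse transform.
#' @keywords internal
t_rfft2 <- function(x) {
  xv <- val(x)
  d <- dim(xv)
  z <- rfft2_raw(xv)
  ag_node(z, list(x), function(g) {
    gf <- array(0 + 0i, dim = d)
    gf[, , , seq_len(dim(g)[4])] <- g
    gx <- Re(fft_dim(fft_dim(gf, 3L, inverse = TRUE), 4L, inverse = TRUE))
    list(gx)
  })
}

#' irfft2 as a differentiable op; vjp is the weighted forward DFT of the
#' cotangent restricted to the half-plane (weight 2 on bins standing for a
#' conjugate pair, 1 on self-conjugate columns), divided by H*W.
#' @keywords internal
t_irfft2 <- function(z, W) {
  zv <- val(z)
  d <- dim(zv)
  H <- d[3]; Wr <- d[4]
  x <- irfft2_raw(zv, W)
  wcol <- rfft_col_weights(W)
  ag_node(x, list(z), function(g) {
    gz <- fft_dim(fft_dim(g + 0i, 3L), 4L)[, , , seq_len(Wr), drop = FALSE]
    for (v in seq_len(Wr)) {
      gz[, , , v] <- gz[, , , v] * (wcol[v] / (H * W))
    }
    list(gz)
  })
}

#' Concatenate along the last axis of two 3-D stacks (real or complex).
#' @keywords internal
t_cat_last <- function(a, b) {
  av <- val(a); bv <- val(b)
  da <- dim(av); db <- dim(bv)
  stopifnot(da[1:2] == db[1:2])
  v <- array(if (is.complex(av) || is.complex(bv)) 0 + 0i else 0,
             dim = c(da[1], da[2], da[3] + db[3]))
  v[, , seq_len(da[3])] <- av
  v[, , da[3] + seq_len(db[3])] <- bv
  ag_node(v, list(a, b), function(g) {
    list(g[, , seq_len(da[3]), drop = FALSE],
         g[, , da[3] + seq_len(db[3]), drop = FALSE])
  })
}

#' Differentiable multi-spectral DCT projection: (N, C, H, W) -> (N, C).
#' `bc` is the fixed per-channel basis matrix (C, H*W).
#' @keywords internal
t_dct_project <- function(x, bc) {
  xv <- val(x)
  d <- dim(xv)
  N <- d[1]; C <- d[2]
  bexp <- bc[rep(seq_len(C), each = N), , drop = FALSE]
  xm <- xv
  dim(xm) <- c(N * C, d[3] * d[4])
  desc <- matrix(rowSums(xm * bexp), N, C)
  ag_node(desc, list(x), function(g) {
    gx <- as.vector(g) * bexp
    dim(gx) <- d
    list(gx)
  })
}
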