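#' Trainable frequency-domain operators
#'
#' Two modules built on the spectral kernels:
#'
#' * **MSCA** (multi-spectral channel attention): channels are split into
#'   `n` parts, each part is summarised by its projection onto one selected
#'   DCT frequency, and the concatenated frequency descriptor passes through
#'   a squeeze-excitation bottleneck. The module returns *pre-sigmoid*
#'   channel logits; the enclosing block applies the sigmoid gate, so the
#'   gating happens exactly once.
#' * **FFEO** (Fourier filtering enhancement operator): the map is taken to
#'   the real-FFT half-plane, bins are split into radially low- and
#'   high-pass halves, each half is filtered by its own two-layer complex
#'   MLP with block-diagonal weights shared across bins, the halves are
#'   reassembled, passed through the soft-shrink enhancement
#'   `alpha * softshrink(z) + (1 - alpha) * (z - softshrink(z))`, inverted
#'   back to the spatial domain and added to the input as a residual.
#'
#' With `alpha = 0.5` the enhancement step reduces algebraically to
#' `0.5 * z` for every threshold `lambda`; the operator is implemented as
#' printed and this collapse is covered by the test suite.
#'
#' @name frequency-modules
NULL

#' Construct the state of a multi-spectral channel attention module
#'
#' @param C channel count (divisible by `n` and by `r`... `C/r >= 1`).
#' @param H,W spatial dimensions of the maps the module will see.
#' @param n number of channel parts / selected frequencies (default 16).
#' @param r squeeze-excitation reduction ratio (default 16).
#' @param freq_set frequency selection rule; `"zigzag7"` takes the `n`
#'   lowest pairs of a 7x7 DCT plane in zigzag order, rescaled to `H x W`.
#' @param activation nonlinearity between the excitation layers; `"identity"`
#'   turns the bottleneck into a purely linear map (used for oracle tests).
#' @param materialize whether to allocate parameter arrays (FALSE counts
#'   shapes only).
#' @return object of class `msca_state`.
#' @export
msca_state <- function(C, H, W, n = 16L, r = 16L, freq_set = "zigzag7",
                       activation = c("relu", "identity"), materialize = TRUE) {
  activation <- match.arg(activation)
  if (C %% n != 0L) stop("C = ", C, " must be divisible by n = ", n)
  cr <- max(1L, C %/% r)
  fp <- switch(freq_set,
    zigzag7 = zigzag_freq_pairs(n, H, W, grid = 7L),
    stop("unknown freq_set: ", freq_set)
  )
  basis <- build_dct_basis(H, W, fp)
  part <- rep(seq_len(n), each = C %/% n)
  bc <- matrix(basis$basis, n, H * W)[part, , drop = FALSE]   # (C, H*W)
  structure(list(
    C = as.integer(C), H = as.integer(H), W = as.integer(W),
    n = as.integer(n), r = as.integer(r), activation = activation,
    basis = basis, part_assignment = part, bc = bc,
    w_down = ag_param(c(C, cr), "trunc_normal", materialize),
    b_down = ag_param(cr, "zeros", materialize),
    w_up = ag_param(c(cr, C), "trunc_normal", materialize),
    b_up = ag_param(C, "zeros", materialize)
  ), class = "msca_state")
}

#' Multi-spectral channel attention forward pass
#'
#' Computes the per-channel DCT frequency descriptor and passes it through
#' the excitation bottleneck. Returns pre-sigmoid logits: the caller gates
#' the feature map with `sigmoid(msca_forward(x))`.
#'
#' @param x feature map, array `(C, H, W)` or batched `(N, C, H, W)`
#'   (an internal tensor is also accepted).
#' @param state an [msca_state()].
#' @return channel logits with the batch layout of the input: `(C)` vector
#'   for a single map, `(N, C)` matrix for a batch.
#' @export
msca_forward <- function(x, state) {
  plain <- !ag_is(x)
  xv <- if (plain) x else val(x)
  single <- length(dim(xv)) == 3L
  if (single) {
    dim(xv) <- c(1L, dim(xv))
    x <- ag_tensor(xv)
  } else if (plain) {
    x <- ag_tensor(xv)
  }
  d <- dim(val(x))
  if (d[2] != state$C) {
    stop("channel mismatch: map has ", d[2], " channels, state expects ", state$C)
  }
  if (d[3] != state$H || d[4] != state$W) {
    stop("spatial mismatch: map is ", d[3], "x", d[4], ", basis is ",
         state$H, "x", state$W)
  }
  freq <- t_dct_project(x, state$bc)
  h <- t_linear(freq, state$w_down, state$b_down)
  if (state$activation == "relu") h <- t_relu(h)
  out <- t_linear(h, state$w_up, state$b_up)
  if (plain) {
    v <- val(out)
    if (single) as.vector(v) else v
  } else {
    out
  }
}

#' Construct the state of a Fourier filtering enhancement operator
#'
#' Weights are block-diagonal: each complex `C x C` layer consists of
#' `N` independent `(C/N) x (C/N)` blocks, one weight set shared by all
#' low-pass bins and a distinct set shared by all high-pass bins.
#'
#' @param C channel count (divisible by `N`).
#' @param H,W spatial dimensions of the maps the operator will see.
#' @param N number of diagonal blocks (default 4).
#' @param alpha mixing weight of the enhancement step, in `[0, 1]`
#'   (default 0.5).
#' @param lambda soft-shrink threshold (default 0.01; provably inert at
#'   `alpha = 0.5`, kept for ablations with other `alpha`).
#' @param materialize whether to allocate parameter arrays.
#' @return object of class `ffeo_state`.
#' @export
ffeo_state <- function(C, H, W, N = 4L, alpha = 0.5, lambda = 0.01,
                       materialize = TRUE) {
  if (C %% N != 0L) stop("C = ", C, " must be divisible by N = ", N)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (lambda < 0) stop("lambda must be non-negative")
  cb <- C %/% N
  mk <- function() ag_param(c(N, cb, cb), "trunc_normal", materialize)
  mkb <- function() ag_param(C, "zeros", materialize)
  structure(list(
    C = as.integer(C), H = as.integer(H), W = as.integer(W),
    N = as.integer(N), alpha = alpha, lambda = lambda,
    partition = partition_frequencies(H, W),
    lp = list(w1_re = mk(), w1_im = mk(), b1_re = mkb(), b1_im = mkb(),
              w2_re = mk(), w2_im = mk(), b2_re = mkb(), b2_im = mkb()),
    hp = list(w1_re = mk(), w1_im = mk(), b1_re = mkb(), b1_im = mkb(),
              w2_re = mk(), w2_im = mk(), b2_re = mkb(), b2_im = mkb())
  ), class = "ffeo_state")
}

#' Apply a block-diagonal matrix to channel vectors
#'
#' `v` rows are split into `N` contiguous chunks of `C/N`; chunk `k` is
#' multiplied by block `k` (as `chunk %*% t(block)`), then the bias is
#' added. Equivalent to a dense multiply by the assembled block-diagonal
#' matrix. Real and complex inputs are both supported.
#'
#' @param v matrix `(M, C)` of row vectors (or a length-`C` vector).
#' @param W array `(N, C/N, C/N)` of diagonal blocks.
#' @param b length-`C` bias (default zero).
#' @return matrix `(M, C)` (or a vector when `v` was a vector).
#' @export
block_diag_apply <- function(v, W, b = NULL) {
  vec_in <- is.null(dim(v))
  if (vec_in) v <- matrix(v, 1L)
  dw <- dim(W)
  if (length(dw) == 2L) { W <- array(W, dim = c(1L, dw)); dw <- dim(W) }
  N <- dw[1]; cb <- dw[2]
  if (dw[2] != dw[3]) stop("blocks must be square")
  if (ncol(v) != N * cb) {
    stop("vector length ", ncol(v), " does not match ", N, " blocks of size ", cb)
  }
  out <- if (is.complex(v) || is.complex(W)) matrix(0 + 0i, nrow(v), ncol(v)) else
    matrix(0, nrow(v), ncol(v))
  for (k in seq_len(N)) {
    cols <- (k - 1L) * cb + seq_len(cb)
    Bk <- W[k, , ]; dim(Bk) <- c(cb, cb)
    out[, cols] <- v[, cols, drop = FALSE] %*% t(Bk)
  }
  if (!is.null(b)) out <- sweep(out, 2L, b, "+")
  if (vec_in) out[1L, ] else out
}

#' Fused differentiable block-diagonal complex layer on (M, C) rows.
#' Weights arrive as separate real/imaginary parameter arrays; cotangents
#' follow the pair convention (Re(g) = dL/dRe, Im(g) = dL/dIm).
#' @keywords internal
t_block_cmatmul <- function(v, w_re, w_im, b_re, b_im) {
  vv <- val(v)
  Wc <- val(w_re) + 1i * val(w_im)
  bc <- as.vector(val(b_re)) + 1i * as.vector(val(b_im))
  dw <- dim(Wc)
  N <- dw[1]; cb <- dw[2]
  out <- matrix(0 + 0i, nrow(vv), ncol(vv))
  for (k in seq_len(N)) {
    cols <- (k - 1L) * cb + seq_len(cb)
    Bk <- Wc[k, , ]; dim(Bk) <- c(cb, cb)
    out[, cols] <- vv[, cols, drop = FALSE] %*% t(Bk)
  }
  out <- sweep(out, 2L, bc, "+")
  ag_node(out, list(v, w_re, w_im, b_re, b_im), function(g) {
    gv <- matrix(0 + 0i, nrow(vv), ncol(vv))
    gW <- array(0 + 0i, dim = dw)
    for (k in seq_len(N)) {
      cols <- (k - 1L) * cb + seq_len(cb)
      Bk <- Wc[k, , ]; dim(Bk) <- c(cb, cb)
      gk <- g[, cols, drop = FALSE]
      gv[, cols] <- gk %*% Conj(Bk)
      gW[k, , ] <- t(gk) %*% Conj(vv[, cols, drop = FALSE])
    }
    gb <- colSums(g)
    list(gv,
         Re(gW), Im(gW),
         array(Re(gb), dim = length(gb)), array(Im(gb), dim = length(gb)))
  })
}

#' Run one band (low- or high-pass) through its two-layer complex MLP.
#' `zb` is the (N, C, B) stack of that band's bins.
#' @keywords internal
ffeo_band_mlp <- function(zb, pars) {
  d <- dim(val(zb))
  m <- t_reshape(t_aperm(zb, c(1, 3, 2)), c(d[1] * d[3], d[2]))
  h <- t_relu(t_block_cmatmul(m, pars$w1_re, pars$w1_im, pars$b1_re, pars$b1_im))
  o <- t_block_cmatmul(h, pars$w2_re, pars$w2_im, pars$b2_re, pars$b2_im)
  t_aperm(t_reshape(o, c(d[1], d[3], d[2])), c(1, 3, 2))
}

#' Fourier filtering enhancement operator forward pass
#'
#' Implements the full pipeline: real FFT, low/high-pass band filtering by
#' block-diagonal complex MLPs, soft-shrink enhancement, inverse FFT and the
#' residual connection. Output shape always equals input shape and the
#' output is real-valued.
#'
#' @param x feature map `(C, H, W)` or `(N, C, H, W)` (array or tensor).
#' @param state an [ffeo_state()].
#' @return feature map of the same shape and type as `x`.
#' @export
ffeo_forward <- function(x, state) {
  plain <- !ag_is(x)
  xv <- if (plain) x else val(x)
  single <- length(dim(xv)) == 3L
  if (single) dim(xv) <- c(1L, dim(xv))
  xt <- if (plain || single) ag_tensor(xv) else x
  d <- dim(val(xt))
  if (d[2] %% state$N != 0L) {
    stop("channel count ", d[2], " not divisible by N = ", state$N)
  }
  if (d[3] != state$H || d[4] != state$W) {
    stop("spatial mismatch: map is ", d[3], "x", d[4], ", partition is for ",
         state$H, "x", state$W)
  }
  part <- state$partition
  z <- t_rfft2(xt)                                  # (N, C, H, Wr) complex
  nb <- part$H * part$half_width
  z3 <- t_reshape(z, c(d[1], d[2], nb))
  zlp <- t_take_last(z3, part$lp_bins)
  zhp <- t_take_last(z3, part$hp_bins)
  flp <- ffeo_band_mlp(zlp, state$lp)
  fhp <- ffeo_band_mlp(zhp, state$hp)
  ztilde <- t_take_last(t_cat_last(flp, fhp),
                        match(seq_len(nb), c(part$lp_bins, part$hp_bins)))
  s <- t_softshrink(ztilde, state$lambda)
  zprime <- t_add(t_scale(s, state$alpha),
                  t_scale(t_sub(ztilde, s), 1 - state$alpha))
  zp <- t_reshape(zprime, c(d[1], d[2], part$H, part$half_width))
  y <- t_add(t_irfft2(zp, state$W), xt)
  if (plain || single) {
    v <- val(y)
    if (single) dim(v) <- d[-1]
    v
  } else {
    y
  }
}
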