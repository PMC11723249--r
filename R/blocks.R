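#' Backbone building blocks
#'
#' The dual-branch backbone combines a convolutional branch (ConvNeXt-style
#' blocks: 7x7 depthwise conv, layer norm, inverted 4x bottleneck with GELU,
#' layer scale, residual) gated by MSCA, and a transformer branch
#' (Swin-style blocks: windowed multi-head self-attention with relative
#' position bias, alternating shifted windows, 4x MLP) gated by FFEO.
#' A shared stem performs the initial 4x reduction and a strided conv with
#' channel doubling moves between stages.
#'
#' @name blocks
#' @keywords internal
NULL

# ---- small structural ops used only by the blocks ---------------------------

#' Select columns of a 2-D tensor; vjp scatters into zeros.
#' @keywords internal
t_take_cols <- function(a, idx) {
  av <- val(a)
  ag_node(av[, idx, drop = FALSE], list(a), function(g) {
    z <- matrix(if (is.complex(av)) 0 + 0i else 0, nrow(av), ncol(av))
    z[, idx] <- g
    list(z)
  })
}

#' Add a fixed (non-trainable) array, e.g. an attention mask.
#' @keywords internal
t_add_const <- function(a, k) {
  ag_node(val(a) + k, list(a), function(g) list(g))
}

#' Tile a (K, T, T) stack to (times*K, T, T) with the new index fastest.
#' @keywords internal
t_expand_first <- function(a, times) {
  av <- val(a)
  d <- dim(av)
  idx <- rep(seq_len(d[1]), each = times)
  ag_node(av[idx, , , drop = FALSE], list(a), function(g) {
    z <- array(0, dim = d)
    for (k in seq_len(d[1])) {
      blk <- g[(k - 1L) * times + seq_len(times), , , drop = FALSE]
      z[k, , ] <- apply(blk, c(2, 3), sum)
    }
    list(z)
  })
}

#' Circular shift of the H, W axes of an (N, H, W, C) token grid.
#' @keywords internal
t_roll_nhwc <- function(a, sh, sw) {
  av <- val(a)
  d <- dim(av)
  roll <- function(x, s1, s2) {
    if (s1 != 0) x <- x[, ((seq_len(d[2]) - 1 - s1) %% d[2]) + 1, , , drop = FALSE]
    if (s2 != 0) x <- x[, , ((seq_len(d[3]) - 1 - s2) %% d[3]) + 1, , drop = FALSE]
    x
  }
  ag_node(roll(av, sh, sw), list(a), function(g) list(roll(g, -sh, -sw)))
}

# ---- stem -------------------------------------------------------------------

#' @keywords internal
stem_new <- function(C, materialize = TRUE) {
  list(type = "stem", C = as.integer(C),
       w = ag_param(c(C, 3L, 4L, 4L), "he", materialize),
       b = ag_param(C, "zeros", materialize),
       ln_g = ag_param(C, "ones", materialize),
       ln_b = ag_param(C, "zeros", materialize))
}

#' Shared stem: 4x4 stride-4 convolution + channel layer norm
#'
#' Reduces the input resolution to one fourth; the single output is consumed
#' by both branches.
#' @keywords internal
stem_forward <- function(x, stem) {
  d <- dim(val(x))
  if (d[3] %% 4L != 0L || d[4] %% 4L != 0L) {
    stop("input spatial dims (", d[3], "x", d[4], ") must be divisible by 4")
  }
  y <- t_conv2d(x, stem$w, stem$b, stride = 4L, padding = 0L)
  t_layernorm_nchw(y, stem$ln_g, stem$ln_b)
}

# ---- ConvNeXt-style block ---------------------------------------------------

#' @keywords internal
convnext_block_new <- function(C, H = NULL, W = NULL, msca_opts = NULL,
                               materialize = TRUE) {
  msca <- NULL
  if (!is.null(msca_opts)) {
    msca <- msca_state(C, H, W, n = msca_opts$n, r = msca_opts$r,
                       freq_set = msca_opts$freq_set %||% "zigzag7",
                       materialize = materialize)
  }
  list(type = "convnext_block", C = as.integer(C),
       dw_w = ag_param(c(C, 7L, 7L), "trunc_normal", materialize),
       dw_b = ag_param(C, "zeros", materialize),
       ln_g = ag_param(C, "ones", materialize),
       ln_b = ag_param(C, "zeros", materialize),
       pw1_w = ag_param(c(C, 4L * C), "trunc_normal", materialize),
       pw1_b = ag_param(4L * C, "zeros", materialize),
       pw2_w = ag_param(c(4L * C, C), "trunc_normal", materialize),
       pw2_b = ag_param(C, "zeros", materialize),
       gamma = ag_param(C, 1, materialize),
       msca = msca)
}

#' ConvNeXt-style block with optional MSCA sigmoid gating (post-residual).
#' @keywords internal
convnext_block_forward <- function(x, blk) {
  d <- dim(val(x))
  y <- t_conv2d(x, blk$dw_w, blk$dw_b, stride = 1L, padding = 3L, groups = d[2])
  m <- t_reshape(t_aperm(y, c(1, 3, 4, 2)), c(d[1] * d[3] * d[4], d[2]))
  m <- t_layernorm(m, blk$ln_g, blk$ln_b)
  m <- t_gelu(t_linear(m, blk$pw1_w, blk$pw1_b))
  m <- t_linear(m, blk$pw2_w, blk$pw2_b)
  y <- t_aperm(t_reshape(m, c(d[1], d[3], d[4], d[2])), c(1, 4, 2, 3))
  y <- t_channel_scale(y, blk$gamma)
  xp <- t_add(x, y)
  if (is.null(blk$msca)) return(xp)
  gate <- t_sigmoid(msca_forward(xp, blk$msca))
  t_channel_gate(xp, gate)
}

# ---- Swin-style block -------------------------------------------------------

#' Largest window size <= `window` that tiles both H and W exactly.
#' @keywords internal
resolve_window <- function(H, W, window) {
  for (w in seq(min(window, H, W), 1L)) {
    if (H %% w == 0L && W %% w == 0L) return(as.integer(w))
  }
  1L
}

#' Relative-position index (1-based rows into the (2w-1)^2 bias table),
#' token order: row coordinate fastest within the window.
#' @keywords internal
relpos_index <- function(w) {
  t <- seq_len(w * w)
  ah <- (t - 1L) %% w
  aw <- (t - 1L) %/% w
  dh <- outer(ah, ah, "-") + w - 1L
  dwd <- outer(aw, aw, "-") + w - 1L
  as.vector(dh * (2L * w - 1L) + dwd + 1L)
}

#' Additive attention mask for shifted windows: token pairs from different
#' pre-shift regions get -100.
#' @keywords internal
swin_attn_mask <- function(H, W, w, s) {
  slices <- function(L) {
    if (L <= w) list(seq_len(L))
    else list(seq_len(L - w), seq.int(L - w + 1L, L - s), seq.int(L - s + 1L, L))
  }
  region <- matrix(0, H, W)
  cnt <- 0
  for (hs in slices(H)) for (ws in slices(W)) {
    region[hs, ws] <- cnt
    cnt <- cnt + 1
  }
  nH <- H %/% w; nW <- W %/% w
  dim(region) <- c(w, nH, w, nW)
  region <- aperm(region, c(2, 4, 1, 3))          # (nH, nW, wh, ww)
  dim(region) <- c(nH * nW, w * w)
  T <- w * w
  mask <- array(0, dim = c(nH * nW, T, T))
  for (k in seq_len(nH * nW)) {
    same <- outer(region[k, ], region[k, ], "==")
    mask[k, , ] <- ifelse(same, 0, -100)
  }
  mask
}

#' @keywords internal
swin_block_new <- function(C, H, W, window, shifted, heads, materialize = TRUE) {
  w <- resolve_window(H, W, window)
  shift <- if (shifted && (H > w || W > w)) w %/% 2L else 0L
  key <- paste("swin_aux", H, W, w, shift, sep = "_")
  aux <- ag_cached(key, function() {
    list(relidx = relpos_index(w),
         mask = if (shift > 0L) swin_attn_mask(H, W, w, shift) else NULL)
  })
  list(type = "swin_block", C = as.integer(C), H = as.integer(H),
       W = as.integer(W), window = w, shift = shift, heads = as.integer(heads),
       relidx = aux$relidx, mask = aux$mask,
       ln1_g = ag_param(C, "ones", materialize),
       ln1_b = ag_param(C, "zeros", materialize),
       qkv_w = ag_param(c(C, 3L * C), "trunc_normal", materialize),
       qkv_b = ag_param(3L * C, "zeros", materialize),
       relpos = ag_param(c((2L * w - 1L)^2, heads), "trunc_normal", materialize),
       proj_w = ag_param(c(C, C), "trunc_normal", materialize),
       proj_b = ag_param(C, "zeros", materialize),
       ln2_g = ag_param(C, "ones", materialize),
       ln2_b = ag_param(C, "zeros", materialize),
       fc1_w = ag_param(c(C, 4L * C), "trunc_normal", materialize),
       fc1_b = ag_param(4L * C, "zeros", materialize),
       fc2_w = ag_param(c(4L * C, C), "trunc_normal", materialize),
       fc2_b = ag_param(C, "zeros", materialize))
}

#' Swin-style block with optional FFEO sigmoid gating applied by the caller.
#' Window attention with relative position bias; the block's `shift` field
#' decides plain vs shifted windows.
#' @keywords internal
swin_block_forward <- function(x, blk) {
  d <- dim(val(x))
  N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  w <- blk$window; s <- blk$shift
  nH <- H %/% w; nW <- W %/% w
  T <- w * w
  heads <- blk$heads
  dh <- C %/% heads
  Bp <- N * nH * nW

  t4 <- t_aperm(x, c(1, 3, 4, 2))                  # (N, H, W, C)
  short <- t4
  m <- t_layernorm(t_reshape(t4, c(N * H * W, C)), blk$ln1_g, blk$ln1_b)
  g4 <- t_reshape(m, c(N, H, W, C))
  if (s > 0L) g4 <- t_roll_nhwc(g4, -s, -s)
  win <- t_reshape(
    t_aperm(t_reshape(g4, c(N, w, nH, w, nW, C)), c(1, 3, 5, 2, 4, 6)),
    c(Bp * T, C))
  qkv <- t_linear(win, blk$qkv_w, blk$qkv_b)       # (Bp*T, 3C)
  split_heads <- function(z) {
    t_reshape(t_aperm(t_reshape(z, c(Bp, T, dh, heads)), c(1, 4, 2, 3)),
              c(Bp * heads, T, dh))
  }
  q <- split_heads(t_take_cols(qkv, seq_len(C)))
  k <- split_heads(t_take_cols(qkv, C + seq_len(C)))
  v <- split_heads(t_take_cols(qkv, 2L * C + seq_len(C)))
  sc <- t_scale(t_bmm(q, k, transB = TRUE), 1 / sqrt(dh))
  bias <- t_reshape(t_aperm(t_gather_rows(blk$relpos, blk$relidx), c(2, 1)),
                    c(heads, T, T))
  sc <- t_add(sc, t_expand_first(bias, Bp))
  if (!is.null(blk$mask)) {
    widx <- rep(rep(seq_len(nH * nW), each = N), times = heads)
    sc <- t_add_const(sc, blk$mask[widx, , , drop = FALSE])
  }
  att <- t_softmax_last(sc)
  o <- t_bmm(att, v)                               # (Bp*heads, T, dh)
  o <- t_reshape(t_aperm(t_reshape(o, c(Bp, heads, T, dh)), c(1, 3, 4, 2)),
                 c(Bp * T, C))
  o <- t_linear(o, blk$proj_w, blk$proj_b)
  o4 <- t_reshape(
    t_aperm(t_reshape(o, c(Bp, T, C)), c(1, 2, 3)), c(N, nH, nW, w, w, C))
  o4 <- t_reshape(t_aperm(o4, c(1, 4, 2, 5, 3, 6)), c(N, H, W, C))
  if (s > 0L) o4 <- t_roll_nhwc(o4, s, s)
  t1 <- t_add(short, o4)

  m2 <- t_layernorm(t_reshape(t1, c(N * H * W, C)), blk$ln2_g, blk$ln2_b)
  m2 <- t_gelu(t_linear(m2, blk$fc1_w, blk$fc1_b))
  m2 <- t_linear(m2, blk$fc2_w, blk$fc2_b)
  t2 <- t_add(t1, t_reshape(m2, c(N, H, W, C)))
  t_aperm(t2, c(1, 4, 2, 3))
}

# ---- downsample and head ----------------------------------------------------

#' @keywords internal
downsample_new <- function(C, materialize = TRUE) {
  list(type = "downsample", C = as.integer(C),
       ln_g = ag_param(C, "ones", materialize),
       ln_b = ag_param(C, "zeros", materialize),
       w = ag_param(c(2L * C, C, 2L, 2L), "he", materialize),
       b = ag_param(2L * C, "zeros", materialize))
}

#' Between-stage reduction: layer norm + 2x2 stride-2 conv with channel
#' doubling, (C, H, W) -> (2C, H/2, W/2).
#' @keywords internal
downsample_forward <- function(x, ds) {
  d <- dim(val(x))
  if (d[3] %% 2L != 0L || d[4] %% 2L != 0L) {
    stop("downsample needs even spatial dims, got ", d[3], "x", d[4])
  }
  y <- t_layernorm_nchw(x, ds$ln_g, ds$ln_b)
  t_conv2d(y, ds$w, ds$b, stride = 2L, padding = 0L)
}

#' @keywords internal
head_new <- function(C, M, materialize = TRUE) {
  list(type = "head", C = as.integer(C), M = as.integer(M),
       ln_g = ag_param(C, "ones", materialize),
       ln_b = ag_param(C, "zeros", materialize),
       w = ag_param(c(C, M), "trunc_normal", materialize),
       b = ag_param(M, "zeros", materialize))
}

#' Classifier head: global average pool, layer norm, linear map to M logits.
#' Returns list(logits, features) where features are the pooled normalised
#' pre-head activations used for embedding export.
#' @keywords internal
head_forward <- function(x, hd) {
  p <- t_gap(x)                                    # (N, C)
  f <- t_layernorm(p, hd$ln_g, hd$ln_b)
  list(logits = t_linear(f, hd$w, hd$b), features = f)
}
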