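#' @title Minimal reverse-mode automatic differentiation over base-R arrays
#'
#' @description
#' The network modules in this package are trained end-to-end, which requires
#' gradients through convolutions, window attention, layer normalisation and
#' the spectral (DCT/FFT) operators. No deep-learning runtime is involved:
#' tensors are plain R arrays wrapped in environments, operations optionally
#' record vector-Jacobian-product closures on a tape, and `ag_backward()`
#' replays the tape in reverse creation order.
#'
#' Conventions:
#' * feature maps are arrays of dim `(N, C, H, W)`; channel descriptors are
#'   `(N, C)` matrices; token matrices are `(rows, C)`.
#' * complex-valued nodes (FFT half-spectra) carry complex arrays; their
#'   gradient `g` is complex with `Re(g) = dL/dRe`, `Im(g) = dL/dIm`.
#'
#' None of this is exported; module-level functions are the public surface.
#' @name autograd
#' @keywords internal
NULL

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL
.ag$cache <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap a value as a leaf tensor (no history).
#' @keywords internal
ag_tensor <- function(value) {
  e <- new.env(parent = emptyenv())
  e$v <- value
  class(e) <- "ag_tensor"
  e
}

ag_is <- function(x) inherits(x, "ag_tensor")

#' Extract the raw array from a tensor (identity on plain arrays).
#' @keywords internal
val <- function(x) if (ag_is(x)) x$v else x

#' Create a tensor recording its parents and vjp on the active tape.
#' `vjp(g)` must return a list of gradients aligned with `parents`
#' (NULL entries for non-differentiable parents).
#' @keywords internal
ag_node <- function(value, parents = list(), vjp = NULL) {
  e <- ag_tensor(value)
  tp <- .ag$tape
  if (!is.null(tp) && !is.null(vjp)) {
    e$parents <- parents
    e$vjp <- vjp
    tp$n <- tp$n + 1L
    if (tp$n > length(tp$nodes)) {
      tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
    }
    tp$nodes[[tp$n]] <- e
  }
  e
}

#' Open a fresh tape; subsequent ops record gradients until `ag_tape_close()`.
#' @keywords internal
ag_tape_open <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  .ag$tape <- tp
  invisible(tp)
}

#' @keywords internal
ag_tape_close <- function() {
  tp <- .ag$tape
  .ag$tape <- NULL
  invisible(tp)
}

#' Reverse-mode sweep: seeds `loss` with gradient 1 and accumulates `$g`
#' on every tensor reachable on the tape (including leaves/parameters).
#' @keywords internal
ag_backward <- function(tape, loss) {
  stopifnot(length(val(loss)) == 1L)
  loss$g <- array(1, dim = dim(loss$v) %||% 1L)
  if (tape$n > 0L) {
    for (k in seq.int(tape$n, 1L)) {
      nd <- tape$nodes[[k]]
      g <- nd$g
      if (is.null(g)) next
      gs <- nd$vjp(g)
      ps <- nd$parents
      for (j in seq_along(ps)) {
        gj <- gs[[j]]
        if (is.null(gj)) next
        p <- ps[[j]]
        if (!ag_is(p)) next        # constant (plain array) parent
        p$g <- if (is.null(p$g)) gj else p$g + gj
      }
      nd$g <- NULL
    }
  }
  invisible(NULL)
}

#' Trainable parameter: a leaf tensor that always knows its shape, and only
#' optionally holds data. Shape-only parameters support exact parameter
#' counting of large reference models without allocating their weights.
#' `init` may be "zeros", "ones", "trunc_normal" (sd 0.02, the convention
#' for layers wrapped in norm + residual), "he" (truncated normal with
#' sd = sqrt(2 / fan_in), for bare convolution paths), or a numeric
#' constant.
#' @keywords internal
ag_param <- function(shape, init = "zeros",
                     materialize = TRUE, sd = 0.02, name = NULL) {
  if (identical(init, "he")) {
    # fan-in: everything but the leading output axis for conv weights
    # (Cout, Cin, kh, kw); depthwise (C, kh, kw) and matrices (Cin, Cout)
    # take the kernel/input axes.
    fan <- switch(as.character(length(shape)),
                  "4" = prod(shape[-1]),
                  "3" = prod(shape[-1]),
                  "2" = shape[1],
                  prod(shape))
    sd <- sqrt(2 / fan)
    init <- "trunc_normal"
  }
  value <- NULL
  if (materialize) {
    n <- prod(shape)
    value <- if (is.numeric(init)) array(init, dim = shape) else switch(init,
      zeros = array(0, dim = shape),
      ones = array(1, dim = shape),
      trunc_normal = {
        x <- stats::rnorm(n, 0, sd)
        # resample tails so the draw stays within 2 sd (truncated normal)
        bad <- abs(x) > 2 * sd
        while (any(bad)) {
          x[bad] <- stats::rnorm(sum(bad), 0, sd)
          bad <- abs(x) > 2 * sd
        }
        array(x, dim = shape)
      },
      stop("unknown parameter init: ", init)
    )
  }
  e <- ag_tensor(value)
  e$shape <- as.integer(shape)
  e$param <- TRUE
  e$name <- name
  e
}

ag_is_param <- function(x) isTRUE(x$param)

#' Recursively collect every `ag_param` in a (nested) module list.
#' @keywords internal
ag_collect_params <- function(module, prefix = "") {
  out <- list()
  if (ag_is(module)) {
    if (ag_is_param(module)) out[[prefix]] <- module
    return(out)
  }
  if (is.list(module)) {
    nms <- names(module) %||% as.character(seq_along(module))
    for (i in seq_along(module)) {
      key <- if (nzchar(prefix)) paste(prefix, nms[i], sep = ".") else nms[i]
      out <- c(out, ag_collect_params(module[[i]], key))
    }
  }
  out
}

#' @keywords internal
ag_zero_grad <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}

# ---- cache for precomputed index structures (im2col maps, DCT bases, masks) ----

ag_cached <- function(key, builder) {
  if (!exists(key, envir = .ag$cache, inherits = FALSE)) {
    assign(key, builder(), envir = .ag$cache)
  }
  get(key, envir = .ag$cache, inherits = FALSE)
}

# ---- elementary ops ----------------------------------------------------------

t_add <- function(a, b) {
  av <- val(a); bv <- val(b)
  stopifnot(identical(dim(av) %||% length(av), dim(bv) %||% length(bv)))
  ag_node(av + bv, list(a, b), function(g) list(g, g))
}

t_sub <- function(a, b) {
  av <- val(a); bv <- val(b)
  ag_node(av - bv, list(a, b), function(g) list(g, -g))
}

t_mul <- function(a, b) {
  av <- val(a); bv <- val(b)
  stopifnot(identical(dim(av) %||% length(av), dim(bv) %||% length(bv)))
  ag_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

#' Multiply by a fixed scalar (or add one) without creating a parent.
#' @keywords internal
t_scale <- function(a, k) {
  av <- val(a)
  ag_node(av * k, list(a), function(g) list(g * k))
}

t_shift <- function(a, k) {
  av <- val(a)
  ag_node(av + k, list(a), function(g) list(g))
}

t_sum <- function(a) {
  av <- val(a)
  ag_node(array(sum(av), 1L), list(a),
          function(g) list(array(as.vector(g), dim = dim(av) %||% length(av))))
}

t_mean <- function(a) {
  av <- val(a)
  n <- length(av)
  ag_node(array(mean(av), 1L), list(a),
          function(g) list(array(as.vector(g) / n, dim = dim(av) %||% length(av))))
}

t_reshape <- function(a, dims) {
  av <- val(a)
  old <- dim(av) %||% length(av)
  v <- av
  dim(v) <- dims
  ag_node(v, list(a), function(g) { dim(g) <- old; list(g) })
}

t_aperm <- function(a, perm) {
  av <- val(a)
  ag_node(aperm(av, perm), list(a),
          function(g) list(aperm(g, order(perm))))
}

#' Matrix product; `Conj(t(.))` keeps the rule valid for complex operands.
#' @keywords internal
t_matmul <- function(a, b) {
  av <- val(a); bv <- val(b)
  ag_node(av %*% bv, list(a, b), function(g) {
    list(g %*% Conj(t(bv)), Conj(t(av)) %*% g)
  })
}

#' Batched matrix multiply on (b, m, k) x (b, k, n) stacks.
#' @keywords internal
t_bmm <- function(a, b, transB = FALSE) {
  av <- val(a); bv <- val(b)
  da <- dim(av); db <- dim(bv)
  stopifnot(da[1] == db[1])
  nb <- da[1]
  n2 <- if (transB) db[2] else db[3]
  out <- array(0, dim = c(nb, da[2], n2))
  for (i in seq_len(nb)) {
    Bi <- bv[i, , , drop = TRUE]; dim(Bi) <- db[2:3]
    Ai <- av[i, , , drop = TRUE]; dim(Ai) <- da[2:3]
    out[i, , ] <- if (transB) Ai %*% t(Bi) else Ai %*% Bi
  }
  ag_node(out, list(a, b), function(g) {
    ga <- array(0, dim = da); gb <- array(0, dim = db)
    for (i in seq_len(nb)) {
      Gi <- g[i, , , drop = TRUE]; dim(Gi) <- c(da[2], n2)
      Ai <- av[i, , , drop = TRUE]; dim(Ai) <- da[2:3]
      Bi <- bv[i, , , drop = TRUE]; dim(Bi) <- db[2:3]
      if (transB) {
        ga[i, , ] <- Gi %*% Bi
        gb[i, , ] <- t(Gi) %*% Ai
      } else {
        ga[i, , ] <- Gi %*% t(Bi)
        gb[i, , ] <- t(Ai) %*% Gi
      }
    }
    list(ga, gb)
  })
}

# ---- activations -------------------------------------------------------------

t_relu <- function(a) {
  av <- val(a)
  if (is.complex(av)) {
    # applied to real and imaginary parts independently
    v <- complex(real = pmax(Re(av), 0), imaginary = pmax(Im(av), 0))
    dim(v) <- dim(av)
    ag_node(v, list(a), function(g) {
      gr <- Re(g) * (Re(av) > 0)
      gi <- Im(g) * (Im(av) > 0)
      gv <- complex(real = gr, imaginary = gi)
      dim(gv) <- dim(av)
      list(gv)
    })
  } else {
    ag_node(pmax(av, 0), list(a), function(g) list(g * (av > 0)))
  }
}

t_gelu <- function(a) {
  av <- val(a)
  ph <- stats::pnorm(av)
  ag_node(av * ph, list(a),
          function(g) list(g * (ph + av * stats::dnorm(av))))
}

t_sigmoid <- function(a) {
  av <- val(a)
  s <- 1 / (1 + exp(-av))
  ag_node(s, list(a), function(g) list(g * s * (1 - s)))
}

#' Soft-shrinkage sign(x) * max(|x| - lam, 0); complex input is shrunk
#' componentwise on real and imaginary parts.
#' @keywords internal
t_softshrink <- function(a, lam) {
  stopifnot(lam >= 0)
  av <- val(a)
  v <- softshrink(av, lam)
  ag_node(v, list(a), function(g) {
    if (is.complex(av)) {
      gv <- complex(real = Re(g) * (abs(Re(av)) > lam),
                    imaginary = Im(g) * (abs(Im(av)) > lam))
      dim(gv) <- dim(av)
      list(gv)
    } else {
      list(g * (abs(av) > lam))
    }
  })
}

# ---- structural ops ----------------------------------------------------------

#' Concatenate along the channel axis (dim 2 of NCHW or dim 2 of (N, C)).
#' @keywords internal
t_cat_c <- function(a, b) {
  av <- val(a); bv <- val(b)
  da <- dim(av); db <- dim(bv)
  stopifnot(length(da) == length(db), da[-2] == db[-2])
  nd <- length(da)
  v <- if (nd == 4L) {
    arr <- array(0, dim = c(da[1], da[2] + db[2], da[3], da[4]))
    arr[, seq_len(da[2]), , ] <- av
    arr[, da[2] + seq_len(db[2]), , ] <- bv
    arr
  } else {
    cbind(av, bv)
  }
  ag_node(v, list(a, b), function(g) {
    if (nd == 4L) {
      list(g[, seq_len(da[2]), , , drop = FALSE],
           g[, da[2] + seq_len(db[2]), , , drop = FALSE])
    } else {
      list(g[, seq_len(da[2]), drop = FALSE],
           g[, da[2] + seq_len(db[2]), drop = FALSE])
    }
  })
}

#' Select columns (last axis) of a (N, C, B) stack of flattened bins.
#' @keywords internal
t_take_last <- function(a, idx) {
  av <- val(a)
  da <- dim(av)
  v <- av[, , idx, drop = FALSE]
  ag_node(v, list(a), function(g) {
    z <- array(if (is.complex(av)) 0 + 0i else 0, dim = da)
    z[, , idx] <- g
    list(z)
  })
}

#' Gather rows with (possibly repeated) indices; vjp scatter-adds.
#' Used for the relative-position bias lookup.
#' @keywords internal
t_gather_rows <- function(a, idx) {
  av <- val(a)
  da <- dim(av)
  v <- av[idx, , drop = FALSE]
  ag_node(v, list(a), function(g) {
    z <- matrix(0, da[1], da[2])
    for (j in seq_len(da[2])) {
      s <- rowsum(g[, j], group = idx)
      z[as.integer(rownames(s)), j] <- s
    }
    list(z)
  })
}

#' Circular shift of the spatial axes of an NCHW map.
#' @keywords internal
t_roll2 <- function(a, sh, sw) {
  av <- val(a)
  d <- dim(av)
  roll <- function(x, s1, s2) {
    if (s1 != 0) {
      i <- ((seq_len(d[3]) - 1 - s1) %% d[3]) + 1
      x <- x[, , i, , drop = FALSE]
    }
    if (s2 != 0) {
      j <- ((seq_len(d[4]) - 1 - s2) %% d[4]) + 1
      x <- x[, , , j, drop = FALSE]
    }
    x
  }
  ag_node(roll(av, sh, sw), list(a),
          function(g) list(roll(g, -sh, -sw)))
}

# ---- reductions / broadcasts on maps ----------------------------------------

#' Global average pool (N, C, H, W) -> (N, C).
#' @keywords internal
t_gap <- function(a) {
  av <- val(a)
  d <- dim(av)
  m <- av
  dim(m) <- c(d[1] * d[2], d[3] * d[4])
  v <- matrix(rowMeans(m), d[1], d[2])
  ag_node(v, list(a), function(g) {
    gx <- array(rep(as.vector(g) / (d[3] * d[4]), d[3] * d[4]), dim = d)
    gx
    list(gx)
  })
}

#' Channel sum with keepdim: (N, C, H, W) -> (N, 1, H, W).
#' @keywords internal
t_sum_channels <- function(a) {
  av <- val(a)
  d <- dim(av)
  v <- array(0, dim = c(d[1], 1L, d[3], d[4]))
  for (c in seq_len(d[2])) v[, 1, , ] <- v[, 1, , ] + av[, c, , ]
  ag_node(v, list(a), function(g) {
    gx <- array(0, dim = d)
    for (c in seq_len(d[2])) gx[, c, , ] <- g[, 1, , ]
    list(gx)
  })
}

#' Multiply an (N, C, H, W) map by an (N, 1, H, W) spatial weight map.
#' @keywords internal
t_mul_spatial <- function(a, m) {
  av <- val(a); mv <- val(m)
  d <- dim(av)
  mb <- array(0, dim = d)
  for (c in seq_len(d[2])) mb[, c, , ] <- mv[, 1, , ]
  ag_node(av * mb, list(a, m), function(g) {
    gm <- array(0, dim = dim(mv))
    for (c in seq_len(d[2])) gm[, 1, , ] <- gm[, 1, , ] + g[, c, , ] * av[, c, , ]
    list(g * mb, gm)
  })
}

#' Gate an (N, C, H, W) map channelwise by an (N, C) matrix.
#' @keywords internal
t_channel_gate <- function(a, s) {
  av <- val(a); sv <- val(s)
  d <- dim(av)
  sb <- array(rep(as.vector(sv), d[3] * d[4]), dim = d)
  ag_node(av * sb, list(a, s), function(g) {
    gs4 <- g * av
    dim(gs4) <- c(d[1] * d[2], d[3] * d[4])
    gs <- matrix(rowSums(gs4), d[1], d[2])
    list(g * sb, gs)
  })
}

#' Scale channels of an (N, C, H, W) map by a length-C parameter vector
#' (ConvNeXt layer scale).
#' @keywords internal
t_channel_scale <- function(a, gam) {
  av <- val(a); gv <- as.vector(val(gam))
  d <- dim(av)
  gb <- array(rep(rep(gv, each = d[1]), d[3] * d[4]), dim = d)
  ag_node(av * gb, list(a, gam), function(g) {
    gg4 <- g * av
    dim(gg4) <- c(d[1], d[2], d[3] * d[4])
    ggam <- apply(gg4, 2, sum)
    list(g * gb, array(ggam, dim = d[2]))
  })
}

# ---- dense / normalisation ---------------------------------------------------

#' Affine layer on row-major feature matrices: (R, Cin) %*% (Cin, Cout) + b.
#' @keywords internal
t_linear <- function(x, w, b = NULL) {
  xv <- val(x); wv <- val(w)
  v <- xv %*% wv
  if (!is.null(b)) v <- sweep(v, 2L, as.vector(val(b)), "+")
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_node(v, parents, function(g) {
    gx <- g %*% t(wv)
    gw <- t(xv) %*% g
    if (is.null(b)) list(gx, gw) else list(gx, gw, array(colSums(g), dim = ncol(g)))
  })
}

#' Layer normalisation across the columns of an (R, C) matrix.
#' @keywords internal
t_layernorm <- function(x, gamma, beta, eps = 1e-6) {
  xv <- val(x)
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  gv <- as.vector(val(gamma)); bv <- as.vector(val(beta))
  v <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
  ag_node(v, list(x, gamma, beta), function(g) {
    gxhat <- sweep(g, 2L, gv, "*")
    m1 <- rowMeans(gxhat)
    m2 <- rowMeans(gxhat * xhat)
    gx <- inv * (gxhat - m1 - xhat * m2)
    list(gx,
         array(colSums(g * xhat), dim = length(gv)),
         array(colSums(g), dim = length(bv)))
  })
}

#' Layer norm over the channel axis of an NCHW map (ConvNeXt-style).
#' @keywords internal
t_layernorm_nchw <- function(x, gamma, beta, eps = 1e-6) {
  d <- dim(val(x))
  m <- t_reshape(t_aperm(x, c(1, 3, 4, 2)), c(d[1] * d[3] * d[4], d[2]))
  m <- t_layernorm(m, gamma, beta, eps)
  t_aperm(t_reshape(m, c(d[1], d[3], d[4], d[2])), c(1, 4, 2, 3))
}

#' Row-wise softmax over the last axis of an (R, T) matrix or (b, T, T) stack.
#' @keywords internal
t_softmax_last <- function(x) {
  xv <- val(x)
  d <- dim(xv)
  m <- xv
  if (length(d) == 3L) dim(m) <- c(d[1] * d[2], d[3])
  m <- m - apply(m, 1, max)
  e <- exp(m)
  p <- e / rowSums(e)
  pv <- p
  if (length(d) == 3L) dim(pv) <- d
  ag_node(pv, list(x), function(g) {
    gm <- g; dim(gm) <- dim(p)
    gx <- p * (gm - rowSums(gm * p))
    dim(gx) <- d
    list(gx)
  })
}

#' Mean cross-entropy from logits with a log-sum-exp stabilised softmax.
#' `labels` are 1-based class indices.
#' @keywords internal
t_softmax_xent <- function(logits, labels) {
  lv <- val(logits)
  n <- nrow(lv)
  m <- lv - apply(lv, 1, max)
  lse <- log(rowSums(exp(m)))
  picked <- m[cbind(seq_len(n), labels)]
  loss <- mean(lse - picked)
  p <- exp(m) / rowSums(exp(m))
  ag_node(array(loss, 1L), list(logits), function(g) {
    oh <- matrix(0, n, ncol(lv))
    oh[cbind(seq_len(n), labels)] <- 1
    list((p - oh) * (as.vector(g) / n))
  })
}

# ---- convolution -------------------------------------------------------------

conv_out_len <- function(L, k, stride, pad) (L + 2L * pad - k) %/% stride + 1L

#' Precompute the im2col linear-index matrix for a given geometry.
#' Rows are output positions (n fastest, then oh, then ow); columns are
#' (c, kh, kw) with channel fastest, indexing into the zero-padded input.
#' @keywords internal
conv_index <- function(N, C, H, W, kh, kw, sh, sw, ph, pw) {
  key <- paste("i2c", N, C, H, W, kh, kw, sh, sw, ph, pw, sep = "_")
  ag_cached(key, function() {
    Hp <- H + 2L * ph; Wp <- W + 2L * pw
    Ho <- conv_out_len(H, kh, sh, ph); Wo <- conv_out_len(W, kw, sw, pw)
    n_r <- rep(seq_len(N), times = Ho * Wo)
    oh_r <- rep(rep(seq_len(Ho), each = N), times = Wo)
    ow_r <- rep(seq_len(Wo), each = N * Ho)
    h0 <- (oh_r - 1L) * sh    # 0-based top row of the patch in padded coords
    w0 <- (ow_r - 1L) * sw
    rowbase <- n_r + N * C * h0 + N * C * Hp * w0
    c_c <- rep(seq_len(C), times = kh * kw)
    dh_c <- rep(rep(seq_len(kh) - 1L, each = C), times = kw)
    dw_c <- rep(seq_len(kw) - 1L, each = C * kh)
    colbase <- N * (c_c - 1L) + N * C * dh_c + N * C * Hp * dw_c
    idx <- outer(rowbase, colbase, "+")
    list(idx = idx, Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo,
         R = N * Ho * Wo, K = C * kh * kw,
         kcol_groups = split(seq_len(C * kh * kw),
                             rep(seq_len(kh * kw), each = C)))
  })
}

pad_nchw <- function(x, ph, pw) {
  if (ph == 0L && pw == 0L) return(x)
  d <- dim(x)
  xp <- array(0, dim = c(d[1], d[2], d[3] + 2L * ph, d[4] + 2L * pw))
  xp[, , ph + seq_len(d[3]), pw + seq_len(d[4])] <- x
  xp
}

crop_nchw <- function(xp, ph, pw, H, W) {
  if (ph == 0L && pw == 0L) return(xp)
  xp[, , ph + seq_len(H), pw + seq_len(W), drop = FALSE]
}

#' 2-D convolution on NCHW maps. `groups` is 1 (dense) or C (depthwise).
#' Weight layout: dense (Cout, Cin, kh, kw); depthwise (C, kh, kw).
#' @keywords internal
t_conv2d <- function(x, w, b = NULL, stride = 1L, padding = 0L, groups = 1L) {
  xv <- val(x); wv <- val(w)
  d <- dim(xv)
  N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  stride <- rep(as.integer(stride), length.out = 2L)
  padding <- rep(as.integer(padding), length.out = 2L)
  dw <- dim(wv)
  depthwise <- groups > 1L
  if (depthwise) {
    stopifnot(groups == C, dw[1] == C)
    kh <- dw[2]; kw <- dw[3]
  } else {
    stopifnot(dw[2] == C)
    kh <- dw[3]; kw <- dw[4]
  }
  ci <- conv_index(N, C, H, W, kh, kw, stride[1], stride[2], padding[1], padding[2])
  xp <- pad_nchw(xv, padding[1], padding[2])
  P <- matrix(xp[as.vector(ci$idx)], ci$R, ci$K)

  if (depthwise) {
    # P columns ordered channel-fastest: view as (R, C, kh*kw)
    Pm <- P
    dim(Pm) <- c(ci$R, C, kh * kw)
    Pm <- aperm(Pm, c(1, 2, 3))
    dim(Pm) <- c(ci$R * C, kh * kw)
    wm <- matrix(wv, C, kh * kw)
    wexp <- wm[rep(seq_len(C), each = ci$R), , drop = FALSE]
    ovec <- rowSums(Pm * wexp)
    out <- array(ovec, dim = c(ci$R, C))   # rows (n, oh, ow), cols channel
    if (!is.null(b)) out <- sweep(out, 2L, as.vector(val(b)), "+")
    dim(out) <- c(N, ci$Ho, ci$Wo, C)
    out <- aperm(out, c(1, 4, 2, 3))
    parents <- if (is.null(b)) list(x, w) else list(x, w, b)
    vjp <- function(g) {
      gm <- aperm(g, c(1, 3, 4, 2))          # (N, Ho, Wo, C)
      dim(gm) <- c(ci$R, C)
      gvec <- as.vector(gm)                  # length R*C, row-major over (R, C)
      gw <- rowsum(Pm * gvec, group = rep(seq_len(C), each = ci$R))
      gw <- array(gw, dim = dim(wv))
      gP <- wexp * gvec
      dim(gP) <- c(ci$R, C, kh * kw)
      dim(gP) <- c(ci$R, C * kh * kw)
      gxp <- numeric(N * C * ci$Hp * ci$Wp)
      for (grp in ci$kcol_groups) {
        ii <- as.vector(ci$idx[, grp])
        gxp[ii] <- gxp[ii] + as.vector(gP[, grp])
      }
      dim(gxp) <- c(N, C, ci$Hp, ci$Wp)
      gx <- crop_nchw(gxp, padding[1], padding[2], H, W)
      if (is.null(b)) list(gx, gw) else list(gx, gw, array(colSums(gm), dim = C))
    }
    return(ag_node(out, parents, vjp))
  }

  Cout <- dw[1]
  wmat <- matrix(aperm(wv, c(2, 3, 4, 1)), ci$K, Cout)
  om <- P %*% wmat
  if (!is.null(b)) om <- sweep(om, 2L, as.vector(val(b)), "+")
  out <- om
  dim(out) <- c(N, ci$Ho, ci$Wo, Cout)
  out <- aperm(out, c(1, 4, 2, 3))
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  vjp <- function(g) {
    gm <- aperm(g, c(1, 3, 4, 2))
    dim(gm) <- c(ci$R, Cout)
    gwmat <- t(P) %*% gm
    gw <- array(gwmat, dim = c(C, kh, kw, Cout))
    gw <- aperm(gw, c(4, 1, 2, 3))
    gP <- gm %*% t(wmat)
    gxp <- numeric(N * C * ci$Hp * ci$Wp)
    for (grp in ci$kcol_groups) {
      ii <- as.vector(ci$idx[, grp])
      gxp[ii] <- gxp[ii] + as.vector(gP[, grp])
    }
    dim(gxp) <- c(N, C, ci$Hp, ci$Wp)
    gx <- crop_nchw(gxp, padding[1], padding[2], H, W)
    if (is.null(b)) list(gx, gw) else list(gx, gw, array(colSums(gm), dim = Cout))
  }
  ag_node(out, parents, vjp)
}
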