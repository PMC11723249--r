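# The two trainable frequency-domain operators: multi-spectral channel
# attention (DCT squeeze-excitation) and the Fourier filtering enhancement
# operator (band-split block-diagonal spectral MLPs + soft-shrink).

test_that("msca_forward reduces to the DCT oracle in linear identity mode", {
  set.seed(20)
  st <- msca_state(16, 7, 7, n = 16, r = 1, activation = "identity")
  st$w_down$v <- diag(16)
  st$w_up$v <- diag(16)
  x <- array(rnorm(16 * 7 * 7), c(16, 7, 7))
  d <- msca_forward(x, st)
  fp <- st$basis$freq_pairs
  oracle <- vapply(1:16, function(c) naive_dct_coeff(x[c, , ], fp[c, 1], fp[c, 2]), 0)
  expect_lt(max(abs(d - oracle)), 1e-5)

  # zero input with zero biases stays zero through the whole chain
  st2 <- msca_state(16, 7, 7)
  expect_equal(msca_forward(array(0, c(16, 7, 7)), st2), rep(0, 16))

  expect_error(msca_forward(array(0, c(8, 7, 7)), st2), "channel mismatch")
  expect_error(msca_state(10, 7, 7, n = 16), "divisible")
})

test_that("msca descriptors are linear and spatially sensitive as expected", {
  set.seed(21)
  st <- msca_state(16, 6, 6, n = 16, r = 4, activation = "identity")
  st$b_down$v <- array(rnorm(4), 4)       # non-zero biases: affine, not linear
  st$b_up$v <- array(rnorm(16), 16)
  x1 <- array(rnorm(16 * 36), c(16, 6, 6))
  x2 <- array(rnorm(16 * 36), c(16, 6, 6))
  # superposition holds with the nonlinearity disabled
  d12 <- msca_forward(x1 + x2, st)
  expect_lt(max(abs(d12 - msca_forward(x1, st) - msca_forward(x2, st) +
                      as.vector(st$b_up$v) +
                      as.vector(val(affnet:::t_linear(
                        affnet:::ag_tensor(matrix(as.vector(st$b_down$v), 1)),
                        st$w_up))))), 1e-5)

  # DC-only frequencies are permutation invariant, higher ones are not
  stdc <- msca_state(4, 4, 4, n = 4, r = 1, activation = "identity")
  stdc$basis <- build_dct_basis(4, 4, matrix(0L, 4, 2))
  stdc$bc <- matrix(stdc$basis$basis, 4, 16)[rep(1:4, each = 1), ]
  stdc$w_down$v <- diag(4); stdc$w_up$v <- diag(4)
  xa <- array(rnorm(4 * 16), c(4, 4, 4))
  xp <- xa
  perm <- sample(16)
  for (c in 1:4) xp[c, , ] <- array(as.vector(xa[c, , ])[perm], c(4, 4))
  expect_equal(msca_forward(xa, stdc), msca_forward(xp, stdc), tolerance = 1e-10)

  sthi <- msca_state(4, 4, 4, n = 4, r = 1, activation = "identity")
  sthi$basis <- build_dct_basis(4, 4, rbind(c(1, 2), c(2, 1), c(3, 3), c(1, 1)))
  sthi$bc <- matrix(sthi$basis$basis, 4, 16)
  sthi$w_down$v <- diag(4); sthi$w_up$v <- diag(4)
  expect_gt(max(abs(msca_forward(xa, sthi) - msca_forward(xp, sthi))), 1e-4)
})

test_that("block_diag_apply equals dense assembly and its stated examples", {
  # one block is an ordinary dense product
  set.seed(22)
  W1 <- array(rnorm(9), c(1, 3, 3))
  v <- matrix(rnorm(6), 2, 3)
  expect_equal(block_diag_apply(v, W1), v %*% t(W1[1, , ]), tolerance = 1e-12)

  # hand example: blocks diag(1), diag(2) on ones
  Wb <- array(0, c(2, 2, 2)); Wb[1, , ] <- diag(2); Wb[2, , ] <- 2 * diag(2)
  expect_equal(block_diag_apply(c(1, 1, 1, 1), Wb), c(1, 1, 2, 2))

  # random complex case vs assembled dense matrix
  for (rep in 1:3) {
    Wc <- array(rnorm(2 * 4 * 4) + 1i * rnorm(32), c(2, 4, 4))
    vv <- matrix(rnorm(24) + 1i * rnorm(24), 3, 8)
    bb <- rnorm(8) + 1i * rnorm(8)
    dense <- matrix(0 + 0i, 8, 8)
    dense[1:4, 1:4] <- Wc[1, , ]
    dense[5:8, 5:8] <- Wc[2, , ]
    ref <- vv %*% t(dense) + matrix(bb, 3, 8, byrow = TRUE)
    expect_lt(max(Mod(block_diag_apply(vv, Wc, bb) - ref)), 1e-6)
  }

  expect_error(block_diag_apply(1:6, Wb), "does not match")
})

test_that("ffeo_forward honours its algebraic identities", {
  set.seed(23)
  x <- array(rnorm(2 * 8 * 6 * 6), c(2, 8, 6, 6))

  # zeroed MLPs: the spectrum contribution dies and the residual passes x
  st <- ffeo_state(8, 6, 6, N = 4)
  for (p in affnet:::ag_collect_params(st)) p$v[] <- 0
  expect_equal(ffeo_forward(x, st), x)

  # alpha = 0.5 collapses the enhancement: output invariant in lambda
  outs <- lapply(c(0, 0.1, 10), function(lam) {
    st2 <- ffeo_state(8, 6, 6, N = 4, alpha = 0.5, lambda = lam)
    set.seed(99)   # same weights for each lambda
    for (p in affnet:::ag_collect_params(st2)) {
      p$v <- array(rnorm(length(p$v), 0, 0.1), dim = dim(p$v) %||% length(p$v))
    }
    ffeo_forward(x, st2)
  })
  expect_equal(outs[[1]], outs[[2]], tolerance = 1e-10)
  expect_equal(outs[[1]], outs[[3]], tolerance = 1e-10)

  # alpha = 1 with a threshold above max |ztilde| shrinks everything to zero
  st3 <- ffeo_state(8, 6, 6, N = 4, alpha = 1, lambda = 1e7)
  set.seed(99)
  for (p in affnet:::ag_collect_params(st3)) {
    p$v <- array(rnorm(length(p$v), 0, 0.1), dim = dim(p$v) %||% length(p$v))
  }
  expect_equal(ffeo_forward(x, st3), x, tolerance = 1e-10)

  # shape preserved, output real, for several sizes
  for (hw in list(c(4L, 4L), c(6L, 8L))) {
    stn <- ffeo_state(8, hw[1], hw[2], N = 2)
    xn <- array(rnorm(8 * hw[1] * hw[2]), c(1, 8, hw[1], hw[2]))
    yn <- ffeo_forward(xn, stn)
    expect_identical(dim(yn), dim(xn))
    expect_true(is.numeric(yn))
  }

  expect_error(ffeo_forward(array(0, c(1, 6, 6, 6)), ffeo_state(8, 6, 6, N = 4)),
               "not divisible|spatial")
  expect_error(ffeo_state(8, 6, 6, N = 3), "divisible")
  expect_error(ffeo_state(8, 6, 6, alpha = 1.5), "alpha")
})

test_that("the enhancement step as printed equals 0.5 * z at alpha = 0.5", {
  set.seed(24)
  z <- matrix(rnorm(40) + 1i * rnorm(40), 5, 8)
  for (lam in c(0, 0.1, 10)) {
    s <- softshrink(z, lam)
    zp <- 0.5 * s + (1 - 0.5) * (z - s)
    expect_lt(max(Mod(zp - 0.5 * z)), 1e-12)
  }
})

test_that("every FFEO and MSCA parameter receives gradient", {
  set.seed(25)
  st <- ffeo_state(4, 4, 4, N = 2)
  ms <- msca_state(4, 4, 4, n = 4, r = 2)
  x <- array(rnorm(2 * 4 * 4 * 4), c(2, 4, 4, 4))
  tp <- affnet:::ag_tape_open()
  xt <- affnet:::ag_tensor(x)
  y <- ffeo_forward(xt, st)
  g <- affnet:::t_sigmoid(msca_forward(y, ms))
  loss <- affnet:::t_sum(affnet:::t_mul(affnet:::t_channel_gate(y, g),
                                        affnet:::t_channel_gate(y, g)))
  affnet:::ag_tape_close()
  affnet:::ag_backward(tp, loss)
  for (ps in list(affnet:::ag_collect_params(st), affnet:::ag_collect_params(ms))) {
    for (nm in names(ps)) {
      expect_false(is.null(ps[[nm]]$g), info = nm)
    }
  }
  # spot-check three parameters against finite differences
  lf <- function() {
    y <- ffeo_forward(affnet:::ag_tensor(x), st)
    g <- affnet:::t_sigmoid(msca_forward(y, ms))
    r <- affnet:::val(affnet:::t_channel_gate(y, g))
    sum(r * r)
  }
  ps <- c(affnet:::ag_collect_params(st), affnet:::ag_collect_params(ms))
  for (nm in c("lp.w1_re", "hp.w2_im", "w_down")) {
    p <- ps[[nm]]
    i <- 1L
    eps <- 1e-6
    orig <- p$v[i]
    p$v[i] <- orig + eps; fp <- lf()
    p$v[i] <- orig - eps; fm <- lf()
    p$v[i] <- orig
    expect_equal(p$g[i], (fp - fm) / (2 * eps), tolerance = 1e-4, info = nm)
  }
})
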