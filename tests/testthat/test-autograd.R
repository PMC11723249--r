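# Reverse-mode engine: every differentiable op is checked against central
# finite differences on random small inputs, and the FFT pair additionally
# against the adjoint (dot-product) identity.

gradcheck <- function(fwd, x, tol = 1e-6) {
  xt <- affnet:::ag_tensor(x)
  tp <- affnet:::ag_tape_open()
  loss <- fwd(xt)
  affnet:::ag_tape_close()
  affnet:::ag_backward(tp, loss)
  gn <- num_grad(function(v) affnet:::val(fwd(affnet:::ag_tensor(v)))[1], x)
  max(abs(xt$g - gn)) / max(1, max(abs(gn)))
}

test_that("elementwise, dense and normalisation ops match finite differences", {
  set.seed(10)
  t_ <- function(f) f   # readability
  x <- matrix(rnorm(20), 4, 5)
  w <- matrix(rnorm(15) * 0.5, 5, 3)
  b <- array(rnorm(3), 3)
  sq <- function(z) affnet:::t_sum(affnet:::t_mul(z, z))

  expect_lt(gradcheck(function(t) sq(affnet:::t_linear(t, w, b)), x), 1e-6)
  expect_lt(gradcheck(function(t) sq(affnet:::t_gelu(t)), x), 1e-6)
  expect_lt(gradcheck(function(t) sq(affnet:::t_sigmoid(t)), x), 1e-6)
  expect_lt(gradcheck(function(t) sq(affnet:::t_relu(t)), x + 0.05), 1e-5)
  expect_lt(gradcheck(function(t) sq(affnet:::t_softshrink(t, 0.3)), x), 1e-5)
  gam <- array(runif(5, 0.5, 1.5), 5); bet <- array(rnorm(5), 5)
  expect_lt(gradcheck(function(t) sq(affnet:::t_layernorm(t, gam, bet)), x), 1e-5)
  expect_lt(gradcheck(function(t) sq(affnet:::t_softmax_last(t)), x), 1e-6)
  expect_lt(gradcheck(function(t) affnet:::t_softmax_xent(t, c(1, 3, 2, 1)),
                      matrix(rnorm(12), 4, 3)), 1e-6)
})

test_that("convolutions (dense and depthwise) match finite differences", {
  set.seed(11)
  x <- array(rnorm(2 * 3 * 6 * 6), c(2, 3, 6, 6))
  w <- array(rnorm(4 * 3 * 3 * 3) * 0.3, c(4, 3, 3, 3))
  b <- array(rnorm(4), 4)
  sq <- function(z) affnet:::t_sum(affnet:::t_mul(z, z))
  expect_lt(gradcheck(function(t) {
    sq(affnet:::t_conv2d(t, w, b, stride = 2, padding = 1))
  }, x), 1e-5)

  # weight and bias gradients
  xt <- affnet:::ag_tensor(x); wt <- affnet:::ag_tensor(w); bt <- affnet:::ag_tensor(b)
  tp <- affnet:::ag_tape_open()
  loss <- sq(affnet:::t_conv2d(xt, wt, bt, stride = 2, padding = 1))
  affnet:::ag_tape_close(); affnet:::ag_backward(tp, loss)
  gw <- num_grad(function(v) {
    r <- affnet:::val(affnet:::t_conv2d(affnet:::ag_tensor(x), v, b,
                                        stride = 2, padding = 1))
    sum(r * r)
  }, w)
  expect_lt(max(abs(wt$g - gw)), 1e-5)

  wd <- array(rnorm(3 * 5 * 5) * 0.3, c(3, 5, 5))
  bd <- array(rnorm(3), 3)
  expect_lt(gradcheck(function(t) {
    sq(affnet:::t_conv2d(t, wd, bd, stride = 1, padding = 2, groups = 3))
  }, x), 1e-5)
})

test_that("structural ops (bmm, gather, roll, reductions) match finite differences", {
  set.seed(12)
  sq <- function(z) affnet:::t_sum(affnet:::t_mul(z, z))
  A <- array(rnorm(24), c(2, 3, 4)); B <- array(rnorm(24), c(2, 4, 3))
  expect_lt(gradcheck(function(t) sq(affnet:::t_bmm(t, B)), A), 1e-6)
  expect_lt(gradcheck(function(t) sq(affnet:::t_bmm(t, aperm(B, c(1, 3, 2)),
                                                    transB = TRUE)), A), 1e-6)
  x4 <- array(rnorm(2 * 3 * 4 * 6), c(2, 3, 4, 6))
  expect_lt(gradcheck(function(t) sq(affnet:::t_gap(t)), x4), 1e-6)
  expect_lt(gradcheck(function(t) sq(affnet:::t_sum_channels(t)), x4), 1e-6)
  m1 <- array(rnorm(2 * 4 * 6), c(2, 1, 4, 6))
  expect_lt(gradcheck(function(t) sq(affnet:::t_mul_spatial(t, m1)), x4), 1e-5)
  s <- matrix(rnorm(6), 2, 3)
  expect_lt(gradcheck(function(t) sq(affnet:::t_channel_gate(t, s)), x4), 1e-5)
  g <- array(rnorm(3), 3)
  expect_lt(gradcheck(function(t) sq(affnet:::t_channel_scale(t, g)), x4), 1e-5)
  xm <- matrix(rnorm(20), 4, 5)
  expect_lt(gradcheck(function(t) {
    sq(affnet:::t_gather_rows(t, c(1, 2, 2, 4, 1, 4)))
  }, xm), 1e-6)
  k <- x4 * 0 + 0.3
  expect_lt(gradcheck(function(t) affnet:::t_sum(affnet:::t_mul(
    affnet:::t_roll2(t, 1, 2), affnet:::ag_tensor(k))), x4), 1e-6)
})

test_that("real FFT ops satisfy the adjoint identity and finite differences", {
  set.seed(13)
  x <- array(rnorm(1 * 2 * 4 * 6), c(1, 2, 4, 6))
  # adjoint (dot-product) test for rfft2: <F x, y> = <x, F' y>
  y <- array(rnorm(1 * 2 * 4 * 4), c(1, 2, 4, 4)) +
    1i * array(rnorm(1 * 2 * 4 * 4), c(1, 2, 4, 4))
  xt <- affnet:::ag_tensor(x)
  tp <- affnet:::ag_tape_open()
  z <- affnet:::t_rfft2(xt)
  # scalar pairing Re(<z, conj(y)>) so that the cotangent of z equals y
  loss <- affnet:::t_sum(affnet:::ag_node(
    array(sum(Re(affnet:::val(z)) * Re(y) + Im(affnet:::val(z)) * Im(y)), 1L),
    list(z), function(g) list(y * as.vector(g))))
  affnet:::ag_tape_close(); affnet:::ag_backward(tp, loss)
  lhs <- sum(Re(affnet:::val(z)) * Re(y) + Im(affnet:::val(z)) * Im(y))
  rhs <- sum(x * xt$g)
  expect_equal(lhs, rhs, tolerance = 1e-8)

  # full chain through rfft2 -> softshrink -> irfft2 against finite differences
  sq <- function(z) affnet:::t_sum(affnet:::t_mul(z, z))
  err <- gradcheck(function(t) {
    z <- affnet:::t_rfft2(t)
    s <- affnet:::t_softshrink(z, 0.1)
    sq(affnet:::t_irfft2(s, 6))
  }, x)
  expect_lt(err, 1e-5)
})
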