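# The reverse-mode engine must agree with central finite differences on
# every differentiable operation it provides.

test_that("compiled conv / transpose-conv / pool kernels backpropagate exactly", {
  set.seed(101)
  x <- array(rnorm(5 * 4 * 2 * 2), c(5, 4, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b <- rnorm(3)
  sv <- array(rnorm(5 * 4 * 3 * 2), c(5, 4, 3, 2))
  xt <- ns$ag_param(x); wt <- ns$ag_param(w); bt <- ns$ag_param(b)
  y <- ns$op_conv2d(xt, wt, bt)
  l <- ns$new_tensor(sum(y$value * sv), list(y), function(g) list(g * sv))
  ns$ag_backward(l)
  expect_lt(max(abs(xt$grad - numeric_grad(function(z)
    sum(ns$cpp_conv2d_forward(array(z, dim(x)), w, b) * sv), x))), 1e-6)
  expect_lt(max(abs(wt$grad - numeric_grad(function(z)
    sum(ns$cpp_conv2d_forward(x, array(z, dim(w)), b) * sv), w))), 1e-6)
  expect_lt(max(abs(bt$grad - numeric_grad(function(z)
    sum(ns$cpp_conv2d_forward(x, w, z) * sv), b))), 1e-6)

  # 1x1 convolution takes a separate fast path
  w1 <- array(rnorm(1 * 1 * 2 * 3), c(1, 1, 2, 3))
  xt <- ns$ag_param(x); wt <- ns$ag_param(w1); bt <- ns$ag_param(b)
  y <- ns$op_conv2d(xt, wt, bt)
  l <- ns$new_tensor(sum(y$value * sv), list(y), function(g) list(g * sv))
  ns$ag_backward(l)
  expect_lt(max(abs(wt$grad - numeric_grad(function(z)
    sum(ns$cpp_conv2d_forward(x, array(z, dim(w1)), b) * sv), w1))), 1e-6)

  # transpose conv with odd output size (5 -> 11 exercises output padding)
  x2 <- array(rnorm(5 * 5 * 2), c(5, 5, 2, 1))
  w2 <- array(rnorm(2 * 2 * 2 * 3), c(2, 2, 2, 3))
  sv2 <- array(rnorm(11 * 11 * 3), c(11, 11, 3, 1))
  xt <- ns$ag_param(x2); wt <- ns$ag_param(w2); bt <- ns$ag_param(b)
  y <- ns$op_convt2x2(xt, wt, bt, 11, 11)
  l <- ns$new_tensor(sum(y$value * sv2), list(y), function(g) list(g * sv2))
  ns$ag_backward(l)
  expect_lt(max(abs(xt$grad - numeric_grad(function(z)
    sum(ns$cpp_convt2x2_forward(array(z, dim(x2)), w2, b, 11, 11) * sv2),
    x2))), 1e-6)
  expect_lt(max(abs(wt$grad - numeric_grad(function(z)
    sum(ns$cpp_convt2x2_forward(x2, array(z, dim(w2)), b, 11, 11) * sv2),
    w2))), 1e-6)

  # max pooling with floor halving (5x6 -> 2x3 drops the last row)
  x3 <- array(rnorm(5 * 6 * 2 * 2), c(5, 6, 2, 2))
  sv3 <- array(rnorm(2 * 3 * 2 * 2), c(2, 3, 2, 2))
  xt <- ns$ag_param(x3)
  y <- ns$op_maxpool2(xt)
  expect_identical(dim(y$value), c(2L, 3L, 2L, 2L))
  l <- ns$new_tensor(sum(y$value * sv3), list(y), function(g) list(g * sv3))
  ns$ag_backward(l)
  expect_lt(max(abs(xt$grad - numeric_grad(function(z)
    sum(ns$cpp_maxpool2_forward(array(z, dim(x3)))$y * sv3), x3))), 1e-6)
})

test_that("R-level ops (batch norm, pooling, resampling, loss) backpropagate", {
  set.seed(202)
  x <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  sv <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  check_op <- function(build, xv = x, weight = sv, tol = 1e-5) {
    xt <- ns$ag_param(xv)
    y <- build(xt)
    l <- ns$new_tensor(sum(y$value * weight), list(y),
                       function(g) list(g * weight))
    ns$ag_backward(l)
    ng <- numeric_grad(function(z) {
      yt <- build(ns$ag_const(array(z, dim(xv))))
      sum(yt$value * weight)
    }, xv)
    expect_lt(max(abs(xt$grad - ng)), tol)
  }
  bn <- ns$nn_batchnorm(3)
  check_op(function(t) ns$op_batchnorm(t, bn$gamma, bn$beta, bn, TRUE),
           tol = 1e-4)
  check_op(ns$op_sigmoid)
  check_op(function(t) ns$op_bilinear(t, 7, 9),
           weight = array(rnorm(7 * 9 * 3 * 2), c(7, 9, 3, 2)))
  check_op(ns$op_channel_meanmax,
           weight = array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2)))
  check_op(ns$op_global_avgpool, weight = matrix(rnorm(6), 2, 3))
  check_op(ns$op_global_maxpool, weight = matrix(rnorm(6), 2, 3))
  alpha <- ns$ag_const(matrix(runif(6), 2, 3))
  check_op(function(t) ns$op_scale_channel(t, alpha))
  s <- ns$ag_const(array(runif(4 * 4 * 2), c(4, 4, 1, 2)))
  check_op(function(t) ns$op_scale_spatial(t, s))

  # softmax cross-entropy against its analytic gradient
  logits <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  target <- array(sample(0:1, 32, replace = TRUE), c(4, 4, 2))
  lt <- ns$ag_param(logits)
  loss <- ns$op_softmax_ce(lt, target)
  ns$ag_backward(loss)
  ng <- numeric_grad(function(z)
    ns$op_softmax_ce(ns$ag_const(array(z, dim(logits))), target)$value,
    logits)
  expect_lt(max(abs(lt$grad - ng)), 1e-6)
})

test_that("gradients accumulate across shared consumers", {
  set.seed(7)
  x <- ns$ag_param(array(rnorm(8), c(2, 2, 2, 1)))
  y <- ns$op_add(x, x)                       # two parent slots, same tensor
  l <- ns$new_tensor(sum(y$value), list(y),
                     function(g) list(array(g, dim(y$value))))
  ns$ag_backward(l)
  expect_equal(x$grad, array(2, dim(x$value)))
})
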