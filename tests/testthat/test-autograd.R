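# Central-difference gradient checks for every kernel of the network engine.
# These are the correctness backbone of the hand-rolled autodiff: each op's
# analytic backward pass must match brute-force numeric differentiation.

asu <- asNamespace("asunet")

test_that("conv2d forward/backward match numeric gradients (all kernel/stride combos)", {
  set.seed(101)
  for (cfg in list(c(3, 1), c(3, 2), c(1, 1), c(2, 2))) {
    k <- cfg[1]; s <- cfg[2]
    x <- array(rnorm(6 * 8 * 3), c(6, 8, 3))
    w <- array(rnorm(k * k * 3 * 4) * 0.3, c(k, k, 3, 4))
    b <- rnorm(4)
    loss <- function(x_, w_, b_) sum(asu$op_conv2d(x_, w_, b_, s)^2)
    xn <- asu$ag_leaf(x, TRUE); wn <- asu$ag_leaf(w, TRUE)
    bn <- asu$ag_leaf(b, TRUE)
    asu$ag_backward(tape_sq_loss(asu$op_conv2d(xn, wn, bn, s)))
    expect_equal(xn$grad, num_grad(function(z) loss(z, w, b), x),
                 tolerance = 1e-6)
    expect_equal(wn$grad, num_grad(function(z) loss(x, z, b), w),
                 tolerance = 1e-6)
    expect_equal(bn$grad, num_grad(function(z) loss(x, w, z), b),
                 tolerance = 1e-6)
  }
})

test_that("transposed conv upsamples by its stride and matches numeric gradients", {
  set.seed(102)
  for (cfg in list(c(3, 2), c(1, 2), c(2, 2), c(3, 1))) {
    k <- cfg[1]; s <- cfg[2]
    x <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
    w <- array(rnorm(k * k * 2 * 3) * 0.3, c(k, k, 2, 3))
    b <- rnorm(2)
    y0 <- asu$op_tconv2d(x, w, b, s)
    expect_equal(dim(y0), c(4 * s, 5 * s, 2))
    loss <- function(x_, w_, b_) sum(asu$op_tconv2d(x_, w_, b_, s)^2)
    xn <- asu$ag_leaf(x, TRUE); wn <- asu$ag_leaf(w, TRUE)
    bn <- asu$ag_leaf(b, TRUE)
    asu$ag_backward(tape_sq_loss(asu$op_tconv2d(xn, wn, bn, s)))
    expect_equal(xn$grad, num_grad(function(z) loss(z, w, b), x),
                 tolerance = 1e-6)
    expect_equal(wn$grad, num_grad(function(z) loss(x, z, b), w),
                 tolerance = 1e-6)
    expect_equal(bn$grad, num_grad(function(z) loss(x, w, z), b),
                 tolerance = 1e-6)
  }
})

test_that("max pooling, nn upsampling, softmax and attention product backprop correctly", {
  set.seed(103)
  x <- array(rnorm(6 * 4 * 2), c(6, 4, 2))

  xn <- asu$ag_leaf(x, TRUE)
  asu$ag_backward(tape_sq_loss(asu$op_maxpool2(xn)))
  expect_equal(xn$grad, num_grad(function(z) sum(asu$op_maxpool2(z)^2), x),
               tolerance = 1e-6)

  xn <- asu$ag_leaf(x, TRUE)
  asu$ag_backward(tape_sq_loss(asu$op_nnup2(xn)))
  expect_equal(xn$grad, num_grad(function(z) sum(asu$op_nnup2(z)^2), x),
               tolerance = 1e-6)

  xn <- asu$ag_leaf(x, TRUE)
  asu$ag_backward(tape_sq_loss(asu$op_softmax_ch(xn)))
  expect_equal(xn$grad, num_grad(function(z) sum(asu$op_softmax_ch(z)^2), x),
               tolerance = 1e-6)

  a <- array(runif(6 * 4), c(6, 4, 1))
  xn <- asu$ag_leaf(x, TRUE); an <- asu$ag_leaf(a, TRUE)
  asu$ag_backward(tape_sq_loss(asu$op_scale_by_map(xn, an)))
  expect_equal(xn$grad,
               num_grad(function(z) sum(asu$op_scale_by_map(z, a)^2), x),
               tolerance = 1e-6)
  expect_equal(an$grad,
               num_grad(function(z) sum(asu$op_scale_by_map(x, z)^2), a),
               tolerance = 1e-6)

  y <- array(rnorm(6 * 4 * 3), c(6, 4, 3))
  xn <- asu$ag_leaf(x, TRUE); yn <- asu$ag_leaf(y, TRUE)
  asu$ag_backward(tape_sq_loss(asu$op_concat(xn, yn)))
  expect_equal(xn$grad, num_grad(function(z) sum(asu$op_concat(z, y)^2), x),
               tolerance = 1e-6)
  expect_equal(yn$grad, num_grad(function(z) sum(asu$op_concat(x, z)^2), y),
               tolerance = 1e-6)
})

test_that("pooling rejects odd spatial sizes", {
  expect_error(asu$op_maxpool2(array(0, c(5, 4, 1))), "even")
})

test_that("whole-network gradients match numeric differentiation on sampled weights", {
  set.seed(104)
  net <- build_network(network_spec("attention_squeeze_unet", c(32, 32),
                                    seed = 9))
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  gt <- matrix(0, 32, 32); gt[8:20, 10:25] <- 1
  tp <- tversky_params()

  loss_at <- function(params) {
    p <- asu$net_forward(net, x, params = params)
    asu$op_ftl(asu$op_channel(p, 2L), gt, tp$alpha, tp$beta, tp$gamma,
               tp$epsilon)
  }
  wrapped <- asu$wrap_params(net$params)
  l <- loss_at(wrapped)
  asu$ag_backward(l)
  nodes <- asu$param_nodes(wrapped)

  # probe a handful of scalar weights spread across the architecture
  picks <- c("p.stem.w", "p.enc2a.expand3.w", "p.up1.attn.psi.w",
             "p.up3.deconv.w", "p.head2.w", "p.out.b")
  for (nm in picks) {
    node <- nodes[[nm]]
    i <- sample(length(node$value), 1)
    eps <- 1e-4
    f <- function(delta) {
      pert <- asu$wrap_params(net$params)
      nd <- asu$param_nodes(pert)[[nm]]
      nd$value[i] <- nd$value[i] + delta
      as.numeric(asu$ag_value(loss_at(pert)))
    }
    ng <- (f(eps) - f(-eps)) / (2 * eps)
    expect_lt(abs(node$grad[i] - ng), 1e-6 + 1e-3 * abs(ng))
  }
})
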