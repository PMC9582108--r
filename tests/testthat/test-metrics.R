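test_that("confusion counts enumerate the four pixel outcomes", {
  cc <- confusion_counts(matrix(1, 2, 2), matrix(1, 2, 2))
  expect_equal(unclass(cc), list(tp = 4, fp = 0, tn = 0, fn = 0))

  cc <- confusion_counts(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_equal(cc$tn, 4)
  expect_equal(cc$tp + cc$fp + cc$fn, 0)

  pred <- matrix(c(1, 0, 1, 0), 2, byrow = FALSE)
  gt <- matrix(c(1, 1, 0, 0), 2, byrow = FALSE)
  cc <- confusion_counts(pred, gt)
  expect_equal(unclass(cc), list(tp = 1, fp = 1, tn = 1, fn = 1))

  expect_error(confusion_counts(matrix(1, 2, 2), matrix(1, 2, 3)), "2x3")
  expect_error(confusion_counts(matrix(0.5, 2, 2), matrix(1, 2, 2)),
               "not binary")
})

test_that("accuracy, dice, jaccard and tversky follow their formulas", {
  c1 <- counts(tp = 1, fp = 1, tn = 1, fn = 1)
  expect_equal(pixel_accuracy(c1), 0.5)
  expect_equal(pixel_accuracy(counts(tp = 3, tn = 5)), 1)
  expect_equal(pixel_accuracy(counts(fp = 2, fn = 2)), 0)
  expect_error(pixel_accuracy(counts()), "undefined")

  c2 <- counts(tp = 2, fp = 1, fn = 1)
  expect_equal(dice(c2), 2 / 3)
  expect_equal(jaccard(c2), 0.5)
  expect_equal(dice(counts(tp = 7)), 1)
  expect_equal(jaccard(counts(tp = 7)), 1)
  expect_equal(dice(counts(fp = 3, fn = 2)), 0)
  expect_equal(jaccard(counts(fp = 3, fn = 2)), 0)

  expect_equal(tversky(c2, 0.5, 0.5), dice(c2))
  expect_equal(tversky(c2, 1, 1), jaccard(c2))
  expect_equal(tversky(counts(tp = 3, fn = 2, fp = 1), 0.7, 0.3), 3 / 4.7)
  expect_error(tversky(c2, -0.1, 0.5), "nonnegative")
})

test_that("degenerate empty-vs-empty masks score 1 by convention, configurably", {
  e <- counts()
  expect_equal(dice(e), 1)
  expect_equal(jaccard(e), 1)
  expect_equal(tversky(e, 0.7, 0.3), 1)
  expect_equal(dice(e, empty_value = 0), 0)
  expect_equal(jaccard(e, empty_value = NA_real_), NA_real_)
})

test_that("threshold jaccard zeroes below the cutoff, keeps the boundary", {
  expect_equal(threshold_jaccard(0.5), 0)
  expect_equal(threshold_jaccard(0.7), 0.7)
  expect_equal(threshold_jaccard(0.65), 0.65)
  expect_equal(threshold_jaccard(0.6499999), 0)
  expect_equal(threshold_jaccard(c(0, 0.64, 0.65, 1)), c(0, 0, 0.65, 1))
  expect_equal(threshold_jaccard(0.5, threshold = 0.4), 0.5)
  expect_error(threshold_jaccard(1.2), "\\[0, 1\\]")
  expect_error(threshold_jaccard(-0.1), "\\[0, 1\\]")
})

test_that("metrics agree with brute-force per-pixel enumeration", {
  set.seed(421)
  for (r in 1:40) {
    pred <- rand_mask(8, 8); gt <- rand_mask(8, 8)
    b <- brute_counts(pred, gt)
    cc <- confusion_counts(pred, gt)
    expect_equal(cc$tp, b$tp)
    expect_equal(dice(cc), brute_dice(b))
    expect_equal(jaccard(cc), brute_jaccard(b))
    expect_equal(pixel_accuracy(cc), brute_accuracy(b))
    expect_equal(tversky(cc, 0.7, 0.3), brute_tversky(b, 0.7, 0.3))
    # algebraic identity Dice = 2J / (1 + J)
    j <- jaccard(cc)
    expect_equal(dice(cc), 2 * j / (1 + j))
    # simultaneous spatial permutation leaves every metric unchanged
    p <- sample(64)
    pp <- matrix(pred[p], 8); gp <- matrix(gt[p], 8)
    expect_equal(unclass(confusion_counts(pp, gp)), unclass(cc))
  }
})

test_that("tversky params validate their domain", {
  expect_s3_class(tversky_params(), "tversky_params")
  expect_error(tversky_params(alpha = -1), "nonnegative")
  expect_error(tversky_params(gamma = 0), "positive")
  expect_error(tversky_params(epsilon = 0), "positive")
})

test_that("focal tversky loss matches (1 - TI)^gamma on constructed cases", {
  # perfect hard prediction: TI = 1 up to epsilon, loss ~ 0
  g <- matrix(c(1, 0, 0, 1), 2)
  expect_lt(focal_tversky_loss(g, g, tversky_params(gamma = 2)), 1e-5)

  # single pixel, p = 0.6 against g = 1 with alpha = beta = 1 gives soft
  # TI = 0.6; gamma = 1 -> loss 0.4
  tp1 <- tversky_params(alpha = 1, beta = 1, gamma = 1)
  expect_equal(focal_tversky_loss(matrix(0.6), matrix(1), tp1), 0.4,
               tolerance = 1e-5)
  # p = 0.75: TI = 0.75; gamma = 2 -> loss 0.0625
  tp2 <- tversky_params(alpha = 1, beta = 1, gamma = 2)
  expect_equal(focal_tversky_loss(matrix(0.75), matrix(1), tp2), 0.0625,
               tolerance = 1e-4)

  expect_error(focal_tversky_loss(matrix(1.2), matrix(1), tp1), "\\[0, 1\\]")
})

test_that("loss is monotone decreasing in the soft tversky index", {
  tp <- tversky_params()
  g <- matrix(1, 4, 4)
  ps <- seq(0.05, 0.95, by = 0.1)
  losses <- vapply(ps, function(p)
    focal_tversky_loss(matrix(p, 4, 4), g, tp), numeric(1))
  tis <- vapply(ps, function(p)
    soft_tversky_index(matrix(p, 4, 4), g, tp), numeric(1))
  expect_true(all(diff(tis) > 0))
  expect_true(all(diff(losses) < 0))
})

test_that("loss gradient on a foreground pixel is negative and matches numeric", {
  set.seed(99)
  g <- rand_mask(5, 5); g[2, 3] <- 1
  p0 <- matrix(runif(25, 0.2, 0.8), 5)
  tp <- tversky_params()
  pn <- asunet:::ag_leaf(p0, requires_grad = TRUE)
  l <- asunet:::op_ftl(pn, g, tp$alpha, tp$beta, tp$gamma, tp$epsilon)
  asunet:::ag_backward(l)
  ng <- num_grad(function(p) focal_tversky_loss(p, g, tp), p0)
  expect_equal(pn$grad, ng, tolerance = 1e-6)
  expect_true(all(pn$grad[g == 1] < 0))
})
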