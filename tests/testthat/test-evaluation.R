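named_masks <- function(ms) stats::setNames(ms, sprintf("im%02d", seq_along(ms)))

test_that("perfect predictions score 1 everywhere with an empty failure list", {
  set.seed(51)
  gt <- named_masks(lapply(1:5, function(i) rand_mask(10, 12)))
  rep <- evaluate_dataset(gt, gt)
  expect_equal(unname(rep$overall["dice"]), 1)
  expect_equal(unname(rep$overall["jsi"]), 1)
  expect_equal(unname(rep$overall["accuracy"]), 1)
  expect_length(rep$failures, 0)
})

test_that("all-background predictions against nonempty truth score 0", {
  set.seed(52)
  gt <- named_masks(lapply(1:4, function(i) {
    m <- matrix(0, 8, 8); m[3:5, 2:6] <- 1; m
  }))
  pred <- named_masks(lapply(1:4, function(i) matrix(0, 8, 8)))
  rep <- evaluate_dataset(pred, gt)
  expect_true(all(rep$per_image$dice == 0))
  expect_true(all(rep$per_image$jsi == 0))
  expect_true(all(rep$per_image$threshold_jaccard == 0))
  expect_equal(rep$failures, rep$per_image$id)
})

test_that("report means equal the brute-force per-pixel oracle and are order-invariant", {
  set.seed(53)
  gt <- named_masks(lapply(1:10, function(i) rand_mask(8, 8)))
  pred <- named_masks(lapply(1:10, function(i) rand_mask(8, 8)))
  rep <- evaluate_dataset(pred, gt)
  bs <- mapply(function(p, g) {
    b <- brute_counts(p, g)
    c(dice = brute_dice(b), jsi = brute_jaccard(b),
      acc = brute_accuracy(b))
  }, pred, gt)
  expect_equal(unname(rep$overall["dice"]), mean(bs["dice", ]))
  expect_equal(unname(rep$overall["jsi"]), mean(bs["jsi", ]))
  expect_equal(unname(rep$overall["accuracy"]), mean(bs["acc", ]))
  expect_equal(rep$failures,
               rep$per_image$id[rep$per_image$jsi < 0.65])

  perm <- sample(10)
  rep2 <- evaluate_dataset(pred[perm], gt[perm])
  expect_equal(rep2$overall, rep$overall)
  expect_setequal(rep2$failures, rep$failures)

  bad <- pred; names(bad)[1] <- "other"
  expect_error(evaluate_dataset(bad, gt), "ids differ")
})

test_that("per-class tables separate classes exactly and drop absent classes", {
  # class A images: perfect predictions; class B: half-overlap predictions
  gt <- list(); pred <- list(); labels <- character()
  for (i in 1:3) {
    m <- matrix(0, 8, 8); m[1:4, ] <- 1
    gt[[paste0("a", i)]] <- m; pred[[paste0("a", i)]] <- m
    labels[paste0("a", i)] <- "NV"
  }
  for (i in 1:2) {
    m <- matrix(0, 8, 8); m[1:4, ] <- 1
    p <- matrix(0, 8, 8); p[1:2, ] <- 1
    gt[[paste0("b", i)]] <- m; pred[[paste0("b", i)]] <- p
    labels[paste0("b", i)] <- "MEL"
  }
  rep <- evaluate_dataset(pred, gt, labels = labels)
  pc <- rep$per_class
  expect_equal(sort(pc$class), c("MEL", "NV"))
  expect_equal(sum(pc$n), 5)
  expect_equal(pc$dice[pc$class == "NV"], 1)
  expect_equal(pc$dice[pc$class == "MEL"], 2 / 3)  # 2*16/(2*16+0+16)
  expect_equal(pc$jsi[pc$class == "MEL"], 0.5)
  expect_equal(pc$threshold_jaccard[pc$class == "MEL"], 0)

  # single-class dataset: per-class row equals the overall row
  rep_nv <- evaluate_dataset(pred[1:3], gt[1:3], labels = labels[1:3])
  expect_equal(unname(unlist(rep_nv$per_class[c("dice", "jsi")])),
               unname(rep_nv$overall[c("dice", "jsi")]))

  expect_error(per_class_report(rep, labels[1:3]), "unlabelled")
})

test_that("comparison overlays color the confusion classes exactly", {
  pred <- matrix(c(1, 0, 1, 0), 2, byrow = FALSE)
  gt <- matrix(c(1, 1, 0, 0), 2, byrow = FALSE)
  img <- comparison_image(pred, gt)
  # pixel (1,1): TP -> green; (2,1): FN -> blue; (1,2): FP -> red; (2,2): TN
  expect_equal(img[1, 1, ], c(0, 1, 0))
  expect_equal(img[2, 1, ], c(0, 0, 1))
  expect_equal(img[1, 2, ], c(1, 0, 0))
  expect_equal(img[2, 2, ], c(0, 0, 0))

  expect_equal(comparison_image(matrix(1, 2, 2), matrix(1, 2, 2))[, , 2],
               matrix(1, 2, 2))
  expect_error(comparison_image(matrix(1, 2, 2), matrix(1, 3, 2)), "differ")

  # color histogram <-> confusion counts bijection on random pairs
  set.seed(54)
  for (r in 1:10) {
    p <- rand_mask(9, 7); g <- rand_mask(9, 7)
    cc <- confusion_counts(p, g)
    ov <- comparison_image(p, g)
    expect_equal(sum(ov[, , 2]), cc$tp)
    expect_equal(sum(ov[, , 1]), cc$fp)
    expect_equal(sum(ov[, , 3]), cc$fn)
    expect_equal(sum(rowSums(matrix(ov, ncol = 3)) == 0), cc$tn)
  }
})

test_that("reports export to CSV with aggregate rows", {
  set.seed(55)
  gt <- named_masks(lapply(1:3, function(i) rand_mask(6, 6)))
  rep <- evaluate_dataset(gt, gt)
  f <- file.path(withr::local_tempdir(), "report.csv")
  write_report(rep, f)
  df <- read.csv(f)
  expect_equal(nrow(df), 4)
  expect_true("__overall__" %in% df$id)
  expect_equal(df$dice[df$id == "__overall__"], 1)
})
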