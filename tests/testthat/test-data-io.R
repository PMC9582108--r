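make_png_mask <- function(m, path) {
  png::writePNG(m, path)
  path
}

test_that("masks binarize at the 127/255 threshold and flag constant masks", {
  tmp <- withr::local_tempdir()
  m <- matrix(c(0, 40 / 255, 128 / 255, 1), 2)
  p <- make_png_mask(m, file.path(tmp, "m.png"))
  got <- load_mask(p)
  expect_equal(got, matrix(c(0, 0, 1, 1), 2), ignore_attr = TRUE)
  expect_false(attr(got, "constant"))

  p2 <- make_png_mask(matrix(1, 4, 4), file.path(tmp, "ones.png"))
  expect_true(attr(load_mask(p2), "constant"))
  expect_error(load_mask(file.path(tmp, "nope.png")), "not found")
})

test_that("images load as HxWx3 in [0,1]; grayscale is replicated to 3 channels", {
  tmp <- withr::local_tempdir()
  a <- array(runif(12 * 16 * 3), c(12, 16, 3))
  png::writePNG(a, file.path(tmp, "ISIC_0000001.png"))
  s <- load_image(file.path(tmp, "ISIC_0000001.png"))
  expect_s3_class(s, "image_sample")
  expect_equal(s$id, "ISIC_0000001")
  expect_equal(dim(s$image), c(12, 16, 3))
  expect_lt(max(abs(s$image - a)), 1 / 255)

  g <- matrix(runif(12 * 16), 12, 16)
  EBImage::writeImage(EBImage::Image(t(g)), file.path(tmp, "gray.jpg"),
                      quality = 100)
  sg <- load_image(file.path(tmp, "gray.jpg"))
  expect_equal(dim(sg$image), c(12, 16, 3))
  expect_equal(sg$image[, , 1], sg$image[, , 2])
  expect_equal(sg$image[, , 1], sg$image[, , 3])

  expect_error(load_image(file.path(tmp, "missing.jpg")), "not found")
})

test_that("resize_normalize hits the 384x512 target and is idempotent", {
  set.seed(31)
  # PH2-sized input: 574 rows x 768 columns
  a <- array(runif(574 * 768 * 3), c(574, 768, 3))
  r <- resize_normalize(a, target = c(384, 512))
  expect_equal(dim(r), c(384, 512, 3))
  expect_true(all(r >= 0 & r <= 1))
  expect_identical(resize_normalize(r, c(384, 512)), r)

  s <- as_sample(array(runif(64 * 64 * 3), c(64, 64, 3)),
                 mask = rand_mask(64, 64))
  s2 <- resize_normalize(s, c(32, 48))
  expect_equal(dim(s2$image), c(32, 48, 3))
  expect_equal(dim(s2$mask), c(32, 48))
  expect_true(all(s2$mask %in% c(0, 1)))  # nearest neighbour keeps binarity
  expect_equal(s2$original_size, c(64, 64))
})

test_that("flip augmentation quadruples samples, is involutive, conserves area", {
  set.seed(32)
  samples <- lapply(1:3, function(i) {
    m <- matrix(0L, 8, 10); m[1, 3:6] <- 1L  # lesion touching the top edge
    as_sample(array(runif(8 * 10 * 3), c(8, 10, 3)), mask = m,
              id = paste0("s", i), class = "MEL")
  })
  aug <- augment_flips(samples)
  expect_length(aug, 12)
  expect_equal(vapply(aug[1:4], function(s) s$provenance, character(1)),
               c("original", "vflip", "hflip", "vhflip"))
  expect_true(all(vapply(aug, function(s) identical(s$class, "MEL"),
                         logical(1))))

  v <- aug[[2]]  # vertical flip
  expect_equal(sum(v$mask), sum(samples[[1]]$mask))
  expect_equal(v$mask[8, ], samples[[1]]$mask[1, ])  # top edge -> bottom edge
  # applying the flip twice recovers the original bit-exactly
  expect_identical(asunet:::flip_array(v$image, TRUE, FALSE),
                   samples[[1]]$image)

  # flips preserve confusion counts against a jointly flipped prediction
  pred <- rand_mask(8, 10)
  cc0 <- confusion_counts(pred, samples[[1]]$mask)
  ccf <- confusion_counts(asunet:::flip_array(pred, TRUE, TRUE),
                          asunet:::flip_array(samples[[1]]$mask, TRUE, TRUE))
  expect_equal(unclass(ccf), unclass(cc0))
})

test_that("one-hot target encoding sums to one and round-trips", {
  m <- rand_mask(6, 7)
  oh <- encode_targets(m)
  expect_equal(dim(oh), c(6, 7, 2))
  expect_equal(oh[, , 1] + oh[, , 2], matrix(1, 6, 7))
  expect_equal(decode_targets(oh), m)
  expect_equal(encode_targets(matrix(1, 3, 3))[, , 2], matrix(1, 3, 3))
})

test_that("class label CSV parsing validates classes and duplicates", {
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "labels.csv")
  writeLines(c("image_id,class", "ISIC_0000000,MEL", "ISIC_0000001,NV"), f)
  lab <- read_class_labels(f)
  expect_equal(lab[["ISIC_0000000"]], "MEL")
  expect_length(lab, 2)

  writeLines(c("image_id,class", "a,XYZ"), f)
  expect_error(read_class_labels(f), "valid classes")
  writeLines(c("image_id,class", "a,MEL", "a,NV"), f)
  expect_error(read_class_labels(f), "duplicate")

  ids <- sprintf("ISIC_%07d", 1:600)
  writeLines(c("image_id,class",
               paste0(ids, ",", sample(asunet:::LESION_CLASSES, 600, TRUE))),
             f)
  expect_length(read_class_labels(f), 600)
})

test_that("datasets load as paired image/mask samples by id", {
  tmp <- withr::local_tempdir()
  dir.create(file.path(tmp, "images")); dir.create(file.path(tmp, "masks"))
  for (i in 1:3) {
    id <- sprintf("IMG_%03d", i)
    png::writePNG(array(runif(8 * 8 * 3), c(8, 8, 3)),
                  file.path(tmp, "images", paste0(id, ".png")))
    png::writePNG(rand_mask(8, 8) + 0,
                  file.path(tmp, "masks", paste0(id, "_segmentation.png")))
  }
  ds <- load_dataset(file.path(tmp, "images"), file.path(tmp, "masks"))
  expect_length(ds, 3)
  expect_equal(ds[[1]]$id, "IMG_001")
  expect_true(all(vapply(ds, function(s) !is.null(s$mask), logical(1))))

  # round trip of a written prediction mask
  m <- rand_mask(8, 8)
  write_mask(m, file.path(tmp, "pred.png"))
  expect_equal(unname(load_mask(file.path(tmp, "pred.png"))), m,
               ignore_attr = TRUE)
})
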