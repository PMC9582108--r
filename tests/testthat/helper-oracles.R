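# Independent oracles used across tests: per-pixel brute-force metric
# enumeration, central-difference numeric gradients, and small fixture
# builders. These deliberately avoid the package's own vectorized paths.

brute_counts <- function(pred, gt) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j]; g <- gt[i, j]
      if (p == 1 && g == 1) tp <- tp + 1L
      else if (p == 1 && g == 0) fp <- fp + 1L
      else if (p == 0 && g == 1) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

brute_dice <- function(b) if (2 * b$tp + b$fp + b$fn == 0) 1 else
  2 * b$tp / (2 * b$tp + b$fp + b$fn)
brute_jaccard <- function(b) if (b$tp + b$fp + b$fn == 0) 1 else
  b$tp / (b$tp + b$fp + b$fn)
brute_accuracy <- function(b) (b$tp + b$tn) / (b$tp + b$fp + b$tn + b$fn)
brute_tversky <- function(b, a, be) if (b$tp + a * b$fn + be * b$fp == 0) 1 else
  b$tp / (b$tp + a * b$fn + be * b$fp)

rand_mask <- function(h, w) matrix(rbinom(h * w, 1, 0.5), h, w)

num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

counts <- function(tp = 0, fp = 0, tn = 0, fn = 0) {
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_counts")
}

as_sample <- function(image, mask = NULL, id = "x", class = NA_character_) {
  structure(list(id = id, image = image, mask = mask, class = class,
                 provenance = "original", original_size = dim(image)[1:2]),
            class = "image_sample")
}

# scalar sum-of-squares loss through the tape, for kernel gradient checks
tape_sq_loss <- function(y) {
  asunet:::ag_op(array(sum(asunet:::ag_value(y)^2), c(1, 1)), list(y),
                 function(g) list(2 * asunet:::ag_value(y) * as.numeric(g)))
}
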