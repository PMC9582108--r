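# Seeded generator of dermoscopy-like image/mask pairs: a textured skin
# background, an elliptical lesion whose boundary is perturbed by low-order
# radial harmonics, and the four classic dermoscopy artifact types (hairs,
# air/oil bubbles, pen marks, specular reflections). The mask is exactly the
# rasterized lesion support; image shading is smoothed at the boundary but the
# label is not. Every sample is fully determined by (seed, index).

#' Synthetic dermoscopy configuration
#'
#' @param n_samples number of image/mask pairs.
#' @param image_size integer `c(height, width)`; default 96 x 128 (the 3:4
#'   aspect of the 384 x 512 network input at 1/4 scale, divisible by 32).
#' @param seed integer; fixes the whole sample stream.
#' @param area_range lesion area as a fraction of the image, `c(lo, hi)` within
#'   (0, 1).
#' @param irregularity_range boundary perturbation amplitude range (relative
#'   radial harmonics; 0 = smooth ellipse).
#' @param contrast_range lesion-vs-skin intensity difference range.
#' @param artifacts named logical list toggling `hair`, `bubbles`, `pen_marks`,
#'   `reflections`.
#' @param artifact_density mean artifact count per image (Poisson).
#' @param edge_softness shading transition width at the lesion border, pixels.
#' @param class_labels `NULL` for unlabelled samples, `"random"` to draw one of
#'   the seven lesion classes per sample, or a single class name. Class presets
#'   override area/irregularity/contrast with class-typical morphology (e.g.
#'   nevi are near-symmetric, melanomas highly irregular).
#' @return A `"synth_config"` object.
#' @export
synth_config <- function(n_samples = 100L, image_size = c(96L, 128L),
                         seed = 1L, area_range = c(0.05, 0.25),
                         irregularity_range = c(0.05, 0.25),
                         contrast_range = c(0.25, 0.55),
                         artifacts = list(hair = TRUE, bubbles = TRUE,
                                          pen_marks = TRUE,
                                          reflections = TRUE),
                         artifact_density = 2,
                         edge_softness = 1.0,
                         class_labels = NULL) {
  stopifnot(n_samples >= 1, length(image_size) == 2L, all(image_size >= 16),
            length(area_range) == 2L, area_range[1] > 0, area_range[2] < 1,
            area_range[1] <= area_range[2],
            irregularity_range[1] >= 0, contrast_range[1] > 0)
  if (!is.null(class_labels) && class_labels != "random")
    class_labels <- match.arg(class_labels, LESION_CLASSES)
  structure(list(n_samples = as.integer(n_samples),
                 image_size = as.integer(image_size), seed = as.integer(seed),
                 area_range = area_range,
                 irregularity_range = irregularity_range,
                 contrast_range = contrast_range,
                 artifacts = utils::modifyList(
                   list(hair = TRUE, bubbles = TRUE, pen_marks = TRUE,
                        reflections = TRUE), as.list(artifacts)),
                 artifact_density = artifact_density,
                 edge_softness = edge_softness,
                 class_labels = class_labels),
            class = "synth_config")
}

# Class-typical morphology presets (area fraction, boundary irregularity,
# contrast). NV near-symmetric, MEL chaotic, DF small and well demarcated,
# AKIEC low contrast; VASC gets a red hue in the renderer.
class_presets <- list(
  AKIEC = list(area = c(0.06, 0.18), irr = c(0.15, 0.30), con = c(0.10, 0.22)),
  BCC   = list(area = c(0.05, 0.15), irr = c(0.10, 0.20), con = c(0.20, 0.40)),
  BKL   = list(area = c(0.08, 0.22), irr = c(0.15, 0.25), con = c(0.28, 0.48)),
  DF    = list(area = c(0.03, 0.08), irr = c(0.04, 0.12), con = c(0.35, 0.55)),
  MEL   = list(area = c(0.10, 0.30), irr = c(0.30, 0.45), con = c(0.30, 0.60)),
  NV    = list(area = c(0.08, 0.20), irr = c(0.02, 0.10), con = c(0.30, 0.50)),
  VASC  = list(area = c(0.04, 0.12), irr = c(0.08, 0.18), con = c(0.30, 0.50))
)

sample_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %%
               2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

#' Generate one synthetic sample
#'
#' @param config a [synth_config()].
#' @param index sample index (1-based); `(seed, index)` fully determines the
#'   output.
#' @return List with `sample` (an `"image_sample"` carrying the image, the
#'   ground-truth `mask`, the class label and the realized `irregularity`
#'   statistic) and `seed` (the derived per-sample seed).
#' @export
generate_sample <- function(config, index) {
  stopifnot(inherits(config, "synth_config"))
  seed_i <- sample_seed(config$seed, index)
  with_seed(seed_i, {
    H <- config$image_size[1]; W <- config$image_size[2]

    cls <- NA_character_
    area_r <- config$area_range; irr_r <- config$irregularity_range
    con_r <- config$contrast_range
    if (!is.null(config$class_labels)) {
      cls <- if (identical(config$class_labels, "random"))
        sample(LESION_CLASSES, 1) else config$class_labels
      pre <- class_presets[[cls]]
      area_r <- pre$area; irr_r <- pre$irr; con_r <- pre$con
    }

    # lesion geometry ------------------------------------------------------
    # draw shapes until one fits inside the frame at the target area; the
    # redraws stay inside the seeded stream, so determinism is preserved
    contrast <- runif1(con_r)
    inset <- 0.08 * diff(area_r)
    phig <- seq(0, 2 * pi, length.out = 721L)[-721L]
    ok <- FALSE
    for (try in 1:25) {
      frac <- stats::runif(1, area_r[1] + inset, area_r[2] - inset)
      amp <- runif1(irr_r)
      theta <- stats::runif(1, 0, pi)
      ecc <- stats::runif(1, 0.6, 1)
      cy <- H * stats::runif(1, 0.42, 0.58)
      cx <- W * stats::runif(1, 0.42, 0.58)
      nh <- 2:5
      ah <- amp * stats::runif(4, 0.5, 1) / sqrt(nh - 1)
      ph <- stats::runif(4, 0, 2 * pi)
      shape_fn <- function(phi) {
        s <- rep(1, length(phi))
        for (i in 1:4) s <- s + ah[i] * cos(nh[i] * phi + ph[i])
        pmax(s, 0.15)
      }
      ell_fn <- function(phi) ecc / sqrt(ecc^2 * cos(phi)^2 + sin(phi)^2)
      prof <- shape_fn(phig) * ell_fn(phig)
      # polar area A = R^2/2 * integral(prof^2); solve R for the target area
      R <- sqrt(2 * frac * H * W / (sum(prof^2) * (2 * pi / 720)))
      maxr <- R * max(prof)
      fit <- min(cy, H - 1 - cy, cx, W - 1 - cx) - 1
      if (maxr <= fit) { ok <- TRUE; break }
    }
    if (!ok)
      stop("infeasible area fraction range [", area_r[1], ", ", area_r[2],
           "] for image size ", H, "x", W)

    rows <- matrix(seq_len(H) - 1 - cy, H, W)
    cols <- matrix(seq_len(W) - 1 - cx, H, W, byrow = TRUE)
    u <- cols * cos(theta) + rows * sin(theta)
    v <- -cols * sin(theta) + rows * cos(theta)
    rho <- sqrt(u^2 + v^2)
    psi <- atan2(v, u)
    rb <- R * shape_fn(psi) * ell_fn(psi)   # boundary radius per pixel angle
    mask <- (rho <= rb) * 1L
    storage.mode(mask) <- "integer"

    # rendering ------------------------------------------------------------
    base <- c(stats::runif(1, 0.74, 0.86), stats::runif(1, 0.55, 0.66),
              stats::runif(1, 0.47, 0.58))
    img <- array(0, c(H, W, 3))
    rn <- matrix(seq_len(H), H, W) / H
    cn <- matrix(seq_len(W), H, W, byrow = TRUE) / W
    tex <- matrix(0, H, W)
    for (k in 1:3) {
      f <- stats::runif(2, 0.5, 3); phs <- stats::runif(1, 0, 2 * pi)
      tex <- tex + sin(2 * pi * (f[1] * rn + f[2] * cn) + phs)
    }
    tex <- 0.02 * tex / 3
    lesion_col <- if (identical(cls, "VASC")) c(0.55, 1.35, 1.25)
                  else c(0.85, 1.15, 1.25)
    edge <- 1 / (1 + exp(-(rb - rho) / max(config$edge_softness, 1e-3)))
    for (k in 1:3)
      img[, , k] <- base[k] + tex - contrast * lesion_col[k] * edge

    # artifacts ------------------------------------------------------------
    a <- config$artifacts
    dens <- config$artifact_density
    if (isTRUE(a$hair)) {
      for (h in seq_len(stats::rpois(1, dens))) {
        p0 <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
        p2 <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
        p1 <- (p0 + p2) / 2 + stats::rnorm(2, 0, 0.25 * c(H, W))
        tt <- seq(0, 1, length.out = 4L * (H + W))
        by <- (1 - tt)^2 * p0[1] + 2 * tt * (1 - tt) * p1[1] + tt^2 * p2[1]
        bx <- (1 - tt)^2 * p0[2] + 2 * tt * (1 - tt) * p1[2] + tt^2 * p2[2]
        ok <- by >= 1 & by <= H & bx >= 1 & bx <= W
        idx <- cbind(round(by[ok]), round(bx[ok]))
        shade <- stats::runif(1, 0.05, 0.2)
        for (k in 1:3) {
          ch <- img[, , k]; ch[idx] <- shade * (1 + 0.3 * (k == 1))
          img[, , k] <- ch
        }
      }
    }
    if (isTRUE(a$bubbles)) {
      for (b in seq_len(stats::rpois(1, dens))) {
        bc <- c(stats::runif(1, 5, H - 4), stats::runif(1, 5, W - 4))
        br <- stats::runif(1, 2, 5)
        d <- sqrt((rows + 1 + cy - bc[1])^2 + (cols + 1 + cx - bc[2])^2)
        ring <- abs(d - br) < 0.9
        img[, , 1][ring] <- img[, , 1][ring] + 0.22
        img[, , 2][ring] <- img[, , 2][ring] + 0.22
        img[, , 3][ring] <- img[, , 3][ring] + 0.22
      }
    }
    if (isTRUE(a$pen_marks) && stats::runif(1) < min(dens / 4, 1)) {
      pr <- maxr * stats::runif(1, 1.25, 1.6)
      a0 <- stats::runif(1, 0, 2 * pi)
      span <- stats::runif(1, pi / 6, 2 * pi / 3)
      arc <- abs(rho - pr) < 1.2 & ((psi - a0) %% (2 * pi)) < span
      img[, , 1][arc] <- 0.15; img[, , 2][arc] <- 0.15
      img[, , 3][arc] <- 0.45
    }
    if (isTRUE(a$reflections)) {
      for (s in seq_len(stats::rpois(1, dens))) {
        rc <- c(stats::runif(1, 2, H - 1), stats::runif(1, 2, W - 1))
        sg <- stats::runif(1, 1, 3)
        d2 <- (rows + 1 + cy - rc[1])^2 + (cols + 1 + cx - rc[2])^2
        gl <- 0.9 * exp(-d2 / (2 * sg^2))
        for (k in 1:3) img[, , k] <- img[, , k] + (1 - img[, , k]) * gl
      }
    }
    img[img < 0] <- 0; img[img > 1] <- 1

    irr_stat <- stats::sd(prof / ell_fn(phig)) # realized boundary irregularity
    smp <- structure(list(id = sprintf("SYN_%05d", index), image = img,
                          mask = mask, class = cls, provenance = "original",
                          original_size = c(H, W),
                          irregularity = irr_stat),
                     class = "image_sample")
    list(sample = smp, seed = seed_i)
  })
}

#' Generate a list of synthetic samples in memory
#'
#' @param config a [synth_config()].
#' @param indices which sample indices to generate; default all.
#' @return List of `"image_sample"` objects.
#' @export
generate_samples <- function(config, indices = seq_len(config$n_samples)) {
  lapply(indices, function(i) generate_sample(config, i)$sample)
}

#' Write a synthetic dataset to disk
#'
#' Writes JPEG images to `out_dir/images`, 0/255 PNG masks to
#' `out_dir/masks` (ISIC-style `<id>_segmentation.png` names), a
#' `labels.csv` when class labels are generated, and a YAML manifest holding
#' the full configuration and per-sample seeds, from which the dataset can be
#' regenerated exactly (in memory; the JPEGs themselves are lossy).
#'
#' @param config a [synth_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
generate_dataset <- function(config, out_dir) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  ids <- character(config$n_samples)
  seeds <- integer(config$n_samples)
  classes <- character(config$n_samples)
  for (i in seq_len(config$n_samples)) {
    g <- generate_sample(config, i)
    s <- g$sample
    ids[i] <- s$id; seeds[i] <- g$seed; classes[i] <- s$class
    EBImage::writeImage(hwc_to_eb(s$image),
                        file.path(out_dir, "images", paste0(s$id, ".jpg")),
                        quality = 95)
    write_mask(s$mask,
               file.path(out_dir, "masks",
                         paste0(s$id, "_segmentation.png")))
  }
  if (!is.null(config$class_labels)) {
    utils::write.csv(data.frame(image_id = ids, class = classes),
                     file.path(out_dir, "labels.csv"), row.names = FALSE)
  }
  manifest <- list(config = unclass(config),
                   samples = list(id = as.list(ids), seed = as.list(seeds)))
  mp <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, mp)
  invisible(mp)
}

#' Regenerate samples from a dataset manifest
#'
#' Rebuilds the exact sample stream recorded by [generate_dataset()].
#'
#' @param manifest_path path to a `manifest.yaml`.
#' @param indices which samples to regenerate; default all.
#' @return List of `"image_sample"` objects, bit-identical to the originally
#'   generated ones.
#' @export
dataset_from_manifest <- function(manifest_path, indices = NULL) {
  m <- yaml::read_yaml(manifest_path)
  cfg <- m$config
  for (f in c("image_size", "area_range", "irregularity_range",
              "contrast_range"))
    cfg[[f]] <- unlist(cfg[[f]])
  cfg$image_size <- as.integer(cfg$image_size)
  config <- do.call(synth_config, cfg)
  if (is.null(indices)) indices <- seq_len(config$n_samples)
  generate_samples(config, indices)
}
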