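LESION_CLASSES <- c("AKIEC", "BCC", "BKL", "DF", "MEL", "NV", "VASC")

# EBImage stores images as width x height x channels; the package convention
# is height x width x channels (row-major, origin top-left).
eb_to_hwc <- function(img) {
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  aperm(a, c(2, 1, 3))
}

hwc_to_eb <- function(a) {
  EBImage::Image(aperm(a, c(2, 1, 3)), colormode = "Color")
}

#' Load a dermoscopic image
#'
#' Reads a JPEG/PNG image into an image sample: an `H x W x 3` array of values
#' in `[0, 1]` plus metadata. Grayscale images are replicated to three
#' channels; an alpha channel is dropped. The sample id is the file stem.
#'
#' @param path path to a JPEG or PNG file.
#' @param id sample id; defaults to the file name without extension.
#' @param class optional lesion class label, one of
#'   `r paste(LESION_CLASSES, collapse = ", ")`.
#' @return An `"image_sample"`: list with `id`, `image` (`H x W x 3`),
#'   `class`, `provenance` (`"original"`), and `original_size`.
#' @export
load_image <- function(path, id = NULL, class = NA_character_) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot decode image ", path, ": ",
                                           conditionMessage(e)))
  a <- eb_to_hwc(img)
  a[a < 0] <- 0; a[a > 1] <- 1
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  if (!is.na(class)) class <- match.arg(class, LESION_CLASSES)
  structure(list(id = id, image = a, mask = NULL, class = class,
                 provenance = "original", original_size = dim(a)[1:2]),
            class = "image_sample")
}

#' Load a binary ground-truth mask
#'
#' Reads a PNG mask and binarizes it: 8-bit values above 127 (i.e. > 0.5 after
#' scaling) become lesion (1), the rest background (0). A mask that is
#' entirely one value is accepted but flagged via the `"constant"` attribute.
#'
#' @param path path to a PNG mask (white = lesion).
#' @return `H x W` matrix of 0/1 with attribute `constant` (logical).
#' @export
load_mask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot decode mask ", path, ": ",
                                           conditionMessage(e)))
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  m <- t(a)
  m <- (m > 127 / 255) * 1
  attr(m, "constant") <- length(unique(as.vector(m))) == 1L
  m
}

#' Resize and normalize a sample
#'
#' Resizes the image (bilinear) and its mask, if present, (nearest neighbour,
#' preserving binarity) to the network input size and clamps values to
#' `[0, 1]`. Applying it twice is the same as applying it once; a sample
#' already at the target size passes through unchanged.
#'
#' @param sample an `"image_sample"` (or a bare `H x W x 3` array).
#' @param target integer `c(height, width)`; default `c(384, 512)`.
#' @return The sample with `image` (and `mask`) at the target size.
#' @export
resize_normalize <- function(sample, target = c(384L, 512L)) {
  bare <- !inherits(sample, "image_sample")
  if (bare) sample <- structure(list(id = NA_character_, image = sample,
                                     mask = NULL, class = NA_character_,
                                     provenance = "original",
                                     original_size = dim(sample)[1:2]),
                                class = "image_sample")
  target <- as.integer(target)
  if (any(dim(sample$image)[1:2] == 0L) || any(target <= 0L))
    stop("zero-sized image or target")
  if (!identical(dim(sample$image)[1:2], target)) {
    eb <- hwc_to_eb(sample$image)
    r <- EBImage::resize(eb, w = target[2], h = target[1], filter = "bilinear")
    a <- eb_to_hwc(r)
    a[a < 0] <- 0; a[a > 1] <- 1
    sample$image <- a
  }
  if (!is.null(sample$mask) && !identical(dim(sample$mask), target)) {
    sample$mask <- resize_mask(sample$mask, target)
  }
  if (bare) sample$image else sample
}

#' Resize a binary mask with nearest-neighbour interpolation
#'
#' @param mask `H x W` binary matrix.
#' @param target integer `c(height, width)`.
#' @return Resized binary matrix (values stay in `{0, 1}`).
#' @export
resize_mask <- function(mask, target) {
  target <- as.integer(target)
  if (identical(dim(mask), target)) return(mask)
  eb <- EBImage::Image(t(mask))
  r <- EBImage::resize(eb, w = target[2], h = target[1], filter = "none")
  m <- t(EBImage::imageData(r))
  (m > 0.5) * 1
}

flip_array <- function(a, vertical, horizontal) {
  nd <- length(dim(a))
  idx_r <- if (vertical) rev(seq_len(dim(a)[1])) else seq_len(dim(a)[1])
  idx_c <- if (horizontal) rev(seq_len(dim(a)[2])) else seq_len(dim(a)[2])
  if (nd == 2L) a[idx_r, idx_c, drop = FALSE]
  else a[idx_r, idx_c, , drop = FALSE]
}

#' Four-fold flip augmentation
#'
#' For every sample returns the original plus its vertical flip, horizontal
#' flip, and combined flip, with image and mask flipped jointly; ids gain a
#' provenance suffix and class labels are preserved. 2,000 samples become
#' 8,000.
#'
#' @param samples list of `"image_sample"` objects (masks optional).
#' @return List of length `4 * length(samples)`.
#' @export
augment_flips <- function(samples) {
  variants <- list(original = c(FALSE, FALSE), vflip = c(TRUE, FALSE),
                   hflip = c(FALSE, TRUE), vhflip = c(TRUE, TRUE))
  out <- vector("list", 4L * length(samples))
  k <- 0L
  for (s in samples) {
    for (v in names(variants)) {
      fl <- variants[[v]]
      k <- k + 1L
      t <- s
      if (any(fl)) {
        t$image <- flip_array(s$image, fl[1], fl[2])
        if (!is.null(s$mask)) t$mask <- flip_array(s$mask, fl[1], fl[2])
        t$id <- paste0(s$id, "_", v)
      }
      t$provenance <- v
      out[[k]] <- t
    }
  }
  out
}

#' One-hot target encoding with background as a class
#'
#' Lesion segmentation is framed as two-class classification: channel 1 is the
#' background (mask 0) and channel 2 the lesion (mask 1), so channels sum to 1
#' at every pixel. `decode_targets()` inverts the encoding by per-pixel argmax.
#'
#' @param mask `H x W` binary matrix.
#' @return `H x W x 2` one-hot array.
#' @export
encode_targets <- function(mask) {
  m <- (as.matrix(mask) > 0.5) * 1
  array(c(1 - m, m), dim = c(dim(m), 2L))
}

#' @rdname encode_targets
#' @param onehot `H x W x 2` array of class scores or probabilities.
#' @export
decode_targets <- function(onehot) {
  (onehot[, , 2] > onehot[, , 1]) * 1
}

#' Read per-image lesion class labels
#'
#' Parses a CSV with header `image_id,class` into a named character vector of
#' class labels. Classes must be among
#' `r paste(LESION_CLASSES, collapse = ", ")`; duplicate ids are an error.
#'
#' @param path CSV file path.
#' @return Named character vector mapping image id to class.
#' @export
read_class_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image_id", "class") %in% names(df)))
    stop("label CSV must have columns image_id,class")
  bad <- setdiff(unique(df$class), LESION_CLASSES)
  if (length(bad))
    stop("unknown class label(s) ", paste(bad, collapse = ", "),
         "; valid classes are ", paste(LESION_CLASSES, collapse = ", "))
  dup <- df$image_id[duplicated(df$image_id)]
  if (length(dup))
    stop("duplicate image ids in label CSV: ",
         paste(unique(dup), collapse = ", "))
  stats::setNames(df$class, df$image_id)
}

#' Write a binary mask as PNG
#'
#' @param mask `H x W` binary matrix.
#' @param path output path (`.png`); lesion pixels are written as 255.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask > 0.5), nrow(mask)), path)
  invisible(path)
}

#' Load a paired image/mask dataset directory
#'
#' Follows the ISIC layout convention: images `<id>.jpg` (or `.png`) in
#' `image_dir` and masks `<id><mask_suffix>.png` in `mask_dir`.
#'
#' @param image_dir directory of dermoscopic images.
#' @param mask_dir directory of mask PNGs; `NULL` to load images only.
#' @param mask_suffix suffix between the id and `.png`, default
#'   `"_segmentation"`.
#' @param labels optional named class vector from [read_class_labels()].
#' @return List of `"image_sample"` objects with masks attached.
#' @export
load_dataset <- function(image_dir, mask_dir = NULL,
                         mask_suffix = "_segmentation", labels = NULL) {
  files <- sort(list.files(image_dir, pattern = "\\.(jpe?g|png)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (!length(files)) stop("no images found in ", image_dir)
  lapply(files, function(f) {
    id <- tools::file_path_sans_ext(basename(f))
    cls <- if (!is.null(labels) && id %in% names(labels)) labels[[id]]
           else NA_character_
    s <- load_image(f, id = id, class = cls)
    if (!is.null(mask_dir)) {
      mp <- file.path(mask_dir, paste0(id, mask_suffix, ".png"))
      if (!file.exists(mp)) stop("missing mask for ", id, ": ", mp)
      s$mask <- load_mask(mp)
    }
    s
  })
}
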