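ARCHITECTURES <- c("unet", "squeeze_unet", "attention_unet",
                   "attention_squeeze_unet")

arch_divisor <- function(architecture) {
  if (architecture %in% c("unet", "attention_unet")) 16L else 32L
}

#' Network specification
#'
#' Describes one of the four segmentation architectures: the proposed
#' Attention Squeeze U-Net and the U-Net, Squeeze U-Net and Attention U-Net
#' baselines. The input spatial size must be divisible by the architecture's
#' total downsampling factor (16 for the U-Net family, 32 for the squeeze
#' family, whose contracting path is a stride-2 stem convolution plus four
#' 2x2 max-pools).
#'
#' @param architecture one of `"attention_squeeze_unet"`, `"squeeze_unet"`,
#'   `"attention_unet"`, `"unet"`.
#' @param input_size integer vector `c(height, width)`; default 384 x 512.
#' @param in_channels input channels (3 for RGB dermoscopy).
#' @param n_classes output classes; 2 (background, lesion).
#' @param seed integer seed fixing the weight initialization.
#' @return A `"network_spec"` object.
#' @examples
#' network_spec("squeeze_unet", input_size = c(96, 128))
#' @export
network_spec <- function(architecture = "attention_squeeze_unet",
                         input_size = c(384L, 512L), in_channels = 3L,
                         n_classes = 2L, seed = 42L) {
  architecture <- match.arg(architecture, ARCHITECTURES)
  input_size <- as.integer(input_size)
  stopifnot(length(input_size) == 2L, all(input_size > 0))
  div <- arch_divisor(architecture)
  if (any(input_size %% div != 0L))
    stop("input size ", input_size[1], "x", input_size[2],
         " must be divisible by ", div, " for architecture ", architecture)
  structure(list(architecture = architecture, input_size = input_size,
                 in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes), seed = as.integer(seed)),
            class = "network_spec")
}

# ---- squeeze family --------------------------------------------------------
# Channel schedule (validated against the printed parameter counts; see the
# methods vignette):
#   stem conv 3x3 s2 -> 64                                 @ H/2
#   pool; fire(16,128) fire(16,128)       -> skip s2 (128) @ H/4
#   pool; fire(32,256) fire(32,256)       -> skip s3 (256) @ H/8
#   pool; fire(48,384) fire(48,384)       -> skip s4 (384) @ H/16
#   pool; fire(56,448) -> skip s5; fire(64,512) -> b       @ H/32
#   up1 s1: deconv3x3 512->192 [gate] fire(64,384)         @ H/32
#   up2 s2: deconv3x3 384->128 [gate] fire(32,256)         @ H/16
#   up3 s2: deconv3x3 256->64  [gate] fire(16,128)         @ H/8
#   up4 s2: deconv3x3 128->32  [gate] fire(16,64)          @ H/4
#   nn x2; conv3x3 64->32; nn x2; conv3x3 32->16; conv1x1 16->classes; softmax

build_squeeze_params <- function(in_channels, n_classes, attention) {
  list(
    stem = new_conv(3L, in_channels, 64L, stride = 2L),
    enc1a = p_fire(64L, 16L, 128L),  enc1b = p_fire(128L, 16L, 128L),
    enc2a = p_fire(128L, 32L, 256L), enc2b = p_fire(256L, 32L, 256L),
    enc3a = p_fire(256L, 48L, 384L), enc3b = p_fire(384L, 48L, 384L),
    enc4a = p_fire(384L, 56L, 448L), enc4b = p_fire(448L, 64L, 512L),
    up1 = p_upblock(512L, 448L, 192L, 64L, 384L, 1L, attention),
    up2 = p_upblock(384L, 384L, 128L, 32L, 256L, 2L, attention),
    up3 = p_upblock(256L, 256L, 64L, 16L, 128L, 2L, attention),
    up4 = p_upblock(128L, 128L, 32L, 16L, 64L, 2L, attention),
    head1 = new_conv(3L, 64L, 32L),
    head2 = new_conv(3L, 32L, 16L),
    out = new_conv(1L, 16L, n_classes)
  )
}

forward_squeeze <- function(p, x, attention) {
  s1 <- f_conv(p$stem, x)                       # H/2
  t <- op_maxpool2(s1)                          # H/4
  t <- f_fire(p$enc1a, t); s2 <- f_fire(p$enc1b, t)
  t <- op_maxpool2(s2)                          # H/8
  t <- f_fire(p$enc2a, t); s3 <- f_fire(p$enc2b, t)
  t <- op_maxpool2(s3)                          # H/16
  t <- f_fire(p$enc3a, t); s4 <- f_fire(p$enc3b, t)
  t <- op_maxpool2(s4)                          # H/32
  s5 <- f_fire(p$enc4a, t); b <- f_fire(p$enc4b, s5)
  d <- f_upblock(p$up1, b, s5, attention)       # H/32
  d <- f_upblock(p$up2, d, s4, attention)       # H/16
  d <- f_upblock(p$up3, d, s3, attention)       # H/8
  d <- f_upblock(p$up4, d, s2, attention)       # H/4
  d <- f_conv(p$head1, op_nnup2(d))             # H/2
  d <- f_conv(p$head2, op_nnup2(d))             # H
  op_softmax_ch(f_conv(p$out, d, relu = FALSE))
}

# ---- U-Net family ----------------------------------------------------------
# Classic schedule 64-128-256-512 with a 1024-channel bottleneck, two 3x3
# convolutions per stage, 2x2 max-pools, and 2x2 stride-2 transposed
# convolutions in the expansive path. The attention variant gates each skip
# with an additive attention block before concatenation.

build_unet_params <- function(in_channels, n_classes, attention) {
  ch <- c(64L, 128L, 256L, 512L, 1024L)
  p <- list()
  cin <- in_channels
  for (i in 1:5) {
    p[[paste0("enc", i)]] <- list(c1 = new_conv(3L, cin, ch[i]),
                                  c2 = new_conv(3L, ch[i], ch[i]))
    cin <- ch[i]
  }
  for (i in 4:1) {
    st <- list(up = new_tconv(2L, ch[i + 1], ch[i], 2L))
    if (attention) st$attn <- p_attn(ch[i], ch[i], max(ch[i] %/% 2L, 1L))
    st$c1 <- new_conv(3L, 2L * ch[i], ch[i])
    st$c2 <- new_conv(3L, ch[i], ch[i])
    p[[paste0("dec", i)]] <- st
  }
  p$out <- new_conv(1L, ch[1], n_classes)
  p
}

forward_unet <- function(p, x, attention) {
  skips <- vector("list", 4)
  t <- x
  for (i in 1:4) {
    t <- f_conv(p[[paste0("enc", i)]]$c2, f_conv(p[[paste0("enc", i)]]$c1, t))
    skips[[i]] <- t
    t <- op_maxpool2(t)
  }
  t <- f_conv(p$enc5$c2, f_conv(p$enc5$c1, t))
  for (i in 4:1) {
    st <- p[[paste0("dec", i)]]
    g <- f_tconv(st$up, t)
    s <- if (attention) f_attn(st$attn, g, skips[[i]])$out else skips[[i]]
    t <- f_conv(st$c2, f_conv(st$c1, op_concat(s, g)))
  }
  op_softmax_ch(f_conv(p$out, t, relu = FALSE))
}

#' Build a segmentation network
#'
#' Instantiates the architecture named in `spec` with Glorot-uniform weights
#' seeded from `spec$seed`. The model maps an `H x W x in_channels` image to an
#' `H x W x n_classes` map of per-pixel class probabilities (softmax over
#' channels).
#'
#' @param spec a [network_spec()].
#' @return An `"asu_network"` object with elements `spec` and `params`.
#' @examples
#' net <- build_network(network_spec("squeeze_unet", input_size = c(96, 128)))
#' count_parameters(net)
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  params <- switch(spec$architecture,
    unet = build_unet_params(spec$in_channels, spec$n_classes, FALSE),
    attention_unet = build_unet_params(spec$in_channels, spec$n_classes, TRUE),
    squeeze_unet = build_squeeze_params(spec$in_channels, spec$n_classes, FALSE),
    attention_squeeze_unet =
      build_squeeze_params(spec$in_channels, spec$n_classes, TRUE))
  structure(list(spec = spec, params = params), class = "asu_network")
}

#' @export
print.asu_network <- function(x, ...) {
  cat("<asu_network> ", x$spec$architecture, "\n",
      "  input: ", x$spec$input_size[1], "x", x$spec$input_size[2], "x",
      x$spec$in_channels, " -> ", x$spec$n_classes, " classes\n",
      "  trainable parameters: ",
      format(count_parameters(x), big.mark = ","), "\n", sep = "")
  invisible(x)
}

# Forward pass. x: H x W x C array (or ag node); params defaults to the
# network's own (plain-array) parameters, but a wrapped (autograd) copy can be
# passed during training.
net_forward <- function(net, x, params = net$params) {
  d <- dim(ag_value(x))
  div <- arch_divisor(net$spec$architecture)
  if (d[1] %% div != 0L || d[2] %% div != 0L)
    stop("input ", d[1], "x", d[2], " not divisible by ", div)
  if (d[3] != net$spec$in_channels)
    stop("input has ", d[3], " channels, expected ", net$spec$in_channels)
  att <- net$spec$architecture %in% c("attention_unet", "attention_squeeze_unet")
  if (net$spec$architecture %in% c("unet", "attention_unet"))
    forward_unet(params, x, att)
  else
    forward_squeeze(params, x, att)
}

#' Per-pixel class probabilities
#'
#' Runs the network on one image and returns the softmax output.
#'
#' @param net an `"asu_network"`.
#' @param image `H x W x in_channels` array with values in `[0, 1]`.
#' @return `H x W x n_classes` array; channels sum to 1 at every pixel.
#' @export
predict_probs <- function(net, image) {
  ag_value(net_forward(net, image))
}
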