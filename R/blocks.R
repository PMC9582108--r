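#' Fire block specification
#'
#' A fire block squeezes its input with a 1x1 convolution to `squeeze_channels`
#' and re-expands it with two parallel convolutions (3x3 and 1x1 in the
#' contracting path; 1x1 and 2x2 in the transposed variant), each producing
#' `output_channels / 2` channels, which are concatenated. `output_channels`
#' must therefore be even.
#'
#' @param squeeze_channels positive integer, channels of the 1x1 squeeze.
#' @param output_channels positive even integer, channels after concatenation.
#' @return An object of class `"fire_spec"`.
#' @examples
#' fire_spec(16, 64)
#' @export
fire_spec <- function(squeeze_channels, output_channels) {
  if (length(squeeze_channels) != 1L || squeeze_channels < 1 ||
      squeeze_channels != round(squeeze_channels))
    stop("squeeze_channels must be a positive integer")
  if (length(output_channels) != 1L || output_channels < 1 ||
      output_channels != round(output_channels))
    stop("output_channels must be a positive integer")
  if (output_channels %% 2 != 0)
    stop("output_channels must be even (got ", output_channels,
         "): the two expand branches each carry output_channels/2 channels")
  structure(list(squeeze_channels = as.integer(squeeze_channels),
                 output_channels = as.integer(output_channels)),
            class = "fire_spec")
}

# ---- internal parameter constructors / forwards ----------------------------

p_fire <- function(cin, cs, co) {
  list(squeeze = new_conv(1L, cin, cs),
       expand3 = new_conv(3L, cs, co %/% 2L),
       expand1 = new_conv(1L, cs, co %/% 2L))
}

f_fire <- function(p, x) {
  s <- f_conv(p$squeeze, x)
  op_concat(f_conv(p$expand3, s), f_conv(p$expand1, s))
}

p_tfire <- function(cin, cs, co, stride) {
  list(up = new_tconv(1L, cin, cs, stride),
       expand1 = new_conv(1L, cs, co %/% 2L),
       expand2 = new_conv(2L, cs, co %/% 2L))
}

f_tfire <- function(p, x) {
  s <- f_tconv(p$up, x)
  op_concat(f_conv(p$expand1, s), f_conv(p$expand2, s))
}

p_attn <- function(g_ch, x_ch, inter_ch) {
  list(wg = new_conv(1L, g_ch, inter_ch),
       wx = new_conv(1L, x_ch, inter_ch),
       psi = new_conv(1L, inter_ch, 1L))
}

# Returns list(out, map): out = x weighted per pixel, map in (0, 1).
f_attn <- function(p, g, x) {
  dg <- dim(ag_value(g)); dx <- dim(ag_value(x))
  if (dg[1] != dx[1] || dg[2] != dx[2])
    stop("attention inputs must share spatial size: g is ",
         dg[1], "x", dg[2], ", x is ", dx[1], "x", dx[2])
  q <- op_relu(op_add(f_conv(p$wg, g, relu = FALSE),
                      f_conv(p$wx, x, relu = FALSE)))
  a <- op_sigmoid(f_conv(p$psi, q, relu = FALSE))
  list(out = op_scale_by_map(x, a), map = a)
}

p_upblock <- function(g_ch, skip_ch, ghat_ch, cs, co, stride, attention) {
  p <- list(deconv = new_tconv(3L, g_ch, ghat_ch, stride))
  if (attention) p$attn <- p_attn(ghat_ch, skip_ch, max(ghat_ch %/% 2L, 1L))
  p$fire <- p_fire(ghat_ch + skip_ch, cs, co)
  p
}

f_upblock <- function(p, g, x, attention) {
  ghat <- f_tconv(p$deconv, g)
  dg <- dim(ag_value(ghat)); dx <- dim(ag_value(x))
  if (dg[1] != dx[1] || dg[2] != dx[2])
    stop("skip/gating size mismatch in upsampling block: upsampled gating is ",
         dg[1], "x", dg[2], " but skip is ", dx[1], "x", dx[2])
  a <- if (attention) f_attn(p$attn, ghat, x)$out else x
  f_fire(p$fire, op_concat(a, ghat))
}

# ---- public block objects --------------------------------------------------

new_block <- function(type, params, meta) {
  structure(c(list(type = type, params = params), meta), class = "asu_block")
}

#' Network building blocks
#'
#' Constructors for the individual blocks of the squeeze/attention
#' architectures. Each returns an `"asu_block"` object whose weights are drawn
#' from the current RNG stream; apply it to an `H x W x C` array with
#' [block_apply()].
#'
#' * `fire_block()`: 1x1 squeeze convolution followed by parallel 3x3 and 1x1
#'   expand convolutions whose outputs are concatenated (spatial size kept).
#' * `transposed_fire_block()`: 1x1 transposed convolution (stride `stride`,
#'   output spatial size multiplied by `stride`) followed by parallel 1x1 and
#'   2x2 expand convolutions, concatenated.
#' * `attention_block()`: additive attention gate; both inputs are projected by
#'   1x1 convolutions to `inter_channels`, summed, passed through ReLU and a
#'   1x1 convolution to a single channel, and squashed by a sigmoid into a
#'   per-pixel attention map in (0, 1) that multiplies the skip input.
#' * `upsampling_block()`: 3x3 stride-2 transposed convolution of the gating
#'   signal to `ghat_channels`, optional attention gate against the skip input,
#'   concatenation, and a fire block.
#'
#' @param in_channels channels of the input feature map.
#' @param spec a [fire_spec()].
#' @param stride upsampling factor of the transposed convolution.
#' @param g_channels,x_channels,skip_channels channels of the gating signal and
#'   of the skip-connection input.
#' @param inter_channels intermediate channels of the attention gate; defaults
#'   to half the gating channels.
#' @param ghat_channels channels of the upsampled gating signal.
#' @param attention logical, include an attention gate in the upsampling block.
#' @return An `"asu_block"` object.
#' @examples
#' set.seed(1)
#' b <- fire_block(64, fire_spec(16, 64))
#' y <- block_apply(b, array(rnorm(8 * 8 * 64), c(8, 8, 64)))
#' dim(y)  # 8 8 64
#' count_parameters(b)  # 6224
#' @export
fire_block <- function(in_channels, spec) {
  stopifnot(inherits(spec, "fire_spec"))
  new_block("fire",
            p_fire(in_channels, spec$squeeze_channels, spec$output_channels),
            list(in_channels = in_channels, spec = spec))
}

#' @rdname fire_block
#' @export
transposed_fire_block <- function(in_channels, spec, stride = 2L) {
  stopifnot(inherits(spec, "fire_spec"))
  new_block("tfire",
            p_tfire(in_channels, spec$squeeze_channels, spec$output_channels,
                    as.integer(stride)),
            list(in_channels = in_channels, spec = spec,
                 stride = as.integer(stride)))
}

#' @rdname fire_block
#' @export
attention_block <- function(g_channels, x_channels, inter_channels = NULL) {
  if (is.null(inter_channels)) inter_channels <- max(g_channels %/% 2L, 1L)
  new_block("attention", p_attn(g_channels, x_channels, inter_channels),
            list(g_channels = g_channels, x_channels = x_channels,
                 inter_channels = inter_channels))
}

#' @rdname fire_block
#' @export
upsampling_block <- function(g_channels, skip_channels, spec,
                             ghat_channels = g_channels %/% 2L,
                             stride = 2L, attention = TRUE) {
  stopifnot(inherits(spec, "fire_spec"))
  new_block("upsampling",
            p_upblock(g_channels, skip_channels, ghat_channels,
                      spec$squeeze_channels, spec$output_channels,
                      as.integer(stride), attention),
            list(g_channels = g_channels, skip_channels = skip_channels,
                 ghat_channels = ghat_channels, spec = spec,
                 stride = as.integer(stride), attention = attention))
}

#' Apply a block to feature maps
#'
#' @param block an `"asu_block"` from [fire_block()] and friends.
#' @param x input feature map, an `H x W x C` array (for the attention and
#'   upsampling blocks this is the skip input).
#' @param g gating feature map, required by the attention and upsampling
#'   blocks.
#' @param return_map for the attention block, also return the attention map.
#' @return The output feature map; for `return_map = TRUE` a list with
#'   elements `out` and `map`.
#' @export
block_apply <- function(block, x, g = NULL, return_map = FALSE) {
  stopifnot(inherits(block, "asu_block"))
  switch(block$type,
    fire = f_fire(block$params, x),
    tfire = f_tfire(block$params, x),
    attention = {
      r <- f_attn(block$params, g, x)
      if (return_map) r else r$out
    },
    upsampling = f_upblock(block$params, g, x, block$attention),
    stop("unknown block type ", block$type))
}

#' Count trainable parameters
#'
#' Total number of trainable scalars (convolution weights and biases) in a
#' block or network.
#'
#' @param x an `"asu_block"` or `"asu_network"` object (or a bare nested
#'   parameter list).
#' @return Nonnegative integer count.
#' @export
count_parameters <- function(x) {
  if (inherits(x, "asu_block") || inherits(x, "asu_network"))
    return(params_count(x$params))
  params_count(x)
}
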