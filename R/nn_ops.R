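# Differentiable tensor operations. Every op accepts either plain numeric
# arrays (inference: no tape is built) or ag_node tensors (training). Feature
# maps are H x W x C arrays; conv weights k x k x Cin x Cout; transposed-conv
# weights k x k x Cout x Cin.

op_conv2d <- function(x, w, b, stride = 1L) {
  k <- dim(ag_value(w))[1]
  y <- .cpp_conv2d_fw(ag_value(x), ag_value(w), ag_value(b), k, as.integer(stride))
  if (!is_ag(x) && !is_ag(w)) return(y)
  xs <- if (is_ag(x)) x else ag_leaf(x)
  ws <- if (is_ag(w)) w else ag_leaf(w)
  bs <- if (is_ag(b)) b else ag_leaf(b)
  ag_op(y, list(xs, ws, bs), function(g) {
    bw <- .cpp_conv2d_bw(xs$value, ws$value, g, k, as.integer(stride))
    list(bw$dx, bw$dw, bw$db)
  })
}

op_tconv2d <- function(x, w, b, stride = 2L) {
  k <- dim(ag_value(w))[1]
  y <- .cpp_tconv2d_fw(ag_value(x), ag_value(w), ag_value(b), k, as.integer(stride))
  if (!is_ag(x) && !is_ag(w)) return(y)
  xs <- if (is_ag(x)) x else ag_leaf(x)
  ws <- if (is_ag(w)) w else ag_leaf(w)
  bs <- if (is_ag(b)) b else ag_leaf(b)
  ag_op(y, list(xs, ws, bs), function(g) {
    bw <- .cpp_tconv2d_bw(xs$value, ws$value, g, k, as.integer(stride))
    list(bw$dx, bw$dw, bw$db)
  })
}

op_maxpool2 <- function(x) {
  v <- ag_value(x)
  d <- dim(v)
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L)
    stop("max pooling requires even spatial dimensions, got ",
         d[1], "x", d[2])
  fw <- .cpp_maxpool2_fw(v)
  if (!is_ag(x)) return(fw$y)
  ag_op(fw$y, list(x), function(g) {
    list(.cpp_maxpool2_bw(g, fw$argmax, d[1], d[2]))
  })
}

op_nnup2 <- function(x) {
  y <- .cpp_nnup2_fw(ag_value(x))
  if (!is_ag(x)) return(y)
  ag_op(y, list(x), function(g) list(.cpp_nnup2_bw(g)))
}

op_relu <- function(x) {
  v <- ag_value(x)
  y <- v * (v > 0)
  if (!is_ag(x)) return(y)
  ag_op(y, list(x), function(g) list(g * (v > 0)))
}

op_sigmoid <- function(x) {
  v <- ag_value(x)
  y <- 1 / (1 + exp(-v))
  if (!is_ag(x)) return(y)
  ag_op(y, list(x), function(g) list(g * y * (1 - y)))
}

op_add <- function(x, y) {
  v <- ag_value(x) + ag_value(y)
  if (!is_ag(x) && !is_ag(y)) return(v)
  xs <- if (is_ag(x)) x else ag_leaf(x)
  ys <- if (is_ag(y)) y else ag_leaf(y)
  ag_op(v, list(xs, ys), function(g) list(g, g))
}

# Concatenate along the channel axis.
op_concat <- function(x, y) {
  vx <- ag_value(x); vy <- ag_value(y)
  dx <- dim(vx); dy <- dim(vy)
  stopifnot(dx[1] == dy[1], dx[2] == dy[2])
  v <- array(c(vx, vy), dim = c(dx[1], dx[2], dx[3] + dy[3]))
  if (!is_ag(x) && !is_ag(y)) return(v)
  xs <- if (is_ag(x)) x else ag_leaf(x)
  ys <- if (is_ag(y)) y else ag_leaf(y)
  ag_op(v, list(xs, ys), function(g) {
    list(array(g[, , seq_len(dx[3]), drop = FALSE], dim = dx),
         array(g[, , dx[3] + seq_len(dy[3]), drop = FALSE], dim = dy))
  })
}

# Multiply a feature map x (H x W x C) by a single-channel map a (H x W x 1),
# broadcasting over channels (the attention-gate product).
op_scale_by_map <- function(x, a) {
  vx <- ag_value(x); va <- ag_value(a)
  d <- dim(vx)
  stopifnot(dim(va)[1] == d[1], dim(va)[2] == d[2], dim(va)[3] == 1L)
  v <- vx * as.vector(va)   # recycles H*W map over channels (column-major)
  if (!is_ag(x) && !is_ag(a)) return(v)
  xs <- if (is_ag(x)) x else ag_leaf(x)
  as_ <- if (is_ag(a)) a else ag_leaf(a)
  ag_op(v, list(xs, as_), function(g) {
    da <- array(rowSums(matrix(g * vx, nrow = d[1] * d[2])), dim = c(d[1], d[2], 1L))
    list(g * as.vector(va), da)
  })
}

# Per-pixel softmax over the channel axis (numerically stabilized).
op_softmax_ch <- function(x) {
  v <- ag_value(x)
  d <- dim(v)
  m <- v[, , 1]
  for (c in seq_len(d[3])[-1]) m <- pmax(m, v[, , c])
  e <- exp(v - as.vector(m))
  s <- array(0, dim = c(d[1], d[2]))
  for (c in seq_len(d[3])) s <- s + e[, , c]
  p <- e / as.vector(s)
  if (!is_ag(x)) return(p)
  ag_op(p, list(x), function(g) {
    dot <- array(0, dim = c(d[1], d[2]))
    for (c in seq_len(d[3])) dot <- dot + g[, , c] * p[, , c]
    list(p * (g - as.vector(dot)))
  })
}

# Soft focal Tversky loss on a foreground-probability map (H x W) against a
# binary mask, as a differentiable scalar op. See focal_tversky_loss() for the
# user-facing (non-tape) version.
op_ftl <- function(p, gt, alpha, beta, gamma, epsilon) {
  pv <- ag_value(p)
  g <- as.numeric(gt)
  pvv <- as.numeric(pv)
  tp <- sum(pvv * g)
  fn <- sum((1 - pvv) * g)
  fp <- sum(pvv * (1 - g))
  den <- tp + alpha * fn + beta * fp
  ti <- (tp + epsilon) / (den + epsilon)
  loss <- (1 - ti)^gamma
  if (!is_ag(p)) return(loss)
  ag_op(array(loss, dim = c(1, 1)), list(p), function(gr) {
    gr <- as.numeric(gr)
    # d ti / d p = [g*(den+eps) - (tp+eps)*(g - alpha*g + beta*(1-g))] / (den+eps)^2
    dden_dp <- g - alpha * g + beta * (1 - g)
    dti_dp <- (g * (den + epsilon) - (tp + epsilon) * dden_dp) / (den + epsilon)^2
    dloss_dti <- -gamma * (1 - ti)^(gamma - 1)
    list(array(gr * dloss_dti * dti_dp, dim = dim(pv)))
  })
}

# Multiply by a fixed scalar constant (e.g. 1/batch_size when averaging).
op_scale <- function(x, k) {
  v <- ag_value(x) * k
  if (!is_ag(x)) return(v)
  ag_op(v, list(x), function(g) list(g * k))
}

# Sum a list of scalar nodes into one scalar node.
op_scalar_sum <- function(nodes) {
  v <- sum(vapply(nodes, function(n) as.numeric(ag_value(n)), numeric(1)))
  if (!any(vapply(nodes, is_ag, logical(1)))) return(v)
  nodes <- lapply(nodes, function(n) if (is_ag(n)) n else ag_leaf(array(n, c(1, 1))))
  ag_op(array(v, c(1, 1)), nodes, function(g) {
    rep(list(array(as.numeric(g), c(1, 1))), length(nodes))
  })
}

# Select one channel of an H x W x C map as an H x W matrix.
op_channel <- function(x, ch) {
  v <- ag_value(x)
  d <- dim(v)
  y <- array(v[, , ch], dim = c(d[1], d[2]))
  if (!is_ag(x)) return(y)
  ag_op(y, list(x), function(g) {
    dx <- array(0, dim = d)
    dx[, , ch] <- g
    list(dx)
  })
}
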