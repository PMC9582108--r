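# Parameterized layers. A layer is a list with class "asu_layer" holding its
# weight array, bias vector and hyperparameters. Weights are drawn with
# Glorot-uniform initialization from the R RNG stream active at construction
# time, so a set.seed() before building a model fixes every weight.

glorot <- function(n, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  stats::runif(n, -lim, lim)
}

new_conv <- function(k, cin, cout, stride = 1L) {
  w <- array(glorot(k * k * cin * cout, k * k * cin, k * k * cout),
             dim = c(k, k, cin, cout))
  structure(list(type = "conv", k = k, cin = cin, cout = cout,
                 stride = as.integer(stride), w = w, b = numeric(cout)),
            class = "asu_layer")
}

new_tconv <- function(k, cin, cout, stride = 2L) {
  # weight of the adjoint convolution: k x k x cout x cin
  w <- array(glorot(k * k * cin * cout, k * k * cin, k * k * cout),
             dim = c(k, k, cout, cin))
  structure(list(type = "tconv", k = k, cin = cin, cout = cout,
                 stride = as.integer(stride), w = w, b = numeric(cout)),
            class = "asu_layer")
}

is_layer <- function(x) inherits(x, "asu_layer") ||
  (is.list(x) && !is.null(x$type) && !is.null(x$w))

f_conv <- function(p, x, relu = TRUE) {
  y <- op_conv2d(x, p$w, p$b, p$stride)
  if (relu) op_relu(y) else y
}

f_tconv <- function(p, x, relu = TRUE) {
  y <- op_tconv2d(x, p$w, p$b, p$stride)
  if (relu) op_relu(y) else y
}

# ---- walking nested parameter structures -----------------------------------

walk_layers <- function(p, fn) {
  if (is_layer(p)) return(fn(p))
  if (is.list(p)) return(lapply(p, walk_layers, fn = fn))
  p
}

# Number of trainable scalars in a nested layer structure.
params_count <- function(p) {
  n <- 0
  rec <- function(q) {
    if (is_layer(q)) {
      n <<- n + length(ag_value(q$w)) + length(ag_value(q$b))
    } else if (is.list(q)) {
      for (e in q) rec(e)
    }
  }
  rec(p)
  n
}

# Wrap every layer's w/b into autograd leaves (training mode).
wrap_params <- function(p) {
  walk_layers(p, function(l) {
    l$w <- ag_leaf(l$w, requires_grad = TRUE)
    l$b <- ag_leaf(l$b, requires_grad = TRUE)
    l
  })
}

# Extract plain arrays back out of a wrapped structure (checkpointing).
unwrap_params <- function(p) {
  walk_layers(p, function(l) {
    l$w <- ag_value(l$w)
    l$b <- ag_value(l$b)
    l
  })
}

# Flat list of all ag leaf nodes in a wrapped structure (optimizer view).
param_nodes <- function(p) {
  acc <- list()
  rec <- function(q, path) {
    if (is_layer(q)) {
      acc[[paste0(path, ".w")]] <<- q$w
      acc[[paste0(path, ".b")]] <<- q$b
    } else if (is.list(q)) {
      nm <- names(q)
      for (i in seq_along(q))
        rec(q[[i]], paste0(path, ".", if (!is.null(nm)) nm[i] else i))
    }
  }
  rec(p, "p")
  acc
}
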