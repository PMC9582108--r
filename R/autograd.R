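#' @useDynLib asunet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Minimal reverse-mode automatic differentiation.
#
# A node is an environment holding $value (numeric array), $grad (accumulated
# cotangent, same shape), $parents (list of nodes), $backfn (function mapping
# the node's grad to a list of parent grads, NULL entries allowed) and
# $needs_grad. Leaves created with requires_grad = TRUE are the trainable
# parameters; everything else is tape-internal. Ops are written so that they
# also accept plain arrays (inference mode, no tape, no activation retention).

.ag_counter <- new.env(parent = emptyenv())
.ag_counter$n <- 0L

ag_leaf <- function(value, requires_grad = FALSE) {
  e <- new.env(parent = emptyenv())
  .ag_counter$n <- .ag_counter$n + 1L
  e$id <- .ag_counter$n
  e$value <- value
  e$grad <- NULL
  e$parents <- list()
  e$backfn <- NULL
  e$needs_grad <- requires_grad
  e$requires_grad <- requires_grad
  class(e) <- "ag_node"
  e
}

ag_op <- function(value, parents, backfn) {
  e <- ag_leaf(value)
  e$parents <- parents
  e$needs_grad <- any(vapply(parents, function(p) p$needs_grad, logical(1)))
  if (e$needs_grad) e$backfn <- backfn
  e
}

is_ag <- function(x) inherits(x, "ag_node")
ag_value <- function(x) if (is_ag(x)) x$value else x

ag_accumulate <- function(node, g) {
  if (!node$needs_grad) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Reverse pass from a scalar root. Topological order by iterative DFS.
ag_backward <- function(root) {
  stopifnot(is_ag(root), length(root$value) == 1L)
  topo <- vector("list", 256L)
  ntopo <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nd <- fr$node
    key <- as.character(nd$id)
    if (fr$stage == 1L) {
      if (!is.null(seen[[key]]) || !nd$needs_grad) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = nd, stage = 2L)
      for (p in nd$parents)
        if (p$needs_grad && is.null(seen[[as.character(p$id)]]))
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
    } else {
      ntopo <- ntopo + 1L
      if (ntopo > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[ntopo]] <- nd
    }
  }
  root$grad <- 1
  # DFS post-order gives children after parents were pushed; reverse order is
  # a valid topological order from the root down.
  for (i in seq_len(ntopo)) {
    nd <- topo[[ntopo - i + 1L]]
    if (is.null(nd$backfn) || is.null(nd$grad)) next
    gs <- nd$backfn(nd$grad)
    for (j in seq_along(nd$parents)) {
      if (!is.null(gs[[j]])) ag_accumulate(nd$parents[[j]], gs[[j]])
    }
    if (!nd$requires_grad) nd$grad <- NULL  # free tape memory early
  }
  invisible(root)
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}
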