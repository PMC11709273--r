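# Tape-based reverse-mode automatic differentiation over base-R matrices.
#
# Every value on the tape is a numeric matrix (scalars are 1x1). Nodes are
# environments carrying the value, the parent nodes, and a backward function
# that maps the gradient at the node to gradients at its parents. This is the
# machinery behind all trainable components: the omics extractors, the
# low-rank fusion, the projector, the generators, the diagnosis head, and the
# differentiable density losses of the knowledge-transfer layer.

.ad <- new.env(parent = emptyenv())
.ad$id <- 0L

ad_node <- function(value, parents = list(), backfn = NULL,
                    requires = NULL) {
  if (is.null(requires)) {
    requires <- length(parents) > 0L &&
      any(vapply(parents, function(p) p$requires, logical(1)))
  }
  .ad$id <- .ad$id + 1L
  n <- new.env(parent = emptyenv())
  n$id <- .ad$id
  n$value <- value
  n$parents <- parents
  n$backfn <- backfn
  n$requires <- requires
  n$grad <- NULL
  class(n) <- "ad_node"
  n
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

#' @noRd
ad_input <- function(value, requires = FALSE) {
  ad_node(as_mat(value), requires = requires)
}

as_node <- function(x) {
  if (inherits(x, "ad_node")) x else ad_input(x)
}

ad_value <- function(x) {
  if (inherits(x, "ad_node")) x$value else as_mat(x)
}

# Detach from the tape: value flows, gradient does not.
ad_detach <- function(x) ad_input(ad_value(x), requires = FALSE)

# --- backward pass ---------------------------------------------------------

# Accumulate gradients of `loss` (a 1x1 node) into every reachable node with
# requires = TRUE; returns invisibly the list of visited nodes.
ad_backward <- function(loss) {
  stopifnot(inherits(loss, "ad_node"), length(loss$value) == 1L)
  # collect the subgraph that requires grad, in topological (id) order
  seen <- new.env(parent = emptyenv())
  stack <- list(loss)
  nodes <- list()
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (!is.null(seen[[key]]) || !n$requires) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- n
    for (p in n$parents) stack[[length(stack) + 1L]] <- p
  }
  if (!length(nodes)) return(invisible(list()))
  ord <- order(vapply(nodes, function(n) n$id, integer(1)), decreasing = TRUE)
  nodes <- nodes[ord]
  for (n in nodes) n$grad <- NULL
  loss$grad <- matrix(1, 1L, 1L)
  for (n in nodes) {
    if (is.null(n$grad) || is.null(n$backfn)) next
    pg <- n$backfn(n$grad, n)
    for (i in seq_along(n$parents)) {
      p <- n$parents[[i]]
      if (!p$requires || is.null(pg[[i]])) next
      p$grad <- if (is.null(p$grad)) pg[[i]] else p$grad + pg[[i]]
    }
  }
  invisible(nodes)
}

# Gradient of a scalar loss node with respect to a (nested) list of parameter
# nodes; returns a structure of matrices matching `params` (zeros where the
# loss does not reach a parameter).
ad_grad <- function(loss, params) {
  # clear any gradients left by a previous backward pass over a shared graph
  rapply(params, function(p) { p$grad <- NULL; NULL },
         classes = "ad_node", how = "unlist")
  ad_backward(loss)
  rapply(params, function(p) {
    if (is.null(p$grad)) array(0, dim(p$value)) else p$grad
  }, classes = "ad_node", how = "replace")
}

# --- primitive operations --------------------------------------------------

ad_matmul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  ad_node(a$value %*% b$value, list(a, b), function(g, n) {
    list(g %*% t(b$value), t(a$value) %*% g)
  })
}

# Addition; `b` may be a 1 x k bias row broadcast over the rows of `a`.
ad_add <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  va <- a$value; vb <- b$value
  if (nrow(vb) == 1L && nrow(va) > 1L && ncol(vb) == ncol(va)) {
    val <- va + matrix(vb, nrow(va), ncol(va), byrow = TRUE)
    ad_node(val, list(a, b), function(g, n) {
      list(g, matrix(colSums(g), 1L))
    })
  } else {
    stopifnot(all(dim(va) == dim(vb)))
    ad_node(va + vb, list(a, b), function(g, n) list(g, g))
  }
}

ad_sub <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  stopifnot(all(dim(a$value) == dim(b$value)))
  ad_node(a$value - b$value, list(a, b), function(g, n) list(g, -g))
}

# Elementwise product; shapes equal, or one operand a 1x1 scalar node.
ad_mul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  va <- a$value; vb <- b$value
  if (length(vb) == 1L) {
    ad_node(va * vb[1L], list(a, b), function(g, n) {
      list(g * vb[1L], matrix(sum(g * va), 1L, 1L))
    })
  } else if (length(va) == 1L) {
    ad_node(vb * va[1L], list(a, b), function(g, n) {
      list(matrix(sum(g * vb), 1L, 1L), g * va[1L])
    })
  } else {
    stopifnot(all(dim(va) == dim(vb)))
    ad_node(va * vb, list(a, b), function(g, n) list(g * vb, g * va))
  }
}

# Division by a positive 1x1 scalar node.
ad_div <- function(a, s) {
  a <- as_node(a); s <- as_node(s)
  stopifnot(length(s$value) == 1L)
  sv <- s$value[1L]
  ad_node(a$value / sv, list(a, s), function(g, n) {
    list(g / sv, matrix(-sum(g * a$value) / sv^2, 1L, 1L))
  })
}

# Multiply / add by a plain numeric constant (kept off the tape).
ad_scale <- function(a, k) {
  a <- as_node(a)
  ad_node(a$value * k, list(a), function(g, n) list(g * k))
}

ad_cadd <- function(a, k) {
  a <- as_node(a)
  ad_node(a$value + k, list(a), function(g, n) list(g))
}

# Elementwise product with a constant matrix (masks, kernel weights).
ad_cmul <- function(a, k) {
  a <- as_node(a)
  k <- as_mat(k)
  stopifnot(all(dim(k) == dim(a$value)))
  ad_node(a$value * k, list(a), function(g, n) list(g * k))
}

ad_exp <- function(a) {
  a <- as_node(a)
  v <- exp(a$value)
  ad_node(v, list(a), function(g, n) list(g * v))
}

ad_log <- function(a, eps = 0) {
  a <- as_node(a)
  ad_node(log(a$value + eps), list(a), function(g, n) list(g / (a$value + eps)))
}

ad_sqrt <- function(a) {
  a <- as_node(a)
  v <- sqrt(a$value)
  ad_node(v, list(a), function(g, n) list(g / (2 * v)))
}

ad_square <- function(a) {
  a <- as_node(a)
  ad_node(a$value^2, list(a), function(g, n) list(2 * a$value * g))
}

ad_tanh <- function(a) {
  a <- as_node(a)
  v <- tanh(a$value)
  ad_node(v, list(a), function(g, n) list(g * (1 - v^2)))
}

ad_sigmoid <- function(a) {
  a <- as_node(a)
  v <- 1 / (1 + exp(-a$value))
  ad_node(v, list(a), function(g, n) list(g * v * (1 - v)))
}

ad_sum <- function(a) {
  a <- as_node(a)
  ad_node(matrix(sum(a$value), 1L, 1L), list(a), function(g, n) {
    list(array(g[1L], dim(a$value)))
  })
}

ad_mean <- function(a) {
  a <- as_node(a)
  k <- length(a$value)
  ad_node(matrix(mean(a$value), 1L, 1L), list(a), function(g, n) {
    list(array(g[1L] / k, dim(a$value)))
  })
}

ad_rowsums <- function(a) {
  a <- as_node(a)
  k <- ncol(a$value)
  ad_node(matrix(rowSums(a$value), ncol = 1L), list(a), function(g, n) {
    list(matrix(g, nrow(a$value), k))
  })
}

ad_colsums <- function(a) {
  a <- as_node(a)
  r <- nrow(a$value)
  ad_node(matrix(colSums(a$value), 1L), list(a), function(g, n) {
    list(matrix(g, r, ncol(a$value), byrow = TRUE))
  })
}

ad_t <- function(a) {
  a <- as_node(a)
  ad_node(t(a$value), list(a), function(g, n) list(t(g)))
}

ad_cbind <- function(nodes) {
  nodes <- lapply(nodes, as_node)
  widths <- vapply(nodes, function(n) ncol(n$value), integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(do.call(cbind, lapply(nodes, function(n) n$value)), nodes,
          function(g, n) {
            lapply(seq_along(starts), function(i) {
              g[, starts[i]:ends[i], drop = FALSE]
            })
          })
}

ad_rbind <- function(nodes) {
  nodes <- lapply(nodes, as_node)
  hts <- vapply(nodes, function(n) nrow(n$value), integer(1))
  ends <- cumsum(hts)
  starts <- ends - hts + 1L
  ad_node(do.call(rbind, lapply(nodes, function(n) n$value)), nodes,
          function(g, n) {
            lapply(seq_along(starts), function(i) {
              g[starts[i]:ends[i], , drop = FALSE]
            })
          })
}

ad_cols <- function(a, idx) {
  a <- as_node(a)
  ad_node(a$value[, idx, drop = FALSE], list(a), function(g, n) {
    out <- array(0, dim(a$value))
    out[, idx] <- out[, idx] + g
    list(out)
  })
}

ad_rows <- function(a, idx) {
  a <- as_node(a)
  ad_node(a$value[idx, , drop = FALSE], list(a), function(g, n) {
    out <- array(0, dim(a$value))
    out[idx, ] <- out[idx, ] + g
    list(out)
  })
}

# Divide each row of a (n x k) by the matching entry of a column node (n x 1).
ad_divcol <- function(a, c) {
  a <- as_node(a); c <- as_node(c)
  cv <- as.vector(c$value)
  stopifnot(nrow(a$value) == length(cv))
  v <- a$value / cv
  ad_node(v, list(a, c), function(g, n) {
    list(g / cv, matrix(-rowSums(g * a$value) / cv^2, ncol = 1L))
  })
}

# D[g, i] = grid[g] - z[i] for a fixed grid and a column node z (n x 1);
# the difference table under the Gaussian kernel of the density losses.
ad_outer_diff <- function(grid, z) {
  z <- as_node(z)
  zv <- as.vector(z$value)
  G <- length(grid)
  v <- matrix(grid, G, length(zv)) - matrix(zv, G, length(zv), byrow = TRUE)
  ad_node(v, list(z), function(g, n) {
    list(matrix(-colSums(g), ncol = 1L))
  })
}

# Dropout with an externally drawn keep-mask (deterministic given the mask).
ad_dropout <- function(a, keep_mask, p) {
  ad_cmul(a, keep_mask / (1 - p))
}

# Class-weighted softmax cross-entropy, mean over the batch:
#   (1/n) sum_i w_i * (-log softmax(logits_i)[y_i])
# Fused into one op for numerical stability.
ad_weighted_ce <- function(logits, y, w) {
  logits <- as_node(logits)
  L <- logits$value
  n <- nrow(L)
  stopifnot(length(y) == n, length(w) == n)
  M <- apply(L, 1L, max)
  E <- exp(L - M)
  P <- E / rowSums(E)
  ll <- log(P[cbind(seq_len(n), y)])
  val <- matrix(-mean(w * ll), 1L, 1L)
  ad_node(val, list(logits), function(g, nd) {
    G <- P
    G[cbind(seq_len(n), y)] <- G[cbind(seq_len(n), y)] - 1
    list(G * (w / n) * g[1L])
  })
}
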