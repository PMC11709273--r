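# Feedforward building blocks and parameter bookkeeping.
#
# Parameters live in nested named lists of `ad_node` leaves so the same
# structure serves the forward pass, gradient collection, SGD/Adam updates,
# and the inner/outer loops of the meta learner.

# Glorot (variance-scaled) initialization; caller controls the RNG state.
init_linear <- function(d_in, d_out) {
  sd <- sqrt(2 / (d_in + d_out))
  list(
    W = ad_input(matrix(stats::rnorm(d_in * d_out, sd = sd), d_in, d_out),
                 requires = TRUE),
    b = ad_input(matrix(0, 1L, d_out), requires = TRUE)
  )
}

# Two-layer MLP parameter block d_in -> hidden -> d_out.
init_mlp <- function(d_in, hidden, d_out) {
  list(l1 = init_linear(d_in, hidden), l2 = init_linear(hidden, d_out))
}

apply_activation <- function(x, activation) {
  switch(activation,
    tanh = ad_tanh(x),
    sigmoid = ad_sigmoid(x),
    identity = x,
    stop("unknown activation: ", activation)
  )
}

# Forward through a two-layer MLP. Dropout (between the layers) is applied
# only when `training` and uses the supplied RNG stream for its keep-mask.
mlp_forward <- function(mlp, x, activation = "tanh", out_activation = "identity",
                        dropout = 0, training = FALSE) {
  h <- apply_activation(ad_add(ad_matmul(x, mlp$l1$W), mlp$l1$b), activation)
  if (training && dropout > 0) {
    keep <- matrix(stats::rbinom(length(ad_value(h)), 1L, 1 - dropout),
                   nrow(ad_value(h)))
    h <- ad_dropout(h, keep, dropout)
  }
  apply_activation(ad_add(ad_matmul(h, mlp$l2$W), mlp$l2$b), out_activation)
}

# --- nested-parameter utilities -------------------------------------------

# Flatten a nested parameter list into a flat named list of nodes.
flatten_params <- function(params, prefix = NULL) {
  out <- list()
  for (nm in names(params)) {
    p <- params[[nm]]
    key <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
    if (inherits(p, "ad_node")) {
      out[[key]] <- p
    } else {
      out <- c(out, flatten_params(p, key))
    }
  }
  out
}

# Deep copy of a parameter tree (fresh leaf nodes, same values).
clone_params <- function(params) {
  rapply(params, function(p) ad_input(p$value, requires = TRUE),
         classes = "ad_node", how = "replace")
}

# params - rate * grads, returning a fresh parameter tree. `grads` is the
# matrix-structure returned by ad_grad().
sgd_update <- function(params, grads, rate) {
  walk2 <- function(p, g) {
    if (inherits(p, "ad_node")) {
      v <- p$value - rate * g
      dimnames(v) <- dimnames(p$value)
      ad_input(v, requires = TRUE)
    } else {
      out <- p
      for (nm in names(p)) out[[nm]] <- walk2(p[[nm]], g[[nm]])
      out
    }
  }
  walk2(params, grads)
}

# Sum two gradient trees (same structure of plain matrices).
add_grads <- function(g1, g2) {
  if (is.null(g1)) return(g2)
  if (is.matrix(g1)) return(g1 + g2)
  out <- g1
  for (nm in names(g1)) out[[nm]] <- add_grads(g1[[nm]], g2[[nm]])
  out
}

zero_grads_like <- function(params) {
  rapply(params, function(p) array(0, dim(p$value)),
         classes = "ad_node", how = "replace")
}

# --- Adam ------------------------------------------------------------------

adam_state <- function(params) {
  list(
    m = zero_grads_like(params),
    v = zero_grads_like(params),
    t = 0L
  )
}

# In-place-style Adam step: mutates the node values of `params`, returns the
# updated optimizer state.
adam_step <- function(params, grads, state, rate = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  fp <- flatten_params(params)
  fg <- flatten_grads(grads)
  fm <- flatten_grads(state$m)
  fv <- flatten_grads(state$v)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (key in names(fp)) {
    g <- fg[[key]]
    m <- beta1 * fm[[key]] + (1 - beta1) * g
    v <- beta2 * fv[[key]] + (1 - beta2) * g^2
    fm[[key]] <- m
    fv[[key]] <- v
    fp[[key]]$value <- fp[[key]]$value -
      rate * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  state$m <- unflatten_like(fm, state$m)
  state$v <- unflatten_like(fv, state$v)
  state
}

flatten_grads <- function(grads, prefix = NULL) {
  out <- list()
  for (nm in names(grads)) {
    g <- grads[[nm]]
    key <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
    if (is.matrix(g) || is.array(g)) out[[key]] <- g
    else out <- c(out, flatten_grads(g, key))
  }
  out
}

unflatten_like <- function(flat, template, prefix = NULL) {
  out <- template
  for (nm in names(template)) {
    key <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
    if (is.matrix(template[[nm]]) || is.array(template[[nm]])) {
      out[[nm]] <- flat[[key]]
    } else {
      out[[nm]] <- unflatten_like(flat, template[[nm]], key)
    }
  }
  out
}

# Scale a gradient tree so its global L2 norm does not exceed max_norm.
clip_grads <- function(grads, max_norm) {
  fg <- flatten_grads(grads)
  total <- sqrt(sum(vapply(fg, function(g) sum(g^2), numeric(1))))
  if (!is.finite(total) || total <= max_norm) return(grads)
  rapply(grads, function(g) g * (max_norm / total),
         classes = c("matrix", "array"), how = "replace")
}

# Maximum absolute entry over a gradient tree (routing assertions).
max_abs_grad <- function(grads) {
  fg <- flatten_grads(grads)
  if (!length(fg)) return(0)
  max(vapply(fg, function(g) max(abs(g)), numeric(1)))
}
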