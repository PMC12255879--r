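# Neural-network layer primitives on top of the autodiff tape: parameter
# initialisation, linear/MLP layers, masked 1-D (dilated) convolution, GRU
# cell, and the Adam optimizer with plateau learning-rate decay.

# Glorot-uniform initial weights, deterministic under the caller's RNG state
init_weight <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

init_linear <- function(n_in, n_out) {
  list(W = init_weight(n_in, n_out), b = matrix(0, 1L, n_out))
}

init_gru <- function(n_in, n_h) {
  list(
    Wz = init_weight(n_in, n_h), Uz = init_weight(n_h, n_h), bz = matrix(0, 1L, n_h),
    Wr = init_weight(n_in, n_h), Ur = init_weight(n_h, n_h), br = matrix(0, 1L, n_h),
    Wh = init_weight(n_in, n_h), Uh = init_weight(n_h, n_h), bh = matrix(0, 1L, n_h)
  )
}

# Bind a (possibly nested) list of parameter matrices onto a tape; returns a
# parallel structure of node ids. Leaf = numeric matrix.
bind_params <- function(tp, params) {
  rapply(params, function(x) ad_leaf(tp, x), classes = "matrix", how = "replace")
}

# Harvest gradients for a bound parameter structure after ad_backward
collect_grads <- function(tp, bound) {
  rapply(bound, function(i) ad_grad(tp, i), classes = "integer", how = "replace")
}

nn_linear <- function(tp, x, lin) {
  ad_bias(tp, ad_mm(tp, x, lin$W), lin$b)
}

# two-layer MLP with ReLU hidden activation
nn_mlp2 <- function(tp, x, l1, l2) {
  nn_linear(tp, ad_relu(tp, nn_linear(tp, x, l1)), l2)
}

# GRU cell: h' = (1-z) * h + z * htilde
nn_gru <- function(tp, x, h, g) {
  z <- ad_sigmoid(tp, ad_bias(tp, ad_add(tp, ad_mm(tp, x, g$Wz), ad_mm(tp, h, g$Uz)), g$bz))
  r <- ad_sigmoid(tp, ad_bias(tp, ad_add(tp, ad_mm(tp, x, g$Wr), ad_mm(tp, h, g$Ur)), g$br))
  rh <- ad_mul(tp, r, h)
  ht <- ad_tanh(tp, ad_bias(tp, ad_add(tp, ad_mm(tp, x, g$Wh), ad_mm(tp, rh, g$Uh)), g$bh))
  omz <- ad_addc(tp, ad_scale(tp, z, -1), 1)
  ad_add(tp, ad_mul(tp, omz, h), ad_mul(tp, z, ht))
}

# Masked 1-D convolution, kernel size 3, given dilation. x is L x D on the
# tape; mask a logical vector of valid positions. Positions outside the valid
# range contribute zeros (same semantics as zero padding to L_max), and output
# rows at masked positions are zeroed, so the result is independent of how
# much trailing padding the caller kept.
nn_conv1d_dilated <- function(tp, x, mask, lin3, dilation = 1L) {
  L <- nrow(ad_value(tp, x))
  allv <- all(mask)
  pos <- seq_len(L)
  left <- pos - dilation
  right <- pos + dilation
  left[left < 1L | left > L] <- 0L
  right[right > L | right < 1L] <- 0L
  if (!allv) {
    left[left != 0L & !mask[pmax(left, 1L)]] <- 0L
    right[right != 0L & !mask[pmax(right, 1L)]] <- 0L
  }
  xl <- ad_gather(tp, x, left)
  xr <- ad_gather(tp, x, right)
  h <- ad_bias(tp, ad_add(tp, ad_add(tp, ad_mm(tp, xl, lin3$Wl), ad_mm(tp, x, lin3$Wc)),
                          ad_mm(tp, xr, lin3$Wr)), lin3$b)
  h <- ad_relu(tp, h)
  if (allv) h else ad_mulc(tp, h, matrix(as.numeric(mask), L, ncol(ad_value(tp, h))))
}

init_conv1d <- function(n_in, n_out) {
  list(Wl = init_weight(n_in, n_out), Wc = init_weight(n_in, n_out),
       Wr = init_weight(n_in, n_out), b = matrix(0, 1L, n_out))
}

# ---- Adam ------------------------------------------------------------------

# state for a flat list of parameter matrices (nested lists allowed)
adam_init <- function(params) {
  list(
    m = rapply(params, function(x) array(0, dim(x)), classes = "matrix", how = "replace"),
    v = rapply(params, function(x) array(0, dim(x)), classes = "matrix", how = "replace"),
    t = 0L
  )
}

# one Adam step; params and grads share structure. Returns list(params, state).
adam_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  tt <- state$t
  walk <- function(p, g, m, v) {
    if (is.matrix(p)) {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g * g
      mhat <- m2 / (1 - beta1^tt)
      vhat <- v2 / (1 - beta2^tt)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m2, v = v2)
    } else {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"),
           m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    }
  }
  res <- walk(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = tt))
}

# elementwise sum of two parameter structures (gradient accumulation)
grad_add <- function(a, b) {
  if (is.matrix(a)) return(a + b)
  Map(grad_add, a, b)
}

grad_scale_tree <- function(a, s) {
  rapply(a, function(x) x * s, classes = c("matrix", "array"), how = "replace")
}
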