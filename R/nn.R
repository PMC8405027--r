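# Layer-level plumbing shared by the teacher and student networks: double-conv
# blocks with ReLU, parameter trees, gradient accumulation and Adam. All
# feature maps are arrays dim c(H, W, C); compiled kernels do the heavy work.

relu <- function(x) x * (x > 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# two 3x3 convolutions with fused ReLUs; the C++ side caches im2col matrices
# and activation masks for the backward pass
block_forward <- function(x, p) {
  nn_block_forward(x, p$W1, p$b1, p$W2, p$b2)
}

block_backward <- function(cache, p, d_out) {
  g <- nn_block_backward(cache$cache, p$W1, p$W2, d_out)
  list(
    dx = g$dx,
    grads = list(W1 = g$dW1, b1 = as.numeric(g$db1),
                 W2 = g$dW2, b2 = as.numeric(g$db2))
  )
}

# He-normal initialisation, biases at zero
init_conv3 <- function(cin, cout) {
  list(W = matrix(rnorm(9 * cin * cout, sd = sqrt(2 / (9 * cin))),
                  9 * cin, cout))
}

init_block <- function(cin, cout) {
  list(
    W1 = init_conv3(cin, cout)$W, b1 = numeric(cout),
    W2 = init_conv3(cout, cout)$W, b2 = numeric(cout)
  )
}

init_upconv <- function(cin, cout) {
  list(Wu = matrix(rnorm(cin * 4 * cout, sd = sqrt(2 / cin)), cin, 4 * cout),
       bu = numeric(cout))
}

concat_channels <- function(a, b) {
  array(c(a, b), dim = c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
}

# ---- parameter-tree utilities -----------------------------------------------

tree_zero <- function(p) {
  if (is.list(p)) lapply(p, tree_zero) else p * 0
}

tree_add <- function(a, b) {
  if (is.list(a)) {
    for (i in seq_along(a)) a[[i]] <- tree_add(a[[i]], b[[i]])
    a
  } else {
    a + b
  }
}

tree_scale <- function(a, s) {
  if (is.list(a)) lapply(a, tree_scale, s = s) else a * s
}

adam_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

adam_walk <- function(p, g, m, v, lr, b1, b2, eps, t) {
  if (is.list(p)) {
    for (i in seq_along(p)) {
      r <- adam_walk(p[[i]], g[[i]], m[[i]], v[[i]], lr, b1, b2, eps, t)
      p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
    }
    list(p = p, m = m, v = v)
  } else {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    p <- p - lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps)
    list(p = p, m = m, v = v)
  }
}

adam_step <- function(params, grads, state, lr,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  r <- adam_walk(params, grads, state$m, state$v, lr, b1, b2, eps, state$t)
  state$m <- r$m
  state$v <- r$v
  list(params = r$p, state = state)
}
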