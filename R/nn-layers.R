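# 2-D convolutional network primitives with exact backprop.
#
# Activations are stored as (positions * batch) x channels matrices, rows
# position-major within each sample (row = p + (b-1)*P, position index
# column-major over the H x W grid). Convolutions are evaluated by im2col
# gather (compiled) + one BLAS matrix multiply; 'same' padding puts the
# extra pad row/col at the bottom/right for even kernels. Max pooling
# uses non-overlapping 2x2 regions with floor division, clamped to one
# region when a dimension is already 1; ties route to the first cell.
# All gradients are verified against finite differences in the tests.

conv_geom <- function(H, W, kh, kw) {
  ph <- (kh - 1L) %/% 2L
  pw <- (kw - 1L) %/% 2L
  P <- H * W
  K <- kh * kw
  idx <- matrix(0L, P, K)
  for (w_ in seq_len(W)) for (h_ in seq_len(H)) {
    p <- h_ + (w_ - 1L) * H
    k <- 0L
    for (dw in seq_len(kw)) for (dh in seq_len(kh)) {
      k <- k + 1L
      oh <- h_ + dh - 1L - ph
      ow <- w_ + dw - 1L - pw
      idx[p, k] <- if (oh >= 1L && oh <= H && ow >= 1L && ow <= W)
        oh + (ow - 1L) * H else 0L
    }
  }
  list(H = H, W = W, kh = kh, kw = kw, P = P, K = K, idx = idx)
}

conv_forward <- function(X, geom, Wmat, bias, B) {
  Xcol <- cpp_im2col(X, geom$idx, B)
  Y <- Xcol %*% Wmat
  Y <- Y + rep(bias, each = nrow(Y))
  list(Y = Y, Xcol = Xcol)
}

conv_backward <- function(dY, Xcol, geom, Wmat, Cin, B) {
  dXcol <- tcrossprod(dY, Wmat)
  list(dW = crossprod(Xcol, dY),
       db = colSums(dY),
       dX = cpp_col2im_add(dXcol, geom$idx, B, Cin))
}

pool_geom <- function(H, W) {
  oh <- max(1L, H %/% 2L)
  ow <- max(1L, W %/% 2L)
  rh <- if (H >= 2L) 2L else 1L
  rw <- if (W >= 2L) 2L else 1L
  G <- matrix(0L, oh * ow, rh * rw)
  for (j in seq_len(ow)) for (i in seq_len(oh)) {
    po <- i + (j - 1L) * oh
    r <- 0L
    for (dw in seq_len(rw)) for (dh in seq_len(rh)) {
      r <- r + 1L
      hi <- if (rh == 2L) 2L * (i - 1L) + dh else 1L
      wi <- if (rw == 2L) 2L * (j - 1L) + dw else 1L
      G[po, r] <- hi + (wi - 1L) * H
    }
  }
  list(H_out = oh, W_out = ow, P_out = oh * ow, P_in = H * W, G = G)
}

pool_forward <- function(X, pg, B) {
  cpp_pool_forward(X, pg$G, B, pg$P_in)
}

pool_backward <- function(dY, Arg, P_in, B) {
  cpp_pool_backward(dY, Arg, P_in, B)
}

bn_forward <- function(X, gamma, beta, running, training, momentum, eps) {
  if (training) {
    f <- cpp_bn_forward_train(X, gamma, beta, eps)
    running$mean <- momentum * running$mean + (1 - momentum) * f$mu
    v <- 1 / f$inv_sd^2 - eps
    running$var <- momentum * running$var + (1 - momentum) * v
    list(Y = f$Y, X = X, mu = f$mu, inv_sd = f$inv_sd,
         running = running, training = TRUE)
  } else {
    inv_sd <- 1 / sqrt(running$var + eps)
    a <- gamma * inv_sd
    list(Y = cpp_colwise_affine(X, a, beta - running$mean * a),
         a = a, running = running, training = FALSE)
  }
}

bn_backward <- function(dY, cache, gamma) {
  if (cache$training) {
    b <- cpp_bn_backward_train(dY, cache$X, cache$mu, cache$inv_sd, gamma)
    list(dX = b$dX, dgamma = b$dgamma, dbeta = b$dbeta)
  } else {
    list(dX = cpp_colwise_affine(dY, cache$a, numeric(length(cache$a))),
         dgamma = NULL, dbeta = NULL)
  }
}

flatten_act <- function(X, P, B) {
  C <- ncol(X)
  matrix(aperm(array(X, c(P, B, C)), c(2L, 1L, 3L)), B, P * C)
}

unflatten_act <- function(dF, P, B) {
  C <- ncol(dF) / P
  matrix(aperm(array(dF, c(B, P, C)), c(2L, 1L, 3L)), P * B, C)
}

glorot_uniform <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1, beta2, eps) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
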