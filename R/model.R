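# Per-subject CNN classifier: two convolutional blocks (conv 3x3/32 and
# conv 2x2/64, each ReLU -> batch-norm -> max-pool 2x2), a 64-unit dense
# layer, 50% dropout, and a sigmoid output giving the next-day event
# probability. Trained with Adam on binary cross-entropy, batch size 32,
# 50 epochs, no early stopping and no validation split.

#' CNN architecture and training hyperparameters
#'
#' Defaults are the reference architecture: 32 3x3 filters then 64 2x2
#' filters (ReLU, batch normalization, 2x2 max pooling after each), a
#' 64-unit ReLU dense layer, dropout 0.5, a single sigmoid output; Adam
#' (learning rate 1e-3), batch size 32, 50 epochs, binary cross-entropy.
#' Convolutions use same-size padding and pooling uses floor division
#' clamped to 1, so both 7- and 14-day windows are admissible.
#'
#' @param conv1_filters,conv1_kernel First convolution: filters, kernel.
#' @param conv2_filters,conv2_kernel Second convolution: filters, kernel.
#' @param dense_units Units in the dense hidden layer.
#' @param dropout Dropout rate applied after the dense hidden layer,
#'   active in training mode only.
#' @param epochs,batch_size Training schedule.
#' @param lr,beta1,beta2,adam_eps Adam optimizer constants.
#' @param bn_momentum,bn_eps Batch-normalization running-average momentum
#'   and variance epsilon.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(conv1_filters = 32L, conv1_kernel = c(3L, 3L),
                       conv2_filters = 64L, conv2_kernel = c(2L, 2L),
                       dense_units = 64L, dropout = 0.5,
                       epochs = 50L, batch_size = 32L,
                       lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                       adam_eps = 1e-8,
                       bn_momentum = 0.9, bn_eps = 1e-3) {
  assert_prob(dropout, "dropout")
  stopifnot(epochs >= 1, batch_size >= 1)
  structure(list(conv1_filters = as.integer(conv1_filters),
                 conv1_kernel = as.integer(conv1_kernel),
                 conv2_filters = as.integer(conv2_filters),
                 conv2_kernel = as.integer(conv2_kernel),
                 dense_units = as.integer(dense_units),
                 dropout = dropout,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr = lr, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps,
                 bn_momentum = bn_momentum, bn_eps = bn_eps),
            class = "model_spec")
}

#' Build an (untrained) per-subject CNN
#'
#' Lays out the network geometry for a given input shape and initializes
#' weights (Glorot uniform, biases zero, batch-norm gamma 1 / beta 0).
#' With same-size convolution padding and clamped floor pooling, an 8 x 7
#' input flattens to 128 units and an 8 x 14 input to 384 units before
#' the dense layer.
#'
#' @param input_shape Integer pair `(n_features, w)`.
#' @param spec A `model_spec`.
#' @param seed Optional seed pinning the weight initialization.
#' @return An object of class `cnn_model` (untrained).
#' @export
build_model <- function(input_shape, spec = model_spec(), seed = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  H <- as.integer(input_shape[1])
  W <- as.integer(input_shape[2])
  if (H < 1) stop_bc("input layer: n_features dimension < 1")
  if (W < 1) stop_bc("input layer: window dimension < 1")
  if (!H %in% c(8L, 9L) || !W %in% c(7L, 14L))
    warning(sprintf(
      "input shape %dx%d outside the standard 8/9 features x 7/14 days",
      H, W), call. = FALSE)
  cg1 <- conv_geom(H, W, spec$conv1_kernel[1], spec$conv1_kernel[2])
  pg1 <- pool_geom(H, W)
  if (pg1$P_out < 1) stop_bc("pool1: output dimension < 1")
  cg2 <- conv_geom(pg1$H_out, pg1$W_out,
                   spec$conv2_kernel[1], spec$conv2_kernel[2])
  pg2 <- pool_geom(pg1$H_out, pg1$W_out)
  if (pg2$P_out < 1) stop_bc("pool2: output dimension < 1")
  F1 <- spec$conv1_filters
  F2 <- spec$conv2_filters
  D <- spec$dense_units
  flat <- pg2$P_out * F2
  init <- function() {
    params <- list(
      W1 = glorot_uniform(cg1$K, F1, cg1$K, cg1$K * F1),
      b1 = numeric(F1), g1 = rep(1, F1), be1 = numeric(F1),
      W2 = glorot_uniform(cg2$K * F1, F2, cg2$K * F1, cg2$K * F2),
      b2 = numeric(F2), g2 = rep(1, F2), be2 = numeric(F2),
      W3 = glorot_uniform(flat, D, flat, D),
      b3 = numeric(D),
      W4 = glorot_uniform(D, 1, D, 1),
      b4 = 0)
    params
  }
  params <- if (is.null(seed)) init() else with_seed(seed, init())
  running <- list(bn1 = list(mean = numeric(F1), var = rep(1, F1)),
                  bn2 = list(mean = numeric(F2), var = rep(1, F2)))
  structure(list(spec = spec,
                 input_shape = c(H, W),
                 geom = list(cg1 = cg1, pg1 = pg1, cg2 = cg2, pg2 = pg2,
                             flat = flat),
                 params = params,
                 running = running,
                 n_params = sum(vapply(params, length, 0L)),
                 trained = FALSE,
                 training_log = NULL,
                 feature_names = NULL),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  g <- x$geom
  cat(sprintf("CNN %dx%d -> conv %dx%d/%d -> pool %dx%d -> conv %dx%d/%d -> pool %dx%d -> dense %d -> 1\n",
              x$input_shape[1], x$input_shape[2],
              x$spec$conv1_kernel[1], x$spec$conv1_kernel[2],
              x$spec$conv1_filters, g$pg1$H_out, g$pg1$W_out,
              x$spec$conv2_kernel[1], x$spec$conv2_kernel[2],
              x$spec$conv2_filters, g$pg2$H_out, g$pg2$W_out,
              x$spec$dense_units))
  cat(sprintf("%d trainable parameters; %s\n", x$n_params,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# ---- forward / backward ----------------------------------------------

# First-layer activations A (post-ReLU conv1), the maps Grad-CAM targets.
conv1_activation <- function(model, X1, B) {
  c1 <- conv_forward(X1, model$geom$cg1, model$params$W1,
                     model$params$b1, B)
  list(A = pmax(c1$Y, 0), Z1 = c1$Y, Xcol1 = c1$Xcol)
}

# Everything after the first ReLU: bn1 -> pool1 -> conv2 -> relu -> bn2
# -> pool2 -> flatten -> dense -> relu -> dropout -> logit.
head_forward <- function(model, A, B, training = FALSE,
                         running = model$running) {
  sp <- model$spec
  g <- model$geom
  p <- model$params
  bn1 <- bn_forward(A, p$g1, p$be1, running$bn1, training,
                    sp$bn_momentum, sp$bn_eps)
  pl1 <- pool_forward(bn1$Y, g$pg1, B)
  c2 <- conv_forward(pl1$Y, g$cg2, p$W2, p$b2, B)
  A2 <- pmax(c2$Y, 0)
  bn2 <- bn_forward(A2, p$g2, p$be2, running$bn2, training,
                    sp$bn_momentum, sp$bn_eps)
  pl2 <- pool_forward(bn2$Y, g$pg2, B)
  Fl <- flatten_act(pl2$Y, g$pg2$P_out, B)
  Z3 <- Fl %*% p$W3 + rep(p$b3, each = B)
  H3 <- pmax(Z3, 0)
  if (training && sp$dropout > 0) {
    mask <- matrix((stats::runif(length(H3)) >= sp$dropout) /
                     (1 - sp$dropout), nrow(H3), ncol(H3))
    Hd <- H3 * mask
  } else {
    mask <- NULL
    Hd <- H3
  }
  logit <- drop(Hd %*% p$W4) + p$b4
  list(logit = logit, prob = stats::plogis(logit),
       cache = list(bn1 = bn1, pl1 = pl1, c2 = c2, A2 = A2,
                    bn2 = bn2, pl2 = pl2, Fl = Fl, Z3 = Z3, Hd = Hd,
                    mask = mask, B = B),
       running = list(bn1 = bn1$running, bn2 = bn2$running))
}

# Backprop from d(logit) to the head parameters and to the first-layer
# activations A (needed both for training and for Grad-CAM).
head_backward <- function(model, dlogit, cache) {
  g <- model$geom
  p <- model$params
  B <- cache$B
  dlogit <- matrix(dlogit, B, 1)
  dW4 <- crossprod(cache$Hd, dlogit)
  db4 <- sum(dlogit)
  dHd <- tcrossprod(dlogit, p$W4)
  if (!is.null(cache$mask)) dHd <- dHd * cache$mask
  dZ3 <- dHd * (cache$Z3 > 0)
  dW3 <- crossprod(cache$Fl, dZ3)
  db3 <- colSums(dZ3)
  dFl <- tcrossprod(dZ3, p$W3)
  dP2 <- unflatten_act(dFl, g$pg2$P_out, B)
  dBn2 <- pool_backward(dP2, cache$pl2$Arg, g$pg2$P_in, B)
  b2b <- bn_backward(dBn2, cache$bn2, p$g2)
  dZ2 <- b2b$dX * (cache$c2$Y > 0)
  c2b <- conv_backward(dZ2, cache$c2$Xcol, g$cg2, p$W2,
                       ncol(cache$pl1$Y), B)
  dBn1 <- pool_backward(c2b$dX, cache$pl1$Arg, g$pg1$P_in, B)
  b1b <- bn_backward(dBn1, cache$bn1, p$g1)
  list(grads = list(W2 = c2b$dW, b2 = c2b$db,
                    g2 = b2b$dgamma, be2 = b2b$dbeta,
                    W3 = dW3, b3 = db3, W4 = dW4, b4 = db4,
                    g1 = b1b$dgamma, be1 = b1b$dbeta),
       dA = b1b$dX)
}

nn_forward <- function(model, X1, B, training = FALSE,
                       running = model$running) {
  a <- conv1_activation(model, X1, B)
  h <- head_forward(model, a$A, B, training, running)
  list(logit = h$logit, prob = h$prob, conv1 = a, head = h$cache,
       running = h$running)
}

nn_backward <- function(model, dlogit, fwd) {
  hb <- head_backward(model, dlogit, fwd$head)
  dZ1 <- hb$dA * (fwd$conv1$Z1 > 0)
  c1b <- conv_backward(dZ1, fwd$conv1$Xcol1, model$geom$cg1,
                       model$params$W1, 1L, fwd$head$B)
  c(hb$grads, list(W1 = c1b$dW, b1 = c1b$db))
}

windows_to_input <- function(x, H, W) {
  # (H, W, B) array -> (H*W*B) x 1 matrix, rows position-major per sample
  matrix(as.double(x), H * W * dim(x)[3], 1)
}

as_window_array <- function(windows) {
  if (inherits(windows, "window_set")) return(windows$x)
  if (is.list(windows) && !is.null(windows$x))
    return(as_window_array(windows$x))
  if (is.matrix(windows)) return(array(windows, c(dim(windows), 1L)))
  if (is.array(windows) && length(dim(windows)) == 3L) return(windows)
  stop_bc("'windows' must be a window_set, a matrix, or a 3-d array")
}

#' Train a per-subject CNN on windowed samples
#'
#' Trains for exactly `spec$epochs` epochs (no early stopping, no
#' validation split) with Adam on binary cross-entropy, logging the mean
#' training loss per epoch. A single-class training set still trains
#' (the loss is well defined) but records a degenerate-class warning.
#'
#' @param train A `window_set` (or list with `x`: features x w x n array
#'   and `y`: 0/1 labels).
#' @param spec A `model_spec`.
#' @param seed Seed pinning initialization, shuffling and dropout; same
#'   seed and platform reproduce the fit.
#' @return A trained `cnn_model` with `training_log` (per-epoch loss).
#' @export
train_subject_model <- function(train, spec = model_spec(), seed = 1L) {
  x <- as_window_array(train)
  y <- if (inherits(train, "window_set")) train$y else train$y
  n <- dim(x)[3]
  if (is.null(y) || n == 0 || length(y) == 0)
    stop_bc("empty training set")
  if (length(y) != n) stop_bc("label count does not match window count")
  if (!is_binary(y)) stop_bc("labels must be binary")
  y <- as.integer(y)
  degenerate <- length(unique(y)) < 2L
  if (degenerate)
    warning("single-class training labels: model trains but cannot learn a decision boundary",
            call. = FALSE)
  H <- dim(x)[1]; W <- dim(x)[2]
  sp <- spec
  with_seed(seed, {
    model <- build_model(c(H, W), sp, seed = NULL)
    g <- model$geom
    geom_list <- list(idx1 = g$cg1$idx, idx2 = g$cg2$idx,
                      G1 = g$pg1$G, G2 = g$pg2$G,
                      P1 = g$pg1$P_in, P2 = g$pg2$P_in,
                      P3 = g$pg2$P_out)
    hp <- list(dropout = sp$dropout, lr = sp$lr, beta1 = sp$beta1,
               beta2 = sp$beta2, adam_eps = sp$adam_eps,
               bn_momentum = sp$bn_momentum, bn_eps = sp$bn_eps)
    # cpp_train_step mutates these in place, batch by batch
    params <- model$params
    running <- model$running
    adam <- adam_init(params)
    log_loss <- numeric(sp$epochs)
    for (ep in seq_len(sp$epochs)) {
      perm <- sample.int(n)
      tot <- 0
      for (start in seq(1L, n, by = sp$batch_size)) {
        idx <- perm[start:min(start + sp$batch_size - 1L, n)]
        B <- length(idx)
        X1 <- windows_to_input(x[, , idx, drop = FALSE], H, W)
        tot <- tot + cpp_train_step(params, adam, running, X1,
                                    as.double(y[idx]), geom_list, B, hp)
      }
      log_loss[ep] <- tot / n
    }
    model$params <- params
    model$running <- running
    model$trained <- TRUE
    model$training_log <- log_loss
    model$degenerate_class <- degenerate
    model$seed <- seed
    if (inherits(train, "window_set"))
      model$feature_names <- train$feature_names
    model
  })
}

#' Predict next-day event probabilities
#'
#' Runs the network in inference mode (dropout disabled, batch-norm
#' running statistics), so repeated calls on the same input are
#' identical.
#'
#' @param model A `cnn_model`.
#' @param windows A `window_set`, a single features x w matrix, or a
#'   features x w x n array; shape must match `model$input_shape`.
#' @return Numeric vector of probabilities in (0, 1), one per window.
#' @export
predict_proba <- function(model, windows) {
  stopifnot(inherits(model, "cnn_model"))
  x <- as_window_array(windows)
  if (!all(dim(x)[1:2] == model$input_shape))
    stop_bc(sprintf("window shape %dx%d does not match model input %dx%d",
                    dim(x)[1], dim(x)[2],
                    model$input_shape[1], model$input_shape[2]))
  B <- dim(x)[3]
  X1 <- windows_to_input(x, dim(x)[1], dim(x)[2])
  fwd <- nn_forward(model, X1, B, training = FALSE)
  unname(fwd$prob)
}
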