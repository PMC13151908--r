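# CNN construction, shape contract, training behavior and prediction.

test_that("layer shapes and parameter counts follow the architecture contract", {
  for (shape in list(c(8L, 7L), c(9L, 7L), c(8L, 14L), c(9L, 14L))) {
    m <- build_model(shape, model_spec(), seed = 1)
    pd <- pool_dims_oracle(shape[1], shape[2])
    expect_identical(c(m$geom$pg2$H_out, m$geom$pg2$W_out), pd)
    flat <- 64L * pd[1] * pd[2]
    expect_identical(m$geom$flat, flat)
    # parameter count oracle: conv + bn + dense layers
    n_oracle <- (3 * 3 * 1 * 32 + 32) + 2 * 32 +
      (2 * 2 * 32 * 64 + 64) + 2 * 64 +
      (flat * 64 + 64) + (64 + 1)
    expect_identical(m$n_params, as.integer(n_oracle))
  }
  m7 <- build_model(c(8, 7), model_spec(), seed = 1)
  expect_identical(m7$geom$flat, 128L)
  m14 <- build_model(c(8, 14), model_spec(), seed = 1)
  expect_identical(m14$geom$flat, 384L)
  expect_error(build_model(c(0, 7)), "n_features")
  expect_warning(build_model(c(5, 6), model_spec()), "outside the standard")
})

test_that("mismatched window shapes are rejected at prediction", {
  m <- build_model(c(8, 7), model_spec(), seed = 1)
  expect_error(predict_proba(m, matrix(0, 8, 14)), "does not match")
  expect_error(predict_proba(m, matrix(0, 9, 7)), "does not match")
})

test_that("zeroed output layer yields probability exactly 0.5", {
  m <- build_model(c(8, 7), model_spec(), seed = 2)
  m$params$W4[] <- 0
  m$params$b4 <- 0
  w <- matrix(rbinom(56, 1, .5), 8, 7)
  expect_identical(predict_proba(m, w), 0.5)
})

test_that("inference is deterministic (dropout off) and training is seed-reproducible", {
  set.seed(3)
  x <- array(rbinom(8 * 7 * 30, 1, .4), c(8, 7, 30))
  y <- rbinom(30, 1, .5)
  sp <- model_spec(epochs = 3)
  m1 <- train_subject_model(list(x = x, y = y), sp, seed = 42)
  m2 <- train_subject_model(list(x = x, y = y), sp, seed = 42)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$training_log, m2$training_log)
  q <- array(rbinom(8 * 7 * 5, 1, .4), c(8, 7, 5))
  expect_identical(predict_proba(m1, q), predict_proba(m1, q))
  expect_equal(predict_proba(m1, q), predict_proba(m2, q))
})

test_that("a separable two-point problem is learned perfectly in 50 epochs", {
  tr <- separable_windows(20)
  m <- train_subject_model(tr, model_spec(), seed = 7)
  probs <- predict_proba(m, tr$x)
  expect_identical(as.integer(probs >= .5), tr$y)
  expect_gt(min(probs[tr$y == 1]), 0.5)
  expect_lt(max(probs[tr$y == 0]), 0.5)
  # loss decreases over training on learnable data
  expect_lt(mean(tail(m$training_log, 5)), mean(head(m$training_log, 5)))
  expect_lt(m$training_log[length(m$training_log)], m$training_log[1])
})

test_that("labels independent of repeated windows cannot beat the conditional-entropy bound", {
  set.seed(11)
  # three distinct patterns, many repeats: memorization is impossible
  pats <- lapply(1:3, function(i) matrix(rbinom(56, 1, .5), 8, 7))
  n <- 60
  which_pat <- sample(1:3, n, replace = TRUE)
  x <- array(0L, c(8, 7, n))
  for (i in seq_len(n)) x[, , i] <- pats[[which_pat[i]]]
  y <- rbinom(n, 1, .5)
  ent <- function(p) ifelse(p %in% c(0, 1), 0,
                            -p * log(p) - (1 - p) * log(1 - p))
  bound <- mean(vapply(1:3, function(k) {
    idx <- which_pat == k
    sum(idx) * ent(mean(y[idx]))
  }, numeric(1))) * 3 / n
  m <- train_subject_model(list(x = x, y = y), model_spec(epochs = 25),
                           seed = 5)
  expect_gte(tail(m$training_log, 1), bound - 0.05)
})

test_that("degenerate training inputs are handled as specified", {
  expect_error(train_subject_model(list(x = array(0, c(8, 7, 0)),
                                        y = integer()),
                                   model_spec(epochs = 1)), "empty")
  x <- array(rbinom(8 * 7 * 10, 1, .5), c(8, 7, 10))
  expect_warning(
    m <- train_subject_model(list(x = x, y = rep(1L, 10)),
                             model_spec(epochs = 2), seed = 1),
    "single-class")
  expect_true(m$degenerate_class)
  expect_true(all(is.finite(m$training_log)))
})

test_that("fused training step agrees with the per-layer reference path", {
  set.seed(5)
  H <- 9L; W <- 7L; B <- 16L
  sp <- model_spec()
  model <- build_model(c(H, W), sp, seed = 3)
  x <- array(rbinom(H * W * B, 1, .35), c(H, W, B))
  y <- rbinom(B, 1, .5)
  X1 <- behavcast:::windows_to_input(x, H, W)

  set.seed(99)
  fwd <- behavcast:::nn_forward(model, X1, B, training = TRUE)
  pr <- pmin(pmax(fwd$prob, 1e-7), 1 - 1e-7)
  loss_r <- -sum(y * log(pr) + (1 - y) * log(1 - pr))
  grads <- behavcast:::nn_backward(model, (fwd$prob - y) / B, fwd)
  upd <- behavcast:::adam_step(model$params, grads,
                               behavcast:::adam_init(model$params),
                               sp$lr, sp$beta1, sp$beta2, sp$adam_eps)

  set.seed(99)
  params <- lapply(model$params, identity)
  running <- lapply(model$running, identity)
  adam <- behavcast:::adam_init(params)
  g <- model$geom
  geom_list <- list(idx1 = g$cg1$idx, idx2 = g$cg2$idx, G1 = g$pg1$G,
                    G2 = g$pg2$G, P1 = g$pg1$P_in, P2 = g$pg2$P_in,
                    P3 = g$pg2$P_out)
  hp <- list(dropout = sp$dropout, lr = sp$lr, beta1 = sp$beta1,
             beta2 = sp$beta2, adam_eps = sp$adam_eps,
             bn_momentum = sp$bn_momentum, bn_eps = sp$bn_eps)
  loss_c <- behavcast:::cpp_train_step(params, adam, running, X1,
                                       as.double(y), geom_list, B, hp)
  expect_equal(loss_c, loss_r, tolerance = 1e-12)
  for (nm in names(upd$params))
    expect_equal(params[[nm]], upd$params[[nm]], tolerance = 1e-12,
                 label = nm, ignore_attr = TRUE)
  expect_equal(running$bn1$mean, fwd$running$bn1$mean, tolerance = 1e-12)
  expect_equal(running$bn2$var, fwd$running$bn2$var, tolerance = 1e-12)
})
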