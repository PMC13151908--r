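# First-layer Grad-CAM attribution. The class score is the pre-sigmoid
# logit of the positive class (c = 1); its gradient is taken with respect
# to the post-ReLU feature maps A^k of the first convolutional layer.
# Neuron weights alpha_k average those gradients over the map, and the
# heatmap is ReLU(sum_k alpha_k A^k). With same-size convolution padding
# the first-layer maps align one-to-one with input cells, so the heatmap
# lives directly on the (feature x day-offset) grid and needs no
# upsampling.

#' First-layer Grad-CAM heatmap for one window
#'
#' @param model A trained `cnn_model`.
#' @param window A features x w binary matrix matching the model input.
#' @param class_sign `+1` (default) attributes the positive class;
#'   `-1` flips the class score, exactly negating the pre-ReLU map.
#' @return An `importance_map`: a non-negative features x w matrix whose
#'   columns are day offsets `-w ... -1`.
#' @export
gradcam_first_layer <- function(model, window, class_sign = 1) {
  stopifnot(inherits(model, "cnn_model"))
  window <- as.matrix(window)
  if (!all(dim(window) == model$input_shape))
    stop_bc(sprintf("window shape %dx%d does not match model input %dx%d",
                    nrow(window), ncol(window),
                    model$input_shape[1], model$input_shape[2]))
  H <- model$input_shape[1]; W <- model$input_shape[2]
  if (H * W < 1) stop_bc("zero-size feature maps")
  X1 <- matrix(as.double(window), H * W, 1)
  a <- conv1_activation(model, X1, 1L)
  h <- head_forward(model, a$A, 1L, training = FALSE)
  hb <- head_backward(model, class_sign, h$cache)
  alpha <- colMeans(hb$dA)                 # (1/Z) sum_ij dY/dA_ij
  L <- matrix(pmax(drop(a$A %*% alpha), 0), H, W)
  new_importance_map(L, model$feature_names %||% rownames(window), W)
}

new_importance_map <- function(L, feature_names, w) {
  dimnames(L) <- list(feature = feature_names %||%
                        paste0("f", seq_len(nrow(L))),
                      day = sprintf("Day %d", seq(-w, -1)))
  structure(L, class = c("importance_map", "matrix"))
}

#' Aggregate Grad-CAM maps over windows and subjects
#'
#' Cell-wise mean of a list of same-shape heatmaps. With
#' `normalize = TRUE` (default) each map is divided by its maximum first
#' (all-zero maps are left as-is), so subjects with larger logits do not
#' dominate the cohort picture. The aggregate carries a feature ranking
#' (descending row sums) and per-day-offset feature orderings.
#'
#' @param maps Non-empty list of `importance_map`s of identical shape.
#' @param normalize Max-normalize each map before averaging.
#' @return An `importance_map` with attributes `feature_ranking`
#'   (feature names, most important first) and `per_day_ranking` (list of
#'   orderings, one per day offset).
#' @export
aggregate_importance <- function(maps, normalize = TRUE) {
  if (!length(maps)) stop_bc("empty list of importance maps")
  d <- dim(maps[[1]])
  if (!all(vapply(maps, function(m) all(dim(m) == d), logical(1))))
    stop_bc("all importance maps must have the same shape")
  if (normalize)
    maps <- lapply(maps, function(m) {
      mx <- max(m)
      if (mx > 0) m / mx else m
    })
  agg <- Reduce(`+`, maps) / length(maps)
  agg <- structure(as.matrix(agg), dimnames = dimnames(maps[[1]]),
                   class = c("importance_map", "matrix"))
  feats <- rownames(agg)
  attr(agg, "feature_ranking") <- feats[order(rowSums(agg),
                                              decreasing = TRUE)]
  attr(agg, "per_day_ranking") <- apply(agg, 2, function(col)
    feats[order(col, decreasing = TRUE)], simplify = FALSE)
  agg
}

#' @export
print.importance_map <- function(x, ...) {
  cat("Grad-CAM importance map (", nrow(x), "features x", ncol(x),
      "day offsets )\n")
  print(round(unclass(x), 4))
  rk <- attr(x, "feature_ranking")
  if (!is.null(rk))
    cat("feature ranking:", paste(rk, collapse = " > "), "\n")
  invisible(x)
}
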