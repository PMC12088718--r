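#' Model configuration for the attention MIL classifier
#'
#' The classifier embeds each slice of a 36-instance bag with a shared
#' convolutional encoder, adds a positional encoding of the in-bag index,
#' contextualizes the instances with one multi-head self-attention block
#' (pre-norm, residual, layer normalization), pools them with gated
#' attention into a bag embedding, and scores it with a dense sigmoid head.
#'
#' @param backbone `"small_cnn"` (default; 4 conv blocks, each 3x3 conv +
#'   ReLU + 2x2 mean pool, then global average pooling and a dense
#'   projection) or `"vgg16_style"` (a VGG16 convolutional stack whose
#'   weights may be supplied externally).
#' @param frozen_layers Number of leading backbone stages (sequential
#'   numbering, pooling layers included) excluded from gradient updates.
#'   Defaults: 0 for `small_cnn`, 15 for `vgg16_style`.
#' @param embed_dim Instance embedding width (divisible by `n_heads`).
#' @param n_heads Attention heads (default 4).
#' @param dropout Dropout rate on the bag embedding before the head.
#' @param l2 L2 penalty coefficient on weight matrices.
#' @param bag_size Instances per bag (default 36).
#' @param input_size Slice side length fed to the encoder (or `c(h, w)`);
#'   must be divisible by 2^(number of pooling stages).
#' @param positional_encoding `"sinusoidal"` (parameter-free sin/cos of the
#'   in-bag index, added to the embeddings) or `"none"`.
#' @param conv_channels Channel widths of the `small_cnn` blocks.
#' @param attention_dim Hidden width of the gated attention scorer.
#' @param global_pool Spatial pooling after the conv stack: `"max"`
#'   (default; suits detection of small localized structures) or
#'   `"mean"`. The pooled vector is projected to `embed_dim` and
#'   layer-normalized so instance content and positional encoding share a
#'   common scale.
#' @return An object of class `milcta_model_config`.
#' @export
model_config <- function(backbone = c("small_cnn", "vgg16_style"),
                         frozen_layers = NULL, embed_dim = 128L,
                         n_heads = 4L, dropout = 0.2, l2 = 1e-4,
                         bag_size = 36L, input_size = 32L,
                         positional_encoding = c("sinusoidal", "none"),
                         conv_channels = c(4L, 8L, 16L, 32L),
                         attention_dim = 64L,
                         global_pool = c("max", "mean")) {
  backbone <- match.arg(backbone)
  positional_encoding <- match.arg(positional_encoding)
  global_pool <- match.arg(global_pool)
  if (is.null(frozen_layers))
    frozen_layers <- if (backbone == "vgg16_style") 15L else 0L
  if (embed_dim %% n_heads != 0)
    abort("embed_dim must be divisible by n_heads")
  if (dropout < 0 || dropout >= 1) abort("dropout must lie in [0, 1)")
  if (length(input_size) == 1L) input_size <- rep(input_size, 2L)
  n_pools <- if (backbone == "small_cnn") length(conv_channels) else 5L
  if (any(input_size %% 2L^n_pools != 0))
    abort(sprintf("input_size must be divisible by %d", 2L^n_pools))
  structure(list(backbone = backbone, frozen_layers = as.integer(frozen_layers),
                 embed_dim = as.integer(embed_dim), n_heads = as.integer(n_heads),
                 dropout = dropout, l2 = l2, bag_size = as.integer(bag_size),
                 input_size = as.integer(input_size),
                 positional_encoding = positional_encoding,
                 conv_channels = as.integer(conv_channels),
                 attention_dim = as.integer(attention_dim),
                 global_pool = global_pool),
            class = "milcta_model_config")
}

#' Training configuration
#'
#' Defaults follow the reference training recipe: binary cross-entropy,
#' Adam at learning rate 1e-4, early stopping with patience 7,
#' learning-rate reduction on plateau (factor 0.2, patience 5), class
#' weighting, and zoom/shift-only augmentation. Rotation is structurally
#' unsupported: it would scramble what the positional encoding represents.
#'
#' @param lr Initial Adam learning rate.
#' @param max_epochs Upper bound on epochs.
#' @param batch_bags Bags per gradient step.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping (best weights are restored).
#' @param plateau_factor,plateau_patience Learning-rate decay on plateau.
#' @param class_weighting Apply balanced inverse-frequency class weights.
#' @param zoom_range,shift_range Augmentation amplitudes (fractions).
#' @param rotation_range Must be 0; any other value is rejected.
#' @param aux_weight Weight of the max-instance auxiliary loss that speeds
#'   up from-scratch encoder training (0 disables it; a pretrained frozen
#'   backbone does not need it). Inference always uses the attention path.
#' @param att_consistency Weight of the attention-evidence consistency
#'   term: the attention distribution of positive bags is pulled toward
#'   the (stop-gradient) softmax of the instance-head logits, so the
#'   interpretable attention tracks instance-level evidence even after
#'   the bag loss saturates. 0 (default) disables it.
#' @param warmup_epochs Slice-level encoder warm-up epochs before bag
#'   training: each training slice inherits its patient's weak label and
#'   the encoder plus instance head are trained on these noisy slice
#'   labels. This plays the role transfer learning plays when a pretrained
#'   backbone is available; 0 (the fine-tuning default) skips it.
#' @param warmup_batch Slices per warm-up gradient step.
#' @param seed Seed for initialization, shuffling, augmentation, dropout.
#' @return An object of class `milcta_train_config`.
#' @export
train_config <- function(lr = 1e-4, max_epochs = 50L, batch_bags = 8L,
                         early_stop_patience = 7L, plateau_factor = 0.2,
                         plateau_patience = 5L, class_weighting = TRUE,
                         zoom_range = 0.1, shift_range = 0.1,
                         rotation_range = 0, aux_weight = 1,
                         att_consistency = 0,
                         warmup_epochs = 0L, warmup_batch = 96L, seed = 1L) {
  if (!identical(as.numeric(rotation_range), 0))
    abort("rotation augmentation is not supported: it would corrupt the positional encoding")
  structure(list(lr = lr, loss = "binary_crossentropy", optimizer = "adam",
                 max_epochs = as.integer(max_epochs),
                 batch_bags = as.integer(batch_bags),
                 early_stop_patience = as.integer(early_stop_patience),
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 class_weighting = isTRUE(class_weighting),
                 zoom_range = zoom_range, shift_range = shift_range,
                 rotation_range = 0, aux_weight = aux_weight,
                 att_consistency = att_consistency,
                 warmup_epochs = as.integer(warmup_epochs),
                 warmup_batch = as.integer(warmup_batch),
                 seed = as.integer(seed)),
            class = "milcta_train_config")
}

#' Initialize an attention MIL model
#'
#' @param config A [model_config()].
#' @param seed Seed for weight initialization.
#' @return An object of class `milcta_model` (configuration, parameter
#'   list, backbone plan, frozen-parameter names, positional encoding).
#' @export
mil_init <- function(config = model_config(), seed = 1L) {
  plan <- backbone_plan(config)
  E <- config$embed_dim
  params <- list()
  layer_of <- integer()
  with_seed(seed, {
    cin <- 1L
    for (st in plan) {
      if (st$op != "conv") next
      nm <- paste0("conv", st$layer_index)
      params[[paste0(nm, "_W")]] <- matrix(
        rnorm(9 * cin * st$out, 0, sqrt(2 / (9 * cin))), 9 * cin, st$out)
      params[[paste0(nm, "_b")]] <- numeric(st$out)
      layer_of[paste0(nm, "_W")] <- st$layer_index
      layer_of[paste0(nm, "_b")] <- st$layer_index
      cin <- st$out
    }
    xav <- function(n_in, n_out)
      matrix(runif(n_in * n_out, -1, 1) * sqrt(6 / (n_in + n_out)), n_in, n_out)
    params$embed_W <- xav(cin, E)
    params$embed_b <- numeric(E)
    params$ln0_g <- rep(1, E); params$ln0_b <- numeric(E)
    params$ln1_g <- rep(1, E); params$ln1_b <- numeric(E)
    for (nm in c("Wq", "Wk", "Wv"))
      params[[paste0("attn_", nm)]] <- xav(E, E)
    # zero-init output projection: the attention block starts as the
    # identity (residual passthrough), so instance content is not scrambled
    # before the encoder has learned anything
    params$attn_Wo <- matrix(0, E, E)
    for (nm in c("bq", "bk", "bv", "bo"))
      params[[paste0("attn_", nm)]] <- numeric(E)
    params$ln2_g <- rep(1, E); params$ln2_b <- numeric(E)
    A <- config$attention_dim
    params$pool_V <- xav(E, A); params$pool_bv <- numeric(A)
    params$pool_U <- xav(E, A); params$pool_bu <- numeric(A)
    params$pool_w <- as.numeric(xav(A, 1L))
    params$head_w <- as.numeric(xav(E, 1L))
    params$head_b <- 0
    params$inst_w <- as.numeric(xav(E, 1L))   # max-instance auxiliary head
    params$inst_b <- 0
  })
  frozen <- names(layer_of)[layer_of <= config$frozen_layers]
  structure(list(config = config, params = params, plan = plan,
                 frozen = frozen,
                 pe = sinusoidal_pe(config$bag_size, E)),
            class = "milcta_model")
}

#' @export
print.milcta_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<milcta_model> %s backbone, embed %d, %d heads, %d parameters (%d frozen tensors)\n",
              x$config$backbone, x$config$embed_dim, x$config$n_heads,
              np, length(x$frozen)))
  invisible(x)
}

# Coerce a bag (array h x w x S or list of matrices) to the pixel-matrix
# layout expected by the encoder.
bag_to_stack <- function(bag_x, config) {
  if (is.list(bag_x)) bag_x <- simplify2array(bag_x)
  d <- dim(bag_x)
  if (length(d) != 3L || d[3] != config$bag_size)
    abort(sprintf("a bag must hold exactly %d slices", config$bag_size))
  if (d[1] != config$input_size[1] || d[2] != config$input_size[2])
    abort("slice size does not match the model's input_size")
  matrix(as.numeric(bag_x), ncol = 1L)
}

#' Embed the slices of a bag
#'
#' Applies the shared convolutional encoder independently to each slice.
#'
#' @param model A `milcta_model`.
#' @param bag_x Array `h x w x bag_size` (or list of matrices).
#' @return A `bag_size x embed_dim` feature matrix.
#' @export
embed_slices <- function(model, bag_x) {
  X <- bag_to_stack(bag_x, model$config)
  backbone_fwd(model, X, model$config$bag_size)
}

#' Add the positional encoding to instance features
#'
#' Sinusoidal mode adds the standard sin/cos encoding of the in-bag
#' position (0-based); `"none"` is the identity.
#'
#' @param model A `milcta_model`.
#' @param features `bag_size x embed_dim` matrix.
#' @return Matrix of the same shape.
#' @export
add_positional_encoding <- function(model, features) {
  if (model$config$positional_encoding == "none") return(features)
  features + model$pe[seq_len(nrow(features)), , drop = FALSE]
}

#' Contextualize instance features with multi-head self-attention
#'
#' One pre-norm block: layer norm, scaled dot-product attention with
#' `n_heads` heads, output projection, residual connection, and a final
#' layer norm. Shape is preserved.
#'
#' @param model A `milcta_model`.
#' @param features `bag_size x embed_dim` matrix (already positionally
#'   encoded if desired).
#' @return `bag_size x embed_dim` contextualized features.
#' @export
multi_head_attention <- function(model, features) {
  p <- model$params; cfg <- model$config
  E <- cfg$embed_dim; N <- nrow(features)
  Xn <- ln_fwd(features, p$ln1_g, p$ln1_b)$Y
  Q <- Xn %*% p$attn_Wq + rep(p$attn_bq, each = N)
  K <- Xn %*% p$attn_Wk + rep(p$attn_bk, each = N)
  V <- Xn %*% p$attn_Wv + rep(p$attn_bv, each = N)
  nh <- cfg$n_heads; dh <- E %/% nh
  Ocat <- matrix(0, N, E)
  for (h in seq_len(nh)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    A <- softmax_rows(Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) /
                        sqrt(dh))
    Ocat[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  O <- Ocat %*% p$attn_Wo + rep(p$attn_bo, each = N)
  ln_fwd(features + O, p$ln2_g, p$ln2_b)$Y
}

#' Gated attention pooling
#'
#' Scores each instance with `w . (tanh(V h) * sigmoid(U h))`, normalizes
#' the scores with a softmax, and returns the attention-weighted bag
#' embedding together with the attention vector (sums to 1).
#'
#' @param model A `milcta_model`.
#' @param contextualized `bag_size x embed_dim` matrix.
#' @return List with `bag_embedding` (length `embed_dim`) and `attention`
#'   (length `bag_size`, non-negative, sums to 1).
#' @export
attention_pool <- function(model, contextualized) {
  p <- model$params; N <- nrow(contextualized)
  Tm <- tanh(contextualized %*% p$pool_V + rep(p$pool_bv, each = N))
  Ug <- sigmoid(contextualized %*% p$pool_U + rep(p$pool_bu, each = N))
  s <- as.numeric((Tm * Ug) %*% p$pool_w)
  a <- exp(s - max(s)); a <- a / sum(a)
  list(bag_embedding = as.numeric(a %*% contextualized), attention = a)
}

#' Predict a single bag
#'
#' Runs the full model in evaluation mode (dropout disabled; repeated
#' calls are deterministic).
#'
#' @param model A `milcta_model`.
#' @param bag_x Array `h x w x bag_size` (or list of matrices).
#' @return An object of class `milcta_bag_prediction`: list with
#'   `bag_prob` in \[0, 1\] and `attention` (length `bag_size`, sums to 1).
#' @export
predict_bag <- function(model, bag_x) {
  X <- bag_to_stack(bag_x, model$config)
  fw <- mil_forward(model, X, 1L, train = FALSE)
  structure(list(bag_prob = fw$prob[1], attention = as.numeric(fw$attention)),
            class = "milcta_bag_prediction")
}

#' Patient-level prediction from all of a patient's bags
#'
#' The patient probability is the maximum over bag probabilities. The
#' per-slice case attention assigns each original slice the maximum
#' attention over all of its occurrences (replicated entries included),
#' renormalized to sum to 1 across the case, so replication cannot inflate
#' a slice's apparent importance.
#'
#' @param model A `milcta_model`.
#' @param bags A bag tibble for one patient ([make_bags()] /
#'   [cohort_bags()] rows) whose `entries` index planes of `x`.
#' @param x Array `h x w x n_slices` of processed slices.
#' @return An object of class `milcta_case_prediction`: list with
#'   `patient_prob`, `case_attention` (named by slice reference, sums to
#'   1), `bag_probs` and `best_bag` (0-based index of the maximal bag).
#' @export
predict_patient <- function(model, bags, x) {
  if (nrow(bags) == 0) abort("predict_patient needs at least one bag")
  probs <- numeric(nrow(bags))
  att_by_slice <- list()
  for (i in seq_len(nrow(bags))) {
    entries <- bags$entries[[i]]
    pr <- predict_bag(model, x[, , entries, drop = FALSE])
    probs[i] <- pr$bag_prob
    for (j in seq_along(entries)) {
      key <- as.character(entries[j])
      att_by_slice[[key]] <- max(att_by_slice[[key]] %||% 0, pr$attention[j])
    }
  }
  att <- unlist(att_by_slice)
  att <- att / sum(att)
  structure(list(patient_prob = max(probs),
                 case_attention = att,
                 bag_probs = probs,
                 best_bag = bags$bag_index[which.max(probs)]),
            class = "milcta_case_prediction")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Balanced inverse-frequency class weights
#'
#' `w_c = N / (2 * N_c)`; a balanced sample yields weight 1 for both
#' classes.
#'
#' @param labels Vector of 0/1 labels containing both classes.
#' @return Named numeric vector `c("0" = w_neg, "1" = w_pos)`.
#' @export
compute_class_weights <- function(labels) {
  n0 <- sum(labels == 0); n1 <- sum(labels == 1)
  if (n0 == 0 || n1 == 0) abort("both classes must be present")
  n <- n0 + n1
  c("0" = n / (2 * n0), "1" = n / (2 * n1))
}

#' Augment a bag with zoom and shift
#'
#' Each slice is independently zoomed by a factor in
#' `[1 - zoom_range, 1 + zoom_range]` and translated by up to
#' `shift_range` of its size (bilinear resampling, zero fill). Slice order
#' is never altered and no rotation path exists. Uses the current RNG.
#'
#' @param bag_x Array `h x w x bag_size`.
#' @param config A [train_config()].
#' @return Augmented array of identical shape.
#' @export
augment_bag <- function(bag_x, config) {
  stopifnot(identical(config$rotation_range, 0))
  d <- dim(bag_x)
  if (config$zoom_range == 0 && config$shift_range == 0) return(bag_x)
  n <- d[3]
  zoom <- runif(n, 1 - config$zoom_range, 1 + config$zoom_range)
  dx <- runif(n, -config$shift_range, config$shift_range) * d[2]
  dy <- runif(n, -config$shift_range, config$shift_range) * d[1]
  out <- warp_stack(as.numeric(bag_x), d[1], d[2], n, zoom, dx, dy)
  array(out, d)
}
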