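# Independent brute-force oracles used across test files.

# Direct 3x3 Sobel correlation with reflect padding, normalized by 4*sqrt(2).
sobel_oracle <- function(m) {
  H <- nrow(m); W <- ncol(m)
  P <- m[c(2L, seq_len(H), H - 1L), c(2L, seq_len(W), W - 1L)]
  Kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)        # d/dx
  Ky <- t(Kx)
  out <- matrix(0, H, W)
  for (y in seq_len(H)) for (x in seq_len(W)) {
    blk <- P[y + 0:2, x + 0:2]
    out[y, x] <- sqrt(sum(blk * Kx)^2 + sum(blk * Ky)^2)
  }
  out / (4 * sqrt(2))
}

# Pairwise Mann-Whitney AUC by explicit enumeration.
auc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Confusion-matrix metrics at one threshold by direct counting.
confusion_oracle <- function(labels, probs, t) {
  pred <- probs >= t
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  list(sens = tp / (tp + fn), spec = tn / (tn + fp),
       prec = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

# A small model configuration that keeps test-time training cheap.
tiny_model_config <- function(...) {
  model_config(embed_dim = 8L, n_heads = 2L, input_size = 16L,
               conv_channels = c(2L, 2L), attention_dim = 4L, ...)
}

# Random processed-slice stack in [0, 1].
random_stack <- function(h, w, n, seed = 1) {
  set.seed(seed)
  array(runif(h * w * n), c(h, w, n))
}
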