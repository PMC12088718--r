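# Internal forward/backward engine for the MIL classifier.
#
# Image stacks use the "pixel matrix" layout of src/nn_ops.cpp: a stack of
# N (H x W) maps is an (H*W*N) x C matrix, column-major within each slice.

EPS_LN <- 1e-5

softmax_rows <- function(M) {
  e <- exp(M - apply(M, 1L, max))
  e / rowSums(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

ln_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  sig <- sqrt(rowMeans(xc^2) + EPS_LN)
  xhat <- xc / sig
  list(Y = sweep(xhat, 2L, g, `*`) + rep(b, each = nrow(X)),
       xhat = xhat, sig = sig)
}

ln_bwd <- function(dY, g, xhat, sig) {
  dxhat <- sweep(dY, 2L, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  list(dX = (dxhat - m1 - xhat * m2) / sig,
       dg = colSums(dY * xhat), db = colSums(dY))
}

# Sinusoidal positional encoding for positions 0..(n-1), dimension d.
sinusoidal_pe <- function(n, d) {
  pos <- seq_len(n) - 1
  i <- seq_len(d) - 1
  angle <- outer(pos, 10000^(-(i %/% 2 * 2) / d))
  pe <- matrix(0, n, d)
  even <- (i %% 2) == 0
  pe[, even] <- sin(angle[, even])
  pe[, !even] <- cos(angle[, !even])
  pe
}

# ---- backbone ---------------------------------------------------------------

# Stage plans: list of elements "conv" (with channels) or "pool", each with a
# sequential layer index (pooling counts, matching the freezing convention).
backbone_plan <- function(config) {
  if (config$backbone == "small_cnn") {
    ch <- config$conv_channels
    stages <- list()
    for (k in seq_along(ch)) {
      stages[[length(stages) + 1L]] <- list(op = "conv", out = ch[k])
      stages[[length(stages) + 1L]] <- list(op = "pool")
    }
  } else { # vgg16_style
    ch <- c(64, 64, NA, 128, 128, NA, 256, 256, 256, NA,
            512, 512, 512, NA, 512, 512, 512, NA)
    stages <- lapply(ch, function(c)
      if (is.na(c)) list(op = "pool") else list(op = "conv", out = c))
  }
  for (k in seq_along(stages)) stages[[k]]$layer_index <- k
  stages
}

backbone_fwd <- function(model, X, N, keep_cache = FALSE) {
  H <- model$config$input_size[1]; W <- model$config$input_size[2]
  cache <- list()
  for (st in model$plan) {
    if (st$op == "conv") {
      nm <- paste0("conv", st$layer_index)
      Y <- conv3_fwd(X, H, W, N, model$params[[paste0(nm, "_W")]],
                     model$params[[paste0(nm, "_b")]], relu = TRUE)
      if (keep_cache)
        cache[[nm]] <- list(X = X, Y = Y, H = H, W = W)
      X <- Y
    } else {
      X <- pool2_fwd(X, H, W, N)
      H <- H %/% 2L; W <- W %/% 2L
    }
  }
  hw <- H * W
  C <- ncol(X)
  if (model$config$global_pool == "mean") {
    feats <- rowsum(X, rep(seq_len(N), each = hw), reorder = FALSE) / hw
    amax <- NULL
  } else {
    feats <- matrix(0, N, C)
    amax <- matrix(0L, N, C)
    for (c in seq_len(C)) {
      m <- matrix(X[, c], hw, N)
      j <- max.col(t(m), ties.method = "first")
      amax[, c] <- j
      feats[, c] <- m[cbind(j, seq_len(N))]
    }
  }
  emb0 <- feats %*% model$params$embed_W +
    rep(model$params$embed_b, each = N)
  # normalize the content embedding so it shares the positional
  # encoding's unit scale
  l0 <- ln_fwd(emb0, model$params$ln0_g, model$params$ln0_b)
  if (keep_cache) {
    cache$gmp <- list(feats = feats, hw = hw, H = H, W = W, amax = amax,
                      C = C, l0 = l0)
    list(emb = l0$Y, cache = cache)
  } else l0$Y
}

backbone_bwd <- function(model, cache, demb, N, grads) {
  l0b <- ln_bwd(demb, model$params$ln0_g, cache$gmp$l0$xhat, cache$gmp$l0$sig)
  grads$ln0_g <- l0b$dg; grads$ln0_b <- l0b$db
  demb0 <- l0b$dX
  feats <- cache$gmp$feats
  grads$embed_W <- t(feats) %*% demb0
  grads$embed_b <- colSums(demb0)
  dfeats <- demb0 %*% t(model$params$embed_W)
  hw <- cache$gmp$hw
  if (model$config$global_pool == "mean") {
    dX <- dfeats[rep(seq_len(N), each = hw), , drop = FALSE] / hw
  } else {
    C <- cache$gmp$C
    dX <- matrix(0, hw * N, C)
    amax <- cache$gmp$amax
    off <- (seq_len(N) - 1L) * hw
    for (c in seq_len(C))
      dX[cbind(amax[, c] + off, c)] <- dfeats[, c]
  }
  H <- cache$gmp$H; W <- cache$gmp$W
  for (st in rev(model$plan)) {
    if (st$op == "pool") {
      dX <- pool2_bwd(dX, H * 2L, W * 2L, N)
      H <- H * 2L; W <- W * 2L
    } else {
      nm <- paste0("conv", st$layer_index)
      cc <- cache[[nm]]
      g <- conv3_bwd(cc$X, cc$H, cc$W, N, model$params[[paste0(nm, "_W")]],
                     dX, cc$Y)
      grads[[paste0(nm, "_W")]] <- g$dW
      grads[[paste0(nm, "_b")]] <- as.numeric(g$db)
      dX <- g$dX
    }
  }
  grads
}

# ---- transformer block + gated attention pooling ----------------------------

# Forward pass over B bags stacked as rows ((b-1)*S + s).
mil_forward <- function(model, X, B, train = FALSE, drop_mask = NULL,
                        keep_cache = FALSE) {
  cfg <- model$config
  S <- cfg$bag_size
  N <- B * S
  bk <- backbone_fwd(model, X, N, keep_cache = keep_cache)
  emb <- if (keep_cache) bk$emb else bk
  E <- cfg$embed_dim
  feats <- emb
  if (cfg$positional_encoding == "sinusoidal")
    feats <- feats + model$pe[rep(seq_len(S), B), , drop = FALSE]

  p <- model$params
  l1 <- ln_fwd(feats, p$ln1_g, p$ln1_b)
  Xn <- l1$Y
  Q <- Xn %*% p$attn_Wq + rep(p$attn_bq, each = N)
  K <- Xn %*% p$attn_Wk + rep(p$attn_bk, each = N)
  V <- Xn %*% p$attn_Wv + rep(p$attn_bv, each = N)
  nh <- cfg$n_heads; dh <- E %/% nh
  Ocat <- matrix(0, N, E)
  Amats <- if (keep_cache) vector("list", B * nh) else NULL
  for (b in seq_len(B)) {
    rows <- (b - 1L) * S + seq_len(S)
    for (h in seq_len(nh)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      A <- softmax_rows(Q[rows, cols, drop = FALSE] %*%
                          t(K[rows, cols, drop = FALSE]) / sqrt(dh))
      Ocat[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
      if (keep_cache) Amats[[(b - 1L) * nh + h]] <- A
    }
  }
  O <- Ocat %*% p$attn_Wo + rep(p$attn_bo, each = N)
  X2 <- feats + O
  l2c <- ln_fwd(X2, p$ln2_g, p$ln2_b)
  Hc <- l2c$Y

  Tm <- tanh(Hc %*% p$pool_V + rep(p$pool_bv, each = N))
  Ug <- sigmoid(Hc %*% p$pool_U + rep(p$pool_bu, each = N))
  Sc <- as.numeric((Tm * Ug) %*% p$pool_w)
  att <- matrix(0, S, B)
  embg <- matrix(0, B, E)
  for (b in seq_len(B)) {
    rows <- (b - 1L) * S + seq_len(S)
    s <- Sc[rows]
    a <- exp(s - max(s)); a <- a / sum(a)
    att[, b] <- a
    embg[b, ] <- as.numeric(a %*% Hc[rows, , drop = FALSE])
  }
  M <- if (train && cfg$dropout > 0) {
    if (is.null(drop_mask))
      drop_mask <- matrix(rbinom(B * E, 1, 1 - cfg$dropout), B, E) /
        (1 - cfg$dropout)
    drop_mask
  } else matrix(1, B, E)
  embd <- embg * M
  z <- as.numeric(embd %*% p$head_w) + p$head_b
  prob <- sigmoid(z)

  out <- list(prob = prob, attention = att)
  if (keep_cache)
    out$cache <- list(bk = bk$cache, feats = feats, l1 = l1, Xn = Xn,
                      Q = Q, K = K, V = V, A = Amats, Ocat = Ocat,
                      X2 = X2, l2 = l2c, Hc = Hc, Tm = Tm, Ug = Ug,
                      att = att, embg = embg, M = M, embd = embd, z = z,
                      B = B, N = N)
  out
}

zero_like <- function(params) lapply(params, function(p) p * 0)

# Weighted-BCE loss and full gradient for one minibatch of bags.
#
# Besides the attention-pooled bag probability (the inference path), a
# max-instance auxiliary head is trained jointly (weight `aux_weight`):
# the highest instance logit in a bag receives the bag's label directly.
# With a randomly initialized encoder the attention path spreads each
# slice's gradient across the bag (~1/bag_size at the uniform-attention
# start); the auxiliary path hands the key instance an undiluted gradient,
# which is what makes from-scratch training converge at desk scale. A
# pretrained, largely frozen backbone does not need it (aux_weight = 0).
mil_loss_grads <- function(model, X, y, B, wts, aux_weight = 1,
                           att_consistency = 0) {
  cfg <- model$config
  S <- cfg$bag_size; E <- cfg$embed_dim; N <- B * S
  fw <- mil_forward(model, X, B, train = TRUE, keep_cache = TRUE)
  ch <- fw$cache
  p <- model$params
  prob <- pmin(pmax(fw$prob, 1e-12), 1 - 1e-12)
  loss <- -mean(wts * (y * log(prob) + (1 - y) * log(1 - prob)))

  grads <- list()
  dz <- wts * (fw$prob - y) / B
  grads$head_w <- as.numeric(t(ch$embd) %*% dz)
  grads$head_b <- sum(dz)
  dembd <- outer(dz, p$head_w)
  dembg <- dembd * ch$M

  dHc <- matrix(0, N, E)

  grads$inst_w <- numeric(E); grads$inst_b <- 0
  dS_extra <- NULL
  if (aux_weight > 0 || att_consistency > 0) {
    zi <- as.numeric(ch$Hc %*% p$inst_w) + p$inst_b
  }
  if (att_consistency > 0) {
    # attention-evidence consistency: pull the attention distribution of
    # positive bags toward the (stop-gradient) softmax of the instance
    # logits, so interpretable attention tracks instance-level evidence
    # even once the bag loss has saturated
    dS_extra <- matrix(0, S, B)
    for (b in seq_len(B)) {
      if (y[b] != 1) next
      rows <- (b - 1L) * S + seq_len(S)
      tgt <- exp(zi[rows] - max(zi[rows]))
      tgt <- tgt / sum(tgt)
      a <- pmin(pmax(ch$att[, b], 1e-12), 1)
      loss <- loss - att_consistency * sum(tgt * log(a)) / B
      dS_extra[, b] <- att_consistency * (ch$att[, b] - tgt) / B
    }
  }
  if (aux_weight > 0) {
    for (b in seq_len(B)) {
      rows <- (b - 1L) * S + seq_len(S)
      k <- rows[which.max(zi[rows])]
      pa <- sigmoid(zi[k])
      pa_c <- min(max(pa, 1e-12), 1 - 1e-12)
      loss <- loss - aux_weight * wts[b] *
        (y[b] * log(pa_c) + (1 - y[b]) * log(1 - pa_c)) / B
      dzi <- aux_weight * wts[b] * (pa - y[b]) / B
      grads$inst_w <- grads$inst_w + dzi * ch$Hc[k, ]
      grads$inst_b <- grads$inst_b + dzi
      dHc[k, ] <- dHc[k, ] + dzi * p$inst_w
    }
  }
  A_dim <- length(p$pool_w)
  dV_p <- matrix(0, E, A_dim); dU_p <- matrix(0, E, A_dim)
  dbv <- numeric(A_dim); dbu <- numeric(A_dim); dw_p <- numeric(A_dim)
  for (b in seq_len(B)) {
    rows <- (b - 1L) * S + seq_len(S)
    a <- ch$att[, b]
    Hb <- ch$Hc[rows, , drop = FALSE]
    da <- as.numeric(Hb %*% dembg[b, ])
    dHc[rows, ] <- dHc[rows, ] + outer(a, dembg[b, ])
    dS <- a * (da - sum(a * da))
    if (!is.null(dS_extra)) dS <- dS + dS_extra[, b]
    TU <- ch$Tm[rows, , drop = FALSE] * ch$Ug[rows, , drop = FALSE]
    dw_p <- dw_p + as.numeric(t(TU) %*% dS)
    dTU <- outer(dS, p$pool_w)
    dpre_T <- dTU * ch$Ug[rows, ] * (1 - ch$Tm[rows, ]^2)
    dpre_U <- dTU * ch$Tm[rows, ] * ch$Ug[rows, ] * (1 - ch$Ug[rows, ])
    dV_p <- dV_p + t(Hb) %*% dpre_T
    dU_p <- dU_p + t(Hb) %*% dpre_U
    dbv <- dbv + colSums(dpre_T)
    dbu <- dbu + colSums(dpre_U)
    dHc[rows, ] <- dHc[rows, ] + dpre_T %*% t(p$pool_V) + dpre_U %*% t(p$pool_U)
  }
  grads$pool_V <- dV_p; grads$pool_U <- dU_p
  grads$pool_bv <- dbv; grads$pool_bu <- dbu; grads$pool_w <- dw_p

  l2b <- ln_bwd(dHc, p$ln2_g, ch$l2$xhat, ch$l2$sig)
  grads$ln2_g <- l2b$dg; grads$ln2_b <- l2b$db
  dX2 <- l2b$dX
  dfeats <- dX2                      # residual path
  dO <- dX2
  grads$attn_Wo <- t(ch$Ocat) %*% dO
  grads$attn_bo <- colSums(dO)
  dOcat <- dO %*% t(p$attn_Wo)

  nh <- cfg$n_heads; dh <- E %/% nh
  dQ <- matrix(0, N, E); dK <- matrix(0, N, E); dV <- matrix(0, N, E)
  for (b in seq_len(B)) {
    rows <- (b - 1L) * S + seq_len(S)
    for (h in seq_len(nh)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      A <- ch$A[[(b - 1L) * nh + h]]
      dOh <- dOcat[rows, cols, drop = FALSE]
      Vh <- ch$V[rows, cols, drop = FALSE]
      dA <- dOh %*% t(Vh)
      dV[rows, cols] <- t(A) %*% dOh
      dSc <- A * (dA - rowSums(dA * A))
      dQ[rows, cols] <- dSc %*% ch$K[rows, cols, drop = FALSE] / sqrt(dh)
      dK[rows, cols] <- t(dSc) %*% ch$Q[rows, cols, drop = FALSE] / sqrt(dh)
    }
  }
  Xn <- ch$Xn
  grads$attn_Wq <- t(Xn) %*% dQ; grads$attn_bq <- colSums(dQ)
  grads$attn_Wk <- t(Xn) %*% dK; grads$attn_bk <- colSums(dK)
  grads$attn_Wv <- t(Xn) %*% dV; grads$attn_bv <- colSums(dV)
  dXn <- dQ %*% t(p$attn_Wq) + dK %*% t(p$attn_Wk) + dV %*% t(p$attn_Wv)
  l1b <- ln_bwd(dXn, p$ln1_g, ch$l1$xhat, ch$l1$sig)
  grads$ln1_g <- l1b$dg; grads$ln1_b <- l1b$db
  dfeats <- dfeats + l1b$dX

  grads <- backbone_bwd(model, ch$bk, dfeats, N, grads)

  # L2 penalty on weight matrices (biases and norm parameters excluded)
  if (cfg$l2 > 0) {
    for (nm in names(p)) {
      if (grepl("_(W|w)$|pool_V|pool_U", nm)) {
        loss <- loss + cfg$l2 * sum(p[[nm]]^2)
        grads[[nm]] <- grads[[nm]] + 2 * cfg$l2 * p[[nm]]
      }
    }
  }
  list(loss = loss, grads = grads, prob = fw$prob)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, frozen = character(),
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    if (nm %in% frozen) next
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}
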