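# Gather the slices of several bags into one encoder stack.
gather_bags <- function(bags, x, rows) {
  entries <- unlist(bags$entries[rows], use.names = FALSE)
  d <- dim(x)
  array(x[, , entries], c(d[1], d[2], length(entries)))
}

#' Train the attention MIL model
#'
#' Minimizes class-weighted binary cross-entropy with Adam. The validation
#' loss is monitored each epoch; after `plateau_patience` epochs without
#' improvement the learning rate is multiplied by `plateau_factor`, and
#' after `early_stop_patience` epochs without improvement training stops
#' and the best-validation weights are restored. Training and validation
#' patients must be disjoint (bags of one patient never cross sets).
#'
#' @param model A `milcta_model` from [mil_init()].
#' @param train_bags,val_bags Bag tibbles ([cohort_bags()]) whose `entries`
#'   index planes of `x`; must carry `patient_id` and `label`.
#' @param x Array `h x w x n_slices` of processed slices.
#' @param config A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return A list with `model` (trained, best-validation weights) and
#'   `history` (tibble: `epoch`, `train_loss`, `val_loss`, `lr`).
#' @export
mil_train <- function(model, train_bags, val_bags, x, config = train_config(),
                      verbose = FALSE) {
  overlap <- intersect(unique(train_bags$patient_id),
                       unique(val_bags$patient_id))
  if (length(overlap) > 0)
    abort(sprintf("patient leakage between train and val sets (%d shared)",
                  length(overlap)))
  wts <- if (config$class_weighting) {
    cw <- compute_class_weights(train_bags$label)
    cw[as.character(train_bags$label)]
  } else rep(1, nrow(train_bags))

  state <- adam_init(model$params)
  lr <- config$lr
  best_val <- Inf; best_params <- model$params
  wait_stop <- 0L; wait_plateau <- 0L
  hist <- list()
  n_tr <- nrow(train_bags)

  with_seed(config$seed, {
    if (config$warmup_epochs > 0)
      model <- warmup_encoder(model, train_bags, x, config, verbose)
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n_tr)
      tl <- 0; nb <- 0L
      for (start in seq(1L, n_tr, by = config$batch_bags)) {
        rows <- ord[start:min(n_tr, start + config$batch_bags - 1L)]
        B <- length(rows)
        stack <- gather_bags(train_bags, x, rows)
        if (config$zoom_range > 0 || config$shift_range > 0)
          stack <- augment_bag(stack, config)
        X <- matrix(as.numeric(stack), ncol = 1L)
        lg <- mil_loss_grads(model, X, train_bags$label[rows], B, wts[rows],
                             aux_weight = config$aux_weight,
                             att_consistency = config$att_consistency)
        up <- adam_step(model$params, lg$grads, state, lr, model$frozen)
        model$params <- up$params; state <- up$state
        tl <- tl + lg$loss * B; nb <- nb + B
      }
      vl <- eval_loss(model, val_bags, x)
      hist[[epoch]] <- c(epoch = epoch, train_loss = tl / nb,
                         val_loss = vl, lr = lr)
      if (verbose)
        message(sprintf("epoch %2d train %.4f val %.4f lr %.2g",
                        epoch, tl / nb, vl, lr))
      if (vl < best_val) {
        best_val <- vl; best_params <- model$params
        wait_stop <- 0L; wait_plateau <- 0L
      } else {
        wait_stop <- wait_stop + 1L
        wait_plateau <- wait_plateau + 1L
        if (wait_plateau >= config$plateau_patience) {
          lr <- lr * config$plateau_factor
          wait_plateau <- 0L
        }
        if (wait_stop >= config$early_stop_patience) break
      }
    }
  })
  model$params <- best_params
  hist <- as_tibble(do.call(rbind, hist))
  list(model = model, history = hist)
}

# Slice-level warm-up: every training slice inherits its patient's weak
# label; the shared encoder and the instance head are trained on these
# noisy labels (class-weighted). Uses the caller's RNG stream.
warmup_encoder <- function(model, train_bags, x, config, verbose = FALSE) {
  per_bag <- purrr::map2(train_bags$entries, train_bags$replicated,
                         function(e, r) e[!r])
  slices <- unlist(per_bag, use.names = FALSE)
  labels <- rep(train_bags$label, lengths(per_bag))
  keep <- !duplicated(slices)
  slices <- slices[keep]; labels <- labels[keep]
  wts <- if (config$class_weighting) {
    cw <- compute_class_weights(labels)
    cw[as.character(labels)]
  } else rep(1, length(labels))

  state <- adam_init(model$params)
  d <- dim(x)
  for (epoch in seq_len(config$warmup_epochs)) {
    ord <- sample(length(slices))
    tl <- 0
    for (start in seq(1L, length(ord), by = config$warmup_batch)) {
      rows <- ord[start:min(length(ord), start + config$warmup_batch - 1L)]
      N <- length(rows)
      stack <- array(x[, , slices[rows]], c(d[1], d[2], N))
      if (config$zoom_range > 0 || config$shift_range > 0)
        stack <- augment_bag(stack, config)
      X <- matrix(as.numeric(stack), ncol = 1L)
      bk <- backbone_fwd(model, X, N, keep_cache = TRUE)
      z <- as.numeric(bk$emb %*% model$params$inst_w) + model$params$inst_b
      p <- sigmoid(z)
      pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      y <- labels[rows]; w <- wts[rows]
      tl <- tl + sum(-w * (y * log(pc) + (1 - y) * log(1 - pc)))
      dz <- w * (p - y) / N
      grads <- list(inst_w = as.numeric(t(bk$emb) %*% dz), inst_b = sum(dz))
      grads <- backbone_bwd(model, bk$cache, outer(dz, model$params$inst_w),
                            N, grads)
      up <- adam_step(model$params, grads, state, config$lr, model$frozen)
      model$params <- up$params; state <- up$state
    }
    if (verbose)
      message(sprintf("warmup %2d slice loss %.4f", epoch,
                      tl / length(slices)))
  }
  model
}

# Unweighted validation BCE in evaluation mode (no augmentation/dropout).
eval_loss <- function(model, bags, x, chunk = 16L) {
  n <- nrow(bags)
  probs <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(n, start + chunk - 1L)
    X <- matrix(as.numeric(gather_bags(bags, x, rows)), ncol = 1L)
    probs[rows] <- mil_forward(model, X, length(rows))$prob
  }
  p <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  y <- bags$label
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Bag probabilities in evaluation mode, chunked for memory.
predict_bags_prob <- function(model, bags, x, chunk = 16L) {
  n <- nrow(bags)
  probs <- numeric(n)
  atts <- matrix(0, model$config$bag_size, n)
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(n, start + chunk - 1L)
    X <- matrix(as.numeric(gather_bags(bags, x, rows)), ncol = 1L)
    fw <- mil_forward(model, X, length(rows))
    probs[rows] <- fw$prob
    atts[, rows] <- fw$attention
  }
  list(probs = probs, attention = atts)
}
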