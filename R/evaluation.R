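#' Area under the ROC curve (Mann--Whitney form)
#'
#' Over all positive/negative score pairs, the fraction of pairs ranked
#' correctly, counting ties as half.
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores Numeric scores, higher = more positive.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0)
    abort("both classes must be present to compute an AUC")
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Brier score
#'
#' Mean squared difference between predicted probability and outcome.
#'
#' @param labels 0/1 vector.
#' @param probs Probabilities in \[0, 1\].
#' @return Non-negative scalar (0 = perfect confident prediction).
#' @export
brier_score <- function(labels, probs) {
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  mean((probs - labels)^2)
}

#' Threshold sweep of confusion-matrix metrics
#'
#' At each threshold `t` a case is predicted positive iff its probability
#' is `>= t`. Precision (and the F-score depending on it) is `NA` when no
#' case is predicted positive.
#'
#' @param labels 0/1 vector.
#' @param probs Probabilities.
#' @param start,stop,step Threshold grid (defaults 0.01 to 0.50 by 0.01).
#' @return Tibble with `threshold`, `sensitivity`, `specificity`,
#'   `precision`, `f_score`.
#' @export
threshold_sweep <- function(labels, probs, start = 0.01, stop = 0.50,
                            step = 0.01) {
  ts <- seq(start, stop, by = step)
  rows <- lapply(ts, function(t) {
    pred <- probs >= t
    tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
    fn <- sum(!pred & labels == 1); tn <- sum(!pred & labels == 0)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    f <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
      2 * prec * sens / (prec + sens) else NA_real_
    c(threshold = t, sensitivity = sens, specificity = spec,
      precision = prec, f_score = f)
  })
  as_tibble(do.call(rbind, rows))
}

#' Calibration table
#'
#' Equal-width probability bins on \[0, 1\] (last bin right-closed); empty
#' bins are dropped. Reports, per occupied bin, the mean predicted
#' probability and the observed event fraction.
#'
#' @param labels 0/1 vector.
#' @param probs Probabilities.
#' @param n_bins Number of equal-width bins (default 10).
#' @return Tibble with `bin_low`, `bin_high`, `mean_predicted`,
#'   `observed`, `count`; counts sum to `length(labels)`.
#' @export
calibration_table <- function(labels, probs, n_bins = 10L) {
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(findInterval(probs, breaks, rightmost.closed = TRUE), n_bins)
  tibble(bin = bin, label = labels, prob = probs) %>%
    group_by(.data$bin) %>%
    summarise(mean_predicted = mean(.data$prob),
              observed = mean(.data$label),
              count = dplyr::n(), .groups = "drop") %>%
    mutate(bin_low = breaks[.data$bin], bin_high = breaks[.data$bin + 1L]) %>%
    select("bin_low", "bin_high", "mean_predicted", "observed", "count") %>%
    arrange(.data$bin_low)
}

#' Aggregate per-repeat AUCs into a mean and 95% confidence interval
#'
#' t-distribution interval over k repeats:
#' `mean +/- t(0.975, k-1) * sd / sqrt(k)`.
#'
#' @param values Numeric vector of per-repeat metric values (>= 2).
#' @param level Confidence level (default 0.95).
#' @param method `"t"` (default) or `"normal"`.
#' @return List with `mean`, `ci_low`, `ci_high`.
#' @export
aggregate_repeats <- function(values, level = 0.95, method = c("t", "normal")) {
  method <- match.arg(method)
  k <- length(values)
  if (k < 2) abort("at least two repeats are required")
  m <- mean(values)
  se <- sd(values) / sqrt(k)
  q <- if (method == "t") qt(1 - (1 - level) / 2, k - 1)
       else stats::qnorm(1 - (1 - level) / 2)
  list(mean = m, ci_low = m - q * se, ci_high = m + q * se)
}

#' Run the full repeated-split experiment on a cohort
#'
#' For each repeat: stratified 70/15/15 patient-level split, 36-slice bag
#' construction, training of the attention MIL classifier, and
#' patient-level evaluation on the held-out test patients (patient
#' probability = max over bag probabilities). Metrics are aggregated
#' across repeats.
#'
#' @param cohort A `milcta_cohort`.
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()]. The experiment default deviates
#'   from the fine-tuning recipe of `train_config()` because the small
#'   encoder trains from scratch: higher learning rate (1e-3), smaller
#'   bag batches (more gradient steps per epoch), and longer patience to
#'   ride out the noisy validation loss of small validation sets.
#' @param pre_params A [preprocess_params()]; its `output_size` must match
#'   the model's `input_size`.
#' @param n_repeats Number of repeated splits (default 5).
#' @param base_seed Master seed; split, initialization and training seeds
#'   derive from it.
#' @param processed Optional precomputed [preprocess_cohort()] result.
#' @param verbose Print progress.
#' @return An object of class `milcta_experiment`: list with `predictions`
#'   (tibble: `repeat_id`, `patient_id`, `label`, `prob`,
#'   `top_slice_index`, `top_slice_has_plaque`), `folds` (per-repeat `auc`,
#'   `brier`), `summary` (mean AUC with 95% CI, mean Brier), `history`
#'   (per-repeat training curves) and the configurations.
#' @export
run_experiment <- function(cohort,
                           model_cfg = model_config(),
                           train_cfg = train_config(
                             lr = 1e-3, max_epochs = 40L, batch_bags = 4L,
                             early_stop_patience = 12L,
                             plateau_patience = 8L, warmup_epochs = 75L,
                             att_consistency = 0.5),
                           pre_params = preprocess_params(
                             output_size = model_cfg$input_size),
                           n_repeats = 5L, base_seed = 1L,
                           processed = NULL, verbose = FALSE) {
  if (!all(pre_params$output_size == model_cfg$input_size))
    abort("preprocess output_size must equal the model input_size")
  if (is.null(processed)) {
    if (verbose) message("preprocessing ", sum(cohort$manifest$n_slices),
                         " slices")
    processed <- preprocess_cohort(cohort, pre_params)
  }
  records <- cohort$manifest
  splits <- repeated_splits(records, n_repeats, base_seed)
  bags_all <- cohort_bags(processed$index, records, model_cfg$bag_size)

  truth_by_pos <- processed$index %>%
    left_join(cohort$truth, by = c("patient_id", "slice_index"))

  preds <- list(); folds <- list(); hists <- list()
  for (r in seq_len(n_repeats)) {
    sp <- splits[[r]]
    bags <- left_join(bags_all, sp[, c("patient_id", "split")], by = "patient_id")
    tr <- filter(bags, .data$split == "train")
    va <- filter(bags, .data$split == "val")
    te <- filter(bags, .data$split == "test")
    model <- mil_init(model_cfg, seed = derive_seed(base_seed, 2L * r))
    tcfg <- train_cfg
    tcfg$seed <- derive_seed(base_seed, 2L * r + 1L)
    if (verbose) message(sprintf("repeat %d: %d/%d/%d bags",
                                 r, nrow(tr), nrow(va), nrow(te)))
    fit <- mil_train(model, tr, va, processed$x, tcfg, verbose = verbose)
    hists[[r]] <- mutate(fit$history, repeat_id = r)

    test_ids <- unique(te$patient_id)
    rows <- lapply(test_ids, function(pid) {
      pb <- filter(te, .data$patient_id == pid)
      cp <- predict_patient(fit$model, pb, processed$x)
      top_pos <- as.integer(names(cp$case_attention)[which.max(cp$case_attention)])
      info <- truth_by_pos[truth_by_pos$pos == top_pos, ]
      tibble(repeat_id = r, patient_id = pid,
             label = records$label[match(pid, records$patient_id)],
             prob = cp$patient_prob,
             top_slice_index = info$slice_index[1],
             top_slice_has_plaque = isTRUE(info$has_plaque[1]))
    })
    preds[[r]] <- bind_rows(rows)
    folds[[r]] <- tibble(repeat_id = r,
                         auc = roc_auc(preds[[r]]$label, preds[[r]]$prob),
                         brier = brier_score(preds[[r]]$label, preds[[r]]$prob))
    if (verbose) message(sprintf("repeat %d: AUC %.3f brier %.3f",
                                 r, folds[[r]]$auc, folds[[r]]$brier))
  }
  predictions <- bind_rows(preds)
  folds <- bind_rows(folds)
  agg <- if (n_repeats >= 2) aggregate_repeats(folds$auc)
         else list(mean = folds$auc[1], ci_low = NA_real_, ci_high = NA_real_)
  structure(list(
    predictions = predictions, folds = folds,
    summary = list(mean_auc = agg$mean, ci_low = agg$ci_low,
                   ci_high = agg$ci_high, mean_brier = mean(folds$brier),
                   n_repeats = n_repeats),
    history = bind_rows(hists),
    model_cfg = model_cfg, train_cfg = train_cfg, base_seed = base_seed
  ), class = "milcta_experiment")
}

#' Fraction of positive test cases whose top-attention slice is a true
#' plaque slice
#'
#' @param experiment A `milcta_experiment`.
#' @return Scalar in \[0, 1\] (NA if there were no positive test cases).
#' @export
attention_hit_rate <- function(experiment) {
  pos <- filter(experiment$predictions, .data$label == 1)
  if (nrow(pos) == 0) return(NA_real_)
  mean(pos$top_slice_has_plaque)
}

#' @export
print.milcta_experiment <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<milcta_experiment> %d repeats | mean AUC %.3f (95%% CI %.3f-%.3f) | mean Brier %.3f\n",
    s$n_repeats, s$mean_auc, s$ci_low, s$ci_high, s$mean_brier))
  invisible(x)
}

#' @describeIn run_experiment Per-repeat test metrics as a tibble.
#' @param x A `milcta_experiment`.
#' @param ... Unused.
#' @export
tidy.milcta_experiment <- function(x, ...) x$folds

#' @describeIn run_experiment One-row experiment summary.
#' @export
glance.milcta_experiment <- function(x, ...) {
  s <- x$summary
  tibble(mean_auc = s$mean_auc, ci_low = s$ci_low, ci_high = s$ci_high,
         mean_brier = s$mean_brier, n_repeats = s$n_repeats,
         attention_hit_rate = attention_hit_rate(x))
}
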