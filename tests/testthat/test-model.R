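test_that("configuration invariants are enforced", {
  expect_error(model_config(embed_dim = 10, n_heads = 4), "divisible")
  expect_error(model_config(dropout = 1), "dropout")
  expect_error(model_config(input_size = 50), "divisible")
  expect_error(train_config(rotation_range = 10), "rotation")
  expect_equal(model_config(backbone = "vgg16_style",
                            input_size = 32)$frozen_layers, 15L)
  expect_equal(model_config()$frozen_layers, 0L)
})

test_that("the shared encoder embeds identical slices identically", {
  m <- mil_init(tiny_model_config(), seed = 2)
  one <- matrix(runif(256), 16, 16)
  bag <- array(rep(one, 36), c(16, 16, 36))
  f <- embed_slices(m, bag)
  expect_equal(dim(f), c(36L, 8L))
  expect_true(all(abs(sweep(f, 2, f[1, ])) < 1e-12))
  bag2 <- random_stack(16, 16, 36, seed = 3)
  f2 <- embed_slices(m, bag2)
  expect_equal(dim(f2), c(36L, 8L))
  expect_gt(stats::sd(f2), 0)
})

test_that("positional encoding is sinusoidal, additive, and injective", {
  m <- mil_init(tiny_model_config(), seed = 2)
  f <- matrix(0.5, 36, 8)
  g <- add_positional_encoding(m, f)
  # position 0: sin(0)=0 on even channels, cos(0)=1 on odd channels
  expect_equal(g[1, ] - f[1, ], rep(c(0, 1), 4))
  # equal content at different positions becomes distinguishable
  expect_false(isTRUE(all.equal(g[1, ], g[2, ])))
  m0 <- mil_init(tiny_model_config(positional_encoding = "none"), seed = 2)
  expect_identical(add_positional_encoding(m0, f), f)
})

test_that("the attention block preserves shape and the pool normalizes", {
  m <- mil_init(tiny_model_config(), seed = 4)
  set.seed(5)
  f <- matrix(rnorm(36 * 8), 36, 8)
  ctx <- multi_head_attention(m, f)
  expect_equal(dim(ctx), dim(f))
  pool <- attention_pool(m, ctx)
  expect_equal(sum(pool$attention), 1, tolerance = 1e-6)
  expect_true(all(pool$attention >= 0))
  expect_equal(length(pool$bag_embedding), 8L)
  # identical instances receive uniform attention
  same <- matrix(rep(f[1, ], each = 36), 36, 8)
  expect_equal(attention_pool(m, same)$attention, rep(1 / 36, 36),
               tolerance = 1e-9)
})

test_that("bag predictions are probabilities with unit-sum attention and
           deterministic in evaluation mode", {
  m <- mil_init(tiny_model_config(), seed = 6)
  bag <- random_stack(16, 16, 36, seed = 7)
  p1 <- predict_bag(m, bag)
  p2 <- predict_bag(m, bag)
  expect_gte(p1$bag_prob, 0); expect_lte(p1$bag_prob, 1)
  expect_equal(sum(p1$attention), 1, tolerance = 1e-6)
  expect_identical(p1, p2)
})

test_that("without positional encoding the model is permutation-equivariant", {
  m <- mil_init(tiny_model_config(positional_encoding = "none"), seed = 8)
  bag <- random_stack(16, 16, 36, seed = 9)
  perm <- sample(36)
  p <- predict_bag(m, bag)
  pp <- predict_bag(m, bag[, , perm])
  expect_equal(pp$bag_prob, p$bag_prob, tolerance = 1e-5)
  expect_equal(pp$attention, p$attention[perm], tolerance = 1e-5)
  # with the encoding on, permutation changes the prediction
  ms <- mil_init(tiny_model_config(), seed = 8)
  expect_false(isTRUE(all.equal(predict_bag(ms, bag[, , perm])$bag_prob,
                                predict_bag(ms, bag)$bag_prob,
                                tolerance = 1e-8)))
})

test_that("patient aggregation takes the max bag probability and renormalizes
           case attention", {
  m <- mil_init(tiny_model_config(), seed = 10)
  x <- random_stack(16, 16, 50, seed = 11)
  bags <- make_bags(1:50)                 # 2 bags, second padded
  bags$patient_id <- "p1"
  cp <- predict_patient(m, bags, x)
  expect_equal(cp$patient_prob, max(cp$bag_probs))
  expect_equal(sum(cp$case_attention), 1, tolerance = 1e-6)
  expect_equal(length(cp$case_attention), 50L)

  # single full bag: case attention equals the bag attention
  b1 <- make_bags(1:36); b1$patient_id <- "p2"
  cp1 <- predict_patient(m, b1, x)
  pb <- predict_bag(m, x[, , 1:36])
  expect_equal(as.numeric(cp1$case_attention), pb$attention,
               tolerance = 1e-12)
  expect_error(predict_patient(m, b1[0, ], x), "at least one bag")
})

test_that("class weights are balanced inverse frequencies", {
  expect_equal(compute_class_weights(rep(c(0, 1), 25)),
               c("0" = 1, "1" = 1))
  w <- compute_class_weights(rep(c(1, 0), c(25, 75)))
  expect_equal(unname(w["1"]), 2.0)
  expect_equal(unname(w["0"]), 100 / 150)
  expect_error(compute_class_weights(rep(1, 5)), "both classes")
})

test_that("augmentation zooms and shifts but never reorders or rotates", {
  cfg <- train_config(zoom_range = 0, shift_range = 0)
  bag <- random_stack(16, 16, 36, seed = 12)
  expect_identical(augment_bag(bag, cfg), bag)
  # constant-valued slices identify their position after warping
  marked <- array(rep(seq_len(36) / 36, each = 256), c(16, 16, 36))
  set.seed(13)
  aug <- augment_bag(marked, train_config(zoom_range = 0.1, shift_range = 0.1))
  for (k in seq_len(36))
    expect_equal(aug[8, 8, k], k / 36, tolerance = 1e-9)
})

test_that("frozen backbone stages stay bitwise identical through training", {
  m <- mil_init(tiny_model_config(frozen_layers = 2L), seed = 14)
  expect_true("conv1_W" %in% m$frozen)
  x <- random_stack(16, 16, 36 * 6, seed = 15)
  bags <- tibble::tibble(
    patient_id = c("a", "a", "b", "c", "d", "e"),
    bag_index = 0L,
    entries = lapply(0:5, function(i) i * 36 + 1:36),
    replicated = list(rep(FALSE, 36)),
    label = c(1L, 1L, 0L, 1L, 0L, 0L))
  fit <- mil_train(m, bags[1:4, ], bags[5:6, ], x,
                   train_config(lr = 1e-3, max_epochs = 1, batch_bags = 2,
                                seed = 16))
  expect_identical(fit$model$params$conv1_W, m$params$conv1_W)
  expect_identical(fit$model$params$conv1_b, m$params$conv1_b)
  expect_false(identical(fit$model$params$conv3_W, m$params$conv3_W))
  expect_false(identical(fit$model$params$head_w, m$params$head_w))
})

test_that("training refuses leaking patients between train and val", {
  m <- mil_init(tiny_model_config(), seed = 17)
  x <- random_stack(16, 16, 72, seed = 18)
  bags <- tibble::tibble(patient_id = c("a", "a"), bag_index = c(0L, 1L),
                         entries = list(1:36, 37:72),
                         replicated = list(rep(FALSE, 36)),
                         label = c(1L, 1L))
  expect_error(mil_train(m, bags[1, ], bags[2, ], x, train_config()),
               "leakage")
})

test_that("early stopping and plateau decay follow their patience counters", {
  m <- mil_init(tiny_model_config(), seed = 19)
  m$frozen <- names(m$params)     # no parameter can change -> flat val loss
  x <- random_stack(16, 16, 36 * 4, seed = 20)
  bags <- tibble::tibble(
    patient_id = c("a", "b", "c", "d"), bag_index = 0L,
    entries = lapply(0:3, function(i) i * 36 + 1:36),
    replicated = list(rep(FALSE, 36)),
    label = c(1L, 0L, 1L, 0L))
  cfg <- train_config(lr = 1e-4, max_epochs = 30, batch_bags = 2,
                      early_stop_patience = 7, plateau_factor = 0.2,
                      plateau_patience = 5, zoom_range = 0, shift_range = 0,
                      seed = 21)
  fit <- mil_train(m, bags[1:2, ], bags[3:4, ], x, cfg)
  h <- fit$history
  # epoch 1 improves from -Inf; epochs 2..8 are flat -> stop at 1 + 7
  expect_equal(nrow(h), 8L)
  # plateau hits after 5 flat epochs: lr drops to 1e-4 * 0.2 = 2e-5
  expect_equal(h$lr[1:6], rep(1e-4, 6))
  expect_equal(h$lr[7:8], rep(2e-5, 2))
  expect_equal(sd(h$val_loss), 0)
})

test_that("the VGG16-style backbone exposes the documented freezing plan", {
  cfg <- model_config(backbone = "vgg16_style", input_size = 32L,
                      embed_dim = 16L, n_heads = 2L, attention_dim = 8L)
  m <- mil_init(cfg, seed = 22)
  conv_ids <- c(1, 2, 4, 5, 7, 8, 9, 11, 12, 13, 15, 16, 17)
  expect_true(all(paste0("conv", conv_ids, "_W") %in% names(m$params)))
  frozen_convs <- conv_ids[conv_ids <= 15]
  expect_setequal(m$frozen,
                  c(paste0("conv", frozen_convs, "_W"),
                    paste0("conv", frozen_convs, "_b")))
  f <- embed_slices(m, random_stack(32, 32, 36, seed = 23))
  expect_equal(dim(f), c(36L, 16L))
})
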