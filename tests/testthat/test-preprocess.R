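test_that("windowing maps HU linearly with clipping", {
  s <- matrix(c(-150, -100, -50, 2000), 2, 2)
  expect_equal(clip_and_normalize(s, c(-150, -50))[1, 1], 0)
  expect_equal(clip_and_normalize(s, c(-150, -50))[2, 1], 0.5)
  expect_equal(clip_and_normalize(s, c(400, 1000))[2, 2], 1)
  # second pass with the unit window is a no-op
  once <- clip_and_normalize(s, c(-150, -50))
  expect_equal(clip_and_normalize(once, c(0, 1)), once)
  s[1, 1] <- NaN
  attr(s, "patient_id") <- "P7"
  expect_error(clip_and_normalize(s, c(-50, 50)), "P7")
})

test_that("Sobel magnitude matches a brute-force convolution oracle", {
  expect_equal(sobel_edges(matrix(0.4, 6, 6)), matrix(0, 6, 6))
  step <- matrix(0, 8, 8); step[, 5:8] <- 1
  got <- sobel_edges(step)
  expect_equal(got, sobel_oracle(step))
  expect_equal(max(got), max(got[2:7, 4:5]))   # boundary attains the max
  set.seed(1)
  for (i in 1:5) {
    m <- matrix(runif(7 * 9), 7, 9)
    e <- sobel_edges(m)
    expect_equal(e, sobel_oracle(m))
    expect_true(all(e >= 0 & e <= 1))
  }
})

test_that("maximum-response fusion is a pointwise max with the right algebra", {
  set.seed(2)
  A <- matrix(runif(30), 5, 6); B <- matrix(runif(30), 5, 6)
  C <- matrix(runif(30), 5, 6)
  expect_identical(fuse_max(list(A)), A)
  expect_equal(fuse_max(list(A, matrix(0, 5, 6))), A)
  f <- fuse_max(list(A, B))
  expect_true(all(f >= A & f >= B))
  expect_true(all(f == A | f == B))
  expect_equal(fuse_max(list(A, B)), fuse_max(list(B, A)))                 # commutative
  expect_equal(fuse_max(list(fuse_max(list(A, B)), C)),
               fuse_max(list(A, fuse_max(list(B, C)))))                    # associative
  expect_error(fuse_max(list(A, matrix(0, 6, 5))), "shape")
  expect_error(fuse_max(list()), "at least one")
})

test_that("small-object removal keeps 20-px components and drops 19-px ones", {
  fused <- matrix(0, 64, 64)
  fused[20:23, 20:24] <- 0.5                 # 4x5 = 20 px
  fused[40:43, 40:44] <- 0.5; fused[40, 40] <- 0   # 19 px
  mask <- threshold_and_clean(fused, preprocess_params())
  expect_true(all(mask[20:23, 20:24]))
  expect_false(any(mask[40:43, 40:44]))
  expect_equal(threshold_and_clean(matrix(0, 32, 32), preprocess_params()),
               matrix(FALSE, 32, 32))
})

test_that("the border frame is zeroed so burned-in text cannot survive", {
  fused <- matrix(0, 64, 64)
  fused[2:8, 3:40] <- 0.9                    # glyph-like strip at the margin
  fused[30:35, 30:35] <- 0.9
  p <- preprocess_params()
  mask <- threshold_and_clean(fused, p)
  m <- p$border_margin_px
  expect_false(any(mask[seq_len(m), ]))
  expect_false(any(mask[, seq_len(m)]))
  expect_false(any(mask[65 - seq_len(m), ]))
  expect_true(any(mask[30:35, 30:35]))
})

test_that("component ranking favours dominance in area, axis and perimeter", {
  mask <- matrix(FALSE, 40, 40)
  mask[10:19, 10:19] <- TRUE                 # 10x10
  mask[30:33, 30:33] <- TRUE                 # 4x4
  tb <- label_and_rank(mask, preprocess_params())
  expect_equal(nrow(tb), 2L)
  expect_equal(sort(tb$rank), 1:2)
  big <- tb[which.max(tb$area), ]
  expect_equal(big$area, 100)
  expect_equal(big$rank, 1L)
  expect_equal(big$composite_score, 1)       # min-max top in every metric
  expect_true(all(diff(tb$composite_score[order(tb$rank)]) <= 0))

  single <- matrix(FALSE, 20, 20); single[5:9, 5:9] <- TRUE
  tb1 <- label_and_rank(single, preprocess_params())
  expect_equal(tb1$composite_score, 1)
  expect_equal(tb1$rank, 1L)

  empty <- label_and_rank(matrix(FALSE, 10, 10), preprocess_params())
  expect_equal(nrow(empty), 0L)
})

test_that("connectivity choice changes which pixels merge", {
  m <- matrix(FALSE, 10, 10)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE           # diagonal touch
  expect_equal(max(milcta:::label_components(m, 8L)), 1L)
  expect_equal(max(milcta:::label_components(m, 4L)), 2L)
})

test_that("a constant slice preprocesses to an all-zero output", {
  out <- preprocess_slice(matrix(10, 96, 96),
                          preprocess_params(output_size = 48L))
  expect_equal(out$output, matrix(0, 48, 48))
  expect_equal(nrow(out$components), 0L)
})

test_that("pipeline output ignores isolated sub-threshold-size structures", {
  cfg <- synthetic_config(rng_seed = 21)
  set.seed(21)
  s <- generate_slice(cfg, list(patient_id = "Z", slice_index = 0L,
                                has_plaque = FALSE, plaque_kind = "none"),
                      noise_sd = 0)
  p <- preprocess_params(output_size = 48L)
  base <- preprocess_slice(s, p)
  s2 <- s
  # pick an empty region well below the centred vessel band
  spot <- c(165, 100)
  if (any(base$retained_mask[spot[1] + (-6:6), spot[2] + (-6:6)]))
    spot <- c(165, 40)
  s2[spot[1], spot[2]] <- 900                # lone bright pixel
  mod <- preprocess_slice(s2, p)
  expect_equal(mod$output, base$output)
})

test_that("plaque-bearing slices keep a retained component over the plaque", {
  cfg <- synthetic_config(n_patients = 20, prevalence = 1,
                          slices_per_patient_range = c(2L, 2L),
                          plaque_slices_per_positive = 2L, rng_seed = 31)
  co <- generate_cohort(cfg)
  p <- preprocess_params(output_size = 48L)
  hit <- 0; tot <- 0
  for (pid in names(co$slices)) {
    for (i in seq_along(co$slices[[pid]])) {
      s <- co$slices[[pid]][[i]]
      pm <- attr(s, "plaque_mask")
      if (is.null(pm)) next
      tot <- tot + 1
      if (any(preprocess_slice(s, p)$retained_mask & pm)) hit <- hit + 1
    }
  }
  expect_gte(tot, 30)
  expect_gte(hit / tot, 0.95)
})
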