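test_that("slice construction honors the plaque contracts", {
  cfg <- synthetic_config(n_patients = 4, rng_seed = 1)
  set.seed(11)
  neg <- generate_slice(cfg, list(patient_id = "A", slice_index = 0L,
                                  has_plaque = FALSE, plaque_kind = "none"))
  expect_true(any(neg > 250))                       # contrast-filled vessel
  lab <- milcta:::label_components(neg > 600, 8L)
  if (max(lab) > 0)                                 # glyphs stay below 25 px
    expect_lt(max(tabulate(lab[lab > 0])), 25)

  cal <- generate_slice(cfg, list(patient_id = "A", slice_index = 1L,
                                  has_plaque = TRUE, plaque_kind = "calcified"))
  lab <- milcta:::label_components(cal >= 600, 8L)
  expect_gte(max(tabulate(lab[lab > 0])), 25)       # compact calcified blob

  soft <- generate_slice(cfg, list(patient_id = "A", slice_index = 2L,
                                   has_plaque = TRUE, plaque_kind = "soft"))
  pm <- attr(soft, "plaque_mask")
  expect_gte(sum(pm), 25)
  core <- soft[pm]
  # lipid core plus denser fibrous components, all well below contrast HU
  expect_true(mean(core > -80 & core < 170) > 0.95)
  expect_lt(mean(core), 110)

  expect_error(generate_slice(synthetic_config(), list(has_plaque = FALSE)),
               NA)
})

test_that("generated slices stay within the physical HU range", {
  cfg <- synthetic_config(n_patients = 6, prevalence = 0.5,
                          slices_per_patient_range = c(2L, 4L),
                          plaque_slices_per_positive = 2L,
                          text_annotation_prob = 1, rng_seed = 3)
  co <- generate_cohort(cfg)
  for (pid in names(co$slices))
    for (s in co$slices[[pid]]) {
      expect_gte(min(s), -1024)
      expect_lte(max(s), 3000)
    }
})

test_that("patient generation enforces slice counts and plaque quotas", {
  cfg <- synthetic_config(slices_per_patient_range = c(6L, 20L),
                          plaque_slices_per_positive = 2L, rng_seed = 5)
  set.seed(7)
  p <- generate_patient(cfg, "P1", is_positive = TRUE)
  expect_equal(sum(p$truth$has_plaque), 2L)
  expect_true(all(p$truth$plaque_kind[p$truth$has_plaque] %in%
                    c("calcified", "soft")))
  n <- generate_patient(cfg, "P2", is_positive = FALSE)
  expect_false(any(n$truth$has_plaque))
  expect_true(all(n$truth$plaque_kind == "none"))
  counts <- replicate(50, length(generate_patient(cfg, "x", FALSE)$slices))
  expect_true(all(counts >= 6 & counts <= 20))
  # has_plaque=false <=> plaque_kind=none
  expect_identical(p$truth$has_plaque, p$truth$plaque_kind != "none")
})

test_that("cohort labels follow the configured prevalence and the truth", {
  cfg <- synthetic_config(n_patients = 100, prevalence = 0.4,
                          slices_per_patient_range = c(2L, 3L),
                          plaque_slices_per_positive = 2L,
                          image_height = 48, image_width = 48, rng_seed = 9)
  co <- generate_cohort(cfg)
  npos <- sum(co$manifest$label)
  expect_gte(npos, 25)          # wide binomial(100, 0.4) interval
  expect_lte(npos, 55)
  # patient label = OR over its slices' plaque flags
  agg <- tapply(co$truth$has_plaque, co$truth$patient_id, any)
  expect_identical(as.logical(co$manifest$label),
                   as.logical(agg[co$manifest$patient_id]))
  # label <-> stenosis percent >= 50
  expect_identical(co$manifest$label == 1, co$manifest$stenosis_percent >= 50)
})

test_that("degenerate prevalences behave as documented", {
  base <- list(n_patients = 10, slices_per_patient_range = c(2L, 2L),
               plaque_slices_per_positive = 1L,
               image_height = 48, image_width = 48, rng_seed = 2)
  co0 <- generate_cohort(do.call(synthetic_config, c(base, prevalence = 0)))
  expect_true(all(co0$manifest$label == 0))
  co1 <- generate_cohort(do.call(synthetic_config, c(base, prevalence = 1)))
  expect_true(all(co1$manifest$label == 1))
  expect_error(
    generate_cohort(do.call(synthetic_config, c(base, prevalence = 0.05))),
    "cannot reliably")
})

test_that("identical configurations yield byte-identical cohorts", {
  cfg <- synthetic_config(n_patients = 5, prevalence = 0.4,
                          slices_per_patient_range = c(2L, 4L),
                          plaque_slices_per_positive = 2L,
                          image_height = 64, image_width = 64, rng_seed = 17)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("configuration validation rejects bad inputs", {
  expect_error(synthetic_config(image_height = 16), "32x32")
  expect_error(synthetic_config(slices_per_patient_range = c(10, 5)))
  expect_error(synthetic_config(prevalence = 1.2))
  expect_error(synthetic_config(plaque_slices_per_positive = 8,
                                slices_per_patient_range = c(6, 20)),
               "plaque_slices_per_positive")
})
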