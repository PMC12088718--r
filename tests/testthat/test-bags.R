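test_that("percent-to-grade binning follows the clinical cut-offs", {
  expect_equal(as.character(grade_from_percent(0)), "none")
  expect_equal(as.character(grade_from_percent(c(1, 24, 24.9))),
               rep("minimal", 3))
  expect_equal(as.character(grade_from_percent(c(25, 49))), rep("mild", 2))
  expect_equal(as.character(grade_from_percent(c(50, 55, 69))),
               rep("moderate", 3))
  expect_equal(as.character(grade_from_percent(c(70, 99))), rep("severe", 2))
  expect_equal(as.character(grade_from_percent(100)), "total_occlusion")
  expect_error(grade_from_percent(101), "0, 100")
  expect_error(grade_from_percent(-1))
})

test_that("artery label is the maximum segment grade, binarized at moderate", {
  r <- artery_label(c("minimal", "severe", "none"))
  expect_equal(as.character(r$grade), "severe")
  expect_equal(r$label, 1L)
  r <- artery_label(c("mild", "mild"))
  expect_equal(as.character(r$grade), "mild")
  expect_equal(r$label, 0L)
  expect_equal(artery_label("none")$label, 0L)
  expect_equal(artery_label(c("none", "total_occlusion"))$label, 1L)
  expect_error(artery_label(character()), "no evaluated segments")
})

test_that("bagging chunks, pads by cycling, and flags replication", {
  b36 <- make_bags(1:36)
  expect_equal(nrow(b36), 1L)
  expect_equal(b36$entries[[1]], 1:36)
  expect_false(any(b36$replicated[[1]]))

  b6 <- make_bags(letters[1:6])
  expect_equal(nrow(b6), 1L)
  expect_equal(b6$entries[[1]], rep(letters[1:6], 6))
  expect_equal(sum(b6$replicated[[1]]), 30L)
  expect_equal(table(b6$entries[[1]])[["a"]], 6L)

  b40 <- make_bags(1:40)
  expect_equal(nrow(b40), 2L)
  expect_equal(b40$entries[[1]], 1:36)
  expect_equal(b40$entries[[2]], c(37:40, 1:32))
  expect_equal(sum(b40$replicated[[2]]), 32L)
  expect_error(make_bags(integer()), "empty")
})

test_that("bag count is ceil(n/36) and no original slice is ever lost", {
  for (n in 1:200) {
    b <- make_bags(seq_len(n))
    expect_equal(nrow(b), ceiling(n / 36))
    originals <- unlist(purrr::map2(b$entries, b$replicated,
                                    function(e, r) e[!r]))
    expect_equal(sort(originals), seq_len(n))
    expect_true(all(lengths(b$entries) == 36L))
  }
})

test_that("stratified splits allocate by round-half-up within class", {
  rec <- tibble::tibble(patient_id = sprintf("p%02d", 1:20),
                        label = rep(c(0, 1), each = 10))
  sp <- split_patients(rec, seed = 4)
  expect_equal(as.vector(table(sp$split)), c(12L, 4L, 4L))
  byc <- table(sp$label, sp$split)
  expect_true(all(byc["0", ] == c(6, 2, 2)))
  expect_true(all(byc["1", ] == c(6, 2, 2)))
  expect_error(split_patients(tibble::tibble(patient_id = c("a", "b", "c"),
                                             label = c(0, 0, 1))),
               "at least 3")
})

test_that("split fractions stay within one patient of 15% per class", {
  set.seed(8)
  for (i in 1:10) {
    n1 <- sample(20:300, 1); n0 <- sample(20:300, 1)
    rec <- tibble::tibble(patient_id = as.character(seq_len(n0 + n1)),
                          label = rep(c(0, 1), c(n0, n1)))
    sp <- split_patients(rec, seed = i)
    expect_equal(nrow(sp), n0 + n1)
    expect_false(any(is.na(sp$split)))
    for (cl in c(0, 1)) {
      n_cl <- sum(sp$label == cl)
      n_te <- sum(sp$label == cl & sp$split == "test")
      expect_lte(abs(n_te - 0.15 * n_cl), 1)
    }
  }
})

test_that("repeated splits are deterministic, distinct, and leakage-free", {
  rec <- tibble::tibble(patient_id = sprintf("p%03d", 1:60),
                        label = rep(c(0, 1), c(36, 24)))
  r1 <- repeated_splits(rec, n_repeats = 5, base_seed = 7)
  r2 <- repeated_splits(rec, n_repeats = 5, base_seed = 7)
  expect_identical(r1, r2)
  expect_equal(length(r1), 5L)
  seeds <- vapply(r1, attr, integer(1), "seed")
  expect_equal(length(unique(seeds)), 5L)
  expect_false(identical(r1[[1]]$split, r1[[2]]$split))
  for (sp in r1) {
    expect_equal(sort(sp$patient_id), sort(rec$patient_id))
    expect_equal(anyDuplicated(sp$patient_id), 0L)
  }
})

test_that("per-patient bags inherit the patient's label and never mix patients", {
  idx <- tibble::tibble(patient_id = rep(c("a", "b"), c(40, 6)),
                        pos = 1:46)
  labels <- tibble::tibble(patient_id = c("a", "b"), label = c(1L, 0L))
  bags <- cohort_bags(idx, labels)
  expect_equal(nrow(bags), 3L)   # ceil(40/36) + ceil(6/36)
  expect_equal(bags$label[bags$patient_id == "a"], c(1L, 1L))
  for (i in seq_len(nrow(bags))) {
    pos_range <- if (bags$patient_id[i] == "a") 1:40 else 41:46
    expect_true(all(bags$entries[[i]] %in% pos_range))
  }
})
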