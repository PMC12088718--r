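#' Stenosis grade levels
#'
#' Ordered severity scale used for per-segment grading.
#' @return Character vector of levels, least to most severe.
#' @export
stenosis_grades <- function() {
  c("none", "minimal", "mild", "moderate", "severe", "total_occlusion")
}

#' Grade a stenosis percentage
#'
#' Cut-offs: 0% none, 1--24% minimal, 25--49% mild, 50--69% moderate,
#' 70--99% severe, 100% total occlusion. Fractional percentages fall in the
#' bin whose bounds enclose them (e.g. 24.5 is still minimal).
#'
#' @param p Numeric vector of percentages in \[0, 100\].
#' @return Ordered factor over [stenosis_grades()].
#' @export
grade_from_percent <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 100))
    abort("stenosis percent must lie in [0, 100]")
  g <- ifelse(p == 0, "none",
       ifelse(p < 25, "minimal",
       ifelse(p < 50, "mild",
       ifelse(p < 70, "moderate",
       ifelse(p < 100, "severe", "total_occlusion")))))
  factor(g, levels = stenosis_grades(), ordered = TRUE)
}

#' Artery-level grade and binary label from segment grades
#'
#' The artery inherits the highest grade observed in any evaluated segment;
#' the binary label is 1 for moderate or worse (>=50% obstruction).
#'
#' @param segment_grades Non-empty vector of grades (character or ordered
#'   factor over [stenosis_grades()]).
#' @return A list with `grade` (ordered factor, length 1) and `label`
#'   (integer 0/1).
#' @export
artery_label <- function(segment_grades) {
  if (length(segment_grades) == 0) abort("no evaluated segments")
  g <- factor(as.character(segment_grades), levels = stenosis_grades(),
              ordered = TRUE)
  if (any(is.na(g))) abort("unknown stenosis grade")
  mx <- max(g)
  list(grade = mx, label = as.integer(mx >= "moderate"))
}

#' Pack a patient's slices into fixed-size bags
#'
#' Slices are chunked, in manifest order, into consecutive bags of
#' `bag_size`; the number of bags is `ceiling(n / bag_size)`. A short final
#' (or only) chunk is padded by cycling the patient's original slices from
#' the start; padded entries are flagged as replicated.
#'
#' @param slice_ids Ordered vector of slice identifiers (any atomic type).
#' @param bag_size Instances per bag (default 36).
#' @return A tibble with one row per bag: `bag_index` (0-based), `entries`
#'   (list column, length `bag_size` each), `replicated` (list column of
#'   logicals), `n_original` (count of non-replicated entries).
#' @export
make_bags <- function(slice_ids, bag_size = 36L) {
  n <- length(slice_ids)
  if (n == 0) abort("cannot build bags from an empty slice list")
  n_bags <- ceiling(n / bag_size)
  entries <- vector("list", n_bags)
  repl <- vector("list", n_bags)
  for (b in seq_len(n_bags)) {
    lo <- (b - 1L) * bag_size + 1L
    hi <- min(n, b * bag_size)
    chunk <- slice_ids[lo:hi]
    k <- length(chunk)
    if (k < bag_size) {
      pad <- slice_ids[((seq_len(bag_size - k) - 1L) %% n) + 1L]
      entries[[b]] <- c(chunk, pad)
      repl[[b]] <- c(rep(FALSE, k), rep(TRUE, bag_size - k))
    } else {
      entries[[b]] <- chunk
      repl[[b]] <- rep(FALSE, bag_size)
    }
  }
  tibble(bag_index = seq_len(n_bags) - 1L, entries = entries,
         replicated = repl,
         n_original = vapply(repl, function(r) sum(!r), integer(1)))
}

#' Build bags for every patient of a cohort
#'
#' @param index Tibble with `patient_id` and a slice reference column
#'   (`pos`), e.g. the `index` of [preprocess_cohort()].
#' @param labels Tibble with `patient_id` and `label`.
#' @param bag_size Instances per bag.
#' @return Tibble of bags with `patient_id`, `bag_index`, `entries`,
#'   `replicated`, `label`.
#' @export
cohort_bags <- function(index, labels, bag_size = 36L) {
  out <- index %>%
    group_by(.data$patient_id) %>%
    summarise(bags = list(make_bags(.data$pos, bag_size)), .groups = "drop") %>%
    tidyr::unnest("bags") %>%
    left_join(labels[, c("patient_id", "label")], by = "patient_id")
  out
}

#' Stratified leakage-free patient-level split
#'
#' Patients are partitioned into train/validation/test at the patient level
#' (so all bags of a patient share a split), stratified by binary label.
#' Within each class the order is shuffled by `seed`; the test and
#' validation counts are `round_half_up(n_class * fraction)` and the
#' remainder trains.
#'
#' @param records Tibble with `patient_id` and `label`.
#' @param fractions `c(train, val, test)` fractions summing to 1.
#' @param seed Integer seed for the within-class shuffle.
#' @return A tibble `patient_id`, `label`, `split` (factor
#'   train/val/test) with attribute `seed`.
#' @export
split_patients <- function(records, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) abort("fractions must sum to 1")
  counts <- table(records$label)
  if (length(counts) < 2) abort("both classes must be present")
  if (any(counts < 3))
    abort("each class needs at least 3 patients to populate all splits")
  res <- with_seed(seed, {
    parts <- lapply(split(records$patient_id, records$label), function(ids) {
      ids <- sample(ids)
      n <- length(ids)
      n_test <- round_half_up(n * fractions[3])
      n_val <- round_half_up(n * fractions[2])
      tibble(patient_id = ids,
             split = rep(c("test", "val", "train"),
                         c(n_test, n_val, n - n_test - n_val)))
    })
    bind_rows(parts)
  })
  out <- left_join(records[, c("patient_id", "label")], res, by = "patient_id")
  out$split <- factor(out$split, levels = c("train", "val", "test"))
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Repeated stratified splits with distinct seeds
#'
#' Five (by default) independent 70/15/15 patient-level splits, seeded
#' `base_seed + 0 .. n_repeats - 1`, emulating repeated random
#' train/validate/test evaluation.
#'
#' @param records Tibble with `patient_id` and `label`.
#' @param n_repeats Number of repeats (default 5).
#' @param base_seed First seed.
#' @param fractions Split fractions, see [split_patients()].
#' @return List of split tibbles, one per repeat.
#' @export
repeated_splits <- function(records, n_repeats = 5L, base_seed = 1L,
                            fractions = c(0.70, 0.15, 0.15)) {
  lapply(seq_len(n_repeats) - 1L, function(i)
    split_patients(records, fractions, seed = base_seed + i))
}
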