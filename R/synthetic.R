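#' Configuration for the synthetic CMR cohort generator
#'
#' Describes a synthetic cohort of curved multiplanar reformation (CMR)
#' slice stacks with known slice-level ground truth. Slices emulate the
#' features a contrast-enhanced coronary CT reformation shows: soft-tissue
#' background, a bright contrast-filled vessel running across the slice,
#' and -- on positive patients -- localized calcified (high-attenuation) or
#' soft (low-attenuation) plaques, plus burned-in text annotations near the
#' image border.
#'
#' @param image_height,image_width Slice size in pixels (minimum 32).
#' @param n_patients Number of patients in the cohort.
#' @param prevalence Fraction of patients with significant (>=50%) stenosis.
#' @param slices_per_patient_range Integer interval; the per-patient slice
#'   count is drawn uniformly from it. Default `c(6, 144)` matches the
#'   spread seen in routine clinical reformation exports.
#' @param plaque_kind_mix Probability that a plaque is calcified (otherwise
#'   soft/low-attenuating).
#' @param plaque_slices_per_positive Number of slices per positive patient
#'   that carry a visible plaque (must not exceed the range minimum, so
#'   that the exact count is always realizable). The reformations of one
#'   artery all traverse the lesion, so a significant stenosis is visible
#'   on many slices of a stack, hidden on the rest by quality and
#'   positioning variability; the default is the largest count the default
#'   slice range permits.
#' @param text_annotation_prob Probability that a slice carries burned-in
#'   annotation glyphs near the border.
#' @param artery Artery label written to the manifest (`"LAD"`, `"RCA"` or
#'   `"LCX"`).
#' @param rng_seed Integer seed; identical configurations (including the
#'   seed) produce byte-identical cohorts.
#' @return An object of class `milcta_synthetic_config`.
#' @export
synthetic_config <- function(image_height = 192, image_width = 192,
                             n_patients = 120, prevalence = 0.4,
                             slices_per_patient_range = c(6L, 144L),
                             plaque_kind_mix = 0.5,
                             plaque_slices_per_positive = 6L,
                             text_annotation_prob = 0.3,
                             artery = c("LAD", "RCA", "LCX"),
                             rng_seed = 1L) {
  artery <- match.arg(artery)
  if (image_height < 32 || image_width < 32)
    abort("slice dimensions must be at least 32x32 pixels")
  r <- as.integer(slices_per_patient_range)
  if (length(r) != 2L || r[1] > r[2] || r[1] < 1L || r[2] > 10000L)
    abort("slices_per_patient_range must be an increasing interval within [1, 10000]")
  if (prevalence < 0 || prevalence > 1) abort("prevalence must lie in [0, 1]")
  if (plaque_slices_per_positive < 1L || plaque_slices_per_positive > r[1])
    abort("plaque_slices_per_positive must be >= 1 and <= the slice-range minimum")
  structure(list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    n_patients = as.integer(n_patients),
    prevalence = prevalence,
    slices_per_patient_range = r,
    plaque_kind_mix = plaque_kind_mix,
    plaque_slices_per_positive = as.integer(plaque_slices_per_positive),
    text_annotation_prob = text_annotation_prob,
    artery = artery,
    rng_seed = as.integer(rng_seed)
  ), class = "milcta_synthetic_config")
}

# Quadratic Bezier vessel centreline y(x) with endpoints on the left/right
# image edges; with the middle control point at x = (W-1)/2 the curve
# parameter coincides with the column coordinate.
vessel_centerline <- function(width, y0, y1, y2) {
  t <- seq(0, 1, length.out = width)
  (1 - t)^2 * y0 + 2 * t * (1 - t) * y1 + t^2 * y2
}

# Feathered ellipse membership in [0,1]: 1 on the core, linear falloff at rim.
ellipse_blob <- function(H, W, cy, cx, ay, ax) {
  dy <- (seq_len(H) - cy) / ay
  dx <- (seq_len(W) - cx) / ax
  e <- 1 - (outer(dy^2, dx^2, `+`))
  pmin(pmax(3 * e, 0), 1)
}

#' Generate a single synthetic CMR slice
#'
#' Draws one Hounsfield-unit slice: smooth soft-tissue background in
#' roughly \[-120, 60\] HU, a curved contrast-filled vessel band
#' (300--500 HU, width 6--12 px) kept near the horizontal midline as
#' reformation software does, optionally a plaque as dictated by `truth`
#' (calcified: spotty calcification -- a dominant >= 25 px nodule above
#' 600 HU adjacent to the vessel wall plus satellite deposits; soft: a
#' heterogeneous low-attenuation stretch of the lumen with denser fibrous
#' components), optional border text glyphs, and additive Gaussian noise
#' (sigma 15 HU). Values are clamped to the physical CT range
#' \[-1024, 3000\] HU.
#'
#' Uses the current RNG stream; callers wanting reproducibility seed it
#' (as [generate_cohort()] does).
#'
#' @param config A [synthetic_config()].
#' @param truth A one-row data frame / list with fields `patient_id`,
#'   `slice_index`, `has_plaque`, `plaque_kind`.
#' @param noise_sd Additive Gaussian noise in HU (default 15).
#' @return A numeric `image_height x image_width` matrix of HU values with
#'   attributes `patient_id`, `slice_index`, `plaque_mask` (logical matrix
#'   of the drawn plaque core, or NULL) and `plaque_center` (c(y, x) or NULL).
#' @export
generate_slice <- function(config, truth, noise_sd = 15) {
  H <- config$image_height; W <- config$image_width
  if (H < 32 || W < 32) abort("slice dimensions must be at least 32x32 pixels")

  # background: offset + two low-frequency waves, kept within ~[-120, 60] HU
  b0 <- runif(1, -80, -20)
  ay <- runif(1, 5, 20); ax <- runif(1, 5, 20)
  py <- runif(1); px <- runif(1)
  fy <- sample(1:3, 1); fx <- sample(1:3, 1)
  bg <- b0 +
    matrix(ay * cos(2 * pi * (fy * seq_len(H) / H + py)), H, W) +
    matrix(ax * cos(2 * pi * (fx * seq_len(W) / W + px)), H, W, byrow = TRUE)

  # vessel band along a quadratic Bezier centreline; reformation software
  # keeps the straightened artery near the middle of the image, so the
  # centreline wanders only moderately about the horizontal midline
  yc <- vessel_centerline(W, runif(1, 0.40, 0.60) * H, runif(1, 0.35, 0.65) * H,
                          runif(1, 0.40, 0.60) * H)
  bw <- runif(1, 6, 12)
  v0 <- runif(1, 330, 470)
  D <- abs(outer(seq_len(H), yc, `-`))
  band <- pmin(pmax(bw / 2 + 0.5 - D, 0), 1)
  img <- bg + (v0 - bg) * band

  plaque_mask <- NULL
  plaque_center <- NULL
  if (isTRUE(truth$has_plaque)) {
    xc <- runif(1, 0.2, 0.8) * W
    ycx <- yc[max(1L, min(W, round(xc)))]
    if (truth$plaque_kind == "calcified") {
      # spotty calcification: a dominant nodule straddling the vessel wall
      # plus satellite deposits, as calcium typically presents on CCTA
      side <- sample(c(-1, 1), 1)
      cy <- ycx + side * (bw / 2 + 2)
      hu <- runif(1, 700, 1000)
      G <- ellipse_blob(H, W, cy, xc, runif(1, 3.5, 5), runif(1, 4.5, 6.5))
      for (k in seq_len(sample(2:4, 1))) {
        sy <- cy + runif(1, -6, 6); sx <- xc + runif(1, -14, 14)
        Gs <- ellipse_blob(H, W, sy, sx, runif(1, 1.8, 3.2), runif(1, 1.8, 3.5))
        G <- pmax(G, Gs)
      }
      img <- img * (1 - G) + (hu + matrix(rnorm(H * W, 0, 40), H, W)) * G
      plaque_mask <- G >= 1            # core pixels at full plaque HU
      plaque_center <- c(cy, xc)
    } else {
      # heterogeneous low-attenuation plaque filling a stretch of the
      # lumen: lipid-range core with denser fibrous components inside
      pax <- runif(1, 12, 20)
      pay <- bw / 2 + runif(1, 1.5, 3)
      hu <- runif(1, 0, 40)
      G <- ellipse_blob(H, W, ycx, xc, pay, pax)
      img <- img * (1 - G) + hu * G
      for (k in seq_len(sample(2:4, 1))) {
        fy <- ycx + runif(1, -pay / 2, pay / 2)
        fx <- xc + runif(1, -pax + 3, pax - 3)
        Gf <- ellipse_blob(H, W, fy, fx, runif(1, 1.5, 2.5), runif(1, 2, 4))
        img <- img * (1 - Gf) + runif(1, 80, 120) * Gf
      }
      plaque_mask <- G >= 1
      plaque_center <- c(ycx, xc)
    }
  }

  if (runif(1) < config$text_annotation_prob) img <- stamp_text(img)

  img <- img + matrix(rnorm(H * W, 0, noise_sd), H, W)
  img <- pmin(pmax(img, -1024), 3000)
  attr(img, "patient_id") <- truth$patient_id
  attr(img, "slice_index") <- truth$slice_index
  attr(img, "plaque_mask") <- plaque_mask
  attr(img, "plaque_center") <- plaque_center
  img
}

# Burned-in annotation glyphs: 5x7 dot-matrix blocks at 1200 HU placed
# entirely within 8 px of the top or bottom border (each glyph has exactly
# 15 lit cells, so no glyph can form a >=25 px component on its own).
stamp_text <- function(img) {
  H <- nrow(img); W <- ncol(img)
  n_glyph <- sample(2:4, 1)
  top <- runif(1) < 0.5
  r0 <- if (top) 2L else H - 8L
  x0 <- sample.int(max(1L, W - 7L * n_glyph - 10L), 1)
  for (g in seq_len(n_glyph)) {
    cells <- matrix(FALSE, 7, 5)
    cells[sample.int(35, 15)] <- TRUE
    rows <- r0 + 0:6
    cols <- x0 + (g - 1L) * 7L + 0:4
    if (max(cols) > W) break
    blk <- img[rows, cols]
    blk[cells] <- 1200
    img[rows, cols] <- blk
  }
  img
}

#' Generate all slices for one synthetic patient
#'
#' The slice count is drawn uniformly from the configured range. Positive
#' patients carry exactly `plaque_slices_per_positive` plaque-bearing slices
#' (each calcified with probability `plaque_kind_mix`, otherwise soft);
#' negative patients carry none. This encodes the weak-supervision
#' assumption that a positive case shows its lesion on at least one slice.
#'
#' @param config A [synthetic_config()].
#' @param patient_id Identifier string.
#' @param is_positive Logical patient label.
#' @return A list with `slices` (list of HU matrices) and `truth` (a tibble
#'   with `patient_id`, `slice_index` (0-based), `has_plaque`,
#'   `plaque_kind`, `center_y`, `center_x`).
#' @export
generate_patient <- function(config, patient_id, is_positive) {
  r <- config$slices_per_patient_range
  n <- r[1] + sample.int(r[2] - r[1] + 1L, 1L) - 1L
  has_plaque <- rep(FALSE, n)
  kind <- rep("none", n)
  if (is_positive) {
    idx <- sample.int(n, config$plaque_slices_per_positive)
    has_plaque[idx] <- TRUE
    kind[idx] <- ifelse(runif(length(idx)) < config$plaque_kind_mix,
                        "calcified", "soft")
  }
  slices <- vector("list", n)
  cy <- cx <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tr <- list(patient_id = patient_id, slice_index = i - 1L,
               has_plaque = has_plaque[i], plaque_kind = kind[i])
    slices[[i]] <- generate_slice(config, tr)
    ctr <- attr(slices[[i]], "plaque_center")
    if (!is.null(ctr)) { cy[i] <- ctr[1]; cx[i] <- ctr[2] }
  }
  truth <- tibble(
    patient_id = patient_id, slice_index = seq_len(n) - 1L,
    has_plaque = has_plaque, plaque_kind = kind,
    center_y = cy, center_x = cx
  )
  list(slices = slices, truth = truth)
}

#' Generate a full synthetic cohort
#'
#' Patient labels are independent Bernoulli draws at the configured
#' prevalence; stenosis percentages consistent with the label are written to
#' the manifest (>=50% for positives). The whole cohort is a deterministic
#' function of the configuration, including its seed.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `milcta_cohort`: a list with
#'   `manifest` (tibble: `patient_id`, `artery`, `stenosis_percent`,
#'   `label`, `n_slices`), `truth` (tibble of per-slice ground truth),
#'   `slices` (named list of per-patient slice lists) and `config`.
#' @export
generate_cohort <- function(config) {
  if (config$n_patients < 2) abort("n_patients must be at least 2")
  if (config$prevalence > 0 && config$prevalence * config$n_patients < 1)
    abort(paste0("prevalence * n_patients < 1: the requested cohort cannot ",
                 "reliably contain a positive case; fix the configuration"))
  with_seed(config$rng_seed, {
    n <- config$n_patients
    ids <- sprintf("P%04d", seq_len(n))
    labels <- rbinom(n, 1, config$prevalence)
    pct <- integer(n)
    pct[labels == 1] <- sample(50:100, sum(labels == 1), replace = TRUE)
    neg <- which(labels == 0)
    zero <- runif(length(neg)) < 0.5
    pct[neg[!zero]] <- sample(1:49, sum(!zero), replace = TRUE)

    slices <- vector("list", n); names(slices) <- ids
    truths <- vector("list", n)
    for (i in seq_len(n)) {
      p <- generate_patient(config, ids[i], labels[i] == 1)
      slices[[i]] <- p$slices
      truths[[i]] <- p$truth
    }
    truth <- dplyr::bind_rows(truths)
    manifest <- tibble(
      patient_id = ids, artery = config$artery,
      stenosis_percent = pct, label = labels,
      n_slices = vapply(slices, length, integer(1))
    )
    structure(list(manifest = manifest, truth = truth, slices = slices,
                   config = config),
              class = "milcta_cohort")
  })
}

#' @export
print.milcta_cohort <- function(x, ...) {
  cat(sprintf("<milcta_cohort> %d patients (%d positive), %d slices, artery %s\n",
              nrow(x$manifest), sum(x$manifest$label),
              sum(x$manifest$n_slices), x$config$artery))
  invisible(x)
}

#' Shuffle cohort labels (permutation null)
#'
#' Returns a copy of the cohort whose patient labels (and manifest stenosis
#' percentages) are randomly permuted, breaking the label--image
#' association while keeping marginals. Used for permutation-null checks of
#' the end-to-end pipeline.
#'
#' @param cohort A `milcta_cohort`.
#' @param seed Integer seed for the permutation.
#' @return A `milcta_cohort` with permuted labels.
#' @export
shuffle_labels <- function(cohort, seed = 1L) {
  with_seed(seed, {
    perm <- sample.int(nrow(cohort$manifest))
    cohort$manifest$label <- cohort$manifest$label[perm]
    cohort$manifest$stenosis_percent <- cohort$manifest$stenosis_percent[perm]
    cohort
  })
}
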