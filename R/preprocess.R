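#' Attenuation windows used by the multi-window pipeline
#'
#' The five Hounsfield-unit intervals targeting, in order: fat/low-density
#' tissue, water-range soft tissue (soft plaque), intermediate soft tissue /
#' fibrous plaque, contrast-enhanced lumen, and calcium.
#'
#' @return A list of five `c(low, high)` HU pairs.
#' @export
hu_windows <- function() {
  list(c(-150, -50), c(-50, 50), c(50, 130), c(130, 400), c(400, 1000))
}

#' Parameters of the slice preprocessing pipeline
#'
#' @param windows List of `c(low, high)` HU windows (default [hu_windows()]).
#' @param edge_threshold Fraction of the maximum attainable edge magnitude
#'   below which fused edges are discarded (default 0.10).
#' @param min_object_px Connected components smaller than this many pixels
#'   are removed (default 20; removal is strict, a 20-px object survives).
#' @param connectivity Pixel connectivity for component labelling, 4 or 8.
#' @param border_margin_px Width of the border frame zeroed to suppress
#'   burned-in text annotations (default 8).
#' @param keep_top_k Number of top-ranked components retained (default 6:
#'   enough for the paired vessel-wall edge curves plus spotty or
#'   heterogeneous plaque fragments; burned-in text and sub-20-px noise
#'   are removed upstream).
#' @param output_size Side length (or `c(h, w)`) of the model-facing output.
#' @return An object of class `milcta_preprocess_params`.
#' @export
preprocess_params <- function(windows = hu_windows(), edge_threshold = 0.10,
                              min_object_px = 20L, connectivity = 8L,
                              border_margin_px = 8L, keep_top_k = 6L,
                              output_size = c(224L, 224L)) {
  if (edge_threshold <= 0 || edge_threshold >= 1)
    abort("edge_threshold must lie strictly between 0 and 1")
  if (min_object_px < 1) abort("min_object_px must be >= 1")
  if (!connectivity %in% c(4L, 8L)) abort("connectivity must be 4 or 8")
  for (w in windows)
    if (length(w) != 2 || w[1] >= w[2]) abort("each window must satisfy low < high")
  if (length(output_size) == 1L) output_size <- rep(output_size, 2L)
  structure(list(windows = windows, edge_threshold = edge_threshold,
                 min_object_px = as.integer(min_object_px),
                 connectivity = as.integer(connectivity),
                 border_margin_px = as.integer(border_margin_px),
                 keep_top_k = as.integer(keep_top_k),
                 output_size = as.integer(output_size)),
            class = "milcta_preprocess_params")
}

#' Clip a slice to an attenuation window and rescale to \[0, 1\]
#'
#' Linear map `v -> (clip(v, low, high) - low) / (high - low)`.
#'
#' @param slice Numeric matrix of HU values.
#' @param window `c(low, high)` in HU.
#' @return Matrix of the same shape with values in \[0, 1\].
#' @export
clip_and_normalize <- function(slice, window) {
  if (any(!is.finite(slice))) {
    id <- attr(slice, "patient_id")
    abort(sprintf("non-finite pixels in slice%s",
                  if (is.null(id)) "" else paste0(" of patient ", id)))
  }
  lo <- window[1]; hi <- window[2]
  (pmin(pmax(slice, lo), hi) - lo) / (hi - lo)
}

#' Sobel edge magnitude
#'
#' 3x3 Sobel gradients with reflect padding at the borders; the magnitude
#' `sqrt(gx^2 + gy^2)` is divided by `4 * sqrt(2)` (the largest magnitude a
#' \[0, 1\] image can attain) so the result again lies in \[0, 1\],
#' keeping edge maps from different attenuation windows on a common scale.
#'
#' @param norm Numeric matrix with values in \[0, 1\].
#' @return Edge-magnitude matrix of the same shape, values in \[0, 1\].
#' @export
sobel_edges <- function(norm) {
  H <- nrow(norm); W <- ncol(norm)
  if (H < 3 || W < 3) abort("sobel_edges needs at least a 3x3 input")
  P <- norm[c(2L, seq_len(H), H - 1L), c(2L, seq_len(W), W - 1L)]
  top <- P[seq_len(H), ]; mid <- P[seq_len(H) + 1L, ]; bot <- P[seq_len(H) + 2L, ]
  cl <- seq_len(W); cm <- cl + 1L; cr <- cl + 2L
  gx <- (top[, cr] + 2 * mid[, cr] + bot[, cr]) -
        (top[, cl] + 2 * mid[, cl] + bot[, cl])
  gy <- (bot[, cl] + 2 * bot[, cm] + bot[, cr]) -
        (top[, cl] + 2 * top[, cm] + top[, cr])
  sqrt(gx^2 + gy^2) / (4 * sqrt(2))
}

#' Fuse edge maps by pointwise maximum response
#'
#' @param edge_maps Non-empty list of equally shaped edge-magnitude matrices.
#' @return The pointwise maximum.
#' @export
fuse_max <- function(edge_maps) {
  if (length(edge_maps) < 1) abort("fuse_max needs at least one edge map")
  d <- dim(edge_maps[[1]])
  for (m in edge_maps)
    if (!identical(dim(m), d)) abort("edge maps must share the same shape")
  Reduce(pmax, edge_maps)
}

# Connected-component labelling of a logical mask via a pixel-adjacency
# graph (EBImage::bwlabel is 4-connected only; 8-connectivity is the
# default here). Components are renumbered in scan order for determinism.
label_components <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, H, W)
  if (length(idx) == 0L) return(lab)
  id <- matrix(0L, H, W)
  id[idx] <- seq_along(idx)
  shifts <- list(c(1L, 0L), c(0L, 1L))                     # down, right
  if (connectivity == 8L)
    shifts <- c(shifts, list(c(1L, 1L), c(-1L, 1L)))       # diagonals
  edges <- list()
  r <- ((idx - 1L) %% H) + 1L
  cc <- ((idx - 1L) %/% H) + 1L
  for (s in shifts) {
    r2 <- r + s[1]; c2 <- cc + s[2]
    ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
    nb <- id[cbind(r2[ok], c2[ok])]
    hit <- nb > 0L
    edges[[length(edges) + 1L]] <- cbind(id[idx[ok]][hit], nb[hit])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(el) && nrow(el) > 0)
    g <- igraph::add_edges(g, t(el))
  memb <- igraph::components(g)$membership
  memb <- match(memb, unique(memb))   # scan-order renumbering
  lab[idx] <- memb
  lab
}

#' Label connected components and rank them by shape metrics
#'
#' Components of a binary mask are labelled (4- or 8-connectivity) and
#' described by pixel area, major axis length of the moment-equivalent
#' ellipse, and perimeter (EBImage's weighted boundary estimator). Each
#' metric is min--max normalized across components (degenerate ranges map
#' to 1), the composite score is their mean, and components are ranked by
#' descending score with ties broken by larger area then smaller label id.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param params A [preprocess_params()].
#' @return A tibble with columns `label`, `area`, `major_axis_length`,
#'   `perimeter`, `composite_score`, `rank` (zero rows for an empty mask).
#' @export
label_and_rank <- function(mask, params = preprocess_params()) {
  mask <- mask > 0
  lab <- label_components(mask, params$connectivity)
  rank_components(lab)
}

# Rank the components of an existing label matrix (see label_and_rank).
rank_components <- function(lab) {
  n <- max(lab)
  if (n == 0L)
    return(tibble(label = integer(), area = numeric(),
                  major_axis_length = numeric(), perimeter = numeric(),
                  composite_score = numeric(), rank = integer()))
  sh <- EBImage::computeFeatures.shape(lab)
  mo <- EBImage::computeFeatures.moment(lab)
  sh <- matrix(sh, nrow = n, dimnames = dimnames(sh))
  mo <- matrix(mo, nrow = n, dimnames = dimnames(mo))
  area <- sh[, "s.area"]
  per <- sh[, "s.perimeter"]
  maj <- mo[, "m.majoraxis"]
  mm <- function(x) {
    r <- range(x)
    if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else rep(1, length(x))
  }
  score <- (mm(area) + mm(maj) + mm(per)) / 3
  ord <- order(-score, -area, seq_len(n))
  rank <- integer(n); rank[ord] <- seq_len(n)
  tibble(label = seq_len(n), area = as.numeric(area),
         major_axis_length = as.numeric(maj), perimeter = as.numeric(per),
         composite_score = as.numeric(score), rank = rank)
}

#' Threshold a fused edge map and clean it
#'
#' Pixels at or above `edge_threshold` form the initial mask; a border frame
#' of `border_margin_px` is zeroed (burned-in text suppression); connected
#' components with fewer than `min_object_px` pixels are removed (strictly
#' below: a `min_object_px`-sized object survives).
#'
#' @param fused Edge-magnitude matrix in \[0, 1\].
#' @param params A [preprocess_params()].
#' @return Logical mask of the same shape.
#' @export
threshold_and_clean <- function(fused, params = preprocess_params()) {
  mask <- fused >= params$edge_threshold
  m <- params$border_margin_px
  if (m > 0) {
    H <- nrow(mask); W <- ncol(mask)
    mask[c(seq_len(min(m, H)), seq(max(1L, H - m + 1L), H)), ] <- FALSE
    mask[, c(seq_len(min(m, W)), seq(max(1L, W - m + 1L), W))] <- FALSE
  }
  lab <- label_components(mask, params$connectivity)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    small <- which(sizes < params$min_object_px)
    if (length(small)) mask[lab %in% small] <- FALSE
  }
  mask
}

# Aspect-preserving resize with zero padding to a target size. Downscaling
# is preceded by a Gaussian anti-aliasing filter (sigma = (1/s - 1)/2) so
# thin edge structures keep their energy instead of aliasing away.
resize_pad <- function(img, out_h, out_w) {
  H <- nrow(img); W <- ncol(img)
  s <- min(out_h / H, out_w / W)
  nh <- max(1L, round(H * s)); nw <- max(1L, round(W * s))
  if (s < 1) {
    sigma <- (1 / s - 1) / 2
    img <- as.matrix(EBImage::imageData(
      EBImage::gblur(EBImage::Image(img), sigma = sigma)))
  }
  r <- EBImage::resize(EBImage::Image(img), w = nh, h = nw)
  r <- as.matrix(EBImage::imageData(r))
  out <- matrix(0, out_h, out_w)
  y0 <- (out_h - nh) %/% 2L; x0 <- (out_w - nw) %/% 2L
  out[y0 + seq_len(nh), x0 + seq_len(nw)] <- r
  pmin(pmax(out, 0), 1)
}

#' Run the full preprocessing pipeline on one slice
#'
#' Window -> clip/normalize -> Sobel -> maximum-response fusion ->
#' threshold + border text removal + small-object removal -> connected
#' component ranking -> keep the `keep_top_k` best components -> mask the
#' fused edge map -> aspect-preserving resize with zero padding.
#'
#' @param slice HU matrix.
#' @param params A [preprocess_params()].
#' @return A list with `output` (matrix of `output_size`, values in
#'   \[0, 1\]), `retained_mask` (logical, source resolution) and
#'   `components` (the ranked component tibble).
#' @export
preprocess_slice <- function(slice, params = preprocess_params()) {
  edges <- lapply(params$windows,
                  function(w) sobel_edges(clip_and_normalize(slice, w)))
  fused <- fuse_max(edges)
  mask <- threshold_and_clean(fused, params)
  lab <- label_components(mask, params$connectivity)
  comp <- rank_components(lab)
  if (nrow(comp) > 0) {
    keep <- comp$label[comp$rank <= params$keep_top_k]
    retained <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  } else {
    retained <- mask & FALSE
  }
  out <- resize_pad(fused * retained, params$output_size[1], params$output_size[2])
  list(output = out, retained_mask = retained, components = comp)
}

#' Preprocess every slice of a cohort
#'
#' @param cohort A `milcta_cohort` (or any list with `slices` as a named
#'   list of per-patient HU-matrix lists).
#' @param params A [preprocess_params()].
#' @param keep_masks Keep per-slice retained masks (memory-heavy; default
#'   FALSE).
#' @return A list with `x` (array `h x w x n_slices` of processed slices),
#'   `index` (tibble: `patient_id`, `slice_index`, `pos` giving each
#'   slice's plane in `x`) and optionally `masks`.
#' @export
preprocess_cohort <- function(cohort, params = preprocess_params(),
                              keep_masks = FALSE) {
  ids <- names(cohort$slices)
  total <- sum(vapply(cohort$slices, length, integer(1)))
  x <- array(0, c(params$output_size[1], params$output_size[2], total))
  pid <- character(total); sidx <- integer(total)
  masks <- if (keep_masks) vector("list", total) else NULL
  k <- 0L
  for (id in ids) {
    for (i in seq_along(cohort$slices[[id]])) {
      k <- k + 1L
      pr <- preprocess_slice(cohort$slices[[id]][[i]], params)
      x[, , k] <- pr$output
      pid[k] <- id; sidx[k] <- i - 1L
      if (keep_masks) masks[[k]] <- pr$retained_mask
    }
  }
  out <- list(x = x, index = tibble(patient_id = pid, slice_index = sidx,
                                    pos = seq_len(total)))
  if (keep_masks) out$masks <- masks
  out
}
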