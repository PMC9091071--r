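#' Copy-paste lesion augmentation with random rescaling
#'
#' Training-time augmentation for the detector: one annotated tumor region
#' is copied, its width and height are independently rescaled by factors
#' drawn uniformly from `[scale_low, scale_high]` (nearest-neighbor
#' resampling), and the copy is pasted at a random location whose center
#' lies in the central vertical band of the image (the middle 40% of the
#' width, full height, where the spine runs). A placement is accepted only
#' when the pasted box has IoU at most 0.2 with every existing annotation
#' and lies fully inside the image; after `max_attempts` failed placements
#' the slice is returned unchanged with a notice.
#'
#' Pre-existing annotations are never modified; the pasted region's box and
#' class are appended.
#'
#' @param slice An [annotated_slice()].
#' @param scale_low,scale_high Rescaling factor range, `0 < scale_low <=
#'   scale_high`.
#' @param max_attempts Placement attempts before giving up.
#' @return An [annotated_slice()] with materialized image.
#' @export
multiscale_selfcutmix <- function(slice, scale_low = 0.5, scale_high = 1,
                                  max_attempts = 10L) {
  stopifnot(inherits(slice, "annotated_slice"))
  if (scale_low <= 0 || scale_low > scale_high)
    abort("need 0 < scale_low <= scale_high")
  if (nrow(slice$boxes) == 0L) return(slice)
  img <- slice_image(slice)
  h <- nrow(img); w <- ncol(img)
  src <- slice$boxes[sample.int(nrow(slice$boxes), 1L), , drop = FALSE]
  region <- img[(src$y0 + 1):src$y1, (src$x0 + 1):src$x1, drop = FALSE]
  fw <- runif(1, scale_low, scale_high)
  fh <- runif(1, scale_low, scale_high)
  new_w <- max(1L, round((src$x1 - src$x0) * fw))
  new_h <- max(1L, round((src$y1 - src$y0) * fh))
  scaled <- resize_mat(region, new_h, new_w, filter = "none")
  for (attempt in seq_len(max_attempts)) {
    cx <- runif(1, 0.3 * w, 0.7 * w)
    cy <- runif(1, 0, h)
    x0 <- round(cx - new_w / 2); y0 <- round(cy - new_h / 2)
    x1 <- x0 + new_w; y1 <- y0 + new_h
    if (x0 < 0 || y0 < 0 || x1 > w || y1 > h) next
    cand <- bbox(x0, y0, x1, y1)
    if (any(iou_vec(cand, slice$boxes) > 0.2)) next
    img[(y0 + 1):y1, (x0 + 1):x1] <- scaled
    boxes <- dplyr::bind_rows(slice$boxes,
                              box_tbl(x0, y0, x1, y1, src$label))
    return(annotated_slice(slice$slice_index, boxes = boxes, image = img))
  }
  inform("selfcutmix: no valid placement found; slice left unchanged")
  annotated_slice(slice$slice_index, boxes = slice$boxes, image = img)
}

detection_cols <- c("x0", "y0", "x1", "y1", "s_bg", "s_benign", "s_malignant")

empty_detections <- function() {
  tibble::new_tibble(
    c(setNames(rep(list(numeric()), 7L), detection_cols),
      list(confidence = numeric())),
    nrow = 0L)
}

#' Greedy non-maximum suppression
#'
#' Class-agnostic greedy NMS over a detection table: repeatedly keep the
#' highest-confidence remaining detection (confidence = max of the benign
#' and malignant scores) and discard every remaining detection whose IoU
#' with it exceeds `iou_threshold`. Confidence ties are broken by lower
#' `x0`, then lower `y0`. The result is sorted by descending confidence and
#' is idempotent: no kept pair overlaps above the threshold.
#'
#' @param detections Tibble with columns `x0, y0, x1, y1, s_bg, s_benign,
#'   s_malignant`.
#' @param iou_threshold Suppression threshold in (0, 1].
#' @return The kept subset, sorted by descending confidence, with a
#'   `confidence` column.
#' @export
nms <- function(detections, iou_threshold = 0.5) {
  if (iou_threshold <= 0 || iou_threshold > 1)
    abort("iou_threshold must be in (0, 1]")
  detections <- as_tibble(detections)
  if (nrow(detections) == 0L) return(empty_detections())
  detections$confidence <- pmax(detections$s_benign, detections$s_malignant)
  ord <- order(-detections$confidence, detections$x0, detections$y0)
  detections <- detections[ord, , drop = FALSE]
  keep <- logical(nrow(detections))
  alive <- rep(TRUE, nrow(detections))
  for (i in seq_len(nrow(detections))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (i == nrow(detections)) break
    rest <- which(alive & seq_len(nrow(detections)) > i)
    if (length(rest) == 0L) break
    bi <- bbox(detections$x0[i], detections$y0[i],
               detections$x1[i], detections$y1[i])
    ious <- iou_vec(bi, detections[rest, , drop = FALSE])
    alive[rest[ious > iou_threshold]] <- FALSE
  }
  detections[keep, , drop = FALSE]
}

#' Reduce one image's detections to a benign/malignant probability pair
#'
#' The per-image detection evidence term: the single highest-confidence
#' post-NMS detection contributes its benign and malignant scores,
#' renormalized to sum to 1 with the background score dropped. An image with
#' no detections (or a top detection with zero mass on both tumor classes)
#' contributes no evidence and returns `NULL`.
#'
#' @param detections Post-NMS detection tibble for one image.
#' @return A probability pair `c(p_b, p_m)`, or `NULL` when there is no
#'   usable detection.
#' @export
image_probability <- function(detections) {
  if (is.null(detections) || nrow(detections) == 0L) return(NULL)
  conf <- pmax(detections$s_benign, detections$s_malignant)
  ord <- order(-conf, detections$x0, detections$y0)
  top <- detections[ord[1L], , drop = FALSE]
  s <- top$s_benign + top$s_malignant
  if (s <= 0) return(NULL)
  prob_pair(top$s_benign / s, top$s_malignant / s, normalize = FALSE)
}

# appearance features of one box: intensity statistics, gradient energy,
# and shape terms; the linear detector head is trained on these
box_features <- function(img, box) {
  h <- nrow(img); w <- ncol(img)
  b <- bbox_clamp(box, h, w)
  if (is.null(b)) return(NULL)
  sub <- img[(b[["y0"]] + 1):b[["y1"]], (b[["x0"]] + 1):b[["x1"]], drop = FALSE]
  gx <- if (ncol(sub) > 1L) sub[, -1L, drop = FALSE] - sub[, -ncol(sub), drop = FALSE] else 0
  gy <- if (nrow(sub) > 1L) sub[-1L, , drop = FALSE] - sub[-nrow(sub), , drop = FALSE] else 0
  c(mean = mean(sub),
    variance = stats::var(as.numeric(sub)) %||% 0,
    grad_energy = mean(gx^2) + mean(gy^2),
    log_area = log(bbox_area(b)),
    aspect = (b[["x1"]] - b[["x0"]]) / (b[["y1"]] - b[["y0"]]))
}

# positive part of (image - background). The background is the elementwise
# max of a smooth low-pass field and a per-column median profile; the column
# profile soaks up the bright vertebral band so that lesions overlapping the
# spine still stand out.
anomaly_map <- function(img, coarse = 8L) {
  bg <- resize_mat(resize_mat(img, coarse, coarse), nrow(img), ncol(img))
  # column medians on a row subsample: the profile only needs to capture the
  # vertical vertebral band, not fine detail
  colmed <- apply(img[seq(1L, nrow(img), by = 3L), , drop = FALSE], 2L, median)
  pmax(img - pmax(bg, matrix(colmed, nrow(img), ncol(img), byrow = TRUE)), 0)
}

# connected components of a binary mask as boxes, filtered by pixel area;
# the mask is dilated to bridge broken lesion rims, hole-filled so a rim
# yields the full lesion extent, then eroded back (a closing) so the box
# stays tight to the lesion
proposals_from_mask <- function(binmask, min_area, max_area, dilate = 3L) {
  if (dilate > 0L) {
    brush <- EBImage::makeBrush(dilate, "disc")
    binmask <- EBImage::erode(
      EBImage::fillHull(EBImage::dilate(binmask, brush)), brush)
  }
  lab <- EBImage::bwlabel(binmask)
  idx <- which(lab > 0)
  if (length(idx) == 0L) return(list())
  h <- nrow(binmask)
  rows <- (idx - 1L) %% h + 1L
  cols <- (idx - 1L) %/% h + 1L
  comp <- lab[idx]
  out <- list()
  for (g in split(seq_along(idx), comp)) {
    if (length(g) < min_area || length(g) > max_area) next
    out[[length(out) + 1L]] <- bbox(min(cols[g]) - 1, min(rows[g]) - 1,
                                    max(cols[g]), max(rows[g]))
  }
  out
}

# candidate boxes: positive part of (image - smooth background) above the
# trained threshold, connected components, area-filtered
propose_boxes <- function(img, threshold, min_area, max_area) {
  proposals_from_mask(anomaly_map(img) > threshold, min_area, max_area)
}

# random background boxes avoiding the annotations, lesion-like sizes
random_bg_boxes <- function(slice, n, min_side = 10L) {
  h <- slice$shape[1L]; w <- slice$shape[2L]
  out <- list()
  for (i in seq_len(4L * n)) {
    if (length(out) >= n) break
    bw <- round(runif(1, min_side, 0.35 * w))
    bh <- round(runif(1, min_side, 0.35 * h))
    x0 <- floor(runif(1, 0, w - bw)); y0 <- floor(runif(1, 0, h - bh))
    cand <- bbox(x0, y0, x0 + bw, y0 + bh)
    if (nrow(slice$boxes) > 0L && any(iou_vec(cand, slice$boxes) > 0.1)) next
    out[[length(out) + 1L]] <- cand
  }
  out
}

#' Train the reference tumor detector
#'
#' A deliberately lightweight, fully deterministic detector standing behind
#' the detector contract; any detector producing the documented detection
#' table can be substituted at the CSV boundary. It works in two stages:
#'
#' 1. *Proposals*: the positive part of (image minus a smooth background
#'    estimate) is thresholded and connected components in the lesion area
#'    range become candidate boxes. The threshold is trained: candidate
#'    quantiles of the anomaly values outside annotated boxes are scanned
#'    and the one maximizing ground-truth box recall (IoU >= 0.5), with
#'    proposal count as tie-break penalty, is kept.
#' 2. *Scoring*: a multinomial logistic model over simple appearance
#'    features (mean, variance, gradient energy, log area, aspect ratio)
#'    assigns each box a background/benign/malignant score triple summing
#'    to 1. It is fitted on annotated boxes (positives) and random
#'    background boxes, with copy-paste augmentation
#'    ([multiscale_selfcutmix()]) applied to training slices with
#'    probability `cutmix_prob`.
#'
#' @param manifest Training [dataset_manifest()]; must contain annotated
#'   boxes of both classes.
#' @param params Optional list overriding `min_area`, `max_area`,
#'   `cutmix_prob`, `bg_per_slice`, `max_threshold_slices`,
#'   `threshold_quantiles`, `nms_threshold`, `decay`.
#' @param seed Integer seed; the same seed gives an identical detector.
#' @return An object of class `ref_detector` with a [detect_slice()] method
#'   via [detect_cohort()].
#' @export
train_reference_detector <- function(manifest, params = list(), seed = 1L) {
  p <- utils::modifyList(list(
    min_area = 60, max_area = 0.25, cutmix_prob = 0.25, bg_per_slice = 2L,
    max_threshold_slices = 80L, threshold_quantiles = c(0.95, 0.98, 0.99, 0.995),
    nms_threshold = 0.5, decay = 1e-3), params)
  slices <- annotated_slice_refs(manifest)
  if (length(slices) == 0L) abort("manifest has no annotated slices")
  labels_present <- unique(unlist(lapply(slices, function(s) s$slice$boxes$label)))
  if (length(labels_present) < 2L)
    abort("detector training needs annotated boxes of both classes")

  withr::with_seed(seed, {
    # feature table from annotated + background + augmented boxes
    feats <- list(); labs <- character(0)
    for (ref in slices) {
      sl <- ref$slice
      if (runif(1) < p$cutmix_prob) sl <- multiscale_selfcutmix(sl)
      img <- slice_image(sl)
      for (bi in seq_len(nrow(sl$boxes))) {
        b <- sl$boxes[bi, , drop = FALSE]
        f <- box_features(img, bbox(b$x0, b$y0, b$x1, b$y1))
        if (is.null(f)) next
        feats[[length(feats) + 1L]] <- f
        labs <- c(labs, b$label)
      }
      for (bb in random_bg_boxes(sl, p$bg_per_slice)) {
        f <- box_features(img, bb)
        if (is.null(f)) next
        feats[[length(feats) + 1L]] <- f
        labs <- c(labs, "bg")
      }
    }
    X <- do.call(rbind, feats)
    y <- factor(labs, levels = c("bg", "benign", "malignant"))
    center <- colMeans(X); scale <- pmax(apply(X, 2L, stats::sd), 1e-8)
    Xs <- scale(X, center = center, scale = scale)
    df <- data.frame(Xs, y = y)
    capture.output(
      model <- nnet::multinom(y ~ ., data = df, decay = p$decay,
                              maxit = 300, trace = FALSE))

    # train the proposal threshold on a subsample of slices
    sub <- slices
    if (length(sub) > p$max_threshold_slices)
      sub <- sub[sort(sample.int(length(sub), p$max_threshold_slices))]
    outside_vals <- list(); cache <- list()
    for (i in seq_along(sub)) {
      img <- slice_image(sub[[i]]$slice)
      anomaly <- anomaly_map(img)
      inbox <- matrix(FALSE, nrow(img), ncol(img))
      bx <- sub[[i]]$slice$boxes
      for (bi in seq_len(nrow(bx)))
        inbox[(bx$y0[bi] + 1):bx$y1[bi], (bx$x0[bi] + 1):bx$x1[bi]] <- TRUE
      outside_vals[[i]] <- anomaly[!inbox][seq(1, sum(!inbox), by = 17L)]
      cache[[i]] <- list(anomaly = anomaly, boxes = bx)
    }
    pool <- unlist(outside_vals)
    max_area_px <- p$max_area * prod(dim(cache[[1L]]$anomaly))
    best <- NULL
    for (q in p$threshold_quantiles) {
      thr <- quantile(pool, q, names = FALSE)
      hit <- 0L; tot <- 0L; n_prop <- 0L
      for (cc in cache) {
        props <- proposals_from_mask(cc$anomaly > thr, p$min_area, max_area_px)
        n_prop <- n_prop + length(props)
        for (bi in seq_len(nrow(cc$boxes))) {
          tot <- tot + 1L
          gt <- bbox(cc$boxes$x0[bi], cc$boxes$y0[bi], cc$boxes$x1[bi], cc$boxes$y1[bi])
          if (length(props) > 0L &&
              any(vapply(props, function(pp) iou(pp, gt), numeric(1)) >= 0.5))
            hit <- hit + 1L
        }
      }
      score <- hit / max(tot, 1L) - 1e-6 * n_prop
      if (is.null(best) || score > best$score)
        best <- list(score = score, threshold = thr, q = q)
    }
  })

  structure(list(model = model, center = center, scale = scale,
                 threshold = best$threshold, threshold_quantile = best$q,
                 min_area = p$min_area, max_area = p$max_area,
                 nms_threshold = p$nms_threshold, seed = seed),
            class = "ref_detector")
}

#' @export
print.ref_detector <- function(x, ...) {
  cat(sprintf("<ref_detector> anomaly threshold %.4f (q=%.3f), NMS IoU %.2f\n",
              x$threshold, x$threshold_quantile, x$nms_threshold))
  invisible(x)
}

#' @rdname train_reference_detector
#' @param x A `ref_detector`.
#' @param ... Unused.
#' @export
tidy.ref_detector <- function(x, ...) {
  co <- stats::coef(x$model)
  as_tibble(co, rownames = "class") |>
    tidyr::pivot_longer(-"class", names_to = "term", values_to = "estimate")
}

# flatten a manifest to slice references (patient/sequence context attached)
annotated_slice_refs <- function(manifest, annotated_only = TRUE) {
  out <- list()
  for (p in manifest$patients) for (sq in p$sequences) for (s in sq$slices) {
    if (annotated_only && nrow(s$boxes) == 0L) next
    out[[length(out) + 1L]] <- list(patient_id = p$patient_id,
                                    sequence_id = sq$sequence_id,
                                    modality = sq$modality, slice = s)
  }
  out
}

#' Detect tumors on one slice
#'
#' Runs the reference detector on a single image: proposals from the
#' trained anomaly threshold, tri-class scoring, then greedy NMS.
#'
#' @param detector A trained [train_reference_detector()] object.
#' @param img Numeric matrix, or an [annotated_slice()].
#' @return Post-NMS detection tibble (`x0, y0, x1, y1, s_bg, s_benign,
#'   s_malignant, confidence`), possibly empty.
#' @export
detect_slice <- function(detector, img) {
  stopifnot(inherits(detector, "ref_detector"))
  if (inherits(img, "annotated_slice")) img <- slice_image(img)
  max_area_px <- detector$max_area * nrow(img) * ncol(img)
  props <- propose_boxes(img, detector$threshold, detector$min_area, max_area_px)
  if (length(props) == 0L) return(empty_detections())
  X <- do.call(rbind, lapply(props, function(b) box_features(img, b)))
  Xs <- scale(X, center = detector$center, scale = detector$scale)
  probs <- predict(detector$model, newdata = data.frame(Xs), type = "probs")
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L,
                                           dimnames = list(NULL, names(probs)))
  det <- tibble::new_tibble(list(
    x0 = vapply(props, `[[`, numeric(1), "x0"),
    y0 = vapply(props, `[[`, numeric(1), "y0"),
    x1 = vapply(props, `[[`, numeric(1), "x1"),
    y1 = vapply(props, `[[`, numeric(1), "y1"),
    s_bg = unname(probs[, "bg"]),
    s_benign = unname(probs[, "benign"]),
    s_malignant = unname(probs[, "malignant"])), nrow = length(props))
  # only boxes the scorer considers tumor rather than background are
  # emitted as detections
  det <- det[pmax(det$s_benign, det$s_malignant) > det$s_bg, , drop = FALSE]
  nms(det, detector$nms_threshold)
}

#' Run a detector over a whole cohort
#'
#' Generic over the detector contract: any object with a `detect_cohort()`
#' method producing the documented table satisfies it. The reference
#' implementation processes every slice (annotated or not) with
#' [detect_slice()].
#'
#' @param detector A trained detector, e.g. [train_reference_detector()].
#' @param manifest A [dataset_manifest()].
#' @return Detection table with one row per kept detection: `patient_id,
#'   sequence_id, slice_index, x0, y0, x1, y1, s_bg, s_benign, s_malignant,
#'   confidence`. This table is also the interchange format for externally
#'   produced detections.
#' @export
detect_cohort <- function(detector, manifest) {
  UseMethod("detect_cohort")
}

#' @rdname detect_cohort
#' @export
detect_cohort.ref_detector <- function(detector, manifest) {
  rows <- list()
  for (ref in annotated_slice_refs(manifest, annotated_only = FALSE)) {
    det <- detect_slice(detector, ref$slice)
    if (nrow(det) == 0L) next
    det$patient_id <- ref$patient_id
    det$sequence_id <- ref$sequence_id
    det$slice_index <- ref$slice$slice_index
    rows[[length(rows) + 1L]] <- det
  }
  if (length(rows) == 0L)
    return(tibble(patient_id = character(), sequence_id = character(),
                  slice_index = integer(), x0 = numeric(), y0 = numeric(),
                  x1 = numeric(), y1 = numeric(), s_bg = numeric(),
                  s_benign = numeric(), s_malignant = numeric(),
                  confidence = numeric()))
  dplyr::bind_rows(rows) |>
    dplyr::select("patient_id", "sequence_id", "slice_index",
                  dplyr::all_of(detection_cols), "confidence")
}
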