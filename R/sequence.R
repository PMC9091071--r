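#' Select the largest tumor region across a sequence
#'
#' Scans boxes over all slices of a sequence and returns the one with
#' maximal area. Ties are broken by lower slice index, then lower `x0`, so
#' the choice is deterministic.
#'
#' @param boxes_by_slice Tibble with columns `slice_index, x0, y0, x1, y1`
#'   (one row per box; a slice may contribute several).
#' @return List with `slice_index` and `box` (a [bbox()]), or `NULL` when no
#'   boxes are present.
#' @export
largest_region <- function(boxes_by_slice) {
  b <- as_tibble(boxes_by_slice)
  if (nrow(b) == 0L) return(NULL)
  area <- (b$x1 - b$x0) * (b$y1 - b$y0)
  ord <- order(-area, b$slice_index, b$x0)
  top <- b[ord[1L], , drop = FALSE]
  list(slice_index = top$slice_index[1L],
       box = bbox(top$x0, top$y0, top$x1, top$y1))
}

# window of N consecutive 0-based positions "centered" on `center`:
# floor(N/2) positions before the center, the center, and the remainder
# after; shifted to fit the sequence ends; cycling 0,1,...,L-1,0,1,... when
# the sequence is shorter than N
stack_positions <- function(L, center, N) {
  if (L < N) return(rep(0:(L - 1L), length.out = N))
  start <- center - floor(N / 2)
  start <- min(max(start, 0L), L - N)
  start + 0:(N - 1L)
}

#' Extract an N-frame crop stack from a sequence
#'
#' The sequence classifier's input: the same rectangular region, cropped
#' from `N` consecutive slices around `center_slice` and resized to 112x112
#' pixels by bilinear interpolation. The window is shifted to fit when it
#' would overrun the sequence ends; when the sequence has fewer than `N`
#' slices, positions cycle from the start (`0, 1, ..., L-1, 0, 1, ...`)
#' until `N` frames are taken, so the stack always has exactly `N` frames.
#'
#' @param sequence An [mri_sequence()].
#' @param box The region to crop ([bbox()]); clamped to image bounds.
#' @param center_slice 0-based slice *position* at the window center.
#' @param N Number of frames (default 16).
#' @return An object of class `crop_stack`: list of `N` 112x112 frames plus
#'   the source box and window positions.
#' @export
extract_crop_stack <- function(sequence, box, center_slice, N = 16L) {
  stopifnot(inherits(sequence, "mri_sequence"))
  if (N < 1L) abort("N must be at least 1")
  L <- length(sequence$slices)
  if (center_slice < 0L || center_slice >= L)
    abort(sprintf("center_slice %d is not a valid position in a %d-slice sequence",
                  center_slice, L))
  h <- sequence$shape[1L]; w <- sequence$shape[2L]
  b <- bbox_clamp(box, h, w)
  if (is.null(b)) abort("crop box lies fully outside the image")
  pos <- stack_positions(L, as.integer(center_slice), as.integer(N))
  frames <- vector("list", N)
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(N)) {
    key <- as.character(pos[i])
    if (is.null(cache[[key]])) {
      img <- slice_image(sequence$slices[[pos[i] + 1L]])
      sub <- img[(b[["y0"]] + 1):b[["y1"]], (b[["x0"]] + 1):b[["x1"]], drop = FALSE]
      cache[[key]] <- resize_mat(sub, 112L, 112L)
    }
    frames[[i]] <- cache[[key]]
  }
  structure(list(frames = frames, source_box = b, center_slice = center_slice,
                 positions = pos, N = as.integer(N)),
            class = "crop_stack")
}

# positions (0-based) of slices carrying at least one annotation
annotated_positions <- function(sequence) {
  which(vapply(sequence$slices, function(s) nrow(s$boxes) > 0L, logical(1))) - 1L
}

# labeled boxes of a sequence as a slice_index-keyed table
labeled_boxes <- function(sequence) {
  rows <- lapply(sequence$slices, function(s) {
    if (nrow(s$boxes) == 0L) return(NULL)
    dplyr::mutate(s$boxes, slice_index = s$slice_index)
  })
  dplyr::bind_rows(rows)
}

#' Draw one training crop stack from a labeled sequence
#'
#' Training-time sampling rule: the crop box is the largest *labeled* region
#' of the sequence; with probability 0.5 the window center is drawn
#' uniformly from the annotated slice positions (tumor-bearing frames), and
#' with probability 0.5 uniformly from all slice positions (plain
#' acquisition order). Consumes the active R random stream.
#'
#' @param sequence An [mri_sequence()] with at least one labeled slice.
#' @param N Number of frames.
#' @return A `crop_stack` (see [extract_crop_stack()]).
#' @export
sample_training_stack <- function(sequence, N = 16L) {
  lb <- labeled_boxes(sequence)
  if (is.null(lb) || nrow(lb) == 0L)
    abort("sequence has no labeled boxes to sample a training stack from")
  lr <- largest_region(lb)
  L <- length(sequence$slices)
  ann <- annotated_positions(sequence)
  center <- if (runif(1) < 0.5) {
    ann[sample.int(length(ann), 1L)]
  } else {
    sample.int(L, 1L) - 1L
  }
  extract_crop_stack(sequence, lr$box, center, N)
}

#' Draw class-balanced sequence references
#'
#' Training-time sampler over the sequences of a manifest with per-class
#' draw probability inversely proportional to the class's sequence count,
#' so benign and malignant sequences are drawn equally often in expectation
#' regardless of class imbalance. Consumes the active R random stream.
#'
#' @param manifest A [dataset_manifest()] with sequences of both classes.
#' @param n_draws Number of draws.
#' @return Tibble `patient_id, sequence_id, true_class`, one row per draw.
#' @export
sample_sequences_balanced <- function(manifest, n_draws) {
  tb <- tidy(manifest)
  counts <- table(factor(tb$true_class, levels = c("benign", "malignant")))
  if (any(counts == 0L))
    abort("balanced sampling needs sequences of both classes")
  wts <- 1 / as.numeric(counts[tb$true_class])
  idx <- sample.int(nrow(tb), n_draws, replace = TRUE, prob = wts / sum(wts))
  tb[idx, c("patient_id", "sequence_id", "true_class")]
}

feature_names_11 <- c("mean", "variance", "grad_energy", paste0("hist", 1:8))

# appearance features of one 112x112 frame: mean, variance, gradient energy
# and an 8-bin intensity histogram
frame_features <- function(f) {
  gx <- f[, -1L, drop = FALSE] - f[, -ncol(f), drop = FALSE]
  gy <- f[-1L, , drop = FALSE] - f[-nrow(f), , drop = FALSE]
  hist8 <- tabulate(pmin(pmax(floor(f * 8) + 1, 1), 8), nbins = 8L) / length(f)
  c(mean(f), stats::var(as.numeric(f)), mean(gx^2) + mean(gy^2), hist8)
}

# per-frame features averaged over the stack's N frames
stack_features <- function(stack) {
  per_frame <- vapply(stack$frames, frame_features, numeric(11L))
  setNames(rowMeans(per_frame), feature_names_11)
}

#' Train the reference sequence classifier
#'
#' A lightweight, deterministic stand-in for a deep sequence classifier,
#' behind the same contract (any model emitting per-sequence benign and
#' malignant probabilities can be substituted at the CSV boundary). Crop
#' stacks drawn by [sample_training_stack()] over class-balanced sequence
#' draws ([sample_sequences_balanced()]) are summarized by per-frame
#' appearance features (mean, variance, gradient energy, 8-bin intensity
#' histogram) averaged over the `N` frames, and a ridge-regularized logistic
#' model is fitted on them.
#'
#' @param manifest Training [dataset_manifest()] with labeled sequences of
#'   both classes.
#' @param N Frames per stack (default 16).
#' @param params Optional list overriding `draws_per_sequence` (default 4)
#'   and ridge penalty `lambda` (default 1e-2).
#' @param seed Integer seed; the same seed gives identical coefficients.
#' @return An object of class `ref_classifier`.
#' @export
train_reference_classifier <- function(manifest, N = 16L, params = list(),
                                       seed = 1L) {
  p <- utils::modifyList(list(draws_per_sequence = 4L, lambda = 1e-2), params)
  tb <- tidy(manifest)
  if (length(unique(tb$true_class)) < 2L)
    abort("classifier training needs sequences of both classes")

  # Per sequence, precompute the per-slice-position feature vector of the
  # largest-labeled-region crop. A stack's features are the mean of its
  # frames' features, so any sampled window reduces to averaging cached
  # columns - identical to stack_features(extract_crop_stack(...)) but
  # rendering each slice once.
  cache <- list()
  for (pt in manifest$patients) for (sq in pt$sequences) {
    lb <- labeled_boxes(sq)
    if (is.null(lb) || nrow(lb) == 0L) next
    lr <- largest_region(lb)
    b <- bbox_clamp(lr$box, sq$shape[1L], sq$shape[2L])
    feats <- vapply(sq$slices, function(s) {
      img <- slice_image(s)
      sub <- img[(b[["y0"]] + 1):b[["y1"]], (b[["x0"]] + 1):b[["x1"]], drop = FALSE]
      frame_features(resize_mat(sub, 112L, 112L))
    }, numeric(11L))
    cache[[paste(pt$patient_id, sq$sequence_id)]] <- list(
      feats = feats, L = length(sq$slices), ann = annotated_positions(sq))
  }

  tb$key <- paste(tb$patient_id, tb$sequence_id)
  tb <- tb[tb$key %in% names(cache), , drop = FALSE]
  if (length(unique(tb$true_class)) < 2L)
    abort("classifier training needs labeled sequences of both classes")
  counts <- table(factor(tb$true_class, levels = c("benign", "malignant")))
  wts <- 1 / as.numeric(counts[tb$true_class])
  withr::with_seed(seed, {
    n_draws <- p$draws_per_sequence * nrow(tb)
    draws <- tb[sample.int(nrow(tb), n_draws, replace = TRUE,
                           prob = wts / sum(wts)), , drop = FALSE]
    X <- matrix(NA_real_, nrow(draws), 11L)
    y <- character(nrow(draws))
    for (i in seq_len(nrow(draws))) {
      cc <- cache[[draws$key[i]]]
      center <- if (runif(1) < 0.5) {
        cc$ann[sample.int(length(cc$ann), 1L)]
      } else {
        sample.int(cc$L, 1L) - 1L
      }
      pos <- stack_positions(cc$L, center, as.integer(N))
      X[i, ] <- rowMeans(cc$feats[, pos + 1L, drop = FALSE])
      y[i] <- draws$true_class[i]
    }
  })
  colnames(X) <- feature_names_11
  fit <- glmnet::glmnet(X, factor(y, levels = c("benign", "malignant")),
                        family = "binomial", alpha = 0, lambda = p$lambda,
                        standardize = TRUE)
  structure(list(fit = fit, N = as.integer(N), lambda = p$lambda, seed = seed),
            class = "ref_classifier")
}

#' @export
print.ref_classifier <- function(x, ...) {
  cat(sprintf("<ref_classifier> N = %d frames, ridge lambda = %g\n", x$N, x$lambda))
  invisible(x)
}

#' @rdname train_reference_classifier
#' @param x A `ref_classifier`.
#' @param ... Unused.
#' @export
tidy.ref_classifier <- function(x, ...) {
  co <- as.matrix(stats::coef(x$fit))
  tibble(term = rownames(co), estimate = co[, 1L])
}

predict_stack <- function(classifier, stack) {
  f <- matrix(stack_features(stack), nrow = 1L)
  colnames(f) <- c("mean", "variance", "grad_energy", paste0("hist", 1:8))
  p_m <- as.numeric(predict(classifier$fit, f, type = "response"))
  prob_pair(1 - p_m, p_m, normalize = FALSE)
}

#' Classify one sequence from its detected tumor regions
#'
#' Test-time path: the crop box and window center come from the largest
#' *detected* region over the sequence's post-NMS detections
#' ([largest_region()]). A sequence with no detections falls back to a
#' centered box of half the image dimensions at the middle slice (with a
#' notice), so a prediction is always produced.
#'
#' @param classifier A [train_reference_classifier()] object.
#' @param sequence An [mri_sequence()].
#' @param detections Detection table for this sequence (columns
#'   `slice_index, x0, y0, x1, y1`); typically a filtered [detect_cohort()]
#'   result.
#' @param N Frames per stack; defaults to the classifier's `N`.
#' @return Probability pair `c(p_b, p_m)`.
#' @export
classify_sequence <- function(classifier, sequence, detections, N = NULL) {
  N <- N %||% classifier$N
  det <- as_tibble(detections)
  h <- sequence$shape[1L]; w <- sequence$shape[2L]
  if (nrow(det) > 0L) {
    lr <- largest_region(det)
    idx <- vapply(sequence$slices, function(s) s$slice_index, integer(1))
    center <- match(lr$slice_index, idx) - 1L
    if (is.na(center)) abort("detection slice_index not found in sequence")
    box <- lr$box
  } else {
    inform(sprintf("sequence %s has no detections; using centered fallback crop",
                   sequence$sequence_id))
    box <- bbox(w / 4, h / 4, 3 * w / 4, 3 * h / 4)
    center <- (length(sequence$slices) - 1L) %/% 2L
  }
  predict_stack(classifier, extract_crop_stack(sequence, box, center, N))
}

#' Classify every sequence of a cohort
#'
#' Generic over the sequence-classifier contract: any object with a
#' `classify_cohort()` method emitting one probability pair per sequence
#' satisfies it.
#'
#' @param classifier A classifier, e.g. [train_reference_classifier()].
#' @param manifest A [dataset_manifest()].
#' @param detections Cohort detection table from [detect_cohort()].
#' @param N Frames per stack; defaults to the classifier's `N`.
#' @return Tibble `patient_id, sequence_id, p_b, p_m` (the sequence-level
#'   evidence term), one row per sequence.
#' @export
classify_cohort <- function(classifier, manifest, detections, N = NULL) {
  UseMethod("classify_cohort")
}

#' @rdname classify_cohort
#' @export
classify_cohort.ref_classifier <- function(classifier, manifest, detections,
                                           N = NULL) {
  rows <- list()
  for (p in manifest$patients) for (sq in p$sequences) {
    det <- detections[detections$patient_id == p$patient_id &
                        detections$sequence_id == sq$sequence_id, , drop = FALSE]
    pr <- classify_sequence(classifier, sq, det, N)
    rows[[length(rows) + 1L]] <- tibble(
      patient_id = p$patient_id, sequence_id = sq$sequence_id,
      p_b = pr[["p_b"]], p_m = pr[["p_m"]])
  }
  dplyr::bind_rows(rows)
}
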