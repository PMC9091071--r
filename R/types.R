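#' Benign/malignant probability pair
#'
#' The common currency of the three evidence sources: a length-2 named
#' numeric vector `c(p_b, p_m)` with the probability that a tumor is benign
#' (`p_b`) or malignant (`p_m`).
#'
#' @param p_b,p_m Nonnegative numeric scalars.
#' @param normalize If `TRUE` (default) the pair is rescaled to sum to 1;
#'   otherwise it must already sum to 1 within `1e-9`.
#' @return Named numeric vector `c(p_b = ..., p_m = ...)`.
#' @examples
#' prob_pair(0.2, 0.6)
#' @export
prob_pair <- function(p_b, p_m, normalize = TRUE) {
  if (!is.numeric(p_b) || !is.numeric(p_m) || length(p_b) != 1L || length(p_m) != 1L)
    abort("p_b and p_m must be numeric scalars")
  if (is.na(p_b) || is.na(p_m) || p_b < 0 || p_m < 0)
    abort("probabilities must be nonnegative and non-missing")
  s <- p_b + p_m
  if (normalize) {
    if (s <= 0) abort("cannot normalize a pair with zero total mass")
    p_b <- p_b / s
    p_m <- p_m / s
  } else if (abs(s - 1) > 1e-9) {
    abort(sprintf("probability pair sums to %.12f, not 1", s))
  }
  c(p_b = p_b, p_m = p_m)
}

is_prob_pair <- function(x) {
  is.numeric(x) && length(x) == 2L && all(x >= 0) && abs(sum(x) - 1) <= 1e-9
}

#' Rectangular pixel box
#'
#' Boxes use 0-based, half-open pixel coordinates: a box covers integer
#' pixel columns `x0 <= x < x1` and rows `y0 <= y < y1`, so its area is
#' `(x1 - x0) * (y1 - y0)` with no off-by-one ambiguity.
#'
#' @param x0,y0,x1,y1 Numeric coordinates with `x1 > x0`, `y1 > y0`.
#' @return Named numeric vector `c(x0, y0, x1, y1)`.
#' @examples
#' b <- bbox(10, 20, 50, 60)
#' bbox_area(b)
#' @export
bbox <- function(x0, y0, x1, y1) {
  v <- c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
  if (anyNA(v)) abort("box coordinates must not be NA")
  if (x1 <= x0 || y1 <= y0) abort("degenerate box: need x1 > x0 and y1 > y0")
  v
}

#' @rdname bbox
#' @param box A box as returned by [bbox()].
#' @export
bbox_area <- function(box) {
  unname((box[["x1"]] - box[["x0"]]) * (box[["y1"]] - box[["y0"]]))
}

# order-normalize two corner points into a valid box
bbox_from_corners <- function(xa, ya, xb, yb) {
  bbox(min(xa, xb), min(ya, yb), max(xa, xb), max(ya, yb))
}

# clamp a box to an image of height h, width w; NULL if nothing remains
bbox_clamp <- function(box, h, w) {
  x0 <- max(box[["x0"]], 0); y0 <- max(box[["y0"]], 0)
  x1 <- min(box[["x1"]], w); y1 <- min(box[["y1"]], h)
  if (x1 <= x0 || y1 <= y0) return(NULL)
  bbox(x0, y0, x1, y1)
}

#' Intersection over union of two boxes
#'
#' Overlap fraction `|a intersect b| / |a union b|` under the half-open pixel
#' convention. Symmetric, in `[0, 1]`, and `1` exactly for identical boxes.
#'
#' @param a,b Boxes as returned by [bbox()].
#' @return A fraction in `[0, 1]`.
#' @examples
#' iou(bbox(0, 0, 10, 10), bbox(5, 0, 15, 10))  # 1/3
#' @export
iou <- function(a, b) {
  ix <- min(a[["x1"]], b[["x1"]]) - max(a[["x0"]], b[["x0"]])
  iy <- min(a[["y1"]], b[["y1"]]) - max(a[["y0"]], b[["y0"]])
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  inter / (bbox_area(a) + bbox_area(b) - inter)
}

# vectorized IoU of one box against a tibble with x0,y0,x1,y1 columns
iou_vec <- function(box, boxes) {
  if (nrow(boxes) == 0L) return(numeric(0))
  ix <- pmin(box[["x1"]], boxes$x1) - pmax(box[["x0"]], boxes$x0)
  iy <- pmin(box[["y1"]], boxes$y1) - pmax(box[["y0"]], boxes$y0)
  inter <- pmax(ix, 0) * pmax(iy, 0)
  areas <- (boxes$x1 - boxes$x0) * (boxes$y1 - boxes$y0)
  inter / (bbox_area(box) + areas - inter)
}

box_tbl <- function(x0 = numeric(), y0 = numeric(), x1 = numeric(),
                    y1 = numeric(), label = character()) {
  tibble::new_tibble(
    list(x0 = as.numeric(x0), y0 = as.numeric(y0), x1 = as.numeric(x1),
         y1 = as.numeric(y1), label = label),
    nrow = length(x0))
}

empty_boxes <- function() box_tbl()

#' Construct an annotated slice
#'
#' One 2-D grayscale MRI slice together with its rectangular tumor
#' annotations. The pixel data may be held in memory (`image`), on disk
#' (`image_path`, read lazily with [slice_image()]), or described by a
#' synthetic render specification (rendered lazily and deterministically).
#'
#' @param slice_index Nonnegative integer acquisition index (DICOM instance
#'   order), not a file-name rank.
#' @param boxes Tibble with columns `x0, y0, x1, y1, label` (label is
#'   `"benign"` or `"malignant"`), 0-based half-open coordinates.
#' @param image Optional numeric matrix (rows = y, cols = x) in `[0, 1]`.
#' @param image_path Optional path to a PNG/TIFF image on disk.
#' @param render Optional render specification produced by the synthetic
#'   cohort generator.
#' @param shape Integer `c(height, width)`; required when `image` is absent.
#' @return An object of class `annotated_slice`.
#' @export
annotated_slice <- function(slice_index, boxes = empty_boxes(), image = NULL,
                            image_path = NULL, render = NULL, shape = NULL) {
  if (length(slice_index) != 1L || is.na(slice_index) || slice_index < 0)
    abort("slice_index must be a single nonnegative integer")
  if (is.null(shape)) {
    if (is.null(image)) abort("shape is required when image is not supplied")
    shape <- dim(image)
  }
  boxes <- as_tibble(boxes)
  stopifnot(all(c("x0", "y0", "x1", "y1", "label") %in% names(boxes)))
  if (nrow(boxes) > 0L) {
    inside <- boxes$x0 >= 0 & boxes$y0 >= 0 &
      boxes$x1 <= shape[2L] & boxes$y1 <= shape[1L] &
      boxes$x1 > boxes$x0 & boxes$y1 > boxes$y0
    if (!all(inside)) abort("every annotation box must lie within image bounds")
  }
  structure(
    list(slice_index = as.integer(slice_index), boxes = boxes, image = image,
         image_path = image_path, render = render, shape = as.integer(shape)),
    class = "annotated_slice"
  )
}

#' Materialize the pixel data of a slice
#'
#' Resolves, in order: in-memory matrix, image file on disk, synthetic render
#' specification. Rendering is deterministic, so repeated calls return
#' identical matrices.
#'
#' @param slice An [annotated_slice()].
#' @return Numeric matrix (rows = y, cols = x).
#' @export
slice_image <- function(slice) {
  stopifnot(inherits(slice, "annotated_slice"))
  if (!is.null(slice$image)) return(slice$image)
  if (!is.null(slice$image_path)) return(read_slice_png(slice$image_path))
  if (!is.null(slice$render)) return(render_from_spec(slice$render))
  abort("slice has no image, image_path or render specification")
}

read_slice_png <- function(path) {
  if (!file.exists(path)) abort(sprintf("image file not found: %s", path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

write_slice_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), target = path)
}

#' Construct an MRI sequence
#'
#' One acquisition series: an ordered stack of 2-D slices of one patient in
#' one weighting.
#'
#' @param sequence_id Identifier string.
#' @param modality One of `"T1"`, `"T2"`, `"FS-T2"`.
#' @param slices List of [annotated_slice()] with strictly increasing
#'   `slice_index` and a common image shape.
#' @return An object of class `mri_sequence`.
#' @export
mri_sequence <- function(sequence_id, modality, slices) {
  modality <- match.arg(modality, c("T1", "T2", "FS-T2"))
  if (length(slices) == 0L) abort("a sequence must contain at least one slice")
  idx <- vapply(slices, function(s) s$slice_index, integer(1))
  if (any(diff(idx) <= 0)) abort("slice_index must be strictly increasing")
  shapes <- vapply(slices, function(s) paste(s$shape, collapse = "x"), character(1))
  if (length(unique(shapes)) != 1L) abort("all slices must share one image shape")
  structure(
    list(sequence_id = sequence_id, modality = modality, slices = slices,
         shape = slices[[1L]]$shape),
    class = "mri_sequence"
  )
}

#' Construct a patient record
#'
#' @param patient_id Identifier string.
#' @param age Age in whole years, 0-120.
#' @param true_class `"benign"`, `"malignant"` or `"unknown"`.
#' @param vertebral_locations Character subset of cervical, thoracic, lumbar,
#'   sacral. May be empty; a patient with tumors at several vertebral levels
#'   carries several tags.
#' @param sequences Nonempty list of [mri_sequence()] objects.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, age, true_class, vertebral_locations,
                           sequences) {
  true_class <- match.arg(true_class, c("benign", "malignant", "unknown"))
  if (length(age) != 1L || is.na(age) || age < 0 || age > 120)
    abort("age must be a single value in 0..120 years")
  bad <- setdiff(vertebral_locations, c("cervical", "thoracic", "lumbar", "sacral"))
  if (length(bad) > 0L)
    abort(sprintf("unknown vertebral location(s): %s", paste(bad, collapse = ", ")))
  if (length(sequences) == 0L) abort("a patient must have at least one sequence")
  structure(
    list(patient_id = patient_id, age = as.integer(age), true_class = true_class,
         vertebral_locations = unique(vertebral_locations), sequences = sequences),
    class = "patient_record"
  )
}
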