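#' Read one annotated slice from a LabelMe JSON file
#'
#' Reads a LabelMe-dialect JSON annotation (rectangle shapes labeled
#' `"benign"` or `"malignant"`, case-insensitively) together with its
#' companion image. LabelMe stores a rectangle as two corner points in any
#' order; corners are order-normalized so that `x0 < x1` and `y0 < y1`, and
#' boxes are converted to the 0-based half-open convention.
#'
#' Boxes partially outside the image are clamped to the image bounds with a
#' warning; a box fully outside the image is an error. Non-rectangle shapes
#' (e.g. polygons) are rejected.
#'
#' @param path Path to the LabelMe JSON file. The companion image is resolved
#'   from the JSON `imagePath` field relative to the JSON's directory.
#' @param slice_index Acquisition index to assign to the slice.
#' @param load_image If `FALSE`, the image is referenced by path and read
#'   lazily by [slice_image()].
#' @return An [annotated_slice()].
#' @export
read_labelme_slice <- function(path, slice_index, load_image = FALSE) {
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  ann <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) abort(sprintf("malformed LabelMe JSON in %s: %s",
                                      path, conditionMessage(e)))
  )
  h <- ann$imageHeight
  w <- ann$imageWidth
  img_path <- file.path(dirname(path), ann$imagePath)
  if (is.null(h) || is.null(w)) {
    img <- read_slice_png(img_path)
    h <- nrow(img); w <- ncol(img)
  }
  rows <- lapply(ann$shapes %||% list(), function(sh) {
    st <- sh$shape_type %||% "rectangle"
    if (!identical(st, "rectangle"))
      abort(sprintf("unsupported shape type '%s' in %s: only rectangles are read",
                    st, path))
    lab <- tolower(sh$label %||% "")
    if (!lab %in% c("benign", "malignant"))
      abort(sprintf("unknown annotation label '%s' in %s", sh$label, path))
    p <- sh$points
    if (length(p) != 2L) abort(sprintf("rectangle in %s must have 2 corner points", path))
    box <- bbox_from_corners(p[[1L]][[1L]], p[[1L]][[2L]], p[[2L]][[1L]], p[[2L]][[2L]])
    clamped <- bbox_clamp(box, h, w)
    if (is.null(clamped))
      abort(sprintf("annotation box fully outside the %dx%d image in %s", h, w, path))
    if (any(clamped != box))
      warn(sprintf("annotation box clamped to image bounds in %s", path))
    tibble(x0 = clamped[["x0"]], y0 = clamped[["y0"]],
           x1 = clamped[["x1"]], y1 = clamped[["y1"]], label = lab)
  })
  boxes <- if (length(rows) > 0L) dplyr::bind_rows(rows) else empty_boxes()
  annotated_slice(
    slice_index = slice_index, boxes = boxes,
    image = if (load_image) read_slice_png(img_path) else NULL,
    image_path = if (load_image) NULL else img_path,
    shape = c(h, w)
  )
}

#' Write one annotated slice as LabelMe JSON (and PNG)
#'
#' Inverse of [read_labelme_slice()]: writes the slice image as PNG and its
#' boxes as rectangle shapes, so that reading the file back reproduces boxes
#' and labels exactly.
#'
#' @param slice An [annotated_slice()].
#' @param json_path Output JSON path; the PNG is written next to it with the
#'   same stem.
#' @return Invisibly, `json_path`.
#' @export
write_labelme_slice <- function(slice, json_path) {
  stopifnot(inherits(slice, "annotated_slice"))
  png_name <- paste0(sub("\\.json$", "", basename(json_path)), ".png")
  img <- slice_image(slice)
  write_slice_png(img, file.path(dirname(json_path), png_name))
  shapes <- purrr::pmap(slice$boxes, function(x0, y0, x1, y1, label) {
    list(label = label,
         points = list(c(x0, y0), c(x1, y1)),
         group_id = NULL,
         shape_type = "rectangle",
         flags = setNames(list(), character(0)))
  })
  doc <- list(
    version = "5.0.0",
    flags = setNames(list(), character(0)),
    shapes = shapes,
    imagePath = png_name,
    imageData = NULL,
    imageHeight = nrow(img),
    imageWidth = ncol(img)
  )
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(json_path)
}
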