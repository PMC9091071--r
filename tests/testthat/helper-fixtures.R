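# In-code fixtures shared across test files. Everything is generated at test
# time; nothing binary ships with the package.

# a toy annotated slice with an in-memory image
toy_slice <- function(slice_index = 0L, h = 40L, w = 40L, boxes = NULL,
                      fill = 0.2) {
  img <- matrix(fill, h, w)
  boxes <- boxes %||% tibble::tibble(x0 = floor(w / 4), y0 = floor(h / 2),
                                     x1 = floor(3 * w / 4), y1 = floor(7 * h / 8),
                                     label = "malignant")
  if (nrow(boxes) > 0L) {
    for (i in seq_len(nrow(boxes)))
      img[(boxes$y0[i] + 1):boxes$y1[i], (boxes$x0[i] + 1):boxes$x1[i]] <- 0.8
  }
  annotated_slice(slice_index, boxes = boxes, image = img)
}

# a toy sequence of L tiny slices; `annotated` gives the 0-based positions
# carrying one box each
toy_sequence <- function(L = 10L, annotated = 0:(L - 1L), h = 24L, w = 24L,
                         modality = "T2", box = c(4, 6, 12, 16)) {
  slices <- lapply(seq_len(L) - 1L, function(i) {
    boxes <- if (i %in% annotated)
      tibble::tibble(x0 = box[1], y0 = box[2], x1 = box[3], y1 = box[4],
                     label = "malignant")
    else
      tibble::tibble(x0 = numeric(), y0 = numeric(), x1 = numeric(),
                     y1 = numeric(), label = character())
    img <- matrix(stats::runif(h * w, 0.1, 0.3), h, w)
    annotated_slice(i, boxes = boxes, image = img)
  })
  mri_sequence("S1", modality, slices)
}

# small memoized cohorts so expensive simulation happens once per run
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, config) {
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- simulate_cohort(config)
  .cohort_cache[[key]]
}

small_cohort <- function() {
  cached_cohort("small", cohort_config(n_patients = 12L, seed = 401L,
                                       image_size = c(128L, 128L),
                                       slices_per_sequence = c(8L, 12L),
                                       lesion_minor_axis = c(6, 15),
                                       lesion_slices = c(4L, 6L)))
}

# a LabelMe JSON + PNG pair written to a temp dir; returns the json path
write_labelme_fixture <- function(dir, shapes, h = 64L, w = 64L,
                                  name = "slice_000") {
  img_name <- paste0(name, ".png")
  png::writePNG(matrix(0.5, h, w), file.path(dir, img_name))
  doc <- list(version = "5.0.0", flags = setNames(list(), character(0)),
              shapes = shapes, imagePath = img_name,
              imageHeight = h, imageWidth = w)
  path <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null")
  path
}

rect_shape <- function(p1, p2, label = "malignant", type = "rectangle") {
  list(label = label, points = list(p1, p2), shape_type = type)
}

# random small integer box (for pixel-counting oracles)
bbox_from_corner_ints <- function(size = 20L) {
  repeat {
    v <- sample.int(size, 4L, replace = TRUE)
    if (v[1] != v[2] && v[3] != v[4]) break
  }
  bbox(min(v[1], v[2]), min(v[3], v[4]), max(v[1], v[2]), max(v[3], v[4]))
}

random_detections <- function(n, size = 100) {
  x0 <- runif(n, 0, size - 12); y0 <- runif(n, 0, size - 12)
  w <- runif(n, 4, 30); h <- runif(n, 4, 30)
  s_b <- runif(n); s_m <- runif(n); s_g <- runif(n)
  tot <- s_b + s_m + s_g
  tibble::tibble(x0 = floor(x0), y0 = floor(y0),
                 x1 = pmin(floor(x0) + ceiling(w), size),
                 y1 = pmin(floor(y0) + ceiling(h), size),
                 s_bg = s_g / tot, s_benign = s_b / tot, s_malignant = s_m / tot)
}
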