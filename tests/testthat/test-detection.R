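test_that("selfcutmix pastes a rescaled copy and preserves existing boxes", {
  boxes <- tibble::tibble(x0 = 30, y0 = 40, x1 = 70, y1 = 60,
                          label = "malignant")  # 40 x 20
  s <- toy_slice(0L, h = 120L, w = 120L, boxes = boxes)
  out <- withr::with_seed(11, multiscale_selfcutmix(s, scale_low = 0.5,
                                                    scale_high = 0.5))
  expect_equal(nrow(out$boxes), 2L)
  # pre-existing annotation unchanged
  expect_equal(as.data.frame(out$boxes[1, ]), as.data.frame(boxes))
  pasted <- out$boxes[2, ]
  expect_equal(pasted$x1 - pasted$x0, 20)  # 40 * 0.5
  expect_equal(pasted$y1 - pasted$y0, 10)  # 20 * 0.5
  expect_equal(pasted$label, "malignant")
  # center in the middle 40% band of the width
  cx <- (pasted$x0 + pasted$x1) / 2
  expect_true(cx >= 0.3 * 120 - 1 && cx <= 0.7 * 120 + 1)
  # paste overlap constraint
  expect_lte(iou(bbox(pasted$x0, pasted$y0, pasted$x1, pasted$y1),
                 bbox(30, 40, 70, 60)), 0.2)
})

test_that("selfcutmix is a no-op on unannotated slices and deterministic", {
  s0 <- toy_slice(0L, boxes = tibble::tibble(x0 = numeric(), y0 = numeric(),
                                             x1 = numeric(), y1 = numeric(),
                                             label = character()))
  expect_identical(multiscale_selfcutmix(s0), s0)
  s <- toy_slice(0L, h = 100L, w = 100L)
  a <- withr::with_seed(5, multiscale_selfcutmix(s))
  b <- withr::with_seed(5, multiscale_selfcutmix(s))
  expect_identical(a$image, b$image)
  expect_identical(a$boxes, b$boxes)
})

test_that("nms keeps the confident box, spares disjoint ones, matches hand trace", {
  two <- tibble::tibble(x0 = c(0, 2), y0 = c(0, 0), x1 = c(10, 12),
                        y1 = c(10, 10),
                        s_bg = c(0.05, 0.25), s_benign = c(0.05, 0.05),
                        s_malignant = c(0.9, 0.7))
  expect_gt(iou(bbox(0, 0, 10, 10), bbox(2, 0, 12, 10)), 0.5)
  kept <- nms(two, 0.5)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$s_malignant, 0.9)

  disjoint <- tibble::tibble(x0 = c(0, 50), y0 = c(0, 50), x1 = c(10, 60),
                             y1 = c(10, 60), s_bg = c(0.1, 0.1),
                             s_benign = c(0.1, 0.2), s_malignant = c(0.8, 0.7))
  expect_equal(nrow(nms(disjoint, 0.5)), 2L)
  expect_equal(nrow(nms(disjoint[0, ], 0.5)), 0L)
})

test_that("nms agrees with the brute-force greedy oracle on random instances", {
  withr::with_seed(97, {
    for (rep in 1:200) {
      det <- random_detections(10)
      thr <- sample(c(0.3, 0.5, 0.7), 1)
      fast <- nms(det, thr)
      slow <- oracle_nms(det, thr)
      expect_equal(nrow(fast), nrow(slow))
      o <- order(-slow$confidence, slow$x0, slow$y0)
      expect_equal(fast[, names(slow)], slow[o, ], ignore_attr = TRUE)
    }
  })
})

test_that("nms output is idempotent and conflict-free", {
  withr::with_seed(131, {
    for (rep in 1:20) {
      kept <- nms(random_detections(15), 0.4)
      expect_identical(nms(kept, 0.4), kept)
      if (nrow(kept) > 1L) {
        for (i in 1:(nrow(kept) - 1)) for (j in (i + 1):nrow(kept)) {
          expect_lte(iou(bbox(kept$x0[i], kept$y0[i], kept$x1[i], kept$y1[i]),
                         bbox(kept$x0[j], kept$y0[j], kept$x1[j], kept$y1[j])),
                     0.4)
        }
      }
    }
  })
})

test_that("image probability renormalizes the top detection without bg", {
  det <- tibble::tibble(x0 = 0, y0 = 0, x1 = 10, y1 = 10,
                        s_bg = 0.6, s_benign = 0.2, s_malignant = 0.2)
  expect_equal(image_probability(det), c(p_b = 0.5, p_m = 0.5))
  det2 <- det; det2$s_bg <- 0.2; det2$s_benign <- 0.2; det2$s_malignant <- 0.6
  expect_equal(image_probability(det2), c(p_b = 0.25, p_m = 0.75))
  expect_null(image_probability(det[0, ]))
  det3 <- det; det3$s_benign <- 0; det3$s_malignant <- 0; det3$s_bg <- 1
  expect_null(image_probability(det3))
  # invariant: adding bg mass and renormalizing leaves D unchanged
  det4 <- det2
  det4[, c("s_bg", "s_benign", "s_malignant")] <-
    det4[, c("s_bg", "s_benign", "s_malignant")] + c(0.5, 0, 0)
  det4[, c("s_bg", "s_benign", "s_malignant")] <-
    det4[, c("s_bg", "s_benign", "s_malignant")] / 1.5
  expect_equal(image_probability(det4), image_probability(det2))
})

test_that("the reference detector recalls lesions on an easy cohort", {
  m <- cached_cohort("det50", cohort_config(n_patients = 50L, seed = 301L))
  sp <- split_dataset(m, 0.3, seed = 301L)
  det <- train_reference_detector(sp$train, seed = 301L)
  refs <- spinewff:::annotated_slice_refs(sp$test)
  hit <- 0L; tot <- 0L
  for (r in refs[seq(1, length(refs), by = 2)]) {
    d <- detect_slice(det, r$slice)
    for (bi in seq_len(nrow(r$slice$boxes))) {
      gt <- bbox(r$slice$boxes$x0[bi], r$slice$boxes$y0[bi],
                 r$slice$boxes$x1[bi], r$slice$boxes$y1[bi])
      tot <- tot + 1L
      if (nrow(d) > 0L && any(spinewff:::iou_vec(gt, d) >= 0.5)) hit <- hit + 1L
    }
  }
  expect_gte(hit / tot, 0.8)

  # determinism: retraining with the same seed reproduces detections
  det2 <- train_reference_detector(sp$train, seed = 301L)
  s <- refs[[1]]$slice
  expect_identical(detect_slice(det, s), detect_slice(det2, s))
})

test_that("a flat lesion-free image yields no detections", {
  m <- cached_cohort("det50", cohort_config(n_patients = 50L, seed = 301L))
  det <- train_reference_detector(split_dataset(m, 0.3, seed = 301L)$train,
                                  seed = 301L)
  flat <- matrix(0.4, 128L, 128L)
  expect_equal(nrow(detect_slice(det, flat)), 0L)
})

test_that("detector training requires both tumor classes", {
  m <- small_cohort()
  benign_only <- Filter(function(p) p$true_class == "benign", m$patients)
  expect_gte(length(benign_only), 2L)
  expect_error(
    train_reference_detector(dataset_manifest(benign_only), seed = 1L),
    "both classes")
})
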