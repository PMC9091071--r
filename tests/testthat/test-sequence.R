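test_that("largest region selection follows area then slice/x0 tie-breaks", {
  b <- tibble::tibble(slice_index = c(2L, 5L, 7L),
                      x0 = c(0, 10, 20), y0 = c(0, 0, 0),
                      x1 = c(20, 40, 50), y1 = c(10, 15, 15))
  # areas 200, 450, 450: tie broken by lower slice index
  lr <- largest_region(b)
  expect_equal(lr$slice_index, 5L)
  expect_equal(unname(lr$box["x0"]), 10)
  single <- b[1, ]
  expect_equal(largest_region(single)$slice_index, 2L)
  expect_null(largest_region(b[0, ]))

  # brute-force max-by-area scan on random instances
  withr::with_seed(41, {
    for (rep in 1:100) {
      n <- sample(1:12, 1)
      tb <- tibble::tibble(
        slice_index = sample(0:20, n, replace = TRUE),
        x0 = sample(0:30, n, replace = TRUE),
        y0 = sample(0:30, n, replace = TRUE))
      tb$x1 <- tb$x0 + sample(1:20, n, replace = TRUE)
      tb$y1 <- tb$y0 + sample(1:20, n, replace = TRUE)
      lr <- largest_region(tb)
      area <- (tb$x1 - tb$x0) * (tb$y1 - tb$y0)
      expect_equal(bbox_area(lr$box), max(area))
    }
  })
})

test_that("crop-stack windows center, shift to fit and cycle as documented", {
  expect_equal(spinewff:::stack_positions(20L, 10L, 16L), 2:17)
  expect_equal(spinewff:::stack_positions(20L, 1L, 16L), 0:15)
  expect_equal(spinewff:::stack_positions(20L, 19L, 16L), 4:19)
  expect_equal(spinewff:::stack_positions(10L, 5L, 16L), c(0:9, 0:5))
  expect_equal(spinewff:::stack_positions(5L, 2L, 1L), 2L)
  expect_equal(spinewff:::stack_positions(7L, 3L, 3L), 2:4)
})

test_that("extract_crop_stack always returns exactly N 112x112 frames", {
  withr::with_seed(55, {
    sq <- toy_sequence(L = 9L, h = 16L, w = 16L, box = c(2, 3, 6, 8))
    st <- extract_crop_stack(sq, bbox(2, 3, 6, 8), 4L, 16L)
    expect_s3_class(st, "crop_stack")
    expect_length(st$frames, 16L)
    expect_true(all(vapply(st$frames, function(f) all(dim(f) == c(112L, 112L)),
                           logical(1))))
    # determinism
    st2 <- extract_crop_stack(sq, bbox(2, 3, 6, 8), 4L, 16L)
    expect_identical(st$frames, st2$frames)
    # out-of-image box errors
    expect_error(extract_crop_stack(sq, bbox(20, 20, 30, 30), 4L, 4L),
                 "outside")
    expect_error(extract_crop_stack(sq, bbox(2, 3, 6, 8), 9L, 4L),
                 "valid position")
  })
})

test_that("training-stack centers follow the 50/50 tumor/index mixture", {
  withr::with_seed(66, {
    L <- 10L
    sq <- toy_sequence(L = L, annotated = 7L, h = 12L, w = 12L,
                       box = c(2, 2, 6, 6))
    n <- 4000L
    centers <- replicate(n, sample_training_stack(sq, N = 2L)$center_slice)
    p_hat <- mean(centers == 7L)
    p_exp <- 0.5 + 0.5 / L
    se <- sqrt(p_exp * (1 - p_exp) / n)
    expect_lt(abs(p_hat - p_exp), 3 * se)
  })
  # degenerate: everything annotated -> both mixture branches coincide
  withr::with_seed(67, {
    sq_all <- toy_sequence(L = 6L, h = 12L, w = 12L, box = c(2, 2, 6, 6))
    centers <- replicate(500, sample_training_stack(sq_all, N = 2L)$center_slice)
    expect_setequal(unique(centers), 0:5)
  })
})

test_that("balanced sequence sampling equalizes class draw rates", {
  mk_patient <- function(id, cls, n_seq) {
    seqs <- lapply(seq_len(n_seq), function(i)
      mri_sequence(sprintf("S%d", i), "T1", list(toy_slice(0L))))
    patient_record(id, 50, cls, "lumbar", seqs)
  }
  # 30 benign vs 90 malignant sequences
  m <- dataset_manifest(c(
    lapply(sprintf("B%02d", 1:10), mk_patient, cls = "benign", n_seq = 3L),
    lapply(sprintf("M%02d", 1:30), mk_patient, cls = "malignant", n_seq = 3L)))
  draws <- withr::with_seed(8, sample_sequences_balanced(m, 12000L))
  expect_lt(abs(mean(draws$true_class == "benign") - 0.5), 0.015)
  # equal counts: sampling is uniform over sequences
  m2 <- dataset_manifest(c(
    lapply("B1", mk_patient, cls = "benign", n_seq = 2L),
    lapply("M1", mk_patient, cls = "malignant", n_seq = 2L)))
  d2 <- withr::with_seed(9, sample_sequences_balanced(m2, 8000L))
  tab <- table(paste(d2$patient_id, d2$sequence_id)) / 8000
  expect_true(all(abs(tab - 0.25) < 0.02))
  # single class errors
  m3 <- dataset_manifest(lapply(c("M1", "M2"), mk_patient,
                                cls = "malignant", n_seq = 1L))
  expect_error(sample_sequences_balanced(m3, 10L), "both classes")
})

test_that("cached training features equal the stack-extraction path", {
  withr::with_seed(77, {
    sq <- toy_sequence(L = 8L, h = 20L, w = 20L, box = c(3, 4, 11, 14))
    lb <- spinewff:::labeled_boxes(sq)
    lr <- largest_region(lb)
    for (center in c(0L, 3L, 7L)) {
      st <- extract_crop_stack(sq, lr$box, center, 5L)
      direct <- spinewff:::stack_features(st)
      feats <- vapply(sq$slices, function(s) {
        img <- slice_image(s)
        b <- lr$box
        sub <- img[(b[["y0"]] + 1):b[["y1"]], (b[["x0"]] + 1):b[["x1"]], drop = FALSE]
        spinewff:::frame_features(spinewff:::resize_mat(sub, 112L, 112L))
      }, numeric(11L))
      pos <- spinewff:::stack_positions(8L, center, 5L)
      cached <- rowMeans(feats[, pos + 1L, drop = FALSE])
      expect_equal(unname(direct), unname(cached), tolerance = 1e-12)
    }
  })
})

test_that("the reference classifier separates easy cohorts and is seed-stable", {
  m <- cached_cohort("cls60", cohort_config(n_patients = 60L, seed = 501L))
  sp <- split_dataset(m, 0.5, seed = 501L)
  cl <- train_reference_classifier(sp$train, seed = 501L)
  cl2 <- train_reference_classifier(sp$train, seed = 501L)
  expect_equal(tidy(cl), tidy(cl2))

  ok <- 0L; tot <- 0L
  for (pt in sp$test$patients) for (sq in pt$sequences) {
    lr <- largest_region(spinewff:::labeled_boxes(sq))
    idx <- vapply(sq$slices, function(s) s$slice_index, integer(1))
    st <- extract_crop_stack(sq, lr$box, match(lr$slice_index, idx) - 1L, 16L)
    pr <- spinewff:::predict_stack(cl, st)
    ok <- ok + ((pr[["p_m"]] >= 0.5) == (pt$true_class == "malignant"))
    tot <- tot + 1L
  }
  expect_gte(ok / tot, 0.85)
})

test_that("label shuffling destroys held-out classification skill", {
  m <- cached_cohort("cls60", cohort_config(n_patients = 60L, seed = 501L))
  sp <- split_dataset(m, 0.5, seed = 501L)
  # permute patient classes in the training split (ages untouched)
  shuffled <- withr::with_seed(13, {
    cls <- vapply(sp$train$patients, `[[`, character(1), "true_class")
    cls <- sample(cls)
    pats <- purrr::imap(sp$train$patients, function(p, i) {
      p$true_class <- cls[[i]]
      for (k in seq_along(p$sequences))
        for (j in seq_along(p$sequences[[k]]$slices))
          if (nrow(p$sequences[[k]]$slices[[j]]$boxes) > 0L)
            p$sequences[[k]]$slices[[j]]$boxes$label <- cls[[i]]
      p
    })
    dataset_manifest(pats, role = "train")
  })
  cl <- train_reference_classifier(shuffled, seed = 77L)
  ok <- 0L; tot <- 0L
  for (pt in sp$test$patients) for (sq in pt$sequences) {
    lr <- largest_region(spinewff:::labeled_boxes(sq))
    idx <- vapply(sq$slices, function(s) s$slice_index, integer(1))
    st <- extract_crop_stack(sq, lr$box, match(lr$slice_index, idx) - 1L, 16L)
    pr <- spinewff:::predict_stack(cl, st)
    ok <- ok + ((pr[["p_m"]] >= 0.5) == (pt$true_class == "malignant"))
    tot <- tot + 1L
  }
  expect_lt(abs(ok / tot - 0.5), 0.15)
})

test_that("classification accuracy degrades as texture contrast vanishes", {
  accs <- matrix(NA_real_, 3L, 5L)
  sds <- c(0.12, 0.06, 0.02)
  for (si in seq_along(sds)) {
    for (ri in 1:5) {
      cfg <- cohort_config(n_patients = 30L, seed = 600L + ri,
                           malignant_texture_sd = sds[si],
                           image_size = c(128L, 128L),
                           slices_per_sequence = c(8L, 14L),
                           lesion_minor_axis = c(6, 16),
                           lesion_slices = c(4L, 7L))
      m <- simulate_cohort(cfg)
      sp <- split_dataset(m, 0.34, seed = ri)
      cl <- train_reference_classifier(sp$train, seed = ri)
      ok <- 0L; tot <- 0L
      for (pt in sp$test$patients) for (sq in pt$sequences) {
        lr <- largest_region(spinewff:::labeled_boxes(sq))
        idx <- vapply(sq$slices, function(s) s$slice_index, integer(1))
        st <- extract_crop_stack(sq, lr$box, match(lr$slice_index, idx) - 1L, 16L)
        pr <- spinewff:::predict_stack(cl, st)
        ok <- ok + ((pr[["p_m"]] >= 0.5) == (pt$true_class == "malignant"))
        tot <- tot + 1L
      }
      accs[si, ri] <- ok / tot
    }
  }
  means <- rowMeans(accs)
  # non-increasing as the malignant texture approaches the benign one,
  # allowing one inversion
  expect_lte(sum(diff(means) > 0.02), 1L)
  expect_gt(means[1], means[3])
})

test_that("sequence classification falls back to a centered crop without detections", {
  m <- small_cohort()
  sp <- split_dataset(m, 0.4, seed = 7)
  cl <- train_reference_classifier(sp$train, seed = 7L)
  sq <- sp$test$patients[[1]]$sequences[[1]]
  empty <- tibble::tibble(slice_index = integer(), x0 = numeric(),
                          y0 = numeric(), x1 = numeric(), y1 = numeric())
  expect_message(pr <- classify_sequence(cl, sq, empty), "fallback")
  expect_equal(sum(pr), 1)
  # with detections, the largest detected box drives the crop
  det <- tibble::tibble(slice_index = sq$slices[[1]]$slice_index,
                        x0 = 10, y0 = 10, x1 = 60, y1 = 60)
  pr2 <- classify_sequence(cl, sq, det)
  expect_equal(sum(pr2), 1)
})
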