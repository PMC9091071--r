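test_that("confusion counting treats malignant as positive", {
  dec <- tibble::tibble(patient_id = sprintf("P%d", 1:5),
                        category = c("malignant", "malignant", "malignant",
                                     "benign", "benign"))
  tru <- tibble::tibble(patient_id = sprintf("P%d", 1:5),
                        true_class = c("malignant", "malignant", "malignant",
                                       "benign", "benign"))
  cc <- confusion(dec, tru)
  expect_equal(unlist(cc[c("TP", "FN", "TN", "FP")]),
               c(TP = 3L, FN = 0L, TN = 2L, FP = 0L))
  # all predicted malignant
  dec2 <- dec; dec2$category <- "malignant"
  cc2 <- confusion(dec2, tru)
  expect_equal(unlist(cc2[c("TP", "FP", "TN", "FN")]),
               c(TP = 3L, FP = 2L, TN = 0L, FN = 0L))
  expect_error(confusion(dec[1:4, ], tru), "same patient ids")

  # random instances against pairwise counting
  withr::with_seed(3, {
    for (rep in 1:50) {
      n <- sample(2:30, 1)
      d <- tibble::tibble(patient_id = sprintf("P%d", 1:n),
                          category = sample(c("benign", "malignant"), n, TRUE))
      t <- tibble::tibble(patient_id = sample(d$patient_id),
                          true_class = sample(c("benign", "malignant"), n, TRUE))
      cc <- confusion(d, t)
      j <- merge(d, t, by = "patient_id")
      expect_equal(cc$TP, sum(j$category == "malignant" & j$true_class == "malignant"))
      expect_equal(cc$TN, sum(j$category == "benign" & j$true_class == "benign"))
      expect_equal(cc$TP + cc$FN + cc$TN + cc$FP, n)
    }
  })
})

test_that("metric formulas are exact and undefined cases are NA", {
  cc <- confusion_counts(TP = 36, FN = 14, TN = 79, FP = 11)
  expect_equal(accuracy(cc), 115 / 140)
  expect_equal(sensitivity(cc), 0.72)
  expect_equal(specificity(cc), 79 / 90)
  # the linear identity ACC * total = SE * P + SP * N
  expect_equal(accuracy(cc) * 140, sensitivity(cc) * 50 + specificity(cc) * 90)
  expect_equal(accuracy(confusion_counts(1, 1, 1, 1)), 0.5)
  expect_true(is.na(sensitivity(confusion_counts(0, 0, 5, 2))))
  expect_true(is.na(specificity(confusion_counts(3, 1, 0, 0))))
})

test_that("rank AUC matches perfect, tied and pair-counted cases", {
  expect_equal(auc_score(c(0.9, 0.8, 0.4, 0.1),
                         c("malignant", "malignant", "benign", "benign")), 1)
  expect_equal(auc_score(rep(0.5, 6),
                         rep(c("malignant", "benign"), 3)), 0.5)
  expect_true(is.na(auc_score(c(0.1, 0.2), c("benign", "benign"))))
  withr::with_seed(7, {
    for (rep in 1:500) {
      n <- sample(4:25, 1)
      labels <- sample(c("benign", "malignant"), n, replace = TRUE)
      if (length(unique(labels)) < 2) labels[1:2] <- c("benign", "malignant")
      scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
      expect_equal(auc_score(scores, labels), oracle_auc_pairs(scores, labels),
                   tolerance = 1e-12)
    }
  })
  # invariance under strictly monotone transforms
  withr::with_seed(8, {
    scores <- runif(30); labels <- sample(c("benign", "malignant"), 30, TRUE)
    labels[1:2] <- c("benign", "malignant")
    expect_equal(auc_score(scores, labels), auc_score(qlogis(scores), labels))
  })
})

test_that("printed operating points pin down unique confusion counts", {
  cc <- recover_confusion(0.720, 0.878, 50, 90)
  expect_equal(cc$TP, 36L); expect_equal(cc$TN, 79L)
  expect_equal(round(accuracy(cc), 3), 0.821)
  cc2 <- recover_confusion(0.660, 0.711, 50, 90)
  expect_equal(cc2$TP, 33L)
  expect_equal(round(accuracy(cc2), 3), 0.693)
})

test_that("cross-validation selects weights deterministically on the grid", {
  expect_equal(length(spinewff:::simplex_grid(0.5)), 6L)
  expect_error(spinewff:::simplex_grid(0.3), "divide")

  # toy contracts: an oracle classifier and a coin-flip detector
  toy_detector <- structure(list(), class = "toy_rand_det")
  toy_classifier <- structure(list(), class = "toy_oracle_cls")
  m <- small_cohort()
  truth_by_id <- setNames(
    vapply(m$patients, `[[`, character(1), "true_class"),
    vapply(m$patients, `[[`, character(1), "patient_id"))

  registerS3method("detect_cohort", "toy_rand_det", function(detector, manifest) {
    rows <- list()
    for (p in manifest$patients) for (sq in p$sequences) {
      s_m <- runif(1)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        patient_id = p$patient_id, sequence_id = sq$sequence_id,
        slice_index = sq$slices[[1]]$slice_index,
        x0 = 0, y0 = 0, x1 = 10, y1 = 10,
        s_bg = 0, s_benign = 1 - s_m, s_malignant = s_m,
        confidence = pmax(s_m, 1 - s_m))
    }
    dplyr::bind_rows(rows)
  }, envir = asNamespace("spinewff"))
  registerS3method("classify_cohort", "toy_oracle_cls",
                   function(classifier, manifest, detections, N = NULL) {
    rows <- list()
    for (p in manifest$patients) for (sq in p$sequences) {
      pm <- if (truth_by_id[[p$patient_id]] == "malignant") 0.95 else 0.05
      rows[[length(rows) + 1L]] <- tibble::tibble(
        patient_id = p$patient_id, sequence_id = sq$sequence_id,
        p_b = 1 - pm, p_m = pm)
    }
    dplyr::bind_rows(rows)
  }, envir = asNamespace("spinewff"))

  trainers <- list(detector = function(manifest, seed) toy_detector,
                   classifier = function(manifest, N, seed) toy_classifier)

  # singleton grid returns its only element
  cv1 <- crossval_select_weights(m, k = 2L, seed = 5L, trainers = trainers,
                                 grid = list(c(1, 0, 0)))
  expect_equal(as.numeric(cv1$weights), c(1, 0, 0))

  # a perfect sequence classifier and a random detector force lambda2 > lambda1
  for (sd in c(11L, 12L, 13L)) {
    cv <- crossval_select_weights(m, grid_step = 0.25, k = 2L, seed = sd,
                                  trainers = trainers)
    expect_gt(cv$weights[[2L]], cv$weights[[1L]])
  }

  # folds partition the training patients
  meta <- patient_meta(m)
  folds <- spinewff:::stratified_folds(meta, 4L, seed = 2L)
  expect_equal(sort(unique(folds)), 1:4)
  expect_equal(length(folds), nrow(meta))
  # determinism of fold assignment
  expect_identical(folds, spinewff:::stratified_folds(meta, 4L, seed = 2L))
})

test_that("subgroup reports count multi-location patients in every group", {
  # hand-built eval object exercising only the location branch
  decisions <- tibble::tibble(
    patient_id = c("P1", "P2", "P3"),
    category = c("malignant", "benign", "benign"),
    malignancy_score = c(0.9, 0.2, 0.4), n_sequences = 1L,
    seq_malignant_fraction = c(1, 0, 0))
  truths <- tibble::tibble(
    patient_id = c("P1", "P2", "P3"), age = c(50, 60, 70),
    true_class = c("malignant", "malignant", "benign"),
    locations = c("cervical;lumbar", "cervical", "sacral"))
  ev <- structure(list(decisions = decisions, truths = truths),
                  class = "wff_eval")
  rep <- subgroup_report(ev, by = "location")
  # P2 is the only error; it counts in cervical only
  expect_equal(rep$n_errors[rep$location == "cervical"], 1L)
  expect_equal(rep$n_patients[rep$location == "cervical"], 2L)
  expect_equal(rep$n_errors[rep$location == "sacral"], 0L)
  # a wrongly predicted multi-location patient increments all its groups
  decisions2 <- decisions; decisions2$category <- c("benign", "benign", "benign")
  ev2 <- structure(list(decisions = decisions2, truths = truths),
                   class = "wff_eval")
  rep2 <- subgroup_report(ev2, by = "location")
  expect_equal(rep2$n_errors[rep2$location == "cervical"], 2L)
  expect_equal(rep2$n_errors[rep2$location == "lumbar"], 1L)
  expect_error(subgroup_report(ev, by = "nonsense"))
})
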