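#' Confusion counts at patient level
#'
#' Malignant is the positive class throughout: `TP` counts malignant
#' patients predicted malignant, `TN` benign predicted benign.
#'
#' @param decisions Tibble with `patient_id` and `category` (predictions).
#' @param truths Tibble with `patient_id` and `true_class`.
#' @return List of class `confusion_counts` with `TP, FN, TN, FP`.
#' @export
confusion <- function(decisions, truths) {
  d <- as_tibble(decisions); t <- as_tibble(truths)
  if (!setequal(d$patient_id, t$patient_id) || nrow(d) != nrow(t))
    abort("decisions and truths must cover the same patient ids")
  m <- dplyr::inner_join(d, t, by = "patient_id")
  confusion_counts(
    TP = sum(m$true_class == "malignant" & m$category == "malignant"),
    FN = sum(m$true_class == "malignant" & m$category == "benign"),
    TN = sum(m$true_class == "benign" & m$category == "benign"),
    FP = sum(m$true_class == "benign" & m$category == "malignant"))
}

#' @rdname confusion
#' @param TP,FN,TN,FP Nonnegative integer counts.
#' @export
confusion_counts <- function(TP, FN, TN, FP) {
  v <- c(TP = TP, FN = FN, TN = TN, FP = FP)
  if (anyNA(v) || any(v < 0)) abort("confusion counts must be nonnegative")
  structure(as.list(v), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FN=%d TN=%d FP=%d\n",
              x$TP, x$FN, x$TN, x$FP))
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' `accuracy = (TP + TN) / (TP + FN + TN + FP)`,
#' `sensitivity = TP / (TP + FN)` (malignant recall),
#' `specificity = TN / (TN + FP)` (benign recall).
#' A metric whose denominator is zero is undefined and reported as `NA`,
#' never silently as 0.
#'
#' @param c A [confusion_counts()] object.
#' @return A fraction in `[0, 1]`, or `NA_real_` when undefined.
#' @export
accuracy <- function(c) {
  tot <- c$TP + c$FN + c$TN + c$FP
  if (tot == 0) return(NA_real_)
  (c$TP + c$TN) / tot
}

#' @rdname accuracy
#' @export
sensitivity <- function(c) {
  if (c$TP + c$FN == 0) return(NA_real_)
  c$TP / (c$TP + c$FN)
}

#' @rdname accuracy
#' @export
specificity <- function(c) {
  if (c$TN + c$FP == 0) return(NA_real_)
  c$TN / (c$TN + c$FP)
}

#' Rank-based AUC with tie half-credit
#'
#' The Mann-Whitney form of the area under the ROC curve: the probability
#' that a random malignant patient's score exceeds a random benign
#' patient's, counting ties as 1/2. Equals the trapezoidal ROC area and is
#' invariant under strictly monotone transforms of the scores.
#'
#' @param scores Numeric malignancy scores.
#' @param labels Character vector of true classes aligned with `scores`.
#' @return AUC in `[0, 1]`, or `NA_real_` when only one class is present.
#' @export
auc_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == "malignant"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Recover integer confusion counts from printed operating points
#'
#' Given a sensitivity/specificity pair reported at finite precision and
#' the known class composition of a test set, finds the unique integer
#' `TP` and `TN` consistent with them (the integers minimizing the absolute
#' error to the printed values; an error is raised when the printed
#' precision does not pin them down uniquely). Useful for auditing
#' published tables: the implied accuracy can then be recomputed exactly.
#'
#' @param se,sp Printed sensitivity and specificity.
#' @param n_pos,n_neg Number of positive (malignant) and negative (benign)
#'   patients.
#' @param digits Decimal precision of the printed values (default 3).
#' @return A [confusion_counts()] object.
#' @examples
#' # a 140-patient test set with 50 malignant / 90 benign
#' cc <- recover_confusion(0.720, 0.878, 50, 90)
#' accuracy(cc)  # 0.8214...
#' @export
recover_confusion <- function(se, sp, n_pos, n_neg, digits = 3) {
  pick <- function(rate, n, what) {
    cand <- 0:n
    err <- abs(cand / n - rate)
    best <- which(err == min(err))
    if (length(best) > 1L)
      abort(sprintf("printed %s %.3f is consistent with several %s counts",
                    what, rate, what))
    if (round(cand[best] / n, digits) != round(rate, digits))
      warn(sprintf("recovered %s count reproduces %.3f only approximately", what, rate))
    cand[best]
  }
  TP <- pick(se, n_pos, "TP")
  TN <- pick(sp, n_neg, "TN")
  confusion_counts(TP = TP, FN = n_pos - TP, TN = TN, FP = n_neg - TN)
}

#' Evaluate fused decisions against the truth
#'
#' @param decisions [fuse_cohort()] output.
#' @param truths Tibble with `patient_id`, `true_class`.
#' @return One-row tibble: `ACC, SE, SP, AUC, TP, FN, TN, FP, n`.
#' @export
metrics_report <- function(decisions, truths) {
  cc <- confusion(decisions, truths)
  m <- dplyr::inner_join(as_tibble(decisions), as_tibble(truths),
                         by = "patient_id")
  tibble(ACC = accuracy(cc), SE = sensitivity(cc), SP = specificity(cc),
         AUC = auc_score(m$malignancy_score, m$true_class),
         TP = cc$TP, FN = cc$FN, TN = cc$TN, FP = cc$FP, n = nrow(m))
}

# ---- end-to-end evaluation object ------------------------------------------

#' Train the full evidence pipeline on a cohort
#'
#' Convenience wrapper training all three evidence sources on one manifest:
#' the reference detector, the reference sequence classifier, and the age
#' table fitted on the training patients' metadata.
#'
#' @param train_manifest Training [dataset_manifest()].
#' @param N Frames per crop stack.
#' @param detector_params,classifier_params Optional parameter lists.
#' @param bin_width,alpha Age-table settings.
#' @param seed Integer seed.
#' @return List of class `wff_models`: `detector`, `classifier`,
#'   `age_table`, `N`, `seed`.
#' @export
train_wff <- function(train_manifest, N = 16L, detector_params = list(),
                      classifier_params = list(), bin_width = 10, alpha = 1,
                      seed = 1L) {
  detector <- train_reference_detector(train_manifest, detector_params,
                                       seed = seed)
  classifier <- train_reference_classifier(train_manifest, N = N,
                                           params = classifier_params,
                                           seed = seed + 1L)
  age_table <- fit_age_table(patient_meta(train_manifest),
                             bin_width = bin_width, alpha = alpha)
  structure(list(detector = detector, classifier = classifier,
                 age_table = age_table, N = as.integer(N), seed = seed),
            class = "wff_models")
}

#' Run detection, classification and fusion on a test cohort
#'
#' Produces a `wff_eval` object holding every intermediate artifact
#' (detection table, sequence predictions, evidence bundle, decisions,
#' metrics), so that fusion ablations and subgroup analyses can be re-run
#' without touching the images again.
#'
#' @param test_manifest Test [dataset_manifest()].
#' @param models A [train_wff()] object.
#' @param weights A [fusion_weights()] object.
#' @return Object of class `wff_eval`.
#' @export
evaluate_wff <- function(test_manifest, models,
                         weights = fusion_weights(0.45, 0.45, 0.1)) {
  detections <- detect_cohort(models$detector, test_manifest)
  seq_preds <- classify_cohort(models$classifier, test_manifest, detections)
  evidence <- build_evidence(test_manifest, detections, seq_preds,
                             models$age_table)
  decisions <- fuse_evidence(evidence, weights)
  truths <- patient_meta(test_manifest)[, c("patient_id", "age", "true_class",
                                            "locations")]
  structure(list(manifest = test_manifest, models = models, weights = weights,
                 detections = detections, seq_preds = seq_preds,
                 evidence = evidence, decisions = decisions, truths = truths,
                 metrics = metrics_report(decisions, truths)),
            class = "wff_eval")
}

#' @export
print.wff_eval <- function(x, ...) {
  cat(sprintf("<wff_eval> %d patients; ACC %.3f, SE %.3f, SP %.3f, AUC %.3f\n",
              nrow(x$decisions), x$metrics$ACC, x$metrics$SE, x$metrics$SP,
              x$metrics$AUC))
  invisible(x)
}

#' @rdname evaluate_wff
#' @param x A `wff_eval`.
#' @param ... Unused.
#' @export
glance.wff_eval <- function(x, ...) x$metrics

#' @rdname evaluate_wff
#' @export
tidy.wff_eval <- function(x, ...) {
  dplyr::inner_join(x$decisions, x$truths, by = "patient_id")
}

# the six canonical weight settings derived from one base triple
strategy_weights <- function(base = c(0.45, 0.45, 0.1)) {
  list(
    "Det"         = fusion_weights(base[1L], 0, 0),
    "Det-Age"     = fusion_weights(base[1L], 0, base[3L]),
    "Seq"         = fusion_weights(0, base[2L], 0),
    "Seq-Age"     = fusion_weights(0, base[2L], base[3L]),
    "Det-Seq"     = fusion_weights(base[1L], base[2L], 0),
    "Det-Seq-Age" = fusion_weights(base[1L], base[2L], base[3L]))
}

#' Fusion-strategy ablation table
#'
#' Re-fuses the cached evidence of a `wff_eval` under the six strategies
#' obtained by zeroing components of a base weight triple - detection only
#' (Det), detection + age (Det-Age), sequence only (Seq), sequence + age
#' (Seq-Age), detection + sequence (Det-Seq) and all three (Det-Seq-Age) -
#' and reports the four metrics for each.
#'
#' @param eval A [evaluate_wff()] object.
#' @param base Base weight triple (default `c(0.45, 0.45, 0.1)`).
#' @return Tibble with 6 rows: `strategy, ACC, SE, SP, AUC, ...`.
#' @export
ablation_report <- function(eval, base = c(0.45, 0.45, 0.1)) {
  stopifnot(inherits(eval, "wff_eval"))
  purrr::imap_dfr(strategy_weights(base), function(w, nm) {
    dec <- fuse_evidence(eval$evidence, w)
    dplyr::bind_cols(tibble(strategy = nm), metrics_report(dec, eval$truths))
  })
}

#' Subgroup error analysis by vertebral location or modality
#'
#' With `by = "location"`, groups prediction errors by vertebral location
#' tag; a patient with tumors at several locations counts in each of its
#' locations (so group sizes can sum to more than the cohort). With
#' `by = "modality"`, patient decisions are re-run three times with the
#' evidence restricted to T1 sequences only, to T2 sequences only (T2 and
#' FS-T2), and to all sequences; the age and detection terms are unchanged,
#' only the set of voting sequences varies.
#'
#' @param eval A [evaluate_wff()] object.
#' @param by `"location"` or `"modality"`.
#' @return A tibble: per location `n_patients, n_errors, error_rate`, or
#'   per modality subset the four metrics.
#' @export
subgroup_report <- function(eval, by = c("location", "modality")) {
  by <- match.arg(by)
  stopifnot(inherits(eval, "wff_eval"))
  if (by == "location") {
    joined <- dplyr::inner_join(eval$decisions, eval$truths, by = "patient_id")
    joined$error <- joined$category != joined$true_class
    joined |>
      dplyr::mutate(location = strsplit(.data$locations, ";", fixed = TRUE)) |>
      tidyr::unnest("location") |>
      dplyr::group_by(.data$location) |>
      dplyr::summarise(n_patients = dplyr::n(), n_errors = sum(.data$error),
                       error_rate = mean(.data$error), .groups = "drop")
  } else {
    subsets <- list("T1" = "T1", "T2" = c("T2", "FS-T2"),
                    "all" = c("T1", "T2", "FS-T2"))
    purrr::imap_dfr(subsets, function(mods, nm) {
      ev <- build_evidence(eval$manifest, eval$detections, eval$seq_preds,
                           eval$models$age_table, modalities = mods)
      dec <- fuse_evidence(ev, eval$weights)
      dplyr::bind_cols(tibble(modalities = nm),
                       metrics_report(dec, eval$truths[
                         eval$truths$patient_id %in% dec$patient_id, ]))
    })
  }
}

# ---- cross-validated weight selection --------------------------------------

# patient-level stratified fold assignment
stratified_folds <- function(meta, k, seed) {
  withr::with_seed(seed, {
    fold <- integer(nrow(meta))
    for (cl in unique(meta$true_class)) {
      idx <- which(meta$true_class == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

# all nonnegative triples on the simplex grid with the given step
simplex_grid <- function(step) {
  n <- round(1 / step)
  if (abs(n * step - 1) > 1e-9) abort("grid step must divide 1")
  grid <- list()
  for (i in 0:n) for (j in 0:(n - i)) {
    grid[[length(grid) + 1L]] <- c(i, j, n - i - j) * step
  }
  grid
}

#' Select fusion weights by stratified k-fold cross-validation
#'
#' Splits the training patients into `k` class-stratified folds; for each
#' fold, trains the evidence models on the remaining folds and caches the
#' held-out evidence; then scores every weight triple on the simplex grid
#' `{(l1, l2, l3) >= 0, l1 + l2 + l3 = 1, step = grid_step}` by mean
#' held-out accuracy. Ties are broken by higher mean AUC, then by lower
#' age weight `l3`, then lexicographically - a deterministic rule.
#'
#' @param train_manifest Training [dataset_manifest()].
#' @param grid_step Simplex grid step; must divide 1 (default 0.05).
#' @param k Number of folds (default 4).
#' @param N Frames per crop stack.
#' @param seed Integer seed (folds and model training).
#' @param trainers Optional list with functions `detector(manifest, seed)`
#'   and `classifier(manifest, N, seed)` overriding the reference trainers
#'   (e.g. to plug in an external model).
#' @param grid Optional list of weight triples overriding the simplex grid.
#' @return List of class `cv_weights`: `weights` (the selected
#'   [fusion_weights()]), `grid` (per-triple mean metrics tibble), `folds`
#'   (per-fold, per-triple results).
#' @export
crossval_select_weights <- function(train_manifest, grid_step = 0.05, k = 4L,
                                    N = 16L, seed = 1L, trainers = list(),
                                    grid = NULL) {
  if (k < 2L) abort("k must be at least 2")
  tr <- utils::modifyList(list(
    detector = function(manifest, seed)
      train_reference_detector(manifest, seed = seed),
    classifier = function(manifest, N, seed)
      train_reference_classifier(manifest, N = N, seed = seed)), trainers)
  grid <- grid %||% simplex_grid(grid_step)
  if (length(grid) == 0L) abort("empty weight grid")
  meta <- patient_meta(train_manifest)
  fold <- stratified_folds(meta, k, seed)

  fold_evidence <- lapply(seq_len(k), function(f) {
    held_ids <- meta$patient_id[fold == f]
    in_train <- vapply(train_manifest$patients,
                       function(p) !(p$patient_id %in% held_ids), logical(1))
    m_train <- dataset_manifest(train_manifest$patients[in_train], role = "train")
    m_held <- dataset_manifest(train_manifest$patients[!in_train], role = "test")
    detector <- tr$detector(m_train, seed = seed + f)
    classifier <- tr$classifier(m_train, N = N, seed = seed + 100L + f)
    age_table <- fit_age_table(patient_meta(m_train))
    det <- detect_cohort(detector, m_held)
    sp <- classify_cohort(classifier, m_held, det, N)
    list(evidence = build_evidence(m_held, det, sp, age_table),
         truths = patient_meta(m_held))
  })

  fold_rows <- list()
  for (gi in seq_along(grid)) {
    w <- grid[[gi]]
    if (sum(w) <= 0) next
    fw <- fusion_weights(w[1L], w[2L], w[3L])
    for (f in seq_len(k)) {
      dec <- fuse_evidence(fold_evidence[[f]]$evidence, fw)
      mr <- metrics_report(dec, fold_evidence[[f]]$truths)
      fold_rows[[length(fold_rows) + 1L]] <- dplyr::bind_cols(
        tibble(grid_index = gi, lambda1 = w[1L], lambda2 = w[2L],
               lambda3 = w[3L], fold = f), mr)
    }
  }
  folds <- dplyr::bind_rows(fold_rows)
  summary <- folds |>
    dplyr::group_by(.data$grid_index, .data$lambda1, .data$lambda2,
                    .data$lambda3) |>
    dplyr::summarise(mean_ACC = mean(.data$ACC),
                     mean_AUC = mean(.data$AUC), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_ACC), dplyr::desc(.data$mean_AUC),
                   .data$lambda3, .data$lambda1, .data$lambda2)
  best <- summary[1L, ]
  structure(list(
    weights = fusion_weights(best$lambda1, best$lambda2, best$lambda3),
    grid = summary, folds = folds, k = k, seed = seed),
    class = "cv_weights")
}

#' @export
print.cv_weights <- function(x, ...) {
  cat(sprintf("<cv_weights> selected (%.2f, %.2f, %.2f); mean CV ACC %.3f over %d folds\n",
              x$weights[[1L]], x$weights[[2L]], x$weights[[3L]],
              x$grid$mean_ACC[1L], x$k))
  invisible(x)
}

#' @rdname crossval_select_weights
#' @param x A `cv_weights` object.
#' @param ... Unused.
#' @export
tidy.cv_weights <- function(x, ...) x$grid
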