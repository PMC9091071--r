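#' Fusion weights for the three evidence terms
#'
#' Nonnegative weights `(lambda1, lambda2, lambda3)` applied to the
#' detection (per image), sequence-classifier (per sequence) and age-prior
#' (per patient) probability pairs. The weights need not sum to 1: fused
#' pairs are renormalized by the sum of weights of the terms actually
#' present, so decisions are invariant to positive rescaling of all three.
#'
#' @param lambda1,lambda2,lambda3 Nonnegative weights for the detection,
#'   sequence and age terms; their sum must be positive.
#' @return Named numeric vector of class `fusion_weights`.
#' @examples
#' fusion_weights(0.45, 0.45, 0.1)   # all three evidence sources
#' fusion_weights(0.45, 0, 0.1)      # detection + age only
#' @export
fusion_weights <- function(lambda1, lambda2, lambda3) {
  w <- c(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3)
  if (anyNA(w) || any(w < 0)) abort("fusion weights must be nonnegative")
  if (sum(w) <= 0) abort("at least one fusion weight must be positive")
  structure(w, class = "fusion_weights")
}

as_fusion_weights <- function(w) {
  if (inherits(w, "fusion_weights")) return(w)
  stopifnot(is.numeric(w), length(w) == 3L)
  fusion_weights(w[[1L]], w[[2L]], w[[3L]])
}

#' Fuse the evidence for one image
#'
#' The weighted late-fusion rule, applied component-wise to the
#' benign/malignant pairs:
#' `P = (lambda1 * D + lambda2 * M + lambda3 * A) / sum(active lambda)`,
#' where `D` is the image's detection term, `M` the sequence-classifier
#' term and `A` the age prior. A term is *active* when it is present
#' (non-`NULL`) and its weight is positive; division by the active weight
#' sum keeps the output a normalized pair even when terms are missing or
#' weights do not sum to 1. When no active term exists the image
#' contributes no vote and `NULL` is returned.
#'
#' @param D,M,A Probability pairs `c(p_b, p_m)` or `NULL` when absent.
#' @param weights A [fusion_weights()] object (or length-3 numeric).
#' @return List with `probs` (normalized pair) and `active_weight_sum`, or
#'   `NULL`.
#' @examples
#' fuse_image(D = c(0.2, 0.8), M = c(0.4, 0.6), A = c(0.3, 0.7),
#'            weights = fusion_weights(0.45, 0.45, 0.1))
#' @export
fuse_image <- function(D = NULL, M = NULL, A = NULL, weights) {
  w <- as_fusion_weights(weights)
  terms <- list(D, M, A)
  raw <- c(p_b = 0, p_m = 0)
  active <- 0
  for (i in 1:3) {
    if (is.null(terms[[i]]) || w[[i]] <= 0) next
    t <- terms[[i]]
    raw <- raw + w[[i]] * c(p_b = t[[1L]], p_m = t[[2L]])
    active <- active + w[[i]]
  }
  if (active <= 0) return(NULL)
  list(probs = prob_pair(raw[["p_b"]] / active, raw[["p_m"]] / active,
                         normalize = FALSE),
       active_weight_sum = active)
}

# malignant on ties at both vote levels: deterministic and
# sensitivity-favoring, mirroring clinical caution
vote_of_pair <- function(pair) {
  if (pair[["p_m"]] >= pair[["p_b"]]) "malignant" else "benign"
}

#' Aggregate fused image scores to a sequence decision
#'
#' Every image with a fused score votes for the class with the larger fused
#' probability; the category with the largest vote share wins, with exact
#' ties going to malignant. When no image produced a score (e.g. no usable
#' detections anywhere and a detection-only weighting), the decision falls
#' back to the remaining evidence: the argmax of
#' `lambda2 * M + lambda3 * A` over the present terms.
#'
#' @param image_scores List of [fuse_image()] results (`NULL` entries are
#'   images without usable evidence and are excluded from the vote).
#' @param M,A Fallback sequence and age pairs for the empty-vote case.
#' @param weights The [fusion_weights()] in use.
#' @return List of class `sequence_decision`: `category`, `vote_fractions`
#'   (named benign/malignant, summing to 1), `mean_malignant_prob`,
#'   `n_votes`.
#' @export
decide_sequence <- function(image_scores, M = NULL, A = NULL, weights) {
  scores <- purrr::compact(image_scores)
  if (length(scores) > 0L) {
    pairs <- lapply(scores, `[[`, "probs")
    votes <- vapply(pairs, vote_of_pair, character(1))
    frac_m <- mean(votes == "malignant")
    category <- if (frac_m >= 0.5) "malignant" else "benign"
    mean_pm <- mean(vapply(pairs, `[[`, numeric(1), "p_m"))
    n_votes <- length(votes)
  } else {
    fb <- fuse_image(D = NULL, M = M, A = A,
                     weights = as_fusion_weights(weights))
    if (is.null(fb)) {
      # no positively-weighted fallback term either: use whatever evidence
      # exists with equal weight, or an uninformative pair (which the
      # malignant tie rule then resolves)
      present <- purrr::compact(list(M, A))
      pair <- if (length(present) > 0L) {
        s <- Reduce(`+`, present) / length(present)
        prob_pair(s[[1L]], s[[2L]])
      } else c(p_b = 0.5, p_m = 0.5)
      fb <- list(probs = pair, active_weight_sum = 0)
    }
    category <- vote_of_pair(fb$probs)
    frac_m <- as.numeric(category == "malignant")
    mean_pm <- fb$probs[["p_m"]]
    n_votes <- 0L
  }
  structure(list(category = category,
                 vote_fractions = c(benign = 1 - frac_m, malignant = frac_m),
                 mean_malignant_prob = mean_pm, n_votes = n_votes),
            class = "sequence_decision")
}

#' Aggregate sequence decisions to a patient decision
#'
#' Majority vote over the sequence categories, exact ties going to
#' malignant. The continuous `malignancy_score` (used for ROC/AUC only,
#' never for the categorical decision) is the mean over sequences of the
#' mean fused malignant probability.
#'
#' @param sequence_decisions Nonempty list of [decide_sequence()] results.
#' @return List of class `patient_decision`: `category`,
#'   `sequence_vote_fractions`, `malignancy_score`, `n_sequences`.
#' @export
decide_patient <- function(sequence_decisions) {
  if (length(sequence_decisions) == 0L)
    abort("cannot decide a patient with no sequence decisions")
  cats <- vapply(sequence_decisions, `[[`, character(1), "category")
  frac_m <- mean(cats == "malignant")
  category <- if (frac_m >= 0.5) "malignant" else "benign"
  score <- mean(vapply(sequence_decisions, `[[`, numeric(1),
                       "mean_malignant_prob"))
  structure(list(category = category,
                 sequence_vote_fractions = c(benign = 1 - frac_m,
                                             malignant = frac_m),
                 malignancy_score = score,
                 n_sequences = length(sequence_decisions)),
            class = "patient_decision")
}

# ---- cohort-level evidence assembly ----------------------------------------

# Evidence bundle: everything needed to re-fuse a cohort under any weight
# setting without touching images again. Per patient: the age pair and, per
# sequence, the classifier pair plus the per-image detection pairs.
build_evidence <- function(manifest, detections, seq_preds, age_table = NULL,
                           modalities = NULL) {
  lapply(manifest$patients, function(p) {
    A <- if (!is.null(age_table)) age_prior(age_table, p$age) else NULL
    seqs <- list()
    for (sq in p$sequences) {
      if (!is.null(modalities) && !(sq$modality %in% modalities)) next
      sp <- seq_preds[seq_preds$patient_id == p$patient_id &
                        seq_preds$sequence_id == sq$sequence_id, , drop = FALSE]
      M <- if (nrow(sp) > 0L)
        prob_pair(sp$p_b[1L], sp$p_m[1L]) else NULL
      det <- detections[detections$patient_id == p$patient_id &
                          detections$sequence_id == sq$sequence_id, , drop = FALSE]
      D_by_image <- lapply(split(det, det$slice_index), image_probability)
      seqs[[length(seqs) + 1L]] <- list(sequence_id = sq$sequence_id,
                                        modality = sq$modality,
                                        M = M, D = unname(D_by_image))
    }
    list(patient_id = p$patient_id, age = p$age, true_class = p$true_class,
         A = A, sequences = seqs)
  })
}

# fuse a prebuilt evidence bundle under one weight setting
fuse_evidence <- function(evidence, weights) {
  w <- as_fusion_weights(weights)
  rows <- lapply(evidence, function(ev) {
    seq_decisions <- lapply(ev$sequences, function(sq) {
      image_scores <- lapply(sq$D, function(D)
        fuse_image(D = D, M = sq$M, A = ev$A, weights = w))
      decide_sequence(image_scores, M = sq$M, A = ev$A, weights = w)
    })
    if (length(seq_decisions) == 0L) return(NULL)
    pd <- decide_patient(seq_decisions)
    tibble(patient_id = ev$patient_id, category = pd$category,
           malignancy_score = pd$malignancy_score,
           n_sequences = pd$n_sequences,
           seq_malignant_fraction = pd$sequence_vote_fractions[["malignant"]])
  })
  dplyr::bind_rows(purrr::compact(rows))
}

#' Fuse detection, sequence and age evidence into patient decisions
#'
#' Runs the full decision cascade for a cohort: per image, the weighted
#' fusion of the detection pair with the sequence and age pairs
#' ([fuse_image()]); per sequence, the image-majority vote
#' ([decide_sequence()]); per patient, the sequence-majority vote
#' ([decide_patient()]).
#'
#' @param manifest The cohort [dataset_manifest()] being decided.
#' @param detections Detection table ([detect_cohort()] format).
#' @param seq_preds Sequence prediction table ([classify_cohort()] format).
#' @param age_table An [fit_age_table()] fitted on *training* metadata, or
#'   `NULL` when age evidence is unused.
#' @param weights A [fusion_weights()] object.
#' @return Tibble with one row per patient: `patient_id`, `category`,
#'   `malignancy_score`, `n_sequences`, `seq_malignant_fraction`.
#' @export
fuse_cohort <- function(manifest, detections, seq_preds, age_table = NULL,
                        weights = fusion_weights(0.45, 0.45, 0.1)) {
  evidence <- build_evidence(manifest, detections, seq_preds, age_table)
  fuse_evidence(evidence, weights)
}
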