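#' Construct a dataset manifest
#'
#' A manifest is the in-memory form of a cohort: a list of
#' [patient_record()]s plus a role tag. [tidy()] flattens it to one row per
#' sequence; [glance()] reports cohort-level counts.
#'
#' @param patients List of [patient_record()] objects with unique ids.
#' @param role `"train"`, `"test"` or `"all"`.
#' @param provenance Free-text description of where the data came from.
#' @return An object of class `dataset_manifest`.
#' @export
dataset_manifest <- function(patients, role = "all", provenance = "") {
  ids <- vapply(patients, function(p) p$patient_id, character(1))
  if (anyDuplicated(ids)) abort("patient ids must be unique within a manifest")
  structure(list(patients = patients, role = role, provenance = provenance),
            class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<dataset_manifest role=%s> %d patients (%d benign / %d malignant), %d sequences, %d slices (%d annotated)\n",
    x$role, g$n_patients, g$n_benign, g$n_malignant, g$n_sequences,
    g$n_slices, g$n_annotated_images))
  invisible(x)
}

#' @rdname dataset_manifest
#' @param x A `dataset_manifest`.
#' @param ... Unused.
#' @export
glance.dataset_manifest <- function(x, ...) {
  tb <- tidy(x)
  cls <- patient_meta(x)$true_class
  tibble(
    n_patients = length(x$patients),
    n_benign = sum(cls == "benign"),
    n_malignant = sum(cls == "malignant"),
    n_sequences = nrow(tb),
    n_slices = sum(tb$n_slices),
    n_annotated_images = sum(tb$n_annotated),
    role = x$role
  )
}

#' @rdname dataset_manifest
#' @export
tidy.dataset_manifest <- function(x, ...) {
  purrr::map_dfr(x$patients, function(p) {
    purrr::map_dfr(p$sequences, function(sq) {
      n_ann <- sum(vapply(sq$slices, function(s) nrow(s$boxes) > 0L, logical(1)))
      tibble(patient_id = p$patient_id, sequence_id = sq$sequence_id,
             modality = sq$modality, age = p$age, true_class = p$true_class,
             n_slices = length(sq$slices), n_annotated = n_ann)
    })
  })
}

#' Per-patient metadata table
#'
#' @param manifest A [dataset_manifest()].
#' @return Tibble with one row per patient: `patient_id`, `age`,
#'   `true_class`, `locations` (semicolon-separated), `n_sequences`.
#' @export
patient_meta <- function(manifest) {
  purrr::map_dfr(manifest$patients, function(p) {
    tibble(patient_id = p$patient_id, age = p$age, true_class = p$true_class,
           locations = paste(p$vertebral_locations, collapse = ";"),
           n_sequences = length(p$sequences))
  })
}

# look up one patient by id
manifest_patient <- function(manifest, patient_id) {
  for (p in manifest$patients) if (p$patient_id == patient_id) return(p)
  abort(sprintf("patient '%s' not found in manifest", patient_id))
}

#' Build a manifest from a cohort directory
#'
#' Expects the layout written by [generate_cohort()]: a `metadata.csv` with
#' one row per sequence (columns `patient_id, sequence_id, modality, age,
#' class, locations`; locations semicolon-separated) and directories
#' `<patient_id>/<sequence_id>/` holding `slice_<index>.json` LabelMe
#' annotations with companion PNGs. Slices are ordered by the acquisition
#' index encoded in the file name, never by lexicographic accident; images
#' are referenced by path and read lazily.
#'
#' @param root Cohort directory.
#' @param role Role tag for the returned manifest.
#' @return A [dataset_manifest()].
#' @export
build_manifest <- function(root, role = "all") {
  meta_path <- file.path(root, "metadata.csv")
  if (!file.exists(meta_path))
    abort(sprintf("metadata.csv not found under %s", root))
  meta <- readr::read_csv(meta_path, show_col_types = FALSE)
  need <- c("patient_id", "sequence_id", "modality", "age", "class", "locations")
  if (!all(need %in% names(meta)))
    abort(sprintf("metadata.csv must have columns %s", paste(need, collapse = ", ")))
  patient_dirs <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  patients <- lapply(patient_dirs, function(pid) {
    prows <- meta[meta$patient_id == pid, , drop = FALSE]
    if (nrow(prows) == 0L)
      abort(sprintf("no metadata row for patient directory '%s'", pid))
    seq_dirs <- sort(list.dirs(file.path(root, pid), recursive = FALSE,
                               full.names = FALSE))
    sequences <- lapply(seq_dirs, function(sid) {
      srow <- prows[prows$sequence_id == sid, , drop = FALSE]
      if (nrow(srow) == 0L)
        abort(sprintf("no metadata row for sequence '%s' of patient '%s'", sid, pid))
      jsons <- list.files(file.path(root, pid, sid), pattern = "\\.json$",
                          full.names = TRUE)
      idx <- as.integer(stringr::str_match(basename(jsons), "slice_(\\d+)\\.json$")[, 2L])
      if (anyNA(idx))
        abort(sprintf("unparseable slice file name under %s/%s", pid, sid))
      if (anyDuplicated(idx))
        abort(sprintf("duplicate slice_index within sequence %s/%s", pid, sid))
      ord <- order(idx)
      slices <- purrr::map2(jsons[ord], idx[ord], read_labelme_slice)
      mri_sequence(sid, srow$modality[1L], slices)
    })
    locs <- prows$locations[1L]
    locs <- if (is.na(locs) || locs == "") character(0) else
      strsplit(locs, ";", fixed = TRUE)[[1L]]
    patient_record(pid, prows$age[1L], prows$class[1L], locs, sequences)
  })
  dataset_manifest(patients, role = role,
                   provenance = sprintf("read from %s", normalizePath(root)))
}

#' Split a cohort into train and test manifests
#'
#' Splitting is always at patient level (a patient's sequences and slices
#' never straddle the split) and stratified by class: the test side receives
#' `round(n_class * test_fraction)` patients of each class, so each side's
#' class ratio is within one patient of the overall ratio. Deterministic
#' given `seed`.
#'
#' @param manifest A [dataset_manifest()]; every patient must have a known
#'   class.
#' @param test_fraction Fraction in (0, 1) of each class assigned to test.
#' @param seed Integer seed.
#' @return Named list with `train` and `test` manifests.
#' @export
split_dataset <- function(manifest, test_fraction = 0.3, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1)
    abort("test_fraction must be strictly between 0 and 1")
  meta <- patient_meta(manifest)
  if (!all(meta$true_class %in% c("benign", "malignant")))
    abort("every patient must have true_class benign or malignant to split")
  counts <- table(meta$true_class)
  if (any(counts < 2L))
    abort("each class needs at least 2 patients to split")
  test_ids <- withr::with_seed(seed, {
    unlist(lapply(c("benign", "malignant"), function(cl) {
      ids <- sort(meta$patient_id[meta$true_class == cl])
      n_test <- round(length(ids) * test_fraction)
      n_test <- max(1L, min(length(ids) - 1L, n_test))
      sample(ids, n_test)
    }))
  })
  in_test <- vapply(manifest$patients, function(p) p$patient_id %in% test_ids,
                    logical(1))
  list(
    train = dataset_manifest(manifest$patients[!in_test], role = "train",
                             provenance = manifest$provenance),
    test = dataset_manifest(manifest$patients[in_test], role = "test",
                            provenance = manifest$provenance)
  )
}
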