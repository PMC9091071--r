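#' Configuration for a synthetic spine-MRI cohort
#'
#' The generator emulates the structure of a sagittal spine-MRI study:
#' per-patient multi-sequence slice stacks (modalities cycling T1, T2,
#' FS-T2), a lesion visible on a contiguous sub-range of slices with a
#' slowly drifting in-plane footprint, rectangle ground-truth boxes, and an
#' age-dependent malignancy law
#' `P(malignant | age) = 1 / (1 + exp(-(age - a0) / s))`.
#'
#' Benign and malignant lesions differ in texture and border: benign lesions
#' are near-homogeneous ellipses with a smooth boundary, malignant lesions
#' carry intensity speckle (`malignant_texture_sd`) and a radially perturbed
#' boundary (relative amplitude `border_irregularity`). Lesion/background
#' contrast and the texture signal are modality dependent (weaker on T1,
#' stronger on T2 and FS-T2), so T2-weighted sequences are genuinely more
#' informative than T1.
#'
#' @param n_patients Number of patients.
#' @param age_low,age_high Age range in years; ages are drawn uniformly.
#' @param a0 Logistic midpoint of the malignancy law, years (default 40:
#'   probability 0.5 at age 40).
#' @param s Logistic scale, years (default 8: probability ~0.99 at age 80).
#' @param sequences_per_patient Sequences per patient (default 4).
#' @param slices_per_sequence Integer range `c(lo, hi)` of slices per
#'   sequence (default 12-24).
#' @param image_size `c(height, width)` pixels (default 256 x 256).
#' @param benign_texture_sd,malignant_texture_sd Intensity speckle standard
#'   deviation inside benign / malignant lesions (image intensities live in
#'   `[0, 1]`).
#' @param border_irregularity Radial boundary perturbation amplitude of
#'   malignant lesions as a fraction of the minor semi-axis.
#' @param modality_contrast Named lesion-minus-background intensity offsets
#'   per modality.
#' @param modality_texture_scale Named multipliers applied to the texture sd
#'   per modality (the class signal is present in all modalities, weaker on
#'   T1).
#' @param lesion_minor_axis Range of the lesion semi-minor axis, pixels.
#' @param lesion_aspect Range of the major/minor axis ratio.
#' @param lesion_slices Integer range of the number of consecutive slices on
#'   which the lesion is visible (annotated).
#' @param location_probs Named categorical over vertebral locations.
#' @param second_location_prob Probability that a patient carries a second,
#'   distinct vertebral location tag.
#' @param seed Integer seed governing all randomness of the cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 60L,
                          age_low = 4L, age_high = 82L,
                          a0 = 40, s = 8,
                          sequences_per_patient = 4L,
                          slices_per_sequence = c(12L, 24L),
                          image_size = c(256L, 256L),
                          benign_texture_sd = 0.02,
                          malignant_texture_sd = 0.12,
                          border_irregularity = 0.25,
                          modality_contrast = c("T1" = 0.18, "T2" = 0.30, "FS-T2" = 0.35),
                          modality_texture_scale = c("T1" = 0.4, "T2" = 1, "FS-T2" = 1),
                          lesion_minor_axis = c(8, 30),
                          lesion_aspect = c(1.2, 2),
                          lesion_slices = c(7L, 11L),
                          location_probs = c(cervical = 0.44, thoracic = 0.27,
                                             lumbar = 0.26, sacral = 0.03),
                          second_location_prob = 0.15,
                          seed = 1L) {
  if (n_patients < 2L) abort("n_patients must be at least 2")
  if (age_low > age_high) abort("age_low must not exceed age_high")
  if (s <= 0) abort("logistic scale s must be positive")
  if (benign_texture_sd < 0 || malignant_texture_sd < 0)
    abort("texture standard deviations must be nonnegative")
  stopifnot(length(slices_per_sequence) == 2L, length(image_size) == 2L)
  cfg <- list(
    n_patients = as.integer(n_patients), age_low = as.integer(age_low),
    age_high = as.integer(age_high), a0 = a0, s = s,
    sequences_per_patient = as.integer(sequences_per_patient),
    slices_per_sequence = as.integer(slices_per_sequence),
    image_size = as.integer(image_size),
    benign_texture_sd = benign_texture_sd,
    malignant_texture_sd = malignant_texture_sd,
    border_irregularity = border_irregularity,
    modality_contrast = modality_contrast,
    modality_texture_scale = modality_texture_scale,
    lesion_minor_axis = lesion_minor_axis,
    lesion_aspect = lesion_aspect,
    lesion_slices = as.integer(lesion_slices),
    location_probs = location_probs,
    second_location_prob = second_location_prob,
    seed = as.integer(seed),
    # fixed background model
    background_base = 0.35, background_noise_amp = 0.08, noise_res = 16L,
    vertebra_intensity = 0.12
  )
  structure(cfg, class = "cohort_config")
}

#' Age-dependent malignancy probability
#'
#' Logistic law `1 / (1 + exp(-(age - a0) / s))`: monotone increasing in
#' age, 0.5 at the midpoint `a0`, approaching 1 for old and 0 for young
#' patients. With the defaults `a0 = 40`, `s = 8` the probability is 0.5 at
#' age 40 and about 0.99 at age 80.
#'
#' @param age Age in years (vectorized).
#' @param a0 Midpoint in years.
#' @param s Scale in years, positive.
#' @return Probability in (0, 1).
#' @examples
#' malignancy_probability(c(20, 40, 80))
#' @export
malignancy_probability <- function(age, a0 = 40, s = 8) {
  if (s <= 0) abort("logistic scale s must be positive")
  1 / (1 + exp(-(age - a0) / s))
}

#' Draw cohort ages and classes only
#'
#' Fast path for studying the age law: samples `(age, class)` pairs under
#' the same distributions as [sample_patient()] without building any imaging
#' data.
#'
#' @param config A [cohort_config()].
#' @return Tibble with `patient_id`, `age`, `true_class`.
#' @export
sample_cohort_ages <- function(config) {
  withr::with_seed(config$seed, {
    age <- (config$age_low:config$age_high)[sample.int(
      config$age_high - config$age_low + 1L, config$n_patients, replace = TRUE)]
    p_m <- malignancy_probability(age, config$a0, config$s)
    cls <- ifelse(runif(config$n_patients) < p_m, "malignant", "benign")
    tibble(patient_id = sprintf("P%04d", seq_len(config$n_patients)),
           age = age, true_class = cls)
  })
}

modality_cycle <- c("T1", "T2", "FS-T2")

# sample one element of a vector (safe for length-1 vectors, where base
# sample() would treat a scalar n as 1:n)
pick1 <- function(v) v[sample.int(length(v), 1L)]

# deterministic per-slice render seed, independent of the sampling stream
derive_render_seed <- function(seed, patient_i, seq_i, slice_i) {
  as.integer((abs(seed) * 1000003 + patient_i * 10007 + seq_i * 101 + slice_i) %%
               2147483629)
}

# elliptical lesion support with optional radial boundary perturbation,
# evaluated on a subwindow around the ellipse (no RNG: perturbation params
# are in `les`); returns list(mask, ys, xs) or NULL when nothing is inside
lesion_mask_sub <- function(les, h, w) {
  r_max <- max(les$a, les$b) * (1 + abs(les$irr)) + 2
  if (les$cx + r_max < 1 || les$cx - r_max > w ||
      les$cy + r_max < 1 || les$cy - r_max > h) return(NULL)
  xs <- max(1, floor(les$cx - r_max)):min(w, ceiling(les$cx + r_max))
  ys <- max(1, floor(les$cy - r_max)):min(h, ceiling(les$cy + r_max))
  dx <- matrix(xs - 0.5 - les$cx, length(ys), length(xs), byrow = TRUE)
  dy <- matrix(ys - 0.5 - les$cy, length(ys), length(xs))
  ct <- cos(les$theta); st <- sin(les$theta)
  u <- (dx * ct + dy * st) / les$a
  v <- (-dx * st + dy * ct) / les$b
  rho2 <- u^2 + v^2
  thr <- 1
  if (les$irr > 0) {
    phi <- atan2(dy, dx)
    g <- 0
    for (k in seq_along(les$wobble_freq))
      g <- g + sin(les$wobble_freq[k] * phi + les$wobble_phase[k])
    thr <- (1 + les$irr * g / length(les$wobble_freq))^2
  }
  m <- rho2 <= thr
  if (!any(m)) return(NULL)
  list(mask = m, ys = ys, xs = xs)
}

# full-image logical mask (test/oracle convenience)
lesion_mask <- function(les, h, w) {
  mask <- matrix(FALSE, h, w)
  sub <- lesion_mask_sub(les, h, w)
  if (!is.null(sub)) mask[sub$ys, sub$xs] <- sub$mask
  mask
}

# tight 0-based half-open bound of a mask; NULL when the mask is empty
mask_bbox <- function(mask) {
  rs <- which(rowSums(mask) > 0)
  cs <- which(colSums(mask) > 0)
  if (length(rs) == 0L) return(NULL)
  bbox(cs[1L] - 1, rs[1L] - 1, cs[length(cs)], rs[length(rs)])
}

mask_bbox_sub <- function(sub) {
  if (is.null(sub)) return(NULL)
  rs <- which(rowSums(sub$mask) > 0)
  cs <- which(colSums(sub$mask) > 0)
  bbox(sub$xs[cs[1L]] - 1, sub$ys[rs[1L]] - 1,
       sub$xs[cs[length(cs)]], sub$ys[rs[length(rs)]])
}

# interpolation weight matrix mapping n_in samples to n_out, pixel-center
# aligned; each row has at most two nonzero weights (linear interpolation)
bilinear_weights <- function(n_out, n_in) {
  pos <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  pos <- pmin(pmax(pos, 1), n_in)
  lo <- pmin(floor(pos), n_in - (n_in > 1L))
  frac <- pos - lo
  W <- matrix(0, n_out, n_in)
  W[cbind(seq_len(n_out), lo)] <- 1 - frac
  if (n_in > 1L) W[cbind(seq_len(n_out), lo + 1L)] <-
      W[cbind(seq_len(n_out), lo + 1L)] + frac
  W
}

# separable resize by matrix multiplication; "bilinear" (default) or
# nearest-neighbor "none"
resize_mat <- function(m, nr, nc, filter = "bilinear") {
  if (nrow(m) == nr && ncol(m) == nc) return(m)
  if (filter == "none") {
    ri <- pmin(pmax(ceiling((seq_len(nr) - 0.5) * nrow(m) / nr), 1L), nrow(m))
    ci <- pmin(pmax(ceiling((seq_len(nc) - 0.5) * ncol(m) / nc), 1L), ncol(m))
    return(m[ri, ci, drop = FALSE])
  }
  bilinear_weights(nr, nrow(m)) %*% m %*% t(bilinear_weights(nc, ncol(m)))
}

# deterministic slice renderer: smooth noise background, a vertical column
# of bright vertebral bodies separated by darker disc gaps, and optionally a
# lesion drawn over it
render_from_spec <- function(spec) {
  h <- spec$shape[1L]; w <- spec$shape[2L]
  withr::with_seed(spec$seed, {
    coarse <- matrix(runif(spec$noise_res^2), spec$noise_res, spec$noise_res)
    img <- spec$base + spec$noise_amp * 2 * (resize_mat(coarse, h, w) - 0.5)
    vb <- spec$vertebra
    body <- ((seq_len(h) + vb$phase) %% vb$period) < vb$body_frac * vb$period
    cols <- abs(seq_len(w) - 0.5 - vb$x_center) <= vb$width / 2
    img[body, cols] <- img[body, cols] + vb$intensity
    if (!is.null(spec$lesion)) {
      les <- spec$lesion
      sub <- lesion_mask_sub(les, h, w)
      if (!is.null(sub)) {
        patch <- img[sub$ys, sub$xs]
        n <- sum(sub$mask)
        patch[sub$mask] <- spec$base + les$offset +
          (if (les$sd > 0) rnorm(n, 0, les$sd) else 0)
        img[sub$ys, sub$xs] <- patch
      }
    }
    pmin(pmax(img, 0), 1)
  })
}

# draw per-sequence lesion geometry; retried by the caller if any slice's
# mask comes out empty
draw_lesion_geometry <- function(config, n_slices, vb_x) {
  h <- config$image_size[1L]; w <- config$image_size[2L]
  b <- runif(1, config$lesion_minor_axis[1L], config$lesion_minor_axis[2L])
  a <- b * runif(1, config$lesion_aspect[1L], config$lesion_aspect[2L])
  theta <- runif(1, 0, pi)
  len <- pick1(config$lesion_slices[1L]:min(config$lesion_slices[2L], n_slices))
  start <- pick1(0:(n_slices - len))
  cx0 <- vb_x + runif(1, -0.15, 0.15) * w
  cy0 <- runif(1, 0.2, 0.8) * h
  drift <- runif(2, -1.5, 1.5)
  centers <- cbind(cx0 + drift[1L] * (seq_len(len) - 1L),
                   cy0 + drift[2L] * (seq_len(len) - 1L))
  list(a = a, b = b, theta = theta, slice_start = start, n_lesion = len,
       centers = centers,
       wobble_freq = sample(2:6, 3L, replace = TRUE),
       wobble_phase = runif(3, 0, 2 * pi))
}

#' Sample one synthetic patient
#'
#' Draws age (uniform on the configured range), class (Bernoulli with
#' [malignancy_probability()]), vertebral location(s), and per-sequence
#' lesion geometry, and assembles a [patient_record()] whose slices carry
#' deterministic render specifications (pixels are rendered lazily by
#' [slice_image()]). Consumes the active R random stream; wrap in
#' `withr::with_seed()` for standalone reproducibility. [simulate_cohort()]
#' does this for you.
#'
#' A lesion whose rendered support would fall fully outside the image on any
#' slice is redrawn, at most 10 times, then an error is raised.
#'
#' @param config A [cohort_config()].
#' @param patient_index Integer index used for the patient id and for
#'   deriving per-slice render seeds.
#' @return List with `patient` (a [patient_record()]) and `truth`
#'   (generator-side ground truth: lesion geometry and per-slice boxes).
#' @export
sample_patient <- function(config, patient_index = 1L) {
  h <- config$image_size[1L]; w <- config$image_size[2L]
  pid <- sprintf("P%04d", patient_index)
  age <- pick1(config$age_low:config$age_high)
  p_m <- malignancy_probability(age, config$a0, config$s)
  cls <- if (runif(1) < p_m) "malignant" else "benign"
  locs <- sample(names(config$location_probs), 1L,
                 prob = config$location_probs)
  if (runif(1) < config$second_location_prob)
    locs <- c(locs, sample(setdiff(names(config$location_probs), locs), 1L))
  tex_sd <- if (cls == "malignant") config$malignant_texture_sd else
    config$benign_texture_sd
  irr <- if (cls == "malignant") config$border_irregularity else 0

  sequences <- vector("list", config$sequences_per_patient)
  truth_seqs <- vector("list", config$sequences_per_patient)
  for (si in seq_len(config$sequences_per_patient)) {
    modality <- modality_cycle[(si - 1L) %% 3L + 1L]
    n_slices <- pick1(config$slices_per_sequence[1L]:config$slices_per_sequence[2L])
    vb <- list(x_center = w / 2 + runif(1, -0.05, 0.05) * w,
               width = 0.16 * w, period = 0.125 * h, body_frac = 0.7,
               phase = runif(1, 0, 0.125 * h),
               intensity = config$vertebra_intensity)
    geom <- NULL
    boxes_by_slice <- NULL
    for (attempt in seq_len(10L)) {
      cand <- draw_lesion_geometry(config, n_slices, vb$x_center)
      boxes <- vector("list", cand$n_lesion)
      ok <- TRUE
      for (j in seq_len(cand$n_lesion)) {
        les <- list(cx = cand$centers[j, 1L], cy = cand$centers[j, 2L],
                    a = cand$a, b = cand$b, theta = cand$theta, irr = irr,
                    wobble_freq = cand$wobble_freq,
                    wobble_phase = cand$wobble_phase)
        bb <- mask_bbox_sub(lesion_mask_sub(les, h, w))
        if (is.null(bb)) { ok <- FALSE; break }
        boxes[[j]] <- bb
      }
      if (ok) { geom <- cand; boxes_by_slice <- boxes; break }
    }
    if (is.null(geom))
      abort(sprintf("could not place a lesion inside the image for %s after 10 attempts", pid))

    slices <- vector("list", n_slices)
    for (k in seq_len(n_slices)) {
      slice_index <- k - 1L
      j <- k - geom$slice_start  # 1-based position within the lesion range
      lesion_spec <- NULL
      boxes <- empty_boxes()
      if (j >= 1L && j <= geom$n_lesion) {
        lesion_spec <- list(
          cx = geom$centers[j, 1L], cy = geom$centers[j, 2L],
          a = geom$a, b = geom$b, theta = geom$theta, irr = irr,
          wobble_freq = geom$wobble_freq, wobble_phase = geom$wobble_phase,
          offset = unname(config$modality_contrast[[modality]]),
          sd = tex_sd * unname(config$modality_texture_scale[[modality]]))
        bb <- boxes_by_slice[[j]]
        boxes <- box_tbl(bb[["x0"]], bb[["y0"]], bb[["x1"]], bb[["y1"]], cls)
      }
      spec <- list(
        seed = derive_render_seed(config$seed, patient_index, si, k),
        shape = c(h, w), base = config$background_base,
        noise_amp = config$background_noise_amp, noise_res = config$noise_res,
        vertebra = vb, lesion = lesion_spec)
      slices[[k]] <- annotated_slice(slice_index, boxes = boxes,
                                     render = spec, shape = c(h, w))
    }
    sid <- sprintf("S%d", si)
    sequences[[si]] <- mri_sequence(sid, modality, slices)
    truth_seqs[[si]] <- list(sequence_id = sid, modality = modality,
                             n_slices = n_slices, geometry = geom)
  }
  patient <- patient_record(pid, age, cls, locs, sequences)
  truth <- list(patient_id = pid, age = age, true_class = cls,
                vertebral_locations = locs, sequences = truth_seqs)
  list(patient = patient, truth = truth)
}

#' Render one slice of a synthetic patient
#'
#' Convenience accessor: renders the pixels of slice `slice_index` of
#' sequence `sequence_index` for a patient produced by [sample_patient()] or
#' found in a simulated manifest.
#'
#' @param patient A [patient_record()] with render specifications.
#' @param sequence_index 1-based sequence position.
#' @param slice_index 0-based acquisition index.
#' @return The rendered [annotated_slice()] with its image materialized.
#' @export
render_slice <- function(patient, sequence_index, slice_index) {
  sq <- patient$sequences[[sequence_index]]
  for (s in sq$slices) {
    if (s$slice_index == slice_index) {
      s$image <- slice_image(s)
      return(s)
    }
  }
  abort(sprintf("slice_index %d not present in sequence %d", slice_index,
                sequence_index))
}

#' Simulate a cohort in memory
#'
#' Draws every patient under `config`'s seed and returns a
#' [dataset_manifest()] whose slices render their pixels lazily and
#' deterministically. The generator-side ground truth is attached as
#' attribute `"truth"`.
#'
#' @param config A [cohort_config()].
#' @param role Role tag for the manifest.
#' @return A [dataset_manifest()].
#' @export
simulate_cohort <- function(config, role = "all") {
  drawn <- withr::with_seed(config$seed, {
    lapply(seq_len(config$n_patients), function(i) sample_patient(config, i))
  })
  manifest <- dataset_manifest(
    lapply(drawn, `[[`, "patient"), role = role,
    provenance = sprintf("synthetic cohort (seed %d)", config$seed))
  attr(manifest, "truth") <- lapply(drawn, `[[`, "truth")
  manifest
}

#' Write a synthetic cohort to disk
#'
#' Renders and writes every slice as PNG with a LabelMe JSON annotation,
#' plus `metadata.csv` (one row per sequence) and `truth.json` (per-patient
#' generator ground truth), in the exact layout that [build_manifest()]
#' reads. Returns the manifest rebuilt from disk.
#'
#' @param config A [cohort_config()].
#' @param out Output directory (created if needed).
#' @return A [dataset_manifest()] built from the written files.
#' @export
generate_cohort <- function(config, out) {
  mem <- simulate_cohort(config)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out)) abort(sprintf("cannot create output directory %s", out))
  meta_rows <- list()
  for (p in mem$patients) {
    for (sq in p$sequences) {
      d <- file.path(out, p$patient_id, sq$sequence_id)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      for (s in sq$slices) {
        write_labelme_slice(s, file.path(d, sprintf("slice_%03d.json", s$slice_index)))
      }
      meta_rows[[length(meta_rows) + 1L]] <- tibble(
        patient_id = p$patient_id, sequence_id = sq$sequence_id,
        modality = sq$modality, age = p$age, class = p$true_class,
        locations = paste(p$vertebral_locations, collapse = ";"))
    }
  }
  readr::write_csv(dplyr::bind_rows(meta_rows), file.path(out, "metadata.csv"))
  truth <- attr(mem, "truth")
  truth_summary <- purrr::map(truth, function(t) {
    list(patient_id = t$patient_id, age = t$age, true_class = t$true_class,
         vertebral_locations = as.list(t$vertebral_locations))
  })
  jsonlite::write_json(truth_summary, file.path(out, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  build_manifest(out)
}
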