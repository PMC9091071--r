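#' Fit a per-age-bin benign/malignant probability table
#'
#' Bins training patients' ages into left-closed, right-open bins of
#' `bin_width` years covering `[0, max_age]` (the last bin is closed on the
#' right via the lookup rule in [age_prior()]) and estimates each bin's
#' malignancy probability with additive smoothing:
#' `p_m = (n_malignant + alpha) / (n_benign + n_malignant + 2 * alpha)`.
#' Smoothing keeps sparse bins away from certainty, so a single age bin can
#' never veto the imaging evidence in the weighted fusion. Bins with no
#' patients receive the global prior, computed with the same smoothing over
#' all records.
#'
#' @param records Tibble (or data frame) with columns `age` and
#'   `true_class` (`"benign"`/`"malignant"`); e.g. [patient_meta()] of the
#'   training manifest.
#' @param bin_width Bin width in years (default 10, decade bins).
#' @param alpha Additive pseudo-count, nonnegative (default 1).
#' @return An object of class `age_table`.
#' @export
fit_age_table <- function(records, bin_width = 10, alpha = 1) {
  if (alpha < 0) abort("smoothing alpha must be nonnegative")
  records <- as_tibble(records)
  if (nrow(records) == 0L) abort("no records to fit an age table on")
  if (any(records$age < 0)) abort("ages must be nonnegative")
  if (!all(records$true_class %in% c("benign", "malignant")))
    abort("true_class must be benign or malignant for every record")
  edges <- seq(0, ceiling(max(records$age) / bin_width) * bin_width +
                 (max(records$age) %% bin_width == 0) * bin_width,
               by = bin_width)
  if (length(edges) < 2L) edges <- c(0, bin_width)
  bin <- findInterval(records$age, edges, rightmost.closed = FALSE)
  n_b <- tabulate(bin[records$true_class == "benign"], nbins = length(edges) - 1L)
  n_m <- tabulate(bin[records$true_class == "malignant"], nbins = length(edges) - 1L)
  g_m <- (sum(n_m) + alpha) / (sum(n_b) + sum(n_m) + 2 * alpha)
  p_m <- ifelse(n_b + n_m > 0,
                (n_m + alpha) / (n_b + n_m + 2 * alpha),
                g_m)
  bins <- tibble(
    bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
    n_benign = n_b, n_malignant = n_m,
    p_b = 1 - p_m, p_m = p_m)
  structure(list(bins = bins, bin_width = bin_width, alpha = alpha,
                 global_prior = prob_pair(1 - g_m, g_m, normalize = FALSE),
                 n_records = nrow(records)),
            class = "age_table")
}

#' @export
print.age_table <- function(x, ...) {
  cat(sprintf("<age_table> %d bins of %g years, alpha = %g, %d records\n",
              nrow(x$bins), x$bin_width, x$alpha, x$n_records))
  print(x$bins)
  invisible(x)
}

#' @rdname fit_age_table
#' @param x An `age_table`.
#' @param ... Unused.
#' @export
tidy.age_table <- function(x, ...) x$bins

#' Look up the age-prior probability pair for a patient
#'
#' Returns the benign/malignant pair of the bin containing `age` (bins are
#' left-closed, right-open; an age on an edge belongs to the upper bin).
#' Ages at or beyond the last edge use the last bin.
#'
#' @param table An [fit_age_table()] object.
#' @param age Age in years, nonnegative.
#' @return Probability pair `c(p_b, p_m)`.
#' @export
age_prior <- function(table, age) {
  stopifnot(inherits(table, "age_table"))
  if (length(age) != 1L || is.na(age) || age < 0)
    abort("age must be a single nonnegative number")
  i <- findInterval(age, table$bins$bin_lo)
  i <- min(max(i, 1L), nrow(table$bins))
  prob_pair(table$bins$p_b[i], table$bins$p_m[i], normalize = FALSE)
}

# round-trip serialization for the CSV/JSON pipeline boundary
write_age_table <- function(table, path) {
  jsonlite::write_json(
    list(bin_width = table$bin_width, alpha = table$alpha,
         n_records = table$n_records,
         global_prior = as.list(table$global_prior),
         bins = table$bins),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_age_table <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(bins = as_tibble(x$bins), bin_width = x$bin_width,
                 alpha = x$alpha,
                 global_prior = prob_pair(x$global_prior$p_b, x$global_prior$p_m),
                 n_records = x$n_records),
            class = "age_table")
}

#' @rdname fit_age_table
#' @param object An `age_table`.
#' @export
autoplot.age_table <- function(object, ...) {
  b <- object$bins
  b$mid <- (b$bin_lo + b$bin_hi) / 2
  ggplot2::ggplot(b, ggplot2::aes(x = .data$mid, y = .data$p_m)) +
    ggplot2::geom_col(fill = "firebrick", alpha = 0.8,
                      width = object$bin_width * 0.9) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "age (years)", y = "P(malignant)",
                  title = "Fitted age-bin malignancy probabilities") +
    ggplot2::ylim(0, 1)
}
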