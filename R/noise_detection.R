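#' Technical-noise model for replicate-free count data
#'
#' Between technical replicates of the same library, read-count differences
#' scale as the square root of the count; the envelope `k * sqrt(N)` (k = 5
#' by default) bounds the variation for any count N, so the relative error
#' `k * sqrt(N) / N` shrinks as counts grow. The model also names the
#' replicate distribution used whenever replicate counts are simulated:
#' Poisson by default, negative binomial when `dispersion > 0`.
#'
#' @param k envelope coefficient (> 0, dimensionless; default 5).
#' @param dispersion negative-binomial dispersion; 0 selects Poisson.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(k = 5, dispersion = 0) {
  stopifnot(k > 0, dispersion >= 0)
  structure(list(k = k, dispersion = dispersion), class = "noise_model")
}

# one draw set from the replicate distribution at given means
.sim_replicate <- function(noise, means) {
  if (noise$dispersion > 0)
    rnbinom(length(means), mu = means, size = 1 / noise$dispersion)
  else
    rpois(length(means), means)
}

#' Sampling-error envelope
#'
#' @param noise a [noise_model].
#' @param n read count(s), non-negative.
#' @return A `data.frame` with columns `n`, `bound` (= k * sqrt(n)) and
#'   `relative_error` (= k * sqrt(n) / n, `Inf` at n = 0).
#' @export
envelope <- function(noise, n) {
  if (any(n < 0)) stop("n must be non-negative")
  bound <- noise$k * sqrt(n)
  data.frame(n = n, bound = bound,
             relative_error = ifelse(n > 0, bound / n, Inf))
}

#' Depth normalization to a reference library
#'
#' Each sample's counts are multiplied by the single proportionality constant
#' `total_mapped(reference) / total_mapped(sample)`, so all libraries share
#' the reference library's sequencing depth. The reference column is
#' unchanged; within-sample ratios between genes are preserved exactly.
#'
#' @param table a raw [count_table].
#' @param reference reference sample id (default: first sample).
#' @return The normalized [count_table] (`normalized` flag set).
#' @export
normalize_depth <- function(table, reference = colnames(table$counts)[1]) {
  if (table$normalized) stop("table is already depth-normalized")
  if (!reference %in% colnames(table$counts))
    stop("reference sample '", reference, "' not in table")
  f <- table$total_mapped[[reference]] / table$total_mapped
  norm <- sweep(table$counts, 2, f[colnames(table$counts)], `*`)
  count_table(norm, table$total_mapped, normalized = TRUE)
}

#' Calibrate the detection threshold from technical replicates
#'
#' Returns the minimal count above which transcripts are reliably seen in
#' both of two independently prepared libraries from the same RNA sample:
#' the smallest integer `c` such that every gene with count >= `c` in either
#' replicate is detected (count >= 1) in the other.
#'
#' @param rep1,rep2 count columns over the same genes, normalized to common
#'   depth.
#' @return The threshold `c` (>= 1), exact (not rounded to a power of two).
#' @export
calibrate_detection_threshold <- function(rep1, rep2) {
  if (length(rep1) != length(rep2)) stop("replicate columns differ in length")
  # genes seen in exactly one replicate force c above their observed count
  discordant <- c(rep1[rep2 < 1 & rep1 >= 1], rep2[rep1 < 1 & rep2 >= 1])
  if (length(discordant) == 0L) return(1)
  floor(max(discordant)) + 1
}

#' Detection threshold on the normalized scale
#'
#' The replicate-concordance threshold is calibrated on raw counts of the
#' lowest-depth library; on depth-normalized data the equivalent detection
#' threshold is that value rescaled by the depth ratio (a raw threshold of 32
#' at half the reference depth becomes 64 normalized). Because dropout in a
#' technical replicate requires a near-zero sampling mean, the rescaled
#' threshold is markedly more conservative than the raw one, not merely
#' equivalent.
#'
#' @param raw_threshold output of [calibrate_detection_threshold()] on the
#'   lowest-depth library's replicates.
#' @param total_reference,total_lowest total mapped reads of the reference
#'   and of the lowest-depth library.
#' @return The detection threshold on normalized counts.
#' @export
detection_threshold_from_calibration <- function(raw_threshold,
                                                 total_reference,
                                                 total_lowest) {
  stopifnot(raw_threshold >= 1, total_reference > 0, total_lowest > 0,
            total_reference >= total_lowest)
  raw_threshold * total_reference / total_lowest
}

#' Monte-Carlo fold-change cutoff at a false-calling rate
#'
#' Simulates technical replicate pairs at expression level `n` under the
#' noise model's replicate distribution and returns the `(1 - alpha)`
#' quantile of the replicate fold change `max(X1, X2) / min(X1, X2)` (zero
#' counts floored at 1). Fold changes beyond this cutoff occur between
#' technical replicates with probability about `alpha`, so using it as a DE
#' cutoff bounds the false-calling rate.
#'
#' @param noise a [noise_model].
#' @param n expression level (mean count, > 0).
#' @param alpha false-calling rate, in (0, 1).
#' @param reps Monte-Carlo iterations (>= 1000).
#' @param seed integer seed (mandatory: no implicit randomness).
#' @return The fold-change cutoff (>= 1).
#' @export
fold_cutoff <- function(noise, n, alpha = 0.05, reps = 10000, seed) {
  if (n <= 0) stop("n must be > 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (reps < 1000) stop("reps must be >= 1000")
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  x1 <- pmax(.sim_replicate(noise, rep(n, reps)), 1)
  x2 <- pmax(.sim_replicate(noise, rep(n, reps)), 1)
  unname(quantile(pmax(x1, x2) / pmin(x1, x2), 1 - alpha))
}

#' Detect genes above a count threshold
#'
#' A gene is detected in a stage when its normalized count reaches the
#' threshold (inclusive, so the printed threshold value itself detects).
#'
#' @param table a normalized [count_table].
#' @param threshold detection threshold on normalized counts (> 0;
#'   64 by default).
#' @return An object of class `detection_result`: the boolean gene x stage
#'   matrix `detected`, `n_detected_any`, `n_detected_all`, and
#'   `per_subset_counts` — the number of detected genes in each exact
#'   stage combination (named e.g. `"PRE+ADULT"`), which partitions
#'   `n_detected_any`.
#' @export
detect_genes <- function(table, threshold = 64) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (!table$normalized) stop("detection requires a depth-normalized table")
  det <- table$counts >= threshold
  any_d <- rowSums(det) > 0
  subset_label <- apply(det, 1, function(r)
    paste(colnames(det)[r], collapse = "+"))
  per_subset <- table(subset_label[any_d])
  structure(list(threshold = threshold,
                 detected = det,
                 n_detected_any = sum(any_d),
                 n_detected_all = sum(rowSums(det) == ncol(det)),
                 per_subset_counts = setNames(as.integer(per_subset),
                                              names(per_subset))),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf(paste0("detection_result: threshold %g; %d genes detected in ",
                     ">=1 stage, %d in all stages\n"),
              x$threshold, x$n_detected_any, x$n_detected_all))
  invisible(x)
}
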