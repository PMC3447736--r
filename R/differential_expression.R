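#' Analysis parameters
#'
#' Bundles the tunable constants of the differential-expression layer. The
#' defaults encode the conservative choices used throughout: a four-fold
#' change cutoff (two-fold as the common alternative), 5% significance,
#' a +1 pseudocount inside every log2, the k = 5 sampling-error envelope,
#' detection threshold 64 on normalized counts, the top-25%-of-range at-peak
#' fraction, and the 100-fold extreme-upregulation rule on the log2 scale.
#'
#' @param fold_cutoff fold-change cutoff (> 1; inclusive).
#' @param alpha significance level, in (0, 1).
#' @param pseudocount added inside log2 (default 1).
#' @param k sampling-error envelope coefficient.
#' @param threshold detection threshold on normalized counts.
#' @param peak_fraction at-peak fraction of the expression range (q).
#' @param extreme_log2 log2 threshold for extreme upregulation
#'   (default log2(100) ~ 6.644).
#' @return An object of class `analysis_params`.
#' @export
analysis_params <- function(fold_cutoff = 4, alpha = 0.05, pseudocount = 1,
                            k = 5, threshold = 64, peak_fraction = 0.75,
                            extreme_log2 = log2(100)) {
  stopifnot(fold_cutoff > 1, alpha > 0, alpha < 1,
            peak_fraction > 0, peak_fraction < 1, k > 0, threshold > 0)
  structure(list(fold_cutoff = fold_cutoff, alpha = alpha,
                 pseudocount = pseudocount, k = k, threshold = threshold,
                 peak_fraction = peak_fraction, extreme_log2 = extreme_log2),
            class = "analysis_params")
}

.log_counts <- function(table, params) log2(table$counts + params$pseudocount)

# direction from a signed log2 ratio under the fold/significance filters
.call_direction <- function(log2_ratio, p, params) {
  lfc <- log2(params$fold_cutoff)
  ifelse(abs(log2_ratio) >= lfc & p < params$alpha,
         ifelse(log2_ratio > 0, "up", "down"), "unchanged")
}

#' Stage-specific differential-expression test
#'
#' Compares each gene's expression in one focal stage against the mean of the
#' other three stages, on `y = log2(count + pseudocount)`. With a single
#' library per stage the only available t-test is the one-sample two-tailed
#' test of the three non-focal values against the focal value (df = 2). A
#' gene is called up/down in the focal stage only if both filters pass:
#' `|y_focal - mean(y_others)| >= log2(fold_cutoff)` and `p < alpha`.
#'
#' @param table a normalized [count_table] with 4 stages.
#' @param params an [analysis_params].
#' @param focal_stages stages to test (default: all).
#' @param detected optional logical gene x stage matrix (from
#'   [detect_genes()]); genes detected in no stage are skipped.
#' @return A `data.frame` of call records: `gene_id`, `contrast` (the focal
#'   stage), `log2_ratio` (focal minus mean of others), `p_value`,
#'   `direction`, and `degenerate` (TRUE when the non-focal values have zero
#'   spread and the p-value is the 0/1 limit).
#' @export
stage_specific_calls <- function(table, params = analysis_params(),
                                 focal_stages = colnames(table$counts),
                                 detected = NULL) {
  stopifnot(ncol(table$counts) == 4L)
  y <- .log_counts(table, params)
  keep <- if (is.null(detected)) rowSums(table$counts >= params$threshold) > 0
  else rowSums(detected) > 0
  y <- y[keep, , drop = FALSE]
  res <- lapply(focal_stages, function(s) {
    yf <- y[, s]
    others <- y[, setdiff(colnames(y), s), drop = FALSE]
    m <- rowMeans(others)
    v <- rowSums((others - m)^2) / 2           # sample variance of the 3 others
    tstat <- (m - yf) / sqrt(v / 3)
    p <- 2 * pt(-abs(tstat), df = 2)
    degen <- v == 0
    p[degen] <- ifelse(yf[degen] == m[degen], 1, 0)
    ratio <- yf - m
    data.frame(gene_id = rownames(y), contrast = s, log2_ratio = ratio,
               p_value = p,
               direction = .call_direction(ratio, p, params),
               degenerate = degen, row.names = NULL,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Settlement-specific differential-expression test
#'
#' Contrasts the two pelagic larval stages against the two benthic
#' post-settlement stages with a pooled-variance two-sample t-test (2 vs 2,
#' df = 2) on `y = log2(count + pseudocount)`. `log2_ratio` is the benthic
#' mean minus the pelagic mean, so `direction = "up"` means upregulated
#' after settlement.
#'
#' @inheritParams stage_specific_calls
#' @param pelagic,benthic the stage labels of the two groups.
#' @return A `data.frame` of call records with `contrast = "settlement"`.
#' @export
settlement_calls <- function(table, params = analysis_params(),
                             pelagic = c("PRE", "COMP"),
                             benthic = c("POST", "ADULT"),
                             detected = NULL) {
  y <- .log_counts(table, params)
  keep <- if (is.null(detected)) rowSums(table$counts >= params$threshold) > 0
  else rowSums(detected) > 0
  y <- y[keep, , drop = FALSE]
  y1 <- y[, pelagic, drop = FALSE]; y2 <- y[, benthic, drop = FALSE]
  m1 <- rowMeans(y1); m2 <- rowMeans(y2)
  sp2 <- (rowSums((y1 - m1)^2) + rowSums((y2 - m2)^2)) / 2   # pooled, df = 2
  tstat <- (m2 - m1) / sqrt(sp2 * (1 / 2 + 1 / 2))
  p <- 2 * pt(-abs(tstat), df = 2)
  degen <- sp2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  ratio <- m2 - m1
  data.frame(gene_id = rownames(y), contrast = "settlement",
             log2_ratio = ratio, p_value = p,
             direction = .call_direction(ratio, p, params),
             degenerate = degen, row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify expression trajectories at stage transitions
#'
#' For each successive stage pair, a gene is up- or downregulated when its
#' fold change (counts floored at 1, so a 64 -> 256 step is exactly 4-fold)
#' reaches the cutoff *and* the count difference exceeds the sampling error
#' between the stages, instantiated conservatively as `k * sqrt(max(n1, n2))`.
#' Genes below the detection threshold in both stages of a pair are excluded
#' (no record).
#'
#' @inheritParams stage_specific_calls
#' @param transitions list of 2-vectors of stage labels; defaults to the
#'   three successive pairs of the table's column order.
#' @return A `data.frame`: `gene_id`, `contrast` (e.g. `"PRE->COMP"`),
#'   `log2_ratio` (second over first stage, floored counts), `direction`,
#'   and `passed_error_gate`.
#' @export
transition_calls <- function(table, params = analysis_params(),
                             transitions = NULL, detected = NULL) {
  stages <- colnames(table$counts)
  if (is.null(transitions))
    transitions <- lapply(seq_len(length(stages) - 1),
                          function(i) stages[c(i, i + 1)])
  if (is.null(detected)) detected <- table$counts >= params$threshold
  res <- lapply(transitions, function(pr) {
    n1 <- table$counts[, pr[1]]; n2 <- table$counts[, pr[2]]
    keep <- detected[, pr[1]] | detected[, pr[2]]
    if (!any(keep))
      return(data.frame(gene_id = character(0), contrast = character(0),
                        log2_ratio = numeric(0), direction = character(0),
                        passed_error_gate = logical(0),
                        stringsAsFactors = FALSE))
    n1 <- n1[keep]; n2 <- n2[keep]
    gate <- abs(n2 - n1) > params$k * sqrt(pmax(n1, n2))
    ratio <- pmax(n2, 1) / pmax(n1, 1)
    dir <- ifelse(gate & ratio >= params$fold_cutoff, "up",
                  ifelse(gate & 1 / ratio >= params$fold_cutoff, "down",
                         "unchanged"))
    data.frame(gene_id = rownames(table$counts)[keep],
               contrast = paste0(pr[1], "->", pr[2]),
               log2_ratio = log2(ratio), direction = dir,
               passed_error_gate = gate, row.names = NULL,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Extreme-upregulation statistic
#'
#' The maximum, over stages, of the gene's log2 count in one stage minus the
#' average of its log2 counts in the other three stages (the "maximum
#' upregulation" statistic). Genes whose statistic reaches `extreme_log2`
#' (100-fold by default) are flagged as extreme.
#'
#' @inheritParams stage_specific_calls
#' @return A `data.frame`: `gene_id`, `focal_stage` (argmax stage),
#'   `max_upregulation` (log2), `is_extreme`.
#' @export
extreme_upregulation <- function(table, params = analysis_params()) {
  y <- .log_counts(table, params)
  k <- ncol(y)
  # y_s - mean(others) = (k*y_s - sum(y)) / (k-1), per stage
  dev <- (k * y - rowSums(y)) / (k - 1)
  j <- max.col(dev, ties.method = "first")
  stat <- dev[cbind(seq_len(nrow(y)), j)]
  data.frame(gene_id = rownames(y), focal_stage = colnames(y)[j],
             max_upregulation = stat,
             is_extreme = stat >= params$extreme_log2,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Relative expression matrix
#'
#' Per gene, expression on `y = log2(count + pseudocount)` rescaled to [0, 1]
#' across stages (`(y - min) / (max - min)`); genes with constant counts map
#' to 0.5 everywhere.
#'
#' @inheritParams stage_specific_calls
#' @param genes optional subset of gene ids.
#' @return Numeric gene x stage matrix with values in [0, 1].
#' @export
relative_expression <- function(table, params = analysis_params(),
                                genes = NULL) {
  y <- .log_counts(table, params)
  if (!is.null(genes)) y <- y[genes, , drop = FALSE]
  lo <- apply(y, 1, min); hi <- apply(y, 1, max)
  rng <- hi - lo
  out <- (y - lo) / ifelse(rng == 0, 1, rng)
  out[rng == 0, ] <- 0.5
  out
}
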