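#' Transfer annotations from best BLAST-style hits
#'
#' Hits above the e-value cutoff (1e-4 by default) are discarded; each gene
#' then inherits the vocabulary terms of its single best surviving hit
#' (lowest e-value, ties broken toward the lexicographically smaller subject
#' id). Genes with no surviving hit are unannotated and get empty term sets.
#'
#' @param annotation `data.frame` with columns `gene_id`, `subject_id`,
#'   `evalue` (see [read_annotation_table()]).
#' @param subject_terms named list: subject id -> character vector of terms.
#' @param evalue_cutoff inclusive e-value cutoff (default 1e-4).
#' @return A list with `terms` (named list gene -> terms), `is_annotated`
#'   (named logical over genes appearing in `annotation`), and `best_hit`
#'   (`data.frame` of the winning hit per annotated gene).
#' @export
transfer_annotations <- function(annotation, subject_terms,
                                 evalue_cutoff = 1e-4) {
  if (any(annotation$evalue < 0)) stop("negative e-value")
  genes <- unique(annotation$gene_id)
  surv <- annotation[annotation$evalue <= evalue_cutoff, , drop = FALSE]
  surv <- surv[order(surv$gene_id, surv$evalue, surv$subject_id), ]
  best <- surv[!duplicated(surv$gene_id), , drop = FALSE]
  terms <- setNames(rep(list(character(0)), length(genes)), genes)
  terms[best$gene_id] <- lapply(best$subject_id, function(s)
    subject_terms[[s]] %||% character(0))
  list(terms = terms,
       is_annotated = setNames(genes %in% best$gene_id, genes),
       best_hit = best)
}

#' Resampling-based term enrichment
#'
#' For each term overlapping the gene set, the observed overlap is compared
#' with its distribution over `R` random gene sets of the same size drawn
#' without replacement from the universe of detected (annotated) genes. The
#' p-value uses the add-one estimator `(b + 1) / (R + 1)`, where `b` counts
#' resamples reaching the observed overlap, so p is never exactly zero.
#' Benjamini-Hochberg adjustment is applied across all tested terms.
#'
#' @param gene_set character vector of gene ids (subset of `universe`).
#' @param gene_terms named list: gene id -> character vector of terms.
#' @param universe character vector: the detected annotated genes that form
#'   the sampling frame.
#' @param R resampling iterations (>= 1000; default 10000).
#' @param seed integer seed (mandatory: no implicit randomness).
#' @return A `data.frame`, one row per tested term: `term`, `universe_size`,
#'   `set_size`, `term_size`, `overlap`, `p_raw`, `p_adj`, sorted by `p_raw`.
#' @export
resampling_enrichment <- function(gene_set, gene_terms, universe,
                                  R = 10000, seed) {
  if (missing(seed)) stop("seed is required")
  if (R < 1000) stop("R must be >= 1000")
  if (!all(gene_set %in% universe))
    stop("gene_set must be a subset of the universe")
  if (length(gene_set) == 0L)
    return(data.frame(term = character(0), universe_size = integer(0),
                      set_size = integer(0), term_size = integer(0),
                      overlap = integer(0), p_raw = numeric(0),
                      p_adj = numeric(0)))
  set.seed(seed)
  term_genes <- .invert_term_map(gene_terms, universe)
  obs <- vapply(term_genes, function(g) sum(gene_set %in% g), integer(1))
  term_genes <- term_genes[obs >= 1L]
  obs <- obs[obs >= 1L]
  if (length(obs) == 0L)
    return(data.frame(term = character(0), universe_size = integer(0),
                      set_size = integer(0), term_size = integer(0),
                      overlap = integer(0), p_raw = numeric(0),
                      p_adj = numeric(0)))
  m <- length(gene_set)
  U <- length(universe)
  samples <- replicate(R, sample.int(U, m))      # m x R index matrix
  memb <- lapply(term_genes, function(g) universe %in% g)
  p_raw <- vapply(seq_along(obs), function(i) {
    counts <- colSums(matrix(memb[[i]][samples], nrow = m))
    (sum(counts >= obs[i]) + 1) / (R + 1)
  }, numeric(1))
  out <- data.frame(term = names(obs),
                    universe_size = U, set_size = m,
                    term_size = vapply(term_genes, length, integer(1)),
                    overlap = obs, p_raw = p_raw,
                    p_adj = bh_adjust(p_raw),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p_raw, out$term), ]
}

.invert_term_map <- function(gene_terms, universe) {
  gene_terms <- gene_terms[names(gene_terms) %in% universe]
  pairs <- data.frame(
    gene = rep(names(gene_terms), lengths(gene_terms)),
    term = unlist(gene_terms, use.names = FALSE),
    stringsAsFactors = FALSE)
  split(pairs$gene, pairs$term)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' thin, validated front end over [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, elementwise in `[p, 1]`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1 | is.na(p))) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' At-peak matrix (top fraction of the expression range)
#'
#' A gene counts as "at peak" in every stage where its normalized count lies
#' within the upper `1 - q` of its own expression range across development:
#' `count >= min + q * (max - min)` on linear normalized counts (q = 0.75
#' keeps the top 25% of the range). Genes with constant counts are at peak in
#' all stages (the inequality holds vacuously); every gene is at peak in the
#' stage of its maximum.
#'
#' @param table a normalized [count_table].
#' @param detected character vector of detected gene ids (the universe).
#' @param q peak fraction in (0, 1) (default 0.75).
#' @param log_scale compute the range on `log2(count + 1)` instead of linear
#'   counts (default `FALSE`).
#' @return A list of class `at_peak_matrix`: logical `matrix` (genes x
#'   stages), `universe`, `q`.
#' @export
at_peak <- function(table, detected = rownames(table$counts), q = 0.75,
                    log_scale = FALSE) {
  stopifnot(q > 0, q < 1)
  x <- table$counts[detected, , drop = FALSE]
  if (log_scale) x <- log2(x + 1)
  lo <- apply(x, 1, min); hi <- apply(x, 1, max)
  cutoff <- lo + q * (hi - lo)
  structure(list(matrix = x >= cutoff, universe = detected, q = q),
            class = "at_peak_matrix")
}

#' Fisher's exact stage enrichment/depletion for a gene family
#'
#' Builds the 2x2 table (family vs non-family) x (at-peak vs not) at one
#' stage and reports both one-sided hypergeometric tails: the upper tail as
#' the enrichment p and the lower tail as the depletion p.
#'
#' @param family character vector of gene ids (non-empty subset of the
#'   at-peak universe).
#' @param peaks an [at_peak] result.
#' @param stage stage label.
#' @return A `data.frame` with two rows (`direction` = `"enriched"`,
#'   `"depleted"`), carrying the 2x2 margins and raw p-values.
#' @export
stage_family_enrichment <- function(family, peaks, stage) {
  if (length(family) == 0L) stop("family must be non-empty")
  if (!all(family %in% peaks$universe))
    stop("family must be a subset of the at-peak universe")
  atp <- peaks$matrix[, stage]
  a <- sum(atp[family])                       # family & at-peak
  fam_n <- length(family)
  peak_n <- sum(atp)
  total <- length(peaks$universe)
  p_enr <- phyper(a - 1, peak_n, total - peak_n, fam_n, lower.tail = FALSE)
  p_dep <- phyper(a, peak_n, total - peak_n, fam_n, lower.tail = TRUE)
  data.frame(stage = stage, direction = c("enriched", "depleted"),
             universe_size = total, family_size = fam_n,
             at_peak_count = peak_n, overlap = a,
             p_raw = c(p_enr, p_dep), stringsAsFactors = FALSE)
}
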