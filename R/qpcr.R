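#' Relative quantification by the delta-delta-Ct method
#'
#' Per replicate, `dCt = ct_target - ct_reference` (reference = the
#' housekeeping gene, e.g. beta-actin); per stage, the replicate mean and sd;
#' then `ddCt = mean dCt(stage) - mean dCt(reference stage)` and
#' `fold = 2^(-ddCt)`, so the reference stage has fold 1 by construction.
#'
#' @param records qPCR records for one gene (see [read_qpcr_table()]).
#' @param reference_stage the stage folds are expressed relative to.
#' @return A `data.frame`, one row per stage: `gene_id`, `stage`,
#'   `delta_ct_mean`, `delta_ct_sd`, `ddct`, `fold`.
#' @export
delta_delta_ct <- function(records, reference_stage) {
  stopifnot(length(unique(records$gene_id)) == 1L)
  if (!reference_stage %in% records$stage)
    stop("reference stage '", reference_stage, "' missing from records")
  dct <- records$ct_target - records$ct_reference
  stages <- unique(records$stage)
  m <- tapply(dct, factor(records$stage, levels = stages), mean)
  s <- tapply(dct, factor(records$stage, levels = stages), sd)
  ddct <- m - m[[reference_stage]]
  data.frame(gene_id = records$gene_id[1], stage = stages,
             delta_ct_mean = as.numeric(m), delta_ct_sd = as.numeric(s),
             ddct = as.numeric(ddct), fold = 2^(-as.numeric(ddct)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-way ANOVA with Bonferroni's post-test
#'
#' Fixed-effects one-way ANOVA on per-stage replicate dCt groups, followed by
#' all pairwise pooled-variance two-sample t-tests with p-values multiplied
#' by the number of comparisons (capped at 1). Replicates are treated as
#' independent biological pools.
#'
#' @param groups named list of numeric vectors (>= 2 groups, >= 2 replicates
#'   each).
#' @return A list: `F`, `p`, `pairwise` (`data.frame` of group pairs with raw
#'   and Bonferroni-adjusted p), and `degenerate` (TRUE when within-group
#'   variance is zero everywhere, where F is 0 with p 1 for equal means and
#'   p 0 for unequal means).
#' @export
anova_bonferroni <- function(groups) {
  stopifnot(length(groups) >= 2L, all(lengths(groups) >= 2L))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  ssw <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  means <- tapply(x, g, mean)
  degenerate <- ssw == 0
  if (degenerate) {
    equal <- length(unique(round(means, 12))) == 1L
    Fval <- if (equal) 0 else Inf
    p <- if (equal) 1 else 0
  } else {
    fit <- aov(x ~ g)
    tab <- anova(fit)
    Fval <- tab[["F value"]][1]
    p <- tab[["Pr(>F)"]][1]
  }
  pairs <- utils::combn(names(groups), 2)
  n_cmp <- ncol(pairs)
  pw <- apply(pairs, 2, function(pr) {
    a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
    p_raw <- if (sd(a) == 0 && sd(b) == 0) {
      if (mean(a) == mean(b)) 1 else 0
    } else t.test(a, b, var.equal = TRUE)$p.value
    c(p_raw = p_raw, p_adj = min(1, p_raw * n_cmp))
  })
  list(F = Fval, p = p, degenerate = degenerate,
       pairwise = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                             p_raw = pw["p_raw", ], p_adj = pw["p_adj", ],
                             row.names = NULL, stringsAsFactors = FALSE))
}

#' Concordance between sequencing and qPCR expression profiles
#'
#' Two statistics, mirroring how cross-platform agreement is usually
#' reported: (1) per gene, the Pearson correlation between the sequencing
#' log2 fold profile (normalized counts + 1, relative to the reference
#' stage) and the qPCR log2 fold profile from [delta_delta_ct()]; (2) pooled
#' over all gene x stage points, the Spearman rank correlation between the
#' replicate-mean dCt and log2(normalized count + 1) — expected negative,
#' since high expression means fewer cycles.
#'
#' @param table a normalized [count_table].
#' @param qpcr qPCR records (see [read_qpcr_table()]) for genes present in
#'   the table.
#' @param reference_stage the stage folds are expressed relative to.
#' @return A list: `per_gene` (`data.frame` with `gene_id`, `pearson_r`;
#'   `NA` where either profile is constant), `spearman_pooled`, and
#'   `n_points` (gene x stage points entering the pooled statistic).
#' @export
qpcr_concordance <- function(table, qpcr, reference_stage = "PRE") {
  stages <- colnames(table$counts)
  genes <- intersect(unique(qpcr$gene_id), rownames(table$counts))
  if (length(genes) == 0L) stop("no qPCR gene found in the count table")
  y <- log2(table$counts[genes, , drop = FALSE] + 1)
  per_gene <- lapply(genes, function(g) {
    rel <- delta_delta_ct(qpcr[qpcr$gene_id == g, ], reference_stage)
    rel <- rel[match(stages, rel$stage), ]
    seq_fold <- y[g, ] - y[g, reference_stage]
    qp_fold <- log2(rel$fold)
    r <- if (sd(seq_fold) == 0 || sd(qp_fold) == 0) NA_real_
    else cor(seq_fold, qp_fold, method = "pearson")
    data.frame(gene_id = g, pearson_r = r,
               dct = rel$delta_ct_mean, stage = stages,
               log_count = as.numeric(y[g, ]),
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, per_gene)
  pooled <- if (sd(all$dct) == 0 || sd(all$log_count) == 0) NA_real_
  else cor(all$dct, all$log_count, method = "spearman")
  list(per_gene = unique(all[, c("gene_id", "pearson_r")]),
       spearman_pooled = pooled,
       n_points = nrow(all))
}
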