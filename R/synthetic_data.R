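#' Configuration for the synthetic dataset generator
#'
#' Defines the study conditions emulated by [generate_dataset()]: a four-stage
#' developmental count matrix with Poisson (or negative-binomial) technical
#' noise under the k*sqrt(N) envelope, planted expression classes, an
#' annotated/non-annotated gene split, planted enriched vocabulary terms,
#' stranded read placements in exon/intron/intergenic space, and Ct values
#' derived from true expression.
#'
#' Stage sequencing depths default to the study-like relative depths
#' (45/33/20/40 million mapped reads for PRE/COMP/POST/ADULT) scaled down
#' 400x for desk runtime. Read placement fractions default to 80.7% exon,
#' 5.7% intron, 13.6% intergenic; 64% of genes are annotated.
#'
#' @param seed integer seed (mandatory).
#' @param n_genes,n_contigs numbers of genes and contigs.
#' @param stages stage labels, in developmental order.
#' @param depths named per-stage total-mapped-read counts.
#' @param class_fractions named fractions (must sum to 1) of `constant`,
#'   `stage_specific`, `transition` and `silent` genes.
#' @param effect_log2_range range of planted log2 effect sizes.
#' @param baseline_log2_mean,baseline_log2_sd log2-normal baseline abundance
#'   parameters.
#' @param annotated_fraction fraction of genes with a transferable best hit.
#' @param n_terms vocabulary size; `n_planted_terms` of them are enriched in
#'   the stage-specific class at odds `planted_odds`.
#' @param n_planted_terms,planted_odds see above.
#' @param read_fractions named fractions (sum 1) of exon/intron/intergenic
#'   read placements.
#' @param n_reads,read_length simulated read number and length (nt).
#' @param dispersion negative-binomial dispersion; 0 selects Poisson.
#' @param ct_intercept,ct_noise_sd,ct_reference_mean qPCR model: the
#'   replicate dCt is `ct_intercept - log2(true abundance)` plus Gaussian
#'   noise, and the reference-gene Ct sits near `ct_reference_mean` cycles.
#' @param n_qpcr_genes,qpcr_replicates qPCR panel size and replicate pools.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed,
                         n_genes = 2000, n_contigs = 20,
                         stages = STAGES,
                         depths = c(PRE = 112500, COMP = 82500,
                                    POST = 50000, ADULT = 100000),
                         class_fractions = c(constant = 0.5,
                                             stage_specific = 0.15,
                                             transition = 0.15,
                                             silent = 0.2),
                         effect_log2_range = c(2, 7),
                         baseline_log2_mean = 4, baseline_log2_sd = 1.5,
                         annotated_fraction = 0.64,
                         n_terms = 150, n_planted_terms = 3,
                         planted_odds = 25,
                         read_fractions = c(exon = 0.807, intron = 0.057,
                                            intergenic = 0.136),
                         n_reads = 50000, read_length = 50,
                         dispersion = 0,
                         ct_intercept = 20, ct_noise_sd = 0.3,
                         ct_reference_mean = 15,
                         n_qpcr_genes = 10, qpcr_replicates = 3) {
  if (missing(seed)) stop("seed is required")
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("class_fractions must sum to 1")
  if (abs(sum(read_fractions) - 1) > 1e-9)
    stop("read_fractions must sum to 1")
  stopifnot(all(depths > 0), length(stages) == length(depths),
            n_genes > 0, n_contigs > 0, dispersion >= 0)
  names(depths) <- stages
  structure(as.list(environment()), class = "synth_config")
}

# planted gene classes, abundances and relative per-stage proportions
.synth_expression <- function(cfg) {
  n <- cfg$n_genes
  n_class <- round(n * cfg$class_fractions)
  n_class[1] <- n - sum(n_class[-1])
  label <- sample(rep(names(n_class), n_class))
  base <- 2^rnorm(n, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  eff <- runif(n, cfg$effect_log2_range[1], cfg$effect_log2_range[2])
  dir <- sample(c(1, -1), n, replace = TRUE)
  ab <- matrix(base, n, length(cfg$stages),
               dimnames = list(NULL, cfg$stages))
  spec_stage <- rep(NA_character_, n)
  trans_idx <- rep(NA_integer_, n)
  i_spec <- which(label == "stage_specific")
  spec_stage[i_spec] <- sample(cfg$stages, length(i_spec), replace = TRUE)
  for (i in i_spec)
    ab[i, spec_stage[i]] <- base[i] * 2^(dir[i] * eff[i])
  i_tr <- which(label == "transition")
  trans_idx[i_tr] <- sample(seq_len(length(cfg$stages) - 1), length(i_tr),
                            replace = TRUE)
  for (i in i_tr)   # step change at the transition, persisting onward
    ab[i, (trans_idx[i] + 1):length(cfg$stages)] <-
      base[i] * 2^(dir[i] * eff[i])
  ab[label == "silent", ] <- 0
  list(label = label, base = base, effect_log2 = eff, direction = dir,
       spec_stage = spec_stage, transition_index = trans_idx,
       abundance = ab,
       proportion = sweep(ab, 2, colSums(ab), `/`))
}

# gene models laid out sequentially on contigs with intergenic gaps
.synth_models <- function(cfg) {
  n <- cfg$n_genes
  ids <- sprintf("g%05d", seq_len(n))
  contig <- sort(rep(sprintf("ctg%02d", seq_len(cfg$n_contigs)),
                     length.out = n))
  n_ex <- sample(1:6, n, replace = TRUE)
  strand_g <- sample(c("+", "-"), n, replace = TRUE)
  ex_starts <- vector("list", n)
  ex_ends <- vector("list", n)
  span_start <- integer(n); span_end <- integer(n)
  pos <- setNames(rep(1L, cfg$n_contigs), unique(contig))
  for (i in seq_len(n)) {
    gap <- sample(2000:15000, 1)
    start <- pos[[contig[i]]] + gap
    ex_len <- sample(150:400, n_ex[i], replace = TRUE)
    in_len <- if (n_ex[i] > 1) sample(200:1500, n_ex[i] - 1, replace = TRUE)
    else integer(0)
    s <- start + cumsum(c(0L, head(ex_len, -1) + in_len))
    ex_starts[[i]] <- s
    ex_ends[[i]] <- s + ex_len - 1L
    span_start[i] <- start
    span_end[i] <- max(ex_ends[[i]])
    pos[[contig[i]]] <- span_end[i]
  }
  genes <- GRanges(contig, IRanges(span_start, span_end), strand = strand_g)
  names(genes) <- ids
  ex_flat <- GRanges(rep(contig, n_ex),
                     IRanges(unlist(ex_starts), unlist(ex_ends)),
                     strand = rep(strand_g, n_ex))
  exons <- S4Vectors::split(ex_flat, factor(rep(ids, n_ex), levels = ids))
  gene_models(genes, exons)
}

# stranded reads placed according to the configured fractions, with labels
.synth_reads <- function(cfg, models, expressed) {
  n_cat <- round(cfg$n_reads * cfg$read_fractions)
  n_cat["exon"] <- cfg$n_reads - sum(n_cat[c("intron", "intergenic")])
  L <- cfg$read_length
  ids <- gene_ids(models)
  g <- models$genes

  # place k reads uniformly inside a pool of eligible intervals, weighted by
  # the number of admissible start positions; plain-vector interval lists are
  # used throughout (S4 extraction per gene would dominate the runtime) and
  # one GRanges is assembled at the end
  place_vec <- function(starts, widths, k) {
    w <- widths - L + 1L
    ok <- w > 0L
    starts <- starts[ok]; w <- w[ok]
    j <- sample.int(length(starts), k, replace = TRUE, prob = w)
    starts[j] + floor(runif(k) * w[j])
  }

  # exon reads: gene sampled by mean expression, position inside its exons
  ex_start_l <- as.list(start(models$exons))
  ex_width_l <- as.list(width(models$exons))
  wts <- rowMeans(expressed$abundance)
  gene_pick <- sample.int(length(ids), n_cat["exon"], replace = TRUE,
                          prob = pmax(wts, 1e-9))
  gene_contig <- as.character(seqnames(g))
  picked <- sort(unique(gene_pick))
  k_per <- tabulate(gene_pick, nbins = length(ids))
  ex_start <- unlist(lapply(picked, function(gi)
    place_vec(ex_start_l[[gi]], ex_width_l[[gi]], k_per[gi])))
  ex_lab <- rep(ids[picked], k_per[picked])
  ex_contig <- rep(gene_contig[picked], k_per[picked])

  # intron reads: genes with an intron wide enough for a full read
  introns <- GenomicRanges::psetdiff(g, models$exons)
  in_start_l <- as.list(start(introns))
  in_width_l <- as.list(width(introns))
  has_intron <- vapply(in_width_l, function(w)
    length(w) > 0 && max(w) >= L, logical(1))
  in_lab <- character(0); in_contig <- character(0); in_start <- integer(0)
  cand <- which(has_intron)
  if (length(cand) > 0 && n_cat["intron"] > 0) {
    gene_pick <- sample(cand, n_cat["intron"], replace = TRUE)
    picked <- sort(unique(gene_pick))
    k_per <- tabulate(gene_pick, nbins = length(ids))
    in_start <- unlist(lapply(picked, function(gi)
      place_vec(in_start_l[[gi]], in_width_l[[gi]], k_per[gi])))
    in_lab <- rep(ids[picked], k_per[picked])
    in_contig <- rep(gene_contig[picked], k_per[picked])
  }

  # intergenic reads: uniform in the gaps between gene spans; read strand is
  # the nearer flanking gene's strand with probability 0.55 (sense-biased)
  merged <- reduce(g, ignore.strand = TRUE)
  gap_by_ct <- lapply(split(IRanges::ranges(merged),
                            as.character(seqnames(merged))),
                      IRanges::gaps)
  gaps <- GRanges(rep(names(gap_by_ct), lengths(gap_by_ct)),
                  unlist(IRanges::IRangesList(gap_by_ct), use.names = FALSE))
  gaps <- gaps[width(gaps) >= L + 2]
  gw <- width(gaps) - L + 1L
  gj <- sample.int(length(gaps), n_cat["intergenic"], replace = TRUE,
                   prob = gw)
  ig <- list(contig = as.character(seqnames(gaps))[gj],
             start = start(gaps)[gj] + floor(runif(n_cat["intergenic"]) *
                                               gw[gj]))
  ig_mid <- ig$start + floor((L - 1) / 2)
  bounds <- gene_boundaries(models)
  bounds_by_ct <- split(bounds, bounds$contig)
  neighbor_strand <- vapply(seq_along(ig$start), function(i) {
    b <- bounds_by_ct[[ig$contig[i]]]
    d <- pmin(abs(b$tss - ig_mid[i]), abs(b$tts - ig_mid[i]))
    b$strand[which.min(d)]
  }, character(1))
  sense <- runif(length(ig$start)) < 0.55
  ig_strand <- ifelse(sense, neighbor_strand,
                      ifelse(neighbor_strand == "+", "-", "+"))

  n_ex <- length(ex_start); n_in <- length(in_start); n_ig <- length(ig$start)
  contig <- c(ex_contig, in_contig, ig$contig)
  starts <- c(ex_start, in_start, ig$start)
  strands <- c(sample(c("+", "-"), n_ex + n_in, replace = TRUE), ig_strand)
  reads <- GRanges(contig, IRanges(starts, starts + L - 1L), strand = strands)
  names(reads) <- sprintf("r%06d", seq_along(reads))
  reads$name <- names(reads)
  reads$score <- 0L
  truth <- data.frame(read_id = names(reads),
                      category = c(rep("exon", n_ex), rep("intron", n_in),
                                   rep("intergenic", n_ig)),
                      gene_id = c(ex_lab, in_lab, rep(NA_character_, n_ig)),
                      stringsAsFactors = FALSE)
  list(reads = reads, labels = truth)
}

# annotation transfer inputs with planted term enrichment
.synth_annotation <- function(cfg, expressed) {
  n <- cfg$n_genes
  ids <- sprintf("g%05d", seq_len(n))
  annotated <- sort(sample.int(n, round(cfg$annotated_fraction * n)))
  subj <- sprintf("sp%05d", seq_len(n))   # one potential subject per gene
  rows <- data.frame(gene_id = ids[annotated],
                     subject_id = subj[annotated],
                     evalue = 10^-runif(length(annotated), 5, 50),
                     stringsAsFactors = FALSE)
  # a worse secondary hit for some genes (exercises best-hit selection)
  sec <- annotated[runif(length(annotated)) < 0.3]
  rows <- rbind(rows, data.frame(
    gene_id = ids[sec], subject_id = sprintf("sp%05dB", sec),
    evalue = 10^-runif(length(sec), 4.2, 4.9), stringsAsFactors = FALSE))
  # sub-cutoff hits for a slice of the unannotated genes
  un <- setdiff(seq_len(n), annotated)
  weak <- un[runif(length(un)) < 0.3]
  rows <- rbind(rows, data.frame(
    gene_id = ids[weak], subject_id = sprintf("sp%05dW", weak),
    evalue = 10^-runif(length(weak), 1, 3.5), stringsAsFactors = FALSE))
  rows <- rows[order(rows$gene_id, rows$evalue), ]

  terms <- sprintf("TERM%04d", seq_len(cfg$n_terms))
  planted <- terms[seq_len(cfg$n_planted_terms)]
  q0 <- 3 / cfg$n_terms                  # ~3 background terms per subject
  in_class <- expressed$label == "stage_specific"
  subject_terms <- setNames(vector("list", n), subj)
  for (i in seq_len(n)) {
    keep <- runif(cfg$n_terms) < q0
    pl <- terms %in% planted &
      runif(cfg$n_terms) < q0 * (if (in_class[i]) cfg$planted_odds else 1)
    subject_terms[[i]] <- terms[keep | pl]
  }
  list(annotation = rows, subject_terms = subject_terms,
       annotated_genes = ids[annotated], planted_terms = planted)
}

.synth_qpcr <- function(cfg, expressed) {
  ids <- sprintf("g%05d", seq_len(cfg$n_genes))
  ok <- which(apply(expressed$abundance, 1, min) > 0)
  # a validation panel targets dynamically expressed genes first, the way a
  # qPCR follow-up would, topped up with constitutive controls
  dyn <- ok[expressed$label[ok] %in% c("stage_specific", "transition")]
  flat <- setdiff(ok, dyn)
  n_dyn <- min(length(dyn), ceiling(0.8 * cfg$n_qpcr_genes))
  panel <- sort(c(sample(dyn, n_dyn),
                  sample(flat, min(length(flat),
                                   cfg$n_qpcr_genes - n_dyn))))
  recs <- list(); folds <- list()
  for (gi in panel) {
    a <- expressed$abundance[gi, ]
    dct_true <- cfg$ct_intercept - log2(a)
    for (s in cfg$stages) {
      ct_ref <- cfg$ct_reference_mean + rnorm(cfg$qpcr_replicates, 0, 0.1)
      dct <- dct_true[[s]] + rnorm(cfg$qpcr_replicates, 0, cfg$ct_noise_sd)
      recs[[length(recs) + 1]] <- data.frame(
        gene_id = ids[gi], stage = s, replicate = seq_len(cfg$qpcr_replicates),
        ct_target = dct + ct_ref, ct_reference = ct_ref,
        stringsAsFactors = FALSE)
    }
    folds[[ids[gi]]] <- setNames(as.numeric(a / a[[cfg$stages[1]]]),
                                 cfg$stages)
  }
  list(records = do.call(rbind, recs), true_folds = folds)
}

#' Generate a complete synthetic dataset with planted truth
#'
#' Draws gene models, stranded reads, a raw 4-stage count table
#' (`X(g,s) ~ Poisson(depth_s * p(g,s))`, negative binomial when
#' `dispersion > 0`), best-hit annotation and term tables with planted
#' enrichment, and a qPCR Ct table, all from one seed; identical seeds give
#' identical outputs. When `out_dir` is given, every component is also
#' written in its standard text format (GFF3, BED6, TSV, JSON truth record).
#'
#' @param cfg a [synth_config].
#' @param out_dir optional output directory.
#' @return A list: `models`, `reads`, `counts` (raw [count_table]),
#'   `annotation`, `subject_terms`, `qpcr`, and `truth` (per-gene class
#'   labels, effects and stage assignments; per-read placement labels;
#'   planted terms; true qPCR folds).
#' @export
generate_dataset <- function(cfg, out_dir = NULL) {
  stopifnot(is(cfg, "synth_config"))
  set.seed(cfg$seed)
  expressed <- .synth_expression(cfg)
  models <- .synth_models(cfg)
  rd <- .synth_reads(cfg, models, expressed)
  ann <- .synth_annotation(cfg, expressed)
  qp <- .synth_qpcr(cfg, expressed)
  counts <- matrix(0, cfg$n_genes, length(cfg$stages),
                   dimnames = list(gene_ids(models), cfg$stages))
  noise <- noise_model(k = 5, dispersion = cfg$dispersion)
  for (s in cfg$stages)
    counts[, s] <- .sim_replicate(noise,
                                  cfg$depths[[s]] * expressed$proportion[, s])
  tab <- count_table(counts, cfg$depths, normalized = FALSE)
  ids <- gene_ids(models)
  truth <- list(
    gene = data.frame(gene_id = ids, class = expressed$label,
                      base_abundance = expressed$base,
                      effect_log2 = ifelse(
                        expressed$label %in% c("stage_specific", "transition"),
                        expressed$direction * expressed$effect_log2, 0),
                      spec_stage = expressed$spec_stage,
                      transition_index = expressed$transition_index,
                      stringsAsFactors = FALSE),
    abundance = expressed$abundance,
    read_labels = rd$labels,
    annotated_genes = ann$annotated_genes,
    planted_terms = ann$planted_terms,
    qpcr_true_folds = qp$true_folds)
  out <- list(models = models, reads = rd$reads, counts = tab,
              annotation = ann$annotation, subject_terms = ann$subject_terms,
              qpcr = qp$records, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_gene_models(models, file.path(out_dir, "models.gff3"))
    write_alignments(rd$reads, file.path(out_dir, "reads.bed"))
    write_count_table(tab, file.path(out_dir, "counts.tsv"))
    write.table(ann$annotation, file.path(out_dir, "annotation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_term_map(ann$subject_terms, file.path(out_dir, "subject_terms.tsv"))
    write.table(qp$records, file.path(out_dir, "qpcr.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    tr <- truth
    tr$abundance <- as.data.frame(tr$abundance)
    jsonlite::write_json(tr, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "columns")
  }
  out
}

#' Simulate a pair of technical replicates
#'
#' Two independent draws from the replicate distribution (Poisson, or
#' negative binomial when the model carries dispersion) at identical means —
#' two independently prepared libraries from the same starting RNA sample.
#'
#' @param noise a [noise_model].
#' @param means non-negative expression vector.
#' @param seed optional integer seed.
#' @return A list with numeric vectors `rep1` and `rep2`.
#' @export
generate_technical_replicates <- function(noise, means, seed = NULL) {
  if (any(means < 0)) stop("means must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  list(rep1 = .sim_replicate(noise, means),
       rep2 = .sim_replicate(noise, means))
}
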