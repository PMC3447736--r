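#' Classify mapped reads against gene models
#'
#' Each read is assigned to one of three categories by an overlap-majority
#' rule: `exon` if at least half of the aligned length overlaps some gene's
#' exon union, otherwise `intron` if at least half overlaps some gene span,
#' otherwise `intergenic`. Among competing genes the one with the larger
#' overlap wins (ties toward the lexicographically smaller gene id). Gene
#' assignment ignores read strand; strand matters only for the intergenic
#' orientation call. Intergenic reads are measured from their midpoint to the
#' nearest gene boundary (TSS or TTS) on the same contig, with TSS preferred
#' on exact ties.
#'
#' @param reads `GRanges` of reads (see [read_alignments()]).
#' @param models a [gene_models] object.
#' @return A `data.frame`, one row per read: `read_id`, `category`,
#'   `gene_id` (`NA` for intergenic), and for intergenic reads
#'   `nearest_boundary` (`"TSS"`/`"TTS"`), `distance_bp`, `orientation`
#'   (`"sense"`/`"antisense"`); reads on contigs without any gene have all
#'   three `NA`.
#' @export
classify_reads <- function(reads, models) {
  n <- length(reads)
  out <- data.frame(read_id = if (n) names(reads) else character(0),
                    category = character(n),
                    gene_id = rep(NA_character_, n),
                    nearest_boundary = rep(NA_character_, n),
                    distance_bp = rep(NA_integer_, n),
                    orientation = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)

  best_overlap <- function(targets, target_gene) {
    # reads may sit on contigs absent from the models; that is a valid
    # intergenic outcome, not a warning condition
    hits <- suppressWarnings(findOverlaps(reads, targets,
                                          ignore.strand = TRUE))
    if (length(hits) == 0L)
      return(data.table::data.table(read = integer(0), gene = character(0),
                                    ov = integer(0)))
    ov <- width(suppressWarnings(
      pintersect(reads[queryHits(hits)], targets[subjectHits(hits)],
                 ignore.strand = TRUE)))
    dt <- data.table::data.table(read = queryHits(hits),
                                 gene = target_gene[subjectHits(hits)],
                                 w = ov)
    dt <- dt[, list(ov = sum(w)), by = c("read", "gene")]
    data.table::setorderv(dt, c("read", "ov", "gene"), order = c(1L, -1L, 1L))
    dt[!duplicated(dt$read), ]
  }

  ex <- unlist(models$exons, use.names = FALSE)
  ex_gene <- rep(names(models$exons), lengths(models$exons))
  best_ex <- best_overlap(ex, ex_gene)
  rlen <- width(reads)
  is_exon <- best_ex$read[2L * best_ex$ov >= rlen[best_ex$read]]
  out$category[is_exon] <- "exon"
  out$gene_id[is_exon] <- best_ex$gene[match(is_exon, best_ex$read)]

  rest <- setdiff(seq_len(n), is_exon)
  if (length(rest) > 0L) {
    best_sp <- best_overlap(models$genes, gene_ids(models))
    best_sp <- best_sp[best_sp$read %in% rest, ]
    is_intron <- best_sp$read[2L * best_sp$ov >= rlen[best_sp$read]]
    out$category[is_intron] <- "intron"
    out$gene_id[is_intron] <- best_sp$gene[match(is_intron, best_sp$read)]
    rest <- setdiff(rest, is_intron)
  }
  if (length(rest) > 0L) {
    out$category[rest] <- "intergenic"
    bounds <- gene_boundaries(models)
    mid <- floor((start(reads) + end(reads)) / 2)
    contig <- as.character(seqnames(reads))
    rstrand <- as.character(strand(reads))
    for (ct in unique(contig[rest])) {
      idx <- rest[contig[rest] == ct]
      b <- bounds[bounds$contig == ct, ]
      if (nrow(b) == 0L) next   # no gene on this contig: stays all-NA
      d_tss <- abs(outer(mid[idx], b$tss, "-"))
      d_tts <- abs(outer(mid[idx], b$tts, "-"))
      j_tss <- max.col(-d_tss, ties.method = "first")
      j_tts <- max.col(-d_tts, ties.method = "first")
      dt1 <- d_tss[cbind(seq_along(idx), j_tss)]
      dt2 <- d_tts[cbind(seq_along(idx), j_tts)]
      use_tss <- dt1 <= dt2                    # ties resolved toward TSS
      j <- ifelse(use_tss, j_tss, j_tts)
      out$nearest_boundary[idx] <- ifelse(use_tss, "TSS", "TTS")
      out$distance_bp[idx] <- as.integer(pmin(dt1, dt2))
      out$orientation[idx] <- ifelse(rstrand[idx] == b$strand[j],
                                     "sense", "antisense")
    }
  }
  out
}

#' Count exonic reads per gene
#'
#' @param classes output of [classify_reads()].
#' @param models a [gene_models] object (defines the gene order of the
#'   returned column).
#' @return Named integer vector of exonic read counts, one entry per gene;
#'   its sum never exceeds the number of classified reads.
#' @export
count_exonic_reads <- function(classes, models) {
  ids <- gene_ids(models)
  tab <- table(factor(classes$gene_id[classes$category == "exon"],
                      levels = ids))
  setNames(as.integer(tab), ids)
}

#' Distance/orientation profile of intergenic reads
#'
#' Bins intergenic reads by the distance from their midpoint to the nearest
#' gene boundary, separately for TSS- and TTS-side reads, and reports the
#' fraction within `max_distance` ("proximal") and the fraction oriented on
#' the sense strand of the neighboring gene.
#'
#' @param classes output of [classify_reads()].
#' @param bin_width bin width in bp (default 1000).
#' @param max_distance distance beyond which reads count as distal
#'   (default 10000).
#' @return A list of class `distance_profile` with per-bin counts
#'   (`counts_by_bin_tss`, `counts_by_bin_tts`), `distal_count`,
#'   `no_neighbor_count` (reads on contigs without genes, reported
#'   separately), `proximal_fraction` and `sense_fraction`.
#' @export
intergenic_profile <- function(classes, bin_width = 1000,
                               max_distance = 10000) {
  ig <- classes[classes$category == "intergenic", ]
  n_bins <- as.integer(ceiling(max_distance / bin_width))
  no_neighbor <- sum(is.na(ig$distance_bp))
  ig <- ig[!is.na(ig$distance_bp), ]
  bin <- floor(ig$distance_bp / bin_width)
  prox <- bin < n_bins
  bin_count <- function(side) {
    b <- bin[prox & ig$nearest_boundary == side]
    setNames(as.integer(table(factor(b, levels = 0:(n_bins - 1)))),
             sprintf("[%d,%d)", (0:(n_bins - 1)) * bin_width,
                     (1:n_bins) * bin_width))
  }
  total <- nrow(ig) + no_neighbor
  structure(list(
    bin_width = bin_width, max_distance = max_distance,
    counts_by_bin_tss = bin_count("TSS"),
    counts_by_bin_tts = bin_count("TTS"),
    distal_count = sum(!prox) + no_neighbor,
    no_neighbor_count = no_neighbor,
    proximal_fraction = if (total > 0) sum(prox) / total else NA_real_,
    sense_fraction = if (nrow(ig) > 0)
      mean(ig$orientation == "sense") else NA_real_,
    n_intergenic = total), class = "distance_profile")
}

#' @export
print.distance_profile <- function(x, ...) {
  cat(sprintf(paste0("distance_profile: %d intergenic reads; %.1f%% within ",
                     "%d bp of a gene boundary; %.1f%% sense\n"),
              x$n_intergenic, 100 * x$proximal_fraction, x$max_distance,
              100 * x$sense_fraction))
  invisible(x)
}

#' Export a depth-normalized coverage track
#'
#' Per-base coverage is rescaled by `scale_to / total_mapped` (reads per
#' 10 million mapped by default) and written as bedGraph runs.
#'
#' @param reads `GRanges` of reads.
#' @param total_mapped total mapped reads in the originating library (> 0).
#' @param path output bedGraph path.
#' @param scale_to target library size (default 1e7).
#' @return `path`, invisibly.
#' @export
export_coverage_track <- function(reads, total_mapped, path,
                                  scale_to = 1e7) {
  if (!is.numeric(total_mapped) || total_mapped <= 0)
    stop("total_mapped must be > 0")
  if (length(reads) == 0L) {
    gr <- GRanges()
    gr$score <- numeric(0)
  } else {
    cov <- coverage(reads) * (scale_to / total_mapped)
    gr <- as(cov, "GRanges")
    gr <- gr[gr$score > 0]
  }
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
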