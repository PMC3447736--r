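#' Gene model container
#'
#' A `gene_models` object bundles the per-locus span of every gene with its
#' merged exon union, annotation status and transferred vocabulary terms.
#' Coordinates are held as [GenomicRanges::GRanges] (1-based, closed);
#' conversion from the 0-based GFF3/BED file conventions happens only at the
#' I/O boundary, inside rtracklayer.
#'
#' @param genes `GRanges` of gene spans (TSS..TTS), named by gene id, with
#'   mandatory `+`/`-` strand.
#' @param exons `GRangesList` parallel to `genes`: the merged (non-overlapping)
#'   exon union of each gene, on the gene's contig and strand.
#' @param is_annotated logical vector, one per gene.
#' @param terms list of character vectors, one per gene (possibly empty).
#' @param best_hit optional `data.frame` with columns `gene_id`, `subject_id`,
#'   `evalue` (one row per annotated gene).
#' @return An object of class `gene_models`.
#' @export
gene_models <- function(genes, exons,
                        is_annotated = rep(FALSE, length(genes)),
                        terms = rep(list(character(0)), length(genes)),
                        best_hit = NULL) {
  stopifnot(is(genes, "GRanges"), is(exons, "GRangesList"),
            length(genes) == length(exons))
  ids <- names(genes)
  if (length(genes) > 0L && (is.null(ids) || anyDuplicated(ids)))
    stop("gene spans must carry unique gene ids as names")
  if (any(as.character(strand(genes)) == "*"))
    stop("unknown strand symbol: gene strand must be '+' or '-'")
  n_ex <- lengths(exons)
  if (any(n_ex == 0L))
    stop("gene ", ids[which(n_ex == 0L)[1]], " has no exons")
  ex_flat <- unlist(exons, use.names = FALSE)
  gi <- rep(seq_along(genes), n_ex)
  bad <- as.character(seqnames(ex_flat)) !=
    as.character(seqnames(genes))[gi] |
    as.character(strand(ex_flat)) != as.character(strand(genes))[gi]
  if (any(bad))
    stop("exons of gene ", ids[gi[which(bad)[1]]],
         " disagree with gene contig/strand")
  outside <- start(ex_flat) < start(genes)[gi] |
    end(ex_flat) > end(genes)[gi]
  if (any(outside))
    stop("exon outside gene span for gene ", ids[gi[which(outside)[1]]])
  names(exons) <- ids
  structure(list(genes = genes, exons = exons,
                 is_annotated = setNames(as.logical(is_annotated), ids),
                 terms = setNames(terms, ids),
                 best_hit = best_hit),
            class = "gene_models")
}

#' @export
length.gene_models <- function(x) length(x$genes)

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes on %d contigs (%d annotated)\n",
              length(x$genes),
              length(unique(as.character(seqnames(x$genes)))),
              sum(x$is_annotated)))
  invisible(x)
}

#' Gene identifiers of a model set
#' @param models a [gene_models] object.
#' @return Character vector of gene ids, in model order.
#' @export
gene_ids <- function(models) names(models$genes)

# Line-level validation of a GFF3 file so that malformed input is reported
# with its line number before the parser sees it.
.validate_gff3_lines <- function(path) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      stop("malformed GFF3 line ", i, ": expected 9 tab-separated fields, got ",
           length(f))
    if (is.na(suppressWarnings(as.integer(f[4]))) ||
        is.na(suppressWarnings(as.integer(f[5]))))
      stop("malformed GFF3 line ", i, ": non-integer coordinates")
    if (as.integer(f[4]) > as.integer(f[5]))
      stop("malformed GFF3 line ", i, ": start > end")
    if (!f[7] %in% c("+", "-", ".", "?"))
      stop("malformed GFF3 line ", i, ": unknown strand symbol '", f[7], "'")
  }
  invisible(TRUE)
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene` and `exon` features (exons linked to their gene through the
#' `Parent` attribute), merges each gene's exon intervals into a
#' non-overlapping union, and returns models sorted by contig and start.
#' GFF3's 1-based inclusive coordinates are converted by rtracklayer at import.
#'
#' @param path path to a GFF3 file.
#' @return A [gene_models] object.
#' @export
read_gene_models <- function(path) {
  .validate_gff3_lines(path)
  gff <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gff$type)
  gr_gene <- gff[type == "gene"]
  gr_exon <- gff[type == "exon"]
  if (length(gr_gene) == 0L) stop("no gene features found in ", path)
  ids <- as.character(gr_gene$ID)
  if (any(is.na(ids)) || any(ids == ""))
    stop("gene feature without an ID attribute")
  if (anyDuplicated(ids)) stop("duplicate gene ID in ", path)
  if (any(as.character(strand(gr_gene)) == "*"))
    stop("unknown strand symbol: gene features must be stranded ('+'/'-')")
  names(gr_gene) <- ids
  parent <- as.character(sapply(gr_exon$Parent, `[`, 1L))
  if (any(!parent %in% ids))
    stop("exon with Parent not matching any gene: ",
         paste(unique(parent[!parent %in% ids]), collapse = ", "))
  ex_by_gene <- split(gr_exon, factor(parent, levels = ids))
  exons <- GRangesList(lapply(seq_along(ids), function(i) {
    ex <- ex_by_gene[[i]]
    if (length(ex) == 0L) {        # a gene with no exon records is its own exon
      ex <- gr_gene[i]
    }
    ex <- reduce(ex)
    strand(ex) <- strand(gr_gene[i])
    mcols(ex) <- NULL
    names(ex) <- NULL
    ex
  }))
  mcols(gr_gene) <- NULL
  ord <- order(as.character(seqnames(gr_gene)), start(gr_gene))
  gene_models(gr_gene[ord], exons[ord])
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gene_models()]; gene and exon features are emitted with
#' `ID`/`Parent` attributes so that a read/write round trip reproduces the
#' original 1-based coordinates field for field.
#'
#' @param models a [gene_models] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  g <- models$genes
  g$type <- "gene"
  g$ID <- names(g)
  ex <- unlist(models$exons)
  ex$type <- "exon"
  ex$Parent <- names(ex)
  names(ex) <- NULL
  all <- c(g, ex)
  names(all) <- NULL
  all$source <- "devexpr"
  rtracklayer::export(GenomicRanges::sort(all, ignore.strand = TRUE), path,
                      format = "gff3")
  invisible(path)
}

#' Collapse overlapping transcripts to one model per locus
#'
#' Among transcripts whose spans overlap on the same contig and strand
#' (clustered transitively: connected components of pairwise span overlap),
#' only the transcript with the greatest span length is retained. Ties are
#' broken toward the lexicographically smaller gene id for determinism.
#'
#' @param models a [gene_models] object.
#' @return A [gene_models] object with at most one transcript per overlap
#'   cluster.
#' @export
dedup_transcripts <- function(models) {
  g <- models$genes
  if (length(g) == 0L) return(models)
  # reduce() merges transitively-overlapping spans, so each reduced range is
  # one connected component of the pairwise-overlap graph (per strand)
  comp <- reduce(g, ignore.strand = FALSE)
  hits <- findOverlaps(g, comp, ignore.strand = FALSE)
  cluster <- integer(length(g))
  cluster[queryHits(hits)] <- subjectHits(hits)
  keep <- vapply(split(seq_along(g), cluster), function(idx) {
    w <- width(g[idx])
    cand <- idx[w == max(w)]
    cand[order(names(g)[cand])][1L]
  }, integer(1))
  keep <- sort(unname(keep))
  gene_models(g[keep], models$exons[keep],
              models$is_annotated[keep], models$terms[keep],
              models$best_hit)
}

#' Gene boundary positions (TSS/TTS)
#'
#' @param models a [gene_models] object.
#' @return A `data.frame` with one row per gene: contig, strand, and the
#'   genomic positions of the transcription start and termination sites
#'   (TSS = span start on `+`, span end on `-`).
#' @export
gene_boundaries <- function(models) {
  g <- models$genes
  plus <- as.character(strand(g)) == "+"
  data.frame(gene_id = names(g),
             contig = as.character(seqnames(g)),
             strand = as.character(strand(g)),
             tss = ifelse(plus, start(g), end(g)),
             tts = ifelse(plus, end(g), start(g)),
             stringsAsFactors = FALSE)
}
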