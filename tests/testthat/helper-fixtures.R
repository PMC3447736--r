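# Fixture builders shared across test files. Everything is generated in code;
# nothing is read from checked-in data files.

# write a GFF3 file from a compact spec: list of
# list(id, contig, start, end, strand, exons = list(c(start, end), ...))
# (1-based inclusive coordinates, as in the file format)
write_toy_gff3 <- function(genes, path = tempfile(fileext = ".gff3")) {
  lines <- "##gff-version 3"
  for (g in genes) {
    lines <- c(lines, paste(g$contig, "test", "gene", g$start, g$end, ".",
                            g$strand, ".", paste0("ID=", g$id), sep = "\t"))
    for (e in g$exons)
      lines <- c(lines, paste(g$contig, "test", "exon", e[1], e[2], ".",
                              g$strand, ".", paste0("Parent=", g$id),
                              sep = "\t"))
  }
  writeLines(lines, path)
  path
}

write_toy_bed <- function(rows, path = tempfile(fileext = ".bed")) {
  writeLines(vapply(rows, paste, "", collapse = "\t"), path)
  path
}

# a count_table built directly from a named matrix spec
toy_counts <- function(m, total_mapped = NULL, normalized = FALSE) {
  if (is.null(total_mapped))
    total_mapped <- setNames(rep(1e6, ncol(m)), colnames(m))
  count_table(m, total_mapped, normalized = normalized)
}

# single-gene four-stage normalized table from log2(count+1) values
table_from_y <- function(y, stages = c("PRE", "COMP", "POST", "ADULT"),
                         gene = "g1") {
  m <- matrix(2^y - 1, nrow = 1, dimnames = list(gene, stages))
  toy_counts(m, normalized = TRUE)
}

# two-gene models on one contig for overlap-arithmetic tests:
# gene A exon [101,200], gene B exon [181,260] (1-based, + strand)
two_gene_models <- function() {
  gr <- GenomicRanges::GRanges(c("c1", "c1"),
                               IRanges::IRanges(c(101, 181), c(200, 260)),
                               strand = "+")
  names(gr) <- c("gA", "gB")
  ex <- S4Vectors::split(gr, names(gr))
  gene_models(gr, ex)
}

make_read <- function(contig, start, end, strand = "+", id = "r1") {
  r <- GenomicRanges::GRanges(contig, IRanges::IRanges(start, end),
                              strand = strand)
  names(r) <- id
  r
}
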