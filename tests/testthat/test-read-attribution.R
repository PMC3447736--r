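test_that("reads map to exon, intron or intergenic by the 50% rule", {
  p <- write_toy_gff3(list(
    list(id = "g1", contig = "c1", start = 101, end = 800, strand = "+",
         exons = list(c(101, 300), c(601, 800)))))
  m <- read_gene_models(p)
  # fully inside an exon
  cl <- classify_reads(make_read("c1", 150, 199), m)
  expect_equal(cl$category, "exon")
  expect_equal(cl$gene_id, "g1")
  # fully inside the intron between the two exons
  cl <- classify_reads(make_read("c1", 400, 449), m)
  expect_equal(cl$category, "intron")
  expect_equal(cl$gene_id, "g1")
  # far outside the gene
  cl <- classify_reads(make_read("c1", 5000, 5049), m)
  expect_equal(cl$category, "intergenic")
  expect_true(is.na(cl$gene_id))
  # read on a contig with no genes: intergenic with no neighbor
  cl <- classify_reads(make_read("c9", 100, 149), m)
  expect_equal(cl$category, "intergenic")
  expect_true(is.na(cl$nearest_boundary))
})

test_that("competing genes resolve by maximal overlap (oracle over all placements)", {
  # gA exon [101,200], gB exon [181,260]; slide a 50-base read across and
  # check every placement against direct overlap arithmetic
  m <- two_gene_models()
  starts <- 60:280
  reads <- GenomicRanges::GRanges("c1", IRanges::IRanges(starts, starts + 49))
  names(reads) <- sprintf("r%03d", seq_along(starts))
  cl <- classify_reads(reads, m)
  ov <- function(s, e, a, b) max(0, min(e, b) - max(s, a) + 1)
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- s + 49
    oa <- ov(s, e, 101, 200); ob <- ov(s, e, 181, 260)
    expected <- if (max(oa, ob) * 2 >= 50)
      c("exon", if (oa > ob) "gA" else if (ob > oa) "gB" else "gA")
    else c("intergenic", NA)
    expect_equal(cl$category[i], expected[1], info = paste("start", s))
    if (expected[1] == "exon")
      expect_equal(cl$gene_id[i], expected[2], info = paste("start", s))
  }
  # the documented example on adjacent exons: a 50-base read overlapping
  # gene A by 30 bases and gene B by 20 -> exon of gene A
  gr <- GenomicRanges::GRanges(c("c1", "c1"),
                               IRanges::IRanges(c(101, 201), c(200, 260)),
                               strand = "+")
  names(gr) <- c("gA", "gB")
  madj <- gene_models(gr, S4Vectors::split(gr, names(gr)))
  cl1 <- classify_reads(make_read("c1", 171, 220), madj)
  expect_equal(unname(c(cl1$category, cl1$gene_id)), c("exon", "gA"))
})

test_that("exonic read counting equals per-gene label tallies", {
  set.seed(21)
  cfg <- synth_config(seed = 21, n_genes = 150, n_reads = 3000, n_contigs = 4)
  d <- generate_dataset(cfg)
  cl <- classify_reads(d$reads, d$models)
  counts <- count_exonic_reads(cl, d$models)
  lab <- d$truth$read_labels
  tal <- table(factor(lab$gene_id[lab$category == "exon"],
                      levels = gene_ids(d$models)))
  expect_equal(unname(counts), as.integer(tal))
  expect_lte(sum(counts), nrow(cl))
  # category totals partition the classified reads
  expect_equal(sum(table(cl$category)), length(d$reads))
  # empty read set gives an all-zero column
  empty <- classify_reads(GenomicRanges::GRanges(), d$models)
  expect_true(all(count_exonic_reads(empty, d$models) == 0L))
})

test_that("intergenic reads are profiled by boundary distance and orientation", {
  # one + strand gene at [2001,4000]: TSS at 2001, TTS at 4000
  p <- write_toy_gff3(list(
    list(id = "g1", contig = "c1", start = 2001, end = 4000, strand = "+",
         exons = list(c(2001, 4000)))))
  m <- read_gene_models(p)
  # read midpoint 500 bp 5' of the TSS, same strand -> TSS side, bin 0, sense
  r <- make_read("c1", 1477, 1526, "+")      # midpoint 1501
  cl <- classify_reads(r, m)
  expect_equal(cl$nearest_boundary, "TSS")
  expect_equal(cl$distance_bp, 500L)
  expect_equal(cl$orientation, "sense")
  prof <- intergenic_profile(cl)
  expect_equal(unname(prof$counts_by_bin_tss[1]), 1L)
  expect_equal(prof$sense_fraction, 1)
  # a read 12 kb away is distal under the 10-kb default
  r2 <- make_read("c1", 15976, 16025, "-")   # midpoint 16000, 12 kb from TTS
  prof2 <- intergenic_profile(classify_reads(r2, m))
  expect_equal(prof2$distal_count, 1L)
  expect_equal(prof2$proximal_fraction, 0)
  # antisense orientation
  cl3 <- classify_reads(make_read("c1", 1477, 1526, "-"), m)
  expect_equal(cl3$orientation, "antisense")
})

test_that("equidistant TSS/TTS neighbors resolve toward the TSS", {
  # gene A (+) TTS at 1000; gene B (+) TSS at 3000; midpoint 2000 is 1000
  # from both boundaries
  p <- write_toy_gff3(list(
    list(id = "gA", contig = "c1", start = 1, end = 1000, strand = "+",
         exons = list(c(1, 1000))),
    list(id = "gB", contig = "c1", start = 3000, end = 4000, strand = "+",
         exons = list(c(3000, 4000)))))
  m <- read_gene_models(p)
  cl <- classify_reads(make_read("c1", 1976, 2025, "+"), m)  # midpoint 2000
  expect_equal(cl$category, "intergenic")
  expect_equal(cl$nearest_boundary, "TSS")
  expect_equal(cl$distance_bp, 1000L)
})

test_that("distance profile is invariant to read order and partitions reads", {
  set.seed(8)
  cfg <- synth_config(seed = 8, n_genes = 100, n_reads = 2000, n_contigs = 3)
  d <- generate_dataset(cfg)
  cl <- classify_reads(d$reads, d$models)
  prof <- intergenic_profile(cl)
  n_ig <- sum(cl$category == "intergenic")
  expect_equal(sum(prof$counts_by_bin_tss) + sum(prof$counts_by_bin_tts) +
                 prof$distal_count, n_ig)
  perm <- cl[sample(nrow(cl)), ]
  prof2 <- intergenic_profile(perm)
  expect_equal(prof2$counts_by_bin_tss, prof$counts_by_bin_tss)
  expect_equal(prof2$counts_by_bin_tts, prof$counts_by_bin_tts)
  expect_equal(prof2$sense_fraction, prof$sense_fraction)
})

test_that("coverage tracks are depth-normalized bedGraph runs", {
  # 5 stacked reads, library of 5e6, scaled to 1e7 -> coverage value 10
  r <- GenomicRanges::GRanges("c1", IRanges::IRanges(rep(101, 5), rep(150, 5)))
  names(r) <- paste0("r", 1:5)
  p <- tempfile(fileext = ".bedGraph")
  export_coverage_track(r, 5e6, p)
  tr <- rtracklayer::import(p, format = "bedGraph")
  expect_equal(tr$score, 10)
  expect_equal(GenomicRanges::start(tr), 101)
  expect_equal(GenomicRanges::end(tr), 150)
  # empty read set -> empty track
  p0 <- tempfile(fileext = ".bedGraph")
  export_coverage_track(GenomicRanges::GRanges(), 1e6, p0)
  expect_equal(length(rtracklayer::import(p0, format = "bedGraph")), 0L)
  expect_error(export_coverage_track(r, 0, tempfile()), "total_mapped")
})

test_that("staggered coverage matches a brute-force per-base pileup", {
  r <- GenomicRanges::GRanges("c1",
                              IRanges::IRanges(c(101, 121, 141),
                                               c(150, 170, 190)))
  names(r) <- paste0("r", 1:3)
  p <- tempfile(fileext = ".bedGraph")
  export_coverage_track(r, 1e7, p)                  # scale factor 1
  tr <- rtracklayer::import(p, format = "bedGraph")
  pile <- vapply(1:250, function(pos)
    sum(pos >= GenomicRanges::start(r) & pos <= GenomicRanges::end(r)),
    numeric(1))
  for (i in seq_along(tr)) {
    run <- GenomicRanges::start(tr)[i]:GenomicRanges::end(tr)[i]
    expect_true(all(pile[run] == tr$score[i]))
  }
  expect_equal(sum(tr$score * GenomicRanges::width(tr)), sum(pile))
})
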