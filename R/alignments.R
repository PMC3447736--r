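#' Read uniquely-mapped reads from a BED6 file
#'
#' Reads are single-end, single-block alignments: exactly six BED columns
#' (contig, start, end, read id, score, strand). Multi-block BED12 records
#' are rejected rather than silently truncated. BED's 0-based half-open
#' coordinates are converted by rtracklayer at import.
#'
#' @param path path to a BED6 file.
#' @return A `GRanges`, one range per read, named by read id.
#' @export
read_alignments <- function(path) {
  lines <- readLines(path)
  body <- which(!(lines == "" | startsWith(lines, "#") |
                    startsWith(lines, "track")))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) > 6L)
      stop("line ", i, ": BED record with ", length(f),
           " columns; multi-block BED12 alignments are not supported")
    if (length(f) < 6L)
      stop("line ", i, ": expected 6 BED columns, got ", length(f))
    s <- suppressWarnings(as.integer(f[2])); e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e))
      stop("line ", i, ": non-integer coordinates")
    if (s >= e)
      stop("line ", i, ": start >= end")
    if (!f[6] %in% c("+", "-"))
      stop("line ", i, ": read strand must be '+' or '-'")
  }
  if (length(body) == 0L)
    return(GRanges())
  reads <- rtracklayer::import(path, format = "bed")
  names(reads) <- reads$name
  reads
}

#' Write reads to BED6
#'
#' Inverse of [read_alignments()]; a read/write/read round trip preserves
#' every field.
#'
#' @param reads `GRanges` of reads, named by read id.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(reads, path) {
  if (length(reads) > 0L && is.null(reads$name)) reads$name <- names(reads)
  if (length(reads) > 0L && is.null(reads$score)) reads$score <- 0L
  rtracklayer::export(reads, path, format = "bed")
  invisible(path)
}
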