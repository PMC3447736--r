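#' Gene-by-stage count table
#'
#' Container for a gene x sample matrix of non-negative read counts with the
#' per-sample total-mapped-read metadata needed for depth normalization.
#'
#' @param counts numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = stage labels).
#' @param total_mapped named positive numeric vector, one entry per sample.
#' @param normalized logical; `TRUE` once [normalize_depth()] has been applied.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, total_mapped, normalized = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene_id in counts")
  if (any(counts < 0)) stop("negative count in matrix")
  if (!all(colnames(counts) %in% names(total_mapped)))
    stop("total_mapped missing for sample(s): ",
         paste(setdiff(colnames(counts), names(total_mapped)), collapse = ", "))
  total_mapped <- total_mapped[colnames(counts)]
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0 for every sample")
  structure(list(counts = counts, total_mapped = total_mapped,
                 normalized = isTRUE(normalized)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (x$normalized) "depth-normalized" else "raw"))
  cat("samples:", paste(sprintf("%s[%.3g]", colnames(x$counts),
                                x$total_mapped), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Read a count table from TSV
#'
#' Expected layout: one `#total_mapped:<sample>=<reads>` comment line per
#' sample (and an optional `#normalized:true` line), then a header row
#' `gene_id<TAB>stage1<TAB>...` followed by one row per gene.
#'
#' @param path path to the TSV file.
#' @return A [count_table].
#' @export
read_count_table <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  tm_lines <- grep("^#total_mapped:", meta, value = TRUE)
  if (length(tm_lines) == 0L) stop("no #total_mapped: header lines in ", path)
  kv <- strsplit(sub("^#total_mapped:", "", tm_lines), "=", fixed = TRUE)
  total_mapped <- setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                           vapply(kv, `[`, "", 1L))
  normalized <- any(grepl("^#normalized:\\s*true", meta))
  df <- read.delim(text = lines[!startsWith(lines, "#")],
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  count_table(m, total_mapped, normalized = normalized)
}

#' Write a count table to TSV
#'
#' @param table a [count_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in colnames(table$counts))
    writeLines(sprintf("#total_mapped:%s=%.10g", s, table$total_mapped[[s]]), con)
  if (table$normalized) writeLines("#normalized:true", con)
  df <- data.frame(gene_id = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(format(df, trim = TRUE, digits = 10, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a best-hit annotation table
#'
#' TSV with header `gene_id<TAB>subject_id<TAB>evalue`. E-value filtering is
#' deliberately *not* applied here; see [transfer_annotations()].
#'
#' @param path path to the TSV file.
#' @return A `data.frame` with columns `gene_id`, `subject_id`, `evalue`.
#' @export
read_annotation_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "subject_id", "evalue") %in% names(df)))
  df$evalue <- as.numeric(df$evalue)
  if (any(df$evalue < 0)) stop("negative e-value in ", path)
  df
}

#' Read a term map (GO/PANTHER or any flat vocabulary)
#'
#' TSV with header `id<TAB>terms`, the terms column a comma-separated list
#' (empty for no terms).
#'
#' @param path path to the TSV file.
#' @return A named list of character vectors.
#' @export
read_term_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                   colClasses = "character")
  out <- lapply(df[[2]], function(x)
    if (is.na(x) || x == "") character(0) else strsplit(x, ",", fixed = TRUE)[[1]])
  names(out) <- df[[1]]
  out
}

#' Write a term map
#' @param terms named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_term_map <- function(terms, path) {
  df <- data.frame(id = names(terms),
                   terms = vapply(terms, paste, "", collapse = ","),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' TSV with header
#' `gene_id<TAB>stage<TAB>replicate<TAB>ct_target<TAB>ct_reference`, one row
#' per gene x stage x replicate. Ct values must be finite and positive.
#'
#' @param path path to the TSV file.
#' @param stages valid stage labels (used to reject unknown stages).
#' @return A `data.frame` of qPCR records.
#' @export
read_qpcr_table <- function(path, stages = STAGES) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "stage", "replicate", "ct_target",
                  "ct_reference") %in% names(df)))
  bad <- setdiff(unique(df$stage), stages)
  if (length(bad) > 0L)
    stop("qPCR record with unknown stage: ", paste(bad, collapse = ", "))
  if (any(!is.finite(df$ct_target)) || any(!is.finite(df$ct_reference)) ||
      any(df$ct_target <= 0) || any(df$ct_reference <= 0))
    stop("Ct values must be finite and > 0")
  df
}

#' Load the full set of pipeline input tables
#'
#' Convenience wrapper around the individual readers.
#'
#' @param counts_path,annotation_path,terms_path,qpcr_path TSV paths; any of
#'   the last three may be `NULL`.
#' @param stages valid stage labels for the qPCR table.
#' @return A list with elements `counts`, `annotation`, `terms`, `qpcr`.
#'   Genes present in the count table but absent from the term map get empty
#'   term sets.
#' @export
load_tables <- function(counts_path, annotation_path = NULL,
                        terms_path = NULL, qpcr_path = NULL,
                        stages = STAGES) {
  counts <- read_count_table(counts_path)
  terms <- if (!is.null(terms_path)) read_term_map(terms_path) else list()
  missing <- setdiff(rownames(counts$counts), names(terms))
  terms[missing] <- rep(list(character(0)), length(missing))
  list(counts = counts,
       annotation = if (!is.null(annotation_path))
         read_annotation_table(annotation_path) else NULL,
       terms = terms,
       qpcr = if (!is.null(qpcr_path)) read_qpcr_table(qpcr_path, stages)
       else NULL)
}
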