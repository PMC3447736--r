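#' Score pipeline calls against planted truth
#'
#' Confusion-matrix metrics for differential-expression calls made on a
#' [generate_dataset()] output, plus the rank of every planted enriched term
#' in an enrichment table.
#'
#' @param truth the `truth` element of a [generate_dataset()] result.
#' @param stage_calls optional output of [stage_specific_calls()].
#' @param transitions optional output of [transition_calls()].
#' @param enrichment optional output of [resampling_enrichment()].
#' @return A list of metric blocks. For each call type: `sensitivity`
#'   (fraction of planted genes called at their planted contrast),
#'   `direction_accuracy` (fraction of those calls with the planted sign),
#'   and `fdp` (fraction of all up/down calls not matching a planted
#'   gene-contrast pair). For enrichment: `planted_term_ranks` in the
#'   BH-adjusted ordering.
#' @export
evaluate_calls <- function(truth, stage_calls = NULL, transitions = NULL,
                           enrichment = NULL) {
  gt <- truth$gene
  check_ids <- function(calls) {
    bad <- setdiff(calls$gene_id, gt$gene_id)
    if (length(bad) > 0)
      stop("calls contain gene ids absent from truth: ",
           paste(head(bad, 3), collapse = ", "))
  }
  score <- function(calls, planted, key) {
    # planted: data.frame gene_id, contrast, expected direction
    called <- calls[calls$direction != "unchanged", ]
    hit <- merge(planted, called, by = c("gene_id", "contrast"))
    sens <- if (nrow(planted) > 0) nrow(hit) / nrow(planted) else NA_real_
    dir_acc <- if (nrow(hit) > 0) mean(hit$expected == hit$direction)
    else NA_real_
    fp <- nrow(called) - nrow(hit)
    list(n_planted = nrow(planted), n_called = nrow(called),
         n_recovered = nrow(hit), sensitivity = sens,
         direction_accuracy = dir_acc,
         fdp = if (nrow(called) > 0) fp / nrow(called) else 0)
  }
  out <- list()
  if (!is.null(stage_calls)) {
    check_ids(stage_calls)
    sp <- gt[gt$class == "stage_specific", ]
    planted <- data.frame(gene_id = sp$gene_id, contrast = sp$spec_stage,
                          expected = ifelse(sp$effect_log2 > 0, "up", "down"),
                          stringsAsFactors = FALSE)
    out$stage_specific <- score(stage_calls, planted)
  }
  if (!is.null(transitions)) {
    check_ids(transitions)
    tr <- gt[gt$class == "transition", ]
    labels <- unique(transitions$contrast)
    planted <- data.frame(gene_id = tr$gene_id,
                          contrast = labels[tr$transition_index],
                          expected = ifelse(tr$effect_log2 > 0, "up", "down"),
                          stringsAsFactors = FALSE)
    out$transition <- score(transitions, planted)
  }
  if (!is.null(enrichment)) {
    ord <- enrichment[order(enrichment$p_adj, enrichment$p_raw), ]
    out$enrichment <- list(
      planted_term_ranks = setNames(
        match(truth$planted_terms, ord$term), truth$planted_terms),
      n_terms_tested = nrow(enrichment))
  }
  out
}
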