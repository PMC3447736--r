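#' Validate and resolve a pipeline configuration
#'
#' Accepts a JSON file path or a list, fills documented defaults, and rejects
#' unknown keys and contradictory values with messages naming the field.
#' Exactly one of `synth` (a [synth_config] argument list) or `inputs`
#' (paths to `counts`, and optionally `models`, `reads`, `annotation`,
#' `subject_terms`, `qpcr`) must be present. Re-validating an already
#' resolved configuration returns an identical structure.
#'
#' @param x JSON path, list, or `pipeline_config`.
#' @return A `pipeline_config` list with all defaults resolved.
#' @export
validate_config <- function(x) {
  if (is.character(x)) x <- jsonlite::read_json(x, simplifyVector = TRUE)
  if (is(x, "pipeline_config")) x <- unclass(x)
  known <- c("seed", "synth", "inputs", "params", "noise", "enrichment",
             "reference", "log_level")
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(x$seed)) stop("config field 'seed' is required")
  has_synth <- !is.null(x$synth)
  has_inputs <- !is.null(x$inputs)
  if (has_synth == has_inputs)
    stop("exactly one of 'synth' or 'inputs' must be present")
  p_def <- unclass(analysis_params())
  p <- utils::modifyList(p_def, as.list(x$params %||% list()))
  bad_p <- setdiff(names(p), names(p_def))
  if (length(bad_p) > 0)
    stop("unknown params key(s): ", paste(bad_p, collapse = ", "))
  if (p$fold_cutoff <= 1) stop("params.fold_cutoff must be > 1")
  if (p$alpha <= 0 || p$alpha >= 1) stop("params.alpha must be in (0, 1)")
  if (p$threshold <= 0) stop("params.threshold must be > 0")
  noise <- utils::modifyList(list(k = 5, dispersion = 0),
                             as.list(x$noise %||% list()))
  if (noise$k <= 0) stop("noise.k must be > 0")
  enr <- utils::modifyList(list(R = 10000, q = 0.75),
                           as.list(x$enrichment %||% list()))
  if (enr$R < 1000) stop("enrichment.R must be >= 1000")
  if (has_inputs) {
    if (is.null(x$inputs$counts)) stop("inputs.counts is required")
    for (f in unlist(x$inputs))
      if (!file.exists(f)) stop("input file does not exist: ", f)
  }
  structure(list(seed = as.integer(x$seed),
                 synth = if (has_synth) as.list(x$synth) else NULL,
                 inputs = if (has_inputs) as.list(x$inputs) else NULL,
                 params = p, noise = noise, enrichment = enr,
                 reference = x$reference %||% "PRE",
                 log_level = x$log_level %||% "info"),
            class = "pipeline_config")
}

.LOG_LEVELS <- c(debug = 1, info = 2, warning = 3, error = 4)

.log <- function(cfg, level, ...) {
  if (.LOG_LEVELS[[level]] >= .LOG_LEVELS[[cfg$log_level]])
    message(sprintf("[%s] %s", level, paste0(...)))
}

# deterministic per-stage seed fan-out from the single top-level seed
.derive_seed <- function(seed, i) (as.integer(seed) %% 2000003L) * 1000L + i

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/ingest, read attribution, depth normalization,
#' detection, differential expression (stage, settlement, and transition
#' calls at both the configured and the two-fold cutoff), extreme-gene
#' scoring, term enrichment, stage-family enrichment, qPCR concordance, and
#' (for synthetic input) truth-recovery metrics. All randomness derives from
#' the single configured seed, so identical configurations produce identical
#' output bundles. Any stage failure aborts with the stage name.
#'
#' @param config a `pipeline_config` (or anything [validate_config()]
#'   accepts).
#' @param out_dir output directory; created if missing.
#' @return Invisibly, a named list of the written file paths (the manifest
#'   records seeds and content hashes).
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  stage <- function(name, expr) {
    .log(cfg, "info", "stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  params <- do.call(analysis_params, cfg$params)

  data <- stage("data", {
    if (!is.null(cfg$synth)) {
      sc <- do.call(synth_config,
                    c(list(seed = .derive_seed(cfg$seed, 1L)), cfg$synth))
      generate_dataset(sc, file.path(out_dir, "synthetic"))
    } else {
      inp <- cfg$inputs
      list(models = if (!is.null(inp$models)) read_gene_models(inp$models),
           reads = if (!is.null(inp$reads)) read_alignments(inp$reads),
           counts = read_count_table(inp$counts),
           annotation = if (!is.null(inp$annotation))
             read_annotation_table(inp$annotation),
           subject_terms = if (!is.null(inp$subject_terms))
             read_term_map(inp$subject_terms),
           qpcr = if (!is.null(inp$qpcr)) read_qpcr_table(inp$qpcr),
           truth = NULL)
    }
  })

  if (!is.null(data$reads) && !is.null(data$models)) {
    stage("attribution", {
      classes <- classify_reads(data$reads, data$models)
      prof <- intergenic_profile(classes)
      outputs["classes"] <- .write_tsv(classes,
                                        file.path(out_dir, "read_classes.tsv"))
      prof_df <- data.frame(
        bin = names(prof$counts_by_bin_tss),
        tss = prof$counts_by_bin_tss, tts = prof$counts_by_bin_tts,
        row.names = NULL)
      outputs["profile"] <- .write_tsv(prof_df,
                                        file.path(out_dir,
                                                  "intergenic_profile.tsv"))
      jsonlite::write_json(
        list(proximal_fraction = prof$proximal_fraction,
             sense_fraction = prof$sense_fraction,
             distal_count = prof$distal_count,
             category_counts = as.list(table(classes$category))),
        file.path(out_dir, "attribution_summary.json"),
        auto_unbox = TRUE, digits = NA)
      outputs["attribution_summary"] <-
        file.path(out_dir, "attribution_summary.json")
      outputs["track"] <- export_coverage_track(
        data$reads, sum(data$counts$total_mapped),
        file.path(out_dir, "coverage.bedGraph"))
      data$read_classes <- classes
    })
  } else .log(cfg, "info", "attribution skipped: no reads/models provided")

  norm <- stage("normalize", {
    ref <- if (cfg$reference %in% colnames(data$counts$counts)) cfg$reference
    else colnames(data$counts$counts)[1]
    normalize_depth(data$counts, ref)
  })
  outputs["normalized"] <- write_count_table(
    norm, file.path(out_dir, "normalized_counts.tsv"))

  det <- stage("detect", detect_genes(norm, params$threshold))
  outputs["detection"] <- .write_tsv(
    data.frame(gene_id = rownames(det$detected), det$detected,
               row.names = NULL),
    file.path(out_dir, "detection.tsv"))
  jsonlite::write_json(
    list(threshold = det$threshold, n_detected_any = det$n_detected_any,
         n_detected_all = det$n_detected_all,
         per_subset_counts = as.list(det$per_subset_counts)),
    file.path(out_dir, "detection_summary.json"),
    auto_unbox = TRUE, digits = NA)
  outputs["detection_summary"] <- file.path(out_dir, "detection_summary.json")

  de <- stage("differential_expression", {
    two_fold <- analysis_params(fold_cutoff = 2, alpha = params$alpha,
                                k = params$k, threshold = params$threshold)
    list(stage = stage_specific_calls(norm, params, detected = det$detected),
         settlement = settlement_calls(norm, params,
                                       detected = det$detected),
         trans4 = transition_calls(norm, params, detected = det$detected),
         trans2 = transition_calls(norm, two_fold, detected = det$detected),
         extreme = extreme_upregulation(norm, params))
  })
  outputs["stage_calls"] <- .write_tsv(de$stage,
                                       file.path(out_dir, "stage_calls.tsv"))
  outputs["settlement_calls"] <- .write_tsv(
    de$settlement, file.path(out_dir, "settlement_calls.tsv"))
  outputs["transition_calls_fold4"] <- .write_tsv(
    de$trans4, file.path(out_dir, "transition_calls_fold4.tsv"))
  outputs["transition_calls_fold2"] <- .write_tsv(
    de$trans2, file.path(out_dir, "transition_calls_fold2.tsv"))
  outputs["extreme"] <- .write_tsv(de$extreme,
                                   file.path(out_dir, "extreme_genes.tsv"))

  enr <- NULL
  if (!is.null(data$annotation) && !is.null(data$subject_terms)) {
    enr <- stage("enrichment", {
      tr <- transfer_annotations(data$annotation, data$subject_terms)
      detected_ids <- rownames(det$detected)[rowSums(det$detected) > 0]
      universe <- intersect(detected_ids,
                            names(tr$is_annotated)[tr$is_annotated])
      de_genes <- unique(de$stage$gene_id[de$stage$direction != "unchanged"])
      gene_set <- intersect(de_genes, universe)
      res <- resampling_enrichment(gene_set, tr$terms, universe,
                                   R = cfg$enrichment$R,
                                   seed = .derive_seed(cfg$seed, 6L))
      peaks <- at_peak(norm, detected_ids, q = cfg$enrichment$q)
      # family: the most common term among detected annotated genes
      fam_term <- if (!is.null(data$truth)) data$truth$planted_terms[1]
      else names(sort(table(unlist(tr$terms[universe])),
                      decreasing = TRUE))[1]
      fam <- intersect(
        names(tr$terms)[vapply(tr$terms, function(t) fam_term %in% t,
                               logical(1))], detected_ids)
      stagefam <- if (length(fam) > 0)
        do.call(rbind, lapply(colnames(norm$counts), function(s)
          cbind(term = fam_term,
                stage_family_enrichment(fam, peaks, s))))
      else NULL
      list(terms = res, stage_family = stagefam)
    })
    outputs["enrichment"] <- .write_tsv(enr$terms,
                                        file.path(out_dir, "enrichment.tsv"))
    if (!is.null(enr$stage_family))
      outputs["stage_family"] <- .write_tsv(
        enr$stage_family, file.path(out_dir, "stage_family.tsv"))
  } else .log(cfg, "info", "enrichment skipped: no annotation provided")

  if (!is.null(data$qpcr)) {
    stage("qpcr", {
      ref_stage <- if (cfg$reference %in% data$qpcr$stage) cfg$reference
      else data$qpcr$stage[1]
      rel <- do.call(rbind, lapply(unique(data$qpcr$gene_id), function(g)
        delta_delta_ct(data$qpcr[data$qpcr$gene_id == g, ], ref_stage)))
      conc <- qpcr_concordance(norm, data$qpcr, ref_stage)
      outputs["qpcr_report"] <- .write_tsv(
        rel, file.path(out_dir, "qpcr_report.tsv"))
      jsonlite::write_json(
        list(spearman_pooled = conc$spearman_pooled,
             n_points = conc$n_points,
             per_gene_pearson = setNames(as.list(conc$per_gene$pearson_r),
                                         conc$per_gene$gene_id)),
        file.path(out_dir, "qpcr_concordance.json"),
        auto_unbox = TRUE, digits = NA, na = "null")
      outputs["qpcr_concordance"] <- file.path(out_dir,
                                                "qpcr_concordance.json")
    })
  } else .log(cfg, "info", "qpcr skipped: no Ct table provided")

  if (!is.null(data$truth)) {
    stage("evaluate", {
      metrics <- evaluate_calls(data$truth, stage_calls = de$stage,
                                transitions = de$trans4,
                                enrichment = enr$terms)
      if (!is.null(data$read_classes)) {
        lab <- data$truth$read_labels
        m <- match(lab$read_id, data$read_classes$read_id)
        metrics$attribution <- list(
          label_agreement = mean(lab$category ==
                                   data$read_classes$category[m]),
          recovered_fractions = as.list(
            table(data$read_classes$category) /
              nrow(data$read_classes)))
      }
      jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
      outputs["metrics"] <- file.path(out_dir, "metrics.json")
    })
  }

  manifest <- list(
    package = "devexpr",
    version = as.character(utils::packageVersion("devexpr")),
    seed = cfg$seed,
    stage_seeds = setNames(lapply(1:6, function(i) .derive_seed(cfg$seed, i)),
                           paste0("stage", 1:6)),
    config = unclass(cfg),
    output_md5 = {
      files <- sort(unname(outputs))
      setNames(as.list(unname(tools::md5sum(files))), basename(files))
    })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  outputs["manifest"] <- file.path(out_dir, "manifest.json")
  .log(cfg, "info", "pipeline complete: ", length(outputs), " outputs")
  invisible(outputs)
}
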