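# Pipeline orchestration: QC -> rRNA partition -> genome-alignment intake ->
# post-filters -> coverage/detection and EM/RPKM -> consolidated summaries,
# with stage-count logging and a written report bundle.

#' Pipeline configuration
#'
#' @param samples data.frame with one row per sample: `label`, `role`
#'   (`"cellular"` or `"exosomal"`), `fastq` (path), `alignments` (SAM/BAM
#'   path of genome alignments for the sample's reads).
#' @param annotation Path to the GTF annotation, or a `transcript_models`
#'   object.
#' @param rrna_ref Path to the rRNA reference FASTA, or a named
#'   `DNAStringSet`.
#' @param qc A [qc_params()].
#' @param max_mismatches,min_match_len rRNA matcher parameters.
#' @param min_aligned_len,min_mapq Post-alignment filter thresholds.
#' @param coverage_threshold,pooled_threshold,sample_threshold Detection
#'   thresholds (strict inequalities).
#' @param rpkm_threshold RPKM detection threshold.
#' @param em_tolerance Junction tolerance for compatibility.
#' @param enrichment_annotation Optional data.frame (`category_id`,
#'   `category_name`, `gene`) enabling the enrichment stage on cellular
#'   detected genes.
#' @param seed Integer recorded in the manifest (all pipeline stages are
#'   deterministic; the seed documents the provenance of simulated inputs).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(samples, annotation, rrna_ref,
                            qc = qc_params(),
                            max_mismatches = 2L, min_match_len = NULL,
                            min_aligned_len = 20L, min_mapq = 10L,
                            coverage_threshold = 0.9,
                            pooled_threshold = 0.9, sample_threshold = 0.5,
                            rpkm_threshold = 1.0,
                            em_tolerance = 0L,
                            enrichment_annotation = NULL,
                            seed = 1L) {
  req <- c("label", "role", "fastq", "alignments")
  missing_fields <- setdiff(req, names(samples))
  if (length(missing_fields) > 0L)
    stop("samples table lacks field(s): ", paste(missing_fields, collapse = ", "))
  if (!all(samples$role %in% c("cellular", "exosomal")))
    stop("sample roles must be 'cellular' or 'exosomal'")
  if (sum(samples$role == "cellular") > 1L)
    stop("at most one cellular sample is supported")
  missing_paths <- c(samples$fastq, samples$alignments,
                     if (is.character(annotation)) annotation,
                     if (is.character(rrna_ref)) rrna_ref)
  missing_paths <- missing_paths[!file.exists(missing_paths)]
  if (length(missing_paths) > 0L)
    stop("input path(s) do not exist: ", paste(missing_paths, collapse = ", "))
  structure(list(samples = samples, annotation = annotation,
                 rrna_ref = rrna_ref, qc = qc,
                 max_mismatches = max_mismatches,
                 min_match_len = min_match_len,
                 min_aligned_len = min_aligned_len, min_mapq = min_mapq,
                 coverage_threshold = coverage_threshold,
                 pooled_threshold = pooled_threshold,
                 sample_threshold = sample_threshold,
                 rpkm_threshold = rpkm_threshold,
                 em_tolerance = em_tolerance,
                 enrichment_annotation = enrichment_annotation,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

log_stage <- function(verbose, ...) if (verbose) message(...)

#' Run the full analysis pipeline
#'
#' Per sample: read QC, rRNA partition, genome-alignment intake restricted
#' to the non-rRNA remainder, multi-mapper/length/MAPQ filters, compartment
#' assignment, coverage and EM/RPKM quantification. Across samples: the
#' cellular coverage-detection rule, the pooled + per-sample exosomal rule,
#' gene-level detection, biotype and overlap summaries, the RPKM-threshold
#' detection set, and (if an annotation table is configured) enrichment of
#' the cellular detected genes. Deterministic given identical inputs.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log stage counts to stderr (default TRUE).
#' @return A `pipeline_bundle`: nested list of every stage's outputs (see
#'   [write_report()]).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  models <- if (inherits(config$annotation, "transcript_models"))
    config$annotation else read_gtf_models(config$annotation)
  index <- if (inherits(config$rrna_ref, "rrna_index")) config$rrna_ref
  else rrna_index(config$rrna_ref)

  per_sample <- list()
  for (i in seq_len(nrow(config$samples))) {
    s <- config$samples[i, ]
    log_stage(verbose, "[", s$label, "] reading ", s$fastq)
    reads <- read_fastq(s$fastq)
    qc <- run_qc(reads, config$qc)
    log_stage(verbose, "[", s$label, "] QC: ", qc$report$input_reads,
              " reads in, ", qc$report$passed, " passed")
    part <- partition_library(qc$kept, index, config$max_mismatches,
                              config$min_match_len)
    log_stage(verbose, "[", s$label, "] rRNA partition: ", nrow(part$hits),
              " rRNA / ", nrow(part$remainder), " remainder")
    aln <- load_alignments(s$alignments)
    aln <- filter_by_read_id(aln, part$remainder$read_id)
    filt <- filter_alignments(aln, config$min_aligned_len, config$min_mapq)
    log_stage(verbose, "[", s$label, "] filters kept ", filt$funnel$kept,
              " of ", filt$funnel$input_records, " records")
    labels <- assign_compartment(filt$kept, models)
    cov <- coverage_table(unlist(filt$kept$blocks), models)
    quantification <- quantify_sample(filt$kept, models,
                                      tolerance = config$em_tolerance)
    per_sample[[s$label]] <- list(
      role = s$role, qc_report = qc$report, rrna_hits = part$hits,
      n_remainder = nrow(part$remainder),
      subunit_fractions = subunit_read_fractions(part$hits),
      density = density_table(part$hits, index),
      funnel = filt$funnel, records = filt$kept,
      compartments = compartment_summary(labels, n_rrna = nrow(part$hits)),
      coverage = cov, abundance = quantification)
  }

  labels_cell <- config$samples$label[config$samples$role == "cellular"]
  labels_exo <- config$samples$label[config$samples$role == "exosomal"]

  calls <- list()
  for (lab in labels_cell)
    calls[[lab]] <- detect_cellular(per_sample[[lab]]$coverage,
                                    config$coverage_threshold)
  if (length(labels_exo) > 0L) {
    pooled <- do.call(pool_blocks,
                      lapply(per_sample[labels_exo], `[[`, "records"))
    pooled_cov <- coverage_table(pooled, models)
    exo_calls <- detect_exosomal(
      pooled_cov, lapply(per_sample[labels_exo], `[[`, "coverage"),
      config$pooled_threshold, config$sample_threshold)
    for (lab in labels_exo)
      calls[[lab]] <- exo_calls[exo_calls$sample == lab, , drop = FALSE]
  } else pooled_cov <- NULL

  gene_sets <- lapply(calls, gene_level_detect, models = models)
  table1 <- biotype_summary(gene_sets)
  table2 <- noncoding_biotype_counts(gene_sets)
  overlaps <- if (length(gene_sets) >= 2L)
    overlap_sets(lapply(gene_sets, function(g) g$gene_name),
                 cellular = if (length(labels_cell)) labels_cell[1]
                 else names(gene_sets)[1])
  else NULL
  rpkm_set <- rpkm_detect(lapply(per_sample, `[[`, "abundance"),
                          config$rpkm_threshold)
  enrichment <- if (!is.null(config$enrichment_annotation) &&
                    length(labels_cell) > 0L &&
                    nrow(gene_sets[[labels_cell[1]]]) > 0L)
    enrich_categories(gene_sets[[labels_cell[1]]]$gene_name,
                      config$enrichment_annotation)
  else NULL

  structure(list(config = config, models = models, per_sample = per_sample,
                 calls = calls, pooled_coverage = pooled_cov,
                 gene_sets = gene_sets, table1 = table1, table2 = table2,
                 overlaps = overlaps, rpkm_detected = rpkm_set,
                 enrichment = enrichment),
            class = "pipeline_bundle")
}

#' Write the consolidated report of a pipeline run
#'
#' One TSV per summary (QC funnels, rRNA hits and density profiles,
#' alignment funnels, compartment distributions, coverage tables, detection
#' calls, abundance tables, the biotype and non-coding summaries, overlaps,
#' RPKM-detected set, optional enrichment), plus a `manifest.tsv` listing
#' every file with its producing stage and row count, and an `index.tsv`
#' linking the summary tables. Percentages are printed to one decimal.
#'
#' @param bundle A `pipeline_bundle` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return The manifest data.frame, invisibly.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(file = character(0), stage = character(0),
                         rows = integer(0), stringsAsFactors = FALSE)
  emit <- function(df, name, stage) {
    path <- file.path(dir, name)
    write_tsv(df, path)
    manifest[nrow(manifest) + 1L, ] <<- list(name, stage, nrow(df))
  }
  for (lab in names(bundle$per_sample)) {
    ps <- bundle$per_sample[[lab]]
    emit(data.frame(field = names(ps$qc_report),
                    count = unlist(ps$qc_report, use.names = FALSE)),
         paste0(lab, "_qc.tsv"), "readqc")
    emit(ps$rrna_hits, paste0(lab, "_rrna_hits.tsv"), "rrna")
    emit(ps$density, paste0(lab, "_rrna_density.tsv"), "rrna")
    sf <- ps$subunit_fractions
    emit(data.frame(subunit = names(sf), fraction = as.numeric(sf)),
         paste0(lab, "_subunit_fractions.tsv"), "rrna")
    emit(filter_funnel_report(ps$funnel), paste0(lab, "_funnel.tsv"),
         "alnfilter")
    emit(ps$compartments, paste0(lab, "_compartments.tsv"), "alnfilter")
    emit(ps$coverage, paste0(lab, "_coverage.tsv"), "covdetect")
    emit(as.data.frame(ps$abundance), paste0(lab, "_abundance.tsv"), "quant")
    if (lab %in% names(bundle$calls))
      emit(bundle$calls[[lab]], paste0(lab, "_detection.tsv"), "covdetect")
    gs <- bundle$gene_sets[[lab]]
    if (!is.null(gs)) emit(gs, paste0(lab, "_genes.tsv"), "covdetect")
  }
  emit(bundle$table1, "table1_biotype_percent.tsv", "covdetect")
  emit(bundle$table2, "table2_noncoding_counts.tsv", "covdetect")
  if (!is.null(bundle$overlaps)) {
    emit(bundle$overlaps$pairwise, "overlaps_pairwise.tsv", "covdetect")
    emit(bundle$overlaps$percent_in_cellular, "overlaps_in_cellular.tsv",
         "covdetect")
  }
  emit(data.frame(transcript_id = bundle$rpkm_detected),
       "rpkm_detected.tsv", "quant")
  if (!is.null(bundle$enrichment))
    emit(bundle$enrichment, "enrichment.tsv", "stats")
  write_tsv(manifest, file.path(dir, "manifest.tsv"))
  idx <- manifest[manifest$stage %in% c("covdetect", "quant", "stats"), ,
                  drop = FALSE]
  write_tsv(idx, file.path(dir, "index.tsv"))
  invisible(manifest)
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat("pipeline_bundle:", length(x$per_sample), "samples (",
      paste(names(x$per_sample), collapse = ", "), ")\n")
  invisible(x)
}
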