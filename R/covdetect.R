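# Coverage-fraction transcript detection. For each transcript the target is
# the CDS union (protein-coding) or the exon union (non-coding); the covered
# fraction is the size of (union of aligned blocks) ∩ (target) divided by
# the target length, overlapping reads counted once. Detection: cellular
# samples require > 90% target coverage; exosomal samples require > 90%
# coverage by the pooled exosomal blocks AND > 50% in the individual sample.

target_ranges <- function(models, transcript_id, target) {
  coding <- models$tx$biotype[models$tx$transcript_id == transcript_id] ==
    "protein_coding"
  if (target == "auto") target <- if (coding) "CDS" else "exon"
  if (target == "CDS") {
    if (!coding)
      stop("CDS coverage requested for non-coding transcript ", transcript_id)
    cds_union(models, transcript_id)
  } else exon_union(models, transcript_id)
}

#' Coverage of one transcript's target by aligned blocks
#'
#' @param blocks A [GenomicRanges::GRanges] (or [IRanges::IRanges]) of
#'   aligned blocks; strand is ignored.
#' @param models A `transcript_models` annotation.
#' @param transcript_id Transcript to measure.
#' @param target `"auto"` (CDS for coding, exon union for non-coding),
#'   `"CDS"` or `"exon"`.
#' @return One-row data.frame: `transcript_id`, `target`, `target_length`,
#'   `covered`, `fraction`.
#' @export
transcript_coverage <- function(blocks, models, transcript_id,
                                target = "auto") {
  coding <- models$tx$biotype[models$tx$transcript_id == transcript_id] ==
    "protein_coding"
  used <- if (target == "auto") (if (coding) "CDS" else "exon") else target
  tgt <- target_ranges(models, transcript_id, target)
  ir <- if (methods::is(blocks, "GRanges")) IRanges::ranges(blocks) else blocks
  covered <- sum(BiocGenerics::width(
    IRanges::intersect(IRanges::reduce(ir), tgt)))
  tl <- sum(BiocGenerics::width(tgt))
  data.frame(transcript_id = transcript_id, target = used,
             target_length = tl, covered = covered,
             fraction = covered / tl, stringsAsFactors = FALSE)
}

#' Coverage table over all transcripts
#'
#' @param blocks Aligned blocks (`GRanges`), e.g. from [pool_blocks()].
#' @param models A `transcript_models` annotation.
#' @return data.frame with one row per transcript (target chosen
#'   automatically: CDS for coding, exon union for non-coding).
#' @export
coverage_table <- function(blocks, models) {
  do.call(rbind, lapply(models$tx$transcript_id, function(id)
    transcript_coverage(blocks, models, id)))
}

#' Cellular detection rule
#'
#' A transcript is detected in a cellular sample iff its target coverage
#' fraction strictly exceeds the threshold (default 0.9, i.e. "over 90%").
#'
#' @param coverage Coverage table from [coverage_table()].
#' @param threshold Coverage threshold (default 0.9; strict inequality).
#' @return data.frame `transcript_id`, `fraction`, `detected`, `rule`.
#' @export
detect_cellular <- function(coverage, threshold = 0.9) {
  data.frame(transcript_id = coverage$transcript_id,
             fraction = coverage$fraction,
             detected = coverage$fraction > threshold,
             rule = "cellular_90", stringsAsFactors = FALSE)
}

#' Exosomal detection rule (pooled + per-sample gates)
#'
#' The aligned blocks of all exosomal samples are pooled; a transcript is
#' detected in sample S iff the pooled coverage fraction exceeds
#' `pooled_threshold` (default 0.9) AND sample S's own fraction exceeds
#' `sample_threshold` (default 0.5), both strictly.
#'
#' @param pooled_coverage Coverage table computed on the pooled blocks.
#' @param sample_coverages Named list of per-sample coverage tables.
#' @param pooled_threshold,sample_threshold Strict thresholds.
#' @return data.frame `transcript_id`, `sample`, `pooled_fraction`,
#'   `fraction`, `detected`, `rule`.
#' @export
detect_exosomal <- function(pooled_coverage, sample_coverages,
                            pooled_threshold = 0.9, sample_threshold = 0.5) {
  ids <- pooled_coverage$transcript_id
  out <- lapply(names(sample_coverages), function(s) {
    sc <- sample_coverages[[s]]
    stopifnot(identical(sc$transcript_id, ids))
    if (any(pooled_coverage$fraction < sc$fraction - 1e-12))
      stop("pooled coverage below a per-sample coverage: pooling is wrong")
    data.frame(transcript_id = ids, sample = s,
               pooled_fraction = pooled_coverage$fraction,
               fraction = sc$fraction,
               detected = pooled_coverage$fraction > pooled_threshold &
                 sc$fraction > sample_threshold,
               rule = "exosome_pooled90_sample50", stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Gene-level detection from isoform calls
#'
#' A gene is detected iff any of its isoforms is detected (the maximum
#' isoform coverage governs). The gene's biotype is `protein_coding` if any
#' detected isoform is coding; otherwise the non-coding biotype of the
#' detected isoform(s) — on a conflict the lexicographically smallest
#' biotype is reported once, with a warning.
#'
#' @param calls Detection-call table (one sample) with `transcript_id`,
#'   `detected`, `fraction`.
#' @param models A `transcript_models` annotation.
#' @return data.frame of detected genes: `gene_id`, `gene_name`, `biotype`,
#'   `max_fraction`, `n_isoforms_detected`.
#' @export
gene_level_detect <- function(calls, models) {
  m <- merge(calls, models$tx[, c("transcript_id", "gene_id", "gene_name",
                                  "biotype")], by = "transcript_id")
  det <- m[m$detected, , drop = FALSE]
  if (nrow(det) == 0L)
    return(data.frame(gene_id = character(0), gene_name = character(0),
                      biotype = character(0), max_fraction = numeric(0),
                      n_isoforms_detected = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(split(det, det$gene_id), function(g) {
    bios <- unique(g$biotype)
    bio <- if ("protein_coding" %in% bios) "protein_coding" else {
      if (length(bios) > 1L) {
        warning("gene ", g$gene_id[1], " has detected isoforms with ",
                "conflicting biotypes (", paste(sort(bios, method = "radix"), collapse = ", "),
                "); reporting the lexicographically smallest")
      }
      sort(bios, method = "radix")[1]
    }
    data.frame(gene_id = g$gene_id[1], gene_name = g$gene_name[1],
               biotype = bio, max_fraction = max(g$fraction),
               n_isoforms_detected = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$gene_id, method = "radix"), , drop = FALSE]
}

#' Protein-coding vs non-coding percentages per sample
#'
#' The percentage split of detected genes between protein-coding and
#' non-coding, one decimal place, per sample.
#'
#' @param gene_sets Named list of detected-gene tables (from
#'   [gene_level_detect()]), one per sample.
#' @return data.frame with rows `protein_coding` / `non_coding` and one
#'   percentage column per sample.
#' @export
biotype_summary <- function(gene_sets) {
  cols <- lapply(gene_sets, function(g) {
    nc <- sum(g$biotype == "protein_coding")
    nn <- sum(g$biotype != "protein_coding")
    tot <- nc + nn
    if (tot == 0) c(0, 0) else round(100 * c(nc, nn) / tot, 1)
  })
  out <- data.frame(transcript_type = c("protein_coding", "non_coding"))
  for (s in names(gene_sets)) out[[s]] <- cols[[s]]
  out
}

#' Non-coding biotype counts per sample
#'
#' Gene-symbol counts per non-coding biotype, sorted in descending order of
#' the first sample's column.
#'
#' @inheritParams biotype_summary
#' @return data.frame with `gene_type` and one count column per sample.
#' @export
noncoding_biotype_counts <- function(gene_sets) {
  nc_sets <- lapply(gene_sets, function(g)
    g[g$biotype != "protein_coding", , drop = FALSE])
  types <- sort(unique(unlist(lapply(nc_sets, function(g) g$biotype))),
                method = "radix")
  out <- data.frame(gene_type = types, stringsAsFactors = FALSE)
  for (s in names(nc_sets))
    out[[s]] <- vapply(types, function(t)
      length(unique(nc_sets[[s]]$gene_name[nc_sets[[s]]$biotype == t])),
      integer(1))
  if (nrow(out) > 0 && length(nc_sets) > 0)
    out <- out[order(-out[[2]], out$gene_type, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap of detected gene sets
#'
#' Pairwise and (when three sets are given) three-way intersection sizes,
#' plus the percentage of each non-cellular set present in the cellular set.
#'
#' @param sets Named list of character vectors of gene symbols.
#' @param cellular Name of the cellular set within `sets` (default the
#'   first).
#' @return List with `pairwise` (data.frame `set_a`, `set_b`,
#'   `intersection`), `three_way` (integer or NA), and `percent_in_cellular`
#'   (data.frame `set`, `percent`, one decimal).
#' @export
overlap_sets <- function(sets, cellular = names(sets)[1]) {
  nm <- names(sets)
  pairs <- utils::combn(nm, 2, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(pairs, function(p)
    data.frame(set_a = p[1], set_b = p[2],
               intersection = length(intersect(sets[[p[1]]], sets[[p[2]]])),
               stringsAsFactors = FALSE)))
  three_way <- if (length(sets) >= 3)
    length(Reduce(intersect, sets[nm[1:3]])) else NA_integer_
  others <- setdiff(nm, cellular)
  pic <- data.frame(set = others,
                    percent = vapply(others, function(s) {
                      n <- length(sets[[s]])
                      if (n == 0) return(0)
                      round(100 * length(intersect(sets[[s]],
                                                   sets[[cellular]])) / n, 1)
                    }, numeric(1)), stringsAsFactors = FALSE, row.names = NULL)
  list(pairwise = pairwise, three_way = three_way, percent_in_cellular = pic)
}
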