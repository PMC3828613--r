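# Post-processing of genome alignments: multi-mapper removal, aligned-length
# and mapping-quality filters (in that order, with exact funnel accounting),
# CIGAR-derived block splitting, and assignment of kept reads to genomic
# compartments (rRNA / known gene / unknown).

#' Load alignments from SAM/BAM into block-split records
#'
#' Unmapped records are dropped. CIGAR `N` runs split an alignment into
#' blocks; `D` consumes reference within a block; `I`/`S`/`H` consume no
#' reference. Multiplicity (number of reported mapped locations per read) is
#' taken from the `NH` tag when present, otherwise inferred by grouping
#' mapped records by read id.
#'
#' @param path Path to a SAM or BAM file (SAM is converted on the fly).
#' @return An object of class `alignment_records`: list with `meta`
#'   (data.frame `read_id`, `chrom`, `strand`, `mapq`, `multiplicity`,
#'   `aligned_len`, `n_blocks`) and `blocks` (a
#'   [GenomicRanges::GRangesList] parallel to `meta`, 1-based closed
#'   coordinates).
#' @export
load_alignments <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    # htslib silently drops records with unparseable CIGARs; validate first
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "@")]
    if (length(body) > 0L) {
      fields <- strsplit(body, "\t", fixed = TRUE)
      cig <- vapply(fields, `[[`, character(1), 6L)
      bad <- !grepl("^(\\*|([0-9]+[MIDNSHP=X])+)$", cig)
      if (any(bad))
        stop("failed to parse alignment file '", path,
             "': malformed CIGAR '", cig[which(bad)[1]], "' in record '",
             vapply(fields, `[[`, character(1), 1L)[which(bad)[1]], "'",
             call. = FALSE)
    }
    bam <- tryCatch(
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop("failed to parse alignment file '", path,
                               "': ", conditionMessage(e), call. = FALSE))
  }
  param <- Rsamtools::ScanBamParam(
    what = c("mapq", "flag"), tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  gal <- GenomicAlignments::readGAlignments(bam, use.names = TRUE, param = param)
  blocks <- GenomicAlignments::grglist(gal, drop.D.ranges = FALSE)
  nh <- S4Vectors::mcols(gal)$NH
  multiplicity <- if (!is.null(nh) && !all(is.na(nh))) {
    as.integer(nh)
  } else {
    cnt <- table(names(gal))
    as.integer(cnt[names(gal)])
  }
  meta <- data.frame(
    read_id = names(gal),
    chrom = as.character(GenomicRanges::seqnames(gal)),
    strand = as.character(BiocGenerics::strand(gal)),
    mapq = S4Vectors::mcols(gal)$mapq,
    multiplicity = multiplicity,
    aligned_len = sum(BiocGenerics::width(blocks)),
    n_blocks = lengths(blocks),
    stringsAsFactors = FALSE)
  rownames(meta) <- NULL
  names(blocks) <- NULL
  structure(list(meta = meta, blocks = blocks), class = "alignment_records")
}

#' Construct alignment records directly
#'
#' Programmatic constructor for the container returned by
#' [load_alignments()], for record sets not originating in a SAM/BAM file.
#'
#' @param read_id,chrom,strand,mapq,multiplicity Per-record vectors.
#' @param blocks A [GenomicRanges::GRangesList] of aligned blocks, one
#'   element per record.
#' @return An `alignment_records` object.
#' @export
alignment_records <- function(read_id, chrom, strand, mapq, multiplicity,
                              blocks) {
  n <- length(read_id)
  stopifnot(length(blocks) == n, all(lengths(blocks) >= 1L),
            all(mapq >= 0L))
  meta <- data.frame(read_id = read_id,
                     chrom = rep_len(chrom, n),
                     strand = rep_len(strand, n),
                     mapq = rep_len(as.integer(mapq), n),
                     multiplicity = rep_len(as.integer(multiplicity), n),
                     aligned_len = sum(BiocGenerics::width(blocks)),
                     n_blocks = lengths(blocks),
                     stringsAsFactors = FALSE)
  names(blocks) <- NULL
  structure(list(meta = meta, blocks = blocks), class = "alignment_records")
}

#' @export
print.alignment_records <- function(x, ...) {
  cat("alignment_records:", nrow(x$meta), "records,",
      length(unique(x$meta$read_id)), "reads\n")
  invisible(x)
}

#' Number of alignment records
#' @param records An `alignment_records` object.
#' @return Integer count.
#' @export
n_records <- function(records) nrow(records$meta)

subset_records <- function(records, idx) {
  structure(list(meta = records$meta[idx, , drop = FALSE],
                 blocks = records$blocks[idx]),
            class = "alignment_records")
}

#' Keep only records whose read id is in a set
#' @param records An `alignment_records` object.
#' @param read_ids Character vector of read ids to keep.
#' @return Subset `alignment_records`.
#' @export
filter_by_read_id <- function(records, read_ids)
  subset_records(records, records$meta$read_id %in% read_ids)

#' Remove multi-mapped reads
#'
#' All records of any read with multiplicity greater than 1 are removed.
#'
#' @param records An `alignment_records` object.
#' @return List with `kept` and `removed` (`alignment_records`).
#' @export
remove_multimapped <- function(records) {
  multi <- records$meta$multiplicity > 1L
  list(kept = subset_records(records, !multi),
       removed = subset_records(records, multi))
}

#' Apply aligned-length and mapping-quality filters
#'
#' Records with aligned length below `min_aligned_len` are removed first
#' (short aligned reads are prone to spurious placement), then records with
#' MAPQ below `min_mapq`. A record failing both is counted once, as short.
#'
#' @param records Uniquely-mapped `alignment_records`.
#' @param min_aligned_len Minimum aligned reference length in bases
#'   (default 20; alignments shorter than 20 nucleotides are eliminated).
#' @param min_mapq Minimum mapping quality (default 10).
#' @return List with `kept`, `removed_short`, `removed_low_mapq`.
#' @export
apply_quality_length_filters <- function(records, min_aligned_len = 20L,
                                         min_mapq = 10L) {
  short <- records$meta$aligned_len < min_aligned_len
  lowq <- !short & records$meta$mapq < min_mapq
  list(kept = subset_records(records, !short & !lowq),
       removed_short = subset_records(records, short),
       removed_low_mapq = subset_records(records, lowq))
}

#' Run the full post-alignment filter funnel
#'
#' Stage order: multi-mapper removal, aligned-length filter, MAPQ filter.
#'
#' @param records An `alignment_records` object.
#' @param min_aligned_len,min_mapq See [apply_quality_length_filters()].
#' @return List with `kept` (`alignment_records`) and `funnel`
#'   (class `filter_funnel`: input_records, removed_multimapped,
#'   removed_short, removed_low_mapq, kept).
#' @export
filter_alignments <- function(records, min_aligned_len = 20L, min_mapq = 10L) {
  mm <- remove_multimapped(records)
  ql <- apply_quality_length_filters(mm$kept, min_aligned_len, min_mapq)
  funnel <- structure(list(
    input_records = n_records(records),
    removed_multimapped = n_records(mm$removed),
    removed_short = n_records(ql$removed_short),
    removed_low_mapq = n_records(ql$removed_low_mapq),
    kept = n_records(ql$kept)), class = "filter_funnel")
  list(kept = ql$kept, funnel = funnel)
}

#' Funnel report with counts and percentages
#'
#' @param funnel A `filter_funnel`.
#' @return data.frame with `stage`, `count`, `percent` (percent of input,
#'   one decimal; 0 for an empty input). Errors if the funnel does not
#'   conserve records.
#' @export
filter_funnel_report <- function(funnel) {
  tot <- funnel$input_records
  parts <- c(funnel$removed_multimapped, funnel$removed_short,
             funnel$removed_low_mapq, funnel$kept)
  if (sum(parts) != tot)
    stop("inconsistent funnel: stages sum to ", sum(parts),
         " but input is ", tot)
  data.frame(
    stage = c("input", "removed_multimapped", "removed_short",
              "removed_low_mapq", "kept"),
    count = c(tot, parts),
    percent = if (tot == 0) rep(0, 5) else
      round(100 * c(tot, parts) / tot, 1))
}

#' Assign kept records to genomic compartments
#'
#' A record is `rRNA` if its read was claimed by the rRNA partition stage,
#' `known_gene` if any of its aligned blocks overlaps any annotated exon by
#' at least one base (either strand), else `unknown`.
#'
#' @param records Kept `alignment_records`.
#' @param models A `transcript_models` annotation.
#' @param rrna_read_ids Read ids claimed by the rRNA partition (normally
#'   empty here, since those reads never reach the genome).
#' @return Character vector of labels, parallel to the records.
#' @export
assign_compartment <- function(records, models, rrna_read_ids = character(0)) {
  n <- n_records(records)
  if (n == 0L) return(character(0))
  exons <- unlist(models$exons)
  BiocGenerics::strand(exons) <- "*"
  flat <- unlist(records$blocks)
  BiocGenerics::strand(flat) <- "*"
  rec_of_block <- rep(seq_len(n), lengths(records$blocks))
  ov <- GenomicRanges::findOverlaps(flat, exons, minoverlap = 1L)
  in_gene <- logical(n)
  in_gene[unique(rec_of_block[S4Vectors::queryHits(ov)])] <- TRUE
  lab <- ifelse(in_gene, "known_gene", "unknown")
  lab[records$meta$read_id %in% rrna_read_ids] <- "rRNA"
  lab
}

#' Compartment distribution summary
#'
#' Counts and percentages of reads per compartment, with the rRNA partition
#' included so the distribution covers the whole library.
#'
#' @param labels Labels from [assign_compartment()].
#' @param n_rrna Number of reads in the rRNA partition.
#' @return data.frame with `compartment`, `count`, `percent` (one decimal).
#' @export
compartment_summary <- function(labels, n_rrna = 0L) {
  cnt <- c(rRNA = n_rrna,
           known_gene = sum(labels == "known_gene"),
           unknown = sum(labels == "unknown"))
  tot <- sum(cnt)
  data.frame(compartment = names(cnt), count = as.integer(cnt),
             percent = if (tot == 0) rep(0, 3) else round(100 * cnt / tot, 1),
             row.names = NULL)
}

#' Write aligned blocks as BED6
#'
#' One line per block: chrom, 0-based start, end, read id, MAPQ as score,
#' strand.
#'
#' @param records An `alignment_records` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blocks_bed <- function(records, path) {
  flat <- unlist(records$blocks)
  idx <- rep(seq_len(n_records(records)), lengths(records$blocks))
  lines <- paste(records$meta$chrom[idx],
                 BiocGenerics::start(flat) - 1L,
                 BiocGenerics::end(flat),
                 records$meta$read_id[idx],
                 records$meta$mapq[idx],
                 records$meta$strand[idx], sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Pool the aligned blocks of one or more record sets
#'
#' @param ... `alignment_records` objects.
#' @return A [GenomicRanges::GRanges] of all blocks (not reduced).
#' @export
pool_blocks <- function(...) {
  grs <- unname(lapply(list(...), function(r) unlist(r$blocks)))
  do.call(c, grs)
}
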