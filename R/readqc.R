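# Raw-read trimming and filtering applied before any mapping: adapter
# removal (exact 3' suffix / adapter-prefix overlap), low-quality 3'-tail
# trimming, and a minimum-length filter with exact funnel accounting.

#' QC parameters
#'
#' @param adapter Adapter sequence to trim from read 3' ends.
#' @param min_overlap Minimum suffix/prefix overlap (bases) for an adapter
#'   match; must be >= 1.
#' @param quality_threshold Phred score below which trailing bases are
#'   trimmed.
#' @param min_length_after Minimum read length after trimming; shorter reads
#'   are removed. The default of 6 reflects libraries in which informative
#'   reads as short as 6 bases are retained.
#' @return An object of class `qc_params`.
#' @export
qc_params <- function(adapter = "AGATCGGAAGAGC", min_overlap = 5L,
                      quality_threshold = 15L, min_length_after = 6L) {
  stopifnot(min_overlap >= 1L, quality_threshold >= 0L, min_length_after >= 1L)
  structure(list(adapter = adapter, min_overlap = as.integer(min_overlap),
                 quality_threshold = as.integer(quality_threshold),
                 min_length_after = as.integer(min_length_after)),
            class = "qc_params")
}

# Length of the longest read suffix exactly matching an adapter prefix of
# length >= min_overlap; 0 if none. Vectorised over reads.
adapter_overlap_len <- function(seqs, adapter, min_overlap) {
  L <- nchar(seqs)
  best <- integer(length(seqs))
  kmax <- min(nchar(adapter), max(L, 0L))
  ks <- seq_len(kmax)
  ks <- ks[ks >= min_overlap]
  for (k in ks) {
    idx <- which(L >= k)
    if (length(idx) == 0L) next
    hit <- substring(seqs[idx], L[idx] - k + 1L, L[idx]) ==
      substr(adapter, 1L, k)
    best[idx][hit] <- k
  }
  best
}

#' Trim adapter read-through from read 3' ends
#'
#' Removes the longest read suffix that exactly matches a prefix of the
#' adapter of length at least `min_overlap`; reads without such an overlap
#' are returned unchanged.
#'
#' @param reads Read table (`read_id`, `seq`, `qual`).
#' @param params A [qc_params()].
#' @return The read table with trimmed `seq`/`qual` and a logical attribute
#'   per read in column `adapter_trimmed`.
#' @export
trim_adapter <- function(reads, params) {
  if (nrow(reads) == 0L) {
    reads$adapter_trimmed <- logical(0)
    return(reads)
  }
  k <- adapter_overlap_len(reads$seq, params$adapter, params$min_overlap)
  keep <- nchar(reads$seq) - k
  reads$seq <- substr(reads$seq, 1L, keep)
  reads$qual <- substr(reads$qual, 1L, keep)
  reads$adapter_trimmed <- k > 0L
  reads
}

#' Trim low-quality 3' tails
#'
#' Removes the maximal trailing run of bases whose Phred quality is below
#' `quality_threshold`.
#'
#' @inheritParams trim_adapter
#' @return The read table with trimmed `seq`/`qual` and a `quality_trimmed`
#'   logical column.
#' @export
trim_low_quality_tail <- function(reads, params) {
  if (nrow(reads) == 0L) {
    reads$quality_trimmed <- logical(0)
    return(reads)
  }
  stopifnot(all(nchar(reads$seq) == nchar(reads$qual)))
  thr <- params$quality_threshold
  qints <- phred_to_int(reads$qual)
  keep <- vapply(qints, function(q) {
    w <- which(q >= thr)
    if (length(w) == 0L) 0L else max(w)
  }, integer(1))
  reads$quality_trimmed <- keep < nchar(reads$seq)
  reads$seq <- substr(reads$seq, 1L, keep)
  reads$qual <- substr(reads$qual, 1L, keep)
  reads
}

#' Remove reads shorter than the minimum length
#'
#' @param reads Read table (already trimmed).
#' @param params A [qc_params()].
#' @return List with `kept` (read table) and `report` (a `qc_report`).
#' @export
filter_reads <- function(reads, params) {
  short <- nchar(reads$seq) < params$min_length_after
  report <- structure(list(
    input_reads = nrow(reads),
    adapter_trimmed = sum(reads$adapter_trimmed %||% logical(0)),
    quality_trimmed = sum(reads$quality_trimmed %||% logical(0)),
    signal_filtered = 0L,  # signal-level (raw-instrument) filters: no-op on FASTQ
    removed_short = sum(short),
    passed = sum(!short)), class = "qc_report")
  list(kept = reads[!short, , drop = FALSE], report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full read-QC stage
#'
#' Adapter trimming, low-quality-tail trimming, then the minimum-length
#' filter, with funnel accounting (`removed_short + passed = input_reads`).
#' Signal-level instrument filters (off-scale, polyclonal) cannot be
#' reproduced from FASTQ and are carried as an explicit zero-count stage in
#' the report.
#'
#' @param reads Read table (`read_id`, `seq`, `qual`).
#' @param params A [qc_params()].
#' @return List with `kept` and `report`.
#' @export
run_qc <- function(reads, params = qc_params()) {
  reads <- trim_adapter(reads, params)
  reads <- trim_low_quality_tail(reads, params)
  filter_reads(reads, params)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:\n")
  for (f in names(x)) cat("  ", f, ": ", x[[f]], "\n", sep = "")
  invisible(x)
}

#' Write a QC report as TSV
#' @param report A `qc_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path)
  write_tsv(data.frame(field = names(report),
                       count = unlist(report, use.names = FALSE)), path)
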