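# rRNA-first read partitioning. QC-passed reads are matched against a small
# rRNA reference set (28S/18S/5.8S/5S analogs) by an ungapped seed-and-extend
# matcher before anything is sent to the genome; rRNA fragments are
# contiguous sub-sequences of a subunit, so ungapped full-read placement is
# the model. Hits feed per-subunit density profiles and read-fraction
# summaries.

#' Index an rRNA reference set for ungapped matching
#'
#' Builds a hash of all seed-length k-mers of the forward subunit sequences,
#' plus raw-byte copies of the sequences for fast Hamming verification.
#'
#' @param refs A named [Biostrings::DNAStringSet] of rRNA subunit sequences,
#'   or a path to a FASTA file.
#' @param seed_length Seed k-mer length (default 12).
#' @return An object of class `rrna_index`.
#' @export
rrna_index <- function(refs, seed_length = 12L) {
  if (is.character(refs)) refs <- Biostrings::readDNAStringSet(refs)
  if (anyDuplicated(names(refs))) stop("rRNA subunit names must be unique")
  seqs <- as.character(refs)
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(seqs)) {
    L <- nchar(seqs[i])
    if (L < seed_length) next
    pos <- seq_len(L - seed_length + 1L)
    kmers <- substring(seqs[i], pos, pos + seed_length - 1L)
    for (j in seq_along(kmers)) {
      k <- kmers[j]
      prev <- get0(k, envir = env)
      assign(k, rbind(prev, c(i, pos[j])), envir = env)
    }
  }
  structure(list(names = names(refs), seqs = seqs,
                 raw = lapply(seqs, charToRaw),
                 lens = nchar(seqs), seed_length = as.integer(seed_length),
                 kmers = env),
            class = "rrna_index")
}

revcomp_chr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))

# Candidate full-read placements found via seed lookup (matrix ref|start),
# then Hamming-verified against max_mm. Returns matrix ref|start|mism.
seed_candidates <- function(seq_chr, rd, index, max_mm) {
  L <- length(rd)
  k <- index$seed_length
  offs <- 1L + (0:max_mm) * k
  offs <- offs[offs + k - 1L <= L]
  cand <- NULL
  for (o in offs) {
    hit <- get0(substr(seq_chr, o, o + k - 1L), envir = index$kmers)
    if (!is.null(hit))
      cand <- rbind(cand, cbind(hit[, 1], hit[, 2] - o + 1L))
  }
  if (is.null(cand)) return(NULL)
  cand <- unique(cand[cand[, 2] >= 1L &
                        cand[, 2] + L - 1L <= index$lens[cand[, 1]], ,
                      drop = FALSE])
  if (nrow(cand) == 0L) return(NULL)
  mism <- vapply(seq_len(nrow(cand)), function(i) {
    r <- index$raw[[cand[i, 1]]]
    sum(r[cand[i, 2]:(cand[i, 2] + L - 1L)] != rd)
  }, numeric(1))
  keep <- mism <= max_mm
  if (!any(keep)) return(NULL)
  cbind(cand[keep, , drop = FALSE], mism[keep])
}

# Fallback for reads too short for pigeonhole seeding: exhaustive all-offset
# scan through Biostrings' C mismatch counter.
scan_candidates <- function(seq_chr, index, max_mm) {
  L <- nchar(seq_chr)
  pat <- Biostrings::DNAString(seq_chr)
  out <- NULL
  for (i in seq_along(index$seqs)) {
    if (index$lens[i] < L) next
    starts <- seq_len(index$lens[i] - L + 1L)
    ed <- Biostrings::neditStartingAt(pat, Biostrings::DNAString(index$seqs[i]),
                                      starting.at = starts)
    hit <- which(ed <= max_mm)
    if (length(hit))
      out <- rbind(out, cbind(i, starts[hit], ed[hit]))
  }
  out
}

# Best placement of a read given both orientations as plain characters.
# Returns c(ref, start, mism, strand_code) (strand 1 = forward) or NULL.
match_rrna_core <- function(fwd, rev, index, max_mm, min_match_len) {
  L <- nchar(fwd)
  if (is.null(min_match_len)) min_match_len <- min(20L, L)
  if (L < min_match_len || L == 0L) return(NULL)
  use_seeds <- L >= (max_mm + 1L) * index$seed_length
  res <- NULL
  strands <- NULL
  for (sc in 1:2) {
    s <- if (sc == 1L) fwd else rev
    cand <- if (use_seeds) seed_candidates(s, charToRaw(s), index, max_mm)
    else scan_candidates(s, index, max_mm)
    if (!is.null(cand) && nrow(cand) > 0L) {
      res <- rbind(res, cand)
      strands <- c(strands, rep(sc, nrow(cand)))
    }
  }
  if (is.null(res)) return(NULL)
  # fewest mismatches, then (length constant) smallest subunit name, then
  # smallest start, forward orientation last tie-break
  o <- order(res[, 3], index$names[res[, 1]], res[, 2], strands)[1L]
  c(res[o, ], strands[o])
}

#' Match one read against the rRNA reference set
#'
#' Finds the best ungapped full-read placement within any subunit, in either
#' orientation, with at most `max_mismatches` substitutions. Seeds of the
#' seed length are taken at `max_mismatches + 1` disjoint offsets, so by
#' pigeonhole every qualifying placement of a read at least
#' `(max_mismatches + 1) * seed_length` bases long is found; shorter reads
#' fall back to an exhaustive all-offset scan. Ties are broken by fewest
#' mismatches, then longest match, then lexicographically smallest subunit
#' name, then smallest start, preferring the forward orientation.
#'
#' @param seq Read sequence (character scalar).
#' @param index An [rrna_index()].
#' @param max_mismatches Maximum substitutions allowed (default 2).
#' @param min_match_len Minimum read length to attempt matching; default
#'   `min(20, nchar(seq))`, i.e. reads of any length are attempted but a
#'   stricter floor can be imposed.
#' @return A one-row `data.frame` (`subunit`, `start` (1-based), `length`,
#'   `mismatches`, `strand`) or `NULL` if no qualifying placement exists.
#' @export
match_rrna <- function(seq, index, max_mismatches = 2L, min_match_len = NULL) {
  hit <- match_rrna_core(seq, revcomp_chr(seq), index, max_mismatches,
                         min_match_len)
  if (is.null(hit)) return(NULL)
  data.frame(subunit = index$names[hit[1]], start = as.integer(hit[2]),
             length = nchar(seq), mismatches = as.integer(hit[3]),
             strand = c("+", "-")[hit[4]], stringsAsFactors = FALSE)
}

#' Partition a library into rRNA and remainder
#'
#' Every read is matched against the rRNA reference; reads with a qualifying
#' hit form the rRNA partition (with their hits), all others the remainder
#' that proceeds to genome alignment. Exact conservation:
#' `nrow(hits) + nrow(remainder) = nrow(reads)`.
#'
#' @param reads Read table (`read_id`, `seq`, ...).
#' @param index An [rrna_index()].
#' @param max_mismatches,min_match_len Passed to [match_rrna()].
#' @return List with `hits` (data.frame `read_id`, `subunit`, `start`,
#'   `length`, `mismatches`, `strand`) and `remainder` (subset of `reads`).
#' @export
partition_library <- function(reads, index, max_mismatches = 2L,
                              min_match_len = NULL) {
  empty_hits <- data.frame(read_id = character(0), subunit = character(0),
                           start = integer(0), length = integer(0),
                           mismatches = integer(0), strand = character(0),
                           stringsAsFactors = FALSE)
  if (nrow(reads) == 0L) return(list(hits = empty_hits, remainder = reads))
  rc <- revcomp_chr(reads$seq)
  hl <- lapply(seq_len(nrow(reads)), function(i)
    match_rrna_core(reads$seq[i], rc[i], index, max_mismatches,
                    min_match_len))
  is_hit <- !vapply(hl, is.null, logical(1))
  hits <- if (any(is_hit)) {
    hm <- do.call(rbind, hl[is_hit])
    data.frame(read_id = reads$read_id[is_hit],
               subunit = index$names[hm[, 1]],
               start = as.integer(hm[, 2]),
               length = nchar(reads$seq[is_hit]),
               mismatches = as.integer(hm[, 3]),
               strand = c("+", "-")[hm[, 4]],
               stringsAsFactors = FALSE)
  } else empty_hits
  list(hits = hits, remainder = reads[!is_hit, , drop = FALSE])
}

#' Per-base read density over one rRNA subunit
#'
#' `depth[i]` is the number of hits whose placement interval contains base
#' `i`; the sum of depths equals the summed matched lengths of the hits.
#'
#' @param hits Hit table from [partition_library()] (or [match_rrna()] rows).
#' @param subunit Subunit name.
#' @param subunit_length Length of the subunit in bases.
#' @return Integer vector of length `subunit_length`.
#' @export
density_profile <- function(hits, subunit, subunit_length) {
  h <- hits[hits$subunit == subunit, , drop = FALSE]
  if (nrow(h) > 0 && (any(h$start < 1) ||
                      any(h$start + h$length - 1L > subunit_length)))
    stop("hit outside subunit ", subunit)
  ir <- IRanges::IRanges(h$start, width = h$length)
  as.integer(IRanges::coverage(ir, width = subunit_length))
}

#' Fraction of rRNA reads per subunit
#'
#' @param hits Hit table.
#' @return Named numeric vector of fractions summing to 1 (empty for no
#'   hits).
#' @export
subunit_read_fractions <- function(hits) {
  if (nrow(hits) == 0L) return(stats::setNames(numeric(0), character(0)))
  tab <- table(hits$subunit)
  stats::setNames(as.numeric(tab) / sum(tab), names(tab))
}

#' Density profiles for all subunits as a long table
#'
#' @param hits Hit table.
#' @param index The [rrna_index()] used for matching (provides lengths).
#' @return data.frame with `subunit`, `position` (1-based), `depth`.
#' @export
density_table <- function(hits, index) {
  do.call(rbind, lapply(seq_along(index$names), function(i) {
    data.frame(subunit = index$names[i],
               position = seq_len(index$lens[i]),
               depth = density_profile(hits, index$names[i], index$lens[i]),
               stringsAsFactors = FALSE)
  }))
}
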