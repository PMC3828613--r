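# Shared fixtures: a toy reference built once per test run, plus small
# constructors for models and alignment records.

toy_ref <- build_reference(default_toy_reference_spec(seed = 42))
toy_idx <- rrna_index(toy_ref$rrna)

`%or%` <- function(a, b) if (is.null(a)) b else a

gr_blocks <- function(starts, ends)
  GenomicRanges::GRanges(rep("chrT", length(starts)),
                         IRanges::IRanges(starts, ends))

# Single-transcript model set from plain interval matrices.
make_tx_models <- function(exons, cds = NULL,
                           biotype = if (is.null(cds)) "lincRNA"
                           else "protein_coding",
                           strand = "+", id = "TX1", gene = "G1") {
  tx <- data.frame(transcript_id = id, gene_id = gene, gene_name = gene,
                   biotype = biotype, strand = strand, chrom = "chrT",
                   stringsAsFactors = FALSE)
  ex <- GenomicRanges::GRangesList(GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(exons[, 1], exons[, 2]), strand = strand))
  names(ex) <- id
  cd <- GenomicRanges::GRangesList(if (is.null(cds)) GenomicRanges::GRanges()
                                   else GenomicRanges::GRanges(
                                     "chrT", IRanges::IRanges(cds[, 1], cds[, 2]),
                                     strand = strand))
  names(cd) <- id
  transcript_models(tx, ex, cd)
}

# alignment_records from a list of per-record specs:
# list(id=, starts=, ends=, mapq=, mult=, strand=)
make_records <- function(specs) {
  grl <- GenomicRanges::GRangesList(lapply(specs, function(r)
    GenomicRanges::GRanges(r$chrom %or% "chrT",
                           IRanges::IRanges(r$starts, r$ends),
                           strand = r$strand %or% "+")))
  alignment_records(
    read_id = vapply(specs, function(r) r$id, character(1)),
    chrom = vapply(specs, function(r) r$chrom %or% "chrT", character(1)),
    strand = vapply(specs, function(r) r$strand %or% "+", character(1)),
    mapq = vapply(specs, function(r) as.integer(r$mapq %or% 60L), integer(1)),
    multiplicity = vapply(specs, function(r) as.integer(r$mult %or% 1L),
                          integer(1)),
    blocks = grl)
}

# Minimal SAM writer for load_alignments tests.
write_test_sam <- function(records, path, chrom = "chrT", chrom_len = 100000L) {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", chrom, "\tLN:", chrom_len))
  writeLines(c(header, records), path)
  path
}

sam_line <- function(qname, pos, cigar, mapq = 60L, flag = 0L, nh = NULL,
                     chrom = "chrT") {
  qlen <- sum(as.integer(
    regmatches(cigar, gregexpr("\\d+(?=[MIS=X])", cigar, perl = TRUE))[[1]]))
  base <- paste(qname, flag, chrom, pos, mapq, cigar, "*", 0L, 0L,
                strrep("A", max(qlen, 1L)), strrep("I", max(qlen, 1L)),
                sep = "\t")
  if (!is.null(nh)) base <- paste0(base, "\tNH:i:", nh)
  base
}
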