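# Transcript models: identity, biotype and exon/CDS structure of every
# annotated isoform. This is the annotation container consumed by the
# compartment, coverage-detection and quantification stages.

#' Construct a transcript model set
#'
#' @param tx A `data.frame` with one row per transcript and columns
#'   `transcript_id`, `gene_id`, `gene_name`, `biotype`, `strand`, `chrom`.
#' @param exons A named [GenomicRanges::GRangesList] of exon intervals
#'   (1-based, closed), one element per transcript, names matching
#'   `tx$transcript_id`. Intervals must be disjoint within a transcript.
#' @param cds A named `GRangesList` of CDS intervals, parallel to `exons`;
#'   zero-length elements for non-coding transcripts. Every CDS base must lie
#'   within the transcript's exons, and a transcript is coding
#'   (biotype `protein_coding`) if and only if its CDS is non-empty.
#' @return An object of class `transcript_models`.
#' @export
transcript_models <- function(tx, exons, cds) {
  req <- c("transcript_id", "gene_id", "gene_name", "biotype", "strand", "chrom")
  stopifnot(is.data.frame(tx), all(req %in% names(tx)))
  if (anyDuplicated(tx$transcript_id))
    stop("duplicated transcript_id in model table")
  if (!setequal(names(exons), tx$transcript_id) ||
      !setequal(names(cds), tx$transcript_id))
    stop("exons/cds names must match tx$transcript_id")
  if (nrow(tx) > 0L) {
    exons <- exons[tx$transcript_id]
    cds <- cds[tx$transcript_id]
  }
  for (i in seq_len(nrow(tx))) {
    id <- tx$transcript_id[i]
    ex <- IRanges::ranges(exons[[id]])
    if (length(ex) == 0L) stop("transcript ", id, " has no exons")
    if (any(diff(BiocGenerics::start(ex)) <= 0) && length(ex) > 1L)
      if (is.unsorted(BiocGenerics::start(ex))) stop("exons of ", id, " not sorted")
    if (length(IRanges::reduce(ex)) != length(ex) &&
        sum(BiocGenerics::width(IRanges::reduce(ex))) != sum(BiocGenerics::width(ex)))
      stop("exons of ", id, " overlap")
    cd <- IRanges::ranges(cds[[id]])
    coding <- tx$biotype[i] == "protein_coding"
    if (coding != (length(cd) > 0L))
      stop("transcript ", id, ": CDS must be non-empty iff biotype is protein_coding")
    if (length(cd) > 0L) {
      outside <- IRanges::setdiff(cd, ex)
      if (sum(BiocGenerics::width(outside)) > 0L)
        stop("CDS of ", id, " extends outside its exons")
    }
  }
  structure(list(tx = tx, exons = exons, cds = cds), class = "transcript_models")
}

#' @export
print.transcript_models <- function(x, ...) {
  cat("transcript_models:", nrow(x$tx), "transcripts,",
      length(unique(x$tx$gene_id)), "genes\n")
  print(table(x$tx$biotype))
  invisible(x)
}

#' Number of transcripts in a model set
#' @param models A `transcript_models` object.
#' @return Integer count.
#' @export
n_transcripts <- function(models) nrow(models$tx)

# Exon union (reduced ranges) of one transcript.
exon_union <- function(models, transcript_id)
  IRanges::reduce(IRanges::ranges(models$exons[[transcript_id]]))

cds_union <- function(models, transcript_id)
  IRanges::reduce(IRanges::ranges(models$cds[[transcript_id]]))

# Spliced (mature) transcript length in bases.
transcript_length <- function(models, transcript_id)
  sum(BiocGenerics::width(exon_union(models, transcript_id)))

models_to_granges <- function(models) {
  rows <- lapply(seq_len(nrow(models$tx)), function(i) {
    t <- models$tx[i, ]
    ex <- models$exons[[t$transcript_id]]
    feats <- GenomicRanges::GRanges(t$chrom, IRanges::ranges(ex), strand = t$strand)
    feats$type <- "exon"
    feats$phase <- NA_integer_
    cd <- models$cds[[t$transcript_id]]
    if (length(cd) > 0L) {
      cdg <- GenomicRanges::GRanges(t$chrom, IRanges::ranges(cd), strand = t$strand)
      cdg$type <- "CDS"
      w <- BiocGenerics::width(cdg)
      if (t$strand == "-") w <- rev(w)
      ph <- (3L - cumsum(c(0L, w[-length(w)])) %% 3L) %% 3L
      cdg$phase <- if (t$strand == "-") rev(ph) else ph
      feats <- c(feats, cdg)
    }
    feats$gene_id <- t$gene_id
    feats$transcript_id <- t$transcript_id
    feats$gene_name <- t$gene_name
    feats$gene_type <- t$biotype
    feats
  })
  do.call(c, rows)
}

#' Write transcript models to a GTF file
#'
#' Emits exon and CDS features with `gene_id`, `transcript_id`, `gene_name`
#' and `gene_type` attributes (1-based inclusive coordinates on disk).
#'
#' @param models A `transcript_models` object.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_gtf_models <- function(models, path) {
  gr <- models_to_granges(models)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read transcript models from a GTF file
#'
#' Exon and CDS features are collected per `transcript_id`; the biotype is
#' taken from the `gene_type` (or `gene_biotype`) attribute and the symbol
#' from `gene_name` (falling back to `gene_id`).
#'
#' @param path GTF path.
#' @return A `transcript_models` object.
#' @export
read_gtf_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type %in% c("exon", "CDS")]
  bio <- if (!is.null(gr$gene_type)) gr$gene_type else gr$gene_biotype
  if (is.null(bio)) stop("GTF lacks gene_type/gene_biotype attributes")
  sym <- if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id
  ids <- unique(gr$transcript_id)
  tx <- do.call(rbind, lapply(ids, function(id) {
    g <- gr[gr$transcript_id == id]
    data.frame(transcript_id = id, gene_id = g$gene_id[1],
               gene_name = sym[match(id, gr$transcript_id)],
               biotype = bio[match(id, gr$transcript_id)],
               strand = as.character(BiocGenerics::strand(g))[1],
               chrom = as.character(GenomicRanges::seqnames(g))[1],
               stringsAsFactors = FALSE)
  }))
  exons <- GenomicRanges::GRangesList(lapply(ids, function(id) {
    BiocGenerics::sort(gr[gr$transcript_id == id & gr$type == "exon"])
  }))
  names(exons) <- ids
  cds <- GenomicRanges::GRangesList(lapply(ids, function(id) {
    BiocGenerics::sort(gr[gr$transcript_id == id & gr$type == "CDS"])
  }))
  names(cds) <- ids
  transcript_models(tx, exons, cds)
}
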