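# Synthetic data: a toy reference (genome + rRNA set + annotation) and
# simulated read libraries with per-read ground truth. Exosome-like libraries
# are dominated by fragmented rRNA tiling the full subunit length; cell-like
# libraries carry a moderate rRNA load and a broad transcript mix. Every
# downstream stage of the package can be exercised on these outputs alone.

#' Specify a toy reference
#'
#' @param chromosome_length Length in bases of the single toy chromosome.
#' @param rrna_lengths Named integer vector of rRNA subunit lengths; names are
#'   the subunit analogs (default `28S`, `18S`, `5.8S`, `5S`). Names must be
#'   unique.
#' @param gene_specs List of gene descriptions. Each element is a list with
#'   `gene_id`, `gene_name`, `biotype`, `strand` and `isoforms`, the latter a
#'   named list mapping transcript ids to lists with an `exons` two-column
#'   matrix (start, end; 1-based closed) and an optional `cds` matrix (NULL or
#'   absent for non-coding isoforms).
#' @param seed Integer seed controlling the generated sequences.
#' @return An object of class `toy_reference_spec`.
#' @export
toy_reference_spec <- function(chromosome_length,
                               rrna_lengths = c("28S" = 1900L, "18S" = 900L,
                                                "5.8S" = 160L, "5S" = 120L),
                               gene_specs = list(),
                               seed = 1L) {
  stopifnot_scalar(chromosome_length, "chromosome_length")
  if (anyDuplicated(names(rrna_lengths))) stop("rRNA subunit names must be unique")
  structure(list(chromosome_length = as.integer(chromosome_length),
                 rrna_lengths = rrna_lengths,
                 gene_specs = gene_specs,
                 seed = as.integer(seed)),
            class = "toy_reference_spec")
}

#' Default toy gene set
#'
#' Ten genes on the toy chromosome: four multi- or single-exon protein-coding
#' genes (one with two isoforms), and six non-coding genes spanning the small
#' non-coding biotypes most abundant in exosomal libraries (snoRNA, snRNA,
#' miRNA, Mt_tRNA, lincRNA, misc non-coding).
#'
#' @return A list of gene specifications for [toy_reference_spec()].
#' @export
default_gene_specs <- function() {
  ex <- function(...) matrix(c(...), ncol = 2, byrow = TRUE,
                             dimnames = list(NULL, c("start", "end")))
  list(
    list(gene_id = "g_coda", gene_name = "CODA", biotype = "protein_coding",
         strand = "+", isoforms = list(
           "CODA-201" = list(exons = ex(2001, 2600, 3401, 3900, 4701, 5200),
                             cds = ex(2201, 2600, 3401, 3900, 4701, 5000)),
           "CODA-202" = list(exons = ex(2001, 2600, 4701, 5200),
                             cds = ex(2201, 2600, 4701, 5000)))),
    list(gene_id = "g_codb", gene_name = "CODB", biotype = "protein_coding",
         strand = "-", isoforms = list(
           "CODB-201" = list(exons = ex(8001, 8900, 9501, 10300),
                             cds = ex(8101, 8900, 9501, 10200)))),
    list(gene_id = "g_codc", gene_name = "CODC", biotype = "protein_coding",
         strand = "+", isoforms = list(
           "CODC-201" = list(exons = ex(13001, 14800),
                             cds = ex(13101, 14600)))),
    list(gene_id = "g_codd", gene_name = "CODD", biotype = "protein_coding",
         strand = "+", isoforms = list(
           "CODD-201" = list(exons = ex(18001, 18700, 19301, 19900),
                             cds = ex(18101, 18700, 19301, 19800)))),
    list(gene_id = "g_sno1", gene_name = "SNORD-T1", biotype = "snoRNA",
         strand = "+", isoforms = list(
           "SNORD-T1-201" = list(exons = ex(23001, 23150)))),
    list(gene_id = "g_snrn", gene_name = "RNU-T1", biotype = "snRNA",
         strand = "-", isoforms = list(
           "RNU-T1-201" = list(exons = ex(26001, 26180)))),
    list(gene_id = "g_mir", gene_name = "MIR-T1", biotype = "miRNA",
         strand = "+", isoforms = list(
           "MIR-T1-201" = list(exons = ex(29001, 29100)))),
    list(gene_id = "g_mttr", gene_name = "MT-TT1", biotype = "Mt_tRNA",
         strand = "+", isoforms = list(
           "MT-TT1-201" = list(exons = ex(32001, 32072)))),
    list(gene_id = "g_linc", gene_name = "LINC-T1", biotype = "lincRNA",
         strand = "-", isoforms = list(
           "LINC-T1-201" = list(exons = ex(35001, 35600, 36401, 36900)))),
    list(gene_id = "g_misc", gene_name = "NCR-T1", biotype = "non_coding",
         strand = "+", isoforms = list(
           "NCR-T1-201" = list(exons = ex(40001, 40500))))
  )
}

#' Default toy reference specification
#' @param seed Integer seed.
#' @return A `toy_reference_spec` with a 60 kb chromosome, four rRNA subunit
#'   analogs and the [default_gene_specs()] gene set.
#' @export
default_toy_reference_spec <- function(seed = 1L)
  toy_reference_spec(60000L, gene_specs = default_gene_specs(), seed = seed)

gene_specs_to_models <- function(gene_specs, chrom, chrom_len) {
  if (length(gene_specs) == 0L) {
    empty <- data.frame(transcript_id = character(0), gene_id = character(0),
                        gene_name = character(0), biotype = character(0),
                        strand = character(0), chrom = character(0),
                        stringsAsFactors = FALSE)
    return(transcript_models(empty, GenomicRanges::GRangesList(),
                             GenomicRanges::GRangesList()))
  }
  tx <- list(); exons <- list(); cds <- list()
  for (g in gene_specs) {
    for (tid in names(g$isoforms)) {
      iso <- g$isoforms[[tid]]
      exm <- iso$exons
      if (any(exm < 1) || any(exm > chrom_len))
        stop("exons of ", tid, " fall outside the chromosome")
      ir <- IRanges::IRanges(exm[, 1], exm[, 2])
      if (is.unsorted(BiocGenerics::start(ir)) ||
          sum(BiocGenerics::width(IRanges::reduce(ir))) != sum(BiocGenerics::width(ir)))
        stop("exons of ", tid, " must be sorted and non-overlapping")
      tx[[tid]] <- data.frame(transcript_id = tid, gene_id = g$gene_id,
                              gene_name = g$gene_name, biotype = g$biotype,
                              strand = g$strand, chrom = chrom,
                              stringsAsFactors = FALSE)
      exons[[tid]] <- GenomicRanges::GRanges(chrom, ir, strand = g$strand)
      cdm <- iso$cds
      cds[[tid]] <- if (is.null(cdm)) GenomicRanges::GRanges() else
        GenomicRanges::GRanges(chrom, IRanges::IRanges(cdm[, 1], cdm[, 2]),
                               strand = g$strand)
    }
  }
  # reject distinct genes sharing an identical exon structure on one strand:
  # their simulated reads would have ambiguous truth
  sig <- vapply(names(exons), function(tid) {
    ir <- IRanges::ranges(exons[[tid]])
    paste(tx[[tid]]$strand,
          paste(BiocGenerics::start(ir), BiocGenerics::end(ir),
                sep = "-", collapse = ","))
  }, character(1))
  txdf <- do.call(rbind, tx)
  for (s in unique(sig[duplicated(sig)])) {
    ids <- names(sig)[sig == s]
    if (length(unique(txdf$gene_id[match(ids, txdf$transcript_id)])) > 1L)
      stop("genes ", paste(unique(txdf$gene_id[match(ids, txdf$transcript_id)]),
                           collapse = ", "),
           " share an identical exon structure on the same strand")
  }
  transcript_models(txdf,
                    GenomicRanges::GRangesList(exons),
                    GenomicRanges::GRangesList(cds))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

#' Build a toy reference from a specification
#'
#' The chromosome is i.i.d. uniform A/C/G/T background with gene loci defined
#' purely by annotation intervals on it; rRNA subunit sequences are generated
#' independently of the genome, mirroring the use of a separate rRNA
#' reference in the analysis. Deterministic given the spec's seed.
#'
#' @param spec A [toy_reference_spec()].
#' @return An object of class `toy_reference`: list with `genome` and `rrna`
#'   ([Biostrings::DNAStringSet]), `models` (`transcript_models`), `chrom`
#'   and the originating `spec`.
#' @export
build_reference <- function(spec) {
  stopifnot(inherits(spec, "toy_reference_spec"))
  chrom <- "chrT"
  models <- gene_specs_to_models(spec$gene_specs, chrom, spec$chromosome_length)
  with_seed(spec$seed, {
    genome_seq <- random_dna(spec$chromosome_length)
    rrna_seqs <- vapply(spec$rrna_lengths, random_dna, character(1))
  })
  genome <- Biostrings::DNAStringSet(genome_seq)
  names(genome) <- chrom
  rrna <- Biostrings::DNAStringSet(rrna_seqs)
  names(rrna) <- names(spec$rrna_lengths)
  structure(list(genome = genome, rrna = rrna, models = models,
                 chrom = chrom, spec = spec),
            class = "toy_reference")
}

#' Write a toy reference to disk
#'
#' Emits `genome.fa`, `rrna.fa` (FASTA) and `annotation.gtf`.
#'
#' @param reference A `toy_reference`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_reference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             rrna = file.path(dir, "rrna.fa"),
             annotation = file.path(dir, "annotation.gtf"))
  Biostrings::writeXStringSet(reference$genome, paths["genome"])
  Biostrings::writeXStringSet(reference$rrna, paths["rrna"])
  write_gtf_models(reference$models, paths["annotation"])
  invisible(paths)
}

#' Describe a read library to simulate
#'
#' @param n_reads Number of reads.
#' @param rrna_fraction Probability that a read originates from an rRNA
#'   subunit fragment, in `[0, 1]`.
#' @param transcript_abundances Named non-negative weights over transcript
#'   ids; at least one must be positive. Relative weights of the non-rRNA,
#'   non-intergenic read mass.
#' @param fragment_length_range Two integers, the uniform range of fragment
#'   lengths in bases (fragments from a source shorter than the sampled
#'   length are truncated to the source length).
#' @param intergenic_fraction Probability that a read originates from an
#'   intergenic genome position (outside every annotated exon).
#' @param rrna_weights Named weights over rRNA subunits.
#' @param spliced_allowed If `FALSE`, transcript fragments are confined to a
#'   single exon instead of the spliced transcript.
#' @param quality_model Named vector `c(mean_q=, tail_len=)`: constant Phred
#'   quality with an exponentially decaying 3' tail of `tail_len` bases.
#' @param adapter Adapter sequence appended (in full) to a fraction of reads.
#' @param adapter_rate Proportion of reads receiving the adapter.
#' @param error_rate Uniform substitution error rate per base.
#' @return An object of class `library_profile`.
#' @export
library_profile <- function(n_reads,
                            rrna_fraction,
                            transcript_abundances,
                            fragment_length_range = c(30L, 500L),
                            intergenic_fraction = 0,
                            rrna_weights = c("28S" = 5, "18S" = 4,
                                             "5.8S" = 0.5, "5S" = 0.5),
                            spliced_allowed = TRUE,
                            quality_model = c(mean_q = 36, tail_len = 5),
                            adapter = "AGATCGGAAGAGC",
                            adapter_rate = 0.15,
                            error_rate = 0) {
  if (rrna_fraction < 0 || rrna_fraction > 1)
    stop("rrna_fraction must lie in [0, 1]")
  if (intergenic_fraction < 0 || rrna_fraction + intergenic_fraction > 1)
    stop("rrna_fraction + intergenic_fraction must not exceed 1")
  if (fragment_length_range[1] > fragment_length_range[2])
    stop("fragment_length_range must be (min, max) with min <= max")
  if (any(transcript_abundances < 0) || !any(transcript_abundances > 0))
    stop("transcript_abundances must be non-negative with at least one positive")
  structure(list(n_reads = as.integer(n_reads),
                 rrna_fraction = rrna_fraction,
                 transcript_abundances = transcript_abundances,
                 fragment_length_range = as.integer(fragment_length_range),
                 intergenic_fraction = intergenic_fraction,
                 rrna_weights = rrna_weights,
                 spliced_allowed = isTRUE(spliced_allowed),
                 quality_model = quality_model,
                 adapter = adapter,
                 adapter_rate = adapter_rate,
                 error_rate = error_rate),
            class = "library_profile")
}

#' Default exosome-like library profile
#'
#' 97% of reads are rRNA fragments; only ~2% fall in annotated transcripts,
#' split between a few coding and small non-coding genes — the regime of a
#' fragmented-rRNA-dominated extracellular-vesicle library.
#'
#' @param n_reads Number of reads (default 20000).
#' @return A `library_profile`.
#' @export
exosome_profile <- function(n_reads = 20000L) {
  library_profile(
    n_reads = n_reads, rrna_fraction = 0.97, intergenic_fraction = 0.01,
    transcript_abundances = c("CODC-201" = 2, "CODB-201" = 1.5, "CODA-201" = 1,
                              "SNORD-T1-201" = 2, "RNU-T1-201" = 1.2,
                              "MT-TT1-201" = 1, "MIR-T1-201" = 0.8,
                              "CODA-202" = 0, "CODD-201" = 0,
                              "LINC-T1-201" = 0, "NCR-T1-201" = 0))
}

#' Default cell-like library profile
#'
#' 24% rRNA, a broad transcript mix (~58% of reads in annotated genes) and an
#' intergenic component, emulating an rRNA-depleted cellular library.
#'
#' @param n_reads Number of reads (default 20000).
#' @return A `library_profile`.
#' @export
cell_profile <- function(n_reads = 20000L) {
  library_profile(
    n_reads = n_reads, rrna_fraction = 0.24, intergenic_fraction = 0.18,
    transcript_abundances = c("CODA-201" = 3, "CODA-202" = 1, "CODB-201" = 2.5,
                              "CODC-201" = 2, "SNORD-T1-201" = 0.5,
                              "RNU-T1-201" = 0.3, "MIR-T1-201" = 0.15,
                              "MT-TT1-201" = 0.1, "LINC-T1-201" = 0.4,
                              "CODD-201" = 0, "NCR-T1-201" = 0))
}

# Spliced transcript sequence (transcript orientation).
tx_spliced_seq <- function(reference, transcript_id) {
  models <- reference$models
  ir <- IRanges::ranges(models$exons[[transcript_id]])
  parts <- as.character(Biostrings::extractAt(reference$genome[[1]], ir))
  s <- paste(parts, collapse = "")
  if (models$tx$strand[models$tx$transcript_id == transcript_id] == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

# Map a spliced-coordinate interval [s, e] (transcript orientation, 1-based)
# to genomic blocks (IRanges, genomic order).
spliced_to_blocks <- function(exons_ir, strand, s, e) {
  w <- BiocGenerics::width(exons_ir)
  gs <- BiocGenerics::start(exons_ir)
  ge <- BiocGenerics::end(exons_ir)
  ord <- if (strand == "-") rev(seq_along(w)) else seq_along(w)
  w <- w[ord]; gs <- gs[ord]; ge <- ge[ord]
  cum <- cumsum(w)
  first <- findInterval(s - 1L, cum) + 1L
  last <- findInterval(e - 1L, cum) + 1L
  starts <- integer(0); ends <- integer(0)
  for (j in first:last) {
    lo <- if (j == 1L) 0L else cum[j - 1L]
    a <- max(s, lo + 1L) - lo   # 1-based offset within exon j (tx orientation)
    b <- min(e, cum[j]) - lo
    if (strand == "+") {
      starts <- c(starts, gs[j] + a - 1L); ends <- c(ends, gs[j] + b - 1L)
    } else {
      starts <- c(starts, ge[j] - b + 1L); ends <- c(ends, ge[j] - a + 1L)
    }
  }
  o <- order(starts)
  IRanges::IRanges(starts[o], ends[o])
}

quality_string <- function(len, mean_q, tail_len) {
  q <- rep(as.integer(mean_q), len)
  d <- min(tail_len, len)
  if (d > 0 && tail_len > 0) {
    t <- seq_len(d)
    q[(len - d + 1):len] <- pmax(2L, as.integer(round(
      mean_q * exp(-t / max(1, tail_len / 2)))))
  }
  intToUtf8(q + 33L)
}

apply_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    n <- nchar(s)
    k <- stats::rbinom(1L, n, rate)
    if (k == 0L) return(s)
    pos <- sample.int(n, k)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate a read library with ground truth
#'
#' Each read is drawn by first choosing its origin class (rRNA with the
#' profile's `rrna_fraction`, intergenic with `intergenic_fraction`,
#' otherwise transcript), then a source weighted by the class weights, then a
#' fragment position uniform over the source. rRNA fragments therefore tile
#' the full subunit length in expectation. One truth record is emitted per
#' read.
#'
#' @param profile A [library_profile()].
#' @param reference A `toy_reference` from [build_reference()].
#' @param seed Integer seed.
#' @return An object of class `sim_library`: list with `reads` (data.frame
#'   `read_id`, `seq`, `qual`), `truth` (one row per read: `read_id`,
#'   `origin_class`, `origin_name`, `origin_start`, `origin_end`, `strand`,
#'   `fragment_length`) and `truth_blocks` (genomic blocks of transcript and
#'   intergenic reads: `read_id`, `start`, `end`).
#' @export
simulate_library <- function(profile, reference, seed = 1L) {
  stopifnot(inherits(profile, "library_profile"),
            inherits(reference, "toy_reference"))
  models <- reference$models
  ab <- profile$transcript_abundances
  missing_ids <- setdiff(names(ab), models$tx$transcript_id)
  if (length(missing_ids) > 0L)
    stop("transcript ids absent from the annotation: ",
         paste(missing_ids, collapse = ", "))
  frmin <- profile$fragment_length_range[1]
  frmax <- profile$fragment_length_range[2]
  rrna_len <- BiocGenerics::width(reference$rrna)
  names(rrna_len) <- names(reference$rrna)
  tx_pos <- names(ab)[ab > 0]
  tx_len <- vapply(tx_pos, function(id) transcript_length(models, id), integer(1))
  src_len <- c(if (profile$rrna_fraction > 0) rrna_len,
               if (length(tx_pos) > 0 &&
                   profile$rrna_fraction + profile$intergenic_fraction < 1) tx_len)
  if (length(src_len) > 0 && all(src_len < frmin))
    stop("minimum fragment length ", frmin,
         " exceeds the length of every source: ",
         paste(names(src_len), collapse = ", "))

  n <- profile$n_reads
  with_seed(seed, {
    u <- stats::runif(n)
    cls <- ifelse(u < profile$rrna_fraction, "rRNA",
                  ifelse(u < profile$rrna_fraction + profile$intergenic_fraction,
                         "intergenic", "transcript"))
    origin <- character(n)
    i_r <- which(cls == "rRNA")
    if (length(i_r))
      origin[i_r] <- sample(names(profile$rrna_weights), length(i_r),
                            replace = TRUE, prob = profile$rrna_weights)
    i_t <- which(cls == "transcript")
    if (length(i_t)) {
      if (length(tx_pos) == 0L) stop("no transcript has positive abundance")
      origin[i_t] <- sample(tx_pos, length(i_t), replace = TRUE,
                            prob = ab[tx_pos])
    }
    i_g <- which(cls == "intergenic")
    fraglen <- frmin + as.integer(floor(stats::runif(n) * (frmax - frmin + 1L)))

    seqs <- character(n)
    o_start <- integer(n); o_end <- integer(n)
    strands <- rep("+", n)
    blocks <- vector("list", n)

    # rRNA fragments: forward-sense substrings of the subunit
    if (length(i_r)) {
      rseq <- as.character(reference$rrna)
      for (sub in unique(origin[i_r])) {
        idx <- i_r[origin[i_r] == sub]
        L <- rrna_len[[sub]]
        fl <- pmin(fraglen[idx], L)
        st <- 1L + as.integer(floor(stats::runif(length(idx)) * (L - fl + 1L)))
        seqs[idx] <- substring(rseq[[sub]], st, st + fl - 1L)
        o_start[idx] <- st; o_end[idx] <- st + fl - 1L
        fraglen[idx] <- fl
      }
    }

    # transcript fragments: substrings of the spliced sequence, projected
    # back to genomic blocks for the truth record
    if (length(i_t)) {
      for (id in unique(origin[i_t])) {
        idx <- i_t[origin[i_t] == id]
        strand <- models$tx$strand[models$tx$transcript_id == id]
        sp <- tx_spliced_seq(reference, id)
        exir <- IRanges::ranges(models$exons[[id]])
        if (profile$spliced_allowed || length(exir) == 1L) {
          L <- nchar(sp)
          fl <- pmin(fraglen[idx], L)
          st <- 1L + as.integer(floor(stats::runif(length(idx)) * (L - fl + 1L)))
        } else {
          # unspliced-only: fragment confined to a single exon
          wts <- BiocGenerics::width(exir)
          exch <- sample(seq_along(wts), length(idx), replace = TRUE, prob = wts)
          cum <- c(0L, cumsum(if (strand == "-") rev(wts) else wts))
          pos_in_tx <- if (strand == "-") match(exch, rev(seq_along(wts))) else exch
          fl <- pmin(fraglen[idx], wts[exch])
          off <- as.integer(floor(stats::runif(length(idx)) * (wts[exch] - fl + 1L)))
          st <- cum[pos_in_tx] + 1L + off
        }
        seqs[idx] <- substring(sp, st, st + fl - 1L)
        o_start[idx] <- st; o_end[idx] <- st + fl - 1L
        strands[idx] <- strand
        fraglen[idx] <- fl
        for (k in seq_along(idx))
          blocks[[idx[k]]] <- spliced_to_blocks(exir, strand, st[k], st[k] + fl[k] - 1L)
      }
    }

    # intergenic fragments: uniform over gaps between annotated exons
    if (length(i_g)) {
      allex <- IRanges::reduce(IRanges::ranges(unlist(models$exons)))
      gapir <- IRanges::gaps(allex, start = 1L,
                             end = reference$spec$chromosome_length)
      gseq <- as.character(reference$genome[[1]])
      gw <- BiocGenerics::width(gapir)
      for (k in i_g) {
        fl <- min(fraglen[k], max(gw))
        ok <- which(gw >= fl)
        gi <- ok[sample.int(length(ok), 1L, prob = gw[ok] - fl + 1L)]
        st <- BiocGenerics::start(gapir)[gi] +
          as.integer(floor(stats::runif(1) * (gw[gi] - fl + 1L)))
        seqs[k] <- substring(gseq, st, st + fl - 1L)
        o_start[k] <- st; o_end[k] <- st + fl - 1L
        fraglen[k] <- fl
        blocks[[k]] <- IRanges::IRanges(st, st + fl - 1L)
      }
    }

    seqs <- apply_substitutions(seqs, profile$error_rate)

    # adapter read-through, then qualities over the full emitted length
    has_ad <- nchar(profile$adapter) > 0 &
      stats::runif(n) < profile$adapter_rate
    out_seq <- ifelse(has_ad, paste0(seqs, profile$adapter), seqs)
    quals <- vapply(nchar(out_seq), quality_string, character(1),
                    mean_q = profile$quality_model[["mean_q"]],
                    tail_len = profile$quality_model[["tail_len"]])
  })

  read_id <- sprintf("read%06d", seq_len(n))
  truth <- data.frame(read_id = read_id, origin_class = cls,
                      origin_name = ifelse(cls == "intergenic",
                                           reference$chrom, origin),
                      origin_start = o_start, origin_end = o_end,
                      strand = strands, fragment_length = fraglen,
                      stringsAsFactors = FALSE)
  has_blocks <- !vapply(blocks, is.null, logical(1))
  truth_blocks <- if (any(has_blocks)) {
    nb <- vapply(blocks[has_blocks], length, integer(1))
    data.frame(read_id = rep(read_id[has_blocks], nb),
               start = unlist(lapply(blocks[has_blocks], BiocGenerics::start)),
               end = unlist(lapply(blocks[has_blocks], BiocGenerics::end)),
               stringsAsFactors = FALSE)
  } else data.frame(read_id = character(0), start = integer(0), end = integer(0))
  structure(list(reads = data.frame(read_id = read_id, seq = out_seq,
                                    qual = quals, stringsAsFactors = FALSE),
                 truth = truth, truth_blocks = truth_blocks,
                 profile = profile, seed = seed),
            class = "sim_library")
}

#' @export
print.sim_library <- function(x, ...) {
  cat("sim_library:", nrow(x$reads), "reads\n")
  print(table(x$truth$origin_class))
  invisible(x)
}

blocks_to_cigar <- function(starts, ends) {
  w <- ends - starts + 1L
  if (length(w) == 1L) return(paste0(w, "M"))
  gaps <- starts[-1] - ends[-length(ends)] - 1L
  paste0(paste0(w[-length(w)], "M", gaps, "N", collapse = ""),
         w[length(w)], "M")
}

#' Write ground-truth alignments to SAM
#'
#' Transcript and intergenic reads are written as mapped records with
#' N-gapped CIGARs spanning introns; the SEQ field is the genome-forward
#' fragment sequence reconstructed from the truth blocks (minus-strand
#' origins get FLAG 16). rRNA-origin reads are emitted unmapped to the
#' genome: they are the business of the rRNA partition stage, not the genome
#' aligner. This lets every downstream stage run without an external aligner.
#'
#' @param sim A `sim_library`.
#' @param reference The `toy_reference` the library was simulated from.
#' @param path Output SAM path.
#' @param mapq Mapping quality assigned to mapped records (default 60).
#' @return `path`, invisibly.
#' @export
emit_truth_alignments <- function(sim, reference, path, mapq = 60L) {
  chrom_len <- reference$spec$chromosome_length
  tb <- sim$truth_blocks
  if (nrow(tb) > 0 && (any(tb$start < 1) || any(tb$end > chrom_len)))
    stop("truth blocks fall outside the reference chromosome")
  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", reference$chrom, "\tLN:", chrom_len))
  gseq <- as.character(reference$genome[[1]])
  lines <- character(0)
  mapped <- sim$truth$origin_class %in% c("transcript", "intergenic")
  if (any(mapped)) {
    sp <- split(tb, tb$read_id)
    ids <- sim$truth$read_id[mapped]
    recs <- vapply(seq_along(ids), function(i) {
      id <- ids[i]
      b <- sp[[id]]
      b <- b[order(b$start), , drop = FALSE]
      seq <- paste(substring(gseq, b$start, b$end), collapse = "")
      strand <- sim$truth$strand[mapped][i]
      paste(id, if (strand == "-") 16L else 0L, reference$chrom, b$start[1],
            mapq, blocks_to_cigar(b$start, b$end), "*", 0L, 0L,
            seq, strrep("I", nchar(seq)), "NH:i:1", sep = "\t")
    }, character(1))
    lines <- c(lines, recs)
  }
  unm <- which(!mapped)
  if (length(unm) > 0) {
    recs <- paste(sim$truth$read_id[unm], 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                  sim$reads$seq[unm], sim$reads$qual[unm], sep = "\t")
    lines <- c(lines, recs)
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Write a simulated library to disk
#'
#' Emits `reads.fastq`, `truth.tsv`, `truth_blocks.tsv` and `truth.sam`.
#'
#' @param sim A `sim_library`.
#' @param reference The originating `toy_reference`.
#' @param dir Output directory.
#' @return Named character vector of paths, invisibly.
#' @export
write_library <- function(sim, reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(reads = file.path(dir, "reads.fastq"),
             truth = file.path(dir, "truth.tsv"),
             truth_blocks = file.path(dir, "truth_blocks.tsv"),
             sam = file.path(dir, "truth.sam"))
  write_fastq(sim$reads, paths["reads"])
  write_tsv(sim$truth, paths["truth"])
  write_tsv(sim$truth_blocks, paths["truth_blocks"])
  emit_truth_alignments(sim, reference, paths["sam"])
  invisible(paths)
}
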