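test_that("degenerate spec: no genes, one rRNA subunit", {
  spec <- toy_reference_spec(5000L, rrna_lengths = c("18S" = 200L),
                             gene_specs = list(), seed = 3)
  ref <- build_reference(spec)
  expect_equal(BiocGenerics::width(ref$genome), 5000L, ignore_attr = TRUE)
  expect_equal(length(ref$rrna), 1L)
  expect_equal(BiocGenerics::width(ref$rrna), 200L, ignore_attr = TRUE)
  expect_equal(n_transcripts(ref$models), 0L)
})

test_that("reference construction is deterministic given the seed", {
  r1 <- build_reference(default_toy_reference_spec(seed = 9))
  r2 <- build_reference(default_toy_reference_spec(seed = 9))
  expect_identical(as.character(r1$genome), as.character(r2$genome))
  expect_identical(as.character(r1$rrna), as.character(r2$rrna))
  r3 <- build_reference(default_toy_reference_spec(seed = 10))
  expect_false(identical(as.character(r1$genome), as.character(r3$genome)))
})

test_that("two-isoform gene yields two transcript records sharing gene_id, each with CDS", {
  m <- toy_ref$models
  iso <- m$tx[m$tx$gene_id == "g_coda", ]
  expect_equal(nrow(iso), 2L)
  expect_setequal(iso$transcript_id, c("CODA-201", "CODA-202"))
  expect_true(all(iso$biotype == "protein_coding"))
  expect_true(all(lengths(m$cds[iso$transcript_id]) > 0))
})

test_that("genes sharing an identical exon structure on one strand are rejected", {
  ex <- matrix(c(100, 200), ncol = 2)
  dup <- list(
    list(gene_id = "gA", gene_name = "A", biotype = "lincRNA", strand = "+",
         isoforms = list(A1 = list(exons = ex))),
    list(gene_id = "gB", gene_name = "B", biotype = "snoRNA", strand = "+",
         isoforms = list(B1 = list(exons = ex))))
  expect_error(build_reference(toy_reference_spec(1000L, gene_specs = dup)),
               "identical exon structure")
})

test_that("GTF round trip preserves the annotation", {
  path <- tempfile(fileext = ".gtf")
  write_gtf_models(toy_ref$models, path)
  back <- read_gtf_models(path)
  expect_setequal(back$tx$transcript_id, toy_ref$models$tx$transcript_id)
  for (id in toy_ref$models$tx$transcript_id) {
    expect_equal(IRanges::ranges(back$exons[[id]]),
                 IRanges::ranges(toy_ref$models$exons[[id]]))
    expect_equal(sum(BiocGenerics::width(back$cds[[id]])),
                 sum(BiocGenerics::width(toy_ref$models$cds[[id]])))
  }
  i <- match(toy_ref$models$tx$transcript_id, back$tx$transcript_id)
  expect_equal(back$tx$biotype[i], toy_ref$models$tx$biotype)
  expect_equal(back$tx$strand[i], toy_ref$models$tx$strand)
})

test_that("origin-class boundaries: all-rRNA and zero-weight sources", {
  prof <- library_profile(n_reads = 10L, rrna_fraction = 1,
                          transcript_abundances = c("CODC-201" = 1))
  sim <- simulate_library(prof, toy_ref, seed = 5)
  expect_true(all(sim$truth$origin_class == "rRNA"))

  prof2 <- library_profile(n_reads = 300L, rrna_fraction = 0,
                           transcript_abundances = c("CODC-201" = 1,
                                                     "CODB-201" = 0),
                           adapter_rate = 0)
  sim2 <- simulate_library(prof2, toy_ref, seed = 5)
  expect_true(all(sim2$truth$origin_name == "CODC-201"))
})

test_that("read/truth conservation and library determinism", {
  prof <- exosome_profile(500L)
  sim <- simulate_library(prof, toy_ref, seed = 21)
  expect_equal(nrow(sim$reads), 500L)
  expect_equal(nrow(sim$truth), 500L)
  expect_identical(sim$reads$read_id, sim$truth$read_id)

  d1 <- tempfile(); d2 <- tempfile()
  write_library(sim, toy_ref, d1)
  write_library(simulate_library(prof, toy_ref, seed = 21), toy_ref, d2)
  for (f in c("reads.fastq", "truth.tsv", "truth.sam"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  d3 <- tempfile()
  write_library(simulate_library(prof, toy_ref, seed = 22), toy_ref, d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "reads.fastq"))),
                         unname(tools::md5sum(file.path(d3, "reads.fastq")))))
})

test_that("empirical class fractions recover the profile within 3 binomial SD", {
  n <- 100000L
  prof <- library_profile(n_reads = n, rrna_fraction = 0.97,
                          transcript_abundances = c("CODC-201" = 1),
                          adapter_rate = 0)
  sim <- simulate_library(prof, toy_ref, seed = 13)
  k <- sum(sim$truth$origin_class == "rRNA")
  expect_lt(abs(k - n * 0.97), 3 * sqrt(n * 0.97 * 0.03))
})

test_that("rRNA fragments tile the full subunit length", {
  sim <- simulate_library(exosome_profile(20000L), toy_ref, seed = 31)
  rt <- sim$truth[sim$truth$origin_class == "rRNA", ]
  for (sub in names(toy_ref$rrna)) {
    h <- rt[rt$origin_name == sub, ]
    depth <- as.integer(IRanges::coverage(
      IRanges::IRanges(h$origin_start, h$origin_end),
      width = BiocGenerics::width(toy_ref$rrna)[names(toy_ref$rrna) == sub]))
    expect_gt(min(depth), 0)
  }
})

test_that("fragment range exceeding every source length is an error", {
  prof <- library_profile(n_reads = 10L, rrna_fraction = 0,
                          transcript_abundances = c("MT-TT1-201" = 1),
                          fragment_length_range = c(500L, 600L),
                          adapter_rate = 0)
  expect_error(simulate_library(prof, toy_ref, seed = 1),
               "MT-TT1-201")
})

test_that("unknown transcript ids in the profile are rejected", {
  prof <- library_profile(n_reads = 10L, rrna_fraction = 0,
                          transcript_abundances = c("NOPE-1" = 1))
  expect_error(simulate_library(prof, toy_ref, seed = 1), "NOPE-1")
})

test_that("truth SAM uses N-gapped CIGARs for spliced reads and plain M otherwise", {
  prof <- library_profile(n_reads = 400L, rrna_fraction = 0,
                          intergenic_fraction = 0.3,
                          transcript_abundances = c("CODB-201" = 1),
                          fragment_length_range = c(150L, 400L),
                          adapter_rate = 0)
  sim <- simulate_library(prof, toy_ref, seed = 17)
  path <- tempfile(fileext = ".sam")
  emit_truth_alignments(sim, toy_ref, path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  cig <- vapply(strsplit(body, "\t"), `[[`, character(1), 6L)
  ids <- vapply(strsplit(body, "\t"), `[[`, character(1), 1L)
  # CODB-201 exons are separated by a 600-base intron
  spliced <- grepl("N", cig)
  expect_true(any(spliced))
  expect_true(all(grepl("600N", cig[spliced])))
  nb <- table(sim$truth_blocks$read_id)
  expect_setequal(ids[spliced], names(nb)[nb == 2])
  inter <- sim$truth$read_id[sim$truth$origin_class == "intergenic"]
  expect_true(all(grepl("^\\d+M$", cig[ids %in% inter])))
})

test_that("an empty truth set yields a header-only SAM that loads as empty", {
  prof <- library_profile(n_reads = 0L, rrna_fraction = 0.5,
                          transcript_abundances = c("CODC-201" = 1))
  sim <- simulate_library(prof, toy_ref, seed = 1)
  path <- tempfile(fileext = ".sam")
  emit_truth_alignments(sim, toy_ref, path)
  expect_true(all(startsWith(readLines(path), "@")))
  expect_equal(n_records(load_alignments(path)), 0L)
})

test_that("truth blocks of transcript reads lie within their transcript's exons", {
  prof <- cell_profile(1500L)
  sim <- simulate_library(prof, toy_ref, seed = 8)
  tr <- sim$truth[sim$truth$origin_class == "transcript", ]
  tb <- sim$truth_blocks
  for (id in unique(tr$origin_name)) {
    ex <- exon_union(toy_ref$models, id)
    b <- tb[tb$read_id %in% tr$read_id[tr$origin_name == id], ]
    out <- IRanges::setdiff(IRanges::IRanges(b$start, b$end), ex)
    expect_equal(sum(BiocGenerics::width(out)), 0L)
  }
  # fragment lengths respect the profile range
  expect_true(all(sim$truth$fragment_length >= 30 |
                    sim$truth$fragment_length ==
                    pmin(sim$truth$fragment_length, 30)))
  expect_true(all(sim$truth$fragment_length <= 500))
})
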