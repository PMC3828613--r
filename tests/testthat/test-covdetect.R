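test_that("coverage is interval set arithmetic: union, not sum", {
  models <- make_tx_models(matrix(c(50, 400), ncol = 2),
                           cds = matrix(c(101, 200), ncol = 2))
  cov <- transcript_coverage(gr_blocks(101, 191), models, "TX1")
  expect_equal(cov$target, "CDS")
  expect_equal(cov$covered, 91L)
  expect_equal(cov$fraction, 0.91)

  none <- transcript_coverage(gr_blocks(integer(0), integer(0)), models, "TX1")
  expect_equal(none$fraction, 0)

  over <- transcript_coverage(gr_blocks(c(101, 141), c(150, 200)),
                              models, "TX1")
  expect_equal(over$covered, 100L)
  expect_equal(over$fraction, 1.0)

  expect_error(
    transcript_coverage(gr_blocks(1, 10),
                        make_tx_models(matrix(c(50, 400), ncol = 2)),
                        "TX1", target = "CDS"),
    "non-coding")
})

test_that("union coverage equals a per-base boolean oracle on random fixtures", {
  set.seed(404)
  for (i in 1:200) {
    len <- 10000L
    n_ex <- sample(1:5, 1)
    starts <- sort(sample(seq(1, len - 400, by = 200), n_ex))
    ends <- starts + sample(50:180, n_ex, replace = TRUE)
    coding <- stats::runif(1) < 0.5
    cds <- if (coding) cbind(starts + 5, ends - 5) else NULL
    models <- make_tx_models(cbind(starts, ends), cds = cds)
    nb <- sample(0:12, 1)
    bs <- if (nb > 0) sample(seq_len(len - 200), nb) else integer(0)
    be <- bs + sample(20:150, max(nb, 1), replace = TRUE)[seq_len(nb)]
    blocks <- gr_blocks(bs, be)
    got <- transcript_coverage(blocks, models, "TX1")
    tgt <- if (coding) cds else cbind(starts, ends)
    want <- oracle_coverage_fraction(bs, be, tgt[, 1], tgt[, 2], len + 200L)
    expect_equal(got$fraction, want, label = paste("fixture", i))
  }
})

test_that("coverage is monotone in added blocks and pooling dominates samples", {
  set.seed(505)
  models <- make_tx_models(matrix(c(100, 1200), ncol = 2),
                           cds = matrix(c(150, 1100), ncol = 2))
  bs <- sample(100:1100, 30); be <- bs + 40
  f_prev <- 0
  for (k in seq(5, 30, by = 5)) {
    f <- transcript_coverage(gr_blocks(bs[1:k], be[1:k]), models, "TX1")$fraction
    expect_gte(f, f_prev)
    f_prev <- f
  }
  a <- gr_blocks(bs[1:10], be[1:10])
  b <- gr_blocks(bs[11:25], be[11:25])
  fa <- transcript_coverage(a, models, "TX1")$fraction
  fb <- transcript_coverage(b, models, "TX1")$fraction
  fp <- transcript_coverage(c(a, b), models, "TX1")$fraction
  expect_gte(fp, max(fa, fb))
})

test_that("cellular rule detects strictly over 90% coverage", {
  cov <- data.frame(transcript_id = c("a", "b", "c"),
                    fraction = c(0.91, 0.22, 0.9))
  calls <- detect_cellular(cov)
  expect_equal(calls$detected, c(TRUE, FALSE, FALSE))
  expect_true(all(calls$rule == "cellular_90"))
})

test_that("exosomal rule is pooled > 90% AND per-sample > 50%", {
  pooled <- data.frame(transcript_id = "t", fraction = 0.92)
  calls <- detect_exosomal(pooled, list(
    s1 = data.frame(transcript_id = "t", fraction = 0.6),
    s2 = data.frame(transcript_id = "t", fraction = 0.3)))
  expect_equal(calls$detected[calls$sample == "s1"], TRUE)
  expect_equal(calls$detected[calls$sample == "s2"], FALSE)

  gate <- detect_exosomal(data.frame(transcript_id = "t", fraction = 0.85),
                          list(s1 = data.frame(transcript_id = "t",
                                               fraction = 0.8),
                               s2 = data.frame(transcript_id = "t",
                                               fraction = 0.8)))
  expect_false(any(gate$detected))

  both <- detect_exosomal(data.frame(transcript_id = "t", fraction = 1.0),
                          list(s1 = data.frame(transcript_id = "t",
                                               fraction = 0.51),
                               s2 = data.frame(transcript_id = "t",
                                               fraction = 0.51)))
  expect_true(all(both$detected))

  expect_error(detect_exosomal(
    data.frame(transcript_id = "t", fraction = 0.4),
    list(s1 = data.frame(transcript_id = "t", fraction = 0.6))), "pool")
})

test_that("gene detection is any-isoform with max coverage governing", {
  m <- toy_ref$models
  calls <- data.frame(transcript_id = m$tx$transcript_id,
                      fraction = 0, detected = FALSE)
  calls$fraction[calls$transcript_id == "CODA-201"] <- 0.95
  calls$detected[calls$transcript_id == "CODA-201"] <- TRUE
  calls$fraction[calls$transcript_id == "CODA-202"] <- 0.2
  genes <- gene_level_detect(calls, m)
  expect_equal(genes$gene_id, "g_coda")
  expect_equal(genes$max_fraction, 0.95)
  expect_equal(genes$biotype, "protein_coding")

  none <- gene_level_detect(transform(calls, detected = FALSE), m)
  expect_equal(nrow(none), 0L)

  # max over isoforms equals a brute-force max
  calls$fraction[calls$transcript_id == "CODA-202"] <- 0.97
  calls$detected[calls$transcript_id == "CODA-202"] <- TRUE
  g2 <- gene_level_detect(calls, m)
  expect_equal(g2$max_fraction,
               max(calls$fraction[calls$transcript_id %in%
                                    c("CODA-201", "CODA-202")]))
})

test_that("conflicting non-coding biotypes in one gene warn and take the smallest", {
  tx <- data.frame(transcript_id = c("t1", "t2"), gene_id = "g",
                   gene_name = "G", biotype = c("snoRNA", "lincRNA"),
                   strand = "+", chrom = "chrT", stringsAsFactors = FALSE)
  ex <- GenomicRanges::GRangesList(
    GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 100)),
    GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 200)))
  names(ex) <- c("t1", "t2")
  cd <- GenomicRanges::GRangesList(GenomicRanges::GRanges(),
                                   GenomicRanges::GRanges())
  names(cd) <- c("t1", "t2")
  m <- transcript_models(tx, ex, cd)
  calls <- data.frame(transcript_id = c("t1", "t2"), fraction = c(0.95, 0.99),
                      detected = TRUE)
  expect_warning(g <- gene_level_detect(calls, m), "conflicting")
  expect_equal(nrow(g), 1L)
  expect_equal(g$biotype, "lincRNA")
})

test_that("biotype percentages reproduce printed detected-gene splits", {
  mk_genes <- function(nc, nn) data.frame(
    gene_id = sprintf("g%d", seq_len(nc + nn)),
    gene_name = sprintf("G%d", seq_len(nc + nn)),
    biotype = c(rep("protein_coding", nc), rep("snoRNA", nn)))
  t1 <- biotype_summary(list(cellular = mk_genes(3115, 317)))
  expect_equal(t1$cellular, c(90.8, 9.2))
  expect_equal(biotype_summary(list(s = mk_genes(1, 0)))$s, c(100.0, 0.0))
  expect_equal(biotype_summary(list(s = mk_genes(50, 50)))$s, c(50.0, 50.0))
})

test_that("non-coding biotype counts are unique gene symbols, sorted by first sample", {
  gs <- list(
    cellular = data.frame(gene_id = sprintf("g%d", 1:6),
                          gene_name = sprintf("G%d", 1:6),
                          biotype = c("snoRNA", "snoRNA", "snRNA", "miRNA",
                                      "protein_coding", "snoRNA")),
    exo = data.frame(gene_id = "g1", gene_name = "G1", biotype = "snoRNA"))
  t2 <- noncoding_biotype_counts(gs)
  expect_equal(t2$gene_type[1], "snoRNA")
  expect_equal(t2$cellular, c(3L, 1L, 1L))
  expect_equal(t2$exo, c(1L, 0L, 0L))
})

test_that("set overlaps: identical, disjoint, and subset cases", {
  idn <- overlap_sets(list(cell = c("a", "b"), exo = c("a", "b")),
                      cellular = "cell")
  expect_equal(idn$pairwise$intersection, 2L)
  expect_equal(idn$percent_in_cellular$percent, 100)

  dis <- overlap_sets(list(cell = c("a", "b"), exo = c("c", "d")),
                      cellular = "cell")
  expect_equal(dis$pairwise$intersection, 0L)
  expect_equal(dis$percent_in_cellular$percent, 0)

  sub <- overlap_sets(list(cell = c("a", "b", "c", "d"),
                           e1 = c("a", "b", "c"),
                           e2 = c("a", "d")), cellular = "cell")
  expect_equal(sub$three_way, 1L)  # {a}
  expect_equal(sub$percent_in_cellular$percent, c(100, 100))
  pw <- sub$pairwise
  expect_equal(pw$intersection[pw$set_a == "e1" & pw$set_b == "e2"], 1L)
})
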