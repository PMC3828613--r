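# Two-isoform model sharing exon1/exon3; isoform B lacks the middle exon.
two_iso_models <- function() {
  tx <- data.frame(transcript_id = c("A", "B"), gene_id = "g",
                   gene_name = "G", biotype = "protein_coding",
                   strand = "+", chrom = "chrT", stringsAsFactors = FALSE)
  exA <- GenomicRanges::GRanges("chrT", IRanges::IRanges(
    c(101, 301, 501), c(200, 400, 600)))
  exB <- GenomicRanges::GRanges("chrT", IRanges::IRanges(
    c(101, 501), c(200, 600)))
  ex <- GenomicRanges::GRangesList(A = exA, B = exB)
  cds <- GenomicRanges::GRangesList(
    A = GenomicRanges::GRanges("chrT", IRanges::IRanges(
      c(111, 301, 501), c(200, 400, 590))),
    B = GenomicRanges::GRanges("chrT", IRanges::IRanges(
      c(111, 501), c(200, 590))))
  transcript_models(tx, ex, cds)
}

test_that("compatibility honours exon containment and junction matching", {
  m <- two_iso_models()
  rec <- make_records(list(
    list(id = "shared", starts = 120L, ends = 170L),              # exon 1
    list(id = "juncA", starts = c(180L, 301L), ends = c(200L, 330L)),
    list(id = "juncB", starts = c(180L, 501L), ends = c(200L, 530L)),
    list(id = "middle", starts = 320L, ends = 360L),              # exon 2 only
    list(id = "intronic", starts = 250L, ends = 280L)))
  cm <- build_compatibility(rec, m, tolerance = 0L)
  expect_equal(cm$n_dropped, 1L)  # the intronic read fits no isoform
  expect_false("intronic" %in% cm$read_ids)
  g <- function(id) cm$compat[cm$read_ids == id, ]
  expect_equal(unname(g("shared")), c(TRUE, TRUE))
  expect_equal(unname(g("juncA")), c(TRUE, FALSE))
  expect_equal(unname(g("juncB")), c(FALSE, TRUE))
  expect_equal(unname(g("middle")), c(TRUE, FALSE))
})

test_that("junction tolerance admits slightly shifted junctions", {
  m <- two_iso_models()
  rec <- make_records(list(
    list(id = "off1", starts = c(180L, 302L), ends = c(200L, 330L))))
  expect_equal(build_compatibility(rec, m, tolerance = 0L)$n_dropped, 1L)
  cm <- build_compatibility(rec, m, tolerance = 2L)
  expect_equal(unname(cm$compat[1, ]), c(TRUE, FALSE))
})

test_that("EM closed forms: single isoform, decoupled counts, worked fixed point", {
  m1 <- list(compat = matrix(TRUE, 7, 1, dimnames = list(NULL, "A")),
             effective_length = c(A = 1000L), read_ids = sprintf("r%d", 1:7),
             n_dropped = 0L)
  class(m1) <- "compatibility_matrix"
  est <- em_abundance(m1)
  expect_equal(est$theta, 1)
  expect_equal(est$mass, 7)

  # no ambiguity: masses equal unique counts exactly
  cmp <- rbind(matrix(c(TRUE, FALSE), 5, 2, byrow = TRUE),
               matrix(c(FALSE, TRUE), 3, 2, byrow = TRUE))
  colnames(cmp) <- c("A", "B")
  m2 <- structure(list(compat = cmp, effective_length = c(A = 500L, B = 800L),
                       read_ids = sprintf("r%d", 1:8), n_dropped = 0L),
                  class = "compatibility_matrix")
  est2 <- em_abundance(m2)
  expect_equal(est2$mass, c(5, 3), tolerance = 1e-9)

  # 30 unique A + 10 unique B + 60 ambiguous, equal lengths -> 75 / 25
  cmp3 <- rbind(matrix(c(TRUE, FALSE), 30, 2, byrow = TRUE),
                matrix(c(FALSE, TRUE), 10, 2, byrow = TRUE),
                matrix(TRUE, 60, 2))
  colnames(cmp3) <- c("A", "B")
  m3 <- structure(list(compat = cmp3,
                       effective_length = c(A = 1000L, B = 1000L),
                       read_ids = sprintf("r%d", 1:100), n_dropped = 0L),
                  class = "compatibility_matrix")
  est3 <- em_abundance(m3, tol = 1e-12)
  expect_equal(est3$mass, c(75, 25), tolerance = 1e-6)
  expect_equal(sum(est3$theta), 1)
})

test_that("EM conserves read mass and increases the likelihood every iteration", {
  set.seed(606)
  for (rep in 1:20) {
    n <- sample(20:150, 1)
    m <- sample(2:3, 1)
    cmp <- matrix(stats::runif(n * m) < 0.6, n, m)
    cmp[rowSums(cmp) == 0, sample(m, 1)] <- TRUE
    colnames(cmp) <- LETTERS[seq_len(m)]
    lens <- sample(200:2000, m)
    names(lens) <- colnames(cmp)
    cm <- structure(list(compat = cmp, effective_length = lens,
                         read_ids = sprintf("r%d", seq_len(n)), n_dropped = 0L),
                    class = "compatibility_matrix")
    est <- em_abundance(cm)
    expect_equal(sum(est$mass), n, tolerance = 1e-9)
    ll <- attr(est, "loglik")
    expect_true(all(diff(ll) >= -1e-9))
  }
})

test_that("isoforms with no compatible reads get zero mass, not an error", {
  cmp <- matrix(c(TRUE, FALSE), 4, 2, byrow = TRUE,
                dimnames = list(NULL, c("A", "B")))
  cm <- structure(list(compat = cmp, effective_length = c(A = 100L, B = 100L),
                       read_ids = sprintf("r%d", 1:4), n_dropped = 0L),
                  class = "compatibility_matrix")
  est <- em_abundance(cm)
  expect_equal(est$mass[est$transcript_id == "B"], 0)
  expect_equal(est$theta[est$transcript_id == "B"], 0)
})

test_that("EM matches the exhaustive simplex grid-search oracle", {
  fixtures <- list(
    list(pat = rbind(c(TRUE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE)),
         counts = c(30, 10, 60), len = c(1000, 1000)),
    list(pat = rbind(c(TRUE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE)),
         counts = c(50, 20, 30), len = c(500, 1500)),
    list(pat = rbind(c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE),
                     c(FALSE, FALSE, TRUE), c(TRUE, TRUE, FALSE),
                     c(FALSE, TRUE, TRUE)),
         counts = c(40, 25, 15, 70, 50), len = c(800, 1200, 400)),
    list(pat = rbind(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE),
                     c(TRUE, TRUE, TRUE)),
         counts = c(80, 60, 60), len = c(1000, 1000, 1000)))
  for (i in seq_along(fixtures)) {
    fx <- fixtures[[i]]
    expect_lte(sum(fx$counts), 200)
    cmp <- fx$pat[rep(seq_len(nrow(fx$pat)), fx$counts), , drop = FALSE]
    colnames(cmp) <- LETTERS[seq_len(ncol(cmp))]
    lens <- fx$len; names(lens) <- colnames(cmp)
    cm <- structure(list(compat = cmp, effective_length = lens,
                         read_ids = sprintf("r%d", seq_len(nrow(cmp))),
                         n_dropped = 0L), class = "compatibility_matrix")
    est <- em_abundance(cm, tol = 1e-10)
    want <- oracle_em_grid(fx$pat, fx$counts, fx$len, step = 0.001)
    expect_equal(est$theta, as.numeric(want), tolerance = 0.005,
                 label = paste("fixture", i))
  }
})

test_that("RPKM follows the definitional formula and its invariances", {
  expect_equal(rpkm(10, 1000, 1e6), 10.0)
  expect_equal(rpkm(0, 1000, 1e6), 0.0)
  expect_equal(rpkm(20, 1000, 2e6), rpkm(10, 1000, 1e6))
  expect_error(rpkm(10, 1000, 0), "positive")
  expect_error(rpkm(10, 0, 1e6), "positive")
})

test_that("RPKM detection is strict in at least one sample", {
  est <- list(
    s1 = data.frame(transcript_id = c("a", "b", "c"), rpkm = c(1.01, 1.0, 0.2)),
    s2 = data.frame(transcript_id = c("a", "b", "c"), rpkm = c(0.0, 1.0, 0.9)))
  expect_equal(rpkm_detect(est), "a")
})

test_that("few reads on a short transcript pass RPKM but fail coverage", {
  models <- make_tx_models(matrix(c(1001, 2800), ncol = 2),
                           cds = matrix(c(1101, 2600), ncol = 2))
  rec <- make_records(lapply(1:4, function(i)
    list(id = sprintf("r%d", i), starts = 1101L + (i - 1L) * 40L,
         ends = 1200L + (i - 1L) * 40L)))
  est <- quantify_sample(rec, models, total_mapped = 1e5)
  cov <- transcript_coverage(unlist(rec$blocks), models, "TX1")
  expect_lt(cov$fraction, 0.9)          # rejected by the coverage rule
  expect_gt(est$rpkm, 1.0)              # retained by the RPKM rule
})

test_that("EM recovers simulated isoform proportions within 0.05 at 5000 reads", {
  w <- c("CODA-201" = 0.3, "CODA-202" = 0.2, "CODB-201" = 0.2,
         "CODC-201" = 0.2, "SNORD-T1-201" = 0.05, "LINC-T1-201" = 0.05)
  prof <- library_profile(n_reads = 5000L, rrna_fraction = 0,
                          transcript_abundances = w, adapter_rate = 0)
  sim <- simulate_library(prof, toy_ref, seed = 55)
  sam <- tempfile(fileext = ".sam")
  emit_truth_alignments(sim, toy_ref, sam)
  rec <- load_alignments(sam)
  cm <- build_compatibility(rec, toy_ref$models)
  expect_equal(nrow(cm$compat), 5000L)
  est <- em_abundance(cm)
  got <- est$theta[match(names(w), est$transcript_id)]
  expect_lt(max(abs(got - w)), 0.05)
})
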