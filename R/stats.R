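# Enrichment and validation statistics: EASE-adjusted one-sided Fisher
# (hypergeometric) test with Benjamini-Hochberg correction, Wilcoxon
# rank-sum comparison of expression distributions, and 2^-ddCt relative
# quantification for qPCR validation.

#' EASE-adjusted one-sided Fisher test
#'
#' The conservative variant of the one-sided Fisher exact test used for
#' gene-set enrichment: the list-hit count is reduced by one before the
#' hypergeometric upper tail is computed, i.e. the p-value is
#' `P(X >= k - 1)` for `X ~ Hypergeom(N, K, n)`. `k = 0` or `k = 1` gives
#' `p = 1`.
#'
#' @param k List hits (genes of the list in the category).
#' @param n List size.
#' @param K Background hits (category size in the universe).
#' @param N Universe size.
#' @return The EASE p-value.
#' @export
ease_fisher <- function(k, n, K, N) {
  if (k < 0 || n < 0 || K < 0 || N < 0 || k > min(n, K) || n > N || K > N)
    stop("invalid 2x2 table bounds: need 0 <= k <= min(n, K), n <= N, K <= N")
  if (k <= 1) return(1)
  # P(X >= k - 1) = 1 - P(X <= k - 2)
  stats::phyper(k - 2, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_i = min_{j >= rank(i)} (m * p_(j) / j)` clipped at 1, returned in the
#' input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Category enrichment of a gene list
#'
#' Categories with fewer than `min_count` list hits are excluded before
#' testing; EASE p-values are computed for the surviving categories and
#' Benjamini-Hochberg adjusted across them. Genes absent from the universe
#' are dropped with a warning.
#'
#' @param genes Character vector of gene symbols (the list).
#' @param annotation data.frame with columns `category_id`, `category_name`,
#'   `gene`: category membership over the universe.
#' @param universe Background gene universe; defaults to all genes in the
#'   annotation.
#' @param min_count Minimum list hits for a category to be tested
#'   (default 5).
#' @param ease_cutoff EASE p-value below which a category is reported
#'   (default 0.1).
#' @param q_cutoff Adjusted-q threshold for the strongly-enriched set
#'   (default 0.05; strict).
#' @return data.frame per tested category: `category_id`, `category_name`,
#'   `k`, `n`, `K`, `N`, `p`, `q`, `reported`, `significant`, ordered by
#'   `p`.
#' @export
enrich_categories <- function(genes, annotation, universe = NULL,
                              min_count = 5L, ease_cutoff = 0.1,
                              q_cutoff = 0.05) {
  if (is.null(universe)) universe <- unique(annotation$gene)
  if (length(universe) == 0L) stop("empty gene universe")
  outside <- setdiff(genes, universe)
  if (length(outside) > 0L) {
    warning(length(outside), " gene(s) outside the universe dropped")
    genes <- intersect(genes, universe)
  }
  genes <- unique(genes)
  N <- length(universe)
  n <- length(genes)
  empty <- data.frame(category_id = character(0), category_name = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p = numeric(0), q = numeric(0),
                      reported = logical(0), significant = logical(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  ann <- annotation[annotation$gene %in% universe, , drop = FALSE]
  cats <- split(ann, ann$category_id)
  rows <- lapply(cats, function(a) {
    members <- unique(a$gene)
    k <- length(intersect(genes, members))
    if (k < min_count) return(NULL)
    data.frame(category_id = a$category_id[1],
               category_name = a$category_name[1],
               k = k, n = n, K = length(members), N = N,
               p = ease_fisher(k, n, length(members), N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$reported <- out$p <= ease_cutoff
  out$significant <- out$q < q_cutoff
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Wilcoxon rank-sum test
#'
#' Rank-sum statistic with midranks for ties. The p-value is exact (full
#' enumeration of rank assignments) when the pooled sample size is at most
#' 12 and there are no ties, and otherwise uses the normal approximation
#' with tie correction and continuity correction.
#'
#' @param a,b Numeric samples (both non-empty).
#' @param exact_max Pooled size up to which the exact branch is used
#'   (default 12).
#' @return List with `statistic` (rank sum of `a`), `p.value` (two-sided)
#'   and `method` (`"exact"` or `"normal_approx"`).
#' @export
rank_sum_test <- function(a, b, exact_max = 12L) {
  stopifnot(length(a) > 0, length(b) > 0)
  pooled <- c(a, b)
  ties <- anyDuplicated(pooled) > 0L
  W <- sum(rank(pooled)[seq_along(a)])
  exact <- (length(pooled) <= exact_max) && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  list(statistic = W, p.value = wt$p.value,
       method = if (exact) "exact" else "normal_approx")
}

#' Relative quantification fold change (2^-ddCt)
#'
#' `dCt = Ct_gene - Ct_control` in the sample and the calibrator;
#' `fold = 2^-(dCt_sample - dCt_calibrator)`.
#'
#' @param ct_gene,ct_control Ct values of the gene of interest and the
#'   endogenous control in the sample.
#' @param calibrator_ct_gene,calibrator_ct_control The same two Ct values in
#'   the calibrator.
#' @return Fold change(s) relative to the calibrator.
#' @export
ddct_fold_change <- function(ct_gene, ct_control,
                             calibrator_ct_gene, calibrator_ct_control) {
  stopifnot(all(is.finite(c(ct_gene, ct_control, calibrator_ct_gene,
                            calibrator_ct_control))),
            all(c(ct_gene, ct_control, calibrator_ct_gene,
                  calibrator_ct_control) > 0))
  ddct <- (ct_gene - ct_control) -
    (calibrator_ct_gene - calibrator_ct_control)
  2^(-ddct)
}

#' Fold changes for a Ct table
#'
#' @param ct_table data.frame with columns `gene`, `sample`, `ct_gene`,
#'   `ct_control`.
#' @param calibrator Name of the calibrator sample in `ct_table$sample`.
#' @return data.frame `gene`, `sample`, `fold_change` for the non-calibrator
#'   samples.
#' @export
qpcr_fold_changes <- function(ct_table, calibrator) {
  cal <- ct_table[ct_table$sample == calibrator, , drop = FALSE]
  if (nrow(cal) == 0L) stop("calibrator sample '", calibrator, "' not found")
  smp <- ct_table[ct_table$sample != calibrator, , drop = FALSE]
  i <- match(smp$gene, cal$gene)
  if (anyNA(i)) stop("calibrator lacks Ct values for: ",
                     paste(unique(smp$gene[is.na(i)]), collapse = ", "))
  data.frame(gene = smp$gene, sample = smp$sample,
             fold_change = ddct_fold_change(smp$ct_gene, smp$ct_control,
                                            cal$ct_gene[i], cal$ct_control[i]),
             stringsAsFactors = FALSE)
}
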