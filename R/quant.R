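# Isoform quantification. Reads compatible with several isoforms are
# apportioned by an expectation-maximisation algorithm over the relative
# expression simplex; expression is reported as expected read mass, theta
# and RPKM (reads per kilobase of transcript per million mapped reads).

#' Build a read-isoform compatibility matrix
#'
#' A read is compatible with an isoform iff every aligned block lies within
#' the isoform's exon union and every junction implied by the read's block
#' gaps coincides with an intron of the isoform within `tolerance` bases on
#' both edges. Reads compatible with no isoform are dropped and counted.
#'
#' @param records Kept `alignment_records`.
#' @param models A `transcript_models` annotation.
#' @param tolerance Junction-edge tolerance in bases (default 0).
#' @return An object of class `compatibility_matrix`: list with `compat`
#'   (logical matrix reads x isoforms), `effective_length` (named, spliced
#'   transcript length in bases), `read_ids`, and `n_dropped`.
#' @export
build_compatibility <- function(records, models, tolerance = 0L) {
  ids <- models$tx$transcript_id
  eff_len <- vapply(ids, function(id) transcript_length(models, id), integer(1))
  n <- n_records(records)
  compat <- matrix(FALSE, n, length(ids), dimnames = list(NULL, ids))
  if (n > 0L) {
    unions <- lapply(ids, function(id) exon_union(models, id))
    introns <- lapply(unions, function(u)
      if (length(u) > 1L) cbind(BiocGenerics::end(u)[-length(u)] + 1L,
                                BiocGenerics::start(u)[-1] - 1L)
      else matrix(integer(0), 0, 2))
    flat <- IRanges::ranges(unlist(records$blocks))
    rec_of_block <- rep(seq_len(n), lengths(records$blocks))
    starts <- split(BiocGenerics::start(flat), rec_of_block)
    ends <- split(BiocGenerics::end(flat), rec_of_block)
    for (j in seq_along(ids)) {
      u <- unions[[j]]
      intr <- introns[[j]]
      ov <- IRanges::findOverlaps(flat, u, type = "within")
      n_within <- tabulate(rec_of_block[S4Vectors::queryHits(ov)], nbins = n)
      contained <- n_within == lengths(records$blocks)
      for (r in which(contained)) {
        s <- starts[[as.character(r)]]; e <- ends[[as.character(r)]]
        ok <- TRUE
        if (length(s) > 1L) {
          for (g in seq_len(length(s) - 1L)) {
            gap_s <- e[g] + 1L; gap_e <- s[g + 1L] - 1L
            hit <- any(abs(intr[, 1] - gap_s) <= tolerance &
                         abs(intr[, 2] - gap_e) <= tolerance)
            if (!hit) { ok <- FALSE; break }
          }
        }
        compat[r, j] <- ok
      }
    }
  }
  orphan <- rowSums(compat) == 0L
  structure(list(compat = compat[!orphan, , drop = FALSE],
                 effective_length = eff_len,
                 read_ids = records$meta$read_id[!orphan],
                 n_dropped = sum(orphan)),
            class = "compatibility_matrix")
}

#' @export
print.compatibility_matrix <- function(x, ...) {
  cat("compatibility_matrix:", nrow(x$compat), "reads x",
      ncol(x$compat), "isoforms (", x$n_dropped, "reads dropped )\n")
  invisible(x)
}

#' Estimate isoform abundance by expectation-maximisation
#'
#' E-step: read r's unit mass is split over its compatible isoforms i in
#' proportion to `theta_i / l_i` (expression per effective-length base).
#' M-step: `theta_i` is proportional to the summed mass. Iterates from a
#' uniform start until `max |d theta| < tol` or `max_iter`; the
#' log-likelihood is non-decreasing across iterations. Isoforms with no
#' compatible reads end with zero mass and theta.
#'
#' @param cm A [build_compatibility()] matrix.
#' @param max_iter Maximum iterations (default 1000).
#' @param tol Convergence tolerance on `max |d theta|` (default 1e-8).
#' @return data.frame `transcript_id`, `theta`, `mass`,
#'   `effective_length`, plus attributes `iterations` and `loglik`
#'   (per-iteration trace).
#' @export
em_abundance <- function(cm, max_iter = 1000L, tol = 1e-8) {
  A <- cm$compat
  if (nrow(A) == 0L) stop("compatibility matrix has no reads")
  len <- cm$effective_length[colnames(A)]
  if (any(len <= 0)) stop("effective lengths must be positive")
  m <- ncol(A)
  theta <- rep(1 / m, m)
  ll <- numeric(0)
  storage.mode(A) <- "double"
  for (it in seq_len(max_iter)) {
    rate <- theta / len                       # expression density per isoform
    num <- sweep(A, 2, rate, `*`)
    denom <- rowSums(num)
    ll <- c(ll, sum(log(denom)))
    w <- num / denom                          # E-step responsibilities
    mass <- colSums(w)
    theta_new <- mass / sum(mass)             # M-step
    delta <- max(abs(theta_new - theta))
    theta <- theta_new
    if (delta < tol) break
  }
  out <- data.frame(transcript_id = colnames(A), theta = theta, mass = mass,
                    effective_length = as.numeric(len),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "iterations") <- it
  attr(out, "loglik") <- ll
  out
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = 1e9 * mass / (length * total)`.
#'
#' @param mass Assigned read mass (expected count).
#' @param effective_length Transcript effective length in bases (> 0).
#' @param total_mapped Total mapped reads in the normalisation denominator
#'   (> 0).
#' @return Numeric RPKM values.
#' @export
rpkm <- function(mass, effective_length, total_mapped) {
  if (any(total_mapped <= 0)) stop("total_mapped must be positive")
  if (any(effective_length <= 0)) stop("effective_length must be positive")
  1e9 * mass / (effective_length * total_mapped)
}

#' Quantify one sample
#'
#' Builds the compatibility matrix, runs EM and attaches RPKM. The RPKM
#' denominator is, by default, the number of post-filter genome-mapped reads
#' (rRNA-partition reads excluded, as quantification happens after rRNA
#' removal); pass `total_mapped` to override, e.g. to include rRNA reads.
#'
#' @param records Kept `alignment_records`.
#' @param models A `transcript_models` annotation.
#' @param tolerance Junction tolerance for [build_compatibility()].
#' @param total_mapped RPKM denominator; default the number of kept records.
#' @param max_iter,tol EM controls.
#' @return data.frame `transcript_id`, `theta`, `mass`, `effective_length`,
#'   `rpkm`, with attribute `n_dropped`.
#' @export
quantify_sample <- function(records, models, tolerance = 0L,
                            total_mapped = NULL, max_iter = 1000L,
                            tol = 1e-8) {
  cm <- build_compatibility(records, models, tolerance)
  if (is.null(total_mapped)) total_mapped <- n_records(records)
  if (nrow(cm$compat) == 0L) {
    out <- data.frame(transcript_id = models$tx$transcript_id, theta = 0,
                      mass = 0, effective_length = as.numeric(
                        cm$effective_length[models$tx$transcript_id]),
                      rpkm = 0, stringsAsFactors = FALSE)
    attr(out, "n_dropped") <- cm$n_dropped
    return(out)
  }
  est <- em_abundance(cm, max_iter, tol)
  est$rpkm <- rpkm(est$mass, est$effective_length, total_mapped)
  attr(est, "n_dropped") <- cm$n_dropped
  est
}

#' RPKM-threshold detection
#'
#' The alternative, coverage-free detection rule: a transcript is retained
#' iff its RPKM strictly exceeds `threshold` in at least one sample.
#'
#' @param estimates Named list of per-sample abundance tables (with
#'   `transcript_id` and `rpkm` columns).
#' @param threshold RPKM threshold (default 1.0; strict).
#' @return Character vector of retained transcript ids (the "RPKM
#'   approach" set, for comparison with the coverage approach).
#' @export
rpkm_detect <- function(estimates, threshold = 1.0) {
  hits <- lapply(estimates, function(e)
    e$transcript_id[e$rpkm > threshold])
  sort(unique(unlist(hits)), method = "radix")
}
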