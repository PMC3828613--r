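# Independent oracles used to cross-check the implementation. These stay
# deliberately naive: character-level scans, per-base boolean arrays, direct
# pmf summation, full enumeration.

# Exhaustive all-offsets Hamming scan of a read against reference sequences
# (named character vector), both orientations, with the matcher's tie-break
# order (mismatches, subunit name, start, forward first).
oracle_match_rrna <- function(seq, refs, max_mm = 2L, min_match_len = NULL) {
  L <- nchar(seq)
  if (is.null(min_match_len)) min_match_len <- min(20L, L)
  if (L < min_match_len || L == 0L) return(NULL)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  rows <- list()
  for (strand in c("+", "-")) {
    sv <- strsplit(if (strand == "+") seq else rc, "", fixed = TRUE)[[1]]
    for (nm in names(refs)) {
      rv <- strsplit(refs[[nm]], "", fixed = TRUE)[[1]]
      if (length(rv) < L) next
      for (st in seq_len(length(rv) - L + 1L)) {
        mm <- sum(rv[st:(st + L - 1L)] != sv)
        if (mm <= max_mm)
          rows[[length(rows) + 1L]] <- data.frame(
            subunit = nm, start = st, mismatches = mm, strand = strand,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(NULL)
  d <- do.call(rbind, rows)
  d[order(d$mismatches, d$subunit, d$start, d$strand != "+"), ][1L, ]
}

# Per-base boolean union-coverage fraction.
oracle_coverage_fraction <- function(block_starts, block_ends,
                                     tgt_starts, tgt_ends, len) {
  covered <- logical(len); target <- logical(len)
  for (i in seq_along(block_starts))
    covered[block_starts[i]:block_ends[i]] <- TRUE
  for (i in seq_along(tgt_starts))
    target[tgt_starts[i]:tgt_ends[i]] <- TRUE
  sum(covered & target) / sum(target)
}

# Independent CIGAR walker: reference blocks (split at N) from a CIGAR + pos.
oracle_cigar_blocks <- function(cigar, pos) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^\\d+", "", ops)
  cur <- pos; bs <- pos; out <- NULL
  for (i in seq_along(op)) {
    if (op[i] %in% c("M", "D", "=", "X")) {
      cur <- cur + n[i]
    } else if (op[i] == "N") {
      out <- rbind(out, c(bs, cur - 1L))
      cur <- cur + n[i]
      bs <- cur
    }
  }
  rbind(out, c(bs, cur - 1L))
}

# Hypergeometric upper tail P(X >= x) by direct pmf summation.
oracle_hyper_tail <- function(x, K, N, n) {
  if (x <= 0) return(1)
  hi <- min(n, K)
  if (x > hi) return(0)
  sum(stats::dhyper(x:hi, K, N - K, n))
}

# Exact two-sided rank-sum p by full enumeration of rank subsets (no ties).
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  N <- length(pooled); m <- length(a)
  W <- sum(rank(pooled)[seq_len(m)])
  mu <- m * (N + 1) / 2
  combs <- utils::combn(N, m)
  Ws <- colSums(matrix(seq_len(N)[combs], nrow = m))
  min(1, sum(abs(Ws - mu) >= abs(W - mu) - 1e-9) / ncol(combs))
}

# Classical step-up significance set at level alpha.
oracle_bh_significant <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- max(c(0L, which(ps <= seq_len(m) / m * alpha)))
  sig <- logical(m)
  if (k > 0L) sig[o[seq_len(k)]] <- TRUE
  sig
}

# Exhaustive simplex grid search maximising the EM likelihood (<= 3
# isoforms). `patterns` is a logical matrix of distinct compatibility
# patterns with `counts` reads each.
oracle_em_grid <- function(patterns, counts, len, step = 0.001) {
  m <- ncol(patterns)
  if (m == 2) {
    t1 <- seq(0, 1, by = step)
    grid <- cbind(t1, 1 - t1)
  } else if (m == 3) {
    t1 <- seq(0, 1, by = step)
    grid <- expand.grid(t1 = t1, t2 = t1)
    grid <- grid[grid$t1 + grid$t2 <= 1 + 1e-12, ]
    grid <- cbind(grid$t1, grid$t2, pmax(0, 1 - grid$t1 - grid$t2))
  } else stop("oracle supports 2 or 3 isoforms")
  B <- sweep(patterns * 1, 2, len, `/`)        # P x m, rows = pattern / len
  vals <- grid %*% t(B)                        # G x P mixture densities
  ll <- log(vals) %*% counts
  ll[!is.finite(ll)] <- -Inf
  grid[which.max(ll), ]
}
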