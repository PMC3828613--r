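# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Phred+33 encode/decode.
int_to_phred <- function(q) vapply(q, function(x) intToUtf8(x + 33L), character(1))
phred_to_int <- function(s) lapply(s, function(x) utf8ToInt(x) - 33L)

stopifnot_scalar <- function(x, name) {
  if (length(x) != 1L || is.na(x)) stop("'", name, "' must be a single non-NA value")
  invisible(x)
}

#' Read a FASTQ file into a read table
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning the
#' plain-table representation (`read_id`, `seq`, `qual`) used throughout the
#' package.
#'
#' @param path Path to a FASTQ file (Phred+33 qualities).
#' @return A `data.frame` with columns `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(
    read_id = sub("\\s.*$", "", names(x)),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities),
    stringsAsFactors = FALSE
  )
}

#' Write a read table to FASTQ
#'
#' @param reads A `data.frame` with columns `read_id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "seq", "qual") %in% names(reads)))
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
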