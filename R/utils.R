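#' Counts per million
#'
#' Library-size normalization to counts (reads) per million mapped reads.
#' Library sizes default to column sums but should normally be the number of
#' assigned/placed reads per sample so that CPM columns sum to at most 1e6.
#'
#' @param counts A numeric matrix, genes (rows) by samples (columns).
#' @param libSizes Numeric vector of per-sample library sizes, recycled from
#'   `colSums(counts)` when `NULL`.
#' @return A numeric matrix of the same dimensions as `counts`.
#' @export
cpm <- function(counts, libSizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(libSizes)) libSizes <- colSums(counts)
  if (length(libSizes) != ncol(counts))
    stop("libSizes must have one entry per sample")
  sweep(counts, 2L, libSizes, "/") * 1e6
}

#' Log2 CPM with a pseudocount
#'
#' @inheritParams cpm
#' @param prior Pseudocount added before taking log2 (default 0.5).
#' @return Matrix of log2(CPM + prior) values.
#' @export
logCPM <- function(counts, libSizes = NULL, prior = 0.5) {
  log2(cpm(counts, libSizes) + prior)
}

# row variances without a matrixStats dependency
rowVars <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

# reverse complement for plain character vectors
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# sample n random bases
randomBases <- function(n, prob = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

#' Read a FASTQ file
#'
#' Minimal four-line-record FASTQ reader (plain or gzip). Used by the
#' synthetic-read round-trip machinery and the trimming front end.
#'
#' @param path Path to a FASTQ file (`.gz` accepted).
#' @return A data.frame with columns `read_id`, `sequence`, `quality`.
#' @export
readFastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ: line count not a multiple of 4")
  idx <- seq(1L, length(lines), by = 4L)
  data.frame(
    read_id = sub("^@", "", sub("\\s.*$", "", lines[idx])),
    sequence = lines[idx + 1L],
    quality = lines[idx + 3L],
    stringsAsFactors = FALSE
  )
}

#' Write a FASTQ file
#'
#' @param reads data.frame with columns `read_id`, `sequence`, `quality`.
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @return Invisibly, `path`.
#' @export
writeFastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)))
  if (any(nchar(reads$sequence) != nchar(reads$quality)))
    stop("sequence/quality length mismatch")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  out <- rbind(paste0("@", reads$read_id), reads$sequence, "+", reads$quality)
  writeLines(as.vector(out), con)
  invisible(path)
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over [stats::p.adjust()] kept as a named surface so that every
#' FDR in the package goes through one place.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values (FDR).
#' @export
bhAdjust <- function(p) stats::p.adjust(p, method = "BH")
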