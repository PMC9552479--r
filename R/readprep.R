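#' Trim polyA tails and adapter from a 3'-end read
#'
#' QuantSeq-style raw reads end in a mixture of the polyA tail and the
#' sequencing adapter, which generic adapter trimmers handle poorly. The
#' trimmer removes, from the 3' end, the earliest-starting of (a) an adapter
#' match (a >= 10 nt prefix of the adapter with <= 10% mismatches, scanned
#' for the leftmost hit; terminal fragments of 5-9 nt must match exactly) or
#' (b) a polyA run of at least `polyAMinRun` bases with >= 90% A content
#' that extends to the read end or up to an adapter match. The fixed
#' `prefixTrim` leading bases (manufacturer's random primer) are then
#' removed. A read is kept only if strictly more than 36 bases remain
#' (>= `minLen`).
#'
#' @param sequence Raw read sequence.
#' @param quality Per-base quality string (trimmed in lockstep).
#' @param adapter Adapter sequence (non-empty).
#' @param polyAMinRun Minimum length of a trimmable polyA run (default 8).
#' @param prefixTrim Leading bases removed after 3' trimming (default 12).
#' @param minLen Minimum kept length after all trimming (default 37,
#'   i.e. "longer than 36").
#' @return A list with `sequence`, `quality`, `trim_reason` (one of
#'   `"polyA"`, `"adapter"`, `"polyA_in_adapter"`, `"none"`) and `kept`.
#' @examples
#' trimRead(paste0(strrep("N", 12), strrep("ACGT", 10), strrep("A", 15),
#'                 "AGATCGGAAGAGC"),
#'          adapter = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC")
#' @export
trimRead <- function(sequence, quality = NULL,
                     adapter = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
                     polyAMinRun = 8, prefixTrim = 12, minLen = 37) {
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  if (!nzchar(sequence)) stop("sequence must have length >= 1")
  if (is.null(quality)) quality <- strrep("I", nchar(sequence))
  if (nchar(quality) != nchar(sequence))
    stop("format error: sequence/quality length mismatch")

  s <- strsplit(sequence, "")[[1]]
  n <- length(s)
  a <- strsplit(adapter, "")[[1]]

  adapterStart <- findAdapterStart(s, a)
  boundary <- if (is.na(adapterStart)) n else adapterStart - 1L
  # a run may stop up to 4 nt short of the boundary: an adapter fragment
  # shorter than the 5 nt exact-match floor can remain after the tail and
  # is trimmed together with the run, so every run end within that slack
  # is tried and the earliest run start wins
  polyAStart <- NA_integer_
  if (boundary >= 1L) {
    for (eb in boundary:max(1L, boundary - 4L)) {
      cand <- findPolyAStart(s, eb, polyAMinRun)
      if (!is.na(cand) && (is.na(polyAStart) || cand < polyAStart))
        polyAStart <- cand
    }
  }

  cut <- n + 1L   # first removed position
  reason <- "none"
  if (!is.na(polyAStart)) {
    cut <- polyAStart
    reason <- if (!is.na(adapterStart)) "polyA_in_adapter" else "polyA"
  } else if (!is.na(adapterStart)) {
    cut <- adapterStart
    reason <- "adapter"
  }

  keptSeq <- substr(sequence, 1L, cut - 1L)
  keptQual <- substr(quality, 1L, cut - 1L)
  # remove the fixed random prefix
  keptSeq <- substr(keptSeq, prefixTrim + 1L, nchar(keptSeq))
  keptQual <- substr(keptQual, prefixTrim + 1L, nchar(keptQual))

  list(sequence = keptSeq, quality = keptQual, trim_reason = reason,
       kept = nchar(keptSeq) >= minLen)
}

# leftmost adapter match start (1-based) or NA.
# full-length-capable positions need >=10 nt with <=10% mismatches;
# terminal fragments of 5-9 nt must match exactly.
findAdapterStart <- function(s, a) {
  n <- length(s); la <- length(a)
  for (i in seq_len(n)) {
    m <- min(n - i + 1L, la)
    if (m >= 10L) {
      mm <- sum(s[i:(i + m - 1L)] != a[seq_len(m)])
      if (mm <= floor(0.1 * m)) return(i)
    } else if (m >= 5L && i + m - 1L == n) {
      if (all(s[i:n] == a[seq_len(m)])) return(i)
    }
  }
  NA_integer_
}

# start of the maximal >=90%-A run ending at `boundary`, or NA if shorter
# than minRun; the run must begin with an A.
findPolyAStart <- function(s, boundary, minRun) {
  if (boundary < 1L) return(NA_integer_)
  best <- NA_integer_
  nA <- 0L
  for (p in boundary:1L) {
    len <- boundary - p + 1L
    if (s[p] == "A") nA <- nA + 1L
    if (nA < 0.9 * len) break
    if (s[p] == "A") best <- p
  }
  if (!is.na(best) && boundary - best + 1L >= minRun) best else NA_integer_
}

#' Trim a set of reads
#'
#' Vectorized front end over [trimRead()].
#'
#' @param reads data.frame with `read_id`, `sequence`, `quality` columns
#'   (as from [readFastq()]).
#' @inheritParams trimRead
#' @return data.frame with `read_id`, `sequence`, `quality`, `trim_reason`,
#'   `kept`.
#' @export
trimReads <- function(reads, adapter = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
                      polyAMinRun = 8, prefixTrim = 12, minLen = 37) {
  out <- lapply(seq_len(nrow(reads)), function(i)
    trimRead(reads$sequence[i], reads$quality[i], adapter,
             polyAMinRun, prefixTrim, minLen))
  data.frame(
    read_id = reads$read_id,
    sequence = vapply(out, `[[`, character(1), "sequence"),
    quality = vapply(out, `[[`, character(1), "quality"),
    trim_reason = vapply(out, `[[`, character(1), "trim_reason"),
    kept = vapply(out, `[[`, logical(1), "kept"),
    stringsAsFactors = FALSE
  )
}

#' Remove reads matching a blocklist of overrepresented transcripts
#'
#' A read is removed iff it shares at least one exact k-mer (default k = 25)
#' with any blocklist sequence or its reverse complement, mirroring the
#' removal of rRNA- and BC1-derived reads that dominate oligo(dT) libraries.
#'
#' @param reads data.frame with `read_id` and `sequence`.
#' @param blocklist A [Biostrings::DNAStringSet] of overrepresented
#'   transcript sequences (e.g. read with
#'   [Biostrings::readDNAStringSet()]).
#' @param k Shared k-mer length (>= 11; default 25).
#' @return A list: `kept` (data.frame of surviving reads) and `removalLog`
#'   (data.frame entry/removed counts per blocklist sequence).
#' @export
filterBlocklist <- function(reads, blocklist, k = 25) {
  if (k < 11) stop("k must be >= 11")
  if (length(blocklist) == 0) {
    warning("empty blocklist: no reads removed")
    return(list(kept = reads,
                removalLog = data.frame(entry = character(),
                                        removed = integer())))
  }
  entryNames <- names(blocklist)
  if (is.null(entryNames))
    entryNames <- sprintf("blocklist%02d", seq_along(blocklist))
  kmerSets <- lapply(seq_along(blocklist), function(b) {
    sq <- as.character(blocklist[[b]])
    rc <- revComp(sq)
    unique(c(allKmers(sq, k), allKmers(rc, k)))
  })
  allSet <- unique(unlist(kmerSets))
  hitEntry <- rep(NA_integer_, nrow(reads))
  for (i in seq_len(nrow(reads))) {
    km <- allKmers(reads$sequence[i], k)
    if (length(km) && any(km %in% allSet)) {
      for (b in seq_along(kmerSets)) {
        if (any(km %in% kmerSets[[b]])) { hitEntry[i] <- b; break }
      }
    }
  }
  removed <- !is.na(hitEntry)
  log <- data.frame(entry = entryNames,
                    removed = vapply(seq_along(blocklist), function(b)
                      sum(hitEntry == b, na.rm = TRUE), integer(1)))
  list(kept = reads[!removed, , drop = FALSE], removalLog = log)
}

allKmers <- function(sq, k) {
  n <- nchar(sq)
  if (n < k) return(character(0))
  substring(sq, 1:(n - k + 1L), k:n)
}
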