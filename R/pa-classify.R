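#' Classify expressed regions against gene annotation
#'
#' Every ER receives every annotation category it overlaps by at least 1 bp,
#' on either strand (classification is strand-agnostic): 3'UTR, 5'UTR,
#' exon, intron; ERs overlapping no gene body are intergenic. Overlapping
#' categories are allowed.
#'
#' @param ers GRanges of expressed regions.
#' @param annotation GRanges of annotation features (`type`, `gene_id`
#'   metadata columns; types gene/exon/five_prime_utr/three_prime_utr).
#' @return `ers` with a `categories` metadata column (comma-separated) and
#'   an `eligible` logical column (TRUE when categories are within
#'   intron/intergenic, the set carried forward to artifact filtering).
#' @export
classifyRegions <- function(ers, annotation) {
  if (length(ers) == 0) {
    mcols(ers)$categories <- character(0)
    mcols(ers)$eligible <- logical(0)
    return(ers)
  }
  byType <- function(tp) annotation[mcols(annotation)$type == tp]
  genes <- byType("gene")
  exons <- byType("exon")
  introns <- intronRanges(annotation)

  catSets <- list(
    "3'UTR" = byType("three_prime_utr"),
    "5'UTR" = byType("five_prime_utr"),
    exon = exons,
    intron = introns
  )
  hits <- lapply(catSets, function(gr)
    GenomicRanges::countOverlaps(ers, gr, ignore.strand = TRUE) > 0)
  geneHit <- GenomicRanges::countOverlaps(ers, genes, ignore.strand = TRUE) > 0

  cats <- vapply(seq_along(ers), function(i) {
    cs <- names(hits)[vapply(hits, `[`, logical(1), i)]
    if (!geneHit[i]) cs <- c(cs, "intergenic")
    paste(cs, collapse = ",")
  }, character(1))
  mcols(ers)$categories <- cats
  mcols(ers)$eligible <- vapply(strsplit(cats, ","), function(cs)
    length(cs) > 0 && all(cs %in% c("intron", "intergenic")), logical(1))
  ers
}

# per-gene introns: gene body minus its exons
intronRanges <- function(annotation) {
  genes <- annotation[mcols(annotation)$type == "gene"]
  exons <- annotation[mcols(annotation)$type == "exon"]
  out <- GenomicRanges::GRanges()
  for (i in seq_along(genes)) {
    g <- genes[i]
    ex <- exons[mcols(exons)$gene_id == mcols(g)$gene_id]
    intr <- GenomicRanges::setdiff(g, ex, ignore.strand = FALSE)
    if (length(intr)) {
      mcols(intr)$gene_id <- mcols(g)$gene_id
      out <- c(out, intr)
    }
  }
  out
}

#' Internal-priming and repeat artifact filter
#'
#' Applied to intron/intergenic ERs only. The downstream window is the
#' sequence 3' of the ER's far end on the working strand (reverse
#' complemented for minus-strand ERs, so "A" always means A on the
#' transcribed strand). An ER is dropped when:
#' (a) any 18-nt window within 150 bp downstream contains >= 12 A
#'     ("18-mer polyA with up to 6 mismatches");
#' (b) any 7-nt window within 20 bp downstream contains >= 6 A
#'     ("7-mer polyA with up to 1 mismatch");
#' (c) strictly more than 50% of the 20 bp downstream are A; or
#' (d) the ER overlaps an annotated repeat interval by more than 20 bp.
#' The first failing rule (in a, b, c, d order) is recorded; windows
#' extending past a chromosome end are truncated and evaluated on the
#' available bases.
#'
#' @param ers GRanges from [classifyRegions()] (needs `eligible` mcol; ERs
#'   with any exonic/UTR category are never filtered).
#' @param genome A [Biostrings::DNAStringSet].
#' @param repeats GRanges of repeat intervals (strand ignored).
#' @return `ers` with a `filter_status` metadata column: one of `kept`,
#'   `drop_18mer`, `drop_7mer`, `drop_Afrac`, `drop_repeat`.
#' @export
filterInternalPriming <- function(ers, genome, repeats = GenomicRanges::GRanges()) {
  if (length(ers) == 0) {
    mcols(ers)$filter_status <- character(0)
    return(ers)
  }
  if (is.null(mcols(ers)$eligible))
    stop("run classifyRegions() first (missing 'eligible' column)")
  status <- rep("kept", length(ers))
  for (i in seq_along(ers)) {
    if (!mcols(ers)$eligible[i]) next
    dw <- downstreamWindow(ers[i], genome, 150L)
    status[i] <- classifyDownstream(dw,
                                    repeatOverlap = maxRepeatOverlap(ers[i],
                                                                     repeats))
  }
  mcols(ers)$filter_status <- status
  ers
}

# downstream genomic sequence on the transcribed strand (character vector)
downstreamWindow <- function(er, genome, w = 150L) {
  ch <- as.character(seqnames(er))
  L <- Biostrings::width(genome)[match(ch, names(genome))]
  if (as.character(strand(er)) == "-") {
    st <- max(1L, start(er) - w); en <- start(er) - 1L
    if (en < st) return(character(0))
    sq <- revComp(as.character(Biostrings::subseq(genome[[ch]], st, en)))
  } else {
    st <- end(er) + 1L; en <- min(L, end(er) + w)
    if (en < st) return(character(0))
    sq <- as.character(Biostrings::subseq(genome[[ch]], st, en))
  }
  strsplit(sq, "")[[1]]
}

maxRepeatOverlap <- function(er, repeats) {
  if (length(repeats) == 0) return(0L)
  hits <- GenomicRanges::findOverlaps(er, repeats, ignore.strand = TRUE)
  if (length(hits) == 0) return(0L)
  ov <- GenomicRanges::pintersect(rep(er, length(hits)),
                                  repeats[S4Vectors::subjectHits(hits)],
                                  ignore.strand = TRUE)
  max(width(ov))
}

# apply rules (a)-(d) to a downstream character vector; first failure wins
classifyDownstream <- function(dw, repeatOverlap = 0L) {
  isA <- dw == "A"
  n <- length(isA)
  # (a) 18-mer with >= 12 A anywhere in the first 150 bases
  if (n >= 18L) {
    cs <- cumsum(isA)
    winA <- cs[18:n] - c(0, cs[seq_len(n - 18L)])
    if (any(winA >= 12L)) return("drop_18mer")
  } else if (n > 0 && sum(isA) >= 12L) {
    return("drop_18mer")
  }
  # (b) 7-mer with >= 6 A within the first 20 bases
  m <- min(n, 20L)
  if (m >= 7L) {
    isA20 <- isA[seq_len(m)]
    cs <- cumsum(isA20)
    winA <- cs[7:m] - c(0, cs[seq_len(m - 7L)])
    if (any(winA >= 6L)) return("drop_7mer")
  } else if (m > 0 && sum(isA[seq_len(m)]) >= 6L) {
    return("drop_7mer")
  }
  # (c) > 50% A within the first 20 bases (exactly 50% is kept)
  if (m > 0 && sum(isA[seq_len(m)]) > 0.5 * m) return("drop_Afrac")
  # (d) repeat overlap > 20 bp (exactly 20 is kept)
  if (repeatOverlap > 20L) return("drop_repeat")
  "kept"
}
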