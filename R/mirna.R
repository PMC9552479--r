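#' miRNA-size read filter
#'
#' Retains adapter-trimmed small-RNA reads of mature-miRNA size: at least
#' 18 and strictly fewer than 23 nucleotides.
#'
#' @param reads Character vector of sequences, or a data.frame with a
#'   `sequence` column.
#' @param minLen Minimum length (default 18).
#' @param maxLen Maximum length (default 22).
#' @return Retained reads in the input representation.
#' @export
preprocessSmallRNA <- function(reads, minLen = 18, maxLen = 22) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  keep <- nchar(seqs) >= minLen & nchar(seqs) <= maxLen
  if (is.data.frame(reads)) reads[keep, , drop = FALSE] else reads[keep]
}

#' Classify a miRNA precursor locus against gene structure
#'
#' A precursor is a mirtron iff its interval lies fully inside an intron of
#' a same-strand gene and overlaps no exon of that gene; the host gene and
#' the intron ordinal in the direction of transcription (reported as
#' `"last"` for the terminal intron) are returned. Precursors overlapping
#' any exon are `exonic_overlap`; the rest are `intergenic`.
#'
#' @param precursor GRanges of length 1 (stranded).
#' @param annotation Annotation GRanges with exon structure (`type`,
#'   `gene_id`).
#' @return data.frame with `chrom`, `start`, `end`, `strand`,
#'   `classification`, `host_gene`, `intron_ordinal`.
#' @export
annotateMirtron <- function(precursor, annotation) {
  stopifnot(length(precursor) == 1)
  out <- data.frame(
    chrom = as.character(seqnames(precursor)),
    start = start(precursor), end = end(precursor),
    strand = as.character(strand(precursor)),
    classification = "intergenic",
    host_gene = NA_character_,
    intron_ordinal = NA_character_,
    stringsAsFactors = FALSE
  )
  annChroms <- unique(as.character(seqnames(annotation)))
  if (!out$chrom %in% annChroms) {
    warning("precursor on unannotated chromosome ", out$chrom,
            "; classified intergenic")
    return(out)
  }
  exons <- annotation[mcols(annotation)$type == "exon"]
  if (length(GenomicRanges::findOverlaps(precursor, exons,
                                         ignore.strand = TRUE))) {
    out$classification <- "exonic_overlap"
    return(out)
  }
  introns <- intronRanges(annotation)
  h <- GenomicRanges::findOverlaps(precursor, introns, type = "within")
  if (length(h)) {
    intr <- introns[S4Vectors::subjectHits(h)[1]]
    host <- mcols(intr)$gene_id
    out$classification <- "mirtron"
    out$host_gene <- host
    hostIntrons <- introns[mcols(introns)$gene_id == host]
    # transcription order: genomic order on +, reversed on -
    ord <- order(start(hostIntrons))
    if (as.character(strand(intr)) == "-") ord <- rev(ord)
    pos <- which(start(hostIntrons)[ord] == start(intr) &
                   end(hostIntrons)[ord] == end(intr))[1]
    out$intron_ordinal <- if (pos == length(hostIntrons)) "last" else
      as.character(pos)
  }
  out
}
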