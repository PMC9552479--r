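#' Count read 3'-ends against an augmented annotation
#'
#' A placement is counted to gene g iff its 3'-end position lies within any
#' exon, 3'UTR (including extensions) or novel internal pA feature of g on
#' the same strand. Placements overlapping features of two or more genes
#' are discarded (ambiguity rule), as are placements below the mapq
#' threshold. Library sizes are the mapq-passing placements per sample, so
#' CPM columns sum to at most 1e6.
#'
#' @param placements Placement data.frame (see [buildEndSignal()]).
#' @param augmented An [AugmentedAnnotation-class] (or plain annotation
#'   GRanges with `type`/`gene_id`).
#' @param mapqMin Minimum mapq (default 255).
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts` (genes x samples) and `librarySize` in `colData`.
#' @export
countReads <- function(placements, augmented, mapqMin = 255) {
  ann <- if (methods::is(augmented, "AugmentedAnnotation"))
    augmentedFeatures(augmented) else augmented
  feat <- ann[mcols(ann)$type %in%
                c("exon", "three_prime_utr", "novel_internal_pa")]
  pl <- placements[placements$mapq >= mapqMin, , drop = FALSE]
  samples <- sort(unique(placements$sample))
  libSizes <- stats::setNames(
    as.numeric(table(factor(pl$sample, levels = samples))), samples)
  geneIds <- sort(unique(mcols(ann)$gene_id))

  counts <- matrix(0L, nrow = length(geneIds), ncol = length(samples),
                   dimnames = list(geneIds, samples))
  if (nrow(pl)) {
    gr <- GenomicRanges::GRanges(pl$chrom,
                                 IRanges::IRanges(pl$pos_3prime,
                                                  pl$pos_3prime),
                                 strand = pl$strand)
    hits <- GenomicRanges::findOverlaps(gr, feat)
    hg <- mcols(feat)$gene_id[S4Vectors::subjectHits(hits)]
    qh <- S4Vectors::queryHits(hits)
    # one gene per placement; multi-gene placements discarded
    geneOf <- tapply(hg, qh, function(g) {
      u <- unique(g)
      if (length(u) == 1L) u else NA_character_
    })
    idx <- as.integer(names(geneOf))
    ok <- !is.na(geneOf)
    if (any(ok)) {
      tab <- table(gene = factor(geneOf[ok], levels = geneIds),
                   sample = factor(pl$sample[idx[ok]], levels = samples))
      counts <- counts + unclass(tab)
    }
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(sample = samples,
                                   librarySize = libSizes,
                                   row.names = samples)
  )
}

#' CPM expression filter
#'
#' Rows with identifier prefixes in `excludePrefixes` (mitochondrial genes,
#' spike-ins) are dropped first; then a gene is retained iff its CPM is
#' strictly greater than `cpmMin` in at least `minSamples` samples. CPM is
#' computed against the assigned-read library sizes from before any row
#' exclusion.
#'
#' @param counts Matrix of counts or the SummarizedExperiment from
#'   [countReads()].
#' @param libSizes Library sizes (ignored when `counts` carries them).
#' @param cpmMin CPM threshold, strict (default 2).
#' @param minSamples Minimum number of samples above threshold (default 10).
#' @param excludePrefixes Identifier prefixes removed before filtering.
#' @return Filtered counts matrix with `libSizes` attribute.
#' @export
cpmFilter <- function(counts, libSizes = NULL, cpmMin = 2, minSamples = 10,
                      excludePrefixes = c("mt-", "ERCC-")) {
  if (methods::is(counts, "SummarizedExperiment")) {
    libSizes <- SummarizedExperiment::colData(counts)$librarySize
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  counts <- as.matrix(counts)
  if (ncol(counts) < minSamples)
    stop("need at least minSamples (", minSamples, ") columns")
  if (is.null(libSizes)) libSizes <- colSums(counts)
  excl <- Reduce(`|`, lapply(excludePrefixes, function(p)
    startsWith(rownames(counts), p)), rep(FALSE, nrow(counts)))
  counts <- counts[!excl, , drop = FALSE]
  cc <- cpm(counts, libSizes)
  keep <- rowSums(cc > cpmMin) >= minSamples
  if (!any(keep))
    stop("all genes filtered out; review cpmMin/minSamples thresholds")
  out <- counts[keep, , drop = FALSE]
  attr(out, "libSizes") <- libSizes
  out
}
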