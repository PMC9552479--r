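#' @import methods
#' @importFrom GenomicRanges GRanges start end width strand seqnames
#' @importFrom GenomicRanges start<- end<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
NULL

#' TruthBundle: a synthetic genome with known ground truth
#'
#' Container for the output of [makeTruthGenome()]: a toy genome, a gene
#' annotation, and truth tables for hidden 3'UTR extensions, intronic
#' polyadenylation sites, decoy A-rich loci (internal-priming traps) and
#' repeat intervals. Downstream recovery tests read only these truth tables.
#'
#' @slot genome A [Biostrings::DNAStringSet] of chromosome sequences.
#' @slot annotation A [GenomicRanges::GRanges] of annotation features with
#'   metadata columns `type` (gene/exon/five_prime_utr/three_prime_utr) and
#'   `gene_id`; coordinates 1-based inclusive.
#' @slot trueExtensions GRanges of hidden 3'UTR extension intervals
#'   (gene end + 1 .. extension pA site in the 3' direction), `gene_id` mcol.
#' @slot trueIntronicPa GRanges (width 1) of hidden intronic pA positions.
#' @slot decoyArich GRanges of A-rich decoy intervals (>= 50% A on the
#'   indicated strand) where internal oligo(dT) priming is simulated.
#' @slot repeats GRanges of repeat intervals.
#' @slot seed Integer seed used to generate the bundle.
#' @export
setClass("TruthBundle", representation(
  genome = "DNAStringSet",
  annotation = "GRanges",
  trueExtensions = "GRanges",
  trueIntronicPa = "GRanges",
  decoyArich = "GRanges",
  repeats = "GRanges",
  seed = "integer"
))

setValidity("TruthBundle", function(object) {
  msgs <- character()
  ann <- object@annotation
  if (!all(c("type", "gene_id") %in% names(mcols(ann))))
    msgs <- c(msgs, "annotation needs 'type' and 'gene_id' metadata columns")
  genes <- ann[mcols(ann)$type == "gene"]
  ext <- object@trueExtensions
  if (length(ext)) {
    gi <- match(mcols(ext)$gene_id, mcols(genes)$gene_id)
    if (anyNA(gi)) {
      msgs <- c(msgs, "extension gene_id absent from annotation")
    } else {
      plus <- as.character(strand(genes)[gi]) == "+"
      ok <- ifelse(plus,
                   start(ext) == end(genes)[gi] + 1L &
                     width(ext) <= 5000L,
                   end(ext) == start(genes)[gi] - 1L &
                     width(ext) <= 5000L)
      if (!all(ok))
        msgs <- c(msgs, "extensions must start at the gene end and stay within 5 kb")
    }
  }
  if (length(object@decoyArich)) {
    paPos <- c(object@trueIntronicPa, GenomicRanges::resize(ext, 1L, fix = "end"))
    if (length(paPos) &&
        length(GenomicRanges::findOverlaps(object@decoyArich, paPos,
                                           ignore.strand = TRUE)))
      msgs <- c(msgs, "decoy A-rich intervals overlap true pA sites")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TruthBundle", function(object) {
  ann <- object@annotation
  cat("TruthBundle\n")
  cat("  genome:", length(object@genome), "chromosome(s),",
      sum(Biostrings::width(object@genome)), "bp\n")
  cat("  genes:", sum(mcols(ann)$type == "gene"),
      "| hidden extensions:", length(object@trueExtensions),
      "| intronic pA:", length(object@trueIntronicPa), "\n")
  cat("  decoy A-rich loci:", length(object@decoyArich),
      "| repeats:", length(object@repeats),
      "| seed:", object@seed, "\n")
})

#' Accessors for TruthBundle
#'
#' @param object A [TruthBundle-class] object.
#' @return The corresponding slot.
#' @name TruthBundle-accessors
#' @export
truthGenome <- function(object) object@genome

#' @rdname TruthBundle-accessors
#' @export
truthAnnotation <- function(object) object@annotation

#' @rdname TruthBundle-accessors
#' @export
trueExtensions <- function(object) object@trueExtensions

#' @rdname TruthBundle-accessors
#' @export
trueIntronicPa <- function(object) object@trueIntronicPa

#' @rdname TruthBundle-accessors
#' @export
decoyArich <- function(object) object@decoyArich

#' @rdname TruthBundle-accessors
#' @export
truthRepeats <- function(object) object@repeats

#' EndSignalTrack: per-strand 3'-end pileups
#'
#' Sparse per-sample pileup of read 3'-most nucleotides, the signal from
#' which expressed regions are detected. RPM scaling is
#' `count * 1e6 / librarySize`.
#'
#' @slot counts data.frame with columns `sample`, `chrom`, `strand`, `pos`,
#'   `count` (positions 1-based; only nonzero positions stored).
#' @slot librarySizes Named numeric vector: placed reads per sample
#'   (post mapq filter).
#' @export
setClass("EndSignalTrack", representation(
  counts = "data.frame",
  librarySizes = "numeric"
))

setValidity("EndSignalTrack", function(object) {
  msgs <- character()
  need <- c("sample", "chrom", "strand", "pos", "count")
  if (!all(need %in% names(object@counts)))
    msgs <- c(msgs, paste("counts needs columns:", paste(need, collapse = ", ")))
  if (length(object@librarySizes) && is.null(names(object@librarySizes)))
    msgs <- c(msgs, "librarySizes must be named by sample")
  if (nrow(object@counts)) {
    tot <- tapply(object@counts$count, object@counts$sample, sum)
    ls <- object@librarySizes[names(tot)]
    if (any(is.na(ls)) || any(tot != ls))
      msgs <- c(msgs, "per-sample counts must sum to the library size")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "EndSignalTrack", function(object) {
  cat("EndSignalTrack\n")
  cat("  samples:", length(object@librarySizes),
      "| nonzero positions:", nrow(object@counts), "\n")
  cat("  library sizes:",
      paste(utils::head(names(object@librarySizes), 4), "=",
            utils::head(object@librarySizes, 4), collapse = ", "),
      if (length(object@librarySizes) > 4) "..." else "", "\n")
})

#' @rdname EndSignalTrack-class
#' @param object An `EndSignalTrack`.
#' @return `trackCounts` returns the sparse pileup data.frame;
#'   `librarySizes` the named per-sample totals.
#' @export
trackCounts <- function(object) object@counts

#' @rdname EndSignalTrack-class
#' @export
librarySizes <- function(object) object@librarySizes

#' AugmentedAnnotation: gene models plus novel pA features
#'
#' The result of assigning filtered expressed regions to genes: the base
#' annotation plus novel internal (intronic) pA features and 3'UTR
#' extensions, with provenance tags, and the per-region assignment report.
#'
#' @slot annotation GRanges of all features; mcols `type`, `gene_id`,
#'   `provenance` (base / novel_internal_pa / extension).
#' @slot novelSites GRanges of added internal pA features (ER padded 5 bp).
#' @slot extensions GRanges of added 3'UTR extension intervals.
#' @slot assignments data.frame: one row per input ER with `gene`, `mode`,
#'   `reason`.
#' @slot report list of summary counts (genes gaining internal sites,
#'   extensions, both).
#' @export
setClass("AugmentedAnnotation", representation(
  annotation = "GRanges",
  novelSites = "GRanges",
  extensions = "GRanges",
  assignments = "data.frame",
  report = "list"
))

setValidity("AugmentedAnnotation", function(object) {
  msgs <- character()
  ann <- object@annotation
  if (!all(c("type", "gene_id", "provenance") %in% names(mcols(ann))))
    msgs <- c(msgs, "annotation needs type/gene_id/provenance mcols")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "AugmentedAnnotation", function(object) {
  r <- object@report
  cat("AugmentedAnnotation\n")
  cat("  features:", length(object@annotation),
      "| novel internal pA:", length(object@novelSites),
      "| extensions:", length(object@extensions), "\n")
  if (length(r))
    cat("  genes w/ internal sites:", r$genes_internal,
        "| w/ extensions:", r$genes_extended,
        "| both:", r$genes_both, "\n")
})

#' @rdname AugmentedAnnotation-class
#' @param object An `AugmentedAnnotation`.
#' @return Accessors return the corresponding slot.
#' @export
augmentedFeatures <- function(object) object@annotation

#' @rdname AugmentedAnnotation-class
#' @export
novelSites <- function(object) object@novelSites

#' @rdname AugmentedAnnotation-class
#' @export
extensionIntervals <- function(object) object@extensions

#' @rdname AugmentedAnnotation-class
#' @export
assignmentReport <- function(object) object@report

#' @rdname AugmentedAnnotation-class
#' @export
assignmentTable <- function(object) object@assignments

#' UnwantedFactors: latent technical covariates
#'
#' Factors of unwanted variation estimated from negative-control genes or
#' replicate groups, to be appended to differential-testing design matrices.
#'
#' @slot W samples-by-k matrix with orthonormal columns.
#' @slot k Number of factors.
#' @slot controlGenes Control-gene identifiers (control-gene mode only).
#' @slot method Either `"control_gene_svd"` or `"replicate_group_svd"`.
#' @export
setClass("UnwantedFactors", representation(
  W = "matrix",
  k = "integer",
  controlGenes = "character",
  method = "character"
))

setValidity("UnwantedFactors", function(object) {
  msgs <- character()
  if (object@k < 1L) msgs <- c(msgs, "k must be >= 1")
  if (ncol(object@W) != object@k) msgs <- c(msgs, "W must have k columns")
  gram <- crossprod(object@W)
  if (max(abs(gram - diag(object@k))) > 1e-8)
    msgs <- c(msgs, "columns of W must be orthonormal")
  if (!object@method %in% c("control_gene_svd", "replicate_group_svd"))
    msgs <- c(msgs, "unknown method")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "UnwantedFactors", function(object) {
  cat("UnwantedFactors |", object@method, "| k =", object@k,
      "|", nrow(object@W), "samples\n")
})

#' @rdname UnwantedFactors-class
#' @param object An `UnwantedFactors` object.
#' @return `factorMatrix` returns the samples-by-k matrix `W`.
#' @export
factorMatrix <- function(object) object@W

#' ModuleSet: co-expression modules
#'
#' Disjoint gene modules from weighted correlation-network clustering,
#' with the soft-threshold exponent used. Module 0 collects unassigned genes.
#'
#' @slot assignment Named integer vector gene -> module id (0 = unassigned).
#' @slot modules Named list, module label -> gene character vector.
#' @slot beta Soft-threshold exponent actually used.
#' @slot minSize Minimum module size imposed.
#' @export
setClass("ModuleSet", representation(
  assignment = "integer",
  modules = "list",
  beta = "numeric",
  minSize = "integer"
))

setValidity("ModuleSet", function(object) {
  msgs <- character()
  if (is.null(names(object@assignment)))
    msgs <- c(msgs, "assignment must be named by gene")
  genes <- unlist(object@modules, use.names = FALSE)
  if (anyDuplicated(genes))
    msgs <- c(msgs, "modules must be disjoint")
  if (length(object@modules) &&
      any(lengths(object@modules) < object@minSize))
    msgs <- c(msgs, "every module must have at least minSize genes")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ModuleSet", function(object) {
  cat("ModuleSet |", length(object@modules), "modules | beta =",
      object@beta, "\n")
  if (length(object@modules))
    cat("  sizes:", paste(names(object@modules), lengths(object@modules),
                          sep = "=", collapse = ", "), "\n")
  cat("  unassigned:", sum(object@assignment == 0L), "genes\n")
})

#' @rdname ModuleSet-class
#' @param object A `ModuleSet`.
#' @return `moduleAssignment` returns the named integer vector;
#'   `moduleList` the named list of gene vectors; `softThreshold` the
#'   exponent used.
#' @export
moduleAssignment <- function(object) object@assignment

#' @rdname ModuleSet-class
#' @export
moduleList <- function(object) object@modules

#' @rdname ModuleSet-class
#' @export
softThreshold <- function(object) object@beta
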