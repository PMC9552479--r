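#' Build a 3'-end signal track from read placements
#'
#' Only the 3'-most nucleotide of each read contributes: the pileup counts,
#' per sample, chromosome and strand, how many reads end at each position.
#' Placements below the mapq threshold (default 255, i.e. uniquely placed)
#' are excluded; the library size is the number of retained placements.
#'
#' @param placements data.frame with columns `read_id`, `sample`, `chrom`,
#'   `pos_3prime` (1-based), `strand`, `mapq` (the documented placement TSV
#'   layout; the stand-in for a coordinate-sorted BAM).
#' @param mapqMin Minimum mapq retained (default 255).
#' @param genome Optional [Biostrings::DNAStringSet]; placements on unknown
#'   chromosomes raise an error naming the offenders.
#' @return An [EndSignalTrack-class].
#' @export
buildEndSignal <- function(placements, mapqMin = 255, genome = NULL) {
  need <- c("read_id", "sample", "chrom", "pos_3prime", "strand", "mapq")
  if (!all(need %in% names(placements)))
    stop("placements must have columns: ", paste(need, collapse = ", "))
  if (!is.null(genome)) {
    bad <- setdiff(unique(placements$chrom), names(genome))
    if (length(bad))
      stop("unknown chromosome(s) vs genome: ", paste(bad, collapse = ", "))
  }
  keep <- placements$mapq >= mapqMin
  pl <- placements[keep, , drop = FALSE]
  libSizes <- table(factor(pl$sample))
  libSizes <- stats::setNames(as.numeric(libSizes), names(libSizes))
  if (nrow(pl)) {
    agg <- stats::aggregate(
      list(count = rep(1L, nrow(pl))),
      by = list(sample = pl$sample, chrom = pl$chrom,
                strand = pl$strand, pos = pl$pos_3prime),
      FUN = sum)
    agg <- agg[order(agg$sample, agg$chrom, agg$strand, agg$pos), ,
               drop = FALSE]
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(sample = character(), chrom = character(),
                      strand = character(), pos = integer(),
                      count = integer())
  }
  methods::new("EndSignalTrack", counts = agg, librarySizes = libSizes)
}

#' Detect expressed regions from a signal track
#'
#' An expressed region (ER) is a maximal run of consecutive positions whose
#' cross-sample mean RPM is at least `cutoffRpm` (default 1). Adjacent runs
#' separated by at least one sub-cutoff position are distinct ERs. The mean
#' RPM at a position is the mean over all samples of
#' `count * 1e6 / librarySize` (zero where a sample has no reads).
#'
#' @param track An [EndSignalTrack-class].
#' @param cutoffRpm RPM cutoff (inclusive; default 1).
#' @return A [GenomicRanges::GRanges] of stranded ERs with metadata column
#'   `mean_rpm` (region mean of per-position mean RPM).
#' @export
detectExpressedRegions <- function(track, cutoffRpm = 1) {
  cnt <- trackCounts(track)
  ls <- librarySizes(track)
  nS <- length(ls)
  if (nS < 1 || nrow(cnt) == 0)
    return(GenomicRanges::GRanges())
  rpm <- cnt$count * 1e6 / ls[cnt$sample]
  key <- paste(cnt$chrom, cnt$strand, cnt$pos, sep = "\r")
  meanRpm <- tapply(rpm, key, sum) / nS
  parts <- do.call(rbind, strsplit(names(meanRpm), "\r", fixed = TRUE))
  pos <- data.frame(chrom = parts[, 1], strand = parts[, 2],
                    pos = as.integer(parts[, 3]),
                    mean_rpm = as.numeric(meanRpm))
  pos <- pos[pos$mean_rpm >= cutoffRpm, , drop = FALSE]
  if (nrow(pos) == 0) return(GenomicRanges::GRanges())
  pos <- pos[order(pos$chrom, pos$strand, pos$pos), , drop = FALSE]
  newRun <- c(TRUE, pos$chrom[-1] != pos$chrom[-nrow(pos)] |
                    pos$strand[-1] != pos$strand[-nrow(pos)] |
                    diff(pos$pos) != 1L)
  runId <- cumsum(newRun)
  st <- tapply(pos$pos, runId, min)
  en <- tapply(pos$pos, runId, max)
  first <- !duplicated(runId)
  GenomicRanges::GRanges(
    pos$chrom[first],
    IRanges::IRanges(as.integer(st), as.integer(en)),
    strand = pos$strand[first],
    mean_rpm = as.numeric(tapply(pos$mean_rpm, runId, mean))
  )
}
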