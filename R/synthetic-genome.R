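#' Generate a toy genome with known polyadenylation truth
#'
#' Builds a small multi-chromosome genome carrying stranded multi-exon gene
#' models, a chosen fraction of genes with a hidden 3'UTR extension (a real
#' pA site downstream of the annotated gene end, within 5 kb), a fraction
#' with a hidden intronic pA site, decoy A-rich loci that attract internal
#' oligo(dT) priming, and repeat intervals. The downstream 150 bp of every
#' true pA site is drawn A-depleted so truth labels remain consistent with
#' the internal-priming artifact definition; decoy loci carry ~85% A runs.
#'
#' @param nGenes Number of genes (positive integer).
#' @param chromSizes Named integer vector of chromosome lengths.
#' @param fracExtensions Fraction of genes given a hidden 3'UTR extension.
#' @param fracIntronicPa Fraction of genes given a hidden intronic pA site.
#' @param nDecoys Number of decoy A-rich intergenic loci.
#' @param nRepeats Number of repeat intervals.
#' @param seed Integer seed; the same seed reproduces the bundle exactly.
#' @return A [TruthBundle-class] object.
#' @examples
#' tb <- makeTruthGenome(nGenes = 10, seed = 1)
#' tb
#' @export
makeTruthGenome <- function(nGenes = 30,
                            chromSizes = c(chr1 = 400000L, chr2 = 300000L),
                            fracExtensions = 0.3,
                            fracIntronicPa = 0.3,
                            nDecoys = 10,
                            nRepeats = 8,
                            seed = 1) {
  if (!is.numeric(nGenes) || nGenes < 1)
    stop("configuration error: nGenes must be a positive integer")
  if (!is.numeric(chromSizes) || any(chromSizes <= 0) ||
      is.null(names(chromSizes)))
    stop("configuration error: chromSizes must be named positive integers")
  for (f in c("fracExtensions", "fracIntronicPa")) {
    v <- get(f)
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("configuration error: ", f, " must lie in [0, 1]")
  }
  if (nDecoys < 0 || nRepeats < 0)
    stop("configuration error: nDecoys/nRepeats must be non-negative")
  seed <- as.integer(seed)
  set.seed(seed)

  chromNames <- names(chromSizes)
  chromSizes <- stats::setNames(as.integer(chromSizes), chromNames)
  # raw genome: uniform bases, one character vector per chromosome
  genomeChars <- lapply(chromSizes, function(n)
    sample(c("A", "C", "G", "T"), n, replace = TRUE))
  names(genomeChars) <- chromNames

  # --- place genes on a regular grid with >= 12 kb pitch ---------------
  pitch <- 12000L
  slots <- do.call(rbind, lapply(chromNames, function(ch) {
    n <- (chromSizes[ch] - 2000L) %/% pitch
    if (n < 1) return(NULL)
    data.frame(chrom = ch, slotStart = 1000L + (seq_len(n) - 1L) * pitch)
  }))
  if (nrow(slots) < nGenes + nDecoys)
    stop("configuration error: chromSizes too small for nGenes + nDecoys")
  pick <- sample(nrow(slots), nGenes + nDecoys)
  geneSlots <- slots[pick[seq_len(nGenes)], , drop = FALSE]
  decoySlots <- slots[pick[nGenes + seq_len(nDecoys)], , drop = FALSE]

  featList <- list()
  for (i in seq_len(nGenes)) {
    gid <- sprintf("gene%03d", i)
    str <- sample(c("+", "-"), 1L)
    s <- geneSlots$slotStart[i]
    ch <- geneSlots$chrom[i]
    # structure in genomic coordinates (5'->3' on + strand):
    # exon1 200 | intron1 800 | exon2 200 | intron2 800 | exon3 400
    ex <- data.frame(
      start = c(s, s + 1000L, s + 2000L),
      end = c(s + 199L, s + 1199L, s + 2399L)
    )
    gStart <- min(ex$start); gEnd <- max(ex$end)
    if (str == "+") {
      utr5 <- c(gStart, gStart + 99L)
      utr3 <- c(gEnd - 299L, gEnd)
    } else {
      utr5 <- c(gEnd - 99L, gEnd)
      utr3 <- c(gStart, gStart + 299L)
    }
    featList[[gid]] <- data.frame(
      chrom = ch,
      start = c(gStart, ex$start, utr5[1], utr3[1]),
      end = c(gEnd, ex$end, utr5[2], utr3[2]),
      strand = str,
      type = c("gene", rep("exon", 3L), "five_prime_utr", "three_prime_utr"),
      gene_id = gid,
      stringsAsFactors = FALSE
    )
  }
  feats <- do.call(rbind, featList)
  annotation <- GenomicRanges::GRanges(
    feats$chrom, IRanges::IRanges(feats$start, feats$end),
    strand = feats$strand, type = feats$type, gene_id = feats$gene_id,
    seqlengths = chromSizes
  )

  genes <- annotation[mcols(annotation)$type == "gene"]
  gid <- mcols(genes)$gene_id

  # --- hidden extensions and intronic pA sites -------------------------
  nExt <- round(fracExtensions * nGenes)
  nInt <- round(fracIntronicPa * nGenes)
  extGenes <- if (nExt > 0) sort(sample(nGenes, nExt)) else integer(0)
  intGenes <- if (nInt > 0) sort(sample(nGenes, nInt)) else integer(0)

  trueExtensions <- GenomicRanges::GRanges(seqlengths = chromSizes)
  if (length(extGenes)) {
    len <- sample(500:2000, length(extGenes), replace = TRUE)
    plus <- as.character(strand(genes)[extGenes]) == "+"
    st <- ifelse(plus, end(genes)[extGenes] + 1L,
                 start(genes)[extGenes] - len)
    en <- ifelse(plus, end(genes)[extGenes] + len,
                 start(genes)[extGenes] - 1L)
    trueExtensions <- GenomicRanges::GRanges(
      as.character(seqnames(genes)[extGenes]),
      IRanges::IRanges(st, en),
      strand = strand(genes)[extGenes],
      gene_id = gid[extGenes],
      seqlengths = chromSizes
    )
  }

  trueIntronicPa <- GenomicRanges::GRanges(seqlengths = chromSizes)
  if (length(intGenes)) {
    # middle of intron 1 (genomic): slotStart + 600
    pos <- geneSlots$slotStart[intGenes] + 600L
    trueIntronicPa <- GenomicRanges::GRanges(
      geneSlots$chrom[intGenes],
      IRanges::IRanges(pos, pos),
      strand = strand(genes)[intGenes],
      gene_id = gid[intGenes],
      seqlengths = chromSizes
    )
  }

  # --- decoy A-rich loci (internal-priming traps) ----------------------
  decoyArich <- GenomicRanges::GRanges(seqlengths = chromSizes)
  if (nDecoys > 0) {
    dStr <- sample(c("+", "-"), nDecoys, replace = TRUE)
    dStart <- decoySlots$slotStart + 3000L
    decoyArich <- GenomicRanges::GRanges(
      decoySlots$chrom, IRanges::IRanges(dStart, dStart + 29L),
      strand = dStr, seqlengths = chromSizes
    )
    for (j in seq_len(nDecoys)) {
      ch <- decoySlots$chrom[j]
      run <- sample(c("A", "C", "G", "T"), 30L, replace = TRUE,
                    prob = c(0.85, 0.05, 0.05, 0.05))
      if (dStr[j] == "-") run <- rev(chartr("ACGT", "TGCA", run))
      genomeChars[[ch]][dStart[j]:(dStart[j] + 29L)] <- run
    }
  }

  # --- repeats: intergenic intervals away from genes -------------------
  repeats <- GenomicRanges::GRanges(seqlengths = chromSizes)
  if (nRepeats > 0 && nDecoys > 0) {
    rIdx <- sample(nDecoys, min(nRepeats, nDecoys))
    rStart <- decoySlots$slotStart[rIdx] + 6000L
    repeats <- GenomicRanges::GRanges(
      decoySlots$chrom[rIdx],
      IRanges::IRanges(rStart, rStart + sample(100:400, length(rIdx),
                                               replace = TRUE)),
      strand = "*", seqlengths = chromSizes
    )
  }

  # --- scrub downstream windows of true pA sites -----------------------
  # draw the 150 bp 3' of each true pA site A-depleted on the transcribed
  # strand so true sites are not artifact-like by chance
  paSites <- rbind(
    data.frame(chrom = as.character(seqnames(genes)),
               pos = ifelse(as.character(strand(genes)) == "+",
                            end(genes), start(genes)),
               strand = as.character(strand(genes))),
    if (length(trueExtensions)) data.frame(
      chrom = as.character(seqnames(trueExtensions)),
      pos = ifelse(as.character(strand(trueExtensions)) == "+",
                   end(trueExtensions), start(trueExtensions)),
      strand = as.character(strand(trueExtensions))) else NULL,
    if (length(trueIntronicPa)) data.frame(
      chrom = as.character(seqnames(trueIntronicPa)),
      pos = start(trueIntronicPa),
      strand = as.character(strand(trueIntronicPa))) else NULL
  )
  for (j in seq_len(nrow(paSites))) {
    ch <- paSites$chrom[j]
    L <- chromSizes[ch]
    if (paSites$strand[j] == "+") {
      win <- (paSites$pos[j] + 1L):min(L, paSites$pos[j] + 150L)
      depleted <- sample(c("A", "C", "G", "T"), length(win), replace = TRUE,
                         prob = c(0.08, 0.31, 0.31, 0.30))
      # cleavage-adjacent bases non-A so the tail/genome boundary is
      # identifiable by the trimmer
      anchor <- (paSites$pos[j] - 1L):paSites$pos[j]
      genomeChars[[ch]][anchor] <- sample(c("C", "G", "T"), 2L,
                                          replace = TRUE)
    } else {
      win <- max(1L, paSites$pos[j] - 150L):(paSites$pos[j] - 1L)
      depleted <- sample(c("T", "G", "C", "A"), length(win), replace = TRUE,
                         prob = c(0.08, 0.31, 0.31, 0.30))
      anchor <- paSites$pos[j]:(paSites$pos[j] + 1L)
      genomeChars[[ch]][anchor] <- sample(c("G", "C", "A"), 2L,
                                          replace = TRUE)
    }
    genomeChars[[ch]][win] <- depleted
  }

  genome <- Biostrings::DNAStringSet(vapply(genomeChars, paste,
                                            character(1), collapse = ""))
  names(genome) <- chromNames

  methods::new("TruthBundle",
               genome = genome, annotation = annotation,
               trueExtensions = trueExtensions,
               trueIntronicPa = trueIntronicPa,
               decoyArich = decoyArich, repeats = repeats, seed = seed)
}

#' Write a TruthBundle to standard flat files
#'
#' Serializes the genome (FASTA), annotation (GTF, 1-based inclusive),
#' repeats and decoy loci (BED, 0-based half-open).
#'
#' @param truth A [TruthBundle-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named vector of file paths.
#' @export
writeTruthBundle <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    annotation = file.path(dir, "annotation.gtf"),
    repeats = file.path(dir, "repeats.bed"),
    decoys = file.path(dir, "decoys.bed")
  )
  Biostrings::writeXStringSet(truth@genome, paths["genome"])
  writeGTF(truth@annotation, paths["annotation"])
  rtracklayer::export(truth@repeats, paths["repeats"], format = "BED")
  rtracklayer::export(truth@decoyArich, paths["decoys"], format = "BED")
  invisible(paths)
}

#' Write a GTF file (1-based inclusive)
#'
#' @param gr GRanges with `type` and `gene_id` metadata columns.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeGTF <- function(gr, path) {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s.t1";',
                   mcols(gr)$gene_id, mcols(gr)$gene_id)
  lines <- sprintf("%s\tEndSeqTools\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   as.character(seqnames(gr)), mcols(gr)$type,
                   start(gr), end(gr), as.character(strand(gr)), attrs)
  writeLines(lines, path)
  invisible(path)
}

#' Read a GTF file into annotation GRanges
#'
#' @param path GTF path.
#' @return GRanges with `type` and `gene_id` metadata columns.
#' @export
readGTF <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  GenomicRanges::GRanges(seqnames(gr), IRanges::IRanges(start(gr), end(gr)),
                         strand = strand(gr),
                         type = as.character(mcols(gr)$type),
                         gene_id = mcols(gr)$gene_id)
}
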