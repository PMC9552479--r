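#' Simulate QuantSeq-style 3'-anchored reads
#'
#' Generates raw reads anchored at every true pA site of a [TruthBundle-class]
#' (annotated gene ends, hidden 3'UTR extensions, hidden intronic sites),
#' internal-priming reads at the decoy A-rich loci, and blocklist
#' (rRNA/BC1-like) reads. Each raw read is: 12 random prefix bases, the
#' transcribed-strand genomic sequence ending at the pA position, a polyA
#' tail, then the sequencing adapter, truncated to `readLength`. A placement
#' table (the stand-in for an alignment BAM) records the 3'-most genomic
#' position of every non-blocklist read; a truth table labels every read.
#'
#' @param truth A [TruthBundle-class].
#' @param nSamples Number of samples.
#' @param readsPerSite Reads generated at each true pA site per sample.
#' @param internalPrimingRate Internal-priming reads per decoy locus per
#'   sample, as a fraction of `readsPerSite` (0 disables).
#' @param blocklistReadsPerSample Blocklist-derived reads per sample.
#' @param adapter Sequencing adapter string (non-empty).
#' @param tailMean Mean polyA-tail length (Poisson, floored at 8).
#' @param readLength Raw read length (default 68 nt, with a 12 nt random
#'   prefix exercising the fixed-prefix trim).
#' @param seed Integer seed.
#' @return A list with elements `reads` (data.frame read_id/sequence/quality),
#'   `placements` (data.frame read_id/sample/chrom/pos_3prime/strand/mapq),
#'   `readTruth` (data.frame read_id/sample/label/gene_id with labels in
#'   true_pa, extension_pa, intronic_pa, internal_priming, blocklist),
#'   `blocklist` (DNAStringSet of blocklist reference sequences).
#' @export
simulateQuantSeqReads <- function(truth,
                                  nSamples = 10,
                                  readsPerSite = 200,
                                  internalPrimingRate = 0.1,
                                  blocklistReadsPerSample = 20,
                                  adapter = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
                                  tailMean = 18,
                                  readLength = 68,
                                  seed = 1) {
  if (!methods::is(truth, "TruthBundle") || length(truth@genome) == 0)
    stop("input error: truth bundle lacking genome")
  if (!nzchar(adapter)) stop("input error: adapter must be non-empty")
  if (internalPrimingRate < 0 || internalPrimingRate > 1)
    stop("input error: internalPrimingRate must lie in [0, 1]")
  set.seed(as.integer(seed))

  genomeChars <- lapply(as.character(truth@genome), function(s)
    strsplit(s, "")[[1]])
  ann <- truth@annotation
  genes <- ann[mcols(ann)$type == "gene"]

  # catalogue of pA sites with labels
  sites <- rbind(
    data.frame(chrom = as.character(seqnames(genes)),
               pos = ifelse(as.character(strand(genes)) == "+",
                            end(genes), start(genes)),
               strand = as.character(strand(genes)),
               gene_id = mcols(genes)$gene_id,
               label = "true_pa", stringsAsFactors = FALSE),
    if (length(truth@trueExtensions)) {
      e <- truth@trueExtensions
      data.frame(chrom = as.character(seqnames(e)),
                 pos = ifelse(as.character(strand(e)) == "+",
                              end(e), start(e)),
                 strand = as.character(strand(e)),
                 gene_id = mcols(e)$gene_id,
                 label = "extension_pa", stringsAsFactors = FALSE)
    } else NULL,
    if (length(truth@trueIntronicPa)) {
      i <- truth@trueIntronicPa
      data.frame(chrom = as.character(seqnames(i)), pos = start(i),
                 strand = as.character(strand(i)),
                 gene_id = mcols(i)$gene_id,
                 label = "intronic_pa", stringsAsFactors = FALSE)
    } else NULL
  )

  nInternalPerDecoy <- round(internalPrimingRate * readsPerSite)
  decoy <- truth@decoyArich
  samples <- sprintf("S%02d", seq_len(nSamples))

  # blocklist reference sequences (synthetic rRNA-like and BC1-like)
  blocklist <- Biostrings::DNAStringSet(c(
    rRNA_like = randomBases(2000),
    BC1_like = randomBases(200)
  ))

  siteInsert <- function(chrom, pos, strand, insLen = 40L) {
    # transcribed-strand sequence ending at pos
    chars <- genomeChars[[chrom]]
    if (strand == "+") {
      paste(chars[max(1L, pos - insLen + 1L):pos], collapse = "")
    } else {
      paste(rev(chartr("ACGT", "TGCA",
                       chars[pos:min(length(chars), pos + insLen - 1L)])),
            collapse = "")
    }
  }
  randomPrefixes <- function(n, len = 12L) {
    m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
                nrow = n)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  mkReads <- function(ins, tails) {
    raw <- paste0(randomPrefixes(length(tails)), ins,
                  strrep("A", tails), adapter)
    substr(raw, 1L, readLength)
  }

  sites$insert <- vapply(seq_len(nrow(sites)), function(r)
    siteInsert(sites$chrom[r], sites$pos[r], sites$strand[r]), character(1))

  readRows <- vector("list", nSamples)
  placeRows <- vector("list", nSamples)
  truthRows <- vector("list", nSamples)
  counter <- 0L
  for (si in seq_len(nSamples)) {
    smp <- samples[si]
    recs <- list(); plc <- list(); trt <- list()
    # true pA sites
    for (r in seq_len(nrow(sites))) {
      n <- readsPerSite
      tails <- pmax(8L, stats::rpois(n, tailMean))
      ids <- sprintf("read%07d", counter + seq_len(n)); counter <- counter + n
      seqs <- mkReads(sites$insert[r], tails)
      recs[[length(recs) + 1L]] <- data.frame(
        read_id = ids, sequence = seqs,
        quality = strrep("I", nchar(seqs)), stringsAsFactors = FALSE)
      plc[[length(plc) + 1L]] <- data.frame(
        read_id = ids, sample = smp, chrom = sites$chrom[r],
        pos_3prime = sites$pos[r], strand = sites$strand[r], mapq = 255L,
        stringsAsFactors = FALSE)
      trt[[length(trt) + 1L]] <- data.frame(
        read_id = ids, sample = smp, label = sites$label[r],
        gene_id = sites$gene_id[r], stringsAsFactors = FALSE)
    }
    # internal priming at decoys: 3' end lands just 5' of the A-rich run,
    # so the downstream window is the genomically encoded A stretch
    if (nInternalPerDecoy > 0 && length(decoy)) {
      for (d in seq_along(decoy)) {
        ch <- as.character(seqnames(decoy)[d])
        dstr <- as.character(strand(decoy)[d])
        pos <- if (dstr == "+") start(decoy)[d] - 1L else end(decoy)[d] + 1L
        n <- nInternalPerDecoy
        tails <- pmax(8L, stats::rpois(n, tailMean))
        ids <- sprintf("read%07d", counter + seq_len(n)); counter <- counter + n
        seqs <- mkReads(siteInsert(ch, pos, dstr), tails)
        recs[[length(recs) + 1L]] <- data.frame(
          read_id = ids, sequence = seqs,
          quality = strrep("I", nchar(seqs)), stringsAsFactors = FALSE)
        plc[[length(plc) + 1L]] <- data.frame(
          read_id = ids, sample = smp, chrom = ch, pos_3prime = pos,
          strand = dstr, mapq = 255L, stringsAsFactors = FALSE)
        trt[[length(trt) + 1L]] <- data.frame(
          read_id = ids, sample = smp, label = "internal_priming",
          gene_id = NA_character_, stringsAsFactors = FALSE)
      }
    }
    # blocklist reads: substrings of the blocklist references
    if (blocklistReadsPerSample > 0) {
      n <- blocklistReadsPerSample
      src <- sample(length(blocklist), n, replace = TRUE)
      ids <- sprintf("read%07d", counter + seq_len(n)); counter <- counter + n
      seqs <- vapply(src, function(b) {
        L <- Biostrings::width(blocklist)[b]
        st <- sample(L - 45L, 1L)
        paste0(randomBases(12L),
               as.character(Biostrings::subseq(blocklist[[b]], st, st + 39L)),
               strrep("A", 12L))
      }, character(1))
      recs[[length(recs) + 1L]] <- data.frame(
        read_id = ids, sequence = seqs,
        quality = strrep("I", nchar(seqs)), stringsAsFactors = FALSE)
      trt[[length(trt) + 1L]] <- data.frame(
        read_id = ids, sample = smp, label = "blocklist",
        gene_id = NA_character_, stringsAsFactors = FALSE)
    }
    readRows[[si]] <- do.call(rbind, recs)
    placeRows[[si]] <- do.call(rbind, plc)
    truthRows[[si]] <- do.call(rbind, trt)
  }

  list(reads = do.call(rbind, readRows),
       placements = do.call(rbind, placeRows),
       readTruth = do.call(rbind, truthRows),
       blocklist = blocklist)
}
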