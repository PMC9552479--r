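makePlacements <- function(df) {
  df$read_id <- sprintf("r%04d", seq_len(nrow(df)))
  if (is.null(df$mapq)) df$mapq <- rep(255L, nrow(df))
  df
}

test_that("end-signal pileups count 3'-most positions per sample", {
  pl <- makePlacements(data.frame(
    sample = "S1", chrom = "chr1",
    pos_3prime = c(100L, 100L, 100L, 105L), strand = "+"))
  tr <- buildEndSignal(pl)
  cnt <- trackCounts(tr)
  expect_identical(cnt$count[cnt$pos == 100], 3L)
  expect_identical(unname(librarySizes(tr)["S1"]), 4)
  # mapq filter removes placements and shrinks the library size
  pl2 <- pl; pl2$mapq <- c(255L, 0L, 255L, 255L)
  tr2 <- buildEndSignal(pl2)
  expect_identical(unname(librarySizes(tr2)["S1"]), 3)
  expect_identical(trackCounts(tr2)$count[trackCounts(tr2)$pos == 100], 2L)
  # unknown chromosomes are reported by name
  genome <- Biostrings::DNAStringSet(c(chr2 = "ACGT"))
  expect_error(buildEndSignal(pl, genome = genome), "chr1")
})

test_that("RPM scaling is linear in the library size", {
  pl <- makePlacements(data.frame(
    sample = "S1", chrom = "chr1",
    pos_3prime = c(rep(50L, 5), seq(1000L, 1994L, by = 2L)), strand = "+"))
  tr <- buildEndSignal(pl)   # library size 503
  ers <- detectExpressedRegions(tr, cutoffRpm = 5 * 1e6 / 503 - 1e-9)
  expect_true(any(GenomicRanges::start(ers) == 50))
})

test_that("ER detection matches the derived example and boundary rule", {
  # mean-RPM vector [0,2,2,0,3] at positions 10..14 -> ERs [11,12] and [14]
  pl <- makePlacements(data.frame(
    sample = "S1", chrom = "chr1",
    pos_3prime = c(11L, 11L, 12L, 12L, 14L, 14L, 14L), strand = "+"))
  tr <- buildEndSignal(pl)
  # library size 7 -> rescale cutoff so counts 2 and 3 clear it, 0 does not
  ers <- detectExpressedRegions(tr, cutoffRpm = 2 * 1e6 / 7)
  expect_identical(GenomicRanges::start(ers), c(11L, 14L))
  expect_identical(GenomicRanges::end(ers), c(12L, 14L))
  # a single sample exactly at cutoff is included (>=)
  pl1 <- makePlacements(data.frame(sample = "S1", chrom = "chr1",
                                   pos_3prime = 20L, strand = "+"))
  tr1 <- buildEndSignal(pl1)
  expect_length(detectExpressedRegions(tr1, cutoffRpm = 1e6), 1L)
  # empty track
  expect_length(detectExpressedRegions(
    buildEndSignal(makePlacements(data.frame(sample = character(),
                                             chrom = character(),
                                             pos_3prime = integer(),
                                             strand = character()))), 1), 0L)
})

test_that("ER detection agrees with a naive per-position scan oracle", {
  set.seed(31)
  for (trial in 1:200) {
    nS <- sample(2:4, 1)
    positions <- sort(sample(1:60, 25))
    pl <- do.call(rbind, lapply(seq_len(nS), function(s) {
      npl <- sample(30:60, 1)
      data.frame(sample = paste0("S", s), chrom = "chr1",
                 pos_3prime = sample(positions, npl, replace = TRUE),
                 strand = sample(c("+", "-"), npl, replace = TRUE))
    }))
    tr <- buildEndSignal(makePlacements(pl))
    cutoff <- stats::runif(1, 0.5, 2) * 1e6 / 40
    ers <- detectExpressedRegions(tr, cutoff)
    # oracle: dense per-position mean RPM per (chrom, strand)
    ls <- librarySizes(tr)
    for (str in c("+", "-")) {
      dense <- rep(0, 60)
      for (s in names(ls)) {
        sub <- pl[pl$sample == s & pl$strand == str, ]
        tab <- table(sub$pos_3prime)
        dense[as.integer(names(tab))] <- dense[as.integer(names(tab))] +
          as.numeric(tab) * 1e6 / ls[s] / length(ls)
      }
      expected <- oracleScanER(dense, 1:60, cutoff)
      got <- ers[as.character(GenomicRanges::strand(ers)) == str]
      expect_identical(nrow(expected), length(got))
      if (length(got)) {
        expect_identical(as.integer(expected[, "start"]),
                         GenomicRanges::start(got))
        expect_identical(as.integer(expected[, "end"]),
                         GenomicRanges::end(got))
      }
    }
  }
})

test_that("region classification allows overlapping categories", {
  tb <- makeTruthGenome(nGenes = 4, seed = 32)
  ann <- truthAnnotation(tb)
  genes <- ann[S4Vectors::mcols(ann)$type == "gene"]
  g <- genes[as.character(GenomicRanges::strand(genes)) == "+"][1]
  gs <- GenomicRanges::start(g)
  # ER inside the annotated 3'UTR (terminal exon)
  utr <- GenomicRanges::GRanges(GenomicRanges::seqnames(g),
                                IRanges::IRanges(GenomicRanges::end(g) - 10,
                                                 GenomicRanges::end(g)),
                                strand = "+")
  cl <- classifyRegions(utr, ann)
  expect_true(grepl("3'UTR", S4Vectors::mcols(cl)$categories))
  expect_true(grepl("exon", S4Vectors::mcols(cl)$categories))
  expect_false(S4Vectors::mcols(cl)$eligible)
  # ER spanning the exon1/intron1 boundary
  span <- GenomicRanges::GRanges(GenomicRanges::seqnames(g),
                                 IRanges::IRanges(gs + 195, gs + 205),
                                 strand = "+")
  cls <- classifyRegions(span, ann)
  expect_setequal(strsplit(S4Vectors::mcols(cls)$categories, ",")[[1]],
                  c("exon", "intron"))
  # ER overlapping nothing
  far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2, 3), strand = "+")
  clf <- classifyRegions(far, ann)
  expect_identical(S4Vectors::mcols(clf)$categories, "intergenic")
  expect_true(S4Vectors::mcols(clf)$eligible)
})

test_that("internal-priming rules match brute-force window checks", {
  set.seed(33)
  for (trial in 1:1000) {
    dw <- sample(c("A", "C", "G", "T"), 150, replace = TRUE,
                 prob = c(stats::runif(1, 0.1, 0.6), 0.2, 0.1, 0.1))
    ov <- sample(0:30, 1)
    expect_identical(EndSeqTools:::classifyDownstream(dw, ov),
                     oracleDownstreamStatus(dw, ov))
  }
})

test_that("filter boundary cases behave exactly as specified", {
  # helper genome: plus-strand ER at [101,110], downstream starts at 111
  mkGenome <- function(downstream) {
    Biostrings::DNAStringSet(c(chr1 = paste0(
      strrep("C", 110), paste(downstream, collapse = ""),
      strrep("G", 200))))
  }
  er <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 110),
                               strand = "+", categories = "intergenic",
                               eligible = TRUE)
  safe <- rep(c("C", "G", "T"), length.out = 150)
  # (c) exactly 50% A in the 20-bp window is kept; 55% is dropped
  win50 <- c(rep(c("A", "G"), 10), safe[21:150])
  expect_identical(
    S4Vectors::mcols(filterInternalPriming(er, mkGenome(win50)))$filter_status,
    "kept")
  # 11 A / 9 G interleaved so no 7-mer window reaches 6 A
  win55 <- c(rep(c("A", "G"), 9), "A", "A", safe[21:150])
  expect_identical(
    S4Vectors::mcols(filterInternalPriming(er, mkGenome(win55)))$filter_status,
    "drop_Afrac")
  # (b) 7-mer with one mismatch directly downstream
  win7 <- c(strsplit("AAAAAAT", "")[[1]], safe[8:150])
  expect_identical(
    S4Vectors::mcols(filterInternalPriming(er, mkGenome(win7)))$filter_status,
    "drop_7mer")
  # (a) 12 A in an 18-mer far from the end
  win18 <- c(safe[1:60], rep(c("A", "A", "G"), 6), safe[79:150])
  expect_identical(
    S4Vectors::mcols(filterInternalPriming(er, mkGenome(win18)))$filter_status,
    "drop_18mer")
  # (d) repeat overlap 21 bp drops, 20 bp keeps (ER [101,110] widened)
  erWide <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200),
                                   strand = "+", categories = "intergenic",
                                   eligible = TRUE)
  genomeSafe <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("C", 200), paste(safe, collapse = ""), strrep("G", 200))))
  rep21 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(180, 260))
  expect_identical(
    S4Vectors::mcols(filterInternalPriming(erWide, genomeSafe,
                                           rep21))$filter_status,
    "drop_repeat")
  rep20 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(181, 260))
  expect_identical(
    S4Vectors::mcols(filterInternalPriming(erWide, genomeSafe,
                                           rep20))$filter_status,
    "kept")
  # minus-strand ERs evaluate the transcribed strand: genomic T upstream
  erMinus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(300, 310),
                                    strand = "-", categories = "intergenic",
                                    eligible = TRUE)
  gMinus <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("C", 250), strrep("T", 49), strrep("G", 100))))
  expect_identical(
    S4Vectors::mcols(filterInternalPriming(erMinus, gMinus))$filter_status,
    "drop_18mer")
  # window truncation at the chromosome end
  erEnd <- GenomicRanges::GRanges("chr1", IRanges::IRanges(396, 399),
                                  strand = "+", categories = "intergenic",
                                  eligible = TRUE)
  gShort <- Biostrings::DNAStringSet(c(chr1 = paste0(strrep("C", 395),
                                                     "AAAA")))
  expect_identical(
    S4Vectors::mcols(filterInternalPriming(erEnd, gShort))$filter_status,
    "kept")
})

test_that("assignment precedence and augmentation follow the rules", {
  tb <- makeTruthGenome(nGenes = 6, fracExtensions = 0, fracIntronicPa = 0,
                        seed = 34)
  ann <- truthAnnotation(tb)
  genes <- ann[S4Vectors::mcols(ann)$type == "gene"]
  gPlus <- genes[as.character(GenomicRanges::strand(genes)) == "+"][1]
  ch <- as.character(GenomicRanges::seqnames(gPlus))
  gEnd <- GenomicRanges::end(gPlus)
  gid <- S4Vectors::mcols(gPlus)$gene_id
  mkEr <- function(st, en, str = "+") {
    GenomicRanges::GRanges(ch, IRanges::IRanges(st, en), strand = str,
                           categories = "intergenic", eligible = TRUE,
                           filter_status = "kept")
  }
  utr3 <- ann[S4Vectors::mcols(ann)$type == "three_prime_utr"]
  # 3 kb downstream -> extension; 6 kb -> unassigned
  aug <- assignAndAugment(mkEr(gEnd + 3000, gEnd + 3010), utr3, ann)
  expect_identical(assignmentTable(aug)$mode, "downstream_5kb")
  expect_identical(assignmentTable(aug)$gene, gid)
  expect_identical(GenomicRanges::end(extensionIntervals(aug)), gEnd + 3010L)
  # the gene row itself was extended monotonically
  newGene <- augmentedFeatures(aug)
  newGene <- newGene[S4Vectors::mcols(newGene)$type == "gene" &
                       S4Vectors::mcols(newGene)$gene_id == gid]
  expect_identical(GenomicRanges::end(newGene), gEnd + 3010L)
  augFar <- assignAndAugment(mkEr(gEnd + 6000, gEnd + 6010), utr3, ann)
  expect_identical(assignmentTable(augFar)$mode, "unassigned")
  # intronic ER gains a padded novel feature
  gs <- GenomicRanges::start(gPlus)
  intrEr <- mkEr(gs + 500, gs + 520)
  S4Vectors::mcols(intrEr)$categories <- "intron"
  augI <- assignAndAugment(intrEr, utr3, ann)
  expect_identical(assignmentTable(augI)$mode, "intronic")
  expect_identical(GenomicRanges::start(novelSites(augI)), gs + 495L)
  expect_identical(GenomicRanges::end(novelSites(augI)), gs + 525L)
  # ER overlapping a RefSeq 3'UTR: assignment only, no annotation change
  utrEr <- mkEr(GenomicRanges::start(utr3[S4Vectors::mcols(utr3)$gene_id ==
                                            gid]),
                GenomicRanges::start(utr3[S4Vectors::mcols(utr3)$gene_id ==
                                            gid]) + 5)
  augU <- assignAndAugment(utrEr, utr3, ann)
  expect_identical(assignmentTable(augU)$mode, "refseq_3utr")
  expect_length(novelSites(augU), 0L)
  expect_length(extensionIntervals(augU), 0L)
})

test_that("augmented GTF re-parses and gene ends grow monotonically", {
  tb <- makeTruthGenome(nGenes = 20, seed = 35)
  sim <- simulateQuantSeqReads(tb, nSamples = 4, readsPerSite = 50,
                               blocklistReadsPerSample = 0, seed = 35)
  tr <- buildEndSignal(sim$placements, genome = truthGenome(tb))
  ers <- detectExpressedRegions(tr)
  ers <- classifyRegions(ers, truthAnnotation(tb))
  ers <- filterInternalPriming(ers, truthGenome(tb), truthRepeats(tb))
  ann <- truthAnnotation(tb)
  utr3 <- ann[S4Vectors::mcols(ann)$type == "three_prime_utr"]
  aug <- assignAndAugment(ers, utr3, ann)
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeAugmentedGTF(aug, gtf)
  back <- readGTF(gtf)
  expect_identical(length(back), length(augmentedFeatures(aug)))
  # per gene: new end >= old end on +, new start <= old start on -
  oldGenes <- ann[S4Vectors::mcols(ann)$type == "gene"]
  newGenes <- back[S4Vectors::mcols(back)$type == "gene"]
  idx <- match(S4Vectors::mcols(oldGenes)$gene_id,
               S4Vectors::mcols(newGenes)$gene_id)
  plus <- as.character(GenomicRanges::strand(oldGenes)) == "+"
  expect_true(all(GenomicRanges::end(newGenes)[idx][plus] >=
                    GenomicRanges::end(oldGenes)[plus]))
  expect_true(all(GenomicRanges::start(newGenes)[idx][!plus] <=
                    GenomicRanges::start(oldGenes)[!plus]))
})
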