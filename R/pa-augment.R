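#' Assign surviving expressed regions to genes and augment the annotation
#'
#' Kept intron/intergenic ERs are assigned with the precedence:
#' (1) ER overlapping a RefSeq-style 3'UTR interval: read-assignment only,
#'     no annotation change;
#' (2) ER intronic in exactly one same-strand gene: a novel internal pA
#'     feature, the ER padded `intronicPad` bp each side (intronic in two or
#'     more same-strand genes: unassigned with reason `ambiguous_host`);
#' (3) ER within `maxDownstream` bp 3' of a same-strand gene end and not
#'     inside another gene: the gene's terminal 3'UTR and gene end are
#'     extended to the ER's far end (monotone: several ERs extend to the
#'     farthest);
#' (4) otherwise unassigned.
#'
#' @param ers GRanges from [filterInternalPriming()] (needs `filter_status`
#'   and `eligible` mcols). Only kept, eligible ERs are assigned.
#' @param refseq3utrs GRanges of RefSeq-style 3'UTR intervals with
#'   `gene_id`.
#' @param annotation Base annotation GRanges (`type`, `gene_id`).
#' @param maxDownstream Maximum downstream distance for extension (5000).
#' @param intronicPad Padding of intronic ERs (5 bp each side).
#' @return An [AugmentedAnnotation-class].
#' @export
assignAndAugment <- function(ers, refseq3utrs, annotation,
                             maxDownstream = 5000, intronicPad = 5) {
  genes <- annotation[mcols(annotation)$type == "gene"]
  introns <- intronRanges(annotation)
  n <- length(ers)
  gene <- rep(NA_character_, n)
  mode <- rep("unassigned", n)
  reason <- rep("", n)

  candidates <- which(mcols(ers)$eligible &
                        mcols(ers)$filter_status == "kept")
  for (i in candidates) {
    er <- ers[i]
    # (1) RefSeq 3'UTR (same strand)
    h <- GenomicRanges::findOverlaps(er, refseq3utrs)
    if (length(h)) {
      gene[i] <- mcols(refseq3utrs)$gene_id[S4Vectors::subjectHits(h)[1]]
      mode[i] <- "refseq_3utr"
      next
    }
    # (2) intronic in same-strand gene(s)
    hIntr <- GenomicRanges::findOverlaps(er, introns)
    hostGenes <- unique(mcols(introns)$gene_id[S4Vectors::subjectHits(hIntr)])
    if (length(hostGenes) == 1L) {
      gene[i] <- hostGenes
      mode[i] <- "intronic"
      next
    }
    if (length(hostGenes) >= 2L) {
      reason[i] <- "ambiguous_host"
      next
    }
    # (3) downstream extension: nearest same-strand gene whose end lies
    # within maxDownstream 5' of the ER, ER not inside another gene
    inGene <- GenomicRanges::countOverlaps(er, genes,
                                           ignore.strand = TRUE) > 0
    if (inGene) next
    plus <- as.character(strand(er)) == "+"
    sameStrand <- genes[as.character(strand(genes)) ==
                          as.character(strand(er)) &
                        as.character(seqnames(genes)) ==
                          as.character(seqnames(er))]
    if (length(sameStrand)) {
      if (plus) {
        d <- end(er) - end(sameStrand)
        ok <- d > 0 & d <= maxDownstream & start(er) > end(sameStrand)
      } else {
        d <- start(sameStrand) - start(er)
        ok <- d > 0 & d <= maxDownstream & end(er) < start(sameStrand)
      }
      if (any(ok)) {
        j <- which(ok)[which.min(d[ok])]
        gene[i] <- mcols(sameStrand)$gene_id[j]
        mode[i] <- "downstream_5kb"
        next
      }
    }
  }

  assignments <- data.frame(
    er = seq_len(n),
    chrom = as.character(seqnames(ers)),
    start = start(ers), end = end(ers),
    strand = as.character(strand(ers)),
    filter_status = mcols(ers)$filter_status,
    gene = gene, mode = mode, reason = reason,
    stringsAsFactors = FALSE
  )

  # --- build augmented annotation --------------------------------------
  ann <- annotation
  mcols(ann)$provenance <- "base"
  sl <- GenomeInfoDb::seqlengths(ann)

  novel <- GenomicRanges::GRanges(seqlengths = sl)
  intronicIdx <- which(mode == "intronic")
  if (length(intronicIdx)) {
    novel <- GenomicRanges::GRanges(
      as.character(seqnames(ers)[intronicIdx]),
      IRanges::IRanges(pmax(1L, start(ers)[intronicIdx] - intronicPad),
                       end(ers)[intronicIdx] + intronicPad),
      strand = strand(ers)[intronicIdx],
      type = "novel_internal_pa",
      gene_id = gene[intronicIdx],
      provenance = "novel_internal_pa",
      seqlengths = sl
    )
  }

  extensions <- GenomicRanges::GRanges(seqlengths = sl)
  extIdx <- which(mode == "downstream_5kb")
  if (length(extIdx)) {
    # farthest ER end per gene in the 3' direction
    extDf <- data.frame(gene = gene[extIdx],
                        st = start(ers)[extIdx], en = end(ers)[extIdx])
    perGene <- split(extDf, extDf$gene)
    extList <- lapply(perGene, function(d) {
      g <- genes[mcols(genes)$gene_id == d$gene[1]]
      if (as.character(strand(g)) == "+") {
        c(st = end(g) + 1L, en = max(d$en))
      } else {
        c(st = min(d$st), en = start(g) - 1L)
      }
    })
    extensions <- GenomicRanges::GRanges(
      vapply(names(extList), function(gn)
        as.character(seqnames(genes[mcols(genes)$gene_id == gn])),
        character(1)),
      IRanges::IRanges(vapply(extList, `[[`, numeric(1), "st"),
                       vapply(extList, `[[`, numeric(1), "en")),
      strand = vapply(names(extList), function(gn)
        as.character(strand(genes[mcols(genes)$gene_id == gn])),
        character(1)),
      type = "three_prime_utr",
      gene_id = names(extList),
      provenance = "extension",
      seqlengths = sl
    )
    # extend the gene rows themselves (monotone in the 3' direction)
    for (k in seq_along(extensions)) {
      gi <- which(mcols(ann)$type == "gene" &
                    mcols(ann)$gene_id == mcols(extensions)$gene_id[k])
      if (as.character(strand(extensions)[k]) == "+") {
        end(ann)[gi] <- max(end(ann)[gi], end(extensions)[k])
      } else {
        start(ann)[gi] <- min(start(ann)[gi], start(extensions)[k])
      }
    }
  }

  aug <- c(ann, novel, extensions)

  genesInternal <- unique(gene[intronicIdx])
  genesExtended <- unique(gene[extIdx])
  report <- list(
    genes_internal = length(genesInternal),
    genes_extended = length(genesExtended),
    genes_both = length(intersect(genesInternal, genesExtended)),
    n_er = n,
    n_assigned = sum(mode != "unassigned"),
    n_ambiguous = sum(reason == "ambiguous_host")
  )

  methods::new("AugmentedAnnotation",
               annotation = aug, novelSites = novel,
               extensions = extensions, assignments = assignments,
               report = report)
}

#' Write an augmented annotation as GTF
#'
#' @param augmented An [AugmentedAnnotation-class].
#' @param path Output GTF path.
#' @return Invisibly, `path`.
#' @export
writeAugmentedGTF <- function(augmented, path) {
  writeGTF(augmentedFeatures(augmented), path)
}
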