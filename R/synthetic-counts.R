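#' Simulate mRNA and miRNA count tables with injected effects
#'
#' Draws negative binomial counts (mean/size parameterization,
#' size = 1/dispersion) for a sex-by-age design mirroring the study layout:
#' five postnatal ages (PD12-PD37) for mRNA, four for miRNA (PD37 absent
#' from the small-RNA experiment), with miRNA replicates 1-3 in batch 1 and
#' 4-6 in batch 2. Sex effects are injected by multiplying the male group
#' mean at the chosen age by `2^log2FC`; a gene with different injected
#' log2FC at two ages is a sex-by-age interaction gene. A multiplicative
#' per-gene batch factor of strength `batchStrength` (sd of log2 factor)
#' perturbs batch-2 samples.
#'
#' @param ages Character vector of ages (mRNA design).
#' @param mirnaAges Ages profiled for miRNA (default drops PD37).
#' @param replicates Replicates per sex per age (>= 2).
#' @param nGenes,nMirna Number of mRNA genes / miRNAs.
#' @param baselineMean Scalar or per-gene vector of baseline NB means; a
#'   scalar is used for every gene.
#' @param dispersion NB dispersion (> 0); size = 1/dispersion.
#' @param effects `NULL` or data.frame with columns `gene`, `age`, `log2FC`
#'   (male-vs-female, positive = male-biased) for the mRNA table.
#' @param mirnaEffects Same layout for the miRNA table.
#' @param batchStrength sd of the per-gene log2 batch factor applied to
#'   miRNA batch 2 (0 = no batch effect).
#' @param seed Integer seed.
#' @return A list: `mrna` (counts matrix), `mirna` (counts matrix),
#'   `meta` (mRNA sample metadata), `mirnaMeta` (with `batch`), and
#'   `deTruth` / `mirnaTruth` truth tables of injected effects.
#' @export
simulateCountTables <- function(ages = c("PD12", "PD22", "PD27", "PD32", "PD37"),
                                mirnaAges = c("PD12", "PD22", "PD27", "PD32"),
                                replicates = 6,
                                nGenes = 2000,
                                nMirna = 100,
                                baselineMean = 200,
                                dispersion = 0.05,
                                effects = NULL,
                                mirnaEffects = NULL,
                                batchStrength = 0,
                                seed = 1) {
  if (replicates < 2) stop("input error: replicates must be >= 2 per group")
  if (dispersion <= 0) stop("input error: dispersion must be > 0")
  set.seed(as.integer(seed))

  simTable <- function(prefix, n, agesUse, eff, withBatch) {
    genes <- sprintf("%s%04d", prefix, seq_len(n))
    if (!is.null(eff)) {
      bad <- setdiff(eff$gene, genes)
      if (length(bad))
        stop("input error: effect gene(s) not in gene list: ",
             paste(utils::head(bad, 5), collapse = ", "))
    }
    meta <- expand.grid(replicate = seq_len(replicates),
                        sex = c("F", "M"), age = agesUse,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    meta$sample <- sprintf("%s_%s_%s_r%d", prefix, meta$age, meta$sex,
                           meta$replicate)
    if (withBatch) meta$batch <- ifelse(meta$replicate <= 3, "b1", "b2")
    base <- if (length(baselineMean) == 1) rep(baselineMean, n) else
      rep_len(baselineMean, n)
    mu <- matrix(base, nrow = n, ncol = nrow(meta))
    dimnames(mu) <- list(genes, meta$sample)
    if (!is.null(eff)) {
      for (r in seq_len(nrow(eff))) {
        male <- meta$sex == "M" & meta$age == eff$age[r]
        mu[eff$gene[r], male] <- mu[eff$gene[r], male] * 2^eff$log2FC[r]
      }
    }
    if (withBatch && batchStrength > 0) {
      bfac <- 2^stats::rnorm(n, 0, batchStrength)
      b2 <- meta$batch == "b2"
      mu[, b2] <- mu[, b2] * bfac
    }
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / dispersion),
                     nrow = n, dimnames = dimnames(mu))
    list(counts = counts, meta = meta)
  }

  m <- simTable("gene", nGenes, ages, effects, withBatch = FALSE)
  mi <- simTable("mir", nMirna, mirnaAges, mirnaEffects, withBatch = TRUE)

  list(mrna = m$counts, meta = m$meta,
       mirna = mi$counts, mirnaMeta = mi$meta,
       deTruth = if (is.null(effects)) data.frame(gene = character(),
                                                  age = character(),
                                                  log2FC = numeric())
                 else effects,
       mirnaTruth = if (is.null(mirnaEffects)) data.frame(gene = character(),
                                                          age = character(),
                                                          log2FC = numeric())
                    else mirnaEffects)
}

#' Simulate a labeled cell-type reference and bulk mixtures
#'
#' Builds per-cell-type mean expression profiles in which each type's marker
#' genes are `markerFc`-fold higher than baseline, draws a labeled
#' cell-by-gene count matrix (equal per-cell depth), and mixes the
#' depth-normalized type profiles by per-sample proportion vectors to
#' produce bulk counts with NB noise.
#'
#' @param cellTypes Character vector of cell-type names.
#' @param nGenes Number of genes.
#' @param markersPerType Marker genes per cell type (disjoint blocks).
#' @param markerFc Fold elevation of a marker in its own type.
#' @param cellsPerType Cells drawn per type.
#' @param proportions Matrix samples-by-celltypes of mixing proportions;
#'   rows must sum to 1 within 1e-9.
#' @param bulkDepth Bulk library depth (reads per sample).
#' @param cellDepth Per-cell depth.
#' @param dispersion NB dispersion for bulk noise.
#' @param seed Integer seed.
#' @return List: `cellExpr` (genes-by-cells counts), `cellLabels`,
#'   `typeMeans` (genes-by-types mean profiles = signature truth),
#'   `bulk` (genes-by-samples counts), `trueProportions`.
#' @export
simulateCellReference <- function(cellTypes = c("somatotrope", "lactotrope",
                                                "gonadotrope", "corticotrope"),
                                  nGenes = 400,
                                  markersPerType = 30,
                                  markerFc = 8,
                                  cellsPerType = 200,
                                  proportions = NULL,
                                  bulkDepth = 1e6,
                                  cellDepth = 5000,
                                  dispersion = 0.05,
                                  seed = 1) {
  set.seed(as.integer(seed))
  nT <- length(cellTypes)
  if (is.null(proportions)) {
    proportions <- matrix(1 / nT, nrow = 6, ncol = nT,
                          dimnames = list(sprintf("bulk%02d", 1:6), cellTypes))
  }
  if (is.null(colnames(proportions))) colnames(proportions) <- cellTypes
  if (is.null(rownames(proportions)))
    rownames(proportions) <- sprintf("bulk%02d", seq_len(nrow(proportions)))
  if (any(abs(rowSums(proportions) - 1) > 1e-9))
    stop("input error: proportions must sum to 1 within 1e-9")
  if (any(proportions < 0))
    stop("input error: proportions must be non-negative")

  genes <- sprintf("cg%04d", seq_len(nGenes))
  base <- stats::rlnorm(nGenes, meanlog = log(5), sdlog = 0.6)
  typeMeans <- matrix(base, nrow = nGenes, ncol = nT,
                      dimnames = list(genes, cellTypes))
  for (t in seq_len(nT)) {
    idx <- (t - 1) * markersPerType + seq_len(markersPerType)
    idx <- idx[idx <= nGenes]
    typeMeans[idx, t] <- typeMeans[idx, t] * markerFc
  }

  # cells: multinomial-like NB counts at equal depth
  labels <- rep(cellTypes, each = cellsPerType)
  prob <- sweep(typeMeans, 2, colSums(typeMeans), "/")
  cellExpr <- matrix(0L, nrow = nGenes, ncol = length(labels),
                     dimnames = list(genes, sprintf("cell%05d",
                                                    seq_along(labels))))
  for (t in seq_len(nT)) {
    cols <- which(labels == cellTypes[t])
    mu <- prob[, t] * cellDepth
    cellExpr[, cols] <- stats::rnbinom(nGenes * length(cols),
                                       mu = mu, size = 1 / 0.2)
  }

  # bulk: proportion-weighted mixture of depth-normalized profiles + NB noise
  mix <- prob %*% t(proportions)          # genes x samples, columns sum to 1
  bulkMu <- mix * bulkDepth
  bulk <- matrix(stats::rnbinom(length(bulkMu), mu = bulkMu,
                                size = 1 / dispersion),
                 nrow = nGenes, dimnames = dimnames(bulkMu))

  list(cellExpr = cellExpr, cellLabels = labels, typeMeans = typeMeans,
       bulk = bulk, trueProportions = proportions)
}
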