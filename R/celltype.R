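#' One-sided KS enrichment of module genes in cell types
#'
#' For each module gene and cell type, a one-sided two-sample
#' Kolmogorov-Smirnov test compares the gene's expression distribution
#' within the cell type against its distribution in all other cells, with
#' the alternative that within-type expression is stochastically greater:
#' D = sup over the pooled values of (F_other - F_within), floored at 0.
#' The one-sided p-value uses the asymptotic tail
#' exp(-2 D^2 n1 n2 / (n1 + n2)), robust to ties in count data. FDR is
#' adjusted over all gene-by-celltype tests.
#'
#' @param moduleGenes Character vector of genes to test.
#' @param cellExpr Genes-by-cells expression matrix.
#' @param cellLabels Cell-type label per column of `cellExpr`.
#' @return data.frame: `gene`, `celltype`, `D`, `p`, `FDR`. Genes absent
#'   from the reference are skipped (message).
#' @export
ksCellTypeEnrichment <- function(moduleGenes, cellExpr, cellLabels) {
  types <- unique(cellLabels)
  if (length(types) < 2) stop("need >= 2 cell types")
  if (min(table(cellLabels)) < 20)
    stop("need >= 20 cells per cell type")
  present <- moduleGenes %in% rownames(cellExpr)
  if (any(!present))
    message(sum(!present), " gene(s) absent from the reference; skipped")
  genes <- moduleGenes[present]
  out <- expand.grid(gene = genes, celltype = types,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  D <- p <- numeric(nrow(out))
  for (i in seq_len(nrow(out))) {
    x <- cellExpr[out$gene[i], cellLabels == out$celltype[i]]
    y <- cellExpr[out$gene[i], cellLabels != out$celltype[i]]
    D[i] <- ksStatGreater(x, y)
    p[i] <- exp(-2 * D[i]^2 * length(x) * length(y) /
                  (length(x) + length(y)))
  }
  out$D <- D
  out$p <- pmin(1, p)
  out$FDR <- bhAdjust(out$p)
  out
}

# sup over pooled values of (F_y - F_x); > 0 when x stochastically greater
ksStatGreater <- function(x, y) {
  v <- sort(unique(c(x, y)))
  Fx <- vapply(v, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(v, function(t) mean(y <= t), numeric(1))
  max(0, max(Fy - Fx))
}

#' Hypergeometric cell-type enrichment of modules
#'
#' With universe N = all module genes tested by KS, K = genes
#' KS-significant (FDR <= `ksFdr`) in the cell type, n = module size and
#' k = module genes significant in the type, the upper-tail hypergeometric
#' p is P(X >= k). FDR is adjusted over all module-by-celltype tests.
#'
#' @param ksRes data.frame from [ksCellTypeEnrichment()].
#' @param moduleSet A [ModuleSet-class] (or named list module -> genes).
#' @param ksFdr KS significance threshold (default 0.05).
#' @return data.frame: `module`, `celltype`, `k`, `K`, `n`, `N`, `p`,
#'   `FDR`.
#' @export
moduleCellTypeEnrichment <- function(ksRes, moduleSet, ksFdr = 0.05) {
  mods <- if (methods::is(moduleSet, "ModuleSet")) moduleList(moduleSet)
          else moduleSet
  testedGenes <- unique(ksRes$gene)
  N <- length(testedGenes)
  types <- unique(ksRes$celltype)
  sig <- ksRes[ksRes$FDR <= ksFdr, , drop = FALSE]
  out <- expand.grid(module = names(mods), celltype = types,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(out)), function(i) {
    mg <- intersect(mods[[out$module[i]]], testedGenes)
    sigType <- unique(sig$gene[sig$celltype == out$celltype[i]])
    k <- length(intersect(mg, sigType))
    K <- length(sigType)
    n <- length(mg)
    if (k > min(K, n))
      stop("internal consistency error: k > min(K, n)")
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    c(k = k, K = K, n = n, N = N, p = p)
  })
  res <- do.call(rbind, res)
  out <- cbind(out, as.data.frame(res))
  out$FDR <- bhAdjust(out$p)
  out
}

#' Build a cell-type signature matrix
#'
#' Restricts the labeled reference to its top `nTopVar` most variable
#' genes and takes per-type mean expression; all-zero rows are dropped.
#' Marker provenance (the type with maximal mean) is kept as an attribute.
#'
#' @param cellExpr Genes-by-cells expression matrix.
#' @param cellLabels Cell-type label per column.
#' @param nTopVar Number of top-variance genes retained (default 3000).
#' @return Genes-by-celltypes signature matrix `S` with attribute
#'   `provenance`.
#' @export
buildSignatureMatrix <- function(cellExpr, cellLabels, nTopVar = 3000) {
  v <- rowVars(cellExpr)
  keep <- order(v, decreasing = TRUE)[seq_len(min(nTopVar, nrow(cellExpr)))]
  sub <- cellExpr[sort(keep), , drop = FALSE]
  types <- unique(cellLabels)
  S <- vapply(types, function(t)
    rowMeans(sub[, cellLabels == t, drop = FALSE]), numeric(nrow(sub)))
  dimnames(S) <- list(rownames(sub), types)
  S <- S[rowSums(S) > 0, , drop = FALSE]
  attr(S, "provenance") <- colnames(S)[max.col(S)]
  S
}

#' Deconvolve bulk samples against a signature
#'
#' Per bulk sample, solves the non-negative least squares problem
#' min ||S p - b||_2 subject to p >= 0 over the genes shared between
#' signature and bulk (bulk CPM-scaled), then renormalizes p to the
#' simplex.
#'
#' @param S Signature matrix from [buildSignatureMatrix()].
#' @param bulk Genes-by-samples bulk count (or expression) matrix.
#' @param libSizes Optional bulk library sizes for CPM scaling.
#' @return list with `proportions` (samples x celltypes, rows on the
#'   simplex) and `residuals` (per-sample residual norm).
#' @export
deconvolveProportions <- function(S, bulk, libSizes = NULL) {
  shared <- intersect(rownames(S), rownames(bulk))
  if (length(shared) < 10)
    stop("fewer than 10 genes shared between signature and bulk")
  Ss <- S[shared, , drop = FALSE]
  if (ncol(Ss) > 1) {
    kap <- kappa(Ss)
    if (qr(Ss)$rank < ncol(Ss))
      warning("signature is rank deficient (condition number ", round(kap),
              ")")
  }
  B <- cpm(bulk[shared, , drop = FALSE], libSizes)
  props <- matrix(NA_real_, nrow = ncol(B), ncol = ncol(Ss),
                  dimnames = list(colnames(B), colnames(Ss)))
  resid <- stats::setNames(numeric(ncol(B)), colnames(B))
  for (j in seq_len(ncol(B))) {
    sol <- pracma::lsqnonneg(Ss, B[, j])
    pj <- sol$x
    if (sum(pj) <= 0) pj <- rep(1 / length(pj), length(pj))
    props[j, ] <- pj / sum(pj)
    resid[j] <- sqrt(sol$resid.norm)
  }
  list(proportions = props, residuals = resid)
}

#' Wilcoxon sex tests on estimated proportions
#'
#' Two-sided exact Wilcoxon rank-sum tests comparing per-sample estimated
#' proportions between sexes, per cell type per age. No multiplicity
#' adjustment (raw p-values, as starred in proportion figures). Ties fall
#' back to the midrank normal approximation (flagged in the output).
#'
#' @param proportions Samples-by-celltypes matrix from
#'   [deconvolveProportions()].
#' @param meta data.frame with `sample`, `sex`, `age` (rows matching the
#'   proportion matrix rows by sample name).
#' @return data.frame: `age`, `celltype`, `p`, `n_F`, `n_M`, `exact`.
#' @export
testProportionSexDifference <- function(proportions, meta) {
  meta <- meta[match(rownames(proportions), meta$sample), , drop = FALSE]
  combos <- expand.grid(age = unique(meta$age),
                        celltype = colnames(proportions),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- meta$age == combos$age[i]
    xf <- proportions[sel & meta$sex == "F", combos$celltype[i]]
    xm <- proportions[sel & meta$sex == "M", combos$celltype[i]]
    if (length(xf) < 3 || length(xm) < 3)
      stop("need >= 3 samples per sex per age")
    ties <- any(duplicated(c(xf, xm)))
    wt <- suppressWarnings(
      stats::wilcox.test(xf, xm, exact = !ties, correct = FALSE))
    data.frame(age = combos$age[i], celltype = combos$celltype[i],
               p = wt$p.value, n_F = length(xf), n_M = length(xm),
               exact = !ties, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Cell-weighted fold-changes
#'
#' Re-localizes a bulk sex-biased fold-change to cell types: with
#' specificity w(g,c) = S(g,c)/sum_c' S(g,c') and proportion factor r(c)
#' equal to the mean over sexes of the mean estimated proportion, the
#' cell-weighted fold-change is cwfc(g,c) = log2FC(g) * w(g,c) * r(c),
#' gene-normalized to cwfc_norm(g,c) = cwfc(g,c)/sum_c'|cwfc(g,c')| so the
#' absolute values sum to 1 per gene. A gene is called cell-type-specific
#' sex-biased in c when |cwfc_norm(g,c)| > 0.5.
#'
#' @param de data.frame with `gene` and `log2FC` (the sex-biased genes).
#' @param S Signature matrix.
#' @param propF,propM Samples-by-celltypes estimated proportions for
#'   female and male bulk samples.
#' @return data.frame: `gene`, `celltype`, `cwfc`, `cwfc_norm`, `called`.
#'   Genes absent from the signature or with an all-zero signature row are
#'   dropped (message).
#' @export
computeCwFC <- function(de, S, propF, propM) {
  inSig <- de$gene %in% rownames(S)
  if (any(!inSig))
    message(sum(!inSig), " gene(s) not detected in the reference; dropped")
  de <- de[inSig, , drop = FALSE]
  Ssub <- S[de$gene, , drop = FALSE]
  zero <- rowSums(Ssub) == 0
  if (any(zero)) {
    message(sum(zero), " gene(s) with all-zero signature rows; dropped")
    de <- de[!zero, , drop = FALSE]
    Ssub <- Ssub[!zero, , drop = FALSE]
  }
  w <- Ssub / rowSums(Ssub)
  r <- (colMeans(propF) + colMeans(propM)) / 2
  cw <- sweep(w, 2, r, "*") * de$log2FC
  norm <- cw / pmax(rowSums(abs(cw)), 1e-300)
  out <- data.frame(
    gene = rep(de$gene, ncol(cw)),
    celltype = rep(colnames(cw), each = nrow(cw)),
    cwfc = as.vector(cw),
    cwfc_norm = as.vector(norm),
    stringsAsFactors = FALSE
  )
  out$called <- abs(out$cwfc_norm) > 0.5
  out
}
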