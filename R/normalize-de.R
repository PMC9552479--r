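#' Select empirical negative-control genes
#'
#' Genes that do NOT respond to the experimental design are identified with
#' a moderated omnibus one-way F-test on log-CPM across all sex-by-age
#' groups; controls are the genes failing to reach FDR < `fdrThreshold`
#' (the least-varying genes, the standard construction of empirical
#' controls).
#'
#' @param counts Genes-by-samples count matrix.
#' @param meta Sample metadata data.frame with `sex` and `age` columns in
#'   column order of `counts`.
#' @param fdrThreshold FDR cutoff below which a gene is "responsive" and
#'   excluded from the controls (default 0.1).
#' @param libSizes Optional library sizes.
#' @return Character vector of control-gene identifiers. Warns when fewer
#'   than 50 controls are found.
#' @export
selectNegativeControls <- function(counts, meta, fdrThreshold = 0.1,
                                   libSizes = NULL) {
  group <- factor(paste(meta$sex, meta$age, sep = ":"))
  if (nlevels(group) < 2 || min(table(group)) < 2)
    stop("need >= 2 groups with >= 2 replicates")
  lc <- logCPM(counts, libSizes)
  design <- stats::model.matrix(~group)
  fit <- limma::eBayes(limma::lmFit(lc, design))
  # omnibus F over all non-intercept coefficients
  tt <- limma::topTable(fit, coef = 2:ncol(design), number = Inf,
                        sort.by = "none")
  fdr <- bhAdjust(tt$P.Value)
  controls <- rownames(counts)[fdr >= fdrThreshold | is.na(fdr)]
  if (length(controls) < 50)
    warning("fewer than 50 negative-control genes found (",
            length(controls), "); proceeding")
  controls
}

#' Estimate factors of unwanted variation
#'
#' Control-gene mode: the first k left singular vectors of the
#' sample-by-gene log-CPM matrix restricted to control genes, after
#' centering each gene across samples. Replicate-group mode: the same SVD
#' on log-CPM centered within sex-by-age groups, so biology is removed by
#' within-group centering and what remains is technical (e.g. the two-batch
#' structure of the small-RNA libraries).
#'
#' @param counts Genes-by-samples count matrix.
#' @param meta Sample metadata (needed for replicate-group mode).
#' @param controls Control-gene identifiers (control-gene mode).
#' @param k Number of factors (>= 1, < number of samples).
#' @param method `"control_gene_svd"` or `"replicate_group_svd"`.
#' @param libSizes Optional library sizes.
#' @return An [UnwantedFactors-class] with orthonormal `W` (samples x k).
#' @export
estimateUnwantedVariation <- function(counts, meta = NULL, controls = NULL,
                                      k = 1,
                                      method = c("control_gene_svd",
                                                 "replicate_group_svd"),
                                      libSizes = NULL) {
  method <- match.arg(method)
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  if (k >= ncol(counts)) stop("k must be smaller than the number of samples")
  lc <- logCPM(counts, libSizes)
  if (method == "control_gene_svd") {
    if (is.null(controls)) stop("control genes required for control_gene_svd")
    lc <- lc[rownames(lc) %in% controls, , drop = FALSE]
    centered <- lc - rowMeans(lc)
  } else {
    if (is.null(meta)) stop("meta required for replicate_group_svd")
    group <- paste(meta$sex, meta$age, sep = ":")
    centered <- lc
    for (g in unique(group)) {
      cols <- group == g
      centered[, cols] <- lc[, cols, drop = FALSE] -
        rowMeans(lc[, cols, drop = FALSE])
    }
  }
  sv <- svd(t(centered), nu = min(k + 2L, ncol(counts)))
  if (sum(sv$d > max(sv$d) * 1e-10) < k)
    stop("k exceeds the rank of the centered matrix")
  W <- sv$u[, seq_len(k), drop = FALSE]
  rownames(W) <- colnames(counts)
  methods::new("UnwantedFactors", W = W, k = k,
               controlGenes = if (is.null(controls)) character(0) else controls,
               method = method)
}

# --- NB dispersion: method-of-moments shrunk to a trimmed-mean common ----
estimateDispersions <- function(counts, group, libSizes) {
  geoLib <- exp(mean(log(libSizes)))
  y <- sweep(counts, 2, libSizes, "/") * geoLib   # depth-equalized counts
  groups <- unique(group)
  num <- rep(0, nrow(counts)); den <- rep(0, nrow(counts))
  for (g in groups) {
    cols <- which(group == g)
    if (length(cols) < 2) next
    m <- rowMeans(y[, cols, drop = FALSE])
    v <- rowVars(y[, cols, drop = FALSE])
    num <- num + (v - m) * length(cols)
    den <- den + m^2 * length(cols)
  }
  phi <- pmax(1e-4, num / pmax(den, 1e-8))
  common <- mean(phi, trim = 0.1)
  0.5 * phi + 0.5 * common
}

# orthonormal basis of the null space of a contrast (rows = coefficients)
nullSpaceBasis <- function(C) {
  C <- rbind(C)
  p <- ncol(C)
  qrC <- qr(t(C))
  qr.Q(qrC, complete = TRUE)[, (qrC$rank + 1L):p, drop = FALSE]
}

#' Negative binomial differential testing
#'
#' Per gene, an NB log-linear model with a log library-size offset is fit
#' over the sex-by-age cell means plus any unwanted-variation factors. The
#' per-gene dispersion is a method-of-moments estimate shrunk 50/50 toward
#' the trimmed-mean common dispersion. The contrast is tested with a
#' quasi-likelihood F statistic: the deviance difference between the full
#' and the contrast-constrained fit, divided by the full model's residual
#' deviance per degree of freedom, referred to F(1, residual df). The
#' denominator absorbs dispersion misestimation, which keeps the extreme
#' tail calibrated at small replicate numbers where the plain chi-square
#' likelihood ratio is anticonservative. Fold changes come from the fitted
#' coefficients (positive log2FC = male-biased). FDR is
#' Benjamini-Hochberg within the contrast.
#'
#' @param counts Genes-by-samples count matrix (filtered).
#' @param meta Sample metadata with `sex` and `age`, in column order.
#' @param W Optional [UnwantedFactors-class] (or samples-by-k matrix)
#'   appended to the design.
#' @param contrast Either `list(type = "sex", age = "PD27")` for the
#'   male-vs-female contrast within one age, or
#'   `list(type = "interaction", ages = c("PD12", "PD22"))` for the
#'   sex-by-age interaction between two ages.
#' @param libSizes Optional library sizes (default column sums).
#' @return data.frame: `gene`, `contrast`, `log2FC`, `p`, `FDR`, `called`
#'   (FDR < 0.05 and |FC| > 1.5 for sex contrasts; FDR < 0.05 for the
#'   interaction), `converged`.
#' @export
testDifferential <- function(counts, meta, W = NULL, contrast,
                             libSizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(libSizes)) libSizes <- colSums(counts)
  group <- factor(paste(meta$sex, meta$age, sep = ":"))
  X <- stats::model.matrix(~0 + group)
  colnames(X) <- levels(group)
  if (!is.null(W)) {
    Wm <- if (methods::is(W, "UnwantedFactors")) factorMatrix(W) else W
    colnames(Wm) <- paste0("W", seq_len(ncol(Wm)))
    X <- cbind(X, Wm)
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is not full rank")

  cvec <- rep(0, ncol(X)); names(cvec) <- colnames(X)
  if (contrast$type == "sex") {
    a <- contrast$age
    need <- c(paste0("M:", a), paste0("F:", a))
    if (!all(need %in% colnames(X)))
      stop("age ", a, " absent from design")
    cvec[need] <- c(1, -1)
    label <- paste0("sex@", a)
  } else if (contrast$type == "interaction") {
    a1 <- contrast$ages[1]; a2 <- contrast$ages[2]
    need <- c(paste0("M:", a2), paste0("F:", a2),
              paste0("M:", a1), paste0("F:", a1))
    if (!all(need %in% colnames(X)))
      stop("interaction ages absent from design")
    cvec[need] <- c(1, -1, -1, 1)
    label <- paste0("sexXage@", a1, ":", a2)
  } else stop("unknown contrast type: ", contrast$type)

  Xred <- X %*% nullSpaceBasis(cvec)
  phi <- estimateDispersions(counts, as.character(group), libSizes)
  off <- log(libSizes)

  nG <- nrow(counts)
  log2FC <- p <- rep(NA_real_, nG)
  converged <- rep(TRUE, nG)
  for (i in seq_len(nG)) {
    yi <- counts[i, ]
    fam <- MASS::negative.binomial(theta = 1 / phi[i])
    fitF <- tryCatch(
      stats::glm.fit(X, yi, family = fam, offset = off,
                     control = list(maxit = 50)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fitF)) {
      fitF <- suppressWarnings(tryCatch(
        stats::glm.fit(X, yi, family = fam, offset = off,
                       control = list(maxit = 100)),
        error = function(e) NULL))
    }
    fitR <- suppressWarnings(tryCatch(
      stats::glm.fit(Xred, yi, family = fam, offset = off,
                     control = list(maxit = 100)),
      error = function(e) NULL))
    if (is.null(fitF) || is.null(fitR) || !fitF$converged) {
      converged[i] <- FALSE
      p[i] <- 1; log2FC[i] <- 0
      next
    }
    lr <- max(0, fitR$deviance - fitF$deviance)
    rdf <- length(yi) - ncol(X)
    s2 <- max(fitF$deviance / rdf, 1e-8)
    p[i] <- stats::pf(lr / s2, 1, rdf, lower.tail = FALSE)
    log2FC[i] <- sum(cvec * fitF$coefficients) / log(2)
  }

  fdr <- bhAdjust(p)
  called <- if (contrast$type == "sex") {
    fdr < 0.05 & abs(log2FC) > log2(1.5)
  } else {
    fdr < 0.05
  }
  data.frame(gene = rownames(counts), contrast = label,
             log2FC = log2FC, p = p, FDR = fdr,
             called = called, converged = converged,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call sex-biased gene sets from differential results
#'
#' Splits called genes into male-biased (log2FC > 0) and female-biased per
#' age, and collects the sex-by-age interaction set (FDR only).
#'
#' @param deList Named list of data.frames from [testDifferential()] (one
#'   per contrast).
#' @param fcMin Fold-change threshold (default 1.5, strict).
#' @param fdrMax FDR threshold (default 0.05, strict).
#' @return A list: `male` and `female` (named lists age -> gene vector) and
#'   `interaction` (named list contrast -> gene vector).
#' @export
callSexBiased <- function(deList, fcMin = 1.5, fdrMax = 0.05) {
  male <- list(); female <- list(); interaction <- list()
  for (de in deList) {
    lbl <- de$contrast[1]
    if (startsWith(lbl, "sex@")) {
      age <- sub("^sex@", "", lbl)
      call <- de$FDR < fdrMax & abs(de$log2FC) > log2(fcMin)
      male[[age]] <- de$gene[call & de$log2FC > 0]
      female[[age]] <- de$gene[call & de$log2FC < 0]
    } else {
      interaction[[lbl]] <- de$gene[de$FDR < fdrMax]
    }
  }
  list(male = male, female = female, interaction = interaction)
}
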