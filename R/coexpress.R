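#' Inverse-gamma variance filter
#'
#' Models per-gene sample variances of log2 normalized expression as an
#' inverse-gamma distribution (maximum likelihood, fit as a gamma on the
#' reciprocals) and keeps genes whose variance is in the upper tail
#' (p < `pThreshold`). Zero-variance genes are never kept. On a degenerate
#' fit the top decile by variance is returned with a warning.
#'
#' @param expr Genes-by-samples matrix of log2 normalized expression.
#' @param pThreshold Upper-tail p cutoff (default 0.1).
#' @return Character vector of retained gene identifiers.
#' @export
filterVariance <- function(expr, pThreshold = 0.1) {
  if (ncol(expr) < 3) stop("need >= 3 samples")
  v <- rowVars(expr)
  pos <- v > 0
  fit <- tryCatch(
    fitdistrplus::fitdist(1 / v[pos], "gamma", method = "mle",
                          lower = c(1e-8, 1e-8)),
    error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit$estimate)) ||
      stats::sd(v[pos]) < 1e-12) {
    warning("degenerate inverse-gamma fit; falling back to top-decile variance")
    cut <- stats::quantile(v, 0.9)
    return(rownames(expr)[v > cut])
  }
  shape <- fit$estimate[["shape"]]
  rate <- fit$estimate[["rate"]]
  # P(V > v) = P(1/V < 1/v) under V ~ InvGamma(shape, rate)
  p <- rep(1, nrow(expr))
  p[pos] <- stats::pgamma(1 / v[pos], shape = shape, rate = rate)
  rownames(expr)[p < pThreshold & pos]
}

# scale-free topology fit index for a connectivity vector
scaleFreeR2 <- function(k, nBins = 10) {
  k <- k[k > 0]
  if (length(k) < nBins || max(k) <= min(k)) return(0)
  br <- seq(min(k) - 1e-9, max(k) + 1e-9, length.out = nBins + 1)
  bin <- cut(k, br, include.lowest = TRUE)
  dk <- as.numeric(tapply(k, bin, mean))
  pk <- as.numeric(table(bin)) / length(k)
  okBin <- !is.na(dk) & pk > 0 & dk > 0
  if (sum(okBin) < 3) return(0)
  fitLm <- stats::lm(log10(pk[okBin]) ~ log10(dk[okBin]))
  r2 <- summary(fitLm)$r.squared
  if (stats::coef(fitLm)[2] >= 0) 0 else r2
}

# soft-threshold fallback when no beta reaches the scale-free criterion:
# the conventional unsigned-network default by sample count
defaultBeta <- function(nSamples) {
  if (nSamples < 20) 9L else if (nSamples < 30) 8L else
    if (nSamples < 40) 7L else 6L
}

# unsigned topological overlap matrix from an adjacency matrix
tomSimilarity <- function(A) {
  diag(A) <- 0
  L <- A %*% A
  k <- colSums(A)
  kmin <- outer(k, k, pmin)
  tom <- (L + A) / (kmin + 1 - A)
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules
#'
#' Builds the unsigned weighted network `|cor|^beta`, chooses `beta`
#' automatically as the smallest integer in 1..20 reaching scale-free fit
#' R^2 >= 0.8 (falling back to the conventional unsigned default for the
#' sample count when none does), converts to topological-overlap
#' dissimilarity, clusters by average-linkage hierarchical clustering and
#' extracts modules with a dynamic cut: candidate cut heights spanning the
#' merge-height distribution are scanned and the height producing the most
#' quality-passing clusters of at least `minSize` genes wins (ties go to
#' the coarser cut). A cluster passes quality when its mean within-cluster
#' dissimilarity is at most `qualityGap` times its mean dissimilarity to
#' non-members, so diffuse noise branches fall to module 0. Modules are
#' labeled by decreasing size; module 0 collects unassigned genes.
#'
#' @param expr Genes-by-samples matrix (log2 normalized, variance
#'   filtered).
#' @param minSize Minimum module size (default 30).
#' @param beta Soft threshold; `NULL` for automatic selection.
#' @param qualityGap Within/between dissimilarity ratio a cluster must not
#'   exceed (default 0.95).
#' @param nHeights Number of candidate cut heights scanned (default 50).
#' @return A [ModuleSet-class].
#' @export
buildModules <- function(expr, minSize = 30, beta = NULL,
                         qualityGap = 0.95, nHeights = 50) {
  expr <- as.matrix(expr)
  if (nrow(expr) < minSize) stop("need at least minSize genes")
  cc <- abs(stats::cor(t(expr)))
  cc[is.na(cc)] <- 0
  if (is.null(beta)) {
    r2s <- vapply(1:12, function(b) scaleFreeR2(colSums(cc^b) - 1),
                  numeric(1))
    beta <- if (any(r2s >= 0.8)) min(which(r2s >= 0.8)) else
      defaultBeta(ncol(expr))
  }
  A <- cc^beta
  diss <- 1 - tomSimilarity(A)
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  genes <- rownames(expr)
  n <- length(genes)

  qualityRatio <- function(members) {
    if (length(members) == n) return(0)  # single all-gene module
    sub <- diss[members, members]
    within <- mean(sub[upper.tri(sub)])
    between <- mean(diss[members, -members, drop = FALSE])
    if (is.nan(within) || between == 0) 0 else within / between
  }
  goodClusters <- function(h) {
    cl <- stats::cutree(hc, h = h)
    sizes <- table(cl)
    ids <- as.integer(names(sizes)[sizes >= minSize])
    out <- lapply(ids, function(cid) {
      members <- which(cl == cid)
      qr <- qualityRatio(members)
      if (qr <= qualityGap) list(members = members, ratio = qr) else NULL
    })
    Filter(Negate(is.null), out)
  }
  hts <- sort(unique(hc$height))
  cands <- unique(stats::quantile(hts, seq(0.02, 1, length.out = nHeights),
                                  type = 1, names = FALSE))
  # best cut: most quality-passing clusters; ties broken by the tightest
  # clusters (lowest mean within/between ratio), then by the coarser cut
  keptClusters <- list(); bestScore <- -1L; bestRatio <- Inf
  for (h in cands) {
    gc <- goodClusters(h * (1 - 1e-9))
    mr <- if (length(gc)) mean(vapply(gc, `[[`, numeric(1), "ratio")) else Inf
    if (length(gc) > bestScore ||
        (length(gc) == bestScore && mr <= bestRatio)) {
      keptClusters <- lapply(gc, `[[`, "members")
      bestScore <- length(gc)
      bestRatio <- mr
    }
  }
  if (length(keptClusters) == 1L && length(keptClusters[[1]]) == n)
    warning("all genes fall in a single module")

  assignment <- stats::setNames(rep(0L, n), genes)
  if (length(keptClusters)) {
    ord <- order(vapply(keptClusters, length, integer(1)),
                 decreasing = TRUE)
    for (m in seq_along(ord))
      assignment[keptClusters[[ord[m]]]] <- m
    # PAM-like stage: adopt unassigned genes whose mean dissimilarity to
    # the nearest module clears the same quality gap, so branch members
    # orphaned by a fine cut rejoin while diffuse genes stay out
    un <- which(assignment == 0L)
    if (length(un) && length(un) < n) {
      memberIdx <- lapply(seq_along(ord), function(m)
        which(assignment == m))
      for (g in un) {
        dMod <- vapply(memberIdx, function(mem) mean(diss[g, mem]),
                       numeric(1))
        m <- which.min(dMod)
        rest <- setdiff(seq_len(n), c(memberIdx[[m]], g))
        dOther <- if (length(rest)) mean(diss[g, rest]) else Inf
        if (dMod[m] <= qualityGap * dOther) assignment[g] <- m
      }
    }
  }
  modules <- lapply(sort(unique(assignment[assignment > 0])), function(m)
    genes[assignment == m])
  names(modules) <- if (length(modules))
    paste0("M", seq_along(modules)) else character(0)
  methods::new("ModuleSet", assignment = assignment, modules = modules,
               beta = as.numeric(beta), minSize = as.integer(minSize))
}

#' Module eigengenes and hub genes
#'
#' The eigengene of a module is the first principal component score (over
#' samples) of the module genes' row-scaled expression, with the sign fixed
#' so that its correlation with the module's mean expression profile is
#' positive. Hubs are the top 10 genes by summed within-module adjacency
#' (`|cor|^beta` row sums); modules smaller than 10 list all their genes.
#'
#' @param moduleSet A [ModuleSet-class].
#' @param expr The expression matrix used to build the modules.
#' @return list with `eigengenes` (samples x modules matrix) and `hubs`
#'   (named list module -> ranked gene vector).
#' @export
summarizeModules <- function(moduleSet, expr) {
  mods <- moduleList(moduleSet)
  if (length(mods) == 0) stop("module set is empty")
  beta <- softThreshold(moduleSet)
  eig <- matrix(NA_real_, nrow = ncol(expr), ncol = length(mods),
                dimnames = list(colnames(expr), names(mods)))
  hubs <- vector("list", length(mods))
  names(hubs) <- names(mods)
  for (m in names(mods)) {
    sub <- expr[mods[[m]], , drop = FALSE]
    scaled <- t(scale(t(sub)))
    scaled[is.na(scaled)] <- 0
    sv <- svd(scaled, nu = 1, nv = 1)
    e <- sv$v[, 1] * sv$d[1]
    mprof <- colMeans(sub)
    if (stats::sd(mprof) > 0 && stats::cor(e, mprof) < 0) e <- -e
    eig[, m] <- e
    Asub <- abs(stats::cor(t(sub)))^beta
    diag(Asub) <- 0
    conn <- rowSums(Asub)
    hubs[[m]] <- names(sort(conn, decreasing = TRUE))[
      seq_len(min(10L, length(conn)))]
  }
  list(eigengenes = eig, hubs = hubs)
}
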