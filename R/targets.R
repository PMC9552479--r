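#' Load and unify miRNA target tables
#'
#' Reads a TargetScan-summary-style predicted-target table and a
#' miRTarBase-style validated-target table, filters predicted pairs by the
#' cumulative weighted context score, and unifies duplicates keeping both
#' source flags.
#'
#' Recognized columns (case- and punctuation-tolerant): miRNA identifier
#' (`miRNA` / `Representative miRNA`), gene (`Gene Symbol` /
#' `Target Gene`), and for predicted tables a context score column whose
#' name contains "context" and "score".
#'
#' @param predicted data.frame or TSV path of predicted targets.
#' @param validated data.frame or TSV path of validated targets (optional).
#' @param scoreMax Retain predicted pairs with score < `scoreMax`
#'   (default -0.1).
#' @return data.frame: `mirna_id`, `gene`, `predicted`, `validated`,
#'   `context_score` (NA for validated-only pairs).
#' @export
loadTargetPairs <- function(predicted, validated = NULL, scoreMax = -0.1) {
  readTab <- function(x) {
    if (is.character(x))
      utils::read.delim(x, check.names = FALSE, stringsAsFactors = FALSE)
    else x
  }
  findCol <- function(df, patterns, what) {
    nm <- tolower(gsub("[^a-z0-9]+", " ", tolower(names(df))))
    for (p in patterns) {
      hit <- grep(p, nm)
      if (length(hit)) return(names(df)[hit[1]])
    }
    stop("format error: missing required column (", what, "); have: ",
         paste(names(df), collapse = ", "))
  }
  pred <- readTab(predicted)
  mCol <- findCol(pred, c("^mirna$", "representative mirna", "mirna"), "miRNA")
  gCol <- findCol(pred, c("gene symbol", "target gene", "^gene$"), "gene")
  sCol <- findCol(pred, c("context.*score"), "context score")
  score <- as.numeric(pred[[sCol]])
  keep <- !is.na(score) & score < scoreMax
  pairs <- data.frame(mirna_id = pred[[mCol]][keep],
                      gene = pred[[gCol]][keep],
                      predicted = TRUE, validated = FALSE,
                      context_score = score[keep],
                      stringsAsFactors = FALSE)
  if (!is.null(validated)) {
    val <- readTab(validated)
    mCol <- findCol(val, c("^mirna$", "mirna"), "miRNA")
    gCol <- findCol(val, c("target gene", "gene symbol", "^gene$"), "gene")
    vp <- data.frame(mirna_id = val[[mCol]], gene = val[[gCol]],
                     predicted = FALSE, validated = TRUE,
                     context_score = NA_real_, stringsAsFactors = FALSE)
    key <- paste(pairs$mirna_id, pairs$gene)
    vkey <- paste(vp$mirna_id, vp$gene)
    both <- vkey %in% key
    pairs$validated[key %in% vkey] <- TRUE
    pairs <- rbind(pairs, vp[!both, , drop = FALSE])
  }
  pairs[!duplicated(paste(pairs$mirna_id, pairs$gene)), , drop = FALSE]
}

#' Spearman correlation with average ranks
#'
#' Pearson correlation of midranks, with an exact permutation p-value for
#' n <= 9 (full enumeration of rank assignments, two-sided) and the
#' t-approximation otherwise.
#'
#' @param x,y Numeric vectors of equal length.
#' @return list with `rho` and `p` (NA rho for constant input).
#' @export
spearmanRho <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    perms <- permutationMatrix(n)
    # rho for each permutation from the cross-product sum
    S <- matrix(ry[perms], nrow(perms)) %*% rx
    mx <- mean(rx); my <- mean(ry)
    sx <- stats::sd(rx); sy <- stats::sd(ry)
    rhoPerm <- (S - n * mx * my) / ((n - 1) * sx * sy)
    p <- mean(abs(rhoPerm) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p)
}

# all permutations of 1..n as an n!-by-n matrix (recursive construction)
permutationMatrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutationMatrix(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub))
  }
  out
}

#' miRNA-target anticorrelation network
#'
#' For every curated target pair whose miRNA and gene are both sex-biased
#' at some profiled age, Spearman's rho is computed on log2-normalized
#' expression over the matched samples (the sample-ID intersection of the
#' two matrices). Pairs are edges of the repression network when rho < 0
#' and BH FDR < `fdrMax` over the tested pairs.
#'
#' @param pairs data.frame from [loadTargetPairs()].
#' @param mirnaExpr,geneExpr Log2-normalized expression matrices (rows
#'   miRNA / gene identifiers, columns sample IDs).
#' @param sexBiasedMirnas,sexBiasedGenes Identifier vectors restricting the
#'   tested pairs (sex-biased at any profiled age).
#' @param fdrMax FDR threshold for a negative edge (default 0.1).
#' @return list with `edges` (all tested pairs: rho, p, FDR,
#'   negative_significant, skipped reason) and `network` (the significant
#'   negative edges with per-node degree columns).
#' @export
correlatePairs <- function(pairs, mirnaExpr, geneExpr,
                           sexBiasedMirnas, sexBiasedGenes, fdrMax = 0.1) {
  matched <- intersect(colnames(mirnaExpr), colnames(geneExpr))
  if (length(matched) < 5)
    stop("need >= 5 matched samples between miRNA and gene expression")
  tested <- pairs[pairs$mirna_id %in% sexBiasedMirnas &
                    pairs$gene %in% sexBiasedGenes &
                    pairs$mirna_id %in% rownames(mirnaExpr) &
                    pairs$gene %in% rownames(geneExpr), , drop = FALSE]
  if (nrow(tested) == 0)
    return(list(edges = data.frame(), network = data.frame()))
  rho <- p <- rep(NA_real_, nrow(tested))
  reason <- rep("", nrow(tested))
  for (i in seq_len(nrow(tested))) {
    x <- mirnaExpr[tested$mirna_id[i], matched]
    y <- geneExpr[tested$gene[i], matched]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      reason[i] <- "constant_vector"
      next
    }
    sp <- spearmanRho(x, y)
    rho[i] <- sp$rho; p[i] <- sp$p
  }
  fdr <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  fdr[ok] <- bhAdjust(p[ok])
  edges <- data.frame(tested, rho = rho, p = p, FDR = fdr,
                      negative_significant = !is.na(rho) & rho < 0 &
                        !is.na(fdr) & fdr < fdrMax,
                      skip_reason = reason,
                      stringsAsFactors = FALSE, row.names = NULL)
  net <- edges[edges$negative_significant, , drop = FALSE]
  if (nrow(net)) {
    net$mirna_degree <- as.integer(table(net$mirna_id)[net$mirna_id])
    net$gene_degree <- as.integer(table(net$gene)[net$gene])
  }
  list(edges = edges, network = net)
}
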