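# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive re-derivations (per-position scans, explicit window
# counting, rank-definition arithmetic, exact enumeration) kept separate
# from the package implementations they check.

# naive per-position ER scan on a dense mean-RPM vector
oracleScanER <- function(meanRpm, positions, cutoff = 1) {
  ok <- meanRpm >= cutoff
  ers <- list()
  i <- 1
  while (i <= length(ok)) {
    if (ok[i] && (i == 1 || !ok[i - 1] || positions[i] - positions[i - 1] > 1)) {
      j <- i
      while (j + 1 <= length(ok) && ok[j + 1] &&
             positions[j + 1] - positions[j] == 1) j <- j + 1
      ers[[length(ers) + 1]] <- c(start = positions[i], end = positions[j])
      i <- j + 1
    } else i <- i + 1
  }
  if (length(ers)) do.call(rbind, ers) else
    matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
}

# brute-force internal-priming window rules on a downstream base vector
oracleDownstreamStatus <- function(dw, repeatOverlap = 0) {
  isA <- dw == "A"
  n <- length(isA)
  has18 <- FALSE
  if (n >= 18) {
    for (s in 1:(n - 17)) if (sum(isA[s:(s + 17)]) >= 12) has18 <- TRUE
  } else if (n > 0 && sum(isA) >= 12) has18 <- TRUE
  if (has18) return("drop_18mer")
  m <- min(n, 20)
  has7 <- FALSE
  if (m >= 7) {
    for (s in 1:(m - 6)) if (sum(isA[s:(s + 6)]) >= 6) has7 <- TRUE
  } else if (m > 0 && sum(isA[1:m]) >= 6) has7 <- TRUE
  if (has7) return("drop_7mer")
  if (m > 0 && sum(isA[1:m]) > 0.5 * m) return("drop_Afrac")
  if (repeatOverlap > 20) return("drop_repeat")
  "kept"
}

# Spearman rho from the rank definition: midranks computed element-wise,
# then the explicit product-moment sum formula
oracleSpearman <- function(x, y) {
  midrank <- function(v) {
    vapply(seq_along(v), function(i)
      sum(v < v[i]) + (1 + sum(v == v[i])) / 2, numeric(1))
  }
  rx <- midrank(x); ry <- midrank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# upper-tail hypergeometric P(X >= k) by direct enumeration of choose terms
oracleHyper <- function(k, K, N, n) {
  tot <- choose(N, n)
  sum(vapply(k:min(K, n), function(j)
    choose(K, j) * choose(N - K, n - j), numeric(1))) / tot
}

# one-sided KS statistic: sup over a fine grid of (F_other - F_within)
oracleKsD <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  d <- vapply(grid, function(t) mean(y <= t) - mean(x <= t), numeric(1))
  max(0, max(d))
}

# planted three-block expression matrix used by module-recovery tests
makeBlockExpr <- function(seed, nPerBlock = 40, nNoise = 20, nSamples = 40,
                          rho = 0.8) {
  set.seed(seed)
  blocks <- lapply(1:3, function(b) {
    base <- rnorm(nSamples)
    t(sapply(seq_len(nPerBlock), function(i)
      base * sqrt(rho) + rnorm(nSamples) * sqrt(1 - rho)))
  })
  expr <- do.call(rbind, c(blocks, list(matrix(rnorm(nNoise * nSamples),
                                               nNoise))))
  rownames(expr) <- sprintf("g%03d", seq_len(nrow(expr)))
  list(expr = expr,
       truth = rep(c(1, 2, 3, 0), c(nPerBlock, nPerBlock, nPerBlock,
                                    nNoise)))
}
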