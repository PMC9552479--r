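test_that("the one-sided KS statistic matches the sup-CDF oracle", {
  # explicit 5-point samples, checked by hand against the CDF difference
  x <- c(5, 6, 7, 8, 9)
  y <- c(1, 2, 3, 4, 5)
  D <- EndSeqTools:::ksStatGreater(x, y)
  expect_equal(D, oracleKsD(x, y))
  expect_equal(D, 0.8)          # F_y - F_x peaks at t = 4
  # identical samples: D = 0, p = 1
  D0 <- EndSeqTools:::ksStatGreater(x, x)
  expect_equal(D0, 0)
  set.seed(91)
  for (i in 1:100) {
    a <- sample(1:8, 5, replace = TRUE)
    b <- sample(1:8, 5, replace = TRUE)
    expect_equal(EndSeqTools:::ksStatGreater(a, b), oracleKsD(a, b))
  }
})

test_that("KS enrichment flags genes elevated in one cell type", {
  set.seed(92)
  hits <- vapply(1:20, function(i) {
    nC <- 200
    expr <- rbind(gX = c(rlnorm(nC, log(40), 0.5),   # 4-fold up in type A
                         rlnorm(nC, log(10), 0.5)))
    labels <- rep(c("A", "B"), each = nC)
    ks <- ksCellTypeEnrichment("gX", expr, labels)
    ks$FDR[ks$celltype == "A"] <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # flat gene: D = 0 and p = 1 in both directions
  set.seed(93)
  flat <- rbind(gF = rep(rlnorm(100, log(10), 0.3), 4))
  labs <- rep(c("A", "B"), each = 200)
  ksF <- ksCellTypeEnrichment("gF", flat, labs)
  expect_equal(min(ksF$p), 1)
  expect_error(ksCellTypeEnrichment("gF", flat, rep("A", 400)), "2 cell")
})

test_that("hypergeometric module enrichment equals exact enumeration", {
  # N=20, K=10, n=5, k=5 -> 252/15504
  ks <- data.frame(gene = sprintf("g%02d", 1:20), celltype = "A",
                   D = 0.5, p = c(rep(1e-4, 10), rep(0.9, 10)))
  ks$FDR <- bhAdjust(ks$p)
  mods <- list(M1 = sprintf("g%02d", 1:5))
  en <- moduleCellTypeEnrichment(ks, mods)
  expect_equal(en$p, 252 / 15504, tolerance = 1e-12)
  expect_equal(en$p, oracleHyper(5, 10, 20, 5), tolerance = 1e-12)
  # k = 0 -> p = 1
  mods0 <- list(M1 = sprintf("g%02d", 11:15))
  expect_equal(moduleCellTypeEnrichment(ks, mods0)$p, 1)
  # random cases vs the enumeration oracle, N <= 25
  set.seed(94)
  for (i in 1:50) {
    N <- sample(10:25, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    genes <- sprintf("x%02d", 1:N)
    ksR <- data.frame(gene = genes, celltype = "A", D = 0.5,
                      p = ifelse(seq_len(N) <= K, 1e-4, 0.9))
    ksR$FDR <- ksR$p            # keep the K set exact
    got <- moduleCellTypeEnrichment(ksR, list(M = genes[sample(N, n)]),
                                    ksFdr = 0.05)
    k <- got$k
    expect_equal(got$p, oracleHyper(k, K, N, n), tolerance = 1e-10)
  }
})

test_that("marker-driven modules enrich in their cell type", {
  ref <- simulateCellReference(cellTypes = c("A", "B", "C"), nGenes = 150,
                               markersPerType = 20, markerFc = 8,
                               cellsPerType = 150, seed = 95)
  markersA <- rownames(ref$cellExpr)[1:20]
  othersTested <- rownames(ref$cellExpr)[61:100]
  ks <- ksCellTypeEnrichment(c(markersA, othersTested), ref$cellExpr,
                             ref$cellLabels)
  en <- moduleCellTypeEnrichment(ks, list(M1 = markersA))
  expect_lt(en$FDR[en$celltype == "A"], 0.05)
})

test_that("deconvolution recovers proportions on the simplex", {
  ref <- simulateCellReference(seed = 96)
  S <- buildSignatureMatrix(ref$cellExpr, ref$cellLabels, nTopVar = 300)
  # noiseless mixture: exact recovery
  pstar <- c(0.5, 0.2, 0.2, 0.1)
  b <- S %*% pstar
  dc <- deconvolveProportions(S, b)
  expect_lt(max(abs(dc$proportions[1, ] - pstar)), 1e-6)
  # bulk equal to one signature column: unit vector
  dc1 <- deconvolveProportions(S, S[, 2, drop = FALSE])
  expect_equal(unname(dc1$proportions[1, 2]), 1, tolerance = 1e-8)
  # simplex invariants on noisy generator bulk (50 samples at depth 1e6)
  props <- matrix(rep(c(0.4, 0.3, 0.2, 0.1), each = 50), nrow = 50)
  ref2 <- simulateCellReference(proportions = props, bulkDepth = 1e6,
                                seed = 97)
  S2 <- buildSignatureMatrix(ref2$cellExpr, ref2$cellLabels, nTopVar = 300)
  dc2 <- deconvolveProportions(S2, ref2$bulk)
  expect_true(all(dc2$proportions >= 0))
  expect_equal(unname(rowSums(dc2$proportions)), rep(1, 50),
               tolerance = 1e-9)
  # loose sanity bound here; the tight accuracy property is asserted once
  # in the end-to-end acceptance checks
  expect_lt(mean(abs(dc2$proportions - ref2$trueProportions)), 0.05)
  expect_error(deconvolveProportions(S[1:5, ], ref2$bulk), "10 genes")
})

test_that("Wilcoxon proportion tests match exact enumeration", {
  props <- matrix(c(0.1, 0.11, 0.12, 0.2, 0.21, 0.22), ncol = 1,
                  dimnames = list(sprintf("s%d", 1:6), "ct"))
  meta <- data.frame(sample = sprintf("s%d", 1:6),
                     sex = rep(c("F", "M"), each = 3), age = "PD12")
  res <- testProportionSexDifference(props, meta)
  expect_equal(res$p, 0.1)      # 2 / C(6,3) most extreme orderings
  expect_true(res$exact)
  # identical groups: p = 1 (ties force the midrank approximation)
  propsEq <- matrix(rep(c(0.1, 0.2, 0.3), 2), ncol = 1,
                    dimnames = list(sprintf("s%d", 1:6), "ct"))
  resEq <- testProportionSexDifference(propsEq, meta)
  expect_equal(resEq$p, 1)
  expect_false(resEq$exact)
  expect_error(testProportionSexDifference(props[1:5, , drop = FALSE],
                                           meta[1:5, ]), ">= 3")
})

test_that("sex-shifted proportions are detected per age", {
  set.seed(98)
  hits <- vapply(1:20, function(i) {
    pF <- 0.20 + rnorm(6, 0, 0.02)
    pM <- 0.28 + rnorm(6, 0, 0.02)
    props <- cbind(somato = c(pF, pM), other = 1 - c(pF, pM))
    rownames(props) <- sprintf("s%02d", 1:12)
    meta <- data.frame(sample = rownames(props),
                       sex = rep(c("F", "M"), each = 6), age = "PD37")
    res <- testProportionSexDifference(props, meta)
    res$p[res$celltype == "somato"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("cwFC identities hold exactly", {
  S <- matrix(c(1, 0, 0, 0,
                1, 1, 1, 1,
                0, 0, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("single", "uniform", "absent"),
                              paste0("ct", 1:4)))
  de <- data.frame(gene = c("single", "uniform", "absent", "missing"),
                   log2FC = c(2, -1, 1, 1))
  pEq <- matrix(0.25, 4, 4, dimnames = list(NULL, paste0("ct", 1:4)))
  expect_message(computeCwFC(de, S, pEq, pEq), "not detected")
  cw <- suppressMessages(computeCwFC(de, S, pEq, pEq))
  # single-type gene: |cwfc_norm| = 1 there, called
  sgl <- cw[cw$gene == "single", ]
  expect_equal(sort(abs(sgl$cwfc_norm)), c(0, 0, 0, 1))
  expect_identical(sum(sgl$called), 1L)
  # uniform 4-type gene with equal proportions: 0.25 everywhere, never called
  uni <- cw[cw$gene == "uniform", ]
  expect_equal(abs(uni$cwfc_norm), rep(0.25, 4))
  expect_false(any(uni$called))
  # |cwfc_norm| sums to 1 per gene; signs track the bulk log2FC
  expect_equal(sum(abs(sgl$cwfc_norm)), 1)
  expect_true(all(sign(uni$cwfc[uni$cwfc != 0]) == -1))
  expect_false(any(cw$gene %in% c("absent", "missing")))
})

test_that("proportion-driven sex bias localizes to the shifted cell type", {
  # genes expressed mostly in one cell type whose proportion differs by sex
  ref <- simulateCellReference(cellTypes = c("A", "B", "C"), nGenes = 150,
                               markersPerType = 20, markerFc = 12,
                               seed = 99)
  S <- buildSignatureMatrix(ref$cellExpr, ref$cellLabels, nTopVar = 150)
  pF <- matrix(rep(c(0.40, 0.30, 0.30), each = 5), nrow = 5,
               dimnames = list(NULL, c("A", "B", "C")))
  pM <- matrix(rep(c(0.20, 0.40, 0.40), each = 5), nrow = 5,
               dimnames = list(NULL, c("A", "B", "C")))
  markersA <- intersect(rownames(S), rownames(ref$cellExpr)[1:20])
  de <- data.frame(gene = markersA, log2FC = 1)   # bulk male bias via A
  cw <- computeCwFC(de, S, pF, pM)
  calledTypes <- cw$celltype[cw$called]
  expect_gte(mean(calledTypes == "A"), 0.9)
})
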