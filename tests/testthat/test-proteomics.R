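suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(S4Vectors)
})

test_that("synthetic proteomes carry exact truth labels and reproduce", {
  sp <- ProteomeSpec(nProteins = 4000, nUp = 643, nDown = 261, seed = 1)
  ae <- generateProteome(sp)
  tr <- rowData(ae)$truth
  expect_equal(sum(tr == "up"), 643)
  expect_equal(sum(tr == "down"), 261)
  expect_equal(dim(ae), c(4000L, 6L))
  expect_true(all(assay(ae, "abundance") > 0))
  expect_equal(levels(colData(ae)$group), c("patterned", "random"))
  ae2 <- generateProteome(sp)
  expect_identical(assay(ae, "abundance"), assay(ae2, "abundance"))
  expect_error(ProteomeSpec(nProteins = 100, nUp = 80, nDown = 30))
  ## regulated effects have the programmed sign on the log2 scale
  lg <- log2(assay(ae, "abundance"))
  lfc <- rowMeans(lg[, 1:3]) - rowMeans(lg[, 4:6])
  expect_gt(min(lfc[tr == "up"]), 0)
  expect_lt(max(lfc[tr == "down"]), 0)
})

test_that("normalization modes behave as documented", {
  m <- matrix(2^10, 6, 4, dimnames = list(paste0("P", 1:6), paste0("s", 1:4)))
  ae <- AbundanceExperiment(m, c("patterned", "patterned", "random", "random"))
  n1 <- normalizeAbundance(ae, "log2_median_center")
  expect_true(all(assay(n1, "normalized") == 0))
  ## doubling one sample shifts its column by exactly -1 after centring
  m2 <- matrix(2^rnorm(60, 10), 15, 4,
               dimnames = list(paste0("P", 1:15), paste0("s", 1:4)))
  m2d <- m2; m2d[, 2] <- m2[, 2] * 2
  a <- assay(normalizeAbundance(AbundanceExperiment(
    m2, c("patterned", "patterned", "random", "random"))), "normalized")
  b <- assay(normalizeAbundance(AbundanceExperiment(
    m2d, c("patterned", "patterned", "random", "random")),
    "log2_median_center"), "normalized")
  a_c <- sweep(a, 2, apply(a, 2, median))
  expect_equal(b[, 2], a_c[, 2], tolerance = 1e-12)
  ## autoscaling gives every protein mean 0, SD 1
  z <- assay(normalizeAbundance(AbundanceExperiment(
    m2, c("patterned", "patterned", "random", "random")), "autoscale"),
    "normalized")
  expect_equal(unname(rowMeans(z)), rep(0, 15))
  expect_equal(unname(apply(z, 1, sd)), rep(1, 15))
})

test_that("Welch t matches the closed form and the t.test oracle", {
  toy <- rbind(P1 = 2^c(1, 2, 3, 5, 6, 7))
  colnames(toy) <- paste0("s", 1:6)
  ae <- AbundanceExperiment(toy[, , drop = FALSE],
                            rep(c("patterned", "random"), each = 3))
  de <- differentialExpression(ae)
  expect_equal(de$t[1], -4.898979, tolerance = 1e-6)
  expect_equal(de$p[1], 0.0080499, tolerance = 1e-5)
  expect_equal(de$log2FC[1], -4)
  ## vectorized statistics agree with stats::t.test row by row
  set.seed(10)
  m <- matrix(2^rnorm(180, 12, 1), 30, 6,
              dimnames = list(paste0("P", 1:30), paste0("s", 1:6)))
  g <- rep(c("patterned", "random"), each = 3)
  dm <- differentialExpression(AbundanceExperiment(m, g))
  for (i in c(1, 7, 19, 30)) {
    tt <- t.test(log2(m[i, 1:3]), log2(m[i, 4:6]))
    expect_equal(dm$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(dm$p[i], tt$p.value, tolerance = 1e-10)
  }
  dp <- differentialExpression(AbundanceExperiment(m, g), varEqual = TRUE)
  for (i in c(2, 25)) {
    tt <- t.test(log2(m[i, 1:3]), log2(m[i, 4:6]), var.equal = TRUE)
    expect_equal(dp$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(dp$p[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("DE results satisfy the partition and BH-monotonicity invariants", {
  ae <- generateProteome(ProteomeSpec(nProteins = 800, nUp = 90, nDown = 40,
                                      seed = 3))
  de <- differentialExpression(normalizeAbundance(ae))
  cnt <- deCounts(de)
  expect_equal(sum(cnt), 800L)
  expect_true(all(de$q >= de$p - 1e-12))
  expect_equal(de$q, p.adjust(de$p, "BH"))
  ord <- order(de$p)
  expect_true(all(diff(de$q[ord]) >= -1e-12))
  sig <- de$q < metadata(de)$alpha
  expect_true(all(de$direction[sig & de$log2FC > 0] == "up"))
  expect_true(all(de$direction[sig & de$log2FC < 0] == "down"))
  expect_true(all(de$direction[!sig] == "ns"))
  ## degenerate zero-variance proteins get p = 1 by convention
  m <- matrix(2^5, 4, 6, dimnames = list(paste0("P", 1:4), paste0("s", 1:6)))
  dd <- differentialExpression(AbundanceExperiment(
    m, rep(c("patterned", "random"), each = 3)))
  expect_true(all(dd$p == 1))
  expect_equal(metadata(dd)$nDegenerate, 4L)
})

test_that("the full null yields no discoveries and FDR stays controlled", {
  ## no regulated proteins: ~0 discoveries at q < 0.05 in >= 95% of seeds
  zeroDisc <- vapply(1:40, function(s) {
    ae <- generateProteome(ProteomeSpec(nProteins = 500, nUp = 0, nDown = 0,
                                        seed = s))
    sum(deCounts(differentialExpression(normalizeAbundance(ae)))[c("up", "down")])
  }, numeric(1))
  expect_gte(sum(zeroDisc == 0), 35)
  ## empirical FDR over 200 synthetic replicates stays below 0.07
  fdr <- vapply(1:200, function(s) {
    ae <- generateProteome(ProteomeSpec(nProteins = 400, nUp = 80,
                                        nDown = 20, seed = 1000 + s))
    de <- differentialExpression(normalizeAbundance(ae))
    tr <- rowData(ae)$truth
    disc <- de$direction != "ns"
    if (!any(disc)) 0 else sum(disc & tr == "null") / sum(disc)
  }, numeric(1))
  expect_lte(mean(fdr), 0.07)
})

test_that("sensitivity reaches the designed power at the programmed effects", {
  ## |log2FC| = 2 +/- 0.3, residual SD 0.25, n = 3/group: the pooled t
  ## attains the design power
  ae <- generateProteome(ProteomeSpec(nProteins = 4000, nUp = 1000,
                                      nDown = 900, seed = 7))
  de <- differentialExpression(normalizeAbundance(ae), varEqual = TRUE)
  tr <- rowData(ae)$truth
  expect_gte(mean(de$direction[tr != "null"] != "ns"), 0.99)
  ## Welch trades some power for variance robustness at n = 3
  dw <- differentialExpression(normalizeAbundance(ae))
  expect_gte(mean(dw$direction[tr != "null"] != "ns"), 0.85)
})

test_that("PCA scores match the eigen-decomposition oracle", {
  set.seed(21)
  for (rep in 1:5) {
    m <- matrix(2^rnorm(240, 15, 2), 40, 6,
                dimnames = list(paste0("P", 1:40), paste0("s", 1:6)))
    ae <- AbundanceExperiment(m, rep(c("patterned", "random"), each = 3))
    pc <- pcaScores(ae)
    X <- scale(t(log2(m)), center = TRUE, scale = FALSE)
    ev <- eigen(cov(X))
    for (j in 1:2) {
      sc <- X %*% ev$vectors[, j]
      expect_lt(min(max(abs(pc@scores[, j] - sc)),
                    max(abs(pc@scores[, j] + sc))), 1e-8)
    }
    expect_equal(pc@explained,
                 (ev$values / sum(ev$values))[1:2], tolerance = 1e-10)
  }
})

test_that("PCA handles constructed covariance and duplicated samples", {
  ## two proteins whose sample covariance is [[2,1],[1,2]]:
  ## PC1 along (1,1)/sqrt(2), explained fraction 3/4
  a <- 1.5; b <- sqrt(0.75)
  X <- rbind(c(a, a), c(-a, -a), c(b, -b), c(-b, b))
  m <- 2^(t(X) + 10)
  dimnames(m) <- list(c("P1", "P2"), paste0("s", 1:4))
  ae <- AbundanceExperiment(m, c("patterned", "patterned", "random", "random"))
  pc <- pcaScores(ae)
  expect_equal(pc@explained[1], 0.75, tolerance = 1e-10)
  expect_equal(unname(abs(pc@scores[, 1])),
               abs(X %*% c(1, 1) / sqrt(2))[, 1], tolerance = 1e-10)
  ## duplicated samples receive identical scores
  md <- cbind(m, s5 = m[, 1])
  aed <- AbundanceExperiment(md, c("patterned", "patterned", "random",
                                   "random", "patterned"))
  pcd <- pcaScores(aed)
  expect_equal(pcd@scores[1, ], pcd@scores[5, ])
  ## group separation on PC1 for a programmed two-group proteome
  aep <- generateProteome(ProteomeSpec(nProteins = 1000, nUp = 150,
                                       nDown = 80, seed = 5))
  pcs <- pcaScores(normalizeAbundance(aep))
  g <- colData(aep)$group
  gap <- min(pcs@scores[g == "patterned", 1]) -
         max(pcs@scores[g == "random", 1])
  spread <- max(abs(pcs@scores[, 1]))
  expect_gt(abs(gap) / spread, 0.5)   # silhouette-like separation
  expect_error(pcaScores(AbundanceExperiment(
    matrix(2, 1, 4, dimnames = list("P1", paste0("s", 1:4))),
    c("patterned", "patterned", "random", "random"))), "2 proteins")
})

test_that("top-k selection orders by significance with clustered layout", {
  ae <- generateProteome(ProteomeSpec(nProteins = 600, nUp = 80, nDown = 40,
                                      seed = 11))
  de <- differentialExpression(normalizeAbundance(ae))
  tk <- topProteins(de, ae, k = 50)
  expect_equal(nrow(tk$table), 50)
  expect_true(all(tk$table$direction != "ns"))
  expect_true(!is.unsorted(tk$table$q))
  ## all top-50 are truly regulated at the programmed effect sizes
  tr <- rowData(ae)$truth[match(rownames(tk$table), rownames(ae))]
  expect_true(all(tr != "null"))
  ## k = 1 returns the single most significant protein (q ties broken by
  ## larger |log2FC|)
  t1 <- topProteins(de, ae, k = 1)
  best <- rownames(de)[order(de$q, -abs(de$log2FC))][1]
  expect_equal(rownames(t1$table), best)
  ## identical rows sit adjacent in the dendrogram order
  m <- assay(ae, "abundance")
  m[2, ] <- m[1, ] * 4   # same autoscaled profile as row 1
  ae2 <- AbundanceExperiment(m, colData(ae)$group,
                             truth = rowData(ae)$truth)
  de2 <- differentialExpression(normalizeAbundance(ae2))
  tk2 <- topProteins(de2, ae2, k = 50)
  if (all(rownames(m)[1:2] %in% rownames(tk2$table))) {
    ord <- rownames(tk2$table)[tk2$rowOrder]
    expect_equal(abs(diff(match(rownames(m)[1:2], ord))), 1)
  }
  ## truncation warns when fewer than k proteins are significant
  aeS <- generateProteome(ProteomeSpec(nProteins = 200, nUp = 5, nDown = 0,
                                       seed = 2))
  deS <- differentialExpression(normalizeAbundance(aeS))
  expect_warning(tkS <- topProteins(deS, aeS, k = 50), "truncating")
  expect_lte(nrow(tkS$table), sum(deS$direction != "ns"))
})

test_that("abundance tables round-trip through TSV", {
  ae <- generateProteome(ProteomeSpec(nProteins = 50, nUp = 5, nDown = 5,
                                      seed = 8))
  tf <- tempfile(fileext = ".tsv")
  writeAbundanceTable(ae, tf)
  back <- readAbundanceTable(tf, as.character(colData(ae)$group))
  expect_equal(assay(back, "abundance"), assay(ae, "abundance"),
               tolerance = 1e-12)
  ## sidecar group map
  gf <- tempfile(fileext = ".tsv")
  write.table(data.frame(sample = colnames(ae),
                         group = colData(ae)$group),
              gf, sep = "\t", row.names = FALSE, quote = FALSE)
  back2 <- readAbundanceTable(tf, gf)
  expect_equal(as.character(colData(back2)$group),
               as.character(colData(ae)$group))
})
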