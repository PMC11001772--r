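#' Normalize a protein abundance table
#'
#' Adds a `normalized` assay on the log2 scale: `log2` (transform only),
#' `log2_median_center` (log2 then per-sample median centring), or
#' `autoscale` (log2 then per-protein centring and unit scaling). The mode
#' is recorded in `metadata()$normalization`.
#'
#' @param ae an [AbundanceExperiment] (strictly positive abundances).
#' @param mode normalization mode.
#' @return The experiment with a `normalized` assay.
#' @export
normalizeAbundance <- function(ae, mode = c("log2", "log2_median_center",
                                            "autoscale")) {
  stopifnot(is(ae, "AbundanceExperiment"))
  mode <- match.arg(mode)
  m <- SummarizedExperiment::assay(ae, "abundance")
  if (any(m <= 0)) stop("abundances must be strictly positive")
  lg <- log2(m)
  norm <- switch(mode,
    log2 = lg,
    log2_median_center = sweep(lg, 2, apply(lg, 2, median)),
    autoscale = {
      ctr <- lg - rowMeans(lg)
      sds <- sqrt(rowSums(ctr^2) / (ncol(lg) - 1))
      sds[sds == 0] <- 1
      ctr / sds
    })
  SummarizedExperiment::assay(ae, "normalized") <- norm
  S4Vectors::metadata(ae)$normalization <- mode
  ae
}

.log2Matrix <- function(ae) {
  if ("normalized" %in% SummarizedExperiment::assayNames(ae))
    SummarizedExperiment::assay(ae, "normalized")
  else log2(SummarizedExperiment::assay(ae, "abundance"))
}

#' Per-protein differential expression
#'
#' Two-sample t-test on log2 abundances for every protein (Welch by
#' default; pooled-variance via `varEqual = TRUE`), Benjamini-Hochberg
#' adjustment across all proteins, and direction calls: `up`/`down` when
#' `q < alpha` (and `|log2FC| >= lfcCutoff` if set), `ns` otherwise. The
#' log2 fold change is mean(patterned) - mean(random), taking the first
#' group level as the test condition. Proteins with zero variance in both
#' groups and equal means get `p = 1` by convention (flagged in metadata).
#'
#' @param ae an [AbundanceExperiment]; the `normalized` assay is used when
#'   present, otherwise log2 abundances.
#' @param alpha FDR level for the direction calls.
#' @param varEqual use the pooled-variance t-test.
#' @param lfcCutoff optional absolute log2FC cutoff for the calls.
#' @return A [DEResult] with columns `log2FC`, `t`, `p`, `q`, `direction`.
#' @examples
#' ae <- generateProteome(ProteomeSpec(nProteins = 300, nUp = 30, nDown = 10))
#' de <- differentialExpression(ae)
#' table(de$direction)
#' @export
differentialExpression <- function(ae, alpha = 0.05, varEqual = FALSE,
                                   lfcCutoff = 0) {
  stopifnot(is(ae, "AbundanceExperiment"))
  lg <- .log2Matrix(ae)
  g <- factor(SummarizedExperiment::colData(ae)$group)
  i1 <- g == levels(g)[1]; i2 <- g == levels(g)[2]
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- rowMeans(lg[, i1, drop = FALSE])
  m2 <- rowMeans(lg[, i2, drop = FALSE])
  v1 <- rowSums((lg[, i1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((lg[, i2, drop = FALSE] - m2)^2) / (n2 - 1)
  lfc <- m1 - m2
  if (varEqual) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tt <- lfc / se
  p <- 2 * pt(-abs(tt), df)
  degenerate <- se == 0
  if (any(degenerate)) {
    eq <- degenerate & lfc == 0
    p[eq] <- 1; tt[eq] <- 0
    p[degenerate & lfc != 0] <- 0
    tt[degenerate & lfc != 0] <- sign(lfc[degenerate & lfc != 0]) * Inf
  }
  q <- p.adjust(p, method = "BH")
  sig <- q < alpha & abs(lfc) >= lfcCutoff
  dir <- ifelse(sig & lfc > 0, "up", ifelse(sig & lfc < 0, "down", "ns"))
  res <- new("DEResult",
             S4Vectors::DataFrame(log2FC = unname(lfc), t = unname(tt),
                                  p = unname(p), q = unname(q),
                                  direction = unname(dir),
                                  row.names = rownames(lg)))
  S4Vectors::metadata(res) <- list(
    alpha = alpha, test = if (varEqual) "pooled t" else "Welch t",
    lfcCutoff = lfcCutoff, groups = levels(g),
    nDegenerate = sum(degenerate))
  res
}

#' Direction counts of a DE result
#'
#' @param de a [DEResult].
#' @return Named integer vector `up`, `down`, `ns` (summing to the number
#'   of proteins).
#' @export
deCounts <- function(de) {
  stopifnot(is(de, "DEResult"))
  c(up = sum(de$direction == "up"), down = sum(de$direction == "down"),
    ns = sum(de$direction == "ns"))
}

#' PCA scores of the samples
#'
#' Principal component analysis of the samples in protein-abundance space
#' (samples as observations, log2 scale, protein means removed). Scores are
#' column-centred; each component's sign is fixed so its largest-magnitude
#' loading is positive.
#'
#' @param ae an [AbundanceExperiment].
#' @param nComponents number of components to keep.
#' @return A [PCAScores].
#' @export
pcaScores <- function(ae, nComponents = 2L) {
  stopifnot(is(ae, "AbundanceExperiment"))
  X <- t(.log2Matrix(ae))
  if (ncol(X) < 2) stop("need at least 2 proteins")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(nComponents, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    ld <- pc$rotation[, j]
    if (ld[which.max(abs(ld))] < 0) scores[, j] <- -scores[, j]
  }
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  new("PCAScores", scores = scores, explained = expl[seq_len(k)])
}

#' Top-k most significant proteins with heatmap ordering
#'
#' Selects the k proteins with the smallest adjusted p (ties broken towards
#' larger |log2FC|), restricted to significant proteins (truncated with a
#' warning when fewer than k are significant), and orders rows and columns
#' by average-linkage hierarchical clustering on Euclidean distances of the
#' autoscaled log2 values.
#'
#' @param de a [DEResult].
#' @param ae the matching [AbundanceExperiment].
#' @param k number of proteins.
#' @return List with `table` (the selected [DEResult] rows in significance
#'   order), `matrix` (autoscaled log2 values), `rowOrder`, `colOrder`.
#' @export
topProteins <- function(de, ae, k = 50L) {
  stopifnot(is(de, "DEResult"), is(ae, "AbundanceExperiment"))
  sig <- which(de$direction != "ns")
  if (length(sig) < k) {
    warning(sprintf("only %d significant proteins; truncating k", length(sig)))
    k <- length(sig)
  }
  ord <- sig[order(de$q[sig], -abs(de$log2FC[sig]))]
  sel <- head(ord, k)
  if (!length(sel))
    return(list(table = de[integer(0), ],
                matrix = matrix(numeric(0), 0, ncol(ae)),
                rowOrder = integer(0), colOrder = integer(0)))
  lg <- log2(SummarizedExperiment::assay(ae, "abundance"))[sel, , drop = FALSE]
  ctr <- lg - rowMeans(lg)
  sds <- sqrt(rowSums(ctr^2) / (ncol(lg) - 1))
  sds[sds == 0] <- 1
  Z <- ctr / sds
  rowOrder <- if (nrow(Z) > 2) hclust(dist(Z), method = "average")$order
              else seq_len(nrow(Z))
  colOrder <- if (ncol(Z) > 2) hclust(dist(t(Z)), method = "average")$order
              else seq_len(ncol(Z))
  list(table = de[sel, ], matrix = Z, rowOrder = rowOrder,
       colOrder = colOrder)
}
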