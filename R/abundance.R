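#' Construct an AbundanceExperiment
#'
#' @param abundance strictly positive proteins x samples matrix with unique
#'   rownames (protein ids) and sample colnames.
#' @param group sample group labels, coercible to a two-level factor; by
#'   convention the first level is the test condition (`patterned`) and the
#'   second the reference (`random`).
#' @param truth optional per-protein truth labels (`up`/`down`/`null`) for
#'   synthetic tables.
#' @return An [AbundanceExperiment].
#' @examples
#' m <- matrix(2^rnorm(60, 20), 10,
#'             dimnames = list(paste0("P", 1:10), paste0("s", 1:6)))
#' ae <- AbundanceExperiment(m, rep(c("patterned", "random"), each = 3))
#' @export
AbundanceExperiment <- function(abundance, group, truth = NULL) {
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)))
    rownames(abundance) <- sprintf("P%05d", seq_len(nrow(abundance)))
  group <- factor(group)
  rd <- S4Vectors::DataFrame(row.names = rownames(abundance))
  if (!is.null(truth)) rd$truth <- truth
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = abundance),
    colData = S4Vectors::DataFrame(group = group,
                                   row.names = colnames(abundance)),
    rowData = rd)
  new("AbundanceExperiment", se)
}

#' Generate a synthetic two-group proteome
#'
#' Simulates a label-free proteomics abundance table for a patterned vs
#' random comparison: per-protein log2 baselines are
#' `Normal(baselineMean, baselineSd)`; the first `nUp` proteins gain a
#' positive log2 shift `Normal(effectMean, effectSd)` in the patterned
#' group and the next `nDown` a negative one; every sample adds
#' `Normal(0, residualSd)` residual noise on the log2 scale; abundances are
#' `2^log2value` (strictly positive). Truth labels `up`/`down`/`null` are
#' attached to `rowData`.
#'
#' @param spec a [ProteomeSpec].
#' @return An [AbundanceExperiment] with `metadata()$spec` echoing the spec.
#' @examples
#' ae <- generateProteome(ProteomeSpec(nProteins = 200, nUp = 20, nDown = 10))
#' table(SummarizedExperiment::rowData(ae)$truth)
#' @export
generateProteome <- function(spec) {
  stopifnot(is(spec, "ProteomeSpec"))
  withSeed(spec@seed, {
    np <- spec@nProteins; k <- spec@nPerGroup
    truth <- rep(c("up", "down", "null"),
                 c(spec@nUp, spec@nDown, np - spec@nUp - spec@nDown))
    baseline <- rnorm(np, spec@baselineMean, spec@baselineSd)
    effect <- numeric(np)
    effect[truth == "up"] <- abs(rnorm(spec@nUp, spec@effectMean,
                                       spec@effectSd))
    effect[truth == "down"] <- -abs(rnorm(spec@nDown, spec@effectMean,
                                          spec@effectSd))
    lpat <- baseline + effect + matrix(rnorm(np * k, 0, spec@residualSd),
                                       np, k)
    lran <- baseline + matrix(rnorm(np * k, 0, spec@residualSd), np, k)
    ab <- 2^cbind(lpat, lran)
    dimnames(ab) <- list(sprintf("P%05d", seq_len(np)),
                         c(paste0("patterned_", seq_len(k)),
                           paste0("random_", seq_len(k))))
    ae <- AbundanceExperiment(ab, rep(c("patterned", "random"), each = k),
                              truth = truth)
    S4Vectors::metadata(ae)$spec <- spec
    ae
  })
}

#' Read / write protein abundance tables
#'
#' TSV interchange: the table holds protein ids in the first column and one
#' column per sample; groups are given either in a two-column sidecar TSV
#' (`sample`, `group`) or as a vector.
#'
#' @param path table path (TSV).
#' @param groups group vector (in column order) or path to a sidecar TSV.
#' @return `readAbundanceTable` returns an [AbundanceExperiment];
#'   `writeAbundanceTable` returns `path` invisibly.
#' @export
readAbundanceTable <- function(path, groups) {
  tab <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    g <- utils::read.delim(groups)
    groups <- g$group[match(colnames(m), g$sample)]
  }
  AbundanceExperiment(m, groups)
}

#' @rdname readAbundanceTable
#' @param ae an [AbundanceExperiment].
#' @export
writeAbundanceTable <- function(ae, path) {
  m <- SummarizedExperiment::assay(ae, "abundance")
  utils::write.table(data.frame(protein_id = rownames(m), m,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
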