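#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn robustScale matrix method.  \code{centre} gives the data
#'   centre label of each sample (column).  Every gene is centred by its
#'   within-centre median and scaled by its within-centre interquartile
#'   spread (75th minus 25th percentile); a constant gene within a
#'   centre is an explicit error naming the gene and the centre.  Every
#'   centre needs at least four samples so the quartiles are estimable.
#' @param centre character/factor of per-sample centre labels
#' @export
setMethod("robustScale", "matrix", function(x, centre, ...) {
  if (ncol(x) != length(centre))
    stop("one centre label per sample (column) is required")
  centre <- as.character(centre)
  centres <- sort(unique(centre))
  sizes <- table(centre)
  if (any(sizes < 4L))
    stop("every centre needs at least four samples for quartiles")
  if (is.null(rownames(x))) rownames(x) <- sprintf("gene%03d", seq_len(nrow(x)))
  med <- matrix(NA_real_, nrow(x), length(centres),
                dimnames = list(rownames(x), centres))
  igs <- med
  out <- x
  for (k in centres) {
    cols <- centre == k
    q <- apply(x[, cols, drop = FALSE], 1L, quantile,
               probs = c(0.25, 0.5, 0.75), names = FALSE)
    spread <- q[3, ] - q[1, ]
    if (any(spread == 0)) {
      g <- rownames(x)[which(spread == 0)[1]]
      stop("gene '", g, "' is constant within centre '", k,
           "' (interquartile spread 0)")
    }
    med[, k] <- q[2, ]
    igs[, k] <- spread
    out[, cols] <- (x[, cols, drop = FALSE] - q[2, ]) / spread
  }
  new("ScaledExpressionMatrix", values = out, centre = centre,
      medians = med, igs = igs)
})

#' @describeIn robustScale CohortExperiment method (uses the
#'   \code{exprs} assay and the \code{centre} column of the clinical
#'   table).
#' @export
setMethod("robustScale", "CohortExperiment", function(x, ...) {
  robustScale(SummarizedExperiment::assay(x, "exprs"),
              centre = as.character(clinicalData(x)$centre), ...)
})

#' Clip scaled expression for heat-map display
#'
#' Identity on [-limit, limit]; saturation outside, so heat-map colour
#' schemes stay comparable across genes.
#'
#' @param x numeric values (a \code{ScaledExpressionMatrix} is accepted)
#' @param limit saturation bound (default 3)
#' @return values clipped to [-limit, limit]
#' @examples
#' clipForHeatmap(c(-5, 1.2, 3.7))  # -3, 1.2, 3
#' @export
clipForHeatmap <- function(x, limit = 3) {
  if (is(x, "ScaledExpressionMatrix")) x <- scaledValues(x)
  pmin(pmax(x, -limit), limit)
}

#' Per-gene subtype association by Kruskal-Wallis
#'
#' Each gene is tested for expression differences among subtype groups
#' with the Kruskal-Wallis rank test (chi-square approximation with tie
#' correction); p-values are BH-adjusted across genes and the table is
#' returned in ascending p order (beanplot order), with lexicographic
#' gene tie-break for determinism.
#'
#' @param x genes x samples matrix or \code{ScaledExpressionMatrix}
#' @param subtype per-sample subtype labels (>= 2 groups, each with >= 2
#'   samples)
#' @param grouping label recorded in the output (e.g. "IntClust-10" or
#'   "PAM50-5")
#' @return data.frame with columns gene, statistic, df, p_raw, p_adj,
#'   grouping, ordered by p ascending
#' @export
kwAssociation <- function(x, subtype, grouping = "IntClust-10") {
  if (is(x, "ScaledExpressionMatrix")) x <- scaledValues(x)
  subtype <- factor(subtype)
  if (nlevels(droplevels(subtype)) < 2L)
    stop("at least two subtype groups are required")
  if (any(table(droplevels(subtype)) < 2L))
    stop("every subtype group needs at least two samples")
  if (ncol(x) != length(subtype))
    stop("one subtype label per sample is required")
  res <- t(apply(x, 1L, function(v) {
    kt <- kruskal.test(v, subtype)
    c(statistic = unname(kt$statistic), df = unname(kt$parameter),
      p_raw = kt$p.value)
  }))
  out <- data.frame(gene = rownames(x), res, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$p_adj <- bhAdjust(out$p_raw)
  out$grouping <- grouping
  out[order(out$p_raw, out$gene), ]
}

#' Random-gene-set enrichment simulation
#'
#' Draws \code{nRuns} random sets of \code{setSize} genes without
#' replacement from a universe with per-gene significance flags and
#' counts the runs in which at least \code{observedSignificant} drawn
#' genes are flagged.  The empirical p-value is exceedances/nRuns (plain
#' k/B convention); the reporting convention rounds it to three
#' decimals.  The exceedance rate converges to the hypergeometric tail
#' P[X >= observed] for X ~ Hypergeom(universe, flagged, setSize).
#'
#' @param flags logical vector: one significance flag per universe gene
#' @param setSize genes drawn per run
#' @param observedSignificant observed number of flagged genes in the
#'   real set
#' @param nRuns simulation runs (default 10000)
#' @param seed integer seed
#' @return an \linkS4class{EnrichmentSimResult}
#' @examples
#' flags <- rep(c(TRUE, FALSE), c(300, 200))
#' enrichmentSimulation(flags, 47, 35, nRuns = 2000, seed = 1)
#' @export
enrichmentSimulation <- function(flags, setSize, observedSignificant,
                                 nRuns = 10000L, seed = 1L) {
  flags <- as.logical(flags)
  if (anyNA(flags)) stop("flags must be TRUE/FALSE without NA")
  if (setSize > length(flags))
    stop("universe must be at least as large as the set")
  if (observedSignificant > setSize)
    stop("observedSignificant cannot exceed setSize")
  set.seed(as.integer(seed))
  n <- length(flags)
  k <- 0L
  for (i in seq_len(nRuns)) {
    if (sum(flags[sample.int(n, setSize)]) >= observedSignificant)
      k <- k + 1L
  }
  p <- k / nRuns
  new("EnrichmentSimResult",
      universeSize = as.integer(n), setSize = as.integer(setSize),
      nRuns = as.integer(nRuns),
      observedSignificant = as.integer(observedSignificant),
      exceedances = as.integer(k), empiricalP = p,
      reportedP = round(p, 3L))
}

#' Empirical p-value reporting convention for enrichment runs
#'
#' Plain k/B convention (no +1 correction) with three-decimal rounding
#' for reporting: 211 exceedances in 10,000 runs reports 0.021.
#'
#' @param exceedances runs meeting or exceeding the observed statistic
#' @param nRuns total runs
#' @return list with empirical_p (k/B) and reported_p (3-decimal)
#' @examples
#' enrichmentEmpiricalP(211, 10000)$reported_p  # 0.021
#' @export
enrichmentEmpiricalP <- function(exceedances, nRuns) {
  if (exceedances < 0 || exceedances > nRuns)
    stop("exceedances must lie in [0, nRuns]")
  p <- exceedances / nRuns
  list(empirical_p = p, reported_p = round(p, 3L))
}
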