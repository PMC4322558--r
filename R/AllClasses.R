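#' @import methods
#' @importFrom stats median quantile rnorm rpois rnbinom rexp runif rbinom
#'   sd setNames aov lm anova coef pchisq pnorm qnorm p.adjust
#'   kruskal.test cor complete.cases uniroot logLik relevel as.formula
#'   predict t.test wilcox.test
#' @importFrom utils read.csv write.csv packageVersion
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Parameters for a synthetic siRNA growth screen
#'
#' Describes the layout and noise structure of a simulated genome-scale
#' co-culture RNAi screen: a multi-well grid per plate with fixed control
#' positions, per-pool multiplicative growth effects, plate random
#' intercepts, a smooth well-position (edge/bowl) effect, monotone
#' stain-degradation drift over plate processing order, and overdispersed
#' (negative-binomial) nuclei counts.
#'
#' Wells not occupied by controls carry siRNA pools; pools are tiled over
#' as many plate layouts as needed and every layout is screened on
#' \code{nReplicates} physical plates.
#'
#' @slot nPools number of siRNA pools.
#' @slot plateRows,plateCols plate grid dimensions (default 8 x 12).
#' @slot nReplicates physical plates per layout (default 2).
#' @slot controlLayout data.frame with columns \code{row}, \code{col}
#'   (0-based grid indices) and \code{condition}; positions are identical
#'   ("static") on every plate.
#' @slot plateSigma standard deviation of plate random intercepts on the
#'   log-count scale.
#' @slot wellEffectAmplitude amplitude of the deterministic quadratic
#'   bowl/edge position effect on the log-count scale.
#' @slot driftRate per-plate-order multiplicative stain-degradation rate in
#'   [0, 1); expected counts on the plate processed at order \eqn{o} are
#'   multiplied by \eqn{(1 - driftRate)^{o-1}}.
#' @slot effectDistribution function of \code{n} returning \code{n} true
#'   relative effects in (0, 1.5].
#' @slot dispersion negative-binomial overdispersion (variance
#'   \eqn{\mu + \phi \mu^2}); 0 gives Poisson counts.
#' @slot baselineCount expected nuclei count of a control well.
#' @slot lethalEffect true relative effect of the positive-lethal control.
#'
#' @export
setClass("ScreenSimParam",
  representation(
    nPools = "integer",
    plateRows = "integer",
    plateCols = "integer",
    nReplicates = "integer",
    controlLayout = "data.frame",
    plateSigma = "numeric",
    wellEffectAmplitude = "numeric",
    driftRate = "numeric",
    effectDistribution = "function",
    dispersion = "numeric",
    baselineCount = "numeric",
    lethalEffect = "numeric"
  )
)

setValidity("ScreenSimParam", function(object) {
  msg <- character()
  if (object@nPools < 1L) msg <- c(msg, "nPools must be positive")
  if (object@baselineCount <= 0) msg <- c(msg, "baselineCount must be positive")
  if (object@plateSigma < 0) msg <- c(msg, "plateSigma must be >= 0")
  if (object@wellEffectAmplitude < 0)
    msg <- c(msg, "wellEffectAmplitude must be >= 0")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  if (object@driftRate < 0 || object@driftRate >= 1)
    msg <- c(msg, "driftRate must be in [0, 1)")
  cl <- object@controlLayout
  if (!all(c("row", "col", "condition") %in% names(cl)))
    msg <- c(msg, "controlLayout needs columns row, col, condition")
  else {
    if (any(cl$row < 0L) || any(cl$row >= object@plateRows) ||
        any(cl$col < 0L) || any(cl$col >= object@plateCols))
      msg <- c(msg, "control layout exceeds the plate grid")
    if (anyDuplicated(cl[, c("row", "col")]))
      msg <- c(msg, "control positions must be unique")
    if (!all(cl$condition %in% c("carrier", "nonsilencing", "positive-lethal")))
      msg <- c(msg, "control conditions must be carrier, nonsilencing or positive-lethal")
  }
  if (nrow(cl) >= object@plateRows * object@plateCols)
    msg <- c(msg, "control layout leaves no wells for siRNA pools")
  if (length(msg)) msg else TRUE
})

#' Parameters for a synthetic METABRIC-like breast cancer cohort
#'
#' Describes a simulated multi-centre expression-plus-outcome cohort:
#' per-centre location/scale batch structure, ten (by default) molecular
#' subtypes with gene-specific expression shifts, subtype-specific Weibull
#' baseline hazards of differing shape (hence non-proportional hazards
#' between subtypes), and a planted threshold-type biomarker effect on one
#' gene.
#'
#' @slot nPatients,nGenes cohort and panel size.
#' @slot nSubtypes number of molecular subtypes (default 10).
#' @slot nCentres number of data centres.
#' @slot centreShift,centreScale standard deviations of the per-centre
#'   additive shift and of the per-centre log multiplicative scale.
#' @slot subtypeEffect nGenes x nSubtypes matrix of mean expression shifts.
#' @slot baselineShapes,baselineScales per-subtype Weibull shape and scale
#'   (time units, e.g. months) of the baseline survival distribution.
#' @slot biomarkerGene index of the gene carrying the planted threshold
#'   effect (0 disables it).
#' @slot biomarkerCutQuantile expression quantile at which the hazard
#'   changes.
#' @slot biomarkerLogHR planted log hazard ratio (high vs low expression).
#' @slot censoringRate target fraction of censored observations.
#'
#' @export
setClass("CohortSimParam",
  representation(
    nPatients = "integer",
    nGenes = "integer",
    nSubtypes = "integer",
    nCentres = "integer",
    centreShift = "numeric",
    centreScale = "numeric",
    subtypeEffect = "matrix",
    baselineShapes = "numeric",
    baselineScales = "numeric",
    biomarkerGene = "integer",
    biomarkerCutQuantile = "numeric",
    biomarkerLogHR = "numeric",
    censoringRate = "numeric"
  )
)

setValidity("CohortSimParam", function(object) {
  msg <- character()
  if (object@nPatients < 2L) msg <- c(msg, "nPatients must be >= 2")
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (object@nSubtypes < 2L) msg <- c(msg, "nSubtypes must be >= 2")
  if (object@nCentres < 1L) msg <- c(msg, "nCentres must be >= 1")
  if (!identical(dim(object@subtypeEffect),
                 c(object@nGenes, object@nSubtypes)))
    msg <- c(msg, "subtypeEffect must be nGenes x nSubtypes")
  if (length(object@baselineShapes) != object@nSubtypes ||
      length(object@baselineScales) != object@nSubtypes)
    msg <- c(msg, "baselineShapes/baselineScales need one value per subtype")
  if (any(object@baselineShapes <= 0) || any(object@baselineScales <= 0))
    msg <- c(msg, "Weibull shapes and scales must be positive")
  if (object@biomarkerGene < 0L || object@biomarkerGene > object@nGenes)
    msg <- c(msg, "biomarkerGene out of range")
  if (object@biomarkerCutQuantile <= 0 || object@biomarkerCutQuantile >= 1)
    msg <- c(msg, "biomarkerCutQuantile must be in (0, 1)")
  if (object@censoringRate < 0 || object@censoringRate >= 1)
    msg <- c(msg, "censoringRate must be in [0, 1)")
  if (object@centreShift < 0 || object@centreScale < 0)
    msg <- c(msg, "centre batch standard deviations must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Container for a simulated (or imported) screen
#'
#' Holds the per-well records of an imaged siRNA screen together with the
#' generating truth table (for simulated screens) so that downstream
#' estimators can be scored against the planted effects.
#'
#' @slot wells data.frame with columns \code{plate_id},
#'   \code{processing_order}, \code{row}, \code{col}, \code{condition},
#'   \code{count}.
#' @slot truth data.frame with columns \code{pool_id}, \code{true_effect}
#'   (empty for imported screens).
#'
#' @export
setClass("ScreenExperiment",
  representation(wells = "data.frame", truth = "data.frame")
)

setValidity("ScreenExperiment", function(object) {
  msg <- character()
  w <- object@wells
  need <- c("plate_id", "processing_order", "row", "col", "condition", "count")
  if (!all(need %in% names(w)))
    return(paste("wells needs columns", paste(need, collapse = ", ")))
  if (any(w$count < 0)) msg <- c(msg, "counts must be nonnegative")
  if (anyDuplicated(w[, c("plate_id", "row", "col")]))
    msg <- c(msg, "(plate_id, row, col) must be unique")
  if (length(msg)) msg else TRUE
})

#' @describeIn ScreenExperiment-class compact display
#' @param object a \code{ScreenExperiment}
#' @export
setMethod("show", "ScreenExperiment", function(object) {
  w <- object@wells
  cat("ScreenExperiment with", nrow(w), "wells on",
      length(unique(w$plate_id)), "plates\n")
  cat("  conditions:", length(unique(w$condition)),
      "| pools with truth:", nrow(object@truth), "\n")
})

#' Cohort container: expression plus clinical outcome
#'
#' A \linkS4class{SummarizedExperiment} whose single assay \code{exprs}
#' holds gene-by-patient expression, whose \code{colData} carries the
#' clinical table (\code{time}, \code{event}, \code{subtype},
#' \code{centre}) and whose metadata stores the simulation truth
#' parameters when the cohort was generated in silico.
#'
#' @export
setClass("CohortExperiment", contains = "SummarizedExperiment")

#' Robustly centred and scaled expression values
#'
#' Per-gene, per-centre scaled expression
#' \eqn{r = (e - med) / igs}, where \eqn{med} is the within-centre median
#' and \eqn{igs} the within-centre interquartile spread (75th minus 25th
#' percentile) of the gene.  After scaling every gene has median 0 and
#' interquartile spread 1 within each centre.
#'
#' @slot values genes x samples matrix of scaled values.
#' @slot centre per-sample centre label.
#' @slot medians,igs genes x centres matrices of the centring medians and
#'   scaling interquartile spreads.
#'
#' @export
setClass("ScaledExpressionMatrix",
  representation(
    values = "matrix",
    centre = "character",
    medians = "matrix",
    igs = "matrix"
  )
)

setValidity("ScaledExpressionMatrix", function(object) {
  if (ncol(object@values) != length(object@centre))
    return("one centre label per sample is required")
  if (any(object@igs <= 0, na.rm = TRUE))
    return("interquartile spreads must be positive")
  TRUE
})

#' @describeIn ScaledExpressionMatrix-class compact display
#' @param object a \code{ScaledExpressionMatrix}
#' @export
setMethod("show", "ScaledExpressionMatrix", function(object) {
  cat("ScaledExpressionMatrix:", nrow(object@values), "genes x",
      ncol(object@values), "samples,",
      ncol(object@medians), "data centre(s)\n")
})

#' Result of a random-gene-set enrichment simulation
#'
#' Summarises a randomization null for the number of subtype-associated
#' genes in a selected gene set: random sets of the same size are drawn
#' without replacement from a flagged universe and the fraction of draws
#' with at least as many flagged genes as observed is the empirical
#' p-value (plain k/B convention, reported rounded to three decimals).
#'
#' @slot universeSize,setSize,nRuns simulation dimensions.
#' @slot observedSignificant observed number of flagged genes in the set.
#' @slot exceedances runs with flagged count >= observed.
#' @slot empiricalP exceedances / nRuns.
#' @slot reportedP empiricalP rounded to three decimals (reporting
#'   convention).
#'
#' @export
setClass("EnrichmentSimResult",
  representation(
    universeSize = "integer",
    setSize = "integer",
    nRuns = "integer",
    observedSignificant = "integer",
    exceedances = "integer",
    empiricalP = "numeric",
    reportedP = "numeric"
  )
)

setValidity("EnrichmentSimResult", function(object) {
  if (object@exceedances < 0L || object@exceedances > object@nRuns)
    return("exceedances must lie in [0, nRuns]")
  if (object@empiricalP < 0 || object@empiricalP > 1)
    return("empiricalP must lie in [0, 1]")
  TRUE
})

#' @describeIn EnrichmentSimResult-class compact display
#' @param object an \code{EnrichmentSimResult}
#' @export
setMethod("show", "EnrichmentSimResult", function(object) {
  cat(sprintf(
    "EnrichmentSimResult: %d/%d runs with >= %d flagged genes (set %d of %d)\n",
    object@exceedances, object@nRuns, object@observedSignificant,
    object@setSize, object@universeSize))
  cat(sprintf("  empirical P = %.4f (reported %.3f)\n",
              object@empiricalP, object@reportedP))
})

#' AIC-guided biomarker dichotomization result
#'
#' Records the candidate quantile grid, the per-quantile Cox AIC values,
#' the chosen cut and whether the median fallback rule fired (AIC range
#' below the fallback delta).
#'
#' @slot gene gene label (may be empty).
#' @slot candidateQuantiles quantile grid (default 0.15, 0.25, 0.50, 0.75).
#' @slot aic per-quantile AIC; NA for cuts excluded by the minimum
#'   events-per-arm rule.
#' @slot chosenQuantile selected cut quantile.
#' @slot fallbackUsed TRUE when the median fallback rule was applied.
#' @slot cutValue expression value at the chosen cut.
#' @slot groups factor with levels \code{low}, \code{high}.
#'
#' @export
setClass("BinarizationResult",
  representation(
    gene = "character",
    candidateQuantiles = "numeric",
    aic = "numeric",
    chosenQuantile = "numeric",
    fallbackUsed = "logical",
    cutValue = "numeric",
    groups = "factor"
  )
)

setValidity("BinarizationResult", function(object) {
  if (!object@chosenQuantile %in% object@candidateQuantiles)
    return("chosenQuantile must be one of the candidate quantiles")
  TRUE
})

#' @describeIn BinarizationResult-class compact display
#' @param object a \code{BinarizationResult}
#' @export
setMethod("show", "BinarizationResult", function(object) {
  cat(sprintf("BinarizationResult%s: cut at %.0f%% quantile%s\n",
              if (length(object@gene) && nzchar(object@gene))
                paste0(" [", object@gene, "]") else "",
              100 * object@chosenQuantile,
              if (object@fallbackUsed) " (median fallback)" else ""))
  aic <- object@aic
  cat("  AIC:", paste(sprintf("%s=%s", names(aic),
                              ifelse(is.na(aic), "excluded",
                                     sprintf("%.2f", aic))),
                      collapse = ", "), "\n")
})
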