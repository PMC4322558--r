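#' @include AllClasses.R
NULL

#' Per-well records of a screen
#' @param x a \code{ScreenExperiment}
#' @return data.frame of well records
#' @export
setGeneric("wellData", function(x) standardGeneric("wellData"))

#' @rdname wellData
#' @export
setMethod("wellData", "ScreenExperiment", function(x) x@wells)

#' Truth table of planted per-pool effects
#' @param x a \code{ScreenExperiment} or \code{CohortExperiment}
#' @return data.frame (screen) or list (cohort) of generating parameters
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname truthTable
#' @export
setMethod("truthTable", "ScreenExperiment", function(x) x@truth)

#' @rdname truthTable
#' @export
setMethod("truthTable", "CohortExperiment", function(x)
  S4Vectors::metadata(x)$truth)

#' Clinical table of a cohort
#' @param x a \code{CohortExperiment}
#' @return data.frame with id, time, event, subtype, centre
#' @export
setGeneric("clinicalData", function(x) standardGeneric("clinicalData"))

#' @rdname clinicalData
#' @export
setMethod("clinicalData", "CohortExperiment", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' Scaled values of a ScaledExpressionMatrix
#' @param x a \code{ScaledExpressionMatrix}
#' @return genes x samples numeric matrix
#' @export
setGeneric("scaledValues", function(x) standardGeneric("scaledValues"))

#' @rdname scaledValues
#' @export
setMethod("scaledValues", "ScaledExpressionMatrix", function(x) x@values)

#' Empirical p-value of an enrichment simulation
#' @param x an \code{EnrichmentSimResult}
#' @param reported if TRUE return the three-decimal reporting-convention
#'   value, otherwise the raw exceedances/nRuns fraction
#' @return numeric scalar
#' @export
setGeneric("empiricalP", function(x, reported = FALSE)
  standardGeneric("empiricalP"))

#' @rdname empiricalP
#' @export
setMethod("empiricalP", "EnrichmentSimResult", function(x, reported = FALSE)
  if (reported) x@reportedP else x@empiricalP)

#' Chosen cut quantile of a dichotomization
#' @param x a \code{BinarizationResult}
#' @return numeric scalar
#' @export
setGeneric("chosenQuantile", function(x) standardGeneric("chosenQuantile"))

#' @rdname chosenQuantile
#' @export
setMethod("chosenQuantile", "BinarizationResult", function(x)
  x@chosenQuantile)

#' Binarized group labels of a dichotomization
#' @param x a \code{BinarizationResult}
#' @return factor with levels low, high
#' @export
setGeneric("binarizedGroups", function(x) standardGeneric("binarizedGroups"))

#' @rdname binarizedGroups
#' @export
setMethod("binarizedGroups", "BinarizationResult", function(x) x@groups)

#' Robustly centre and scale expression within data centres
#'
#' @param x genes x samples matrix or a \code{CohortExperiment}
#' @param ... passed to methods (\code{centre} labels for the matrix
#'   method)
#' @return a \code{ScaledExpressionMatrix}
#' @export
setGeneric("robustScale", function(x, ...) standardGeneric("robustScale"))

#' Quantile-normalize per-plate count vectors
#'
#' @param x wells x plates matrix (one column per plate) or a
#'   \code{ScreenExperiment}
#' @param ... unused
#' @return object of the same shape with a common within-plate
#'   distribution (the cross-plate rank means)
#' @export
setGeneric("quantileNormalize", function(x, ...)
  standardGeneric("quantileNormalize"))

#' Estimate per-pool relative growth effects
#'
#' @param x a \code{ScreenExperiment} or a data.frame of well records
#' @param ... passed to methods
#' @return data.frame of per-pool effects (see
#'   \code{\link{estimateEffects,data.frame-method}})
#' @export
setGeneric("estimateEffects", function(x, ...)
  standardGeneric("estimateEffects"))

#' AIC-guided dichotomization of a biomarker
#'
#' @param x a \code{CohortExperiment} or numeric expression vector
#' @param ... passed to methods
#' @return a \code{BinarizationResult}
#' @export
setGeneric("binarizeExpression", function(x, ...)
  standardGeneric("binarizeExpression"))
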