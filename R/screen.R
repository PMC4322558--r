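#' @include AllClasses.R AllGenerics.R
NULL

CONTROL_CONDITIONS <- c("carrier", "nonsilencing", "positive-lethal")

#' @describeIn quantileNormalize matrix method: columns are per-plate
#'   count vectors of equal length.  Every output column has the same
#'   sorted values (the cross-plate rank means); within-plate rank order
#'   is preserved and ties share the mean of their tied reference values.
#'   Missing values are an explicit error (no silent imputation).
#' @export
setMethod("quantileNormalize", "matrix", function(x, ...) {
  if (anyNA(x)) stop("missing values are not allowed in quantile normalization")
  if (!is.numeric(x)) stop("counts must be numeric")
  if (ncol(x) == 1L) return(x)
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
})

#' @describeIn quantileNormalize ScreenExperiment method: normalizes the
#'   per-plate count vectors in place (all plates share one grid, so the
#'   vectors have equal length).
#' @export
setMethod("quantileNormalize", "ScreenExperiment", function(x, ...) {
  w <- x@wells
  w <- w[order(w$plate_id, w$row, w$col), ]
  plates <- unique(w$plate_id)
  m <- matrix(w$count, ncol = length(plates),
              dimnames = list(NULL, plates))
  w$count <- as.vector(quantileNormalize(m))
  rownames(w) <- NULL
  methods::initialize(x, wells = w)
})

#' Estimate the well-position effect surface from all-control plates
#'
#' Plates screened with the same control condition in every well isolate
#' the positional artefact.  The per-position multiplicative adjustment
#' is the exponentiated mean log count at that position across the
#' supplied plates, centred so the adjustments have geometric mean 1.
#'
#' @param x a \code{ScreenExperiment} or data.frame of well records from
#'   all-control plates
#' @param plates optional plate ids to use; by default plates carrying a
#'   single condition in every well are detected automatically
#' @return data.frame with columns row, col, adjustment (geometric mean 1)
#' @export
estimateWellEffects <- function(x, plates = NULL) {
  w <- if (is(x, "ScreenExperiment")) wellData(x) else x
  if (is.null(plates)) {
    byPlate <- split(w$condition, w$plate_id)
    plates <- names(byPlate)[vapply(byPlate,
                                    function(z) length(unique(z)) == 1L,
                                    logical(1))]
  }
  w <- w[w$plate_id %in% plates, ]
  if (nrow(w) == 0L)
    stop("no all-control plates supplied")
  w$logc <- log(w$count + 0.5)
  agg <- stats::aggregate(logc ~ row + col, data = w, FUN = mean)
  agg$adjustment <- exp(agg$logc - mean(agg$logc))
  agg[order(agg$row, agg$col), c("row", "col", "adjustment")]
}

## fit one mixed model for a group of replicate plates sharing a layout
fitLayoutModel <- function(dat, controlCondition) {
  dat$condition <- relevel(factor(dat$condition), ref = controlCondition)
  dat$rc <- dat$row - mean(dat$row)
  dat$cc <- dat$col - mean(dat$col)
  dat$rc2 <- dat$rc^2
  dat$cc2 <- dat$cc^2
  nPlates <- length(unique(dat$plate_id))
  fit <- NULL
  if (nPlates >= 2L) {
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lmerTest::lmer(count ~ condition + rc + cc + rc2 + cc2 +
                         (1 | plate_id), data = dat))),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    if (nPlates < 2L)
      warning("layout with a single plate: dropping the plate random intercept")
    fit <- lm(count ~ condition + rc + cc + rc2 + cc2, data = dat)
  }
  co <- summary(fit)$coefficients
  b0 <- co["(Intercept)", "Estimate"]
  posCoef <- function(nm) if (nm %in% rownames(co)) co[nm, "Estimate"] else 0
  ## model-estimated control count at a set of wells: intercept plus the
  ## position surface evaluated at those wells (plate intercepts average
  ## out); the ratio of estimated siRNA to estimated control counts is
  ## taken at the condition's own well positions so that the position
  ## adjustment cancels from the estimand
  basePred <- b0 + posCoef("rc") * dat$rc + posCoef("cc") * dat$cc +
    posCoef("rc2") * dat$rc2 + posCoef("cc2") * dat$cc2
  conds <- setdiff(levels(dat$condition), controlCondition)
  res <- lapply(conds, function(g) {
    nm <- paste0("condition", g)
    if (!nm %in% rownames(co))
      return(data.frame(pool_id = g, relative_effect = NA_real_,
                        p_raw = NA_real_, fit_ok = FALSE,
                        stringsAsFactors = FALSE))
    pcol <- grep("^Pr\\(", colnames(co), value = TRUE)[1]
    ctrlAtWells <- mean(basePred[dat$condition == g])
    data.frame(pool_id = g,
               relative_effect = max(0, 1 + co[nm, "Estimate"] /
                                          ctrlAtWells),
               p_raw = co[nm, pcol],
               fit_ok = TRUE, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' @describeIn estimateEffects data.frame method.  Records are grouped
#'   into sets of replicate plates sharing a pool layout; within each
#'   group a linear mixed model (Gaussian, natural count scale) with
#'   fixed condition effects, a plate random intercept and centred
#'   linear-plus-quadratic row/column covariates is fitted.  The relative
#'   effect of a condition is its model-estimated count divided by the
#'   model-estimated count under the reference control; \code{p_raw} is
#'   the Wald test of the condition contrast.  Fit failures are flagged
#'   per pool (excluded from BH with a warning), never fatal.
#' @param controlCondition reference control label (default
#'   \code{"carrier"}, the transfection-reagent-only condition)
#' @export
setMethod("estimateEffects", "data.frame",
          function(x, controlCondition = "carrier", ...) {
  need <- c("plate_id", "row", "col", "condition", "count")
  if (!all(need %in% names(x)))
    stop("records need columns ", paste(need, collapse = ", "))
  if (!controlCondition %in% x$condition)
    stop("control condition '", controlCondition, "' absent from records")
  pools <- setdiff(unique(x$condition),
                   c(controlCondition, CONTROL_CONDITIONS))
  if (length(pools) == 0L && !any(x$condition %in%
                                  setdiff(CONTROL_CONDITIONS,
                                          controlCondition)))
    stop("no non-control conditions to estimate (singular design)")

  sig <- vapply(split(x, x$plate_id), function(p)
    paste(p$condition[order(p$row, p$col)], collapse = "|"), character(1))
  groups <- split(names(sig), sig)
  res <- do.call(rbind, lapply(groups, function(pl) {
    fitLayoutModel(x[x$plate_id %in% pl, ], controlCondition)
  }))
  rownames(res) <- NULL
  ## a condition present in several layout groups (controls) keeps the
  ## estimate from its first group
  res <- res[!duplicated(res$pool_id), ]
  res$is_control <- res$pool_id %in% CONTROL_CONDITIONS

  if (any(!res$fit_ok))
    warning(sum(!res$fit_ok), " pool(s) with failed fits excluded from BH")
  res$p_adj <- NA_real_
  poolRows <- !res$is_control & res$fit_ok
  res$p_adj[poolRows] <- bhAdjust(res$p_raw[poolRows])

  ## rank pools from smallest to largest effect; ties by pool id
  res$rank <- NA_integer_
  ord <- order(res$relative_effect[poolRows], res$pool_id[poolRows])
  res$rank[which(poolRows)[ord]] <- seq_len(sum(poolRows))
  res[order(!poolRows, res$rank), ]
})

#' @describeIn estimateEffects ScreenExperiment method (uses the well
#'   records).
#' @export
setMethod("estimateEffects", "ScreenExperiment",
          function(x, controlCondition = "carrier", ...) {
  estimateEffects(wellData(x), controlCondition = controlCondition, ...)
})

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric p-values in [0, 1] (NA allowed and preserved)
#' @return adjusted p-values; each in [p, 1], monotone in input ranks
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call hits from estimated growth effects
#'
#' A pool is a hit when its relative effect is at or below
#' \code{threshold} (growth reduced to 25\% or less of control by
#' default) and its BH-adjusted p-value is below \code{alpha}.
#'
#' @param effects data.frame with columns pool_id, relative_effect, p_adj
#'   (controls, flagged by an \code{is_control} column, are ignored)
#' @param threshold relative-effect cutoff (default 0.25)
#' @param alpha adjusted-p cutoff (default 0.05)
#' @return the effects table restricted to pools, ranked from smallest to
#'   largest relative effect, with logical column \code{is_hit}
#' @export
callHits <- function(effects, threshold = 0.25, alpha = 0.05) {
  if (nrow(effects) == 0L) stop("effects table is empty")
  e <- effects
  if ("is_control" %in% names(e)) e <- e[!e$is_control, ]
  e <- e[order(e$relative_effect, e$pool_id), ]
  e$rank <- seq_len(nrow(e))
  e$is_hit <- !is.na(e$p_adj) &
    e$relative_effect <= threshold & e$p_adj < alpha
  e$threshold <- threshold
  e$alpha <- alpha
  rownames(e) <- NULL
  e
}

#' Secondary-screen reproducibility of primary hits
#'
#' A primary hit is reproducible when it meets the hit criteria again in
#' at least one of the two clone secondary screens.  Pools missing from
#' both secondary tables are flagged untested and, by default, excluded
#' from the reproducibility denominator.
#'
#' @param primaryHits data.frame of primary hits (column pool_id)
#' @param secondaryL9,secondaryE11 effect tables (pool_id,
#'   relative_effect, p_adj) for the two clonal lines
#' @param threshold,alpha hit criteria applied to the secondary effects
#' @param countUntested if TRUE untested pools stay in the denominator
#' @return data.frame with per-pool logicals \code{hit_L9},
#'   \code{hit_E11} (NA when absent from that table),
#'   \code{reproducible}, \code{untested}; attribute
#'   \code{reproducible_fraction}
#' @export
secondaryReproducibility <- function(primaryHits, secondaryL9,
                                     secondaryE11,
                                     threshold = 0.25, alpha = 0.05,
                                     countUntested = FALSE) {
  hitIn <- function(tab, id) {
    i <- match(id, tab$pool_id)
    ifelse(is.na(i), NA,
           tab$relative_effect[i] <= threshold & tab$p_adj[i] < alpha)
  }
  ids <- primaryHits$pool_id
  hL9 <- hitIn(secondaryL9, ids)
  hE11 <- hitIn(secondaryE11, ids)
  untested <- is.na(hL9) & is.na(hE11)
  repro <- (!is.na(hL9) & hL9) | (!is.na(hE11) & hE11)
  out <- data.frame(pool_id = ids, hit_L9 = hL9, hit_E11 = hE11,
                    reproducible = repro, untested = untested,
                    stringsAsFactors = FALSE)
  denom <- if (countUntested) length(ids) else sum(!untested)
  attr(out, "reproducible_fraction") <-
    if (denom > 0) sum(repro) / denom else NA_real_
  out
}

## round half-up (round() in R rounds half to even)
roundHalfUp <- function(x, digits = 1L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Percentage of a stage count, rounded half-up to one decimal
#'
#' @param numerator,denominator nonnegative counts
#' @return 100 * numerator / denominator, one-decimal half-up rounding
#' @examples
#' stagePercent(2337, 21121)  # 11.1
#' stagePercent(47, 140)      # 33.6
#' @export
stagePercent <- function(numerator, denominator) {
  if (denominator == 0) stop("denominator must be positive")
  roundHalfUp(100 * numerator / denominator, 1L)
}

#' Screen funnel accounting
#'
#' Summarises the counts at each stage of the screening funnel (library,
#' primary hits, retested, reproducible, confirmed, ...) with each
#' stage's percentage of the previous stage and of the full library.
#'
#' @param stageCounts named vector of nonnegative integers, monotone
#'   non-increasing along the funnel
#' @return data.frame with columns stage, count, pct_of_previous,
#'   pct_of_first
#' @examples
#' screenAccounting(c(library = 21121, primary_hits = 2337))
#' @export
screenAccounting <- function(stageCounts) {
  if (is.null(names(stageCounts)) || any(!nzchar(names(stageCounts))))
    stop("stage counts must be named")
  if (any(stageCounts < 0)) stop("stage counts must be nonnegative")
  if (any(diff(stageCounts) > 0))
    stop("stage counts must be monotone non-increasing along the funnel")
  n <- length(stageCounts)
  prev <- c(NA, stageCounts[-n])
  data.frame(
    stage = names(stageCounts),
    count = as.vector(stageCounts),
    pct_of_previous = c(NA_real_, vapply(seq_len(n - 1L), function(i)
      stagePercent(stageCounts[i + 1L], stageCounts[i]), numeric(1))),
    pct_of_first = vapply(seq_len(n), function(i)
      stagePercent(stageCounts[i], stageCounts[1L]), numeric(1)),
    stringsAsFactors = FALSE)
}
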