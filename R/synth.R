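#' @include AllClasses.R AllGenerics.R
NULL

## counts with variance mu + phi mu^2; phi = 0 degenerates to Poisson
rCounts <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(rpois(n, mu))
  rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Default control layout: one full column of controls, static on every
#' plate (carrier rows 0-3, nonsilencing rows 4-5, positive-lethal rows
#' 6-7 of column 0 on an 8-row plate).
#'
#' @param plateRows number of grid rows
#' @return data.frame with columns row, col, condition
#' @export
defaultControlLayout <- function(plateRows = 8L) {
  n1 <- ceiling(plateRows / 2)
  n2 <- ceiling(plateRows / 4)
  cond <- c(rep("carrier", n1), rep("nonsilencing", n2),
            rep("positive-lethal", plateRows - n1 - n2))
  data.frame(row = seq_len(plateRows) - 1L, col = 0L, condition = cond,
             stringsAsFactors = FALSE)
}

## default distribution of true relative effects: most pools null, a
## minority with genuine growth reduction, mirroring a genome-scale
## screen in which roughly one pool in nine reduces growth to <= 25%
defaultEffectDistribution <- function(n) {
  u <- runif(n)
  eff <- rep(1, n)
  strong <- u < 0.12
  mild <- u >= 0.12 & u < 0.22
  eff[strong] <- runif(sum(strong), 0.02, 0.25)
  eff[mild] <- runif(sum(mild), 0.25, 0.90)
  eff
}

#' Construct screen simulation parameters
#'
#' @param nPools number of siRNA pools.
#' @param plateRows,plateCols plate grid (default 8 x 12, a 96-well plate).
#' @param nReplicates physical plates per layout (default 2, matching a
#'   two-replicate primary screen).
#' @param controlLayout static control positions
#'   (\code{\link{defaultControlLayout}}).
#' @param plateSigma log-scale SD of plate random intercepts.
#' @param wellEffectAmplitude log-scale amplitude of the quadratic
#'   edge/bowl position effect.
#' @param driftRate per-plate-order stain-degradation rate in [0, 1).
#' @param effectDistribution function drawing true relative effects.
#' @param dispersion negative-binomial overdispersion; 0 for Poisson.
#' @param baselineCount expected control-well nuclei count.
#' @param lethalEffect relative effect of the positive-lethal control.
#' @return a \linkS4class{ScreenSimParam}
#' @examples
#' p <- ScreenSimParam(nPools = 44)
#' @export
ScreenSimParam <- function(nPools,
                           plateRows = 8L, plateCols = 12L,
                           nReplicates = 2L,
                           controlLayout = defaultControlLayout(plateRows),
                           plateSigma = 0.15,
                           wellEffectAmplitude = 0.1,
                           driftRate = 0.01,
                           effectDistribution = defaultEffectDistribution,
                           dispersion = 0.05,
                           baselineCount = 1500,
                           lethalEffect = 0.02) {
  new("ScreenSimParam",
      nPools = as.integer(nPools),
      plateRows = as.integer(plateRows), plateCols = as.integer(plateCols),
      nReplicates = as.integer(nReplicates),
      controlLayout = controlLayout,
      plateSigma = plateSigma,
      wellEffectAmplitude = wellEffectAmplitude,
      driftRate = driftRate,
      effectDistribution = effectDistribution,
      dispersion = dispersion,
      baselineCount = baselineCount,
      lethalEffect = lethalEffect)
}

## deterministic log-scale bowl over the grid, geometric mean 1
wellSurface <- function(rows, cols, amplitude) {
  u <- function(i, n) if (n == 1L) 0 else 2 * (i / (n - 1L)) - 1
  g <- expand.grid(row = seq_len(rows) - 1L, col = seq_len(cols) - 1L)
  b <- u(g$row, rows)^2 + u(g$col, cols)^2
  logw <- amplitude * (b - mean(b))
  data.frame(row = g$row, col = g$col, logw = logw)
}

#' Simulate a plate-based siRNA growth screen
#'
#' Expected nuclei count for pool \eqn{g} in well \eqn{w} of plate
#' \eqn{p} is \code{baselineCount} x true effect(g) x plate factor(p) x
#' well factor(w) x drift(p); carrier and nonsilencing controls carry
#' true effect 1, the positive-lethal control \code{lethalEffect}.
#' Counts are negative-binomial on the natural scale.
#'
#' @param param a \linkS4class{ScreenSimParam}
#' @param seed integer seed; fixed seed gives bitwise-identical output
#' @return a \linkS4class{ScreenExperiment}; the truth table holds the
#'   planted per-pool relative effects
#' @examples
#' scr <- simulateScreen(ScreenSimParam(nPools = 20), seed = 1)
#' head(wellData(scr))
#' @export
simulateScreen <- function(param, seed) {
  stopifnot(is(param, "ScreenSimParam"))
  validObject(param)
  set.seed(as.integer(seed))

  effects <- param@effectDistribution(param@nPools)
  if (any(effects <= 0) || any(effects > 1.5))
    stop("true relative effects must lie in (0, 1.5]")
  poolIds <- sprintf("pool%05d", seq_len(param@nPools))
  truth <- data.frame(pool_id = poolIds, true_effect = effects,
                      stringsAsFactors = FALSE)

  grid <- expand.grid(row = seq_len(param@plateRows) - 1L,
                      col = seq_len(param@plateCols) - 1L)
  grid <- grid[order(grid$row, grid$col), ]
  key <- paste(grid$row, grid$col)
  ctrlKey <- paste(param@controlLayout$row, param@controlLayout$col)
  ctrlCond <- setNames(as.character(param@controlLayout$condition), ctrlKey)
  freeIdx <- which(!(key %in% ctrlKey))
  nFree <- length(freeIdx)
  nLayouts <- ceiling(param@nPools / nFree)

  surf <- wellSurface(param@plateRows, param@plateCols,
                      param@wellEffectAmplitude)
  logw <- setNames(surf$logw, paste(surf$row, surf$col))

  effectOf <- c(setNames(effects, poolIds),
                carrier = 1, nonsilencing = 1,
                "positive-lethal" = param@lethalEffect)

  out <- vector("list", nLayouts * param@nReplicates)
  plateNo <- 0L
  for (l in seq_len(nLayouts)) {
    slot <- ((l - 1L) * nFree + 1L):min(l * nFree, param@nPools)
    cond <- rep("carrier", nrow(grid))
    cond[match(ctrlKey, key)] <- ctrlCond
    cond[freeIdx[seq_along(slot)]] <- poolIds[slot]
    for (r in seq_len(param@nReplicates)) {
      plateNo <- plateNo + 1L
      order_ <- plateNo
      plateFac <- exp(rnorm(1L, 0, param@plateSigma))
      drift <- (1 - param@driftRate)^(order_ - 1L)
      mu <- param@baselineCount * effectOf[cond] *
        plateFac * exp(logw[key]) * drift
      out[[plateNo]] <- data.frame(
        plate_id = sprintf("L%03dR%d", l, r),
        processing_order = order_,
        row = grid$row, col = grid$col,
        condition = cond,
        count = rCounts(length(mu), mu, param@dispersion),
        stringsAsFactors = FALSE)
    }
  }
  wells <- do.call(rbind, out)
  rownames(wells) <- NULL
  new("ScreenExperiment", wells = wells, truth = truth)
}

#' Construct cohort simulation parameters
#'
#' Defaults emulate a METABRIC-like cohort: 1,996 patients, ten molecular
#' subtypes, five data centres with location/scale batch structure,
#' subtype-specific Weibull baseline hazards of differing shape (so
#' hazards between subtypes are non-proportional) and roughly half of
#' observations censored.
#'
#' @param nPatients,nGenes cohort and gene panel size.
#' @param nSubtypes,nCentres numbers of subtypes and data centres.
#' @param centreShift,centreScale batch SDs (additive shift; log scale).
#' @param subtypeEffect nGenes x nSubtypes matrix of expression shifts
#'   (default all zero).
#' @param baselineShapes,baselineScales per-subtype Weibull parameters;
#'   defaults mix shapes 0.6 to 1.8 with scales 80 to 200 months.
#' @param biomarkerGene gene index carrying the planted threshold effect
#'   (0 = none).
#' @param biomarkerCutQuantile quantile of the planted threshold.
#' @param biomarkerLogHR planted log hazard ratio above the threshold.
#' @param censoringRate target censored fraction.
#' @return a \linkS4class{CohortSimParam}
#' @export
CohortSimParam <- function(nPatients = 1996L, nGenes = 47L,
                           nSubtypes = 10L, nCentres = 5L,
                           centreShift = 0.3, centreScale = 0.15,
                           subtypeEffect = matrix(0, nGenes, nSubtypes),
                           baselineShapes = seq(0.6, 1.8,
                                                length.out = nSubtypes),
                           baselineScales = seq(80, 200,
                                                length.out = nSubtypes),
                           biomarkerGene = 0L,
                           biomarkerCutQuantile = 0.5,
                           biomarkerLogHR = 0,
                           censoringRate = 0.5) {
  new("CohortSimParam",
      nPatients = as.integer(nPatients), nGenes = as.integer(nGenes),
      nSubtypes = as.integer(nSubtypes), nCentres = as.integer(nCentres),
      centreShift = centreShift, centreScale = centreScale,
      subtypeEffect = subtypeEffect,
      baselineShapes = baselineShapes, baselineScales = baselineScales,
      biomarkerGene = as.integer(biomarkerGene),
      biomarkerCutQuantile = biomarkerCutQuantile,
      biomarkerLogHR = biomarkerLogHR,
      censoringRate = censoringRate)
}

#' Simulate a multi-centre expression-plus-outcome cohort
#'
#' Expression is Gaussian around subtype-specific means, then distorted
#' by per-centre location/scale batch factors.  Survival times are drawn
#' from subtype-specific Weibull baselines; when a biomarker gene is
#' planted, patients above its cut quantile have their hazard multiplied
#' by \code{exp(biomarkerLogHR)}.  Censoring is independent exponential
#' with the rate calibrated so the expected censored fraction matches
#' \code{censoringRate}.
#'
#' @param param a \linkS4class{CohortSimParam}
#' @param seed integer seed
#' @return a \linkS4class{CohortExperiment}; \code{truthTable()} returns
#'   the planted parameters
#' @examples
#' coh <- simulateCohort(CohortSimParam(nPatients = 200, nGenes = 5), seed = 1)
#' head(clinicalData(coh))
#' @export
simulateCohort <- function(param, seed) {
  stopifnot(is(param, "CohortSimParam"))
  validObject(param)
  set.seed(as.integer(seed))

  n <- param@nPatients
  G <- param@nGenes
  subtype <- sample.int(param@nSubtypes, n, replace = TRUE)
  centre <- sample.int(param@nCentres, n, replace = TRUE)

  expr <- matrix(rnorm(G * n), nrow = G) + param@subtypeEffect[, subtype,
                                                               drop = FALSE]
  shift <- rnorm(param@nCentres, 0, param@centreShift)
  scale <- exp(rnorm(param@nCentres, 0, param@centreScale))
  expr <- sweep(expr, 2, scale[centre], `*`)
  expr <- sweep(expr, 2, shift[centre], `+`)
  rownames(expr) <- sprintf("gene%03d", seq_len(G))
  colnames(expr) <- sprintf("pt%04d", seq_len(n))

  lp <- rep(0, n)
  biomarkerHigh <- rep(NA, n)
  if (param@biomarkerGene > 0L) {
    x <- expr[param@biomarkerGene, ]
    cut <- quantile(x, param@biomarkerCutQuantile, names = FALSE)
    biomarkerHigh <- x > cut
    lp <- param@biomarkerLogHR * as.numeric(biomarkerHigh)
  }
  shape <- param@baselineShapes[subtype]
  scaleW <- param@baselineScales[subtype]
  u <- runif(n)
  timeDeath <- scaleW * (-log(u) / exp(lp))^(1 / shape)

  event <- rep(1L, n)
  time <- timeDeath
  if (param@censoringRate > 0) {
    target <- param@censoringRate
    f <- function(r) mean(1 - exp(-r * timeDeath)) - target
    rate <- uniroot(f, c(1e-8, 1e4), extendInt = "upX")$root
    cens <- rexp(n, rate)
    event <- as.integer(timeDeath <= cens)
    time <- pmin(timeDeath, cens)
  }
  time <- pmax(time, .Machine$double.eps)

  clin <- S4Vectors::DataFrame(
    id = colnames(expr),
    time = time, event = event,
    subtype = factor(paste0("IC", subtype),
                     levels = paste0("IC", seq_len(param@nSubtypes))),
    centre = factor(paste0("centre", centre),
                    levels = paste0("centre", seq_len(param@nCentres))))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = expr), colData = clin)
  S4Vectors::metadata(se)$truth <- list(
    biomarkerGene = if (param@biomarkerGene > 0L)
      rownames(expr)[param@biomarkerGene] else NA_character_,
    biomarkerCutQuantile = param@biomarkerCutQuantile,
    biomarkerLogHR = param@biomarkerLogHR,
    subtypeEffect = param@subtypeEffect,
    baselineShapes = param@baselineShapes,
    baselineScales = param@baselineScales,
    centreShift = shift, centreScale = scale)
  new("CohortExperiment", se)
}

#' Simulate 3D acinar (or colony) count tables
#'
#' Treated counts are negative-binomial around \code{baseline /
#' foldDecrease}; control counts around \code{baseline}.
#'
#' @param geneEffects named numeric vector of true fold decreases (> 0);
#'   values above 1 mean growth reduction
#' @param nReplicates replicates per condition (>= 2; default 4)
#' @param baseline expected control acini per well
#' @param dispersion negative-binomial overdispersion; 0 for Poisson
#' @param seed integer seed
#' @return data.frame with columns gene, condition, replicate, count;
#'   control rows have gene NA and condition "carrier-control"
#' @examples
#' simulateAssayCounts(c(PROCR = 31.6), nReplicates = 4, seed = 1)
#' @export
simulateAssayCounts <- function(geneEffects, nReplicates = 4L,
                                baseline = 200, dispersion = 0.02,
                                seed = 1L) {
  if (baseline <= 0) stop("baseline must be positive")
  if (any(geneEffects <= 0)) stop("fold decreases must be positive")
  if (nReplicates < 2L) stop("at least two replicates are required")
  if (is.null(names(geneEffects)))
    names(geneEffects) <- sprintf("gene%02d", seq_along(geneEffects))
  set.seed(as.integer(seed))
  ctrl <- data.frame(gene = NA_character_, condition = "carrier-control",
                     replicate = seq_len(nReplicates),
                     count = rCounts(nReplicates, baseline, dispersion),
                     stringsAsFactors = FALSE)
  trt <- do.call(rbind, lapply(names(geneEffects), function(g) {
    data.frame(gene = g, condition = "silenced",
               replicate = seq_len(nReplicates),
               count = rCounts(nReplicates, baseline / geneEffects[[g]],
                               dispersion),
               stringsAsFactors = FALSE)
  }))
  rbind(ctrl, trt)
}

#' Simulate live-cell imaging time series
#'
#' Red-object density follows logistic growth whose rate is scaled by the
#' per-condition growth effect; the caspase-positive green fraction rises
#' over time in inverse proportion to growth (controlled by
#' \code{coupling}), emulating the inverse relation between apoptosis and
#' proliferation.  Conditions are measured in triplicate every
#' \code{stepHours} hours.
#'
#' @param conditionEffects named vector of growth-rate multipliers in
#'   [0, 1.5] (1 = control-like growth)
#' @param coupling apoptosis-proliferation inverse-coupling strength in
#'   [0, 1]
#' @param horizonHours observation window (must be divisible by
#'   \code{stepHours}); default 84
#' @param stepHours imaging interval; default 4
#' @param nReplicates wells per condition; default 3
#' @param baselineDensity,carryingCapacity,growthRate logistic-growth
#'   parameters (objects per mm^2; per hour)
#' @param noiseSd log-scale measurement noise SD
#' @param seed integer seed
#' @return data.frame with columns condition, replicate, time,
#'   red_density, green_fraction
#' @examples
#' ts <- simulateTimeSeries(c(control = 1, siA = 0.2), seed = 1)
#' @export
simulateTimeSeries <- function(conditionEffects, coupling = 1,
                               horizonHours = 84, stepHours = 4,
                               nReplicates = 3L,
                               baselineDensity = 50,
                               carryingCapacity = 800,
                               growthRate = 0.06,
                               noiseSd = 0.05, seed = 1L) {
  if (horizonHours < 0) stop("horizonHours must be nonnegative")
  if (horizonHours %% stepHours != 0)
    stop("horizonHours must be divisible by stepHours")
  if (is.null(names(conditionEffects)))
    names(conditionEffects) <- sprintf("cond%02d",
                                       seq_along(conditionEffects))
  set.seed(as.integer(seed))
  times <- seq(0, horizonHours, by = stepHours)
  rows <- lapply(names(conditionEffects), function(cc) {
    eff <- conditionEffects[[cc]]
    r <- growthRate * eff
    mu <- carryingCapacity /
      (1 + ((carryingCapacity - baselineDensity) / baselineDensity) *
         exp(-r * times))
    gmu <- pmin(pmax(2 + coupling * 40 * (1 - pmin(eff, 1)) *
                       (times / max(horizonHours, 1)), 0), 100)
    do.call(rbind, lapply(seq_len(nReplicates), function(rep_) {
      data.frame(condition = cc, replicate = rep_, time = times,
                 red_density = mu * exp(rnorm(length(times), 0, noiseSd)),
                 green_fraction = pmin(pmax(
                   gmu + rnorm(length(times), 0, 1), 0), 100),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
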