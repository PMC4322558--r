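#' @include AllClasses.R AllGenerics.R
#' @importFrom survival Surv coxph strata survdiff
NULL

coxAIC <- function(fit) {
  ## AIC on the partial likelihood: -2 logPL + 2 k
  -2 * fit$loglik[2] + 2 * sum(!is.na(coef(fit)))
}

#' @describeIn binarizeExpression numeric method.  For each candidate
#'   quantile the expression is dichotomized (high = above the cut) and a
#'   Cox model with the single binarized covariate is fitted; its AIC is
#'   \eqn{-2\ell + 2k} on the partial likelihood.  The chosen cut
#'   minimises AIC; when the AIC range over eligible candidates is below
#'   \code{aicFallbackDelta} (default 3.0) the median cut is used instead
#'   (to keep case counts adequate within subtype groups).  Candidates
#'   whose arms carry fewer than \code{minEventsPerArm} events are
#'   excluded; if that excludes the median, the fallback reverts to the
#'   eligible AIC minimum so the events-per-arm guarantee always holds.
#' @param time,event survival times and 1/0 event indicators
#' @param quantiles candidate cut quantiles
#' @param minEventsPerArm minimum events required in each arm (default
#'   10)
#' @param aicFallbackDelta AIC range below which the median fallback
#'   fires (default 3.0)
#' @param gene optional gene label carried into the result
#' @export
setMethod("binarizeExpression", "numeric",
          function(x, time, event, quantiles = c(0.15, 0.25, 0.5, 0.75),
                   minEventsPerArm = 10L, aicFallbackDelta = 3.0,
                   gene = "", ...) {
  if (length(unique(x)) < 4L)
    stop("at least four distinct expression values are required")
  if (sum(event) == 0L) stop("no events in the data")
  cuts <- quantile(x, quantiles, names = FALSE, type = 7)
  aic <- setNames(rep(NA_real_, length(quantiles)),
                  sprintf("q%02d", round(100 * quantiles)))
  for (i in seq_along(quantiles)) {
    high <- x > cuts[i]
    evts <- c(sum(event[high]), sum(event[!high]))
    if (any(evts < minEventsPerArm)) next
    fit <- tryCatch(coxph(Surv(time, event) ~ high, ties = "breslow"),
                    error = function(e) NULL)
    if (!is.null(fit)) aic[i] <- coxAIC(fit)
  }
  eligible <- which(!is.na(aic))
  if (length(eligible) == 0L)
    stop("every candidate cut leaves an arm below the event minimum")
  best <- eligible[which.min(aic[eligible])]
  fallback <- FALSE
  if (length(eligible) > 1L &&
      diff(range(aic[eligible])) < aicFallbackDelta) {
    medIdx <- which(quantiles == 0.5)
    if (length(medIdx) == 1L && medIdx %in% eligible) {
      best <- medIdx
      fallback <- TRUE
    }
  }
  groups <- factor(ifelse(x > cuts[best], "high", "low"),
                   levels = c("low", "high"))
  new("BinarizationResult", gene = gene,
      candidateQuantiles = quantiles, aic = aic,
      chosenQuantile = quantiles[best], fallbackUsed = fallback,
      cutValue = cuts[best], groups = groups)
})

#' @describeIn binarizeExpression CohortExperiment method for one gene of
#'   the expression assay.
#' @export
setMethod("binarizeExpression", "CohortExperiment",
          function(x, gene, ...) {
  clin <- clinicalData(x)
  expr <- SummarizedExperiment::assay(x, "exprs")[gene, ]
  binarizeExpression(as.numeric(expr), time = clin$time,
                     event = clin$event, gene = gene, ...)
})

#' Subtype-stratified Cox hazard ratio
#'
#' Cox model with a shared log hazard ratio for the binarized biomarker
#' and per-stratum (subtype) baseline hazards left unconstrained, which
#' absorbs the non-proportional hazards between subtypes.  Ties use the
#' Breslow approximation.
#'
#' @param time,event survival data
#' @param group factor with levels low/high (high vs low is reported)
#' @param strataVar subtype labels (NULL for unstratified)
#' @return list with hazard_ratio, ci_low, ci_high (Wald 95\%), log_hr,
#'   se, p_value, n_events
#' @export
stratifiedCox <- function(time, event, group, strataVar = NULL) {
  if (sum(event) == 0L) stop("no events in the data")
  group <- droplevels(factor(group))
  if (nlevels(group) < 2L) stop("a binarized group is empty")
  df <- data.frame(time = time, event = event, group = group)
  if (is.null(strataVar)) {
    fit <- coxph(Surv(time, event) ~ group, data = df,
                 ties = "breslow")
  } else {
    df$str <- factor(strataVar)
    fit <- coxph(Surv(time, event) ~ group + strata(str), data = df,
                 ties = "breslow")
  }
  b <- coef(fit)[1]
  se <- sqrt(fit$var[1, 1])
  list(hazard_ratio = exp(b),
       ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
       log_hr = unname(b), se = se,
       p_value = 2 * pnorm(-abs(b / se)),
       n_events = sum(event))
}

#' Omnibus biomarker-by-subtype interaction test
#'
#' Likelihood-ratio comparison of a Cox model with binarized expression,
#' subtype and their interaction against a subtype-only model.  The
#' degrees of freedom equal the number of biomarker-related parameters
#' (main effect plus one interaction per extra subtype), so the test
#' detects any survival effect of the biomarker, including effects that
#' reverse direction between subtypes.
#'
#' @param time,event survival data
#' @param group binarized biomarker factor
#' @param subtype subtype labels
#' @return list with statistic, df, p_value, converged
#' @export
omnibusInteractionTest <- function(time, event, group, subtype) {
  df <- data.frame(time = time, event = event,
                   group = droplevels(factor(group)),
                   subtype = droplevels(factor(subtype)))
  if (nlevels(df$subtype) < 2L)
    stop("at least two subtypes are required")
  if (nlevels(df$group) < 2L) stop("a biomarker arm is empty")
  converged <- TRUE
  full <- withCallingHandlers(
    coxph(Surv(time, event) ~ group * subtype, data = df,
          ties = "breslow"),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  red <- coxph(Surv(time, event) ~ subtype, data = df, ties = "breslow")
  stat <- 2 * (full$loglik[2] - red$loglik[2])
  dfree <- sum(!is.na(coef(full))) - sum(!is.na(coef(red)))
  list(statistic = stat, df = dfree,
       p_value = pchisq(stat, dfree, lower.tail = FALSE),
       converged = converged)
}

## Harrington-Fleming weighted score contributions of one stratum.
## Weights are S(t-)^rho with S the left-continuous pooled Kaplan-Meier
## estimate within the stratum; Breslow-style handling of ties.
grhoStratum <- function(time, event, g1, rho) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; g1 <- g1[ord]
  ut <- unique(time[event == 1])
  n <- length(time)
  U <- 0; V <- 0
  S <- 1  # KM estimate just before the current event time
  for (t in ut) {
    atRisk <- time >= t
    nAll <- sum(atRisk)
    n1 <- sum(atRisk & g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g1)
    w <- S^rho
    U <- U + w * (d1 - d * n1 / nAll)
    if (nAll > 1)
      V <- V + w^2 * d * (n1 / nAll) * (1 - n1 / nAll) *
        (nAll - d) / (nAll - 1)
    S <- S * (1 - d / nAll)
  }
  c(U = U, V = V)
}

#' Stratified G-rho (Harrington-Fleming) weighted rank test
#'
#' Two-group weighted rank test with weights \eqn{\hat S(t-)^\rho}, the
#' left-continuous pooled Kaplan-Meier estimate computed within each
#' stratum; score and variance are summed across strata and referred to
#' a chi-square distribution on one degree of freedom.  \eqn{\rho = 0}
#' is the stratified log-rank test; \eqn{\rho = 1} places heavier weight
#' on earlier event times, guarding against hazards that change over
#' follow-up.  Strata without events contribute nothing.
#'
#' @param time,event survival data
#' @param group two-level factor
#' @param strataVar optional stratum labels
#' @param rho weight exponent (>= 0; default 1)
#' @return list with statistic (chi-square, 1 df), p_value, score U,
#'   variance V, rho
#' @export
grhoTest <- function(time, event, group, strataVar = NULL, rho = 1.0) {
  if (rho < 0) stop("rho must be nonnegative")
  group <- droplevels(factor(group))
  if (nlevels(group) != 2L)
    stop("exactly two non-empty groups are required")
  g1 <- group == levels(group)[2]
  if (is.null(strataVar)) strataVar <- rep(1L, length(time))
  parts <- split(seq_along(time), strataVar)
  UV <- vapply(parts, function(idx) {
    if (sum(event[idx]) == 0L) return(c(U = 0, V = 0))
    grhoStratum(time[idx], event[idx], g1[idx], rho)
  }, numeric(2))
  U <- sum(UV["U", ]); V <- sum(UV["V", ])
  if (V <= 0) {
    stat <- 0
  } else {
    stat <- U^2 / V
  }
  list(statistic = stat,
       p_value = pchisq(stat, df = 1L, lower.tail = FALSE),
       U = U, V = V, rho = rho)
}

#' BH adjustment of a per-gene survival panel
#'
#' Adjusts the omnibus and G-rho p-value families separately across
#' genes (one p-value per gene per family) and flags genes significant
#' at adjusted 0.05 and 0.1.
#'
#' @param results data.frame with columns gene, omnibus_p, grho_p
#' @return the table with omnibus_p_adj, grho_p_adj and logical flag
#'   columns sig_omnibus_05, sig_grho_05, sig_omnibus_10, sig_grho_10
#' @export
adjustGenePanel <- function(results) {
  if (anyDuplicated(results$gene))
    stop("one p-value per gene per family is required")
  results$omnibus_p_adj <- bhAdjust(results$omnibus_p)
  results$grho_p_adj <- bhAdjust(results$grho_p)
  results$sig_omnibus_05 <- !is.na(results$omnibus_p_adj) &
    results$omnibus_p_adj < 0.05
  results$sig_grho_05 <- !is.na(results$grho_p_adj) &
    results$grho_p_adj < 0.05
  results$sig_omnibus_10 <- !is.na(results$omnibus_p_adj) &
    results$omnibus_p_adj < 0.1
  results$sig_grho_10 <- !is.na(results$grho_p_adj) &
    results$grho_p_adj < 0.1
  results
}

#' Per-gene subtype-stratified survival analysis
#'
#' For every requested gene: AIC-guided dichotomization, stratified Cox
#' hazard ratio with Wald CI, omnibus biomarker-by-subtype interaction
#' LRT, stratified G-rho test (rho = 1), then BH adjustment across genes
#' within each test family.
#'
#' @param cohort a \linkS4class{CohortExperiment}
#' @param genes gene names (default: all genes of the assay)
#' @param quantiles candidate cut quantiles
#' @param rho G-rho weight exponent
#' @param minEventsPerArm events-per-arm floor for candidate cuts
#' @return data.frame with one row per gene: chosen_quantile,
#'   fallback_used, hazard_ratio, ci_low, ci_high, omnibus_p, grho_p and
#'   their BH-adjusted versions with significance flags
#' @export
geneSurvivalAnalysis <- function(cohort, genes = NULL,
                                 quantiles = c(0.15, 0.25, 0.5, 0.75),
                                 rho = 1.0, minEventsPerArm = 10L) {
  clin <- clinicalData(cohort)
  expr <- SummarizedExperiment::assay(cohort, "exprs")
  if (is.null(genes)) genes <- rownames(expr)
  rows <- lapply(genes, function(g) {
    bin <- binarizeExpression(as.numeric(expr[g, ]), time = clin$time,
                              event = clin$event, quantiles = quantiles,
                              minEventsPerArm = minEventsPerArm,
                              gene = g)
    grp <- binarizedGroups(bin)
    cox <- stratifiedCox(clin$time, clin$event, grp, clin$subtype)
    omn <- omnibusInteractionTest(clin$time, clin$event, grp,
                                  clin$subtype)
    gr <- grhoTest(clin$time, clin$event, grp, clin$subtype, rho = rho)
    data.frame(gene = g,
               chosen_quantile = chosenQuantile(bin),
               fallback_used = bin@fallbackUsed,
               hazard_ratio = cox$hazard_ratio,
               ci_low = cox$ci_low, ci_high = cox$ci_high,
               omnibus_p = omn$p_value, grho_p = gr$p_value,
               stringsAsFactors = FALSE)
  })
  adjustGenePanel(do.call(rbind, rows))
}
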