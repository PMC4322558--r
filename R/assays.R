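#' @include AllClasses.R AllGenerics.R
NULL

#' The packaged 47-gene acinar panel
#'
#' Loads the curated summary table of the 47 validated growth-regulator
#' genes from the co-culture screen: per-gene primary-screen rank, median
#' secondary-screen rank, 3D acinar-assay rank and fold decrease (missing
#' for the three genes without 3D data), and the binary shRNA outcome
#' (lethal vs growth-postselection).  Structural counts (47 genes, 44
#' with 3D data, 24 shRNA-lethal) are validated at load time.
#'
#' @return data.frame with columns gene, refseq, rank_primary,
#'   rank_secondary, rank_3d, fold_decrease_3d, shrna_outcome
#' @examples
#' panel <- acinarPanel()
#' nrow(panel)  # 47
#' @export
acinarPanel <- function() {
  path <- system.file("extdata", "acinar_panel_47.csv",
                      package = "GrowthScreen", mustWork = TRUE)
  fx <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "refseq", "rank_primary", "rank_secondary", "rank_3d",
            "fold_decrease_3d", "shrna_outcome")
  if (!all(need %in% names(fx)))
    stop("panel file is missing columns: ",
         paste(setdiff(need, names(fx)), collapse = ", "))
  if (nrow(fx) != 47L) stop("panel must contain 47 genes")
  if (anyDuplicated(fx$gene)) stop("panel genes must be unique")
  if (any(fx$fold_decrease_3d <= 0, na.rm = TRUE))
    stop("fold decreases must be positive")
  if (sum(!is.na(fx$fold_decrease_3d)) != 44L)
    stop("panel must contain 44 genes with 3D data")
  if (sum(fx$shrna_outcome == "lethal") != 24L)
    stop("panel must contain 24 shRNA-lethal genes")
  fx
}

## bias-corrected percentile bootstrap interval
bcBootstrapCI <- function(est, boot, level = 0.95) {
  boot <- boot[is.finite(boot)]
  if (length(boot) == 0L) return(c(NA_real_, NA_real_))
  prop <- mean(boot < est) + 0.5 * mean(boot == est)
  z0 <- qnorm(min(max(prop, 1e-6), 1 - 1e-6))
  a <- (1 - level) / 2
  probs <- pnorm(2 * z0 + qnorm(c(a, 1 - a)))
  unname(quantile(boot, probs, type = 7))
}

#' Fold decrease in acinar formation with bootstrap CI
#'
#' Fold decrease is the mean control count divided by the mean silenced
#' count, so values above 1 mean growth reduction.  The 95\% interval is
#' a seeded bias-corrected percentile bootstrap over replicates (B =
#' 2000).  A zero silenced mean yields an infinite fold with a one-sided
#' interval.
#'
#' @param table data.frame with columns gene, condition, replicate,
#'   count
#' @param gene gene label to evaluate
#' @param controlLabels condition labels treated as control
#' @param B bootstrap draws
#' @param seed integer seed for the bootstrap
#' @param level confidence level
#' @return list with fold_decrease, ci_low, ci_high, n_control,
#'   n_silenced
#' @examples
#' tab <- simulateAssayCounts(c(PROCR = 30), seed = 1)
#' acinarFoldDecrease(tab, "PROCR")
#' @export
acinarFoldDecrease <- function(table, gene,
                               controlLabels = c("carrier-control",
                                                 "nonsilencing-control"),
                               B = 2000L, seed = 1L, level = 0.95) {
  ctrl <- table$count[table$condition %in% controlLabels &
                        (is.na(table$gene) | table$gene == gene)]
  sil <- table$count[!is.na(table$gene) & table$gene == gene &
                       table$condition == "silenced"]
  if (length(ctrl) < 2L) stop("control condition missing or has < 2 replicates")
  if (length(sil) < 2L) stop("silenced condition missing or has < 2 replicates")
  if (mean(ctrl) == 0) stop("all-zero control counts")
  est <- mean(ctrl) / mean(sil)
  set.seed(as.integer(seed))
  boot <- vapply(seq_len(B), function(i) {
    mean(sample(ctrl, replace = TRUE)) / mean(sample(sil, replace = TRUE))
  }, numeric(1))
  if (!is.finite(est)) {
    ci <- c(quantile(boot[is.finite(boot)], 0.025, type = 7,
                     names = FALSE), Inf)
  } else {
    ci <- bcBootstrapCI(est, boot, level)
  }
  list(gene = gene, fold_decrease = est, ci_low = ci[1], ci_high = ci[2],
       n_control = length(ctrl), n_silenced = length(sil))
}

#' Dunnett many-to-one comparisons against a shared control
#'
#' One-way fit of counts on condition followed by Dunnett's single-step
#' family-wise adjustment of every treatment-vs-control contrast
#' (multivariate t reference distribution).
#'
#' @param table data.frame with columns condition and count; one level is
#'   the control
#' @param controlLabel the control condition label
#' @return data.frame with columns condition, estimate, p_adj
#' @examples
#' tab <- simulateAssayCounts(c(A = 4, B = 1), seed = 2)
#' tab$condition[tab$condition == "silenced"] <- tab$gene[tab$condition == "silenced"]
#' dunnettAdjust(tab[, c("condition", "count")], "carrier-control")
#' @export
dunnettAdjust <- function(table, controlLabel) {
  if (!controlLabel %in% table$condition)
    stop("control label absent from table")
  reps <- table(table$condition)
  if (any(reps < 2L)) stop("every group needs at least two replicates")
  dat <- data.frame(
    condition = relevel(factor(table$condition), ref = controlLabel),
    count = table$count)
  fit <- aov(count ~ condition, data = dat)
  gl <- multcomp::glht(fit,
                       linfct = multcomp::mcp(condition = "Dunnett"))
  sm <- summary(gl)
  data.frame(
    condition = sub(paste0(" - ", controlLabel, " == 0$"), "",
                    names(sm$test$coefficients)),
    estimate = as.vector(sm$test$coefficients),
    p_adj = as.vector(sm$test$pvalues),
    stringsAsFactors = FALSE)
}

#' Surviving fraction of colonies across patients
#'
#' Per-patient ratio of target to nonsilencing-control colony counts; the
#' summary is the mean of per-patient ratios with a seeded bootstrap 95\%
#' CI over patients.  Every patient must contribute a paired target and
#' control count; a missing patient is an error, not a silent drop.
#'
#' @param table data.frame with columns gene, condition, replicate
#'   (patient index), count
#' @param gene target gene label
#' @param controlLabel control condition label (default
#'   "nonsilencing-control")
#' @param B bootstrap draws
#' @param seed integer seed
#' @return list with fraction, ci_low, ci_high, fold_decrease
#'   (1/fraction), per_patient ratios
#' @export
survivingFraction <- function(table, gene,
                              controlLabel = "nonsilencing-control",
                              B = 2000L, seed = 1L) {
  tgt <- table[!is.na(table$gene) & table$gene == gene &
                 table$condition == "silenced", ]
  ctl <- table[table$condition == controlLabel &
                 (is.na(table$gene) | table$gene == gene), ]
  patients <- sort(unique(c(tgt$replicate, ctl$replicate)))
  it <- match(patients, tgt$replicate)
  ic <- match(patients, ctl$replicate)
  if (anyNA(it) || anyNA(ic))
    stop("every patient needs paired target and control counts")
  if (any(ctl$count[ic] == 0))
    stop("control count is zero for a patient")
  ratio <- tgt$count[it] / ctl$count[ic]
  est <- mean(ratio)
  set.seed(as.integer(seed))
  boot <- vapply(seq_len(B), function(i)
    mean(sample(ratio, replace = TRUE)), numeric(1))
  ci <- bcBootstrapCI(est, boot)
  list(gene = gene, fraction = est, ci_low = ci[1], ci_high = ci[2],
       fold_decrease = 1 / est, per_patient = ratio)
}

#' Count panel genes beyond a fold-decrease threshold
#'
#' @param fixture the panel table (\code{\link{acinarPanel}()})
#' @param direction "above" or "below" (strict comparison)
#' @param threshold positive fold-decrease threshold (Inf allowed)
#' @return integer count; genes with missing fold decrease never count
#' @examples
#' countFoldThreshold(acinarPanel(), "above", 10)  # 3
#' @export
countFoldThreshold <- function(fixture, direction = c("above", "below"),
                               threshold) {
  direction <- match.arg(direction)
  if (is.na(threshold) || threshold <= 0)
    stop("threshold must be positive")
  f <- fixture$fold_decrease_3d
  f <- f[!is.na(f)]
  if (direction == "above") sum(f > threshold) else sum(f < threshold)
}

#' Accounting summary of the packaged acinar panel
#'
#' Direct counts over the panel: total genes, genes with 3D data,
#' shRNA-lethal genes, genes without a significant 3D reduction (fold
#' decrease below the panel convention threshold of 1.7, chosen strictly
#' between the largest non-significant and smallest significant printed
#' fold values) and genes required in 3D (total minus not-reduced; the
#' genes lacking 3D data are counted as required).
#'
#' @param fixture the panel table (any data.frame with the panel columns)
#' @param notReducedThreshold panel convention threshold (default 1.7)
#' @return list with total, with_3d_data, shrna_lethal, not_reduced_3d,
#'   required_3d
#' @examples
#' fixtureSummary(acinarPanel())
#' @export
fixtureSummary <- function(fixture, notReducedThreshold = 1.7) {
  f <- fixture$fold_decrease_3d
  notReduced <- sum(!is.na(f) & f < notReducedThreshold)
  list(
    total = nrow(fixture),
    with_3d_data = sum(!is.na(f)),
    shrna_lethal = sum(fixture$shrna_outcome == "lethal"),
    not_reduced_3d = notReduced,
    required_3d = nrow(fixture) - notReduced)
}
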