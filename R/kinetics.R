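#' @include AllClasses.R AllGenerics.R
NULL

#' Trapezoidal area under a serial measurement curve
#'
#' @param times strictly increasing observation times (hours)
#' @param values measurements at those times (no missing values)
#' @return area over the observed window (e.g. counts h / mm^2)
#' @examples
#' aucTrapezoid(c(0, 4, 8), c(1, 3, 2))  # 18
#' @export
aucTrapezoid <- function(times, values) {
  if (length(times) < 2L) stop("at least two time points are required")
  if (length(times) != length(values)) stop("times and values differ in length")
  if (anyNA(times) || anyNA(values)) stop("missing time points are rejected")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  pracma::trapz(times, values)
}

#' Per-well AUC summaries of a live-cell time series table
#'
#' @param ts data.frame with columns condition, replicate, time and the
#'   measurement channels
#' @param channel column to integrate ("red_density" or
#'   "green_fraction")
#' @return data.frame with columns condition, replicate, auc
#' @export
aucByCondition <- function(ts, channel = c("red_density",
                                           "green_fraction")) {
  channel <- match.arg(channel)
  parts <- split(ts, list(ts$condition, ts$replicate), drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(p) {
    p <- p[order(p$time), ]
    data.frame(condition = p$condition[1], replicate = p$replicate[1],
               auc = aucTrapezoid(p$time, p[[channel]]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$condition, out$replicate), ]
}

#' Spearman rank correlation
#'
#' @param x,y equal-length numeric vectors (length >= 3); average ranks
#'   for ties
#' @return rank correlation in [-1, 1]
#' @examples
#' spearmanRho(1:4, c(2, 1, 4, 3))  # 0.6
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("at least three observations are required")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("rank correlation is undefined for a constant vector")
  cor(x, y, method = "spearman")
}

#' Permutation test for a rank correlation
#'
#' Permutes the pairing of \code{y} against \code{x}; the two-sided
#' empirical p-value uses the (k+1)/(B+1) convention where k counts
#' permutations with |rho| at least the observed |rho|.  When no
#' permutation reaches the observed value the result additionally
#' reports the bound "< 1/nPerm".
#'
#' @param x,y paired vectors
#' @param nPerm number of permutations (>= 1000)
#' @param seed integer seed
#' @return list with rho, p_value, p_bound (character or NA),
#'   exceedances, n_perm
#' @export
correlationPermutationTest <- function(x, y, nPerm = 10000L, seed = 1L) {
  if (nPerm < 1000L) stop("use at least 1000 permutations")
  obs <- spearmanRho(x, y)
  set.seed(as.integer(seed))
  k <- 0L
  for (i in seq_len(nPerm)) {
    r <- cor(x, sample(y), method = "spearman")
    if (abs(r) >= abs(obs) - 1e-12) k <- k + 1L
  }
  list(rho = obs,
       p_value = (k + 1) / (nPerm + 1),
       p_bound = if (k == 0L) sprintf("< %g", 1 / nPerm) else NA_character_,
       exceedances = k, n_perm = as.integer(nPerm))
}

#' One-way ANOVA of AUCs with per-condition contrasts against control
#'
#' @param aucs data.frame with columns condition and auc (>= 2 replicates
#'   per condition)
#' @param controlLabel control condition label
#' @return list with omnibus_p (one-way ANOVA F test) and contrasts
#'   (data.frame condition, estimate, p_value of the Wald contrast vs
#'   control)
#' @export
anovaVsControl <- function(aucs, controlLabel) {
  if (!controlLabel %in% aucs$condition)
    stop("control label absent from AUC table")
  reps <- table(aucs$condition)
  if (any(reps < 2L)) stop("every condition needs at least two replicates")
  dat <- data.frame(
    condition = relevel(factor(aucs$condition), ref = controlLabel),
    auc = aucs$auc)
  fit <- lm(auc ~ condition, data = dat)
  om <- anova(fit)[["Pr(>F)"]][1]
  co <- summary(fit)$coefficients
  rows <- grep("^condition", rownames(co), value = TRUE)
  list(omnibus_p = om,
       contrasts = data.frame(
         condition = sub("^condition", "", rows),
         estimate = co[rows, "Estimate"],
         p_value = co[rows, "Pr(>|t|)"],
         row.names = NULL, stringsAsFactors = FALSE))
}
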