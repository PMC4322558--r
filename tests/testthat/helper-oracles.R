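# Independent oracles used to cross-check the package's estimators.
# These are written from the defining formulas, not from the package code.

# Cox partial log-likelihood for a single binary covariate, Breslow ties.
bruteCoxLogLik <- function(beta, time, event, x) {
  ll <- 0
  for (t in unique(time[event == 1])) {
    dead <- which(event == 1 & time == t)
    risk <- which(time >= t)
    ll <- ll + beta * sum(x[dead]) -
      length(dead) * log(sum(exp(beta * x[risk])))
  }
  ll
}

# AIC = -2 max logPL + 2k by direct 1-d maximization.
bruteCoxAIC <- function(time, event, x) {
  opt <- optimize(bruteCoxLogLik, c(-20, 20), maximum = TRUE,
                  tol = 1e-10, time = time, event = event, x = x)
  -2 * opt$objective + 2
}

# Stratified log-rank chi-square from the defining score/variance sums
# (unit weights; hypergeometric variance; Breslow-style tie handling).
bruteStratLogRank <- function(time, event, g1, strat) {
  U <- 0; V <- 0
  for (s in unique(strat)) {
    idx <- strat == s
    tt <- time[idx]; ee <- event[idx]; gg <- g1[idx]
    for (t in unique(tt[ee == 1])) {
      risk <- tt >= t
      n <- sum(risk); n1 <- sum(risk & gg)
      d <- sum(ee == 1 & tt == t)
      d1 <- sum(ee == 1 & tt == t & gg)
      U <- U + d1 - d * n1 / n
      if (n > 1)
        V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  U^2 / V
}

# Kruskal-Wallis statistic from the rank formula with tie correction.
bruteKruskalWallis <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(z) length(z) * mean(z)^2)) -
    3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Spearman rho from 1 - 6 sum d^2 / (n (n^2 - 1)) (no ties).
bruteSpearman <- function(x, y) {
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (length(x) * (length(x)^2 - 1))
}

# Cox fit that returns NULL when the partial likelihood is degenerate
# (separation / monotone likelihood), so oracle comparisons only use
# well-posed instances.
fitCoxClean <- function(time, event, x) {
  ok <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, ties = "breslow"),
    warning = function(w) {
      ok <<- FALSE
      invokeRestart("muffleWarning")
    })
  if (ok) fit else NULL
}

makeSurvivalInstance <- function(n = 40, nStrata = 3) {
  list(time = round(rexp(n, 0.2), 2) + 0.01,
       event = rbinom(n, 1, 0.7),
       group = factor(sample(c("low", "high"), n, TRUE),
                      levels = c("low", "high")),
       strat = sample(seq_len(nStrata), n, TRUE))
}
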