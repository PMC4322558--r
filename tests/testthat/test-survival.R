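test_that("binarization: AIC minimum rule, median fallback and event floor", {
  # planted threshold at the 25% quantile with a strong effect
  coh <- simulateCohort(CohortSimParam(nPatients = 600, nGenes = 2,
                                       biomarkerGene = 1L,
                                       biomarkerCutQuantile = 0.25,
                                       biomarkerLogHR = 1.5), seed = 3)
  b <- binarizeExpression(coh, "gene001")
  expect_equal(chosenQuantile(b), 0.25)
  expect_false(b@fallbackUsed)
  expect_s4_class(b, "BinarizationResult")

  # null biomarker: flat AIC profile triggers the median fallback
  fallbacks <- vapply(1:20, function(s) {
    cohN <- simulateCohort(CohortSimParam(nPatients = 400, nGenes = 1,
                                          biomarkerGene = 1L,
                                          biomarkerLogHR = 0), seed = s)
    binarizeExpression(cohN, "gene001")@fallbackUsed
  }, logical(1))
  expect_gt(mean(fallbacks), 0.5)
  fbCut <- binarizeExpression(
    simulateCohort(CohortSimParam(nPatients = 400, nGenes = 1,
                                  biomarkerGene = 1L,
                                  biomarkerLogHR = 0), seed = 1),
    "gene001")
  if (fbCut@fallbackUsed) expect_equal(chosenQuantile(fbCut), 0.5)

  # the chosen cut never leaves an arm below the event floor
  set.seed(10)
  n <- 80
  x <- rnorm(n); tme <- rexp(n); ev <- rbinom(n, 1, 0.5)
  bb <- binarizeExpression(x, time = tme, event = ev,
                           minEventsPerArm = 10L)
  grp <- binarizedGroups(bb)
  expect_gte(min(tapply(ev, grp, sum)), 10)

  # all candidate cuts infeasible is an explicit error
  expect_error(binarizeExpression(x, time = tme, event = ev,
                                  minEventsPerArm = 500L),
               "event minimum")
})

test_that("binarization recovers a planted 25% cut in the majority of replicates", {
  hits <- vapply(1:100, function(s) {
    coh <- simulateCohort(CohortSimParam(nPatients = 500, nGenes = 1,
                                         biomarkerGene = 1L,
                                         biomarkerCutQuantile = 0.25,
                                         biomarkerLogHR = 1.2),
                          seed = 5000 + s)
    chosenQuantile(binarizeExpression(coh, "gene001")) == 0.25
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("Cox AIC agrees with a brute-force partial likelihood", {
  set.seed(400)
  checked <- 0L
  attempts <- 0L
  while (checked < 25L && attempts < 500L) {
    attempts <- attempts + 1L
    n <- sample(5:8, 1)
    tme <- sample(1:6, n, replace = TRUE)      # forces ties
    ev <- rbinom(n, 1, 0.8)
    if (sum(ev) < 2) ev[1:2] <- 1L
    x <- rbinom(n, 1, 0.5)
    if (length(unique(x)) < 2) x[1] <- 1L - x[1]
    fit <- fitCoxClean(tme, ev, x)   # skip degenerate likelihoods
    if (is.null(fit)) next
    mine <- -2 * fit$loglik[2] + 2
    expect_lt(abs(mine - bruteCoxAIC(tme, ev, x)), 1e-8)
    checked <- checked + 1L
  }
  expect_gte(checked, 25L)
})

test_that("stratified Cox: null centring, reduction and planted HR recovery", {
  # single stratum equals unstratified Cox
  set.seed(21)
  n <- 120
  tme <- rexp(n); ev <- rbinom(n, 1, 0.7)
  grp <- factor(sample(c("low", "high"), n, TRUE),
                levels = c("low", "high"))
  a <- stratifiedCox(tme, ev, grp, rep(1L, n))
  b <- stratifiedCox(tme, ev, grp, NULL)
  expect_equal(a$hazard_ratio, b$hazard_ratio, tolerance = 1e-10)

  # planted HR 2.0, ten strata with different Weibull baselines, n = 2000
  hrs <- vapply(1:100, function(s) {
    coh <- simulateCohort(CohortSimParam(nPatients = 2000, nGenes = 1,
                                         biomarkerGene = 1L,
                                         biomarkerCutQuantile = 0.5,
                                         biomarkerLogHR = log(2)),
                          seed = 6000 + s)
    clin <- clinicalData(coh)
    x <- SummarizedExperiment::assay(coh, "exprs")[1, ]
    grp <- factor(ifelse(x > median(x), "high", "low"),
                  levels = c("low", "high"))
    stratifiedCox(clin$time, clin$event, grp,
                  clin$subtype)$hazard_ratio
  }, numeric(1))
  expect_gte(mean(hrs), 1.8); expect_lte(mean(hrs), 2.2)

  expect_error(stratifiedCox(tme, rep(0L, n), grp, NULL), "no events")
  expect_error(stratifiedCox(tme, ev, factor(rep("low", n)), NULL),
               "empty")
})

test_that("stratified Cox HR is rank-based in time within strata", {
  set.seed(31)
  n <- 100
  tme <- rexp(n); ev <- rbinom(n, 1, 0.6)
  grp <- factor(sample(c("low", "high"), n, TRUE),
                levels = c("low", "high"))
  st <- sample(1:3, n, TRUE)
  a <- stratifiedCox(tme, ev, grp, st)
  # strictly monotone transform of time within each stratum
  tme2 <- tme
  for (s in 1:3) tme2[st == s] <- exp(tme[st == s]) + s
  b <- stratifiedCox(tme2, ev, grp, st)
  expect_equal(a$hazard_ratio, b$hazard_ratio, tolerance = 1e-8)
})

test_that("omnibus interaction test: null uniformity, crossing-effect power, zero case", {
  ps <- vapply(1:150, function(s) {
    coh <- simulateCohort(CohortSimParam(nPatients = 400, nGenes = 1,
                                         nSubtypes = 4L,
                                         biomarkerGene = 1L,
                                         biomarkerLogHR = 0),
                          seed = 7000 + s)
    clin <- clinicalData(coh)
    x <- SummarizedExperiment::assay(coh, "exprs")[1, ]
    grp <- factor(ifelse(x > median(x), "high", "low"),
                  levels = c("low", "high"))
    omnibusInteractionTest(clin$time, clin$event, grp,
                           clin$subtype)$p_value
  }, numeric(1))
  se <- sqrt(0.05 * 0.95 / 150)
  expect_lte(mean(ps < 0.05), 0.05 + 3 * se)
  expect_lt(max(abs(sort(ps) - (1:150) / 150)), 0.12)

  # crossing effects: harmful in one subtype, protective in another,
  # pooled marginal effect ~ 0 -- the interaction test must be powered
  power <- vapply(1:40, function(s) {
    set.seed(7500 + s)
    n <- 1000
    sub <- factor(sample(c("A", "B"), n, TRUE))
    grp <- factor(sample(c("low", "high"), n, TRUE),
                  levels = c("low", "high"))
    lhr <- ifelse(sub == "A", 0.7, -0.7) * (grp == "high")
    tme <- rexp(n, rate = 0.1 * exp(lhr))
    cens <- rexp(n, 0.05)
    ev <- as.integer(tme <= cens)
    omnibusInteractionTest(pmin(tme, cens), ev, grp, sub)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(power), 0.8)

  # no interaction, huge n: LRT statistic near zero expectation scale
  set.seed(8)
  n <- 4000
  sub <- factor(sample(c("A", "B"), n, TRUE))
  grp <- factor(rep(c("low", "high"), n / 2), levels = c("low", "high"))
  tme <- rexp(n, 0.1); ev <- rep(1L, n)
  res <- omnibusInteractionTest(tme, ev, grp, sub)
  expect_lt(res$statistic, 12)  # ~ chi-square(2) scale, not a real effect
  expect_equal(res$df, 2L)
})

test_that("G-rho test equals survdiff and has the stated exact properties", {
  # rho = 0: equals an independently coded stratified log-rank
  set.seed(50)
  for (i in 1:100) {
    inst <- makeSurvivalInstance(n = sample(20:50, 1),
                                 nStrata = sample(1:3, 1))
    if (sum(inst$event) == 0 || length(unique(inst$group)) < 2) next
    mine <- grhoTest(inst$time, inst$event, inst$group, inst$strat,
                     rho = 0)
    oracle <- bruteStratLogRank(inst$time, inst$event,
                                inst$group == "high", inst$strat)
    expect_lt(abs(mine$statistic - oracle), 1e-8)
  }

  # rho = 1 agrees with survival::survdiff (independent implementation)
  set.seed(51)
  for (i in 1:30) {
    inst <- makeSurvivalInstance(n = 40, nStrata = 2)
    mine <- grhoTest(inst$time, inst$event, inst$group, inst$strat,
                     rho = 1)
    sd_ <- survival::survdiff(
      survival::Surv(inst$time, inst$event) ~ inst$group +
        survival::strata(inst$strat), rho = 1)
    expect_lt(abs(mine$statistic - sd_$chisq), 1e-8)
  }

  # perfectly balanced duplicated groups: statistic exactly 0
  set.seed(52)
  tme <- rexp(30); ev <- rbinom(30, 1, 0.7)
  time2 <- c(tme, tme); ev2 <- c(ev, ev)
  grp2 <- factor(rep(c("low", "high"), each = 30),
                 levels = c("low", "high"))
  expect_equal(grhoTest(time2, ev2, grp2, NULL, rho = 1)$statistic, 0)

  expect_error(grhoTest(tme, ev, factor(rep("low", 30)), NULL), "two")
  expect_error(grhoTest(tme, ev, factor(rep(c("low", "high"), 15),
                                        levels = c("low", "high")),
                        NULL, rho = -1), "nonnegative")
})

test_that("rho = 1 upweights early differences relative to the log-rank", {
  wins <- vapply(1:30, function(s) {
    set.seed(9000 + s)
    n <- 150
    grp <- factor(rep(c("low", "high"), each = n / 2),
                  levels = c("low", "high"))
    # early separation, late convergence: excess early hazard in one arm
    tme <- c(rexp(n / 2, 0.05),
             ifelse(runif(n / 2) < 0.35, rexp(n / 2, 0.6),
                    rexp(n / 2, 0.05)))
    cens <- runif(n, 15, 40)
    ev <- as.integer(tme <= cens)
    tt <- pmin(tme, cens)
    p1 <- grhoTest(tt, ev, grp, NULL, rho = 1)$p_value
    p0 <- grhoTest(tt, ev, grp, NULL, rho = 0)$p_value
    p1 < p0
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})

test_that("G-rho type-I error is controlled under the global null", {
  ps <- vapply(1:150, function(s) {
    set.seed(9500 + s)
    n <- 200
    grp <- factor(sample(c("low", "high"), n, TRUE),
                  levels = c("low", "high"))
    st <- sample(1:4, n, TRUE)
    tme <- rexp(n, 0.1); cens <- rexp(n, 0.05)
    ev <- as.integer(tme <= cens)
    grhoTest(pmin(tme, cens), ev, grp, st, rho = 1)$p_value
  }, numeric(1))
  se <- sqrt(0.05 * 0.95 / 150)
  expect_lte(mean(ps < 0.05), 0.05 + 3 * se)
})

test_that("panel adjustment flags genes within each test family", {
  res <- data.frame(gene = paste0("g", 1:46),
                    omnibus_p = c(1e-6, runif(45)),
                    grho_p = runif(46))
  adj <- adjustGenePanel(res)
  expect_true(all(adj$omnibus_p_adj >= adj$omnibus_p))
  expect_true(adj$sig_omnibus_05[1])
  one <- adjustGenePanel(data.frame(gene = "g", omnibus_p = 0.2,
                                    grho_p = 1))
  expect_equal(one$omnibus_p_adj, 0.2)
  flat <- adjustGenePanel(data.frame(gene = paste0("g", 1:5),
                                     omnibus_p = rep(1, 5),
                                     grho_p = rep(1, 5)))
  expect_true(all(flat$omnibus_p_adj == 1) && !any(flat$sig_grho_10))
  expect_error(adjustGenePanel(data.frame(gene = c("a", "a"),
                                          omnibus_p = c(0.1, 0.2),
                                          grho_p = c(0.1, 0.2))),
               "one p-value per gene")
})

test_that("the per-gene survival pipeline runs end to end", {
  coh <- simulateCohort(CohortSimParam(nPatients = 800, nGenes = 4,
                                       biomarkerGene = 2L,
                                       biomarkerCutQuantile = 0.5,
                                       biomarkerLogHR = 0.8), seed = 17)
  panel <- geneSurvivalAnalysis(coh)
  expect_equal(nrow(panel), 4L)
  expect_true(all(panel$hazard_ratio > 0))
  expect_true(all(panel$ci_low <= panel$hazard_ratio &
                    panel$hazard_ratio <= panel$ci_high))
  expect_true(all(panel$omnibus_p_adj >= panel$omnibus_p))
  # the planted biomarker is the standout gene
  expect_equal(panel$gene[which.min(panel$grho_p)], "gene002")
  expect_gt(panel$hazard_ratio[panel$gene == "gene002"], 1.5)
})
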