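test_that("quantile normalization follows the rank-mean contract", {
  m <- cbind(p1 = c(1, 2, 3), p2 = c(4, 5, 6))
  out <- quantileNormalize(m)
  expect_equal(unname(out[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, 2]), c(2.5, 3.5, 4.5))

  # identical plates are unchanged; a single plate is its own reference
  same <- cbind(a = c(3, 1, 7), b = c(3, 1, 7))
  expect_equal(quantileNormalize(same), same)
  one <- cbind(a = c(9, 2, 5))
  expect_equal(quantileNormalize(one), one)

  # after normalization all sorted columns are identical (exact, in the
  # absence of ties)
  set.seed(1)
  big <- matrix(sample(seq_len(10000), 96 * 6), ncol = 6)
  nb <- quantileNormalize(big)
  ref <- sort(nb[, 1])
  for (j in 2:6) expect_equal(sort(nb[, j]), ref)
  # within-plate rank order preserved
  for (j in 1:6) expect_equal(order(nb[, j]), order(big[, j]))

  # tied input values share the mean of their tied reference values
  tied <- quantileNormalize(cbind(c(1, 2, 2), c(10, 20, 30)))
  expect_equal(unname(tied[, 1]), c(5.5, 13.5, 13.5))

  expect_error(quantileNormalize(cbind(c(1, NA), c(2, 3))), "missing")
})

test_that("well-position surface estimation recovers planted edge effects", {
  # spatially flat control plates -> all adjustments 1
  grid <- expand.grid(row = 0:7, col = 0:11)
  flat <- do.call(rbind, lapply(1:2, function(p)
    data.frame(plate_id = paste0("ctl", p), processing_order = p,
               row = grid$row, col = grid$col, condition = "carrier",
               count = 500)))
  surfFlat <- estimateWellEffects(flat)
  expect_equal(surfFlat$adjustment, rep(1, nrow(surfFlat)))

  # planted quadratic bowl: recovered surface tracks the truth
  p <- ScreenSimParam(nPools = 1, wellEffectAmplitude = 0.4,
                      plateSigma = 0, driftRate = 0, dispersion = 0.01,
                      effectDistribution = function(n) rep(1, n),
                      controlLayout = data.frame(row = 0L, col = 0L,
                                                 condition = "carrier"),
                      nReplicates = 6L, baselineCount = 2000)
  scr <- simulateScreen(p, seed = 21)
  w <- wellData(scr)
  w$condition <- "carrier"   # treat as all-control plates
  surf <- estimateWellEffects(w)
  u <- function(i, n) 2 * (i / (n - 1)) - 1
  truthSurf <- u(surf$row, 8)^2 + u(surf$col, 12)^2
  expect_gte(cor(surf$adjustment, truthSurf, method = "spearman"), 0.9)
  # multiplicative adjustments have geometric mean 1
  expect_equal(mean(log(surf$adjustment)), 0, tolerance = 1e-12)

  # two noisy all-control plates: surface equals that of their average
  set.seed(3)
  n1 <- flat; n1$count <- rpois(nrow(n1), 500)
  s2 <- estimateWellEffects(n1)
  avg <- flat[flat$plate_id == "ctl1", ]
  avg$count <- exp((log(n1$count[n1$plate_id == "ctl1"] + 0.5) +
                    log(n1$count[n1$plate_id == "ctl2"] + 0.5)) / 2) - 0.5
  s1 <- estimateWellEffects(avg)
  expect_equal(s2$adjustment, s1$adjustment, tolerance = 1e-10)

  expect_error(estimateWellEffects(wellData(scr)[0, ]), "all-control")
})

test_that("mixed-model effect estimation: null, planted and lethal cases", {
  eff <- function(n) { e <- rep(1, n); e[1] <- 0.25; e }
  p <- ScreenSimParam(nPools = 20, effectDistribution = eff)
  scr <- quantileNormalize(simulateScreen(p, seed = 7))
  res <- estimateEffects(scr)

  planted <- res$relative_effect[res$pool_id == "pool00001"]
  expect_gte(planted, 0.18); expect_lte(planted, 0.33)
  expect_lt(res$p_adj[res$pool_id == "pool00001"], 0.05)

  nulls <- res[!res$is_control & res$pool_id != "pool00001", ]
  expect_lt(abs(mean(nulls$relative_effect) - 1), 0.1)

  lethal <- res$relative_effect[res$pool_id == "positive-lethal"]
  expect_lt(lethal, 0.05)

  # ranks are a permutation 1..n over pools
  expect_setequal(res$rank[!res$is_control], seq_len(sum(!res$is_control)))
  expect_error(estimateEffects(wellData(scr), controlCondition = "nope"),
               "absent")
})

test_that("relative effects absorb a multiplicative plate artefact", {
  # rescaling one plate changes ranks nowhere, so quantile normalization
  # restores the plate up to the (slightly shifted) reference quantiles;
  # relative effects move by less than the simulation noise floor
  p <- ScreenSimParam(nPools = 10, nReplicates = 6L,
                      effectDistribution = function(n)
                        seq(0.2, 1, length.out = n))
  scr <- simulateScreen(p, seed = 13)
  w2 <- wellData(scr)
  w2$count[w2$plate_id == w2$plate_id[1]] <-
    w2$count[w2$plate_id == w2$plate_id[1]] * 3
  scaled <- methods::new("ScreenExperiment", wells = w2,
                         truth = truthTable(scr))
  r1 <- estimateEffects(quantileNormalize(scr))
  r2 <- estimateEffects(quantileNormalize(scaled))
  expect_lt(max(abs(r1$relative_effect - r2$relative_effect)), 0.03)
  expect_equal(order(r1$relative_effect), order(r2$relative_effect))
})

test_that("estimation error shrinks with more replicate plates", {
  eff <- function(n) seq(0.1, 1.2, length.out = n)
  mae <- vapply(c(2L, 8L), function(reps) {
    errs <- vapply(1:3, function(s) {
      p <- ScreenSimParam(nPools = 15, nReplicates = reps,
                          effectDistribution = eff, dispersion = 0.1)
      scr <- simulateScreen(p, seed = 30 + s)
      res <- estimateEffects(quantileNormalize(scr))
      tr <- truthTable(scr)
      mean(abs(res$relative_effect[match(tr$pool_id, res$pool_id)] -
                 tr$true_effect))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_lt(mae[2], mae[1])
})

test_that("BH adjustment matches the step-up rule", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.2, 0.8)
  expect_true(all(bhAdjust(p) >= p))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("hit calling applies both criteria and ranks smallest first", {
  eff <- data.frame(pool_id = c("a", "b", "c", "d"),
                    relative_effect = c(0.10, 0.10, 0.80, 0.20),
                    p_adj = c(0.001, 0.20, 0.001, 0.04))
  hits <- callHits(eff)
  expect_equal(hits$is_hit[match(c("a", "b", "c", "d"), hits$pool_id)],
               c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(hits$pool_id, c("a", "b", "d", "c"))  # ties by pool id
  expect_equal(hits$rank, 1:4)
  # hit set identical whether computed before or after ranking
  expect_setequal(hits$pool_id[hits$is_hit],
                  eff$pool_id[eff$relative_effect <= 0.25 &
                                eff$p_adj < 0.05])
  expect_error(callHits(eff[0, ]), "empty")
})

test_that("secondary-screen reproducibility follows the one-or-both rule", {
  prim <- data.frame(pool_id = c("a", "b", "c", "d"))
  l9 <- data.frame(pool_id = c("a", "b", "c"),
                   relative_effect = c(0.1, 0.6, 0.2),
                   p_adj = c(0.01, 0.01, 0.30))
  e11 <- data.frame(pool_id = c("a", "b"),
                    relative_effect = c(0.9, 0.15),
                    p_adj = c(0.9, 0.02))
  rep_ <- secondaryReproducibility(prim, l9, e11)
  expect_equal(rep_$reproducible, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(rep_$untested, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(attr(rep_, "reproducible_fraction"), 2 / 3)
  withDen <- secondaryReproducibility(prim, l9, e11, countUntested = TRUE)
  expect_equal(attr(withDen, "reproducible_fraction"), 0.5)
})

test_that("reproducibility holds for true strong effects across regenerated screens", {
  eff <- function(n) c(rep(0.1, 5), rep(1, n - 5))
  p <- ScreenSimParam(nPools = 15, effectDistribution = eff)
  prim <- callHits(estimateEffects(quantileNormalize(
    simulateScreen(p, seed = 41))))
  sec1 <- callHits(estimateEffects(quantileNormalize(
    simulateScreen(p, seed = 42))))
  sec2 <- callHits(estimateEffects(quantileNormalize(
    simulateScreen(p, seed = 43))))
  rep_ <- secondaryReproducibility(prim[prim$is_hit, ], sec1, sec2)
  expect_gte(mean(rep_$reproducible), 0.9)
})

test_that("screen accounting reproduces funnel percentages", {
  acc <- screenAccounting(c(library = 21121, primary_hits = 2337))
  expect_equal(acc$pct_of_previous[2], 11.1)
  acc2 <- screenAccounting(c(retested = 388, reproducible = 140,
                             confirmed = 47))
  expect_equal(acc2$pct_of_previous[3], 33.6)
  expect_equal(stagePercent(0, 10), 0)
  expect_error(stagePercent(1, 0), "denominator")
  expect_error(screenAccounting(c(a = 5, b = 9)), "monotone")
})
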