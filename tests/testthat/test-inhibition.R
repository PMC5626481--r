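test_that("history integration has the exponential-kernel shape", {
  p <- InhibitionParams(deltaTc = 0.002, tauI = 0.003)
  fr <- 2000
  expect_equal(integrateHistory(numeric(100), p, fr), numeric(100))

  # impulse: peak at t0 + deltaTc, decay by e over tauI
  x <- numeric(200); x[50] <- 1
  ai <- integrateHistory(x, p, fr)
  shift <- round(p@deltaTc * fr)
  expect_equal(which.max(ai), 50 + shift)
  nTau <- round(p@tauI * fr)
  expect_equal(ai[50 + shift + nTau] / ai[50 + shift], exp(-1),
               tolerance = 1e-10)

  # constant rate converges to the rate itself (unit-area kernel)
  ai2 <- integrateHistory(rep(120, 500), p, fr)
  expect_equal(tail(ai2, 1), 120, tolerance = 1e-6)
  expect_true(all(ai2 >= 0))
})

test_that("sigmoid activation hits its closed-form values", {
  p <- InhibitionParams(I0 = 200, O = 10, slopeS = 5)
  expect_equal(sigmoidInhibitionRate(10, p), 100)
  expect_equal(sigmoidInhibitionRate(1e6, p), 200, tolerance = 1e-9)
  expect_equal(sigmoidInhibitionRate(11, p), 200 / (1 + exp(-5)),
               tolerance = 1e-12)
  si <- sigmoidInhibitionRate(seq(-50, 50, by = 1), p)
  expect_true(all(si >= 0 & si <= 200))
  expect_true(all(diff(si) >= 0))  # monotone in AI
})

test_that("spontaneous failures are Bernoulli relabelings", {
  ev <- makeUnitEvents(list(list(times = sort(runif(10000, 0, 100)))), 100)
  same <- applySpontaneousFailures(ev, 0, seed = 1)
  expect_identical(eventTable(same), eventTable(ev))
  all <- applySpontaneousFailures(ev, 1, seed = 1)
  expect_true(all(eventTable(all)$label == "failure"))
  out <- applySpontaneousFailures(ev, 0.36, seed = 2)
  nf <- sum(eventTable(out)$label == "failure")
  expect_lt(abs(nf - 3600), 3 * sqrt(10000 * 0.36 * 0.64))
  # times never move
  expect_identical(eventTable(out)$time, eventTable(ev)$time)
})

test_that("subtractive deletion relabels without moving events", {
  set.seed(6)
  trials <- lapply(1:5, function(j) list(times = sort(runif(300, 0, 3))))
  ev <- makeUnitEvents(trials, 3)
  fr <- 2000
  nBins <- floor(3 * fr)
  # SI far above the input rate deletes everything
  out <- applySubtractiveInhibition(ev, 1, rep(1e5, nBins), fr, seed = 1)
  expect_true(all(eventTable(out)$label == "failure"))
  expect_identical(eventTable(out)$time, eventTable(ev)$time)
  # I0 = 0 (SI = 0) touches nothing
  out0 <- applySubtractiveInhibition(ev, 1, numeric(nBins), fr, seed = 1)
  expect_identical(eventTable(out0), eventTable(ev))
  expect_error(applySubtractiveInhibition(ev, 1, numeric(10), fr), "bins")
})

test_that("within-bin deletion is uniform across trials (hypergeometric)", {
  # 3 events in one bin across trials, nDelete = 2: each event deleted
  # with frequency 2/3 over seeds
  fr <- 1000
  ev <- makeUnitEvents(list(list(times = 0.0101), list(times = 0.0105),
                            list(times = 0.0108)), 0.05)
  nBins <- floor(0.05 * fr)
  si <- numeric(nBins)
  si[11] <- 2 / 3 * fr  # nDelete = si * nTrials / fr = 2 exactly
  nSeeds <- 600
  delCount <- numeric(3)
  for (s in seq_len(nSeeds)) {
    out <- applySubtractiveInhibition(ev, 1, si, fr, seed = s)
    delCount <- delCount + (eventTable(out)$label == "failure")
  }
  p <- delCount / nSeeds
  se <- sqrt((2 / 3) * (1 / 3) / nSeeds)
  expect_true(all(abs(p - 2 / 3) < 3.5 * se))
})

test_that("stronger inhibition never increases expected SBC counts", {
  set.seed(12)
  trials <- lapply(1:4, function(j) list(times = sort(runif(150, 0, 1))))
  ev <- makeUnitEvents(trials, 1)
  fr <- 2000
  counts <- SummarizedExperiment::assay(binEvents(ev, "anf", fr))
  psth <- counts[1, ] * fr / 4
  means <- vapply(c(0, 40, 120, 300), function(I0) {
    p <- InhibitionParams(I0 = I0, O = 100)
    ai <- integrateHistory(psth, p, fr)
    si <- sigmoidInhibitionRate(ai, p)
    mean(vapply(1:50, function(s) {
      out <- applySubtractiveInhibition(ev, 1, si, fr, seed = s)
      sum(eventTable(out)$label == "success")
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) <= 0))
})

test_that("grid fit recovers a degenerate target with no inhibition", {
  set.seed(21)
  trials <- lapply(1:6, function(j) list(times = sort(runif(400, 0, 4))))
  ev <- makeUnitEvents(trials, 4)
  fit <- fitCellParams(ev, 1, targetFailSpont = 0.3,
                       targetFailDriven = 0.3,
                       spontWindow = c(0, 2), drivenWindow = c(2, 4),
                       seed = 2)
  expect_equal(fit$params@I0, 0)
  expect_lt(abs(fit$achievedDriven - 0.3), 0.03)
})

test_that("grid fit is self-consistent on a unit with known parameters", {
  fx <- defaultStimulusFixture()
  u <- defaultUnits(3, seed = 5)[2]
  anf <- simulateANFPopulation(fx$specBand, u, nTrials = 10, seed = 31,
                               normWindow = fx$drivenFrames)
  truth <- InhibitionParams(I0 = 150, O = 100, pSpontFail = 0.3)
  sim <- simulateSBC(anf, truth, seed = 32)
  targetDriven <- failureFraction(sim, fx$drivenWindow)
  fit <- fitCellParams(anf, 1, targetFailSpont = 0.3,
                       targetFailDriven = targetDriven,
                       spontWindow = fx$spontWindow,
                       drivenWindow = fx$drivenWindow, seed = 33)
  expect_lt(abs(fit$achievedDriven - targetDriven), 0.02)
  # applying the fitted parameters reproduces the fraction on fresh draws
  applied <- simulateSBC(anf, fit$params, seed = 34)
  expect_lt(abs(failureFraction(applied, fx$drivenWindow) - targetDriven),
            0.03)
})

test_that("parameter validity is enforced", {
  expect_error(InhibitionParams(tauI = 0), "tauI")
  expect_error(InhibitionParams(I0 = -5), "I0")
  expect_error(InhibitionParams(pSpontFail = 1.5), "pSpontFail")
  ev <- makeUnitEvents(list(list(times = 0.1), list(times = 0.2)), 1)
  expect_error(fitCellParams(ev, 1, -0.1, 0.5, c(0, 0.5), c(0.5, 1)),
               "targets")
  expect_error(fitCellParams(ev, 1, 0.3, 0.5, c(0, 0.5), c(0.5, 1),
                             gridI0 = numeric(0)), "grid")
})
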