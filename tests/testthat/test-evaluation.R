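test_that("correlation decomposition is exact on identical inputs", {
  set.seed(1)
  M <- matrix(rnorm(200 * 5), 200, 5)
  q <- correlationDecomposition(M, M)
  expect_equal(q$overall, 1)
  expect_equal(q$temporal, 1)
  expect_equal(q$spectral, 1)
  # location invariance
  q2 <- correlationDecomposition(M, M + 7)
  expect_equal(q2$overall, 1)
  expect_equal(q2$temporal, 1)
  expect_equal(q2$spectral, 1)
  expect_error(correlationDecomposition(M, M[, 1:3]), "match")
})

test_that("decomposition handles flattened bands like the toy case", {
  # hand-built 3x4 (time x freq) example: replace each band's time course
  # by its mean; temporal correlation becomes undefined per band (excluded),
  # spectral correlation equals that of the band-mean profile
  real <- matrix(c(1, 2, 3,
                   2, 4, 6,
                   1, 1, 4,
                   5, 3, 1), 3, 4)
  flat <- matrix(rep(colMeans(real), each = 3), 3, 4)
  q <- correlationDecomposition(real, flat)
  expect_true(is.nan(q$temporal))  # every band constant in the recon
  # independent hand computation of the spectral part
  expected <- mean(vapply(1:3, function(t)
    cor(real[t, ], colMeans(real)), numeric(1)))
  expect_equal(q$spectral, expected)
})

test_that("CLD columns are conditional densities", {
  set.seed(2)
  real <- matrix(rnorm(500 * 4, sd = 6), 500, 4)
  cld <- conditionalLevelDensity(real, real, binWidth = 1)
  cs <- colSums(cld@pcond)
  pop <- setdiff(seq_along(cs), cld@emptyColumns)
  expect_true(all(abs(cs[pop] - 1) < 1e-9))
  # identical recon: all mass on the diagonal
  expect_true(all(which(cld@pcond > 0, arr.ind = TRUE)[, 1] ==
                  which(cld@pcond > 0, arr.ind = TRUE)[, 2]))
  # affine compression: slope of the mass line is 0.5
  cld2 <- conditionalLevelDensity(real, 0.5 * real, binWidth = 1)
  sl <- suppressWarnings(cldSlope(c(real), c(0.5 * real)))
  expect_equal(sl$slope, 0.5, tolerance = 1e-10)
  expect_warning(conditionalLevelDensity(matrix(1, 5, 2), matrix(1, 5, 2)),
                 "constant")
})

test_that("CLD differences cancel column-wise and antisymmetrize", {
  set.seed(3)
  real <- matrix(rnorm(400, sd = 5), 100, 4)
  ed <- seq(-40, 40, by = 2)
  a <- conditionalLevelDensity(real, real + rnorm(400), edges = ed)
  b <- conditionalLevelDensity(real, 0.7 * real, edges = ed)
  expect_true(all(abs(cldDifference(a, a)) < 1e-12))
  d <- cldDifference(a, b)
  expect_true(all(abs(colSums(d)) < 1e-9))
  expect_equal(d, -cldDifference(b, a))
  bad <- conditionalLevelDensity(real, real, binWidth = 2)
  expect_error(cldDifference(a, bad), "edges")
})

test_that("regression slope recovers affine maps", {
  set.seed(4)
  x <- rnorm(2000, sd = 8)
  fit <- cldSlope(x, 0.6 * x + rnorm(2000, sd = 1e-4))
  expect_equal(fit$slope, 0.6, tolerance = 1e-3)
  expect_true(fit$ci[1] <= 0.6 && 0.6 <= fit$ci[2])
  same <- suppressWarnings(cldSlope(x, x))
  expect_equal(same$slope, 1)
  indep <- cldSlope(x, rnorm(2000))
  expect_lt(abs(indep$slope), 0.05)
  expect_error(cldSlope(rep(1, 10), rnorm(10)), "variance")
})

test_that("autocorrelation width matches the Gaussian closed form", {
  fr <- 2000
  tt <- seq(-0.5, 0.5, by = 1 / fr)
  sigma <- 0.005
  bump <- exp(-tt^2 / (2 * sigma^2))
  M <- matrix(rep(bump, 3), ncol = 3)
  w <- autocorrWidth(M, relativeHeights = 0.5, maxLag = 0.1, frameRate = fr)
  # autocorrelation of a Gaussian(sigma) is Gaussian(sigma*sqrt(2)):
  # full width at half max = 2 * sigma * sqrt(2) * sqrt(2 log 2)
  expected <- 2 * sigma * sqrt(2) * sqrt(2 * log(2))
  expect_equal(unname(w), expected, tolerance = 0.05)
})

test_that("autocorrelation width shrinks for noise and with height", {
  set.seed(5)
  M <- matrix(rnorm(4000 * 3), 4000, 3)
  w <- autocorrWidth(M, relativeHeights = c(0.3, 0.6), frameRate = 2000)
  expect_true(all(w <= 2 * 2 / 2000))  # delta-like: under 2 lag samples

  fr <- 2000
  tt <- seq(0, 2, by = 1 / fr)
  slow <- matrix(sin(2 * pi * 3 * tt) + 0.2 * sin(2 * pi * 40 * tt))
  ws <- autocorrWidth(slow, relativeHeights = seq(0.2, 0.8, by = 0.2),
                      frameRate = fr)
  expect_true(all(diff(ws) <= 1e-12))  # nonincreasing in height
})

test_that("modulation spectrum finds line components and obeys Parseval", {
  fr <- 2000
  tt <- seq(0, 4 - 1 / fr, by = 1 / fr)
  M <- matrix(sin(2 * pi * 120 * tt), ncol = 1)
  ms <- modulationSpectrum(M, band = c(100, 150), nSegments = 4,
                           frameRate = fr)
  expect_equal(ms$rate[which.max(ms$psd)], 120, tolerance = 1)
  total <- sum(ms$psd) * (ms$rate[2] - ms$rate[1])
  expect_gt(ms$bandPower / total, 0.95)

  flat <- modulationSpectrum(matrix(5, 4000, 2), frameRate = fr)
  expect_true(all(flat$psd == 0))

  # Parseval: with a single segment the PSD integral equals the variance
  set.seed(6)
  x <- matrix(rnorm(4096), ncol = 1)
  p1 <- modulationSpectrum(x, nSegments = 1, frameRate = fr)
  integ <- sum(p1$psd) * (p1$rate[2] - p1$rate[1])
  expect_equal(integ, mean((x - mean(x))^2), tolerance = 0.01)

  expect_error(modulationSpectrum(M, band = c(100, 5000), frameRate = fr),
               "Nyquist")
})

test_that("spectral correlation is 1 at zero separation and 0 for noise", {
  set.seed(7)
  shared <- rnorm(600)
  M <- matrix(rep(shared, 5), 600, 5) + matrix(rnorm(3000, sd = 1e-8), 600)
  sc <- spectralCorrelation(M)
  expect_equal(sc$correlation[sc$separation == 0], 1)
  expect_true(all(sc$correlation[-c(1, nrow(sc))] > 0.99))

  noise <- matrix(rnorm(600 * 12), 600, 12)
  scN <- spectralCorrelation(noise)
  expect_lt(max(abs(scN$correlation[scN$separation > 0 &
                                    scN$separation < 7]), na.rm = TRUE),
            0.05)
  expect_error(spectralCorrelation(matrix(1, 5, 1)), "2 frequency bands")
})

test_that("Cohen's U1 counts range nonoverlap", {
  expect_equal(cohensU1(c(1, 2, 3), c(3, 4, 5)), 4 / 6)
  expect_equal(cohensU1(1:5, 10:14), 1)
  expect_equal(cohensU1(1:5, 1:5), 0)
  set.seed(8)
  for (i in 1:20) {
    a <- rnorm(sample(2:30, 1)); b <- rnorm(sample(2:30, 1), mean = runif(1, -2, 2))
    u <- cohensU1(a, b)
    expect_gte(u, 0); expect_lte(u, 1)
    expect_equal(u, cohensU1(b, a))
  }
  expect_error(cohensU1(numeric(0), 1), "nonempty")
})
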