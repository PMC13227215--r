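test_that("the low-count filter applies the 50-read total threshold", {
  k <- rbind(g_at_49 = c(24L, 25L, 0L), g_at_50 = c(25L, 25L, 0L),
             g_big = c(100L, 5L, 8L))
  colnames(k) <- c("s1", "s2", "s3")
  x <- NutriSet(k)
  kept <- filterLowCounts(x)          # default minTotal = 50
  expect_identical(rownames(kept), c("g_at_50", "g_big"))
  expect_identical(rownames(filterLowCounts(x, 0)), rownames(k))
  expect_warning(filterLowCounts(x, 1000), "removed")
})

test_that("filtering a random matrix equals a brute-force row-sum scan", {
  set.seed(7)
  k <- matrix(rpois(600, 9), 100, 6,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%d", 1:6)))
  x <- NutriSet(k)
  expect_identical(rownames(filterLowCounts(x, 50)),
                   rownames(k)[sapply(seq_len(nrow(k)), function(i)
                     sum(k[i, ]) >= 50)])
})

test_that("size factors are symmetric, scale-equivariant and geomean 1", {
  k <- matrix(rep(c(10L, 40L, 200L), 4), 3, 4,
              dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
  expect_equal(unname(estimateSizeFactors(NutriSet(k))), rep(1, 4))
  k2 <- k; k2[, 2] <- k2[, 2] * 2L
  s <- estimateSizeFactors(NutriSet(k2))
  expect_equal(unname(s[2] / s[1]), 2)
  expect_equal(exp(mean(log(s))), 1, tolerance = 1e-6)
})

test_that("size factors match the brute-force median-of-ratios oracle", {
  set.seed(11)
  k <- matrix(rnbinom(400, mu = 60, size = 5) + 1L, 50, 8,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:8)))
  expect_equal(unname(estimateSizeFactors(NutriSet(k))),
               oracleSizeFactors(k), tolerance = 1e-10)
})

test_that("size factors agree with an independent median-of-ratios tool", {
  set.seed(12)
  k <- nbNullCounts(300, 10, seed = 12)
  mine <- estimateSizeFactors(NutriSet(k))
  ref <- DESeq2::estimateSizeFactorsForMatrix(k)
  # same factors up to the geometric-mean-1 rescale (and the plain- vs
  # log-space median, which differ only for even reference counts)
  expect_lt(diff(range(mine / ref)) / mean(mine / ref), 1e-3)
})

test_that("no all-positive reference gene raises the documented error", {
  k <- rbind(a = c(0L, 5L, 9L), b = c(3L, 0L, 2L), c = c(4L, 1L, 0L))
  colnames(k) <- paste0("s", 1:3)
  expect_error(estimateSizeFactors(NutriSet(k)), "pseudo-reference")
})

test_that("the dispersion trend recovers simulator parameters within 20%", {
  cfg <- simConfig(nGenes = 5000, nDietProgram = 10, nStockProgram = 10,
                   nWeightProgram = 10, dietLfc = 0, stockLfc = 0,
                   weightBeta = 0, viralStockLfc = 0, colonySd = 0,
                   dispersionA0 = 0.05, dispersionA1 = 2,
                   baselineLogmeanRange = c(0, 9), seed = 31)
  sim <- simulateExperiment(cfg)
  tr <- trendCoefs(fitDispersionTrend(sim))
  expect_lt(abs(tr["a0"] - 0.05) / 0.05, 0.20)
  expect_lt(abs(tr["a1"] - 2) / 2, 0.20)
})

test_that("Poisson data clamp a0 to the floor with a small slope", {
  set.seed(4)
  k <- matrix(rpois(5000 * 20, lambda = rep(2^runif(5000, 2, 8), 20)),
              5000, 20)
  dimnames(k) <- list(sprintf("g%04d", 1:5000), sprintf("s%02d", 1:20))
  x <- NutriSet(k)
  tr <- suppressWarnings(trendCoefs(fitDispersionTrend(x)))
  expect_lt(tr["a0"], 0.01)
  expect_lt(tr["a1"], 0.5)
})

test_that("constant-count genes are excluded from the trend without crashing", {
  set.seed(5)
  k <- nbNullCounts(200, 8, seed = 5)
  k[1:10, ] <- 7L   # zero-variance rows
  tr <- fitDispersionTrend(NutriSet(k))
  expect_s4_class(tr, "DispersionTrend")
  expect_gt(trendCoefs(tr)["a0"], 0)
})

test_that("the VST closed form is exact at u = 0 and asymptotically log2", {
  vstVal <- function(u, a0, a1)
    log2((1 + a1 + 2 * a0 * u + 2 * sqrt(a0 * u * (1 + a1 + a0 * u))) /
           (4 * a0))
  tr <- new("DispersionTrend", a0 = 0.1, a1 = 1)
  k0 <- matrix(0L, 1, 1, dimnames = list("g", "s"))
  v0 <- vstTransform(k0, s = c(s = 1), trend = tr)
  expect_equal(v0[1, 1], log2((1 + 1) / (4 * 0.1)))
  expect_equal(v0[1, 1], log2(5), tolerance = 1e-12)
  # u large: value - log2(u) converges (to zero, at rate ~1/u)
  gap4 <- vstVal(1e4, 0.1, 1) - log2(1e4)
  gap6 <- vstVal(1e6, 0.1, 1) - log2(1e6)
  expect_lt(abs(gap6), abs(gap4))
  expect_lt(abs(gap6), 1e-4)
})

test_that("the VST is strictly increasing in the normalized count", {
  tr <- new("DispersionTrend", a0 = 0.05, a1 = 2)
  u <- matrix(as.integer(c(0, 1, 2, 5, 17, 120, 3000, 54321)), 8, 1,
              dimnames = list(paste0("g", 1:8), "s"))
  v <- vstTransform(u, s = c(s = 1), trend = tr)
  expect_true(all(diff(v[, 1]) > 0))
  expect_true(all(is.finite(v)))
})

test_that("the VST flattens the mean-variance relationship where raw log fails", {
  set.seed(77)
  k <- nbNullCounts(4000, 30, logMeanRange = c(1.5, 10.1), seed = 77)
  x <- NutriSet(k)
  s <- estimateSizeFactors(x)
  v <- vstTransform(x, s)
  rawlog <- log2(sweep(k, 2, s, `/`) + 1)
  mu <- rowMeans(sweep(k, 2, s, `/`))
  bins <- cut(log10(mu), breaks = seq(0.5, 3, by = 0.5))  # 2.5 decades
  sdRatio <- function(m) {
    sds <- tapply(apply(m, 1, sd), bins, median)
    max(sds, na.rm = TRUE) / min(sds, na.rm = TRUE)
  }
  expect_lt(sdRatio(v), 2)
  expect_gt(sdRatio(rawlog), 2)
})

test_that("re-estimating a deepened sample's factor leaves its VST column put", {
  # doubling one library's counts is pure depth: against the fixed
  # gene-wise geometric reference its ratio (and factor) exactly doubles,
  # so normalized counts and the transform are unchanged
  set.seed(6)
  k <- nbNullCounts(500, 6, seed = 6)
  x <- NutriSet(k)
  s <- estimateSizeFactors(x)
  tr <- fitDispersionTrend(x, s)
  ref <- k[rowSums(k > 0) == ncol(k), ]
  geo <- exp(rowMeans(log(ref)))
  k2 <- k; k2[, 3] <- k2[, 3] * 2L
  s2 <- s
  s2[3] <- median(k2[rownames(ref), 3] / geo) /
    median(k[rownames(ref), 3] / geo) * s[3]
  v1 <- vstTransform(NutriSet(k), s, tr)
  v2 <- vstTransform(NutriSet(k2), s2, tr)
  expect_equal(v2[, 3], v1[, 3], tolerance = 1e-6)
})

test_that("log-cpm matches its closed form and an independent reimplementation", {
  # single zero count in a library of total 999,999 -> exactly -1
  k <- matrix(c(0L, 999999L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(logCPM(k)["a", 1], -1)
  set.seed(19)
  km <- matrix(rpois(80, 50), 20, 4,
               dimnames = list(paste0("g", 1:20), paste0("s", 1:4)))
  L <- colSums(km)
  direct <- log2(t(t(km + 0.5) / (L + 1)) * 1e6)
  expect_equal(unclass(logCPM(km)), direct, tolerance = 1e-12,
               ignore_attr = TRUE)
  # doubling a deep library barely moves values for large counts
  kb <- matrix(rpois(80, 2000), 20, 4,
               dimnames = dimnames(km))
  kb2 <- kb; kb2[, 2] <- kb2[, 2] * 2L
  expect_lt(max(abs(logCPM(kb2)[, 2] - logCPM(kb)[, 2])), 1e-3)
})
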