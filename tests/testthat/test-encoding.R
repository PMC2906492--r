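# Ensemble averaging, background statistics, the 58-element Z vector.

test_that("ensembleMean is the element-wise mean", {
  v1 <- setNames(rep(0, 29), featureSchema())
  v2 <- setNames(rep(2, 29), featureSchema())
  expect_equal(unname(ensembleMean(list(v1))), rep(0, 29))
  expect_equal(unname(ensembleMean(list(v1, v2))), rep(1, 29))

  set.seed(3)
  vs <- lapply(1:10, function(i) setNames(rnorm(29), featureSchema()))
  manual <- colMeans(do.call(rbind, vs))
  expect_equal(ensembleMean(vs), manual)
  expect_error(ensembleMean(list()), "empty")
})

test_that("background stats match direct enumeration on a 2-residue toy", {
  s <- generateToyStructure(2, seed = 21)
  bg <- backgroundStats(s, k_background = 1, seed = 5)
  expect_identical(bg@l, 2L)
  expect_identical(nrow(backgroundPool(bg)), 38L)  # l x 19 x k_background

  # independent oracle: rebuild each of the 38 mutants and pool by hand
  specs <- enumerateSaturation(s)
  pool <- t(vapply(seq_along(specs), function(i) {
    ens <- buildMutantEnsemble(s, specs[[i]], k = 1,
                               seed = ThermoShift:::childSeed(5, paste0("bg", i)))
    computeFeatures(structureModels(ens)[[1]])
  }, numeric(29)))
  expect_equal(unname(backgroundMean(bg)), unname(colMeans(pool)))
  sdPop <- apply(pool, 2, function(x) sqrt(mean((x - mean(x))^2)))
  expect_equal(unname(backgroundSd(bg)), unname(sdPop))

  bg2 <- backgroundStats(s, k_background = 1, seed = 5)
  expect_equal(backgroundPool(bg2), backgroundPool(bg))
})

test_that("a constant feature backend gives zero spread and U = constant", {
  s <- generateToyStructure(3, seed = 2)
  bg <- backgroundStats(s, k_background = 1, seed = 1,
                        backend = constantBackend(7))
  expect_equal(unname(backgroundMean(bg)), rep(7, 29))
  expect_equal(unname(backgroundSd(bg)), rep(0, 29))

  # sigma = 0 guard: v = 0; all-ties pool: midrank percentile 0.5
  z <- encodeMutant(setNames(rep(7, 29), featureSchema()), bg)
  expect_equal(unname(z[1:29]), rep(0, 29))
  expect_equal(unname(z[30:58]), rep(0.5, 29))
})

test_that("encodeMutant matches brute-force z-scores and midrank percentiles", {
  set.seed(77)
  pool <- matrix(rnorm(120 * 29), 120, 29)
  colnames(pool) <- featureSchema()
  bg <- new("BackgroundStats", U = colMeans(pool),
            S = apply(pool, 2, function(x) sqrt(mean((x - mean(x))^2))),
            pool = pool, l = 4L, protein_id = "p", seed = 1L)
  # include exact ties with the pool to exercise the midrank convention
  N <- setNames(rnorm(29), featureSchema())
  N[5] <- pool[17, 5]
  z <- encodeMutant(N, bg)
  expect_length(z, 58L)

  vBrute <- (N - colMeans(pool)) /
    apply(pool, 2, function(x) sqrt(mean((x - mean(x))^2)))
  yBrute <- vapply(1:29, function(j)
    (sum(pool[, j] < N[j]) + 0.5 * sum(pool[, j] == N[j])) / nrow(pool),
    numeric(1))
  expect_equal(unname(z[1:29]), unname(vBrute))
  expect_equal(unname(z[30:58]), yBrute)
  expect_true(all(z[30:58] >= 0 & z[30:58] <= 1))

  expect_error(encodeMutant(N[1:10], bg), "mismatch")
})

test_that("V is affine-invariant and Y is monotone-invariant per feature", {
  set.seed(12)
  pool <- matrix(rnorm(80 * 29), 80, 29)
  colnames(pool) <- featureSchema()
  mkbg <- function(p) new("BackgroundStats", U = colMeans(p),
                          S = apply(p, 2, function(x) sqrt(mean((x - mean(x))^2))),
                          pool = p, l = 3L, protein_id = "p", seed = 1L)
  N <- setNames(rnorm(29), featureSchema())
  z0 <- encodeMutant(N, mkbg(pool))

  # common affine rescale of feature 4 across mutant and background
  pool2 <- pool; pool2[, 4] <- 3 * pool[, 4] - 1
  N2 <- N; N2[4] <- 3 * N[4] - 1
  z1 <- encodeMutant(N2, mkbg(pool2))
  expect_equal(z1[4], z0[4], tolerance = 1e-9)

  # strictly monotone transform of feature 9 leaves its percentile unchanged
  pool3 <- pool; pool3[, 9] <- exp(pool[, 9])
  N3 <- N; N3[9] <- exp(N[9])
  z2 <- encodeMutant(N3, mkbg(pool3))
  expect_equal(z2[9 + 29], z0[9 + 29])

  # shifting a pool column shifts mu, leaves sigma unchanged
  pool4 <- pool; pool4[, 7] <- pool[, 7] + 2.5
  bg4 <- mkbg(pool4)
  expect_equal(bg4@U[7], mkbg(pool)@U[7] + 2.5, tolerance = 1e-9)
  expect_equal(bg4@S[7], mkbg(pool)@S[7], tolerance = 1e-9)
})

test_that("encodeDataset composes per-mutant encoding and caches backgrounds", {
  s <- generateToyStructure(3, seed = 31)
  specs <- enumerateSaturation(s)[c(1, 20, 40)]
  records <- data.frame(
    protein_id = "toy",
    mutation_spec = vapply(specs, formatMutationSpec, character(1)),
    ddg = c(1.2, -0.5, -2.0))
  ThermoShift:::backgroundCallCount(reset = TRUE)
  enc <- encodeDataset(records, list(toy = s), k = 2, seed = 9)
  expect_identical(nrow(enc), 3L)
  expect_identical(ThermoShift:::backgroundCallCount(), 1L)
  expect_identical(enc$n_sites, rep(1L, 3))

  # compositional check against individual encodeMutant calls
  bg <- backgroundStats(s, k_background = 1,
                        seed = ThermoShift:::childSeed(9, "toy"))
  ens <- buildMutantEnsemble(s, specs[[1]], k = 2,
                             seed = ThermoShift:::childSeed(9, "mut1"))
  N <- ensembleMean(lapply(structureModels(ens), computeFeatures))
  zManual <- encodeMutant(N, bg)
  zGot <- as.numeric(enc[1, paste0("z", 1:58)])
  expect_equal(zGot, unname(zManual))

  expect_error(encodeDataset(transform(records, protein_id = "nope"),
                             list(toy = s), k = 1, seed = 1), "nope")
  empty <- encodeDataset(records[0, ], list(toy = s), k = 1, seed = 1)
  expect_identical(nrow(empty), 0L)
})

test_that("encoded datasets round-trip through TSV", {
  d <- generateDataset(syntheticConfig(n_mutants = 40, seed = 2))$data
  p <- tempfile(fileext = ".tsv")
  writeEncodedDataset(d, p)
  d2 <- readEncodedDataset(p)
  expect_equal(d2$ddg, d$ddg)
  expect_equal(as.matrix(d2[, paste0("z", 1:58)]),
               as.matrix(d[, paste0("z", 1:58)]))
  expect_identical(d2$n_sites, d$n_sites)
})
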