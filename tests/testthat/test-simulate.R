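test_that("neutral draw count matches the closed-form Poisson mean", {
  # expected subclonal count: mu*L*(1/fmin - 1/fmax) = 150*(1/0.12-1/0.24)
  expected <- 5e-6 * 3e7 * (1 / 0.12 - 1 / 0.24)
  expect_equal(expected, 625)
  counts <- vapply(1:200, function(s)
    length(sampleNeutralVafs(muEff = 5e-6, L = 3e7, fMin = 0.12,
                             fMax = 0.24, clonalCount = 0L, seed = s)), 0L)
  se <- sqrt(expected / 200)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("neutral draws respect their support and the clonal level", {
  f <- sampleNeutralVafs(muEff = 5e-6, fMin = 0.12, fMax = 0.24,
                         clonalCount = 10L, seed = 3)
  sub <- f[f != 0.5]
  expect_true(all(sub >= 0.12 & sub <= 0.24))
  expect_equal(sum(f == 0.5), 10L)
  expect_length(sampleNeutralVafs(muEff = 5e-6, fMin = 0.2, fMax = 0.2,
                                  clonalCount = 0L, seed = 1), 0L)
  expect_error(sampleNeutralVafs(muEff = 5e-6, fMin = 0, seed = 1), "fMin")
})

test_that("empirical cumulative M(f) follows the 1/f model at grid points", {
  f <- sampleNeutralVafs(muEff = 5e-5, L = 3e7, fMin = 0.12, fMax = 0.24,
                         clonalCount = 0L, seed = 42)
  for (g in c(0.13, 0.15, 0.18, 0.21, 0.23)) {
    expected <- 5e-5 * 3e7 * (1 / g - 1 / 0.24)
    expect_lt(abs(sum(f >= g) - expected), 4 * sqrt(expected) + 1)
  }
})

test_that("subclone injection is the identity at k = 0 and exact at zero jitter", {
  f <- c(0.13, 0.2)
  expect_identical(injectSubclone(f, 0.18, 0L), f)
  expect_equal(injectSubclone(f, 0.18, 3L, jitterSd = 0),
               c(f, rep(0.18, 3)))
  out <- injectSubclone(f, 0.18, 50L, jitterSd = 0.01, seed = 1)
  expect_length(out, 52L)
  expect_error(injectSubclone(f, 0.7, 1L), "fS")
})

test_that("read observation reproduces the per-copy VAF model in expectation", {
  # 50% of cells, purity 0.7, triploid: expected VAF 0.1167
  rd <- observeReads(rep(0.5, 10000), purity = 0.7, localCn = 3,
                     depthMean = 125, seed = 1)
  v <- 0.5 * 0.7 / 3
  expect_equal(v, 0.1166667, tolerance = 1e-6)
  se <- sd(rd$alt / rd$depth) / sqrt(10000)
  expect_lt(abs(mean(rd$alt / rd$depth) - v), 3 * se)
  # heterozygous clonal diploid at purity 1: expected VAF 0.25
  rd2 <- observeReads(rep(0.5, 10000), purity = 1, localCn = 2,
                      depthMean = 125, seed = 2)
  se2 <- sd(rd2$alt / rd2$depth) / sqrt(10000)
  expect_lt(abs(mean(rd2$alt / rd2$depth) - 0.25), 3 * se2)
  expect_true(all(rd$depth >= 1))
})

test_that("a zero mixing weight silences the shared subclonal pool in that lesion", {
  cfg <- simulationConfig(seed = 21, mixing = c(dys = 1, scc = 0),
                          ffpeRate = 0, cnClass = 2)
  tab <- mutations(simulatePair(cfg))
  sh <- tab[tab$sim_pool == "shared_subclonal", ]
  expect_gt(nrow(sh), 0)
  expect_true(all(sh$scc_alt == 0L))
  expect_gt(sum(sh$dys_alt), 0)
})

test_that("simulated profiles realise the requested pair-relationship class", {
  evSets <- function(p) list(
    dys = regionsHit(callEvents(dysProfile(p))),
    scc = regionsHit(callEvents(sccProfile(p))))
  e2 <- evSets(simulatePair(simulationConfig(seed = 31, cnClass = 2)))
  expect_gt(length(e2$dys), 0)
  expect_setequal(e2$dys, e2$scc)
  e3 <- evSets(simulatePair(simulationConfig(seed = 32, cnClass = 3)))
  expect_true(all(e3$dys %in% e3$scc))
  expect_gt(length(setdiff(e3$scc, e3$dys)), 0)
  e4 <- evSets(simulatePair(simulationConfig(seed = 33, cnClass = 4)))
  expect_length(e4$dys, 0)
  expect_length(e4$scc, 0)
})

test_that("FFPE artifacts are low-VAF C>T calls private to one lesion", {
  tab <- mutations(simulatePair(simulationConfig(seed = 41, ffpeRate = 50)))
  art <- tab[grepl("^ffpe", tab$sim_pool), ]
  expect_gt(nrow(art), 10)
  expect_true(all(art$substitution_class == "C>T"))
  vafD <- art$dys_alt / art$dys_depth
  vafS <- art$scc_alt / art$scc_depth
  expect_true(all(pmax(vafD, vafS) <= 0.2)) # binomial spread above U(0,0.1]
  expect_true(all(art$dys_alt == 0 | art$scc_alt == 0))
})

test_that("cohort simulation is reproducible and validates through the readers", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfgs <- lapply(1:3, function(i)
    simulationConfig(seed = 50 + i, cnClass = i))
  simulateCohort(cfgs, d1)
  simulateCohort(cfgs, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  pairs <- loadCohort(file.path(d1, "metadata.tsv"),
                      file.path(d1, "segments.tsv"),
                      file.path(d1, "purity.tsv"), d1)
  expect_length(pairs, 3L)
  for (p in pairs) {
    expect_s4_class(p, "LesionPair")
    expect_true(validObject(p))
    expect_true(validObject(dysProfile(p)))
  }
  expect_error(simulateCohort(list(cfgs[[1]], cfgs[[1]]), d2), "duplicate")
})

test_that("a cohort of class-4 pairs is flat with zero genome altered", {
  pairs <- lapply(61:63, function(s)
    simulatePair(simulationConfig(seed = s, cnClass = 4)))
  for (p in pairs) {
    expect_equal(fractionGenomeAltered(callEvents(dysProfile(p))), 0)
    expect_equal(fractionGenomeAltered(callEvents(sccProfile(p))), 0)
  }
})

test_that("artifact positions in paired lesions are effectively independent", {
  tab <- mutations(simulatePair(simulationConfig(seed = 71, ffpeRate = 100,
                                                 muEff = 1e-7,
                                                 clonalCount = 0L)))
  art <- tab[grepl("^ffpe", tab$sim_pool), ]
  keyD <- art[art$sim_pool == "ffpe_dys", c("chrom", "pos")]
  keyS <- art[art$sim_pool == "ffpe_scc", c("chrom", "pos")]
  shared <- merge(keyD, keyS)
  expect_equal(nrow(shared), 0L) # n^2 / 2.9e9 collisions expected: none
})
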