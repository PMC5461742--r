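test_that("exact linear M(f) data recover slope and intercept to machine precision", {
  vafs <- exactLinearVafs(a = 150, b = -625)
  fit <- fitNeutrality(vafs)
  expect_equal(fit@slope, 150, tolerance = 1e-9)
  expect_equal(fit@intercept, -625, tolerance = 1e-9)
  expect_equal(fit@rSquared, 1.0, tolerance = 1e-12)
  expect_equal(muEff(fit), 150 / 3e7, tolerance = 1e-12)
  expect_true(isNeutral(fit))
})

test_that("the fit window is closed and the insufficiency guard engages", {
  # boundary VAFs 0.12 and 0.24 are inside the window
  v <- c(rep(0.12, 6), rep(0.18, 5), rep(0.24, 4))
  fit <- fitNeutrality(v)
  expect_equal(fit@nWindow, 15L)
  # values outside are excluded
  fit2 <- fitNeutrality(c(v, 0.119, 0.241, 0.5, 0.01))
  expect_equal(fit2@nWindow, 15L)
  short <- fitNeutrality(c(0.13, 0.15, 0.2, 0.21, 0.23))
  expect_equal(short@status, "insufficient")
  expect_true(is.na(isNeutral(short)))
  expect_true(is.na(muEff(short)))
})

test_that("R-squared is invariant under reordering of the input VAFs", {
  v <- observedNeutralVafs(seed = 5)
  fit <- fitNeutrality(v)
  fitRev <- fitNeutrality(rev(v))
  fitPerm <- fitNeutrality(sample(v))
  expect_equal(rSquared(fitRev), rSquared(fit))
  expect_equal(rSquared(fitPerm), rSquared(fit))
  expect_equal(fitRev@slope, fit@slope)
})

test_that("simulated neutral lesions are recovered as neutral with the true rate", {
  for (s in 1:5) {
    fit <- fitNeutrality(observedNeutralVafs(seed = 300 + s))
    expect_gte(rSquared(fit), 0.98)
    expect_lt(abs(fit@slope - 150) / 150, 0.15)
  }
})

test_that("an injected subclone breaks the linear 1/f signature", {
  broken <- vapply(1:11, function(s) {
    f <- sampleNeutralVafs(muEff = 5e-6, fMin = 0.06, fMax = 0.5,
                           clonalCount = 0L, seed = 500 + s)
    nw <- sum(f >= 0.12 & f <= 0.24)
    f2 <- injectSubclone(f, 0.18, ceiling(0.3 * nw), seed = 600 + s)
    rSquared(fitNeutrality(f2)) < 0.98
  }, TRUE)
  expect_gt(mean(broken), 0.5)
})

test_that("recovered mutation rate scales linearly with the simulated rate", {
  mus <- c(1e-6, 2e-6, 5e-6)
  recovered <- vapply(mus, function(mu) {
    mean(vapply(1:10, function(s) {
      f <- sampleNeutralVafs(muEff = mu, fMin = 0.06, fMax = 0.5,
                             clonalCount = 0L, seed = 700 + s)
      rd <- observeReads(pmin(2 * f, 1), 1, 2, 125, seed = 800 + s)
      muEff(fitNeutrality(rd$alt / rd$depth))
    }, 0))
  }, 0)
  b <- coef(lm(recovered ~ 0 + mus))[[1]]
  expect_gt(b, 0.85)
  expect_lt(b, 1.15)
})

test_that("per-class rates partition the overall signal", {
  v <- observedNeutralVafs(seed = 9)
  calls <- data.frame(vaf = v, substitution_class = "C>T")
  r <- perTypeRates(calls)
  overall <- fitNeutrality(v)
  expect_equal(r$mu_eff[r$class == "C>T"], muEff(overall))
  expect_true(all(r$status[r$class != "C>T"] == "insufficient"))
  # 50/50 split with identical spectra: each class about half the overall
  calls2 <- data.frame(vaf = v,
                       substitution_class = rep(c("C>T", "T>C"),
                                                length.out = length(v)))
  r2 <- perTypeRates(calls2)
  for (cls in c("C>T", "T>C"))
    expect_equal(r2$mu_eff[r2$class == cls], muEff(overall) / 2,
                 tolerance = 0.15)
  # indels never enter a substitution class
  calls3 <- data.frame(vaf = v, substitution_class = "indel")
  expect_true(all(perTypeRates(calls3)$status == "insufficient"))
})

test_that("the neutrality proportion test matches its closed form", {
  res <- neutralityProportionTest(14, 16, 0.5)
  expect_equal(res$chi2, 9)
  expect_equal(round(res$p, 4), 0.0027)
  res2 <- neutralityProportionTest(8, 16, 0.5)
  expect_equal(res2$chi2, 0)
  expect_equal(res2$p, 1)
  res3 <- neutralityProportionTest(16, 16, 0.5)
  expect_equal(res3$chi2, 16)
  expect_equal(res3$p, stats::pchisq(16, 1, lower.tail = FALSE))
  expect_equal(res3$p, 6.33e-5, tolerance = 1e-3)
  expect_error(neutralityProportionTest(0, 0), "nTotal")
})

test_that("pair evolution labels flag the early-selection pattern", {
  mk <- function(r2) new("NeutralityFit", slope = 100, intercept = 0,
                         rSquared = r2, nWindow = 50L, muEff = 100 / 3e7,
                         neutral = r2 > 0.98, status = "ok",
                         window = c(0.12, 0.24), L = 3e7)
  insuf <- fitNeutrality(c(0.15, 0.2))
  expect_equal(classifyPairEvolution(mk(0.95), mk(0.99))$annotation,
               "early-selection pattern")
  expect_equal(classifyPairEvolution(mk(0.999), mk(0.999))$annotation,
               "both_neutral")
  expect_equal(classifyPairEvolution(insuf, mk(0.99))$annotation,
               "insufficient")
})
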