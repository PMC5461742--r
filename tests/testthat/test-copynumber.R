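test_that("event calling honours the strict ratio thresholds", {
  len <- hg19Autosomes()
  seg <- data.frame(chrom = names(len), start = 1, end = unname(len),
                    ratio = 1.0)
  seg$ratio[seg$chrom == "7"] <- 1.5
  seg$ratio[seg$chrom == "18"] <- 1.1 # exactly 1 + delta: neutral
  seg$ratio[seg$chrom == "4"] <- 0.7
  track <- callEvents(SegmentProfile("S", seg, 0.8))
  calls <- binCalls(track)
  chr <- as.character(GenomicRanges::seqnames(bins(track)))
  expect_true(all(calls[chr == "7"] == "gain"))
  expect_true(all(calls[chr == "18"] == "neutral"))
  expect_true(all(calls[chr == "4"] == "loss"))
  expect_true(all(calls[chr == "1"] == "neutral"))
})

test_that("fraction genome altered sums altered bases over the autosomes", {
  expect_equal(fractionGenomeAltered(callEvents(flatProfile())), 0)
  len <- hg19Autosomes()
  seg <- data.frame(chrom = names(len), start = 1, end = unname(len),
                    ratio = 1.0)
  seg$ratio[seg$chrom == "7"] <- 1.5
  track <- callEvents(SegmentProfile("S", seg, 0.8))
  expect_equal(fractionGenomeAltered(track), len[["7"]] / sum(len))
  seg$ratio <- 1.4 # whole-genome gain
  expect_equal(fractionGenomeAltered(callEvents(SegmentProfile("S", seg, 0.8))),
               1.0)
})

test_that("cohort frequencies count samples per bin and are deterministic", {
  gain8q <- profileFromEvents("A", "8q_gain")
  flat <- flatProfile("B")
  cf <- cohortFrequency(list(callEvents(gain8q), callEvents(flat)))
  in8q <- cf$freq$chrom == "8" & cf$freq$start >= 46800000
  expect_true(all(cf$freq$gain_freq[in8q] %in% c(0, 0.5)))
  expect_gt(sum(cf$freq$gain_freq[in8q] == 0.5), 90)
  expect_true(all(cf$freq$gain_freq[!in8q] == 0))
  cf2 <- cohortFrequency(list(callEvents(gain8q), callEvents(flat)))
  expect_identical(cf, cf2)
  expect_equal(cor(cf$freq$gain_freq, cf$freq$gain_freq), 1.0)
})

test_that("paired difference profiles score direction-aware novel changes", {
  a <- callEvents(flatProfile("A"))
  b <- callEvents(profileFromEvents("B", "8q_gain"))
  d <- pairedDifferenceProfile(list(list(a = a, b = b)))
  in8q <- d$chrom == "8" & d$start >= 46800000
  expect_true(all(d$mean_change[in8q] %in% c(0, 1)))
  expect_gt(sum(d$mean_change[in8q] == 1), 90)
  expect_true(all(d$mean_change[!in8q] == 0))
  # identical tracks give all zeros
  dd <- pairedDifferenceProfile(list(list(a = b, b = b)))
  expect_true(all(dd$mean_change == 0))
  # averaging over pairs
  d2 <- pairedDifferenceProfile(list(list(a = a, b = b),
                                     list(a = a, b = a)))
  expect_true(all(d2$mean_change[in8q] %in% c(0, 0.5)))
  expect_true(all(d2$mean_change >= -1 & d2$mean_change <= 1))
})

test_that("pair classification reproduces the four relationship patterns", {
  tr <- function(...) callEvents(profileFromEvents(...))
  both <- tr("X1", c("8q_gain", "5p_gain"))
  expect_equal(classifyPair(both, tr("X2", c("8q_gain", "5p_gain"))), 2L)
  expect_equal(classifyPair(tr("X3", "8q_gain"),
                            tr("X4", c("8q_gain", "3p_loss"))), 3L)
  flat <- callEvents(flatProfile())
  expect_equal(classifyPair(flat, flat), 4L)
  expect_equal(classifyPair(flat, tr("X5", "8q_gain")), 3L)
  expect_equal(classifyPair(tr("X6", c("8q_gain", "7_gain")),
                            tr("X7", c("8q_gain", "11_loss"))), 1L)
  # direction-matched: 8q gain in one and 8q loss in the other is not shared
  gain8 <- tr("X8", "8q_gain")
  loss8 <- callEvents(profileFromEvents("X9", "8q_gain"))
  # build an 8q loss by hand
  len <- hg19Autosomes()
  seg <- data.frame(chrom = names(len), start = 1, end = unname(len),
                    ratio = 1.0)
  seg <- rbind(seg[seg$chrom != "8", ],
               data.frame(chrom = "8", start = 1, end = 46799999, ratio = 1),
               data.frame(chrom = "8", start = 46800000, end = len[["8"]],
                          ratio = 0.7))
  loss8 <- callEvents(SegmentProfile("X9", seg, 0.8))
  expect_equal(classifyPair(gain8, loss8), 1L)
})

test_that("the expected-frequency chi-squared reproduces the cohort table", {
  er <- ExpectedRates() # rates 0.12/0.38/0.30, sizes 38/69/149
  expect_equal(round(expectedFrequencyTest(c(19, 40, 88), er)$p, 4), 0.0009)
  expect_equal(round(expectedFrequencyTest(c(15, 43, 76), er)$p, 4), 0.0428)
  expect_equal(round(expectedFrequencyTest(c(11, 50, 107), er)$p, 4), 0.3994)
  expect_equal(round(expectedFrequencyTest(c(15, 33, 74), er)$p, 4), 0.0067)
})

test_that("the frequency test degrees of freedom and edge cases behave", {
  er <- ExpectedRates()
  # observed equal to scaled expected: perfect fit
  eStar <- c(0.12, 0.38, 0.30) * c(38, 69, 149)
  o <- eStar * 2
  res <- expectedFrequencyTest(o, er)
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)
  expect_equal(res$df, 2L)
  # the test must not be scale-invariant in the observed counts
  r1 <- expectedFrequencyTest(c(19, 40, 88), er)
  r2 <- expectedFrequencyTest(2 * c(19, 40, 88), er)
  expect_false(isTRUE(all.equal(r1$chi2, r2$chi2)))
  expect_error(expectedFrequencyTest(c(0, 0, 0), er), "not all zero")
  expect_error(expectedFrequencyTest(c(1, 1, 1),
                                     ExpectedRates(rates = c(0, 0.5, 0.5))),
               "zero")
})

test_that("group FGA comparison matches the exact rank-sum oracle", {
  res <- compareGroupFga(list(a = c(0, 0, 0), b = c(1, 1, 1)))
  expect_equal(res$p, 0.1)
  expect_equal(res$p, bruteRankSumP(c(0, 0, 0), c(1, 1, 1)))
  x <- c(0.05, 0.11, 0.22, 0.31); y <- c(0.12, 0.18, 0.40, 0.55, 0.61)
  expect_equal(compareGroupFga(list(x = x, y = y))$p, bruteRankSumP(x, y))
  same <- compareGroupFga(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_gt(same$p, 0.99)
  expect_error(compareGroupFga(list(a = numeric(), b = 1)), "empty")
})

test_that("bonferroni guard reports the 11-region threshold", {
  expect_equal(bonferroniThreshold(0.05, 11), 0.0045)
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
})

test_that("classification recovers the generating class across seeds", {
  for (s in 1:5) for (k in 1:4) {
    p <- simulatePair(simulationConfig(seed = 4000 + 4 * s + k, cnClass = k))
    expect_equal(classifyPair(callEvents(dysProfile(p)),
                              callEvents(sccProfile(p))), k,
                 label = sprintf("seed %d class %d", s, k))
  }
})
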