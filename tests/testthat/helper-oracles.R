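# Independent brute-force oracles used to validate the analytic tests.

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
bruteRankSumP <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  uOf <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  uObs <- uOf(seq_len(n1))
  mu <- n1 * length(y) / 2
  combs <- utils::combn(length(pooled), n1)
  u <- apply(combs, 2L, uOf)
  mean(abs(u - mu) >= abs(uObs - mu) - 1e-9)
}

# Exact two-sample KS p by full enumeration of group assignments.
bruteKsP <- function(x, y) {
  dOf <- function(a, b) {
    grid <- sort(unique(c(a, b)))
    max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
  }
  pooled <- c(x, y)
  n1 <- length(x)
  dObs <- dOf(x, y)
  combs <- utils::combn(length(pooled), n1)
  d <- apply(combs, 2L, function(idx) dOf(pooled[idx], pooled[-idx]))
  mean(d >= dObs - 1e-9)
}

# VAFs constructed so that M(f) = a/f + b holds exactly at every point:
# place increments of the cumulative count at a descending 1/f grid.
exactLinearVafs <- function(a = 150, b = -625, nGrid = 20) {
  x <- (ceiling(-b) + seq_len(nGrid) * 15) / a # 1/f values; M = a*x + b integer
  M <- a * x + b
  stopifnot(all(abs(M - round(M)) < 1e-9), all(diff(M) > 0))
  counts <- diff(c(0, round(M)))
  rep(1 / x, times = counts)
}

# One simulated neutral lesion observed at depth: wider support than the
# fit window so the window is interior (see the methods vignette).
observedNeutralVafs <- function(seed, muEff = 5e-6, depth = 125) {
  f <- sampleNeutralVafs(muEff = muEff, L = 3e7, fMin = 0.06, fMax = 0.5,
                         clonalCount = 0L, seed = seed)
  rd <- observeReads(pmin(2 * f, 1), purity = 1, localCn = 2,
                     depthMean = depth, seed = seed + 100000L)
  rd$alt / rd$depth
}

# A two-segment toy profile builder: named events from the catalogue.
profileFromEvents <- function(sampleId, regions, purity = 0.8) {
  cat <- cnEventCatalogue()
  idx <- match(regions, paste0(S4Vectors::mcols(cat)$region, "_",
                               S4Vectors::mcols(cat)$direction))
  stopifnot(!anyNA(idx))
  ev <- cat[idx]
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ev)),
    start = GenomicRanges::start(ev), end = GenomicRanges::end(ev),
    ratio = ifelse(S4Vectors::mcols(ev)$direction == "gain", 1.3, 0.7))
  len <- hg19Autosomes()
  base <- do.call(rbind, lapply(names(len), function(ch) {
    data.frame(chrom = ch, start = 1, end = len[[ch]], ratio = 1.0)
  }))
  # carve the baseline around events on the same chromosome
  for (i in seq_len(nrow(df))) {
    j <- which(base$chrom == df$chrom[i] & base$ratio == 1.0 &
                 base$start <= df$end[i] & base$end >= df$start[i])
    pieces <- list()
    for (jj in j) {
      if (base$start[jj] < df$start[i])
        pieces[[length(pieces) + 1L]] <-
          data.frame(chrom = df$chrom[i], start = base$start[jj],
                     end = df$start[i] - 1, ratio = 1.0)
      if (base$end[jj] > df$end[i])
        pieces[[length(pieces) + 1L]] <-
          data.frame(chrom = df$chrom[i], start = df$end[i] + 1,
                     end = base$end[jj], ratio = 1.0)
    }
    base <- rbind(base[-j, ], do.call(rbind, pieces))
  }
  seg <- rbind(base, df)
  seg <- seg[seg$end >= seg$start, ]
  SegmentProfile(sampleId, seg, purity)
}

# Minimal paired mutation table row.
mutRow <- function(chrom = "1", pos = 1000, ref = "C", alt = "T",
                   dys_alt = 0L, dys_depth = 100L, scc_alt = 0L,
                   scc_depth = 100L, somatic_score = 30,
                   consequence = "missense_variant", sift = "deleterious",
                   polyphen = "probably_damaging", gene = "GENE0001") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             dys_alt = dys_alt, dys_depth = dys_depth, scc_alt = scc_alt,
             scc_depth = scc_depth, somatic_score = somatic_score,
             consequence = consequence, sift = sift, polyphen = polyphen,
             gene = gene,
             substitution_class = substitutionClass(ref, alt),
             stringsAsFactors = FALSE)
}

flatProfile <- function(sampleId = "FLAT", purity = 0.8) {
  len <- hg19Autosomes()
  SegmentProfile(sampleId, data.frame(chrom = names(len), start = 1,
                                      end = unname(len), ratio = 1.0),
                 purity)
}
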