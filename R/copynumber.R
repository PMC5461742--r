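#' Call per-bin copy-number events from a segmented profile
#'
#' Tiles the autosomes into fixed-size bins and labels each bin `gain` if
#' the dominant overlapping segment has ratio strictly above
#' `1 + gainDelta`, `loss` if strictly below `1 - lossDelta`, otherwise
#' `neutral`. Bins not covered by any segment are neutral and counted in
#' `nUncovered`. Sex-chromosome segments are ignored.
#'
#' @param profile A [SegmentProfile-class] with ratios normalised so that
#'   1.0 is the diploid baseline.
#' @param gainDelta,lossDelta Ratio deviations defining events
#'   (strict inequalities); both default to 0.1.
#' @param binSize Bin width in bases (default 1 Mb).
#' @return A [CNEventTrack-class].
#' @export
#' @examples
#' seg <- data.frame(chrom = "8", start = 1, end = 146364022, ratio = 1.3)
#' track <- callEvents(SegmentProfile("S1", seg, 0.8))
#' table(binCalls(track))
callEvents <- function(profile, gainDelta = 0.1, lossDelta = 0.1,
                       binSize = 1e6) {
  stopifnot(is(profile, "SegmentProfile"))
  grid <- binGrid(binSize)
  seg <- autosomalSegments(profile)
  GenomeInfoDb::seqlevels(seg) <-
    union(GenomeInfoDb::seqlevels(seg), GenomeInfoDb::seqlevels(grid))
  ov <- GenomicRanges::findOverlaps(grid, seg)
  call <- rep("neutral", length(grid))
  covered <- rep(FALSE, length(grid))
  if (length(ov)) {
    w <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(grid)[S4Vectors::queryHits(ov)],
      GenomicRanges::ranges(seg)[S4Vectors::subjectHits(ov)]))
    # dominant segment per bin: the one with the largest overlap
    ord <- order(S4Vectors::queryHits(ov), -w)
    keep <- !duplicated(S4Vectors::queryHits(ov)[ord])
    qh <- S4Vectors::queryHits(ov)[ord][keep]
    ratio <- S4Vectors::mcols(seg)$ratio[S4Vectors::subjectHits(ov)[ord][keep]]
    covered[qh] <- TRUE
    call[qh][ratio > 1 + gainDelta] <- "gain"
    call[qh][ratio < 1 - lossDelta] <- "loss"
  }
  S4Vectors::mcols(grid)$call <- factor(call,
                                        levels = c("loss", "neutral", "gain"))
  new("CNEventTrack", sampleId = sampleId(profile), bins = grid,
      binSize = binSize, nUncovered = sum(!covered))
}

#' @keywords internal
binGrid <- function(binSize) {
  si <- autosomeSeqinfo()
  grid <- GenomicRanges::tileGenome(GenomeInfoDb::seqlengths(si),
                                    tilewidth = binSize,
                                    cut.last.tile.in.chrom = TRUE)
  GenomeInfoDb::seqinfo(grid) <- si
  grid
}

#' Fraction of the autosomal genome altered
#'
#' Sums the bases of autosomal gain or loss and divides by the autosomal
#' genome size.
#'
#' @param track A [CNEventTrack-class].
#' @return A value in [0, 1]; 0 for a flat profile.
#' @export
fractionGenomeAltered <- function(track) {
  stopifnot(is(track, "CNEventTrack"))
  b <- bins(track)
  altered <- binCalls(track) != "neutral"
  sum(GenomicRanges::width(b)[altered]) / sum(GenomicRanges::width(b))
}

#' Per-bin gain/loss frequencies across a cohort
#'
#' For each bin, the fraction of samples with a gain and with a loss, plus
#' a summary of the per-sample fractions of genome altered.
#'
#' @param tracks List of [CNEventTrack-class] on the same bin grid.
#' @return A list with `freq` (data.frame: chrom, start, end, gain_freq,
#'   loss_freq) and `fga` (named numeric of per-sample FGA values).
#' @export
cohortFrequency <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  grids <- vapply(tracks, function(t) length(bins(t)), 0L)
  if (length(unique(grids)) != 1L)
    stop("tracks are on inconsistent bin grids")
  ref <- bins(tracks[[1L]])
  for (t in tracks)
    if (!identical(GenomicRanges::ranges(bins(t)), GenomicRanges::ranges(ref)))
      stop("tracks are on inconsistent bin grids")
  calls <- vapply(tracks, function(t) as.character(binCalls(t)),
                  character(length(ref)))
  freq <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ref)),
    start = GenomicRanges::start(ref), end = GenomicRanges::end(ref),
    gain_freq = rowMeans(calls == "gain"),
    loss_freq = rowMeans(calls == "loss"))
  fga <- vapply(tracks, fractionGenomeAltered, 0)
  names(fga) <- vapply(tracks, sampleId, "")
  list(freq = freq, fga = fga)
}

#' Mean per-bin signed change seen in sample B but not sample A
#'
#' For each pair, a bin scores +1 if B has a gain there and A does not,
#' -1 if B has a loss and A does not, 0 otherwise; the output is the
#' per-bin mean over pairs (values in [-1, 1]).
#'
#' @param pairs List of lists with elements `a` and `b`
#'   ([CNEventTrack-class] on a common grid); conventionally `a` is the
#'   earlier lesion (e.g. LGD or HGD) and `b` the later (HGD or SCC).
#' @return data.frame: chrom, start, end, mean_change.
#' @export
pairedDifferenceProfile <- function(pairs) {
  stopifnot(length(pairs) >= 1L)
  ref <- bins(pairs[[1L]]$a)
  delta <- vapply(pairs, function(p) {
    a <- binCalls(p$a); b <- binCalls(p$b)
    if (length(a) != length(ref) || length(b) != length(ref))
      stop("pair tracks are on inconsistent bin grids")
    as.numeric((b == "gain" & a != "gain") - (b == "loss" & a != "loss"))
  }, numeric(length(ref)))
  data.frame(chrom = as.character(GenomicRanges::seqnames(ref)),
             start = GenomicRanges::start(ref),
             end = GenomicRanges::end(ref),
             mean_change = rowMeans(delta))
}

#' Classify the relationship between a pair of copy-number profiles
#'
#' The four pair-relationship classes: (1) dysplasia and SCC share some
#' events but each has independent ones; (2) nearly identical profiles;
#' (3) the dysplasia's events are a subset of the SCC's, or the dysplasia
#' is flat while the SCC is not; (4) both profiles flat.
#'
#' A sample is flat when its fraction of genome altered is below
#' `tauFlat`. For non-flat samples the unique fraction `u` is the share of
#' its altered bins not altered in the same direction in the partner
#' (direction-matched: an 8q gain in one sample does not match an 8q loss
#' in the other). Class 2 requires both `u` below `tauU`; class 3 a flat
#' dysplasia with non-flat SCC, or `u_dys < tauU <= u_scc`; class 1
#' otherwise.
#'
#' @param dysTrack,sccTrack [CNEventTrack-class] on the same grid.
#' @param tauFlat FGA below which a profile counts as flat (default 0.01).
#' @param tauU Unique-fraction tolerance (default 0.10).
#' @return Integer class in 1:4.
#' @export
classifyPair <- function(dysTrack, sccTrack, tauFlat = 0.01, tauU = 0.10) {
  a <- binCalls(dysTrack); b <- binCalls(sccTrack)
  if (length(a) != length(b)) stop("tracks are on inconsistent bin grids")
  flatD <- fractionGenomeAltered(dysTrack) < tauFlat
  flatS <- fractionGenomeAltered(sccTrack) < tauFlat
  if (flatD && flatS) return(4L)
  if (flatD && !flatS) return(3L)
  altD <- a != "neutral"; altS <- b != "neutral"
  uD <- if (any(altD)) sum(altD & (a != b)) / sum(altD) else 0
  uS <- if (any(altS)) sum(altS & (a != b)) / sum(altS) else 0
  if (uD < tauU && uS < tauU) return(2L)
  if (uD < tauU && uS >= tauU) return(3L)
  1L
}

#' Chi-squared test of observed event counts against expected group rates
#'
#' Tests whether a recurrent event's per-group frequencies deviate from
#' what each group's overall fraction of genome altered predicts. Raw
#' expected counts `e*_g = r_g * n_g` are rescaled so their total matches
#' the observed total, then a goodness-of-fit chi-squared with
#' `G - 1` degrees of freedom is computed.
#'
#' @param observed Non-negative event counts per group (not all zero).
#' @param rates An [ExpectedRates-class] giving `r_g` and `n_g`.
#' @return List with `chi2`, `df`, `p`, and the scaled `expected` counts.
#' @export
#' @examples
#' # 8q gain counts in the LGD/HGD/SCC cohorts:
#' expectedFrequencyTest(c(19, 40, 88), ExpectedRates())$p # 0.0009
expectedFrequencyTest <- function(observed, rates = ExpectedRates()) {
  stopifnot(is(rates, "ExpectedRates"))
  if (length(observed) != length(rates@groups))
    stop("observed counts and rate groups differ in length")
  if (any(observed < 0) || sum(observed) == 0)
    stop("observed counts must be >= 0 and not all zero")
  eStar <- rates@rates * rates@sizes
  if (any(eStar == 0)) stop("an expected count is zero; test undefined")
  e <- eStar * sum(observed) / sum(eStar)
  chi2 <- sum((observed - e)^2 / e)
  df <- length(observed) - 1L
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df = df, lower.tail = FALSE), expected = e)
}

#' Pairwise Mann-Whitney comparison of fraction-genome-altered groups
#'
#' Two-sided rank-sum tests between every pair of groups. For small
#' samples (combined n at most `exactLimit`) the p-value is computed by
#' exhaustive enumeration of all group assignments, which stays exact in
#' the presence of ties; larger comparisons use [stats::wilcox.test()].
#'
#' @param groups Named list of numeric FGA vectors (>= 2 groups, each
#'   non-empty).
#' @param exactLimit Combined sample size up to which the permutation
#'   distribution is enumerated exhaustively (default 12).
#' @return data.frame: group1, group2, p.
#' @export
compareGroupFga <- function(groups, exactLimit = 12L) {
  stopifnot(length(groups) >= 2L)
  if (any(vapply(groups, length, 0L) == 0L)) stop("empty group")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_along(groups))
  combos <- utils::combn(seq_along(groups), 2L)
  out <- apply(combos, 2L, function(idx) {
    x <- groups[[idx[1L]]]; y <- groups[[idx[2L]]]
    p <- if (length(x) + length(y) <= exactLimit) exactRankSumP(x, y)
         else suppressWarnings(
           stats::wilcox.test(x, y, alternative = "two.sided"))$p.value
    data.frame(group1 = nm[idx[1L]], group2 = nm[idx[2L]], p = p)
  })
  do.call(rbind, out)
}

#' Exact two-sided rank-sum p by enumeration of group assignments; the
#' Mann-Whitney U null is symmetric, so two-sided means at-least-as-far
#' from the null mean in either direction.
#' @keywords internal
exactRankSumP <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  uOf <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  uObs <- uOf(seq_len(n1))
  mu <- n1 * length(y) / 2
  u <- apply(utils::combn(length(pooled), n1), 2L, uOf)
  mean(abs(u - mu) >= abs(uObs - mu) - 1e-9)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param m Number of tests (>= 1).
#' @return `alpha / m`, rounded to 4 decimal places for reporting.
#' @export
#' @examples
#' bonferroniThreshold(0.05, 11) # 0.0045
bonferroniThreshold <- function(alpha = 0.05, m = 1L) {
  stopifnot(m >= 1L, alpha > 0)
  round(alpha / m, 4L)
}

#' Which catalogue regions does a track hit?
#'
#' A recurrent region counts as hit when at least half of its bins carry a
#' call in the region's direction.
#'
#' @param track A [CNEventTrack-class].
#' @param catalogue A catalogue `GRanges` (default [cnEventCatalogue()]).
#' @param minFrac Minimum fraction of region bins altered in-direction.
#' @return Character vector of region labels (e.g. `"8q_gain"`).
#' @export
regionsHit <- function(track, catalogue = cnEventCatalogue(),
                       minFrac = 0.5) {
  b <- bins(track)
  calls <- binCalls(track)
  hit <- character()
  for (i in seq_along(catalogue)) {
    ov <- S4Vectors::queryHits(GenomicRanges::findOverlaps(b, catalogue[i]))
    if (!length(ov)) next
    dirn <- S4Vectors::mcols(catalogue)$direction[i]
    if (mean(calls[ov] == dirn) >= minFrac)
      hit <- c(hit, paste0(S4Vectors::mcols(catalogue)$region[i], "_", dirn))
  }
  hit
}
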