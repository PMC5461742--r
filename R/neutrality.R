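#' The 1/f test for neutral subclonal evolution
#'
#' Under neutral growth the cumulative number of subclonal mutations with
#' VAF at least f is linear in 1/f. High-VAF calls (above the window) are
#' likely clonal and low-VAF calls likely errors or FFPE artifacts, so the
#' fit uses only mutations inside the closed window (default
#' [0.12, 0.24]). For each mutation i with VAF f_i in the window,
#' `M(f_i)` is the number of window mutations with VAF >= f_i (ties share
#' the count); ordinary least squares with intercept of M on 1/f gives the
#' slope, intercept and R-squared. A sample is called neutral when
#' R-squared exceeds 0.98. The effective mutation rate (mutations per base
#' per effective cell division, i.e. division minus death) is the gradient
#' divided by the callable genome size `L` (default the 30-Mb exome).
#'
#' @param vafs Numeric VAFs in [0, 1].
#' @param window Closed VAF window, length 2 (default `c(0.12, 0.24)`).
#' @param L Callable genome size in bases (default 3e7).
#' @param nMin Minimum window mutations for a meaningful fit (default 10);
#'   below it the result is flagged `"insufficient"` and the neutral flag
#'   is `NA`.
#' @param r2Threshold Neutrality cutoff on R-squared (default 0.98,
#'   strict).
#' @return A [NeutralityFit-class].
#' @export
#' @examples
#' f <- sampleNeutralVafs(muEff = 5e-6, seed = 1)
#' fitNeutrality(f) # recovers slope ~150, R-squared near 1
fitNeutrality <- function(vafs, window = c(0.12, 0.24), L = 3e7,
                          nMin = 10L, r2Threshold = 0.98) {
  stopifnot(length(window) == 2L, window[1L] <= window[2L], L > 0)
  f <- vafs[!is.na(vafs) & vafs >= window[1L] & vafs <= window[2L]]
  n <- length(f)
  insufficient <- function() new("NeutralityFit", slope = NA_real_,
    intercept = NA_real_, rSquared = NA_real_, nWindow = as.integer(n),
    muEff = NA_real_, neutral = NA, status = "insufficient",
    window = window, L = L)
  if (n < nMin) return(insufficient())
  x <- 1 / f
  M <- vapply(f, function(fi) sum(f >= fi), 0L)
  if (stats::var(x) == 0) return(insufficient())
  slope <- stats::cov(x, M) / stats::var(x)
  intercept <- mean(M) - slope * mean(x)
  r2 <- if (stats::var(M) == 0) 1 else stats::cor(x, M)^2
  new("NeutralityFit", slope = slope, intercept = intercept,
      rSquared = r2, nWindow = as.integer(n), muEff = slope / L,
      neutral = r2 > r2Threshold, status = "ok", window = window, L = L)
}

SUBSTITUTION_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Per-substitution-class mutation rates
#'
#' Runs [fitNeutrality()] separately on each pyrimidine-context
#' substitution class (indels are excluded), with the same window and
#' genome size. Classes with fewer than `nMin` window mutations are
#' reported with status `"insufficient"` and `NA` rate.
#'
#' @param calls Mutation data.frame with `substitution_class` and a VAF
#'   column `vaf` (or computed from `alt`/`depth` columns via `vafColumn`).
#' @param vafColumn Name of the VAF column (default `"vaf"`).
#' @inheritParams fitNeutrality
#' @return data.frame: class, n_window, slope, r_squared, mu_eff, status.
#' @export
perTypeRates <- function(calls, vafColumn = "vaf", window = c(0.12, 0.24),
                         L = 3e7, nMin = 10L) {
  stopifnot(vafColumn %in% names(calls),
            "substitution_class" %in% names(calls))
  out <- lapply(SUBSTITUTION_CLASSES, function(cls) {
    v <- calls[[vafColumn]][calls$substitution_class == cls]
    fit <- fitNeutrality(v, window = window, L = L, nMin = nMin)
    data.frame(class = cls, n_window = fit@nWindow, slope = fit@slope,
               r_squared = fit@rSquared, mu_eff = fit@muEff,
               status = fit@status)
  })
  do.call(rbind, out)
}

#' Chi-squared test of the observed proportion of neutral samples
#'
#' Goodness-of-fit chi-squared (df 1) of the observed neutral /
#' non-neutral split against an expected neutral fraction. Observing 14
#' neutral of 16 against a 50% expectation gives chi2 = 9, p = 0.0027.
#'
#' @param nNeutral Number of samples called neutral.
#' @param nTotal Total samples (> 0).
#' @param expectedFraction Expected neutral fraction (default 0.5).
#' @return List with `chi2`, `df`, `p`.
#' @export
#' @examples
#' neutralityProportionTest(14, 16)$p # 0.0027
neutralityProportionTest <- function(nNeutral, nTotal,
                                     expectedFraction = 0.5) {
  if (nTotal == 0) stop("nTotal must be > 0")
  stopifnot(nNeutral >= 0, nNeutral <= nTotal,
            expectedFraction > 0, expectedFraction < 1)
  o <- c(nNeutral, nTotal - nNeutral)
  e <- c(expectedFraction, 1 - expectedFraction) * nTotal
  chi2 <- sum((o - e)^2 / e)
  list(chi2 = chi2, df = 1L,
       p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Label the evolutionary mode of a lesion pair
#'
#' Combines the per-lesion neutrality fits: each lesion gets a neutral
#' flag, and a non-neutral dysplasia paired with a neutral SCC is
#' annotated as the early-selection pattern (a selectively advantaged
#' subclone emerging before invasion, fixed by the time of carcinoma).
#' Insufficient fits propagate as `"insufficient"` with no pattern call.
#'
#' @param dysFit,sccFit [NeutralityFit-class] objects.
#' @return List with `dys_neutral`, `scc_neutral` (logical or NA) and
#'   `annotation` (`"both_neutral"`, `"early-selection pattern"`,
#'   `"insufficient"`, or `"other"`).
#' @export
classifyPairEvolution <- function(dysFit, sccFit) {
  stopifnot(is(dysFit, "NeutralityFit"), is(sccFit, "NeutralityFit"))
  dn <- isNeutral(dysFit); sn <- isNeutral(sccFit)
  annotation <- if (is.na(dn) || is.na(sn)) "insufficient"
    else if (!dn && sn) "early-selection pattern"
    else if (dn && sn) "both_neutral"
    else "other"
  list(dys_neutral = dn, scc_neutral = sn, annotation = annotation)
}
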