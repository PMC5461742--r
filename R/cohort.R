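#' Compare the VAF distributions of shared versus all mutations
#'
#' Two-sample two-sided Kolmogorov-Smirnov test of whether the shared
#' calls' VAF distribution differs from that of all calls, optionally
#' after dropping VAFs below the artifact floor (0.12). Reports medians
#' and the direction of shift alongside the p-value.
#'
#' @param vafsAll,vafsShared Numeric VAF vectors.
#' @param applyFloor Drop VAFs below `floor` from both sets first.
#' @param floor Artifact floor (default 0.12).
#' @param method `"ks"` (default) or `"ranksum"`.
#' @return List with `p` (NA and `flagged = TRUE` if a set is empty after
#'   flooring), `n_all`, `n_shared`, `median_all`, `median_shared`,
#'   `direction` (`"shared_higher"`, `"shared_lower"` or `"none"`).
#' @export
compareSharedVsAll <- function(vafsAll, vafsShared, applyFloor = FALSE,
                               floor = 0.12, method = c("ks", "ranksum")) {
  method <- match.arg(method)
  if (applyFloor) {
    vafsAll <- vafsAll[vafsAll >= floor]
    vafsShared <- vafsShared[vafsShared >= floor]
  }
  if (length(vafsAll) == 0L || length(vafsShared) == 0L)
    return(list(p = NA_real_, flagged = TRUE, n_all = length(vafsAll),
                n_shared = length(vafsShared), median_all = NA_real_,
                median_shared = NA_real_, direction = NA_character_))
  p <- if (method == "ks")
    suppressWarnings(stats::ks.test(vafsShared, vafsAll))$p.value
  else
    suppressWarnings(stats::wilcox.test(vafsShared, vafsAll))$p.value
  mAll <- stats::median(vafsAll); mSh <- stats::median(vafsShared)
  list(p = p, flagged = FALSE, n_all = length(vafsAll),
       n_shared = length(vafsShared), median_all = mAll,
       median_shared = mSh,
       direction = if (mSh > mAll) "shared_higher"
                   else if (mSh < mAll) "shared_lower" else "none")
}

#' Baseline of calls shared between versus within patients
#'
#' For every pair of samples, counts identical calls (same chrom, pos,
#' ref, alt; no fuzzy matching) per VAF bin (a call is binned by the mean
#' of its two VAFs). Comparing within-patient to between-patient pairs
#' establishes how many shared calls recurrent FFPE artifacts alone would
#' produce: true sharing shows up as within-patient counts exceeding every
#' between-patient count at higher VAFs.
#'
#' @param callSets Named list (one element per sample) of data.frames with
#'   columns `chrom`, `pos`, `ref`, `alt`, `vaf`.
#' @param patients Named character vector mapping sample name to patient.
#' @param vafBins Bin boundaries (default `c(0, 0.05, 0.1, 0.2, 1)`).
#' @return List with `pairCounts` (data.frame: sample1, sample2,
#'   same_patient, one count column per bin), `binSummary` (per-bin
#'   rank-sum p comparing within vs between distributions) and
#'   `gapHighVaf` (min within-patient minus max between-patient shared
#'   count over bins above 0.1; positive means no overlap at all).
#' @export
betweenPatientBaseline <- function(callSets, patients,
                                   vafBins = c(0, 0.05, 0.1, 0.2, 1)) {
  stopifnot(length(callSets) >= 2L, !is.null(names(callSets)))
  patients <- patients[names(callSets)]
  if (length(unique(patients)) < 2L)
    stop("need samples from at least two patients")
  nb <- length(vafBins) - 1L
  binNames <- paste0("bin", seq_len(nb))
  keyed <- lapply(callSets, function(d)
    data.frame(key = paste(d$chrom, d$pos, d$ref, d$alt, sep = ":"),
               vaf = d$vaf, stringsAsFactors = FALSE))
  combos <- utils::combn(names(callSets), 2L)
  rows <- apply(combos, 2L, function(pr) {
    a <- keyed[[pr[1L]]]; b <- keyed[[pr[2L]]]
    i <- match(a$key, b$key)
    hit <- !is.na(i)
    counts <- integer(nb)
    if (any(hit)) {
      v <- (a$vaf[hit] + b$vaf[i[hit]]) / 2
      bin <- cut(v, vafBins, include.lowest = TRUE, labels = FALSE)
      tb <- table(factor(bin, levels = seq_len(nb)))
      counts <- as.integer(tb)
    }
    out <- data.frame(sample1 = pr[1L], sample2 = pr[2L],
                      same_patient = patients[[pr[1L]]] == patients[[pr[2L]]])
    out[binNames] <- as.list(counts)
    out
  })
  pairCounts <- do.call(rbind, rows)
  binSummary <- do.call(rbind, lapply(seq_len(nb), function(j) {
    w <- pairCounts[[binNames[j]]][pairCounts$same_patient]
    b <- pairCounts[[binNames[j]]][!pairCounts$same_patient]
    p <- if (length(w) && length(b))
      suppressWarnings(stats::wilcox.test(w, b))$p.value else NA_real_
    data.frame(bin = binNames[j], vaf_lo = vafBins[j],
               vaf_hi = vafBins[j + 1L],
               median_within = if (length(w)) stats::median(w) else NA_real_,
               median_between = if (length(b)) stats::median(b) else NA_real_,
               p = p)
  }))
  high <- which(vafBins[-length(vafBins)] >= 0.1)
  highCounts <- rowSums(pairCounts[binNames[high]])
  w <- highCounts[pairCounts$same_patient]
  b <- highCounts[!pairCounts$same_patient]
  gap <- if (length(w) && length(b)) min(w) - max(b) else NA_real_
  list(pairCounts = pairCounts, binSummary = binSummary, gapHighVaf = gap)
}

#' Assemble the cohort summary report
#'
#' One row per patient combining the stage outputs: pair class, per-lesion
#' fractions of genome altered, raw/filtered/shared mutation counts, the
#' neutrality flags and rates. Missing stages are reported as NA
#' (non-fatal). A run manifest (config echo, seed, thresholds, package
#' version) is attached.
#'
#' @param patients Character vector of patient ids.
#' @param classes,fga,mutationCounts,neutrality Named-by-patient stage
#'   results: `classes` integer; `fga` list of c(dys, scc); mutation
#'   counts list of c(raw, filtered, shared); neutrality list as from
#'   [classifyPairEvolution()] plus optional rates.
#' @param manifest Named list recorded alongside (seed, thresholds, ...).
#' @return List with `report` (data.frame) and `manifest`.
#' @export
assembleReport <- function(patients, classes = NULL, fga = NULL,
                           mutationCounts = NULL, neutrality = NULL,
                           manifest = list()) {
  getNum <- function(lst, pid, idx) {
    if (is.null(lst) || is.null(lst[[pid]])) return(NA_real_)
    as.numeric(lst[[pid]][idx])
  }
  rows <- lapply(patients, function(pid) {
    raw <- getNum(mutationCounts, pid, 1L)
    fil <- getNum(mutationCounts, pid, 2L)
    sh <- getNum(mutationCounts, pid, 3L)
    neut <- if (!is.null(neutrality)) neutrality[[pid]] else NULL
    data.frame(
      patient = pid,
      class = if (!is.null(classes) && pid %in% names(classes))
        classes[[pid]] else NA_integer_,
      fga_dys = getNum(fga, pid, 1L), fga_scc = getNum(fga, pid, 2L),
      n_raw = raw, n_filtered = fil, n_shared = sh,
      shared_fraction = if (!is.na(fil) && fil > 0) sh / fil else NA_real_,
      dys_neutral = if (!is.null(neut)) neut$dys_neutral else NA,
      scc_neutral = if (!is.null(neut)) neut$scc_neutral else NA,
      annotation = if (!is.null(neut)) neut$annotation else NA_character_)
  })
  manifest$package_version <- as.character(utils::packageVersion("clonalPair"))
  list(report = do.call(rbind, rows), manifest = manifest)
}
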