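#' Initial somatic-call filter
#'
#' Keeps calls with a somatic score strictly above `scoreMin` (score 10
#' corresponds to somatic p = 0.1) that are supported by at least
#' `minReads` alt reads in at least one lesion.
#'
#' @param calls Mutation data.frame (see [LesionPair-class]).
#' @param scoreMin Somatic-score floor (strict; default 10).
#' @param minReads Minimum alt reads in the lesion where called (default 3).
#' @return The filtered data.frame.
#' @export
initialFilter <- function(calls, scoreMin = 10, minReads = 3L) {
  keep <- calls$somatic_score > scoreMin &
    (calls$dys_alt >= minReads | calls$scc_alt >= minReads)
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Minimum VAF implied by the clonality model
#'
#' With tumour cell content `p` and local tumour copy number `nT`, each
#' tumour-cell chromosomal copy contributes `p / nT` of the reads, so a
#' mutation carried on a single copy (m = 1) by a fraction `c` of tumour
#' cells has expected VAF `c * p / nT`. For example, in a triploid region
#' at 70% tumour content each copy contributes 23.3% of reads and a
#' mutation in over 50% of cells has a minimum VAF of 11.7%.
#'
#' `model = "mixture"` instead dilutes the denominator by normal-cell DNA:
#' `c * p / (p * nT + 2 * (1 - p))`.
#'
#' @param cellFrac Cellular frequency `c` in (0, 1].
#' @param purity Tumour cell content `p` in (0, 1].
#' @param tumorCn Local tumour copy number `nT` (>= 1; 0 is an error:
#'   no threshold is definable in a homozygous deletion).
#' @param model `"per_copy"` (default) or `"mixture"`.
#' @return The minimum VAF.
#' @export
#' @examples
#' clonalVafThreshold(0.5, 0.7, 3) # 0.1167
clonalVafThreshold <- function(cellFrac, purity, tumorCn,
                               model = c("per_copy", "mixture")) {
  model <- match.arg(model)
  if (any(tumorCn == 0)) stop("tumor copy number 0: no threshold definable")
  stopifnot(all(cellFrac > 0 & cellFrac <= 1),
            all(purity > 0 & purity <= 1), all(tumorCn >= 1))
  if (model == "per_copy") cellFrac * purity / tumorCn
  else cellFrac * purity / (purity * tumorCn + 2 * (1 - purity))
}

#' Consequence whitelist filter
#'
#' A call has a possible effect on protein function when any consequence
#' term is in the whitelist (splice sites, frameshifts, stop gained/lost,
#' coding insertions/deletions, initiator and incomplete terminal codons,
#' feature elongations/truncations) or it is a missense variant labelled
#' possibly/probably damaging by PolyPhen or deleterious by SIFT.
#'
#' @param consequence Character vector; each element the comma-separated
#'   consequence terms of one call.
#' @param sift,polyphen Label vectors (may be NA).
#' @return Logical vector.
#' @export
#' @examples
#' passesEffectFilter("stop_gained", NA, NA)                   # TRUE
#' passesEffectFilter("missense_variant", "tolerated", "benign") # FALSE
passesEffectFilter <- function(consequence, sift = NA, polyphen = NA) {
  whitelist <- c("splice_acceptor_variant", "splice_donor_variant",
                 "splice_region_variant", "frameshift_variant",
                 "stop_gained", "stop_lost", "inframe_deletion",
                 "inframe_insertion", "initiator_codon_variant",
                 "start_lost", "incomplete_terminal_codon_variant",
                 "feature_elongation", "feature_truncation",
                 "transcript_truncation")
  n <- max(length(consequence), length(sift), length(polyphen))
  consequence <- rep_len(as.character(consequence), n)
  sift <- rep_len(as.character(sift), n)
  polyphen <- rep_len(as.character(polyphen), n)
  terms <- strsplit(ifelse(is.na(consequence), "", consequence), ",")
  vapply(seq_len(n), function(i) {
    tt <- trimws(terms[[i]])
    if (any(tt %in% whitelist)) return(TRUE)
    if ("missense_variant" %in% tt) {
      return(isTRUE(polyphen[i] %in% c("possibly_damaging",
                                       "probably_damaging")) ||
             isTRUE(sift[i] == "deleterious"))
    }
    FALSE
  }, logical(1))
}

#' Stringent clonality + effect filter for a lesion pair
#'
#' A call passes in a lesion when its VAF there is at least the clonal VAF
#' threshold for `cellFrac` of cells (given that lesion's purity and the
#' local tumour copy number from its segment profile, `cn = round(2 *
#' ratio)` clipped to [1, 8]; 2 where no segment covers the call) and its
#' somatic score is strictly above `scoreMin`. A call is retained when it
#' passes in at least one lesion and passes the consequence filter.
#'
#' @param pair A [LesionPair-class] with mutation table and both profiles.
#' @param cellFrac Cellular-frequency cutoff (default 0.5: present in over
#'   half the tumour cells).
#' @param scoreMin Somatic-score floor (strict; default 15, p < 0.05).
#' @param model Clonality model, see [clonalVafThreshold()].
#' @return The mutation table augmented with `dys_vaf`, `scc_vaf`,
#'   `dys_cn`, `scc_cn`, `dys_pass`, `scc_pass`, `effect_pass` and
#'   `retained`; attribute `nOutsideSegments` counts calls that fell back
#'   to cn = 2.
#' @export
stringentFilter <- function(pair, cellFrac = 0.5, scoreMin = 15,
                            model = "per_copy") {
  stopifnot(is(pair, "LesionPair"))
  tab <- mutations(pair)
  if (is.null(tab)) stop("pair has no mutation table")
  dysP <- dysProfile(pair); sccP <- sccProfile(pair)
  if (is.null(dysP) || is.null(sccP))
    stop("pair needs both segment profiles for the clonality filter")
  tab$dys_vaf <- ifelse(tab$dys_depth > 0, tab$dys_alt / tab$dys_depth, 0)
  tab$scc_vaf <- ifelse(tab$scc_depth > 0, tab$scc_alt / tab$scc_depth, 0)
  cnOf <- function(profile) localCnAt(profile, tab$chrom, tab$pos)
  tab$dys_cn <- cnOf(dysP); tab$scc_cn <- cnOf(sccP)
  outside <- outsideSegments(dysP, tab$chrom, tab$pos) |
    outsideSegments(sccP, tab$chrom, tab$pos)
  thrD <- clonalVafThreshold(cellFrac, purity(dysP), tab$dys_cn, model)
  thrS <- clonalVafThreshold(cellFrac, purity(sccP), tab$scc_cn, model)
  tab$dys_pass <- tab$dys_vaf >= thrD & tab$somatic_score > scoreMin
  tab$scc_pass <- tab$scc_vaf >= thrS & tab$somatic_score > scoreMin
  tab$effect_pass <- passesEffectFilter(tab$consequence, tab$sift,
                                        tab$polyphen)
  tab$retained <- (tab$dys_pass | tab$scc_pass) & tab$effect_pass
  attr(tab, "nOutsideSegments") <- sum(outside)
  tab
}

#' @keywords internal
outsideSegments <- function(profile, chrom, pos) {
  q <- GenomicRanges::GRanges(normChrom(chrom), IRanges::IRanges(pos, pos))
  seg <- segments(profile)
  GenomeInfoDb::seqlevels(q) <-
    union(GenomeInfoDb::seqlevels(q), GenomeInfoDb::seqlevels(seg))
  is.na(GenomicRanges::findOverlaps(q, seg, select = "first"))
}

#' Partition retained calls into dysplasia-only, shared and SCC-only
#'
#' A retained call is shared when it passes the stringent filter in both
#' lesions, or passes in one and is present in the other at lower cellular
#' frequency (the rescue rule; presence means at least `minReads` alt
#' reads there). Otherwise it is private to the lesion where it passes.
#'
#' @param filtered Output of [stringentFilter()].
#' @param minReads Alt-read presence cutoff for the rescue rule (default 3,
#'   mirroring the initial read-support filter).
#' @return The retained rows with a `partition` column
#'   (`dysplasia_only` / `shared` / `scc_only`).
#' @export
partitionShared <- function(filtered, minReads = 3L) {
  tab <- filtered[filtered$retained, , drop = FALSE]
  part <- ifelse(
    (tab$dys_pass & tab$scc_pass) |
      (tab$dys_pass & tab$scc_alt >= minReads) |
      (tab$scc_pass & tab$dys_alt >= minReads), "shared",
    ifelse(tab$dys_pass, "dysplasia_only", "scc_only"))
  tab$partition <- part
  rownames(tab) <- NULL
  tab
}

#' Tally partitioned genes against a curated gene list
#'
#' Intersects the genes mutated in each partition with a curated list.
#' Partition precedence for the counts is shared > private: a gene with
#' both a shared and a private call counts once, as shared. The per-gene
#' presence matrix keeps all partitions a gene appears in (one row per
#' gene, logical columns per partition), mirroring per-lesion reporting.
#'
#' @param partitioned Output of [partitionShared()] (needs `gene` and
#'   `partition` columns), or a list with character vectors
#'   `dysplasia_only`, `shared`, `scc_only` of gene symbols.
#' @param curated Character vector of gene symbols (non-empty; upper-cased
#'   for matching).
#' @return List with `counts` (named: dys_only, shared, scc_only) and
#'   `presence` (data.frame gene x partition flags).
#' @export
genesetTally <- function(partitioned, curated) {
  if (length(curated) == 0L) stop("curated gene list is empty")
  curated <- toupper(curated)
  if (is.data.frame(partitioned)) {
    sets <- split(toupper(partitioned$gene), partitioned$partition)
    sets <- lapply(c(dysplasia_only = "dysplasia_only", shared = "shared",
                     scc_only = "scc_only"),
                   function(k) unique(sets[[k]]))
    sets <- lapply(sets, function(x) if (is.null(x)) character() else x)
  } else {
    sets <- lapply(partitioned, function(x)
      unique(toupper(as.character(x))))
    if (is.null(names(sets)))
      names(sets) <- c("dysplasia_only", "shared", "scc_only")
  }
  hit <- lapply(sets, function(s) intersect(s, curated))
  # precedence shared > private for the counts
  dysOnly <- setdiff(hit$dysplasia_only, hit$shared)
  sccOnly <- setdiff(hit$scc_only, hit$shared)
  genes <- sort(unique(c(hit$dysplasia_only, hit$shared, hit$scc_only)))
  presence <- data.frame(
    gene = genes,
    dysplasia_only = genes %in% hit$dysplasia_only,
    shared = genes %in% hit$shared,
    scc_only = genes %in% hit$scc_only)
  list(counts = c(dys_only = length(dysOnly), shared = length(hit$shared),
                  scc_only = length(sccOnly)),
       presence = presence)
}

#' Compare shared-variant proportions between two variant sets
#'
#' Two-proportion chi-squared test (no continuity correction) of the
#' fraction of shared variants in one set against another, e.g. a curated
#' gene-list tally against the full filtered list.
#'
#' @param shared1,total1 Shared and total counts of the first set.
#' @param shared2,total2 Counts of the second set.
#' @return The two-sided p-value.
#' @export
#' @examples
#' compareSharedProportions(50, 100, 50, 100) # identical proportions: p = 1
compareSharedProportions <- function(shared1, total1, shared2, total2) {
  stopifnot(total1 > 0, total2 > 0, shared1 <= total1, shared2 <= total2)
  suppressWarnings(stats::prop.test(c(shared1, shared2), c(total1, total2),
                                    correct = FALSE))$p.value
}
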