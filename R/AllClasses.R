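#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width mcols findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' SegmentProfile: one sample's segmented copy-number profile
#'
#' Holds the segmented, normalised copy-number ratios of a single sample
#' (ratio 1.0 = diploid baseline) together with its tumour cell content
#' (purity). Segments live in a [GenomicRanges::GRanges] with a `ratio`
#' metadata column; coordinates are 1-based inclusive as in SEG files.
#' Sex-chromosome segments are kept but excluded from all autosomal
#' statistics (see [autosomalSegments()]).
#'
#' @slot sampleId Sample identifier.
#' @slot segments `GRanges` with numeric metadata column `ratio` (> 0);
#'   segments must not overlap within a chromosome.
#' @slot purity Tumour cell fraction in (0, 1].
#' @export
setClass("SegmentProfile",
  representation(sampleId = "character", segments = "GRanges",
                 purity = "numeric"))

setValidity("SegmentProfile", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L || is.na(object@sampleId))
    msg <- c(msg, "sampleId must be a single non-NA string")
  if (length(object@purity) != 1L || is.na(object@purity) ||
      object@purity <= 0 || object@purity > 1)
    msg <- c(msg, "purity must be a single value in (0, 1]")
  seg <- object@segments
  if (!("ratio" %in% colnames(S4Vectors::mcols(seg))))
    msg <- c(msg, "segments must carry a 'ratio' metadata column")
  else {
    r <- S4Vectors::mcols(seg)$ratio
    if (any(!is.finite(r)) || any(r <= 0))
      msg <- c(msg, "all segment ratios must be finite and > 0")
  }
  if (length(seg) > 1L) {
    ov <- GenomicRanges::findOverlaps(seg, drop.self = TRUE,
                                      drop.redundant = TRUE)
    if (length(ov) > 0L)
      msg <- c(msg, sprintf("segments overlap (e.g. segment %d and %d)",
                            S4Vectors::queryHits(ov)[1L],
                            S4Vectors::subjectHits(ov)[1L]))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SegmentProfile
#'
#' @param sampleId Sample identifier.
#' @param segments A `GRanges` with a `ratio` metadata column, or a
#'   data.frame with columns `chrom`, `start`, `end`, `ratio`
#'   (1-based inclusive coordinates).
#' @param purity Tumour cell fraction in (0, 1].
#' @return A [SegmentProfile-class] object.
#' @export
#' @examples
#' seg <- data.frame(chrom = c("1", "8"), start = c(1, 1),
#'                   end = c(5e7, 1e8), ratio = c(1.0, 1.3))
#' SegmentProfile("S1", seg, purity = 0.8)
SegmentProfile <- function(sampleId, segments, purity) {
  if (is.data.frame(segments)) {
    if (any(segments$end < segments$start))
      stop("segment end < start at row ", which(segments$end < segments$start)[1L])
    segments <- GenomicRanges::GRanges(
      seqnames = normChrom(segments$chrom),
      ranges = IRanges::IRanges(start = segments$start, end = segments$end),
      ratio = segments$ratio)
  }
  new("SegmentProfile", sampleId = as.character(sampleId),
      segments = segments, purity = as.numeric(purity))
}

#' @describeIn SegmentProfile-class sample identifier
#' @param object,x A `SegmentProfile`.
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @export
setMethod("sampleId", "SegmentProfile", function(object) object@sampleId)

#' @describeIn SegmentProfile-class tumour cell fraction
#' @export
setGeneric("purity", function(object) standardGeneric("purity"))
#' @export
setMethod("purity", "SegmentProfile", function(object) object@purity)

#' @describeIn SegmentProfile-class all segments (including sex chromosomes)
#' @export
setGeneric("segments", function(object) standardGeneric("segments"))
#' @export
setMethod("segments", "SegmentProfile", function(object) object@segments)

#' Autosomal segments of a profile
#'
#' @param object A [SegmentProfile-class].
#' @return `GRanges` restricted to chr1-22.
#' @export
autosomalSegments <- function(object) {
  seg <- segments(object)
  seg[isAutosome(GenomicRanges::seqnames(seg))]
}

setMethod("show", "SegmentProfile", function(object) {
  seg <- object@segments
  cat("SegmentProfile '", object@sampleId, "': ", length(seg),
      " segments, purity ", format(object@purity), "\n", sep = "")
  n.sex <- sum(!isAutosome(GenomicRanges::seqnames(seg)))
  if (n.sex > 0) cat("  (", n.sex, " non-autosomal segments flagged)\n", sep = "")
})

#' CNEventTrack: binned gain/neutral/loss calls over the autosomes
#'
#' Per-bin three-level copy-number calls on a fixed grid tiling the
#' autosomes, plus the set of named recurrent regions hit.
#'
#' @slot sampleId Sample identifier.
#' @slot bins `GRanges` tiling chr1-22 with metadata column `call`, a factor
#'   with levels `loss`, `neutral`, `gain`.
#' @slot binSize Bin width in bases (last bin of each chromosome may be
#'   shorter).
#' @slot nUncovered Number of bins not covered by any segment (called
#'   neutral).
#' @export
setClass("CNEventTrack",
  representation(sampleId = "character", bins = "GRanges",
                 binSize = "numeric", nUncovered = "integer"))

setValidity("CNEventTrack", function(object) {
  calls <- S4Vectors::mcols(object@bins)$call
  if (is.null(calls)) return("bins must carry a 'call' metadata column")
  if (!is.factor(calls) ||
      !identical(levels(calls), c("loss", "neutral", "gain")))
    return("call must be a factor with levels loss, neutral, gain")
  TRUE
})

#' @describeIn CNEventTrack-class the binned call track
#' @param object A `CNEventTrack`.
#' @export
setGeneric("bins", function(object) standardGeneric("bins"))
#' @export
setMethod("bins", "CNEventTrack", function(object) object@bins)
#' @export
setMethod("sampleId", "CNEventTrack", function(object) object@sampleId)

#' Per-bin calls of a track as a factor vector
#' @param object A [CNEventTrack-class].
#' @export
binCalls <- function(object) S4Vectors::mcols(bins(object))$call

setMethod("show", "CNEventTrack", function(object) {
  calls <- binCalls(object)
  cat("CNEventTrack '", object@sampleId, "': ", length(calls), " bins of ",
      format(object@binSize, scientific = FALSE), " bp; ",
      sum(calls == "gain"), " gain / ", sum(calls == "loss"), " loss\n",
      sep = "")
})

#' LesionPair: a patient's paired dysplasia and carcinoma samples
#'
#' Binds a patient's dysplasia and SCC samples: metadata (dysplasia grade,
#' FFPE block adjacency), the paired somatic mutation table, and the two
#' copy-number profiles.
#'
#' The mutation table is a data.frame with one row per somatic call and
#' columns `chrom`, `pos`, `ref`, `alt`, `dys_alt`, `dys_depth`, `scc_alt`,
#' `scc_depth`, `somatic_score`, `consequence` (comma-separated terms),
#' `sift`, `polyphen`, `gene`, `substitution_class`. Extra columns are
#' preserved.
#'
#' @slot patientId Patient identifier.
#' @slot dysplasiaId,sccId Sample identifiers (distinct).
#' @slot grade `"LGD"`, `"HGD"` or `NA`.
#' @slot adjacency `"same_block"` or `"different_block"`.
#' @slot mutations Paired mutation table (may be NULL).
#' @slot dysProfile,sccProfile [SegmentProfile-class] objects (may be NULL).
#' @export
setClass("LesionPair",
  representation(patientId = "character", dysplasiaId = "character",
                 sccId = "character", grade = "character",
                 adjacency = "character", mutations = "data.frameOrNULL",
                 dysProfile = "ANY", sccProfile = "ANY"))

setValidity("LesionPair", function(object) {
  msg <- character()
  if (identical(object@dysplasiaId, object@sccId))
    msg <- c(msg, "dysplasia and SCC sample ids must be distinct")
  if (!is.na(object@grade) && !object@grade %in% c("LGD", "HGD"))
    msg <- c(msg, "grade must be LGD, HGD or NA")
  if (!object@adjacency %in% c("same_block", "different_block"))
    msg <- c(msg, "adjacency must be same_block or different_block")
  for (slot in c("dysProfile", "sccProfile")) {
    p <- slot(object, slot)
    if (!is.null(p) && !is(p, "SegmentProfile"))
      msg <- c(msg, paste(slot, "must be a SegmentProfile or NULL"))
  }
  mut <- object@mutations
  if (!is.null(mut)) {
    need <- c("chrom", "pos", "ref", "alt", "dys_alt", "dys_depth",
              "scc_alt", "scc_depth", "somatic_score")
    miss <- setdiff(need, names(mut))
    if (length(miss))
      msg <- c(msg, paste("mutation table missing columns:",
                          paste(miss, collapse = ", ")))
    else if (any(mut$dys_alt > mut$dys_depth | mut$scc_alt > mut$scc_depth))
      msg <- c(msg, "alt reads exceed depth in mutation table")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LesionPair
#'
#' @param patientId,dysplasiaId,sccId Identifiers.
#' @param grade Dysplasia grade, `"LGD"`, `"HGD"` or `NA`.
#' @param adjacency `"same_block"` or `"different_block"`.
#' @param mutations Paired mutation table (see [LesionPair-class]) or NULL.
#' @param dysProfile,sccProfile [SegmentProfile-class] objects or NULL.
#' @return A [LesionPair-class].
#' @export
LesionPair <- function(patientId, dysplasiaId, sccId, grade = NA_character_,
                       adjacency = "same_block", mutations = NULL,
                       dysProfile = NULL, sccProfile = NULL) {
  new("LesionPair", patientId = as.character(patientId),
      dysplasiaId = as.character(dysplasiaId), sccId = as.character(sccId),
      grade = as.character(grade), adjacency = adjacency,
      mutations = mutations, dysProfile = dysProfile, sccProfile = sccProfile)
}

#' @describeIn LesionPair-class patient identifier
#' @param object A `LesionPair`.
#' @export
setGeneric("patientId", function(object) standardGeneric("patientId"))
#' @export
setMethod("patientId", "LesionPair", function(object) object@patientId)

#' @describeIn LesionPair-class the paired mutation table
#' @export
setGeneric("mutations", function(object) standardGeneric("mutations"))
#' @export
setMethod("mutations", "LesionPair", function(object) object@mutations)

#' Accessors for the two profiles of a pair
#' @param object A [LesionPair-class].
#' @export
dysProfile <- function(object) object@dysProfile
#' @rdname dysProfile
#' @export
sccProfile <- function(object) object@sccProfile
#' @rdname dysProfile
#' @export
pairGrade <- function(object) object@grade
#' @rdname dysProfile
#' @export
pairAdjacency <- function(object) object@adjacency
#' @rdname dysProfile
#' @export
dysplasiaId <- function(object) object@dysplasiaId
#' @rdname dysProfile
#' @export
sccId <- function(object) object@sccId

setMethod("show", "LesionPair", function(object) {
  cat("LesionPair patient '", object@patientId, "': dysplasia '",
      object@dysplasiaId, "' (", object@grade, ", ", object@adjacency,
      ") vs SCC '", object@sccId, "'\n", sep = "")
  if (!is.null(object@mutations))
    cat("  ", nrow(object@mutations), " somatic calls\n", sep = "")
  if (!is.null(object@dysProfile)) cat("  CN profiles attached\n")
})

#' NeutralityFit: result of the 1/f neutral-evolution fit
#'
#' Ordinary least-squares fit of the cumulative mutation count M(f) against
#' 1/f over the subclonal VAF window, with the derived effective mutation
#' rate and the neutrality call.
#'
#' @slot slope Mutations per unit 1/f (the gradient).
#' @slot intercept Mutations.
#' @slot rSquared Coefficient of determination of the with-intercept OLS.
#' @slot nWindow Number of mutations inside the VAF window.
#' @slot muEff Mutations per base per effective cell division, `slope / L`.
#' @slot neutral `TRUE` if `rSquared > 0.98`; `NA` when insufficient.
#' @slot status `"ok"` or `"insufficient"`.
#' @slot window The VAF window used (length 2).
#' @slot L Callable genome size in bases used for the rate.
#' @export
setClass("NeutralityFit",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", nWindow = "integer", muEff = "numeric",
                 neutral = "logical", status = "character",
                 window = "numeric", L = "numeric"))

setValidity("NeutralityFit", function(object) {
  msg <- character()
  if (!object@status %in% c("ok", "insufficient"))
    msg <- c(msg, "status must be 'ok' or 'insufficient'")
  if (object@status == "ok") {
    if (!is.finite(object@rSquared) ||
        object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12)
      msg <- c(msg, "rSquared must lie in [0, 1]")
    if (abs(object@muEff - object@slope / object@L) > 1e-12 * abs(object@slope))
      msg <- c(msg, "muEff must equal slope / L")
    if (is.na(object@neutral))
      msg <- c(msg, "neutral flag must be defined when status is 'ok'")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn NeutralityFit-class is the sample called neutral? (`NA` when
#'   the window held fewer than `nMin` mutations)
#' @param object A `NeutralityFit`.
#' @export
setGeneric("isNeutral", function(object) standardGeneric("isNeutral"))
#' @export
setMethod("isNeutral", "NeutralityFit", function(object) object@neutral)

#' @describeIn NeutralityFit-class effective mutation rate, slope / L
#' @export
setGeneric("muEff", function(object) standardGeneric("muEff"))
#' @export
setMethod("muEff", "NeutralityFit", function(object) object@muEff)

#' @describeIn NeutralityFit-class R-squared of the M(f) ~ 1/f fit
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))
#' @export
setMethod("rSquared", "NeutralityFit", function(object) object@rSquared)

setMethod("show", "NeutralityFit", function(object) {
  if (object@status == "insufficient") {
    cat("NeutralityFit: insufficient (", object@nWindow,
        " mutations in window)\n", sep = "")
  } else {
    cat("NeutralityFit: n=", object@nWindow, ", slope=",
        signif(object@slope, 5), ", R2=", signif(object@rSquared, 5),
        ", mu_eff=", signif(object@muEff, 4), " /base/division, ",
        if (object@neutral) "neutral" else "non-neutral", "\n", sep = "")
  }
})

#' ExpectedRates: expected per-group event rates for the frequency test
#'
#' Expected event rates per sample group, taken from each group's overall
#' fraction of genome altered, together with group sizes. Defaults are the
#' cohort values for LGD, HGD and SCC: rates 0.12, 0.38, 0.30 with sizes
#' 38, 69 and 149.
#'
#' @slot groups Group labels.
#' @slot rates Expected per-sample event rates in [0, 1].
#' @slot sizes Positive integer group sizes.
#' @export
setClass("ExpectedRates",
  representation(groups = "character", rates = "numeric", sizes = "integer"))

setValidity("ExpectedRates", function(object) {
  msg <- character()
  n <- length(object@groups)
  if (length(object@rates) != n || length(object@sizes) != n)
    msg <- c(msg, "groups, rates and sizes must have equal length")
  if (any(object@rates < 0 | object@rates > 1))
    msg <- c(msg, "rates must lie in [0, 1]")
  if (any(object@sizes <= 0L))
    msg <- c(msg, "sizes must be positive integers")
  if (length(msg)) msg else TRUE
})

#' @rdname ExpectedRates-class
#' @param groups,rates,sizes Group labels, expected rates, group sizes.
#' @export
#' @examples
#' ExpectedRates() # the LGD/HGD/SCC cohort defaults
ExpectedRates <- function(groups = c("LGD", "HGD", "SCC"),
                          rates = c(0.12, 0.38, 0.30),
                          sizes = c(38L, 69L, 149L)) {
  new("ExpectedRates", groups = groups, rates = as.numeric(rates),
      sizes = as.integer(sizes))
}

setMethod("show", "ExpectedRates", function(object) {
  cat("ExpectedRates:", paste(sprintf("%s %.2f (n=%d)", object@groups,
                                      object@rates, object@sizes),
                              collapse = ", "), "\n")
})
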