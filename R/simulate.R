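#' SimulationConfig: generative parameters for a synthetic lesion pair
#'
#' Parameters of the synthetic tumour-evolution generator. Defaults describe
#' the study conditions the pipeline expects: an effective mutation rate of
#' 5e-6 mutations per base per effective division over a 30-Mb callable
#' exome, subclonal allele fractions supported on [0.12, 0.24] (the fit
#' window), 125x mean sequencing depth, tumour purities of 0.8, and a
#' handful of FFPE artifact calls per lesion.
#'
#' @slot muEff Mutations per base per effective cell division.
#' @slot L Callable genome size in bases.
#' @slot fMin,fMax Subclonal allele-fraction support, 0 < fMin <= fMax <= 0.5
#'   (pre-purity scale; the clonal level is 0.5).
#' @slot depthMean Mean sequencing depth.
#' @slot purity Named numeric of length 2 (`dys`, `scc`), each in (0, 1].
#' @slot clonalCount Number of fully clonal mutations (allele fraction 0.5).
#' @slot subcloneF,subcloneK Optional selected subclone: `subcloneK` extra
#'   mutations at allele fraction `subcloneF` (0 disables), injected into
#'   the dysplasia private pool.
#' @slot ffpeRate Expected number of independent FFPE artifact calls per
#'   lesion.
#' @slot mixing Named numeric of length 2: per-lesion weight applied to the
#'   shared subclonal pool's allele fractions.
#' @slot sharedFrac Fraction of the subclonal Poisson intensity assigned to
#'   the shared pool; each lesion's private pool gets `1 - sharedFrac`.
#' @slot jitterSd SD of the jitter applied to injected subclone fractions.
#' @slot cnClass Copy-number pair-relationship class to generate (1-4).
#' @slot grade,adjacency Metadata for the generated pair.
#' @slot seed Integer seed; every draw in [simulatePair()] is a function of
#'   it (no global RNG state is consumed).
#' @export
setClass("SimulationConfig",
  representation(muEff = "numeric", L = "numeric", fMin = "numeric",
                 fMax = "numeric", depthMean = "numeric", purity = "numeric",
                 clonalCount = "integer", subcloneF = "numeric",
                 subcloneK = "integer", ffpeRate = "numeric",
                 mixing = "numeric", sharedFrac = "numeric",
                 jitterSd = "numeric", cnClass = "integer",
                 grade = "character", adjacency = "character",
                 seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@muEff <= 0) msg <- c(msg, "muEff must be > 0")
  if (object@L <= 0) msg <- c(msg, "L must be > 0")
  if (!(object@fMin > 0 && object@fMin <= object@fMax && object@fMax <= 0.5))
    msg <- c(msg, "need 0 < fMin <= fMax <= 0.5")
  if (object@depthMean <= 0) msg <- c(msg, "depthMean must be > 0")
  if (length(object@purity) != 2L || any(object@purity <= 0 | object@purity > 1))
    msg <- c(msg, "purity must be two values in (0, 1]")
  if (object@clonalCount < 0L || object@subcloneK < 0L || object@ffpeRate < 0)
    msg <- c(msg, "counts and rates must be >= 0")
  if (object@subcloneK > 0L &&
      !(object@subcloneF > 0 && object@subcloneF <= 0.5))
    msg <- c(msg, "subcloneF must lie in (0, 0.5]")
  if (length(object@mixing) != 2L || any(object@mixing < 0 | object@mixing > 1))
    msg <- c(msg, "mixing must be two weights in [0, 1]")
  if (object@sharedFrac < 0 || object@sharedFrac > 1)
    msg <- c(msg, "sharedFrac must lie in [0, 1]")
  if (!object@cnClass %in% 1:4) msg <- c(msg, "cnClass must be 1, 2, 3 or 4")
  if (length(msg)) msg else TRUE
})

#' @rdname SimulationConfig-class
#' @param muEff,L,fMin,fMax,depthMean,purity,clonalCount,subcloneF,subcloneK
#'   See slots.
#' @param ffpeRate,mixing,sharedFrac,jitterSd,cnClass,grade,adjacency,seed
#'   See slots.
#' @export
#' @examples
#' cfg <- simulationConfig(seed = 7, cnClass = 2)
#' pair <- simulatePair(cfg)
simulationConfig <- function(muEff = 5e-6, L = 3e7, fMin = 0.12, fMax = 0.24,
                             depthMean = 125, purity = c(dys = 0.8, scc = 0.8),
                             clonalCount = 60L, subcloneF = 0, subcloneK = 0L,
                             ffpeRate = 30, mixing = c(dys = 1, scc = 1),
                             sharedFrac = 0.5, jitterSd = 0.01, cnClass = 1L,
                             grade = "HGD", adjacency = "same_block",
                             seed = 1L) {
  if (length(purity) == 1L) purity <- c(dys = purity, scc = purity)
  if (length(mixing) == 1L) mixing <- c(dys = mixing, scc = mixing)
  names(purity) <- names(mixing) <- c("dys", "scc")
  new("SimulationConfig", muEff = muEff, L = L, fMin = fMin, fMax = fMax,
      depthMean = depthMean, purity = purity,
      clonalCount = as.integer(clonalCount), subcloneF = subcloneF,
      subcloneK = as.integer(subcloneK), ffpeRate = ffpeRate,
      mixing = mixing, sharedFrac = sharedFrac, jitterSd = jitterSd,
      cnClass = as.integer(cnClass), grade = grade, adjacency = adjacency,
      seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: mu_eff=", object@muEff, ", L=", object@L,
      ", f in [", object@fMin, ",", object@fMax, "], depth ",
      object@depthMean, "x, class ", object@cnClass, ", seed ",
      object@seed, "\n", sep = "")
})

#' Draw allele fractions from a neutral 1/f^2 subclonal spectrum
#'
#' Under neutral growth the cumulative count of subclonal mutations with
#' allele fraction >= f is linear in 1/f:
#' `M(f) = muEff * L * (1/f - 1/fMax)`. This generator inverts that model:
#' the number of subclonal mutations is
#' `N ~ Poisson(muEff * L * (1/fMin - 1/fMax))` and each fraction is drawn
#' by inverse-CDF sampling from the density proportional to 1/f^2 on
#' `[fMin, fMax]`. `clonalCount` fully clonal fractions at 0.5 are appended.
#'
#' @param config A [SimulationConfig-class]; alternatively pass the
#'   individual parameters.
#' @param muEff,L,fMin,fMax,clonalCount Override or replace `config`.
#' @param seed Optional integer; when given, draws are made under this seed
#'   without touching the global RNG state.
#' @return Numeric vector of true allele fractions in
#'   `[fMin, fMax]` plus `clonalCount` values at 0.5.
#' @export
#' @examples
#' f <- sampleNeutralVafs(muEff = 5e-6, L = 3e7, fMin = 0.12, fMax = 0.24,
#'                        clonalCount = 0, seed = 1)
#' length(f) # ~ Poisson with mean 150 * (1/0.12 - 1/0.24) = 625
sampleNeutralVafs <- function(config = NULL, muEff = 5e-6, L = 3e7,
                              fMin = 0.12, fMax = 0.24, clonalCount = 0L,
                              seed = NULL) {
  if (!is.null(config)) {
    muEff <- config@muEff; L <- config@L; fMin <- config@fMin
    fMax <- config@fMax; clonalCount <- config@clonalCount
    if (is.null(seed)) seed <- config@seed
  }
  if (fMin <= 0) stop("fMin must be > 0")
  if (fMax < fMin || fMax > 0.5) stop("need fMin <= fMax <= 0.5")
  draw <- function() {
    lambda <- muEff * L * (1 / fMin - 1 / fMax)
    n <- stats::rpois(1L, lambda)
    u <- stats::runif(n)
    f <- 1 / (1 / fMin - u * (1 / fMin - 1 / fMax))
    c(f, rep(0.5, clonalCount))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Inject a selected subclone into an allele-fraction draw
#'
#' Selection shows up in a VAF spectrum as an extra cluster of mutations at
#' the subclone's frequency; this appends `k` fractions at `fS` with
#' Gaussian jitter (SD `jitterSd`, truncated to (0, 0.5]).
#'
#' @param vafs Numeric vector of allele fractions.
#' @param fS Subclone allele fraction in (0, 0.5].
#' @param k Number of extra mutations (>= 0).
#' @param jitterSd Jitter SD; 0 appends exact copies of `fS`.
#' @param seed Optional integer seed (draws isolated from global state).
#' @return The augmented vector.
#' @export
injectSubclone <- function(vafs, fS, k, jitterSd = 0.01, seed = NULL) {
  stopifnot(k >= 0)
  if (k == 0) return(vafs)
  if (!(fS > 0 && fS <= 0.5)) stop("fS must lie in (0, 0.5]")
  draw <- function() fS + stats::rnorm(k, 0, jitterSd)
  extra <- if (jitterSd == 0) rep(fS, k)
           else if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  extra <- pmin(pmax(extra, 1e-6), 0.5)
  c(vafs, extra)
}

#' Observe read counts for mutations under purity and copy number
#'
#' The expected observed VAF of a mutation carried on a single copy
#' (m = 1) by a fraction `cellFrac` of tumour cells is
#' `v = cellFrac * purity / localCn`: each tumour-cell chromosomal copy
#' contributes `purity / localCn` of the reads. Sequencing is emulated as
#' `depth ~ Poisson(depthMean)` (floored at 1) and
#' `alt ~ Binomial(depth, v)`.
#'
#' @param cellFrac Cellular frequencies (fraction of tumour cells carrying
#'   the mutation), recycled against the longest argument.
#' @param purity Tumour cell content in (0, 1].
#' @param localCn Local tumour copy number (>= 1), recycled.
#' @param depthMean Mean depth.
#' @param seed Optional integer seed (draws isolated from global state).
#' @return data.frame with columns `alt`, `depth`.
#' @export
#' @examples
#' # a fully clonal mutation in 50% of cells, purity 0.7, triploid region:
#' # expected VAF = 0.5 * 0.7 / 3 = 0.1167
#' r <- observeReads(0.5, 0.7, 3, depthMean = 1e5, seed = 1)
#' r$alt / r$depth
observeReads <- function(cellFrac, purity, localCn, depthMean = 125,
                         seed = NULL) {
  stopifnot(depthMean > 0, all(localCn >= 1), all(purity > 0 & purity <= 1))
  n <- max(length(cellFrac), length(localCn))
  cellFrac <- rep_len(cellFrac, n); localCn <- rep_len(localCn, n)
  v <- pmin(cellFrac * purity / localCn, 1)
  draw <- function() {
    depth <- pmax(stats::rpois(n, depthMean), 1L)
    alt <- stats::rbinom(n, depth, v)
    data.frame(alt = alt, depth = depth)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

CONSEQUENCE_POOL <- c(missense_variant = 0.45, synonymous_variant = 0.30,
                      stop_gained = 0.05, splice_region_variant = 0.05,
                      frameshift_variant = 0.05, intron_variant = 0.10)

SUBSTITUTION_SPECTRUM <- c(`C>A` = 0.15, `C>G` = 0.10, `C>T` = 0.35,
                           `T>A` = 0.10, `T>C` = 0.20, `T>G` = 0.10)

#' @keywords internal
randomPositions <- function(n) {
  len <- hg19Autosomes()
  chrom <- sample(names(len), n, replace = TRUE, prob = len / sum(len))
  pos <- floor(stats::runif(n) * len[chrom]) + 1
  data.frame(chrom = chrom, pos = as.integer(pos))
}

#' @keywords internal
annotateCalls <- function(n) {
  cls <- sample(names(SUBSTITUTION_SPECTRUM), n, replace = TRUE,
                prob = SUBSTITUTION_SPECTRUM)
  ref <- substr(cls, 1L, 1L)
  alt <- substr(cls, 3L, 3L)
  cons <- sample(names(CONSEQUENCE_POOL), n, replace = TRUE,
                 prob = CONSEQUENCE_POOL)
  mis <- cons == "missense_variant"
  sift <- ifelse(mis, sample(c("deleterious", "tolerated"), n, TRUE,
                             prob = c(0.4, 0.6)), NA)
  poly <- ifelse(mis, sample(c("probably_damaging", "possibly_damaging",
                               "benign"), n, TRUE, prob = c(0.25, 0.2, 0.55)),
                 NA)
  gene <- sprintf("GENE%04d", sample.int(400L, n, replace = TRUE))
  data.frame(ref = ref, alt = alt, consequence = cons, sift = sift,
             polyphen = poly, gene = gene, stringsAsFactors = FALSE)
}

#' @keywords internal
simulateCnProfiles <- function(cnClass, purity) {
  cat <- cnEventCatalogue()
  pick <- function(idx) cat[idx]
  k <- length(cat)
  ord <- sample.int(k)
  events <- switch(cnClass,
    `1` = list(dys = ord[1:3], scc = ord[c(1:2, 4)]),   # 2 shared + 1 unique each
    `2` = list(dys = ord[1:3], scc = ord[1:3]),
    `3` = list(dys = ord[1L], scc = ord[1:3]),
    `4` = list(dys = integer(), scc = integer()))
  build <- function(idx, sid, pur) {
    si <- autosomeSeqinfo()
    genome <- GenomicRanges::GRanges(
      seqnames = GenomeInfoDb::seqnames(si),
      ranges = IRanges::IRanges(1, GenomeInfoDb::seqlengths(si)),
      seqinfo = si)
    ev <- cat[idx]
    base <- GenomicRanges::setdiff(genome, ev)
    S4Vectors::mcols(base)$ratio <- 1.0
    dirn <- S4Vectors::mcols(ev)$direction
    S4Vectors::mcols(ev) <- NULL
    S4Vectors::mcols(ev)$ratio <- as.numeric(ifelse(dirn == "gain", 1.3, 0.7))
    seg <- sort(c(base, ev))
    SegmentProfile(sid, seg, pur)
  }
  list(dys = build(events$dys, "dys", purity[["dys"]]),
       scc = build(events$scc, "scc", purity[["scc"]]),
       eventIdx = events)
}

#' @keywords internal
localCnAt <- function(profile, chrom, pos) {
  q <- GenomicRanges::GRanges(normChrom(chrom), IRanges::IRanges(pos, pos))
  seg <- segments(profile)
  GenomeInfoDb::seqlevels(q) <-
    union(GenomeInfoDb::seqlevels(q), GenomeInfoDb::seqlevels(seg))
  hit <- GenomicRanges::findOverlaps(q, seg, select = "first")
  ratio <- S4Vectors::mcols(seg)$ratio[hit]
  cn <- ifelse(is.na(ratio), 2L, pmin(pmax(round(2 * ratio), 1), 8))
  as.integer(cn)
}

#' Simulate one paired dysplasia/SCC lesion
#'
#' Generates a [LesionPair-class] with the statistical structure the
#' analysis assumes. Mutations come from three pools sharing a common
#' ancestor: (i) clonal mutations at allele fraction 0.5 in both lesions;
#' (ii) a shared subclonal pool (same positions in both lesions,
#' per-lesion allele fraction = pool fraction x the lesion's `mixing`
#' weight, emulating spatially mixed subclones); (iii) private neutral
#' pools per lesion. An optional selected subclone (`subcloneK` mutations
#' at `subcloneF`) is injected into the dysplasia private pool. Independent
#' low-VAF C>T FFPE artifact calls are appended per lesion. Read counts
#' follow [observeReads()] with the lesion's purity and the local copy
#' number from its simulated profile; copy-number profiles are drawn from
#' the recurrent-event catalogue according to `cnClass` (see
#' [classifyPair()]).
#'
#' The mutation table carries a `sim_pool` column recording each call's
#' generating pool (clonal, shared_subclonal, private_dys, private_scc,
#' subclone_dys, ffpe_dys, ffpe_scc).
#'
#' @param config A [SimulationConfig-class].
#' @return A [LesionPair-class] with mutation table and both profiles.
#' @export
simulatePair <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  withr::with_seed(config@seed, {
    prof <- simulateCnProfiles(config@cnClass, config@purity)
    lambda <- config@muEff * config@L * (1 / config@fMin - 1 / config@fMax)
    drawPool <- function(intensity) {
      n <- stats::rpois(1L, intensity)
      u <- stats::runif(n)
      1 / (1 / config@fMin - u * (1 / config@fMin - 1 / config@fMax))
    }
    fShared <- drawPool(config@sharedFrac * lambda)
    fPrivD <- drawPool((1 - config@sharedFrac) * lambda)
    fPrivS <- drawPool((1 - config@sharedFrac) * lambda)
    if (config@subcloneK > 0L)
      fPrivD <- injectSubclone(fPrivD, config@subcloneF, config@subcloneK,
                               config@jitterSd)
    pools <- data.frame(
      f = c(rep(0.5, config@clonalCount), fShared, fPrivD, fPrivS),
      pool = c(rep("clonal", config@clonalCount),
               rep("shared_subclonal", length(fShared)),
               c(rep("private_dys",
                     length(fPrivD) - min(config@subcloneK, length(fPrivD))),
                 rep("subclone_dys", min(config@subcloneK, length(fPrivD)))),
               rep("private_scc", length(fPrivS))))
    n <- nrow(pools)
    loc <- randomPositions(n)
    ann <- annotateCalls(n)
    # cellular fraction per lesion: c = 2f (single mutated copy of two in a
    # diploid ancestor), shared pool weighted by per-lesion mixing
    cD <- with(pools, ifelse(pool == "clonal", 1,
            ifelse(pool == "shared_subclonal",
                   pmin(2 * f * config@mixing[["dys"]], 1),
            ifelse(pool %in% c("private_dys", "subclone_dys"),
                   pmin(2 * f, 1), 0))))
    cS <- with(pools, ifelse(pool == "clonal", 1,
            ifelse(pool == "shared_subclonal",
                   pmin(2 * f * config@mixing[["scc"]], 1),
            ifelse(pool == "private_scc", pmin(2 * f, 1), 0))))
    cnD <- localCnAt(prof$dys, loc$chrom, loc$pos)
    cnS <- localCnAt(prof$scc, loc$chrom, loc$pos)
    rd <- observeReads(cD, config@purity[["dys"]], cnD, config@depthMean)
    rs <- observeReads(cS, config@purity[["scc"]], cnS, config@depthMean)
    score <- stats::runif(n, 20, 80)
    tab <- data.frame(chrom = loc$chrom, pos = loc$pos, ref = ann$ref,
                      alt = ann$alt, dys_alt = rd$alt, dys_depth = rd$depth,
                      scc_alt = rs$alt, scc_depth = rs$depth,
                      somatic_score = round(score, 2),
                      consequence = ann$consequence, sift = ann$sift,
                      polyphen = ann$polyphen, gene = ann$gene,
                      sim_pool = pools$pool, stringsAsFactors = FALSE)
    # independent FFPE artifact calls, C>T at observed VAF <= 0.1
    ffpe <- function(lesion) {
      nf <- stats::rpois(1L, config@ffpeRate)
      if (nf == 0L) return(NULL)
      locF <- randomPositions(nf)
      depth <- pmax(stats::rpois(nf, config@depthMean), 1L)
      vObs <- stats::runif(nf, 0, 0.1)
      alt <- pmax(stats::rbinom(nf, depth, vObs), 1L)
      other <- pmax(stats::rpois(nf, config@depthMean), 1L)
      out <- data.frame(chrom = locF$chrom, pos = locF$pos, ref = "C",
                        alt = "T",
                        dys_alt = if (lesion == "dys") alt else 0L,
                        dys_depth = if (lesion == "dys") depth else other,
                        scc_alt = if (lesion == "scc") alt else 0L,
                        scc_depth = if (lesion == "scc") depth else other,
                        somatic_score = round(stats::runif(nf, 5, 15), 2),
                        consequence = "synonymous_variant",
                        sift = NA_character_, polyphen = NA_character_,
                        gene = sprintf("GENE%04d",
                                       sample.int(400L, nf, replace = TRUE)),
                        sim_pool = paste0("ffpe_", lesion),
                        stringsAsFactors = FALSE)
      out
    }
    tab <- rbind(tab, ffpe("dys"), ffpe("scc"))
    tab <- tab[!duplicated(tab[, c("chrom", "pos")]), , drop = FALSE]
    tab <- tab[order(suppressWarnings(as.integer(tab$chrom)), tab$pos), ,
               drop = FALSE]
    rownames(tab) <- NULL
    tab$substitution_class <- substitutionClass(tab$ref, tab$alt)
    LesionPair(patientId = paste0("SIM", config@seed),
               dysplasiaId = paste0("SIM", config@seed, "_D"),
               sccId = paste0("SIM", config@seed, "_T"),
               grade = config@grade, adjacency = config@adjacency,
               mutations = tab,
               dysProfile = renameProfile(prof$dys,
                                          paste0("SIM", config@seed, "_D")),
               sccProfile = renameProfile(prof$scc,
                                          paste0("SIM", config@seed, "_T")))
  })
}

#' @keywords internal
renameProfile <- function(profile, sid) {
  profile@sampleId <- sid
  profile
}

#' Simulate and write a whole cohort
#'
#' Runs [simulatePair()] for each config and writes the exact formats the
#' readers consume: one SEG file + purity table for all samples,
#' `metadata.tsv`, and `mutations_<patient>.tsv` per patient. Fixed seeds
#' make the output byte-reproducible.
#'
#' @param configs List of [SimulationConfig-class] objects (seeds must give
#'   distinct sample ids).
#' @param dir Output directory (created).
#' @return Invisibly, the list of [LesionPair-class] objects written.
#' @export
simulateCohort <- function(configs, dir) {
  if (length(configs) < 1L) stop("need at least one pair config")
  pairs <- lapply(configs, simulatePair)
  ids <- unlist(lapply(pairs, function(p) c(dysplasiaId(p), sccId(p))))
  if (anyDuplicated(ids))
    stop("duplicate sample ids (reuse of seeds?): ",
         ids[duplicated(ids)][1L])
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  profiles <- unlist(lapply(pairs, function(p)
    list(dysProfile(p), sccProfile(p))), recursive = FALSE)
  names(profiles) <- vapply(profiles, sampleId, "")
  writeSegments(profiles, file.path(dir, "segments.tsv"),
                file.path(dir, "purity.tsv"))
  meta <- do.call(rbind, lapply(pairs, function(p) data.frame(
    patient = patientId(p),
    sample = c(dysplasiaId(p), sccId(p)),
    role = c("dysplasia", "scc"),
    grade = c(pairGrade(p), NA),
    block = if (pairAdjacency(p) == "same_block") "same" else "different")))
  writeTsv(meta, file.path(dir, "metadata.tsv"))
  for (p in pairs)
    writeMutations(mutations(p),
                   file.path(dir, paste0("mutations_", patientId(p), ".tsv")))
  invisible(pairs)
}
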