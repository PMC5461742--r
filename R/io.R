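#' Convert somatic p-values to somatic scores and back
#'
#' The somatic caller convention: `score = -10 * log10(p)`, so a somatic
#' p-value of 0.1 corresponds to score 10 and p = 0.05 to score ~13.
#'
#' @param p Somatic p-values in (0, 1].
#' @param score Somatic scores (>= 0).
#' @return Numeric vector of scores (resp. p-values).
#' @export
#' @examples
#' scoreFromP(0.1)  # 10
#' pFromScore(20)   # 0.01
scoreFromP <- function(p) {
  stopifnot(all(p > 0 & p <= 1))
  -10 * log10(p)
}

#' @rdname scoreFromP
#' @export
pFromScore <- function(score) 10^(-score / 10)

#' Pyrimidine-context substitution class
#'
#' Maps ref/alt alleles to one of the six pyrimidine-context single-base
#' substitution classes (C>A, C>G, C>T, T>A, T>C, T>G); purine references
#' are complemented. Multi-base or symbolic alleles are classed `"indel"`.
#'
#' @param ref,alt Character vectors of reference and alternate alleles.
#' @return Character vector of classes.
#' @export
#' @examples
#' substitutionClass(c("C", "G", "AT"), c("T", "A", "A"))
substitutionClass <- function(ref, alt) {
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- rep("indel", length(ref))
  snv <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% names(comp) & alt %in% names(comp) & ref != alt
  r <- ref[snv]; a <- alt[snv]
  flip <- r %in% c("A", "G")
  r[flip] <- comp[r[flip]]; a[flip] <- comp[a[flip]]
  out[snv] <- paste0(r, ">", a)
  out
}

#' Read segmented copy-number profiles with purities
#'
#' Reads a SEG-like TSV (columns `sample`, `chrom`, `start`, `end`, `ratio`;
#' 1-based inclusive coordinates) and a purity table (`sample`, `purity`)
#' and returns one [SegmentProfile-class] per sample. Invalid rows
#' (end <= start, overlapping segments) and samples without a purity entry
#' are rejected with an error naming the offending line or sample.
#'
#' @param segPath Path to the SEG-like TSV.
#' @param purityPath Path to the purity TSV.
#' @return Named list of [SegmentProfile-class] objects.
#' @export
readSegments <- function(segPath, purityPath) {
  tab <- utils::read.delim(segPath, colClasses = c(
    sample = "character", chrom = "character"))
  need <- c("sample", "chrom", "start", "end", "ratio")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("segment file missing columns: ", paste(miss, collapse = ", "))
  bad <- which(tab$end <= tab$start)
  if (length(bad))
    stop("segment end <= start at line ", bad[1L] + 1L, " of ", segPath)
  pur <- utils::read.delim(purityPath, colClasses = c(sample = "character"))
  if (!all(c("sample", "purity") %in% names(pur)))
    stop("purity file must have columns sample, purity")
  out <- list()
  for (sid in unique(tab$sample)) {
    p <- pur$purity[match(sid, pur$sample)]
    if (is.na(p)) stop("missing purity for sample '", sid, "'")
    sub <- tab[tab$sample == sid, , drop = FALSE]
    prof <- tryCatch(
      SegmentProfile(sid, sub[, c("chrom", "start", "end", "ratio")], p),
      error = function(e) stop("invalid segments for sample '", sid, "': ",
                               conditionMessage(e), call. = FALSE))
    out[[sid]] <- prof
  }
  out
}

#' Write segmented profiles back to SEG + purity TSVs
#'
#' Inverse of [readSegments()]: writing then reading reproduces identical
#' profiles (coordinates are 1-based inclusive in both directions).
#'
#' @param profiles List of [SegmentProfile-class] objects.
#' @param segPath,purityPath Output paths.
#' @return Invisibly, `segPath`.
#' @export
writeSegments <- function(profiles, segPath, purityPath) {
  rows <- lapply(profiles, function(p) {
    seg <- segments(p)
    data.frame(sample = sampleId(p),
               chrom = as.character(GenomicRanges::seqnames(seg)),
               start = GenomicRanges::start(seg),
               end = GenomicRanges::end(seg),
               ratio = S4Vectors::mcols(seg)$ratio)
  })
  writeTsv(do.call(rbind, rows), segPath)
  writeTsv(data.frame(sample = vapply(profiles, sampleId, ""),
                      purity = vapply(profiles, purity, 0)), purityPath)
  invisible(segPath)
}

MUTATION_COLUMNS <- c("chrom", "pos", "ref", "alt", "dys_alt", "dys_depth",
                      "scc_alt", "scc_depth", "somatic_score")

#' Read a paired somatic mutation table
#'
#' Reads a Varscan-style paired mutation table as TSV (or VCF, see
#' [readMutationsVcf()]). Required columns: `chrom`, `pos`, `ref`, `alt`,
#' per-lesion read support `dys_alt`, `dys_depth`, `scc_alt`, `scc_depth`,
#' and either `somatic_score` or `somatic_p` (converted via
#' [scoreFromP()]). Optional columns `consequence` (comma-separated terms,
#' preserved verbatim), `sift`, `polyphen`, `gene` and any extras are kept.
#' Records with alt reads exceeding depth are dropped with a warning. A
#' `substitution_class` column is derived from ref/alt.
#'
#' @param path Path to the TSV (or a `.vcf` file).
#' @param ... Passed to [readMutationsVcf()] for VCF input.
#' @return A mutation data.frame (see [LesionPair-class]).
#' @export
readMutations <- function(path, ...) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
    return(readMutationsVcf(path, ...))
  tab <- utils::read.delim(path, colClasses = c(chrom = "character"))
  if (!"somatic_score" %in% names(tab)) {
    if (!"somatic_p" %in% names(tab))
      stop("mutation table needs a somatic_score or somatic_p column")
    tab$somatic_score <- scoreFromP(tab$somatic_p)
    tab$somatic_p <- NULL
  }
  miss <- setdiff(MUTATION_COLUMNS, names(tab))
  if (length(miss))
    stop("mutation table missing columns: ", paste(miss, collapse = ", "))
  bad <- tab$dys_alt > tab$dys_depth | tab$scc_alt > tab$scc_depth
  if (any(bad)) {
    warning(sum(bad), " record(s) with alt reads > depth dropped")
    tab <- tab[!bad, , drop = FALSE]
  }
  for (col in c("consequence", "sift", "polyphen", "gene"))
    if (!col %in% names(tab)) tab[[col]] <- NA_character_
  tab$substitution_class <- substitutionClass(tab$ref, tab$alt)
  rownames(tab) <- NULL
  tab
}

#' Read a paired mutation table from a two-sample VCF
#'
#' Reads per-sample `AD` (ref,alt) and `DP` FORMAT fields for the dysplasia
#' and SCC samples, and the somatic score (`SSC`) or somatic p-value
#' (`SPV`) from INFO. Optional INFO keys `CSQ` (consequence terms,
#' `&`-separated), `SIFT`, `POLYPHEN` and `GENE` are carried through.
#'
#' @param path Path to an uncompressed or bgzipped VCF.
#' @param dysSample,sccSample Sample names in the VCF header.
#' @return A mutation data.frame as from [readMutations()].
#' @export
readMutationsVcf <- function(path, dysSample, sccSample) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  for (s in c(dysSample, sccSample))
    if (!s %in% colnames(ad)) stop("sample '", s, "' not in VCF")
  altOf <- function(x) as.integer(vapply(strsplit(x, ","), function(v)
    if (length(v) >= 2L) v[2L] else "0", ""))
  info1 <- function(key) {
    v <- vcfR::extract.info(vcf, element = key)
    if (is.null(v)) rep(NA_character_, nrow(fix)) else v
  }
  score <- suppressWarnings(as.numeric(info1("SSC")))
  spv <- suppressWarnings(as.numeric(info1("SPV")))
  if (all(is.na(score))) {
    if (all(is.na(spv))) stop("VCF carries neither SSC nor SPV")
    score <- scoreFromP(spv)
  }
  tab <- data.frame(
    chrom = normChrom(fix$CHROM), pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    dys_alt = altOf(ad[, dysSample]), dys_depth = as.integer(dp[, dysSample]),
    scc_alt = altOf(ad[, sccSample]), scc_depth = as.integer(dp[, sccSample]),
    somatic_score = score,
    consequence = gsub("&", ",", info1("CSQ")),
    sift = info1("SIFT"), polyphen = info1("POLYPHEN"),
    gene = info1("GENE"), stringsAsFactors = FALSE)
  bad <- tab$dys_alt > tab$dys_depth | tab$scc_alt > tab$scc_depth
  if (any(bad)) {
    warning(sum(bad), " record(s) with alt reads > depth dropped")
    tab <- tab[!bad, , drop = FALSE]
  }
  tab$substitution_class <- substitutionClass(tab$ref, tab$alt)
  rownames(tab) <- NULL
  tab
}

#' @rdname readMutations
#' @param tab A mutation data.frame.
#' @export
writeMutations <- function(tab, path) writeTsv(tab, path)

#' Read cohort sample metadata
#'
#' TSV columns: `patient`, `sample`, `role` (`dysplasia`|`scc`), `grade`
#' (`LGD`|`HGD`|`NA`), `block` (`same`|`different`).
#'
#' @param path Path to the metadata TSV.
#' @return data.frame.
#' @export
readMetadata <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character",
                           na.strings = c("NA", ""))
  need <- c("patient", "sample", "role", "grade", "block")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (!all(tab$role %in% c("dysplasia", "scc")))
    stop("metadata role must be 'dysplasia' or 'scc'")
  if (!all(is.na(tab$grade) | tab$grade %in% c("LGD", "HGD")))
    stop("metadata grade must be LGD, HGD or NA")
  if (!all(is.na(tab$block) | tab$block %in% c("same", "different")))
    stop("metadata block must be 'same' or 'different'")
  tab
}

#' Read a curated gene list
#'
#' One symbol per line; `#` starts a comment; symbols are upper-cased.
#'
#' @param path Path to the list.
#' @return Character vector of gene symbols.
#' @export
readGeneList <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  toupper(lines[nzchar(lines)])
}

#' Assemble LesionPair objects from cohort files
#'
#' Combines metadata, segment profiles and per-patient mutation tables
#' (files named `mutations_<patient>.tsv` in `mutationDir`) into a list of
#' [LesionPair-class] objects.
#'
#' @param metadataPath,segPath,purityPath,mutationDir Paths as written by
#'   [simulateCohort()] or prepared by hand.
#' @return Named list of [LesionPair-class], one per patient.
#' @export
loadCohort <- function(metadataPath, segPath, purityPath, mutationDir) {
  meta <- readMetadata(metadataPath)
  profiles <- readSegments(segPath, purityPath)
  out <- list()
  for (pid in unique(meta$patient)) {
    sub <- meta[meta$patient == pid, , drop = FALSE]
    dys <- sub[sub$role == "dysplasia", ][1L, ]
    scc <- sub[sub$role == "scc", ][1L, ]
    if (is.na(dys$sample) || is.na(scc$sample))
      stop("patient '", pid, "' lacks a dysplasia/scc pair in metadata")
    mutPath <- file.path(mutationDir, paste0("mutations_", pid, ".tsv"))
    mut <- if (file.exists(mutPath)) readMutations(mutPath) else NULL
    out[[pid]] <- LesionPair(
      patientId = pid, dysplasiaId = dys$sample, sccId = scc$sample,
      grade = dys$grade,
      adjacency = if (identical(dys$block, "different")) "different_block"
                  else "same_block",
      mutations = mut,
      dysProfile = profiles[[dys$sample]],
      sccProfile = profiles[[scc$sample]])
  }
  out
}

#' Deterministic TSV writer used for all stage outputs
#' @keywords internal
writeTsv <- function(tab, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
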