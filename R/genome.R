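#' hg19 autosome lengths
#'
#' Chromosome lengths for chr1-chr22 of the hg19 human reference assembly.
#' All genome-wide statistics in this package (fraction of genome altered,
#' cohort frequency tracks, bin grids) are computed over the autosomes only;
#' sex chromosomes are parsed but excluded.
#'
#' @return Named integer-valued numeric vector of lengths in bases,
#'   names `"1"`..`"22"`.
#' @export
#' @examples
#' sum(hg19Autosomes()) # ~2.88 Gb autosomal genome
hg19Autosomes <- function() {
  c(`1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
    `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
    `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
    `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
    `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
    `21` = 48129895, `22` = 51304566)
}

#' Seqinfo for the autosomal genome
#' @keywords internal
autosomeSeqinfo <- function() {
  len <- hg19Autosomes()
  GenomeInfoDb::Seqinfo(seqnames = names(len), seqlengths = unname(len),
                        genome = "hg19")
}

AUTOSOME_NAMES <- as.character(1:22)

#' Normalise chromosome labels ("chr1" -> "1"); returns character vector.
#' @keywords internal
normChrom <- function(x) sub("^chr", "", as.character(x))

#' Is a chromosome label autosomal?
#' @keywords internal
isAutosome <- function(x) normChrom(x) %in% AUTOSOME_NAMES

#' Catalogue of recurrent copy-number events
#'
#' The eleven recurrent arm-level events used throughout: losses of 3p, 4p,
#' 5q, 9p, whole chromosome 11 and 18q; gains of 3q, 5p, whole chromosome 7,
#' 8q and 12p. Coordinates are approximate hg19 arm boundaries shipped as a
#' plain-text data file; they are conventions for simulation and region
#' naming, not claims about breakpoints.
#'
#' @return A [GenomicRanges::GRanges] with metadata columns `region`
#'   (e.g. `"8q"`) and `direction` (`"gain"` or `"loss"`).
#' @export
#' @examples
#' cnEventCatalogue()
cnEventCatalogue <- function() {
  path <- system.file("extdata", "cn_event_catalogue.tsv",
                      package = "clonalPair", mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#",
                           colClasses = c("character", "character",
                                          "numeric", "numeric", "character"))
  gr <- GenomicRanges::GRanges(
    seqnames = normChrom(tab$chrom),
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    region = tab$region, direction = tab$direction,
    seqinfo = autosomeSeqinfo())
  gr
}
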