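#' Normalize chromosome labels
#'
#' Strips any leading "chr" prefix and upper-cases the sex chromosomes, so
#' that "chr1", "1", "chrX" and "x" all map to the internal labels
#' "1".."22", "X", "Y", "MT".
#'
#' @param chrom character vector of chromosome labels.
#' @return character vector of normalized labels.
#' @examples
#' normalize_chrom(c("chr1", "X", "chrx", "22"))
#' @export
normalize_chrom <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  sex <- toupper(x) %in% c("X", "Y", "MT", "M")
  x[sex] <- toupper(x[sex])
  x[x == "M"] <- "MT"
  x
}

#' Chromosome sizes of the hg19 (GRCh37) assembly
#'
#' Lengths in bp of chromosomes 1-22, X and Y, used for coordinate
#' validation and for placing simulated calls.
#'
#' @return named integer-valued numeric vector of chromosome lengths.
#' @export
hg19_chrom_sizes <- function() {
  c(`1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
    `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
    `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
    `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
    `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
    `21` = 48129895, `22` = 51304566, X = 155270560, Y = 59373566)
}

round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' CNV size in kilobases
#'
#' Size is defined as `(end - start) / 1000`, rounded half away from zero.
#' This convention reproduces published "Size (kb)" table columns computed
#' from UCSC-style 1-based coordinates (e.g. 145,064,742-145,950,454 is
#' 886 kb). The inclusive-length alternative `end - start + 1` is
#' indistinguishable at kb rounding.
#'
#' @param start,end 1-based inclusive coordinates (vectors recycled).
#' @return integer-valued numeric vector of sizes in kb.
#' @examples
#' size_kb(145064742, 145950454) # 886
#' @export
size_kb <- function(start, end) {
  stopifnot(all(end >= start), all(start >= 1))
  round_half_up((end - start) / 1000)
}

#' Overlap length between two genomic intervals
#'
#' Number of shared integer positions under the 1-based inclusive
#' convention; 0 when the chromosomes differ or the intervals are disjoint.
#' All arguments are recycled, so the function also works pairwise on
#' vectors of intervals.
#'
#' @param chrom1,start1,end1 first interval(s).
#' @param chrom2,start2,end2 second interval(s).
#' @return numeric vector of overlap lengths in bp.
#' @examples
#' overlap_bp("1", 1, 100, "1", 51, 150) # 50
#' @export
overlap_bp <- function(chrom1, start1, end1, chrom2, start2, end2) {
  ov <- pmin(end1, end2) - pmax(start1, start2) + 1
  ov <- pmax(ov, 0)
  ov[normalize_chrom(chrom1) != normalize_chrom(chrom2)] <- 0
  ov
}

#' Reciprocal overlap fraction between two genomic intervals
#'
#' `min(overlap / length(a), overlap / length(b))` with inclusive lengths
#' `end - start + 1`; 0 for disjoint intervals or different chromosomes,
#' 1 for identical intervals. This is the standard CNV-equivalence
#' measure; two calls are treated as the same locus when it is >= 0.8.
#'
#' @inheritParams overlap_bp
#' @return numeric vector of fractions in `[0, 1]`.
#' @examples
#' reciprocal_overlap("1", 1, 100, "1", 41, 140) # 0.6
#' @export
reciprocal_overlap <- function(chrom1, start1, end1, chrom2, start2, end2) {
  ov <- overlap_bp(chrom1, start1, end1, chrom2, start2, end2)
  pmin(ov / (end1 - start1 + 1), ov / (end2 - start2 + 1))
}
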