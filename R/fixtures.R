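fixture_path <- function(file) {
  system.file("extdata", file, package = "cnvburden", mustWork = TRUE)
}

read_fixture_cnvs <- function(file) {
  df <- read.delim(fixture_path(file), stringsAsFactors = FALSE)
  df$type <- normalize_cnv_type(df$type)
  df$chrom <- normalize_chrom(df$chrom)
  df
}

#' Packaged CNV fixtures transcribed from a published ASD cohort
#'
#' Three small tables of rare CNVs reported in a Taiwanese autism
#' spectrum disorder case-control study: `fixture_hotspot_cnvs()` - the
#' 14 patient CNVs at ASD hot-spot regions; `fixture_pathogenic_cnvs()` -
#' the 49 rare (>= 400 kb) putative pathogenic CNVs with their parental
#' origin where established by family qPCR; `fixture_twohit_cnvs()` - the
#' CNV pairs of the five two-hit patients. Columns include 1-based hg19
#' coordinates, the printed size in kb (`size_kb_printed`), the CNV type,
#' gene annotations as published, and the number of carrier subjects among
#' 1093 controls (525 male controls for X-chromosome CNVs).
#'
#' @return data.frame, one row per CNV.
#' @export
fixture_hotspot_cnvs <- function() read_fixture_cnvs("table3_hotspot_cnvs.tsv")

#' @rdname fixture_hotspot_cnvs
#' @export
fixture_pathogenic_cnvs <- function() read_fixture_cnvs("table4_pathogenic_cnvs.tsv")

#' @rdname fixture_hotspot_cnvs
#' @export
fixture_twohit_cnvs <- function() read_fixture_cnvs("table5_twohit_cnvs.tsv")

#' Packaged synthetic hot-spot and pathogenic reference region sets
#'
#' `fixture_hotspot_regions()` covers the ASD hot-spot loci (7q31.2, 7q35,
#' 15q11-13, 15q13.3, 16p11.2, 22q11.2, 22q13.3, Xp22.3) named in the 2013
#' ACMG ASD clinical-genetics guideline. `fixture_pathogenic_regions()` is
#' a synthetic stand-in for a curated pathogenic-CNV reference (ClinGen /
#' DECIPHER style) covering the loci of the packaged pathogenic fixture.
#' Both are labeled fixtures for testing and examples, not redistributions
#' of the curated databases; supply real exports for production use.
#'
#' @return a [region_set()].
#' @export
fixture_hotspot_regions <- function() {
  read_region_bed(fixture_path("hotspot_regions_synthetic.bed"), name = "hot_spots")
}

#' @rdname fixture_hotspot_regions
#' @export
fixture_pathogenic_regions <- function() {
  read_region_bed(fixture_path("pathogenic_reference_synthetic.bed"),
                  name = "pathogenic_reference")
}
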