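# Labels of regions overlapping each call, honoring dosage direction.
# Returns a list (one character vector per call, possibly empty).
region_hits <- function(calls, regions, min_fraction = NULL) {
  out <- rep(list(character(0)), nrow(calls))
  if (is.null(regions) || nrow(regions) == 0 || nrow(calls) == 0) {
    if (!is.null(regions) && nrow(regions) == 0) warning("empty region set")
    return(out)
  }
  hits <- overlap_hits(calls, regions)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  keep <- regions$dosage[si] == "any" | regions$dosage[si] == calls$type[qi]
  if (!is.null(min_fraction) && length(qi)) {
    ov <- overlap_bp(calls$chrom[qi], calls$start[qi], calls$end[qi],
                     regions$chrom[si], regions$start[si], regions$end[si])
    keep <- keep & (ov / (calls$end[qi] - calls$start[qi] + 1)) >= min_fraction
  }
  qi <- qi[keep]; si <- si[keep]
  for (i in unique(qi)) out[[i]] <- regions$label[si[qi == i]]
  out
}

#' Annotate CNV calls with hot-spot hits
#'
#' Labels each call with the hot-spot regions it overlaps (any overlap by
#' default). Hot spots are genomic regions with an especially strong
#' reported ASD association per the 2013 ACMG clinical-genetics
#' guideline; a CNV at a hot spot is considered pathogenic regardless of
#' its size. A region with a dosage direction other than "any" matches
#' only calls of that CNV type.
#'
#' @param calls CNV call table.
#' @param hotspots hot-spot [region_set()].
#' @param min_fraction optional minimum overlapped fraction of the call.
#' @return `calls` with an added list-column `hot_spot_hits`.
#' @export
annotate_hot_spots <- function(calls, hotspots, min_fraction = NULL) {
  calls <- as.data.frame(calls)
  calls$hot_spot_hits <- region_hits(calls, hotspots, min_fraction)
  calls
}

#' Classify rare CNVs as pathogenic
#'
#' A call is flagged pathogenic when it hits a hot-spot region (any size)
#' or when it is at least `min_size_kb` (default 400 kb) and overlaps a
#' region of the curated pathogenic reference set (ClinGen / DECIPHER
#' style). Reference evidence labels are recorded per call; the flag is
#' monotone in the reference set (adding regions never un-flags a call).
#'
#' @param calls CNV call table, ideally already passed through
#'   [annotate_hot_spots()] (a missing `hot_spot_hits` column is treated
#'   as no hot-spot evidence).
#' @param pathogenic_regions pathogenic reference [region_set()].
#' @param min_size_kb minimum size for the reference-overlap route.
#' @param min_fraction optional minimum overlapped fraction of the call.
#' @return `calls` with list-column `pathogenic_evidence` and logical
#'   `pathogenic`.
#' @export
classify_pathogenic <- function(calls, pathogenic_regions, min_size_kb = 400,
                                min_fraction = NULL) {
  calls <- as.data.frame(calls)
  if (!"hot_spot_hits" %in% names(calls)) {
    calls$hot_spot_hits <- rep(list(character(0)), nrow(calls))
  }
  evidence <- region_hits(calls, pathogenic_regions, min_fraction)
  big <- size_kb(calls$start, calls$end) >= min_size_kb
  # evidence below the size threshold is dropped: the reference route
  # applies to >= min_size_kb calls only
  evidence[!big] <- list(character(0))
  calls$pathogenic_evidence <- evidence
  calls$pathogenic <- lengths(calls$hot_spot_hits) > 0 | lengths(evidence) > 0
  calls
}

#' Annotate CNV calls with overlapped genes
#'
#' @param calls CNV call table.
#' @param genes gene [region_set()] (labels are gene symbols).
#' @return `calls` with list-column `genes`, symbols sorted by genomic
#'   position.
#' @export
annotate_genes <- function(calls, genes) {
  calls <- as.data.frame(calls)
  if (!is.null(genes) && nrow(genes)) {
    genes$dosage <- "any"  # genes are not dosage-directional
    # region_set() is position-sorted, so hit labels come out in order
  }
  calls$genes <- region_hits(calls, genes)
  calls
}

match_in_parent <- function(child, parent_calls, min_overlap) {
  if (is.null(parent_calls)) return(NA)
  if (nrow(parent_calls) == 0) return(FALSE)
  same <- parent_calls$type == child$type & parent_calls$chrom == child$chrom
  if (!any(same)) return(FALSE)
  p <- parent_calls[same, , drop = FALSE]
  any(reciprocal_overlap(child$chrom, child$start, child$end,
                         p$chrom, p$start, p$end) >= min_overlap)
}

#' Determine the parental origin of child CNV calls
#'
#' A child call is labeled `maternal` (`paternal`) when the mother's
#' (father's) call set contains a call of the same type matching at
#' reciprocal overlap >= `min_overlap`; `de_novo` when both parental call
#' sets are available and neither matches; `unknown` when either parent's
#' calls are unavailable (`NULL`, as opposed to an empty call table which
#' means genotyped with no calls); `biparental` (with a warning) when both
#' parents match. Interval matching stands in for the wet-lab family
#' qPCR used to establish origins in practice.
#'
#' @param child_calls CNV call table of one child.
#' @param mother_calls,father_calls parental call tables, or `NULL` when
#'   that parent was not genotyped.
#' @param min_overlap reciprocal-overlap threshold (default 0.8).
#' @return character vector of origins, one per child call.
#' @export
call_inheritance <- function(child_calls, mother_calls, father_calls,
                             min_overlap = 0.8) {
  n <- nrow(child_calls)
  origins <- character(n)
  for (i in seq_len(n)) {
    child <- child_calls[i, ]
    in_mother <- match_in_parent(child, mother_calls, min_overlap)
    in_father <- match_in_parent(child, father_calls, min_overlap)
    origins[i] <- if (isTRUE(in_mother) && isTRUE(in_father)) {
      warning("call matched in both parents (biparental): sample ",
              child$sample_id, " ", child$chrom, ":", child$start)
      "biparental"
    } else if (isTRUE(in_mother)) "maternal"
    else if (isTRUE(in_father)) "paternal"
    else if (is.na(in_mother) || is.na(in_father)) "unknown"
    else "de_novo"
  }
  origins
}

#' Infer origins for all trio-linked calls in a cohort
#'
#' Applies [call_inheritance()] to every call of every sample whose
#' manifest row links a mother and/or father; calls of samples without
#' trio links get origin "unknown".
#'
#' @param calls CNV call table for the whole cohort (children and
#'   parents).
#' @param manifest sample manifest with `mother_id` / `father_id` links.
#' @param min_overlap reciprocal-overlap threshold.
#' @return `calls` with an added `origin` column.
#' @export
infer_origins <- function(calls, manifest, min_overlap = 0.8) {
  calls <- as.data.frame(calls)
  calls$origin <- "unknown"
  by_sample <- split(seq_len(nrow(calls)), calls$sample_id)
  get_calls <- function(id) {
    if (is.na(id)) return(NULL)
    idx <- by_sample[[id]]
    if (is.null(idx)) calls[integer(0), , drop = FALSE] else calls[idx, , drop = FALSE]
  }
  linked <- manifest[!is.na(manifest$mother_id) | !is.na(manifest$father_id), , drop = FALSE]
  for (j in seq_len(nrow(linked))) {
    idx <- by_sample[[linked$sample_id[j]]]
    if (is.null(idx)) next
    calls$origin[idx] <- call_inheritance(calls[idx, , drop = FALSE],
                                          get_calls(linked$mother_id[j]),
                                          get_calls(linked$father_id[j]),
                                          min_overlap = min_overlap)
  }
  calls
}

#' Detect two-hit carriers
#'
#' Finds samples carrying two or more pathogenic CNVs at distinct loci
#' (pairwise reciprocal overlap < `min_overlap`). The default scope is
#' autosomal, matching the published two-hit definition under which a
#' patient with one autosomal and one X-chromosome pathogenic CNV is not
#' counted; scope "all" includes sex chromosomes. Output order is
#' deterministic (by sample id) and stable under permutation of the input.
#'
#' @param classified_calls output of [classify_pathogenic()] (needs the
#'   `pathogenic` column).
#' @param scope "autosomal" or "all".
#' @param min_overlap reciprocal-overlap threshold defining "same locus".
#' @return data.frame with one row per hit of each two-hit sample
#'   (columns of the input plus `n_hits`), or a 0-row frame.
#' @export
detect_two_hit <- function(classified_calls, scope = c("autosomal", "all"),
                           min_overlap = 0.8) {
  scope <- match.arg(scope)
  calls <- as.data.frame(classified_calls)
  stopifnot("pathogenic" %in% names(calls))
  calls <- calls[calls$pathogenic, , drop = FALSE]
  if (scope == "autosomal") calls <- calls[calls$chrom %in% as.character(1:22), , drop = FALSE]
  if (nrow(calls) == 0) return(cbind(calls, n_hits = integer(0)))
  clustered <- cluster_loci(calls, min_overlap = min_overlap)
  per_sample <- tapply(clustered$locus_id, clustered$sample_id,
                       function(x) length(unique(x)))
  two_hit_ids <- sort(names(per_sample)[per_sample >= 2])
  out <- clustered[clustered$sample_id %in% two_hit_ids, , drop = FALSE]
  out <- out[order(out$sample_id, match(out$chrom, valid_chroms()), out$start), , drop = FALSE]
  out$n_hits <- as.vector(per_sample[out$sample_id])
  rownames(out) <- NULL
  out
}

#' Count control carriers of each call's locus
#'
#' For each (case) call, counts the distinct control subjects carrying a
#' matching CNV (same type, reciprocal overlap >= `min_overlap`) and the
#' corresponding control carrier frequency. The denominator is the number
#' of control subjects for autosomal calls and of male control subjects
#' for X-chromosome calls (only males are screened on X).
#'
#' @param calls CNV call table to look up.
#' @param control_calls CNV call table of the control cohort.
#' @param manifest sample manifest (provides the denominators).
#' @param min_overlap reciprocal-overlap threshold.
#' @return `calls` with added `control_carriers`, `control_n` and
#'   `control_freq` columns.
#' @export
control_carrier_lookup <- function(calls, control_calls, manifest,
                                   min_overlap = 0.8) {
  calls <- as.data.frame(calls)
  control_ids <- manifest$sample_id[manifest$group == "control"]
  male_ids <- manifest$sample_id[manifest$sex == "male"]
  cc <- control_calls[control_calls$sample_id %in% control_ids, , drop = FALSE]
  count_one <- function(i) {
    child <- calls[i, ]
    pool <- cc[cc$chrom == child$chrom & cc$type == child$type, , drop = FALSE]
    if (child$chrom == "X") pool <- pool[pool$sample_id %in% male_ids, , drop = FALSE]
    if (nrow(pool) == 0) return(0L)
    hit <- reciprocal_overlap(child$chrom, child$start, child$end,
                              pool$chrom, pool$start, pool$end) >= min_overlap
    length(unique(pool$sample_id[hit]))
  }
  calls$control_carriers <- vapply(seq_len(nrow(calls)), count_one, integer(1))
  on_x <- calls$chrom == "X"
  calls$control_n <- ifelse(on_x, length(intersect(control_ids, male_ids)),
                            length(control_ids))
  calls$control_freq <- carrier_frequency(calls$control_carriers, calls$control_n)
  calls
}
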