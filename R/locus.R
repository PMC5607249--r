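# Iterative union-find with path halving; edges as integer index pairs.
union_find <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(from)) {
    ra <- find(from[k]); rb <- find(to[k])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(n), find, integer(1))
}

#' Cluster CNV calls into loci by reciprocal overlap
#'
#' Two calls belong to the same locus when they share chromosome and CNV
#' type and overlap by at least `min_overlap` of their length (reciprocal
#' by default: the minimum of the two mutual fractions). Loci are the
#' connected components of this relation (single linkage), so transitive
#' chains can join calls whose direct pairwise overlap is below the
#' threshold. Deletions and duplications are clustered separately. Output
#' is invariant to input order: calls are canonically sorted before
#' component labeling and locus ids are assigned by (chromosome, span
#' start, type).
#'
#' @param calls QC-filtered CNV call table.
#' @param min_overlap overlap threshold (default 0.8).
#' @param mode "reciprocal" (both fractions must reach the threshold) or
#'   "unilateral" (either fraction suffices).
#' @return `calls` with an added `locus_id` column, sorted canonically.
#' @export
cluster_loci <- function(calls, min_overlap = 0.8,
                         mode = c("reciprocal", "unilateral")) {
  mode <- match.arg(mode)
  calls <- as.data.frame(calls)
  if (nrow(calls) == 0) {
    calls$locus_id <- character(0)
    return(calls)
  }
  ord <- order(match(calls$chrom, valid_chroms()), calls$start, calls$end,
               calls$type, calls$sample_id)
  calls <- calls[ord, , drop = FALSE]
  n <- nrow(calls)
  grp <- paste(calls$chrom, calls$type)
  hits <- GenomicRanges::findOverlaps(as_granges(calls), drop.self = TRUE,
                                      drop.redundant = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  same <- grp[qi] == grp[si]
  qi <- qi[same]; si <- si[same]
  if (length(qi)) {
    ov <- overlap_bp(calls$chrom[qi], calls$start[qi], calls$end[qi],
                     calls$chrom[si], calls$start[si], calls$end[si])
    f1 <- ov / (calls$end[qi] - calls$start[qi] + 1)
    f2 <- ov / (calls$end[si] - calls$start[si] + 1)
    frac <- if (mode == "reciprocal") pmin(f1, f2) else pmax(f1, f2)
    keep <- frac >= min_overlap
    qi <- qi[keep]; si <- si[keep]
  }
  comp <- union_find(n, qi, si)
  # stable locus ids ordered by first (canonically sorted) member
  first <- !duplicated(comp)
  rank <- match(comp, comp[first])
  calls$locus_id <- sprintf("L%04d", rank)
  rownames(calls) <- NULL
  calls
}

#' Rarity selection configuration
#'
#' @param max_frequency carrier-frequency threshold; loci strictly below
#'   it are rare (default 0.01, i.e. < 1%).
#' @param frequency_reference group whose carrier frequency defines
#'   rarity: "cases" (the study's convention), "controls" or "combined".
#' @return list of class `rarity_config`.
#' @export
rarity_config <- function(max_frequency = 0.01,
                          frequency_reference = c("cases", "controls", "combined")) {
  stopifnot(max_frequency > 0, max_frequency <= 1)
  structure(list(max_frequency = max_frequency,
                 frequency_reference = match.arg(frequency_reference)),
            class = "rarity_config")
}

#' Carrier frequency
#'
#' Distinct-carrier count divided by the reference denominator. A subject
#' carrying two member calls of a locus counts once.
#'
#' @param n_carriers distinct carrier count.
#' @param n_reference reference group size (must be > 0).
#' @return carrier fraction.
#' @examples
#' carrier_frequency(5, 1093) # 0.00457... i.e. 0.46%
#' @export
carrier_frequency <- function(n_carriers, n_reference) {
  if (any(n_reference <= 0)) stop("zero reference denominator: degenerate cohort")
  n_carriers / n_reference
}

# Eligible denominator sizes per locus chromosome: X loci are assessed in
# males only (X is analyzed in male samples only; female X calls never
# enter numerators or denominators).
eligible_counts <- function(manifest, chrom) {
  male <- manifest$sex == "male"
  case <- manifest$group == "case"
  on_x <- chrom == "X"
  data.frame(
    n_case = ifelse(on_x, sum(case & male), sum(case)),
    n_control = ifelse(on_x, sum(!case & male), sum(!case))
  )
}

#' Summarize loci with carrier counts and frequencies
#'
#' One row per locus: union span, type, member/carrier counts and carrier
#' frequencies in cases and controls. X-chromosome loci use male-only
#' numerators and denominators.
#'
#' @param clustered output of [cluster_loci()].
#' @param manifest sample manifest.
#' @param rarity a [rarity_config()]; sets the `freq_reference` column and
#'   the `rare` flag (strict `<` threshold).
#' @return data.frame of locus summaries ordered by (chrom, start, type).
#' @export
locus_summary <- function(clustered, manifest, rarity = rarity_config()) {
  stopifnot("locus_id" %in% names(clustered))
  if (nrow(clustered) == 0) {
    return(data.frame(locus_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0), type = character(0),
                      n_members = integer(0), n_case_carriers = integer(0),
                      n_control_carriers = integer(0), case_freq = numeric(0),
                      control_freq = numeric(0), freq_reference = numeric(0),
                      rare = logical(0)))
  }
  male_ids <- manifest$sample_id[manifest$sex == "male"]
  case_ids <- manifest$sample_id[manifest$group == "case"]
  sp <- split(clustered, clustered$locus_id)
  rows <- lapply(sp, function(m) {
    chrom <- m$chrom[1]
    carriers <- unique(m$sample_id)
    if (chrom == "X") carriers <- intersect(carriers, male_ids)
    data.frame(locus_id = m$locus_id[1], chrom = chrom,
               start = min(m$start), end = max(m$end), type = m$type[1],
               n_members = nrow(m),
               n_case_carriers = length(intersect(carriers, case_ids)),
               n_control_carriers = length(setdiff(carriers, case_ids)))
  })
  out <- do.call(rbind, rows)
  denom <- eligible_counts(manifest, out$chrom)
  out$case_freq <- carrier_frequency(out$n_case_carriers, denom$n_case)
  out$control_freq <- carrier_frequency(out$n_control_carriers, denom$n_control)
  out$freq_reference <- switch(rarity$frequency_reference,
    cases = out$case_freq,
    controls = out$control_freq,
    combined = carrier_frequency(out$n_case_carriers + out$n_control_carriers,
                                 denom$n_case + denom$n_control))
  out$rare <- out$freq_reference < rarity$max_frequency
  out <- out[order(match(out$chrom, valid_chroms()), out$start, out$type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select rare CNV calls
#'
#' Keeps the calls whose locus carrier frequency in the reference group is
#' strictly below the rarity threshold. With 335 cases and the default 1%
#' threshold, loci carried by up to 3 distinct cases survive.
#'
#' @param clustered output of [cluster_loci()].
#' @param manifest sample manifest.
#' @param rarity a [rarity_config()].
#' @return the rare subset of `clustered` (with `locus_id`).
#' @export
select_rare <- function(clustered, manifest, rarity = rarity_config()) {
  loci <- locus_summary(clustered, manifest, rarity)
  keep <- loci$locus_id[loci$rare]
  clustered[clustered$locus_id %in% keep, , drop = FALSE]
}
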