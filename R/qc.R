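#' QC filter configuration
#'
#' Defaults follow the study's call-level criteria: segments supported by
#' at least 20 contiguous probes, at least 10 kb in size, and not
#' overlapping any blacklist region (centromeres, antibody variable
#' regions, T-cell receptor loci).
#'
#' @param min_probes minimum supporting probe count (default 20).
#' @param min_size_kb minimum size in kb, boundary inclusive (default 10).
#' @param exclusion_sets list of [region_set()]s; calls overlapping any of
#'   them are removed.
#' @param exclusion_rule "any_overlap" (>= 1 bp, the default) or
#'   "fraction_of_call" (removed only when the overlapped fraction of the
#'   call reaches `exclusion_fraction`).
#' @param exclusion_fraction minimum overlapped fraction of the call under
#'   the "fraction_of_call" rule.
#' @return a list of class `qc_config`.
#' @export
qc_config <- function(min_probes = 20, min_size_kb = 10,
                      exclusion_sets = list(),
                      exclusion_rule = c("any_overlap", "fraction_of_call"),
                      exclusion_fraction = 0.5) {
  stopifnot(min_probes >= 1, min_size_kb >= 0,
            exclusion_fraction > 0, exclusion_fraction <= 1)
  structure(list(min_probes = min_probes, min_size_kb = min_size_kb,
                 exclusion_sets = exclusion_sets,
                 exclusion_rule = match.arg(exclusion_rule),
                 exclusion_fraction = exclusion_fraction),
            class = "qc_config")
}

#' Filter CNV calls by supporting probe count
#'
#' Keeps calls with `n_probes >= min_probes` (boundary inclusive),
#' preserving row order. Calls with missing `n_probes` are a validation
#' error naming the offending rows.
#'
#' @param calls CNV call table.
#' @param min_probes minimum probe count.
#' @return the surviving subset of `calls`.
#' @export
filter_by_probes <- function(calls, min_probes = 20) {
  if (!"n_probes" %in% names(calls) || anyNA(calls$n_probes)) {
    bad <- if ("n_probes" %in% names(calls)) which(is.na(calls$n_probes)) else seq_len(nrow(calls))
    stop("n_probes missing for call row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  calls[calls$n_probes >= min_probes, , drop = FALSE]
}

#' Filter CNV calls by size
#'
#' Keeps calls whose [size_kb()] is at least `min_size_kb` (boundary
#' inclusive; a 10,000 bp call passes the default 10 kb threshold, a
#' 9,400 bp call rounds to 9 kb and is removed).
#'
#' @param calls CNV call table.
#' @param min_size_kb minimum size in kb.
#' @return the surviving subset of `calls`.
#' @export
filter_by_size <- function(calls, min_size_kb = 10) {
  if (nrow(calls) == 0) return(calls)
  calls[size_kb(calls$start, calls$end) >= min_size_kb, , drop = FALSE]
}

#' Remove CNV calls overlapping blacklist regions
#'
#' Drops any call that overlaps a region of the supplied exclusion sets.
#' The default rule removes a call on any overlap (>= 1 bp), matching the
#' usual blacklist treatment of centromeric, antibody variable and T-cell
#' receptor regions; a fraction-of-call rule is available for sensitivity
#' analysis. Calls are removed, never trimmed.
#'
#' @param calls CNV call table.
#' @param exclusion_sets a [region_set()] or list of them.
#' @param rule "any_overlap" or "fraction_of_call".
#' @param min_fraction overlapped fraction of the call required for
#'   removal under "fraction_of_call".
#' @return the surviving subset of `calls`.
#' @export
filter_by_exclusion_regions <- function(calls, exclusion_sets,
                                        rule = c("any_overlap", "fraction_of_call"),
                                        min_fraction = 0.5) {
  rule <- match.arg(rule)
  if (inherits(exclusion_sets, "region_set")) exclusion_sets <- list(exclusion_sets)
  if (nrow(calls) == 0 || !length(exclusion_sets)) return(calls)
  regions <- do.call(rbind, lapply(exclusion_sets, function(r) {
    as.data.frame(r)[, c("chrom", "start", "end")]
  }))
  if (nrow(regions) == 0) return(calls)
  hits <- overlap_hits(calls, regions)
  if (rule == "fraction_of_call" && length(hits)) {
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ov <- overlap_bp(calls$chrom[qi], calls$start[qi], calls$end[qi],
                     regions$chrom[si], regions$start[si], regions$end[si])
    frac <- ov / (calls$end[qi] - calls$start[qi] + 1)
    drop_idx <- unique(qi[frac >= min_fraction])
  } else {
    drop_idx <- unique(S4Vectors::queryHits(hits))
  }
  if (length(drop_idx)) calls[-drop_idx, , drop = FALSE] else calls
}

#' Apply all QC filters and summarize attrition
#'
#' Applies the probe-count, size and exclusion-region filters in order and
#' reports per-filter kept/dropped call counts. The surviving calls are the
#' input to locus clustering and all downstream stages.
#'
#' @param calls CNV call table.
#' @param config a [qc_config()].
#' @return list with elements `calls` (survivors) and `summary`
#'   (data.frame of per-filter input/kept/dropped counts).
#' @export
apply_qc <- function(calls, config = qc_config()) {
  stopifnot(inherits(config, "qc_config"))
  steps <- list(
    probes = function(x) filter_by_probes(x, config$min_probes),
    size = function(x) filter_by_size(x, config$min_size_kb),
    exclusion = function(x) filter_by_exclusion_regions(
      x, config$exclusion_sets, rule = config$exclusion_rule,
      min_fraction = config$exclusion_fraction)
  )
  out <- calls
  summary <- data.frame(filter = names(steps), input = NA_integer_,
                        kept = NA_integer_, dropped = NA_integer_)
  for (i in seq_along(steps)) {
    n_in <- nrow(out)
    out <- steps[[i]](out)
    summary$input[i] <- n_in
    summary$kept[i] <- nrow(out)
    summary$dropped[i] <- n_in - nrow(out)
  }
  list(calls = out, summary = summary)
}

#' QC report for a cohort
#'
#' Deterministic structured summary of filter attrition plus per-sample
#' kept-call counts; the kept total equals the call set passed downstream.
#'
#' @param calls CNV call table.
#' @param manifest sample manifest.
#' @param config a [qc_config()].
#' @return list with `n_samples`, `n_calls_in`, `n_calls_kept`,
#'   `per_filter` (attrition table) and `calls` (survivors).
#' @export
qc_report <- function(calls, manifest, config = qc_config()) {
  res <- apply_qc(calls, config)
  list(n_samples = nrow(manifest),
       n_cases = sum(manifest$group == "case"),
       n_controls = sum(manifest$group == "control"),
       n_calls_in = nrow(calls),
       n_calls_kept = nrow(res$calls),
       per_filter = res$summary,
       calls = res$calls)
}
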