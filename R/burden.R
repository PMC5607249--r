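#' Assign CNV sizes to burden size bins
#'
#' Bins follow the published table layout "<100 Kb", "100-400 Kb",
#' ">400 Kb": sizes (in kb, after [size_kb()] rounding) below 100 fall in
#' `lt100kb`, 100 through 400 inclusive in `100to400kb`, and strictly
#' above 400 in `gt400kb`, so every call lands in exactly one bin.
#'
#' @param size sizes in kb.
#' @return factor with levels `lt100kb`, `100to400kb`, `gt400kb`.
#' @export
size_bin <- function(size) {
  cut(size, breaks = c(-Inf, 100, 400, Inf), right = FALSE,
      labels = c("lt100kb", "100to400kb", "gt400kb")) |>
    (\(f) {
      # cut() with right = FALSE puts 400 in the upper bin; the table's
      # "100-400" is inclusive of 400, so reassign the boundary.
      f[size == 400] <- "100to400kb"
      f
    })()
}

burden_strata <- function() {
  expand.grid(cnv_type = c("deletion", "duplication", "both"),
              size_bin = c("lt100kb", "100to400kb", "gt400kb", "total"),
              stringsAsFactors = FALSE)
}

#' Count rare CNV calls per burden stratum
#'
#' Counts events (not carriers) per CNV type and size bin for one scope:
#' `autosomal` uses chromosomes 1-22 and all subjects; `x_male` uses the X
#' chromosome and male subjects only (calls from female samples are
#' excluded). Calls on Y or MT are excluded from both scopes; their count
#' is attached as attribute `n_excluded_chrom`.
#'
#' @param rare_calls rare CNV call table (after [select_rare()]).
#' @param manifest sample manifest.
#' @param scope "autosomal" or "x_male".
#' @return data.frame of case/control event counts per (type, bin),
#'   including "both"-type and "total"-bin margins, with eligible subject
#'   counts `case_n` / `control_n`.
#' @export
stratify_calls <- function(rare_calls, manifest, scope = c("autosomal", "x_male")) {
  scope <- match.arg(scope)
  calls <- as.data.frame(rare_calls)
  n_excluded <- sum(calls$chrom %in% c("Y", "MT"))
  if (scope == "autosomal") {
    eligible <- manifest$sample_id
    calls <- calls[calls$chrom %in% as.character(1:22), , drop = FALSE]
  } else {
    eligible <- manifest$sample_id[manifest$sex == "male"]
    calls <- calls[calls$chrom == "X" & calls$sample_id %in% eligible, , drop = FALSE]
  }
  case_ids <- manifest$sample_id[manifest$group == "case"]
  case_n <- length(intersect(eligible, case_ids))
  control_n <- length(setdiff(eligible, case_ids))
  calls$bin <- as.character(size_bin(size_kb(calls$start, calls$end)))
  calls$is_case <- calls$sample_id %in% case_ids
  strata <- burden_strata()
  count_events <- function(type, bin, in_cases) {
    sel <- calls$is_case == in_cases
    if (type != "both") sel <- sel & calls$type == type
    if (bin != "total") sel <- sel & calls$bin == bin
    sum(sel)
  }
  strata$case_count <- mapply(count_events, strata$cnv_type, strata$size_bin, TRUE)
  strata$control_count <- mapply(count_events, strata$cnv_type, strata$size_bin, FALSE)
  strata$case_n <- case_n
  strata$control_n <- control_n
  strata$scope <- scope
  attr(strata, "n_excluded_chrom") <- n_excluded
  strata
}

#' Per-subject CNV rate
#'
#' @param count CNV event count.
#' @param n_subjects number of eligible subjects (> 0).
#' @return `count / n_subjects`, unrounded.
#' @examples
#' cnv_rate(907, 335) # 2.707... printed as 2.71
#' @export
cnv_rate <- function(count, n_subjects) {
  if (any(n_subjects <= 0)) stop("n_subjects must be positive")
  count / n_subjects
}

#' Two-sample rate likelihood-ratio chi-square test
#'
#' Compares per-subject event rates between two groups. The default
#' "poisson" method models group event counts as Poisson with exposures
#' equal to the subject counts and computes the likelihood-ratio statistic
#' `2 * [l(lambda1_hat, lambda2_hat) - l(lambda0_hat)]` with
#' `lambda_i_hat = count_i / n_i` and pooled
#' `lambda0_hat = (c1 + c2) / (n1 + n2)`, referred to chi-square with 1
#' degree of freedom. The statistic is 0 exactly when the observed rates
#' are equal (including the all-zero case). The "contingency" method is an
#' exploratory G-test of independence on the 2x2 table of event counts
#' versus subject counts, provided for comparison only.
#'
#' @param case_count,control_count event counts (>= 0).
#' @param case_n,control_n subject counts (> 0).
#' @param method "poisson" (default) or "contingency".
#' @return list with `statistic` and `p_value`.
#' @export
rate_lr_test <- function(case_count, case_n, control_count, control_n,
                         method = c("poisson", "contingency")) {
  method <- match.arg(method)
  if (case_count < 0 || control_count < 0) stop("counts must be non-negative")
  if (case_n <= 0 || control_n <= 0) stop("subject counts must be positive")
  xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))
  if (method == "poisson") {
    c1 <- case_count; c2 <- control_count
    l1 <- c1 / case_n; l2 <- c2 / control_n
    l0 <- (c1 + c2) / (case_n + control_n)
    stat <- if (c1 + c2 == 0) 0 else 2 * (xlogy(c1, l1 / l0) + xlogy(c2, l2 / l0))
  } else {
    tab <- rbind(c(case_count, control_count), c(case_n, control_n))
    expctd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- 2 * sum(ifelse(tab == 0, 0, tab * log(tab / expctd)))
  }
  stat <- max(stat, 0)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Flag significant burden strata after Bonferroni correction
#'
#' The published analysis corrects the per-scope family of 12 tests (3
#' size bins x 2 CNV types plus margins) and states the corrected
#' significance level as P < 0.005 (strict inequality). That stated
#' threshold is the default; pass `threshold = NULL` to use the exact
#' quotient `alpha / m` (0.05 / 12 = 0.00417) instead.
#'
#' @param cells burden table with a `p_value` column.
#' @param alpha family-wise error rate.
#' @param m number of tests in the family.
#' @param threshold corrected per-test threshold; default 0.005.
#' @return `cells` with a logical `significant` column.
#' @export
apply_bonferroni <- function(cells, alpha = 0.05, m = 12, threshold = 0.005) {
  if (is.null(threshold)) threshold <- alpha / m
  cells$significant <- cells$p_value < threshold
  cells
}

#' Build the stratified rare-CNV burden table
#'
#' The machine form of the published burden tables: per CNV type
#' (deletion, duplication, both) and size bin (<100 kb, 100-400 kb,
#' >400 kb, total) the case/control event counts, per-subject rates,
#' likelihood-ratio chi-square statistic, p-value and Bonferroni-corrected
#' significance flag. Bin counts are additive into the margins (asserted).
#'
#' @param rare_calls rare CNV call table.
#' @param manifest sample manifest.
#' @param scope "autosomal" (all subjects, chromosomes 1-22) or "x_male"
#'   (male subjects, X chromosome).
#' @param method test variant, see [rate_lr_test()].
#' @param threshold corrected significance threshold, see
#'   [apply_bonferroni()].
#' @return data.frame with one row per stratum.
#' @export
build_burden_table <- function(rare_calls, manifest,
                               scope = c("autosomal", "x_male"),
                               method = "poisson", threshold = 0.005) {
  strata <- stratify_calls(rare_calls, manifest, scope)
  # additivity of margins
  pick <- function(type, bin, col) strata[strata$cnv_type == type & strata$size_bin == bin, col]
  for (col in c("case_count", "control_count")) {
    for (type in c("deletion", "duplication", "both")) {
      stopifnot(pick(type, "total", col) ==
                  sum(vapply(c("lt100kb", "100to400kb", "gt400kb"),
                             function(b) pick(type, b, col), numeric(1))))
    }
    for (bin in c("lt100kb", "100to400kb", "gt400kb", "total")) {
      stopifnot(pick("both", bin, col) ==
                  pick("deletion", bin, col) + pick("duplication", bin, col))
    }
  }
  strata$case_rate <- cnv_rate(strata$case_count, strata$case_n)
  strata$control_rate <- cnv_rate(strata$control_count, strata$control_n)
  tests <- mapply(function(c1, n1, c2, n2) rate_lr_test(c1, n1, c2, n2, method = method),
                  strata$case_count, strata$case_n,
                  strata$control_count, strata$control_n, SIMPLIFY = FALSE)
  strata$lr_chisq <- vapply(tests, `[[`, numeric(1), "statistic")
  strata$p_value <- vapply(tests, `[[`, numeric(1), "p_value")
  strata <- apply_bonferroni(strata, threshold = threshold)
  ord <- order(match(strata$cnv_type, c("deletion", "duplication", "both")),
               match(strata$size_bin, c("lt100kb", "100to400kb", "gt400kb", "total")))
  strata <- strata[ord, c("scope", "cnv_type", "size_bin", "case_count",
                          "control_count", "case_n", "control_n", "case_rate",
                          "control_rate", "lr_chisq", "p_value", "significant")]
  rownames(strata) <- NULL
  strata
}

#' Round a burden table for display
#'
#' Rates are printed to 2 decimals for the autosomal table and 3 decimals
#' for the male-X table, matching the published precision; internal values
#' stay unrounded.
#'
#' @param tbl output of [build_burden_table()].
#' @param digits rate decimals; defaults by scope.
#' @return data.frame with rounded rate and statistic columns.
#' @export
format_burden_table <- function(tbl, digits = NULL) {
  if (is.null(digits)) digits <- if (all(tbl$scope == "x_male")) 3 else 2
  tbl$case_rate <- round(tbl$case_rate, digits)
  tbl$control_rate <- round(tbl$control_rate, digits)
  tbl$lr_chisq <- round(tbl$lr_chisq, 2)
  tbl$p_value <- signif(tbl$p_value, 2)
  tbl
}
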