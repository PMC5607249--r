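valid_chroms <- function() c(as.character(1:22), "X", "Y", "MT")

normalize_cnv_type <- function(type) {
  x <- tolower(as.character(type))
  x[x %in% c("del", "deletion", "loss")] <- "deletion"
  x[x %in% c("dup", "duplication", "gain")] <- "duplication"
  bad <- !x %in% c("deletion", "duplication")
  if (any(bad)) {
    stop("unrecognized CNV type(s): ", paste(unique(type[bad]), collapse = ", "))
  }
  x
}

#' Construct a validated CNV call table
#'
#' A CNV call table is a plain data.frame with one row per segment-level
#' call and columns `sample_id`, `chrom`, `start`, `end`, `type`
#' ("deletion"/"duplication"; "Del"/"Dup" accepted on input), `n_probes`
#' and optionally `copy_state`. Coordinates are 1-based inclusive.
#'
#' @param df data.frame with at least the required columns.
#' @param require_probes require the `n_probes` column to be present and
#'   non-missing (it is mandatory for QC filtering but absent from
#'   annotation-only fixtures).
#' @return the validated, normalized data.frame.
#' @export
as_cnv_calls <- function(df, require_probes = TRUE) {
  req <- c("sample_id", "chrom", "start", "end", "type")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("CNV call table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)
  df$sample_id <- as.character(df$sample_id)
  df$chrom <- normalize_chrom(df$chrom)
  df$type <- normalize_cnv_type(df$type)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  bad_chrom <- !df$chrom %in% valid_chroms()
  if (any(bad_chrom)) {
    stop("unknown chromosome in call row(s) ",
         paste(utils::head(which(bad_chrom), 5), collapse = ", "))
  }
  bad_coord <- is.na(df$start) | is.na(df$end) | df$start < 1 | df$end < df$start
  if (any(bad_coord)) {
    stop("invalid coordinates (need 1 <= start <= end) in call row(s) ",
         paste(utils::head(which(bad_coord), 5), collapse = ", "))
  }
  if (!"n_probes" %in% names(df)) {
    if (require_probes) stop("CNV call table lacks column(s): n_probes")
    df$n_probes <- NA_real_
  } else if (require_probes) {
    bad_np <- is.na(df$n_probes) | df$n_probes < 1
    if (any(bad_np)) {
      stop("missing or invalid n_probes in call row(s) ",
           paste(utils::head(which(bad_np), 5), collapse = ", "))
    }
  }
  if ("copy_state" %in% names(df)) {
    cs <- df$copy_state
    known <- !is.na(cs)
    # diploid baseline: deletion < 2 < duplication (autosomes and male X
    # with copy_state already on the appropriate baseline)
    inconsistent <- known &
      ((df$type == "deletion" & cs >= 2) | (df$type == "duplication" & cs <= 2))
    if (any(inconsistent)) {
      stop("copy_state inconsistent with type in call row(s) ",
           paste(utils::head(which(inconsistent), 5), collapse = ", "))
    }
  }
  rownames(df) <- NULL
  df
}

#' Read a tab-delimited CNV call table
#'
#' Expected header columns: `sample_id`, `chrom`, `start`, `end`, `type`,
#' `n_probes` and optionally `copy_state`; coordinates 1-based inclusive.
#'
#' @param path file path.
#' @inheritParams as_cnv_calls
#' @return validated call table (see [as_cnv_calls()]).
#' @export
read_cnv_calls <- function(path, require_probes = TRUE) {
  as_cnv_calls(read.delim(path, stringsAsFactors = FALSE), require_probes = require_probes)
}

#' Construct a validated sample manifest
#'
#' One row per subject with columns `sample_id`, `sex` ("male"/"female"),
#' `group` ("case"/"control") and optional trio links `mother_id`,
#' `father_id` (`NA` = parent not genotyped). Trio links must reference
#' samples present in the manifest.
#'
#' @param df data.frame of subject records.
#' @return validated manifest data.frame.
#' @export
as_sample_manifest <- function(df) {
  req <- c("sample_id", "sex", "group")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("manifest lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in manifest")
  df$sex <- tolower(as.character(df$sex))
  df$sex[df$sex %in% c("m")] <- "male"
  df$sex[df$sex %in% c("f")] <- "female"
  if (!all(df$sex %in% c("male", "female"))) stop("sex must be male/female")
  df$group <- tolower(as.character(df$group))
  if (!all(df$group %in% c("case", "control"))) stop("group must be case/control")
  for (col in c("mother_id", "father_id")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
    df[[col]] <- as.character(df[[col]])
    df[[col]][!is.na(df[[col]]) & df[[col]] == ""] <- NA_character_
    dangling <- !is.na(df[[col]]) & !df[[col]] %in% df$sample_id
    if (any(dangling)) {
      stop(col, " references unknown sample(s): ",
           paste(unique(df[[col]][dangling]), collapse = ", "))
    }
  }
  rownames(df) <- NULL
  df
}

#' Read a tab-delimited sample manifest
#'
#' @param path file path; columns `sample_id`, `sex`, `group`,
#'   `mother_id`, `father_id` (empty = unknown).
#' @return validated manifest (see [as_sample_manifest()]).
#' @export
read_sample_manifest <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  as_sample_manifest(df)
}

#' Construct a region set
#'
#' A region set is a named collection of genomic regions (1-based
#' inclusive) used for exclusion filtering, hot-spot matching, pathogenic
#' reference matching or gene annotation. Each region can carry a label
#' and a dosage direction ("deletion", "duplication" or "any") restricting
#' which CNV types it matches.
#'
#' @param chrom,start,end region coordinates (1-based inclusive).
#' @param label optional region labels (unique when present).
#' @param dosage optional per-region dosage direction; defaults to "any".
#' @param name name of the set (e.g. "centromeres", "hot_spots").
#' @return data.frame of class `region_set`, sorted by chromosome and start.
#' @export
region_set <- function(chrom, start, end, label = NULL, dosage = NULL,
                       name = "regions") {
  chrom <- normalize_chrom(chrom)
  known <- chrom %in% valid_chroms()
  if (!all(known)) {
    warning("skipping region(s) on unknown chromosome(s): ",
            paste(unique(chrom[!known]), collapse = ", "))
  }
  n <- length(chrom)
  if (is.null(label)) label <- sprintf("%s_%d", name, seq_len(n))
  if (is.null(dosage)) dosage <- rep("any", n)
  dosage <- tolower(as.character(dosage))
  dosage[dosage %in% c("del", "loss")] <- "deletion"
  dosage[dosage %in% c("dup", "gain")] <- "duplication"
  dosage[!dosage %in% c("deletion", "duplication")] <- "any"
  df <- data.frame(chrom = chrom, start = as.numeric(start), end = as.numeric(end),
                   label = as.character(label), dosage = dosage,
                   stringsAsFactors = FALSE)[known, , drop = FALSE]
  stopifnot(all(df$end >= df$start), all(df$start >= 1))
  df <- df[order(match(df$chrom, valid_chroms()), df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "set_name") <- name
  class(df) <- c("region_set", "data.frame")
  df
}

#' Read a BED file into a region set
#'
#' BED coordinates (0-based half-open) are converted to the package's
#' 1-based inclusive convention at this boundary. Columns beyond the
#' first three are interpreted as `name` (column 4) and, when its values
#' are "deletion"/"duplication"/"any" (or Del/Dup), a dosage direction
#' (column 5, else BED score/strand columns are ignored). Regions on
#' chromosomes outside 1-22/X/Y/MT are skipped with a warning.
#'
#' @param path BED3+ file path.
#' @param name name for the region set.
#' @return a [region_set()].
#' @export
read_region_bed <- function(path, name = sub("\\.bed$", "", basename(path))) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 3) stop("BED file needs at least 3 columns: ", path)
  label <- if (ncol(df) >= 4) as.character(df[[4]]) else NULL
  dosage <- NULL
  if (ncol(df) >= 5) {
    cand <- tolower(as.character(df[[5]]))
    if (all(cand %in% c("deletion", "duplication", "any", "del", "dup"))) dosage <- cand
  }
  region_set(df[[1]], as.numeric(df[[2]]) + 1, as.numeric(df[[3]]),
             label = label, dosage = dosage, name = name)
}

# GRanges view of a call table or region set (internal).
as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
}

# findOverlaps between two tables; disjoint chromosome sets are a normal
# situation here, so the seqlevel-mismatch warning is silenced
overlap_hits <- function(query_df, subject_df) {
  withCallingHandlers(
    GenomicRanges::findOverlaps(as_granges(query_df), as_granges(subject_df)),
    warning = function(w) {
      if (grepl("sequence levels in common", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (col in names(df)) {
    if (is.list(df[[col]])) {
      df[[col]] <- vapply(df[[col]], function(x) paste(x, collapse = ","), character(1))
    }
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
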