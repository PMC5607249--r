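#' Run the full rare-CNV case-control pipeline
#'
#' Executes the analysis stages in study order - QC filtering, locus
#' clustering, rarity selection, stratified burden tables (autosomal and
#' male-X), and, when region sets are supplied, hot-spot / pathogenic
#' classification, gene annotation, trio inheritance and two-hit
#' detection. When `outdir` is given, writes the burden tables, locus
#' table, classified-CNV table, two-hit report, QC report (JSON) and a
#' small run log; outputs are deterministic for identical inputs.
#'
#' @param calls CNV call table (see [as_cnv_calls()]) or path to one.
#' @param manifest sample manifest (see [as_sample_manifest()]) or path.
#' @param qc a [qc_config()].
#' @param rarity a [rarity_config()].
#' @param hotspots,pathogenic,genes optional [region_set()]s enabling the
#'   classification stages.
#' @param threshold Bonferroni-corrected significance threshold.
#' @param outdir optional output directory (created if needed).
#' @return list with `qc`, `loci`, `rare_calls`, `burden_autosomal`,
#'   `burden_x_male`, and (when region sets are given) `classified` and
#'   `two_hit`.
#' @export
run_pipeline <- function(calls, manifest, qc = qc_config(),
                         rarity = rarity_config(), hotspots = NULL,
                         pathogenic = NULL, genes = NULL,
                         threshold = 0.005, outdir = NULL) {
  if (is.character(calls)) calls <- read_cnv_calls(calls)
  if (is.character(manifest)) manifest <- read_sample_manifest(manifest)
  calls <- as_cnv_calls(calls)
  manifest <- as_sample_manifest(manifest)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  qc_res <- stage("qc_filter", qc_report(calls, manifest, qc))
  clustered <- stage("cluster_loci", cluster_loci(qc_res$calls))
  loci <- stage("locus_frequency", locus_summary(clustered, manifest, rarity))
  rare <- stage("select_rare", select_rare(clustered, manifest, rarity))
  burden_a <- stage("burden_autosomal",
                    build_burden_table(rare, manifest, "autosomal",
                                       threshold = threshold))
  burden_x <- stage("burden_x_male",
                    build_burden_table(rare, manifest, "x_male",
                                       threshold = threshold))
  out <- list(qc = qc_res[setdiff(names(qc_res), "calls")],
              loci = loci, rare_calls = rare,
              burden_autosomal = burden_a, burden_x_male = burden_x)
  if (!is.null(hotspots) || !is.null(pathogenic)) {
    classified <- rare
    if (!is.null(hotspots)) {
      classified <- stage("annotate_hot_spots", annotate_hot_spots(classified, hotspots))
    }
    classified <- stage("classify_pathogenic",
                        classify_pathogenic(classified, pathogenic))
    if (!is.null(genes)) {
      classified <- stage("annotate_genes", annotate_genes(classified, genes))
    }
    has_trios <- any(!is.na(manifest$mother_id)) || any(!is.na(manifest$father_id))
    if (has_trios) {
      classified <- stage("infer_origins", infer_origins(classified, manifest))
    }
    control_calls <- clustered[clustered$sample_id %in%
      manifest$sample_id[manifest$group == "control"], , drop = FALSE]
    classified <- stage("control_carriers",
                        control_carrier_lookup(classified, control_calls, manifest))
    out$classified <- classified
    out$two_hit <- stage("detect_two_hit", detect_two_hit(classified))
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(format_burden_table(burden_a), file.path(outdir, "burden_autosomal.tsv"))
    write_tsv(format_burden_table(burden_x), file.path(outdir, "burden_x_male.tsv"))
    write_tsv(loci, file.path(outdir, "loci.tsv"))
    write_tsv(rare, file.path(outdir, "rare_calls.tsv"))
    if (!is.null(out$classified)) {
      write_tsv(out$classified, file.path(outdir, "classified_cnvs.tsv"))
      write_tsv(out$two_hit, file.path(outdir, "two_hit.tsv"))
    }
    jsonlite::write_json(out$qc, file.path(outdir, "qc_report.json"),
                         auto_unbox = TRUE, dataframe = "rows", pretty = TRUE)
    log <- list(n_calls_in = nrow(calls), n_samples = nrow(manifest),
                n_rare_calls = nrow(rare),
                input_digest = digest_inputs(calls, manifest))
    jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

# cheap content fingerprint (sum-based; avoids external digest deps)
digest_inputs <- function(calls, manifest) {
  fmt <- function(df) paste(vapply(df, function(col) paste(col, collapse = ","),
                                   character(1)), collapse = ";")
  sprintf("%08x", sum(utf8ToInt(fmt(calls))) + sum(utf8ToInt(fmt(manifest))) %% 2^31)
}
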