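#' Default per-stratum CNV rate parameters
#'
#' Mean rare-CNV events per subject for cases and controls, per scope
#' (autosomal: all subjects; x: male subjects), CNV type and size bin.
#' Defaults are calibrated to the published cohort: the autosomal rates
#' reproduce case/control totals 2.71 and 0.77 events per subject, the
#' male-X rates 0.217 and 0.011.
#'
#' @return data.frame with columns `scope`, `cnv_type`, `size_bin`,
#'   `case_rate`, `control_rate`.
#' @export
default_rate_params <- function() {
  data.frame(
    scope = rep(c("autosomal", "x"), each = 6),
    cnv_type = rep(rep(c("deletion", "duplication"), each = 3), 2),
    size_bin = rep(c("lt100kb", "100to400kb", "gt400kb"), 4),
    case_rate = c(333, 88, 18, 263, 150, 55, 10, 7, 8, 6, 27, 7) /
      rep(c(335, 299), each = 6),
    control_rate = c(394, 43, 14, 229, 144, 19, 1, 1, 0, 1, 3, 0) /
      rep(c(1093, 525), each = 6)
  )
}

#' Simulation configuration for synthetic CNV cohorts
#'
#' Defines the cohort structure and data-generating process of
#' [simulate_cohort()] and [simulate_trios()]. Defaults emulate the
#' published study: 335 cases (299 male) vs 1093 controls (525 male) on
#' hg19, per-subject event counts Poisson with the per-stratum rates of
#' [default_rate_params()], log-uniform sizes within each bin, and probe
#' support derived from the SNP-array probe density (~0.7 kb median probe
#' spacing, i.e. ~1.4 probes per kb).
#'
#' @param seed integer RNG seed; all randomness flows from it.
#' @param n_cases,n_controls subject counts.
#' @param male_fraction_cases,male_fraction_controls male fractions.
#' @param genome named vector of chromosome lengths (with X).
#' @param rate_params per-stratum rates, see [default_rate_params()].
#' @param common_loci optional data.frame (`label`, `chrom`, `start`,
#'   `end`, `type`, `case_freq`, `control_freq`) of planted recurrent loci
#'   whose carriers receive a call at exactly those coordinates; plant
#'   frequencies >= 1% to test rarity exclusion.
#' @param trio_fraction fraction of case subjects given simulated parents.
#' @param transmission_prob probability a child call is inherited (copied
#'   into one parent) rather than de novo.
#' @param probe_density probes per kb for `n_probes` emission.
#' @param n_decoys number of QC-violating decoy calls to plant (0 =
#'   QC-clean); decoys cycle through low probe support, sub-10 kb size
#'   and blacklist placement (the latter only when `blacklist` is given).
#' @param blacklist optional [region_set()] in which blacklist decoys are
#'   placed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1, n_cases = 335, n_controls = 1093,
                              male_fraction_cases = 299 / 335,
                              male_fraction_controls = 525 / 1093,
                              genome = hg19_chrom_sizes(),
                              rate_params = default_rate_params(),
                              common_loci = NULL,
                              trio_fraction = 0, transmission_prob = 0.5,
                              probe_density = 1.4,
                              n_decoys = 0, blacklist = NULL) {
  stopifnot(n_cases >= 1, n_controls >= 1,
            male_fraction_cases >= 0, male_fraction_cases <= 1,
            male_fraction_controls >= 0, male_fraction_controls <= 1,
            all(genome > 0), all(rate_params$case_rate >= 0),
            all(rate_params$control_rate >= 0),
            trio_fraction >= 0, trio_fraction <= 1,
            transmission_prob >= 0, transmission_prob <= 1,
            probe_density > 0, n_decoys >= 0)
  # sanity: expected placed bp must fit comfortably in the genome
  # (mean of a log-uniform size on [a, b] is (b - a) / log(b / a))
  mean_size_bp <- 1000 * vapply(bin_size_ranges, function(r) {
    (r[2] - r[1]) / log(r[2] / r[1])
  }, numeric(1))
  expected_events <- rate_params$case_rate * n_cases +
    rate_params$control_rate * n_controls
  expected_bp <- sum(expected_events * mean_size_bp[rate_params$size_bin])
  if (expected_bp > 0.5 * sum(genome)) {
    stop("configured rates imply expected CNV footprint exceeding genome capacity")
  }
  structure(list(seed = seed, n_cases = n_cases, n_controls = n_controls,
                 male_fraction_cases = male_fraction_cases,
                 male_fraction_controls = male_fraction_controls,
                 genome = genome, rate_params = rate_params,
                 common_loci = common_loci, trio_fraction = trio_fraction,
                 transmission_prob = transmission_prob,
                 probe_density = probe_density,
                 n_decoys = n_decoys, blacklist = blacklist),
            class = "simulation_config")
}

# size in kb drawn log-uniformly within the bin, kept clear of the
# rounding boundary so the realized bin always equals the planted one
bin_size_ranges <- list(lt100kb = c(10, 99.4), `100to400kb` = c(100, 399.4),
                        gt400kb = c(401, 3000))

sim_probes <- function(size_kb_val, density) {
  pmax(20, round_half_up(density * size_kb_val))
}

sim_manifest <- function(config) {
  n_male_cases <- round(config$n_cases * config$male_fraction_cases)
  n_male_controls <- round(config$n_controls * config$male_fraction_controls)
  data.frame(
    sample_id = c(sprintf("case_%04d", seq_len(config$n_cases)),
                  sprintf("ctrl_%04d", seq_len(config$n_controls))),
    sex = c(rep(c("male", "female"),
                c(n_male_cases, config$n_cases - n_male_cases)),
            rep(c("male", "female"),
                c(n_male_controls, config$n_controls - n_male_controls))),
    group = rep(c("case", "control"), c(config$n_cases, config$n_controls)),
    mother_id = NA_character_, father_id = NA_character_
  )
}

place_background <- function(n, scope, genome, bin, blacklist = NULL) {
  if (n == 0) {
    return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0)))
  }
  chroms <- if (scope == "x") "X" else intersect(names(genome), as.character(1:22))
  lens <- genome[chroms]
  chrom <- sample(chroms, n, replace = TRUE, prob = lens / sum(lens))
  rng <- bin_size_ranges[[bin]]
  sz <- round(1000 * exp(runif(n, log(rng[1]), log(rng[2]))))
  start <- floor(runif(n, 1, genome[chrom] - sz)) + 1
  out <- data.frame(chrom = chrom, start = start, end = start + sz)
  # background calls are guaranteed QC-clean: redraw any that touch the
  # blacklist so only planted decoys can violate the exclusion filter
  if (!is.null(blacklist) && nrow(blacklist)) {
    for (iter in 1:100) {
      hit <- vapply(seq_len(nrow(out)), function(i) {
        any(overlap_bp(out$chrom[i], out$start[i], out$end[i],
                       blacklist$chrom, blacklist$start, blacklist$end) > 0)
      }, logical(1))
      if (!any(hit)) break
      redrawn <- Recall(sum(hit), scope, genome, bin, blacklist = NULL)
      out[hit, ] <- redrawn
    }
  }
  out
}

#' Simulate a case-control CNV cohort
#'
#' Per subject and stratum, the event count is Poisson with the group's
#' rate; X-chromosome events are assigned to male subjects only. Each
#' background event is placed uniformly on a length-weighted random
#' chromosome with a log-uniform size within its bin; planted common loci
#' add calls at fixed coordinates to Bernoulli-sampled carriers. The truth
#' table records, per call, the planted stratum, origin class
#' ("background", "common" with its label, or a decoy kind) so recovery
#' can be checked end to end. Fully reproducible for a fixed seed.
#'
#' @param config a [simulation_config()].
#' @return list with `manifest`, `calls` (validated call table), `truth`
#'   and the `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  manifest <- sim_manifest(config)
  rp <- config$rate_params
  pieces <- list()
  for (grp in c("case", "control")) {
    rate_col <- paste0(grp, "_rate")
    for (i in seq_len(nrow(rp))) {
      eligible <- manifest$sample_id[manifest$group == grp &
        (rp$scope[i] != "x" | manifest$sex == "male")]
      if (!length(eligible)) next
      k <- rpois(length(eligible), rp[[rate_col]][i])
      total <- sum(k)
      if (total == 0) next
      pos <- place_background(total, rp$scope[i], config$genome, rp$size_bin[i],
                              blacklist = config$blacklist)
      pieces[[length(pieces) + 1]] <- data.frame(
        sample_id = rep(eligible, k),
        pos,
        type = rp$cnv_type[i],
        planted = "background",
        locus_label = sprintf("bg_%s_%s_%s_%d", grp, rp$scope[i], rp$size_bin[i],
                              seq_len(total)),
        scope = rp$scope[i], size_bin = rp$size_bin[i]
      )
    }
  }
  if (!is.null(config$common_loci)) {
    cl <- config$common_loci
    for (i in seq_len(nrow(cl))) {
      on_x <- normalize_chrom(cl$chrom[i]) == "X"
      for (grp in c("case", "control")) {
        freq <- cl[[paste0(grp, "_freq")]][i]
        eligible <- manifest$sample_id[manifest$group == grp &
          (!on_x | manifest$sex == "male")]
        carriers <- eligible[rbinom(length(eligible), 1, freq) == 1]
        if (!length(carriers)) next
        pieces[[length(pieces) + 1]] <- data.frame(
          sample_id = carriers, chrom = normalize_chrom(cl$chrom[i]),
          start = cl$start[i], end = cl$end[i], type = cl$type[i],
          planted = "common", locus_label = cl$label[i],
          scope = if (on_x) "x" else "autosomal",
          size_bin = as.character(size_bin(size_kb(cl$start[i], cl$end[i])))
        )
      }
    }
  }
  calls <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(sample_id = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0), type = character(0),
               planted = character(0), locus_label = character(0),
               scope = character(0), size_bin = character(0))
  calls$n_probes <- sim_probes(size_kb(calls$start, calls$end), config$probe_density)
  if (config$n_decoys > 0) calls <- add_decoys(calls, manifest, config)
  truth <- calls[, c("sample_id", "chrom", "start", "end", "type", "planted",
                     "locus_label", "scope", "size_bin")]
  calls <- as_cnv_calls(calls[, c("sample_id", "chrom", "start", "end", "type",
                                  "n_probes")])
  list(manifest = as_sample_manifest(manifest), calls = calls, truth = truth,
       config = config)
}

add_decoys <- function(calls, manifest, config) {
  kinds <- c("decoy_low_probe", "decoy_small")
  if (!is.null(config$blacklist) && nrow(config$blacklist)) {
    kinds <- c(kinds, "decoy_blacklist")
  }
  kind <- rep_len(kinds, config$n_decoys)
  samples <- sample(manifest$sample_id, config$n_decoys, replace = TRUE)
  rows <- lapply(seq_len(config$n_decoys), function(i) {
    if (kind[i] == "decoy_blacklist") {
      j <- sample(nrow(config$blacklist), 1)
      r <- config$blacklist[j, ]
      sz <- min(50000, r$end - r$start)
      start <- r$start
      np <- 70
    } else if (kind[i] == "decoy_small") {
      sz <- round(runif(1, 1000, 9400))  # rounds below the 10 kb threshold
      start <- floor(runif(1, 1e6, 2e8))
      np <- 20
    } else {
      sz <- 50000
      start <- floor(runif(1, 1e6, 2e8))
      np <- sample(19, 1)  # below the 20-probe threshold
    }
    chrom <- if (kind[i] == "decoy_blacklist") r$chrom else "1"
    data.frame(sample_id = samples[i], chrom = chrom, start = start,
               end = start + sz, type = "deletion", planted = kind[i],
               locus_label = paste0(kind[i], "_", i),
               scope = "autosomal", size_bin = "lt100kb", n_probes = np)
  })
  rbind(calls, do.call(rbind, rows))
}

#' Simulate parents and call transmission for case trios
#'
#' Gives the first `trio_fraction` of case subjects a genotyped mother and
#' father. Each child call is independently transmitted with probability
#' `transmission_prob` - copied at exact coordinates into one parent's
#' call set (mother or father with equal probability) - or left de novo.
#' Parents additionally receive background calls at control autosomal
#' rates so inheritance matching must discriminate, and the truth table
#' records the planted origin of every child call.
#'
#' @param config a [simulation_config()] with `trio_fraction > 0`.
#' @param cohort output of [simulate_cohort()] under the same config.
#' @return list with `manifest` (cohort manifest with trio links plus
#'   parent records), `calls` (cohort + parent calls), `truth` (planted
#'   origin per child call).
#' @export
simulate_trios <- function(config, cohort) {
  stopifnot(inherits(config, "simulation_config"), config$trio_fraction > 0)
  set.seed(config$seed + 1)
  manifest <- cohort$manifest
  case_ids <- manifest$sample_id[manifest$group == "case"]
  children <- case_ids[seq_len(round(config$trio_fraction * length(case_ids)))]
  parent_rows <- data.frame(
    sample_id = c(paste0(children, "_mo"), paste0(children, "_fa")),
    sex = rep(c("female", "male"), each = length(children)),
    group = "control", mother_id = NA_character_, father_id = NA_character_
  )
  manifest$mother_id[match(children, manifest$sample_id)] <- paste0(children, "_mo")
  manifest$father_id[match(children, manifest$sample_id)] <- paste0(children, "_fa")
  manifest <- rbind(manifest, parent_rows)

  child_calls <- cohort$calls[cohort$calls$sample_id %in% children, , drop = FALSE]
  n <- nrow(child_calls)
  transmitted <- rbinom(n, 1, config$transmission_prob) == 1
  from_mother <- rbinom(n, 1, 0.5) == 1
  origin <- ifelse(!transmitted, "de_novo",
                   ifelse(from_mother, "maternal", "paternal"))
  parent_calls <- child_calls[transmitted, , drop = FALSE]
  if (nrow(parent_calls)) {
    parent_calls$sample_id <- paste0(parent_calls$sample_id,
                                     ifelse(from_mother[transmitted], "_mo", "_fa"))
  }
  # background noise in parents at control autosomal rates
  rp <- config$rate_params[config$rate_params$scope == "autosomal", , drop = FALSE]
  noise <- list()
  for (i in seq_len(nrow(rp))) {
    k <- rpois(nrow(parent_rows), rp$control_rate[i])
    total <- sum(k)
    if (total == 0) next
    pos <- place_background(total, "autosomal", config$genome, rp$size_bin[i])
    noise[[length(noise) + 1]] <- data.frame(
      sample_id = rep(parent_rows$sample_id, k), pos, type = rp$cnv_type[i],
      n_probes = sim_probes(size_kb(pos$start, pos$end), config$probe_density))
  }
  all_parent <- rbind(parent_calls[, c("sample_id", "chrom", "start", "end",
                                       "type", "n_probes")],
                      if (length(noise)) do.call(rbind, noise))
  truth <- cbind(child_calls[, c("sample_id", "chrom", "start", "end", "type")],
                 origin = origin)
  list(manifest = as_sample_manifest(manifest),
       calls = as_cnv_calls(rbind(cohort$calls, all_parent)),
       truth = truth)
}

#' Deterministic cohort reproducing the published burden-table margins
#'
#' Builds, without randomness, a cohort of 335 cases (299 male) and 1093
#' controls (525 male) whose rare-CNV counts per stratum equal the
#' published tables exactly (e.g. 333 case autosomal deletions < 100 kb;
#' 65 male-case X-chromosome CNVs). Calls are placed at non-overlapping
#' private positions (round-robin over subjects and chromosomes with
#' generous gaps) so that every call is rare, and bin-representative
#' sizes (50 kb, 250 kb, 500 kb) put each call in its intended size bin.
#' Running [build_burden_table()] on this cohort reproduces the published
#' rate columns after rounding (2.71/0.77 autosomal total, 0.217/0.011
#' male-X total).
#'
#' @return list with `manifest` and `calls`.
#' @export
make_paper_fixture_cohort <- function() {
  manifest <- sim_manifest(simulation_config())
  counts <- default_rate_params()
  counts$case_count <- c(333, 88, 18, 263, 150, 55, 10, 7, 8, 6, 27, 7)
  counts$control_count <- c(394, 43, 14, 229, 144, 19, 1, 1, 0, 1, 3, 0)
  sizes_bp <- c(lt100kb = 50000, `100to400kb` = 250000, gt400kb = 500000)
  genome <- hg19_chrom_sizes()
  cursors <- setNames(rep(1e6, 23), c(as.character(1:22), "X"))
  auto_cycle <- 0L
  pieces <- list()
  for (i in seq_len(nrow(counts))) {
    for (grp in c("case", "control")) {
      n <- counts[[paste0(grp, "_count")]][i]
      if (n == 0) next
      on_x <- counts$scope[i] == "x"
      eligible <- manifest$sample_id[manifest$group == grp &
        (!on_x | manifest$sex == "male")]
      sz <- sizes_bp[[counts$size_bin[i]]]
      chrom <- start <- numeric(n)
      chrom <- character(n)
      for (j in seq_len(n)) {
        ch <- if (on_x) "X" else {
          auto_cycle <- auto_cycle %% 22L + 1L
          as.character(auto_cycle)
        }
        chrom[j] <- ch
        start[j] <- cursors[[ch]]
        cursors[[ch]] <- cursors[[ch]] + sz + 50000
        if (cursors[[ch]] > genome[[ch]] - sz) {
          stop("fixture cohort placement overflow on chromosome ", ch)
        }
      }
      pieces[[length(pieces) + 1]] <- data.frame(
        sample_id = rep_len(eligible, n), chrom = chrom, start = start,
        end = start + sz, type = counts$cnv_type[i],
        n_probes = sim_probes(sz / 1000, 1.4))
    }
  }
  calls <- do.call(rbind, pieces)
  list(manifest = as_sample_manifest(manifest), calls = as_cnv_calls(calls))
}
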