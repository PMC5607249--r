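zero_rates <- function() {
  rp <- default_rate_params()
  rp$case_rate <- rp$control_rate <- 0
  rp
}

small_config <- function(seed = 1, ...) {
  simulation_config(seed = seed, n_cases = 60, n_controls = 120, ...)
}

test_that("zero rates give an empty call table with the manifest intact", {
  sim <- simulate_cohort(small_config(rate_params = zero_rates()))
  expect_equal(nrow(sim$calls), 0)
  expect_equal(nrow(sim$manifest), 180)
  expect_equal(sum(sim$manifest$group == "case"), 60)
})

test_that("identical seeds reproduce byte-identical cohorts; seeds differ", {
  a <- simulate_cohort(small_config(seed = 7))
  b <- simulate_cohort(small_config(seed = 7))
  c <- simulate_cohort(small_config(seed = 8))
  expect_identical(a, b)
  expect_false(identical(a$calls, c$calls))
})

test_that("event totals track the planted Poisson rates", {
  cfg <- simulation_config(seed = 42)
  sim <- simulate_cohort(cfg)
  auto_case <- sim$truth$scope == "autosomal" &
    sim$calls$sample_id %in% sim$manifest$sample_id[sim$manifest$group == "case"]
  expected <- 335 * 2.71
  expect_lt(abs(sum(auto_case) - 907), 3 * sqrt(expected))
  # every simulated call passes QC by construction
  qc <- apply_qc(sim$calls, qc_config())
  expect_equal(nrow(qc$calls), nrow(sim$calls))
})

test_that("planted common loci are excluded by rarity selection; private calls survive", {
  common <- data.frame(label = "common5pct", chrom = "6", start = 30e6,
                       end = 30.5e6, type = "deletion",
                       case_freq = 0.05, control_freq = 0.05)
  # study-sized cohort: with 335 cases, up to 3 case carriers stay rare
  sim <- simulate_cohort(simulation_config(seed = 3, common_loci = common))
  cl <- cluster_loci(sim$calls)
  rare <- select_rare(cl, sim$manifest)
  planted_common <- sim$truth$planted == "common"
  expect_gt(sum(planted_common), 0)
  expect_false(any(rare$start == 30e6 & rare$chrom == "6"))
  # background (private) calls are retained
  expect_gt(nrow(rare), 0.9 * sum(!planted_common))
})

test_that("QC removes exactly the planted decoys", {
  blk <- region_set("9", 40e6, 42e6, name = "blacklist")
  cfg <- small_config(seed = 5, n_decoys = 9, blacklist = blk)
  sim <- simulate_cohort(cfg)
  qc <- apply_qc(sim$calls, qc_config(exclusion_sets = list(blk)))
  is_decoy <- grepl("^decoy", sim$truth$planted)
  expect_equal(sum(is_decoy), 9)
  kept_key <- with(qc$calls, paste(sample_id, chrom, start, end))
  truth_key <- with(sim$truth, paste(sample_id, chrom, start, end))
  expect_setequal(setdiff(truth_key, kept_key), truth_key[is_decoy])
})

test_that("trio simulation recovers planted transmission labels exactly at the extremes", {
  for (p in c(0, 1)) {
    cfg <- small_config(seed = 11, trio_fraction = 0.5, transmission_prob = p)
    cohort <- simulate_cohort(cfg)
    trio <- simulate_trios(cfg, cohort)
    inferred <- infer_origins(trio$calls, trio$manifest)
    child_ids <- trio$manifest$sample_id[!is.na(trio$manifest$mother_id)]
    kid_calls <- inferred[inferred$sample_id %in% child_ids, ]
    expect_gt(nrow(kid_calls), 0)
    if (p == 0) {
      expect_true(all(kid_calls$origin == "de_novo"))
    } else {
      expect_true(all(kid_calls$origin %in% c("maternal", "paternal")))
    }
  }
})

test_that("the deterministic fixture cohort reproduces the published margins exactly", {
  fx <- make_paper_fixture_cohort()
  fx2 <- make_paper_fixture_cohort()
  expect_identical(fx, fx2)
  expect_equal(nrow(fx$manifest), 1428)
  expect_equal(sum(fx$manifest$group == "case"), 335)
  expect_equal(sum(fx$manifest$sex == "male" & fx$manifest$group == "case"), 299)
  auto <- fx$calls[fx$calls$chrom %in% as.character(1:22), ]
  case_ids <- fx$manifest$sample_id[fx$manifest$group == "case"]
  expect_equal(sum(auto$sample_id %in% case_ids), 907)
  expect_equal(sum(!auto$sample_id %in% case_ids), 843)
  x <- fx$calls[fx$calls$chrom == "X", ]
  expect_equal(sum(x$sample_id %in% case_ids), 65)
  expect_equal(sum(!x$sample_id %in% case_ids), 6)
  # deletions < 100 kb in cases: the printed 333
  sz <- size_kb(auto$start, auto$end)
  expect_equal(sum(auto$type == "deletion" & sz < 100 & auto$sample_id %in% case_ids),
               333)
  # no two fixture calls overlap, so every call is private and rare
  cl <- cluster_loci(fx$calls)
  expect_equal(length(unique(cl$locus_id)), nrow(fx$calls))
})
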