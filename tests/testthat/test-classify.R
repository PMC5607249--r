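test_that("hot-spot annotation matches regions and honors dosage direction", {
  hotspots <- fixture_hotspot_regions()
  dup16p <- make_calls("16", 29591757, 30191895, type = "duplication")
  hit <- annotate_hot_spots(dup16p, hotspots)
  expect_true("hs_16p11.2" %in% hit$hot_spot_hits[[1]])
  off <- annotate_hot_spots(make_calls("3", 1e6, 2e6), hotspots)
  expect_length(off$hot_spot_hits[[1]], 0)
  # deletion-specific region does not match a duplication
  del_only <- region_set("16", 29.5e6, 30.2e6, label = "r", dosage = "deletion")
  expect_length(annotate_hot_spots(dup16p, del_only)$hot_spot_hits[[1]], 0)
  expect_warning(annotate_hot_spots(dup16p, del_only[0, ]), "empty region set")
})

test_that("pathogenic classification needs >= 400 kb plus reference overlap", {
  ref <- region_set("15", 32e6, 33e6, label = "ref15")
  just_under <- make_calls("15", 32458661, 32857470)  # 399 kb, overlapping
  out <- classify_pathogenic(just_under, ref)
  expect_false(out$pathogenic)
  big_no_overlap <- make_calls("15", 90e6, 90.8e6)    # 800 kb, no reference
  expect_false(classify_pathogenic(big_no_overlap, ref)$pathogenic)
  big_overlap <- make_calls("15", 32.2e6, 32.7e6)     # 500 kb, overlapping
  expect_true(classify_pathogenic(big_overlap, ref)$pathogenic)
  # hot-spot evidence bypasses the size threshold
  small_hs <- annotate_hot_spots(just_under, fixture_hotspot_regions())
  expect_true(suppressWarnings(classify_pathogenic(small_hs, ref[0, ])$pathogenic))
})

test_that("pathogenic flagging is monotone in the reference set", {
  set.seed(5)
  calls <- make_calls("7", s <- floor(runif(20, 1e6, 1e8)), s + 5e5)
  small_ref <- region_set("7", 2e7, 2.5e7)
  big_ref <- region_set(c("7", "7"), c(2e7, 6e7), c(2.5e7, 9e7))
  f_small <- classify_pathogenic(calls, small_ref)$pathogenic
  f_big <- classify_pathogenic(calls, big_ref)$pathogenic
  expect_true(all(f_big[f_small]))  # adding regions never un-flags
})

test_that("gene annotation returns position-sorted symbols and matches brute force", {
  genes <- region_set("1", c(1e6, 3e6, 5e6), c(2e6, 4e6, 6e6),
                      label = c("GENE1", "GENE2", "GENE3"))
  one <- annotate_genes(make_calls("1", 0.5e6, 2.5e6), genes)
  expect_equal(one$genes[[1]], "GENE1")
  none <- annotate_genes(make_calls("1", 2.2e6, 2.8e6), genes)
  expect_length(none$genes[[1]], 0)
  span <- annotate_genes(make_calls("1", 0.5e6, 5.5e6), genes)
  expect_equal(span$genes[[1]], c("GENE1", "GENE2", "GENE3"))

  set.seed(8)
  toy <- region_set("2", gs <- sort(floor(runif(50, 1e6, 1e8))), gs + 5e4,
                    label = sprintf("G%02d", 1:50))
  calls <- make_calls("2", cs <- floor(runif(20, 1e6, 1e8)), cs + 3e5)
  ann <- annotate_genes(calls, toy)
  for (i in seq_len(20)) {
    oracle <- toy$label[overlap_bp(calls$chrom[i], calls$start[i], calls$end[i],
                                   toy$chrom, toy$start, toy$end) > 0]
    expect_equal(ann$genes[[i]], oracle)
  }
})

test_that("inheritance calls maternal/paternal/de novo/unknown correctly", {
  child <- make_calls("2", c(1e6, 5e6), c(2e6, 6e6), type = "duplication",
                      sample_id = "kid")
  mom_match <- make_calls("2", 1e6, 2e6, type = "duplication", sample_id = "mom")
  dad_empty <- mom_match[0, ]
  expect_equal(call_inheritance(child, mom_match, dad_empty),
               c("maternal", "de_novo"))
  # same coordinates but opposite type never matches
  mom_del <- make_calls("2", 1e6, 2e6, type = "deletion", sample_id = "mom")
  expect_equal(call_inheritance(child, mom_del, dad_empty),
               c("de_novo", "de_novo"))
  # a parent without call data makes the origin unknown
  expect_equal(call_inheritance(child, NULL, dad_empty),
               c("unknown", "unknown"))
  expect_warning(
    both <- call_inheritance(child[1, ], mom_match,
                             make_calls("2", 1e6, 2e6, type = "duplication",
                                        sample_id = "dad")),
    "biparental")
  expect_equal(both, "biparental")
  # 80% reciprocal threshold governs matching
  mom_shift <- make_calls("2", 1.5e6, 2.5e6, type = "duplication")
  expect_equal(call_inheritance(child[1, ], mom_shift, dad_empty), "de_novo")
})

test_that("infer_origins applies trio links across a cohort", {
  manifest <- as_sample_manifest(data.frame(
    sample_id = c("kid", "mom", "dad", "solo"),
    sex = c("male", "female", "male", "male"),
    group = c("case", "control", "control", "case"),
    mother_id = c("mom", NA, NA, NA), father_id = c("dad", NA, NA, NA)))
  calls <- make_calls("3", c(1e6, 9e6, 1e6), c(2e6, 9.5e6, 2e6),
                      sample_id = c("kid", "solo", "dad"))
  out <- infer_origins(calls, manifest)
  expect_equal(out$origin[out$sample_id == "kid"], "paternal")
  expect_equal(out$origin[out$sample_id == "solo"], "unknown")
})

test_that("two-hit detection requires two pathogenic CNVs at distinct loci", {
  t4 <- classify_pathogenic(fixture_pathogenic_cnvs(), fixture_pathogenic_regions())
  th <- detect_two_hit(t4, scope = "autosomal")
  expect_setequal(unique(th$sample_id),
                  c("U-2075", "U-1753", "U-1255", "U-1414", "U-1999"))
  # permutation stability
  th2 <- detect_two_hit(t4[rev(seq_len(nrow(t4))), ], scope = "autosomal")
  expect_equal(th2, th)
  # a single pathogenic CNV is not a two-hit
  one <- t4[t4$sample_id == "U-866", ]
  expect_equal(nrow(detect_two_hit(one, "autosomal")), 0)
  # two calls at the same locus are one hit
  same_locus <- classify_pathogenic(
    make_calls("4", c(1e6, 1.01e6), c(2e6, 2.01e6), sample_id = "dupcarrier",
               type = "duplication"),
    region_set("4", 0.5e6, 3e6))
  expect_equal(nrow(detect_two_hit(same_locus, "autosomal")), 0)
  # under scope "all", U-728 (one autosomal + one X CNV) becomes a two-hit
  th_all <- detect_two_hit(t4, scope = "all")
  expect_true("U-728" %in% th_all$sample_id)
})

test_that("control carrier lookup counts distinct carriers with X denominators", {
  manifest <- make_manifest(2, 6, control_sex = c("male", "male", "male",
                                                  "female", "female", "female"))
  ctrl <- manifest$sample_id[manifest$group == "control"]
  control_calls <- make_calls("18", rep(7.08e6, 4), rep(7.56e6, 4),
                              type = "duplication",
                              sample_id = c(ctrl[1], ctrl[1], ctrl[2], ctrl[4]))
  query <- make_calls(c("18", "X"), c(7.08e6, 1e6), c(7.56e6, 2e6),
                      type = "duplication", sample_id = c("case001", "case002"))
  out <- control_carrier_lookup(query, control_calls, manifest)
  expect_equal(out$control_carriers, c(3, 0))  # ctrl1 counted once
  expect_equal(out$control_n, c(6, 3))         # X denominator: male controls
  expect_equal(out$control_freq[1], 0.5)
})
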