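test_that("parse_protein_change handles the HGVSp-short notations", {
  p <- parse_protein_change("S1344L")
  expect_equal(p[c("ref_aa", "position", "kind", "alt_aa")],
               list(ref_aa = "S", position = 1344L, kind = "missense",
                    alt_aa = "L"))
  p <- parse_protein_change("E1705*")
  expect_equal(p$kind, "nonsense")
  expect_equal(p$position, 1705L)
  expect_equal(p$alt_aa, "*")
  p <- parse_protein_change("X1843_splice")
  expect_equal(p$kind, "splice")
  expect_equal(p$position, 1843L)
  expect_true(is.na(p$ref_aa))
  p <- parse_protein_change("K1140Rfs*5")
  expect_equal(p$kind, "frameshift")
  expect_equal(p$position, 1140L)
  # unparseable input degrades to 'other'
  p <- parse_protein_change("not-a-change")
  expect_equal(p$kind, "other")
  expect_true(is.na(p$position))
})

test_that("is_hotspot requires a missense hit at a configured residue", {
  cfg <- hotspot_config()
  expect_true(is_hotspot(mut_record("P", "D1709N"), cfg))
  expect_true(is_hotspot(mut_record("P", "S1344L"), cfg))
  # RNase IIIa catalytic residue not in the hotspot list
  expect_false(is_hotspot(mut_record("P", "D1320N"), cfg))
  # recurrent but non-hotspot PAZ allele
  expect_false(is_hotspot(mut_record("P", "R944Q"), cfg))
  # truncation at a hotspot residue is not a hotspot allele
  expect_false(is_hotspot(mut_record("P", "E1705*",
                                     variant_class = "nonsense"), cfg))
  # wrong gene
  expect_false(is_hotspot(mut_record("P", "S1344L", gene = "TP53"), cfg))
  # reference mismatch at configured residue warns and rejects
  expect_warning(res <- is_hotspot(mut_record("P", "Q1705L"), cfg),
                 "mismatch")
  expect_false(res)
})

test_that("is_truncating follows the class definition", {
  expect_true(is_truncating(mut_record("P", "E1705*", "nonsense")))
  expect_true(is_truncating(mut_record("P", "K10Rfs*2", "frameshift_indel")))
  expect_true(is_truncating(mut_record("P", "X100_splice", "splice_site")))
  expect_false(is_truncating(mut_record("P", "E100del", "inframe_indel")))
  expect_false(is_truncating(mut_record("P", "S1344L", "missense")))
})

test_that("flag_hypermutated supports metadata and count rules", {
  meta <- data.frame(sample_id = c("A", "B"),
                     hypermutated = c(TRUE, FALSE))
  cfg <- hotspot_config()
  expect_true(flag_hypermutated("A", NULL, meta, cfg))
  expect_false(flag_hypermutated("B", NULL, meta, cfg))
  expect_error(flag_hypermutated("Z", NULL, meta, cfg), "absent")

  cnt_cfg <- hotspot_config(hypermutation_rule = "mutation_count",
                            hypermutation_threshold = 1000L)
  few <- do.call(rbind, lapply(1:5, function(i)
    mut_record("A", sprintf("A%dG", i), gene = "GENEX")))
  expect_false(flag_hypermutated("A", few, NULL, cnt_cfg))
  many <- do.call(rbind, lapply(1:4000, function(i)
    mut_record("A", sprintf("A%dG", i), gene = "GENEX")))
  expect_true(flag_hypermutated("A", many, NULL, cnt_cfg))
})

test_that("classify_sample applies the genotype rules", {
  cfg <- hotspot_config()
  meta <- data.frame(sample_id = "P", hypermutated = FALSE)

  # no DICER1 alterations -> WT
  wt <- classify_sample(mut_record("P", "R175H", gene = "TP53"),
                        metadata = meta, config = cfg, sample_id = "P")
  expect_equal(wt$status, "WT")

  # only a non-hotspot alteration -> VUS
  vus <- classify_sample(mut_record("P", "R944Q"), metadata = meta,
                         config = cfg, sample_id = "P")
  expect_equal(vus$status, "VUS")

  # single hotspot -> HOTSPOT
  hot <- classify_sample(mut_record("P", "E1813G"), metadata = meta,
                         config = cfg, sample_id = "P")
  expect_equal(hot$status, "HOTSPOT")
  expect_equal(hot$hotspot_alleles, "E1813G")

  # two distinct alleles at the same hotspot residue -> biallelic
  dbl <- classify_sample(rbind(mut_record("P", "S1344L"),
                               mut_record("P", "S1344T")),
                         metadata = meta, config = cfg, sample_id = "P")
  expect_equal(dbl$status, "HOTSPOT_BIALLELIC")
  expect_true("second_hotspot:S1344T" %in% dbl$second_hits)

  # identical duplicated records count once (caller duplication guard)
  dup <- classify_sample(rbind(mut_record("P", "S1344L"),
                               mut_record("P", "S1344L")),
                         metadata = meta, config = cfg, sample_id = "P")
  expect_equal(dup$status, "HOTSPOT")

  # hotspot plus splice-inactivating event -> biallelic
  spl <- classify_sample(rbind(mut_record("P", "E1813G"),
                               mut_record("P", "X1843_splice",
                                          variant_class = "splice_site")),
                         metadata = meta, config = cfg, sample_id = "P")
  expect_equal(spl$status, "HOTSPOT_BIALLELIC")
})

test_that("copy-loss evidence obeys the TCGA/panel switch", {
  meta <- data.frame(sample_id = "P", hypermutated = FALSE)
  hetloss <- data.frame(sample_id = "P", gene = "DICER1", call = -1L)
  deepdel <- data.frame(sample_id = "P", gene = "DICER1", call = -2L)
  rec <- mut_record("P", "E1705K")

  tcga <- hotspot_config(use_copy_loss = TRUE)
  panel <- hotspot_config(use_copy_loss = FALSE)

  expect_equal(classify_sample(rec, hetloss, meta, tcga, "P")$status,
               "HOTSPOT_BIALLELIC")
  panel_call <- classify_sample(rec, hetloss, meta, panel, "P")
  expect_equal(panel_call$status, "HOTSPOT")
  expect_false("HETLOSS" %in% panel_call$second_hits)
  # deep deletions are second-hit eligible in both modes
  expect_equal(classify_sample(rec, deepdel, meta, panel, "P")$status,
               "HOTSPOT_BIALLELIC")
})

test_that("classification is order-independent and biallelic implies hotspot", {
  sim <- simulate_mutation_table(sim_config(n_tumor_types = 2,
                                            samples_per_type = 40,
                                            seed = 21))
  calls <- classify_cohort(sim$mutations, sim$cna, sim$metadata)

  # record order must not matter
  perm <- sim$mutations[sample(nrow(sim$mutations)), , drop = FALSE]
  calls_perm <- classify_cohort(perm, sim$cna, sim$metadata)
  expect_equal(calls$status, calls_perm$status)

  # biallelic samples are a subset of would-be hotspot samples
  biallelic <- calls$sample_id[calls$status == "HOTSPOT_BIALLELIC"]
  expect_true(all(nzchar(calls$hotspot_alleles[
    calls$sample_id %in% biallelic])))
})
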