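# build a normalized matrix from explicit per-arm values
arm_matrix <- function(v5, v3, samples = "S1") {
  loci <- paste0("L", seq_along(v5))
  m <- matrix(rep(c(rbind(v5, v3)), length(samples)),
              ncol = length(samples),
              dimnames = list(c(rbind(paste0(loci, "|5p"),
                                      paste0(loci, "|3p"))), samples))
  m
}

test_that("m53 is exact on constructed ratios", {
  set <- paste0("L", 1:5)
  v3 <- c(10, 20, 30, 40, 50)
  # equal arms -> 0; doubled 5p -> exactly 1
  expect_equal(m53_score(arm_matrix(v3, v3), set, "S1")$m53, 0)
  expect_equal(m53_score(arm_matrix(2 * v3, v3), set, "S1")$m53, 1)

  # hand-computed toy: medians 24 (5p) and 30 (3p)
  v5 <- c(12, 80, 24, 7, 31)
  sc <- m53_score(arm_matrix(v5, v3), set, "S1")
  expect_equal(sc$m5, 24)
  expect_equal(sc$m3, 30)
  expect_equal(sc$m53, log2(24 / 30))

  # zero median errors loudly, naming the sample
  expect_error(m53_score(arm_matrix(c(0, 0, 0, 1, 2), v3), set, "S1"), "S1")
})

test_that("m53 is invariant under per-sample positive scaling", {
  set.seed(5)
  v5 <- runif(9, 1, 100)
  v3 <- runif(9, 1, 100)
  set <- paste0("L", 1:9)
  base <- m53_score(arm_matrix(v5, v3), set, "S1")$m53
  for (s in c(0.01, 3, 1e4)) {
    expect_equal(m53_score(arm_matrix(s * v5, s * v3), set, "S1")$m53, base)
  }
})

test_that("median of logs equals log of median for odd-length positive data", {
  set.seed(8)
  for (n in c(3, 7, 15, 51)) {
    x <- rlnorm(n, 2, 1)
    expect_equal(median(log2(x)), log2(median(x)))
  }
})

test_that("m53_cohort keeps undefined scores visible", {
  set <- paste0("L", 1:3)
  m <- arm_matrix(c(5, 6, 7), c(5, 6, 7), samples = c("S1", "S2"))
  m[, "S2"] <- 0  # S2 has no expression: score undefined
  meta <- data.frame(sample_id = c("S1", "S2"), tumor_type = "TT")
  sc <- m53_cohort(m, set, meta)
  expect_equal(nrow(sc), 2L)
  expect_true(sc$defined[sc$sample_id == "S1"])
  expect_false(sc$defined[sc$sample_id == "S2"])
  expect_true(is.na(sc$m53[sc$sample_id == "S2"]))

  # all-identical samples -> zero variance
  m2 <- arm_matrix(c(5, 9, 7), c(4, 6, 7), samples = paste0("S", 1:4))
  meta2 <- data.frame(sample_id = paste0("S", 1:4), tumor_type = "TT")
  sc2 <- m53_cohort(m2, set, meta2)
  expect_equal(var(sc2$m53), 0)
})

test_that("within-cohort ranks are dense and flag the minimum", {
  sc <- data.frame(sample_id = paste0("S", 1:6),
                   tumor_type = rep(c("A", "B"), each = 3),
                   m5 = 1, m3 = 1,
                   m53 = c(-1, 0, 2, 0, 0, 1), defined = TRUE)
  r <- rank_within_cohort(sc)
  expect_equal(r$rank[r$tumor_type == "A"], c(1L, 2L, 3L))
  expect_equal(r$rank[r$tumor_type == "B"], c(1L, 1L, 2L))  # tie shares rank
  expect_equal(r$is_min[r$tumor_type == "B"], c(TRUE, TRUE, FALSE))
})

test_that("a planted biallelic sample ranks lowest in its cohort", {
  cfg <- sim_config(n_tumor_types = 1, samples_per_type = 60,
                    genotype_freqs = c(WT = 59 / 60, VUS = 0, HOTSPOT = 0,
                                       HOTSPOT_BIALLELIC = 1 / 60),
                    delta_biallelic = 0.4, seed = 61)
  co <- simulate_cohort(cfg)
  # ensure exactly one biallelic sample was planted under this seed
  idx <- which(co$metadata$genotype == "HOTSPOT_BIALLELIC")
  expect_true(length(idx) >= 1L)
  norm <- normalize_counts(co$counts)
  mset <- curate_mirna_set(norm, character(0))
  r <- rank_within_cohort(m53_cohort(norm, mset, co$metadata))
  expect_true(all(r$rank[match(co$metadata$sample_id[idx], r$sample_id)] <=
                    length(idx)))
})

test_that("bh_adjust reproduces the step-up and matches p.adjust", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(12)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, p.adjust(p, method = "BH"))
    expect_true(all(adj >= p - 1e-12))
    # order preservation in the sorted domain
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
  }
})

test_that("arm differential expression handles degenerate and planted cases", {
  # constant arm across all samples: logFC 0, p 1
  m <- arm_matrix(c(50, 60), c(50, 60), samples = paste0("S", 1:8))
  storage.mode(m) <- "integer"
  de <- arm_diff_expression(m, paste0("S", 1:4), paste0("S", 5:8))
  expect_equal(de$log2_fold_change, rep(0, 4))
  expect_equal(de$p_value, rep(1, 4))

  # planted 5p deficiency dominates the significant-down list at FDR 0.01
  cfg <- sim_config(n_tumor_types = 1, samples_per_type = 60,
                    genotype_freqs = c(WT = 0.5, VUS = 0, HOTSPOT = 0,
                                       HOTSPOT_BIALLELIC = 0.5),
                    delta_biallelic = 0.5, seed = 17)
  co <- simulate_cohort(cfg)
  mutants <- co$metadata$sample_id[co$metadata$genotype == "HOTSPOT_BIALLELIC"]
  wt <- co$metadata$sample_id[co$metadata$genotype == "WT"]
  de2 <- arm_diff_expression(co$counts, mutants, wt)
  sig_down <- de2[de2$fdr < 0.01 & de2$log2_fold_change < 0, ]
  expect_gt(nrow(sig_down), 0)
  expect_gt(mean(sig_down$arm == "5p"), 0.9)
})

test_that("arm DE is calibrated under the null", {
  cfg <- sim_config(n_tumor_types = 1, samples_per_type = 40,
                    n_loci = 100,
                    genotype_freqs = c(WT = 1, VUS = 0, HOTSPOT = 0,
                                       HOTSPOT_BIALLELIC = 0), seed = 99)
  co <- simulate_cohort(cfg)
  ids <- co$metadata$sample_id
  de <- arm_diff_expression(co$counts, ids[1:20], ids[21:40])
  # 200 arms, expect ~5% below 0.05; allow 3 binomial Sds
  frac <- mean(de$p_value < 0.05)
  expect_lt(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(de)))
})

test_that("strand-shift test separates planted shifts and respects ties", {
  # identical logFC distributions -> p = 1
  de_same <- data.frame(arm = rep(c("5p", "3p"), each = 3),
                        log2_fold_change = rep(c(-1, 0, 1), 2))
  res <- strand_shift_test(de_same)
  expect_equal(res$p_value, 1, tolerance = 0.05)
  expect_equal(res$direction, 0)

  # fully separated lists, n = 20 each
  de_sep <- data.frame(arm = rep(c("5p", "3p"), each = 20),
                       log2_fold_change = c(rep(-1, 20), rep(0.2, 20)))
  res2 <- strand_shift_test(de_sep)
  expect_lt(res2$p_value, 1e-6)
  expect_equal(res2$direction, -1)

  # one class empty -> error
  expect_error(strand_shift_test(
    data.frame(arm = "5p", log2_fold_change = 1)), "two arms")
})
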