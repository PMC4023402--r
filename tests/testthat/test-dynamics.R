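test_that("protein correction divides ratios in linear space", {
  expect_equal(correct_site_ratio(6, 2), 3)
  expect_equal(correct_site_ratio(5, 1), 5)
  expect_equal(correct_site_ratio(2, 2), 1)
  expect_error(correct_site_ratio(2, 0), class = "acstoich_domain_error")

  sites <- tibble::tibble(protein_id = c("P1", "P2", "P3"),
                          silac_ratio = c(6, 4, NA))
  proteins <- tibble::tibble(protein_id = c("P1", "P2"),
                             silac_ratio = c(2, NA))
  out <- suppressMessages(corrected_site_ratios(sites, proteins))
  expect_equal(out$corrected_ratio, c(3, NA, NA))
  expect_equal(out$excluded, c(FALSE, TRUE, TRUE))
})

test_that("exclusive localization requires exactly one tracked compartment", {
  expect_equal(
    exclusive_localization(c("mitochondrion", "mitochondrion;nucleus", "",
                             "other", "cytoplasm")),
    c("mitochondrion", NA, NA, NA, "cytoplasm")
  )
})

test_that("rank-sum test matches exact enumeration and is symmetric", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)),
               oracle_ranksum_exact(c(1, 2, 3), c(4, 5, 6)))

  set.seed(31)
  for (i in 1:10) {
    a <- rnorm(sample(2:6, 1)); b <- rnorm(sample(2:8, 1))
    expect_equal(wilcoxon_rank_sum(a, b), oracle_ranksum_exact(a, b))
    expect_equal(wilcoxon_rank_sum(a, b), wilcoxon_rank_sum(b, a))
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1), class = "acstoich_domain_error")
})

test_that("normal approximation stays close to enumeration beyond the exact regime", {
  set.seed(32)
  for (i in 1:5) {
    a <- rnorm(9); b <- rnorm(9, mean = runif(1, -1, 1))
    expect_lt(abs(wilcoxon_rank_sum(a, b) - oracle_ranksum_exact(a, b)), 0.02)
  }
})

test_that("Fisher enrichment equals brute-force hypergeometric tails", {
  expect_equal(fisher_enrichment(3, 3, 3, 10), 1 / choose(10, 3))
  expect_equal(fisher_enrichment(0, 4, 6, 20), 1)
  expect_equal(fisher_enrichment(5, 5, 5, 5), 1)
  expect_error(fisher_enrichment(4, 3, 5, 10), class = "acstoich_domain_error")

  set.seed(33)
  for (i in 1:25) {
    N <- sample(5:30, 1); n <- sample(1:N, 1); K <- sample(1:N, 1)
    k <- sample(max(0, n + K - N):min(n, K), 1)
    expect_equal(fisher_enrichment(k, n, K, N), oracle_hypergeom_tail(k, n, K, N),
                 tolerance = 1e-12)
  }
})

test_that("term enrichment reports counts, raw and BH-adjusted p-values", {
  ann <- tibble::tibble(
    protein_id = c("P1", "P2", "P3", "P1", "P4", "P5"),
    term = c("nuc", "nuc", "nuc", "mito", "mito", "cyt")
  )
  out <- term_enrichment(c("P1", "P2"), paste0("P", 1:6), ann)
  nuc <- out[out$term == "nuc", ]
  expect_equal(nuc$k, 2); expect_equal(nuc$K, 3)
  expect_equal(nuc$n, 2); expect_equal(nuc$N, 6)
  expect_equal(nuc$p, oracle_hypergeom_tail(2, 2, 3, 6))
  expect_equal(out$p_bh, p.adjust(out$p, method = "BH"))
  expect_error(term_enrichment("P9", c("P1", "P2"), ann),
               class = "acstoich_domain_error")
})

test_that("fraction above and corresponding-peptide checks enumerate correctly", {
  expect_equal(fraction_above(c(5, 15, 25), 10), 2 / 3)
  expect_equal(fraction_above(c(5, 15, 25), 0), 1)
  expect_equal(fraction_above(c(5, 15, 25), Inf), 0)

  cp <- cp_abundance_check(c(0.9, 1.0, 1.1, 0.3))
  expect_equal(cp$median_ratio, 0.95)
  expect_equal(cp$fraction_within_2fold, 0.75)
  flat <- cp_abundance_check(rep(1, 5))
  expect_equal(flat$median_ratio, 1)
  expect_equal(flat$fraction_within_2fold, 1)
  expect_error(cp_abundance_check(numeric(0)), class = "acstoich_domain_error")
})

test_that("TMT purity filter is inclusive at the threshold and content-preserving", {
  rec <- tibble::tibble(peptide = c("A", "B", "C"),
                        parent_purity = c(0.95, 0.85, 0.90),
                        reporter_1 = c(10, 20, 30))
  kept <- tmt_purity_filter(rec)
  expect_equal(kept$peptide, c("A", "C"))
  expect_equal(kept$reporter_1, c(10, 30))
  expect_identical(kept[1, ], rec[1, ])
})

test_that("TMT relative abundance handles identical, degenerate and noisy groups", {
  same <- tmt_relative_abundance(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$ratio, 1); expect_equal(same$p_value, 1)

  degen <- tmt_relative_abundance(c(2, 2, 2), c(1, 1, 1))
  expect_equal(degen$ratio, 2)
  expect_equal(degen$p_value, 0)
  expect_equal(degen$flag, "degenerate")

  short <- tmt_relative_abundance(5, c(1, 2))
  expect_true(is.na(short$p_value)); expect_equal(short$flag, "no_p_value")

  set.seed(34)
  for (i in 1:5) {
    a <- rnorm(4, mean = runif(1, 0, 2), sd = 1) + 5
    b <- rnorm(4, sd = 1) + 5
    expect_lt(abs(tmt_relative_abundance(a, b)$p_value - oracle_permutation_t(a, b)),
              0.05)
  }
})

test_that("acetyl-CoA pool arithmetic recovers the mitochondrial fold change", {
  expect_equal(mito_pool_fold_change(3, 2, 3.9), 1.9)
  expect_equal(mito_pool_fold_change(3, 2, 3), 1)
  expect_error(mito_pool_fold_change(2, 2.5, 3), class = "acstoich_domain_error")
})

test_that("compartment concentration fold behaves like a concentration ratio", {
  expect_equal(compartment_concentration_fold(1 / 3, 0.02),
               (1 / 3 / 0.02) / ((2 / 3) / 0.98))
  expect_gt(compartment_concentration_fold(1 / 3, 0.02), 20)
  expect_lt(compartment_concentration_fold(1 / 3, 0.02), 30)
  expect_gt(compartment_concentration_fold(1 / 3, 0.015), 30)
  expect_equal(compartment_concentration_fold(0.25, 0.25), 1)
  # strictly increasing in the pool fraction at fixed volume
  p <- seq(0.05, 0.95, by = 0.05)
  folds <- compartment_concentration_fold(p, 0.1)
  expect_true(all(diff(folds) > 0))
  expect_error(compartment_concentration_fold(1.2, 0.5),
               class = "acstoich_domain_error")
})

test_that("compartment summaries report consistent medians and Wilcoxon p-values", {
  one <- suppressMessages(compartment_summaries(
    tibble::tibble(compartment = "cytoplasm", ratio = c(2, 4, 8))))
  expect_equal(one$median_linear_ratio, 4)
  expect_equal(one$median_log2_ratio, 2)
  expect_true(is.na(one$p_vs_reference))

  two <- suppressMessages(compartment_summaries(tibble::tibble(
    compartment = rep(c("cytoplasm", "nucleus"), each = 3),
    ratio = rep(c(2, 4, 8), 2)
  )))
  expect_equal(two$p_vs_reference[two$compartment == "nucleus"], 1)
  expect_equal(two$median_linear_ratio, 2^two$median_log2_ratio)

  # a +2 log2 shift in mitochondria is recovered in the medians
  set.seed(35)
  cyto <- 2^rnorm(200)
  mito <- 2^(rnorm(200) + 2)
  shifted <- suppressMessages(compartment_summaries(tibble::tibble(
    compartment = rep(c("cytoplasm", "mitochondrion"), each = 200),
    ratio = c(cyto, mito)
  )))
  diff_log2 <- shifted$median_log2_ratio[shifted$compartment == "mitochondrion"] -
    shifted$median_log2_ratio[shifted$compartment == "cytoplasm"]
  expect_equal(diff_log2, 2, tolerance = 0.3)
  expect_lt(shifted$p_vs_reference[shifted$compartment == "mitochondrion"], 1e-6)

  gl <- glance(shifted)
  expect_equal(gl$reference, "cytoplasm")
  expect_equal(gl$n_sites_total, 400)
})
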