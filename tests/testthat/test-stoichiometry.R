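test_that("upper-bound estimator matches the fold-change rule", {
  expect_equal(stoichiometry_upper_bound(10, 1.0), 0.1)
  expect_equal(stoichiometry_upper_bound(20, 1.0), 0.05)
  expect_equal(stoichiometry_upper_bound(1, 1.0), 1.0)
  expect_error(stoichiometry_upper_bound(0.8), class = "acstoich_domain_error")
})

test_that("upper bound is strictly decreasing in ratio and linear in c_max", {
  set.seed(11)
  for (i in 1:20) {
    r <- sort(1 + rexp(2, 0.2))
    expect_gt(stoichiometry_upper_bound(r[1]), stoichiometry_upper_bound(r[2]))
    k <- runif(1, 0.1, 5)
    expect_equal(stoichiometry_upper_bound(r[1], c_max = k),
                 k * stoichiometry_upper_bound(r[1], c_max = 1))
  }
})

test_that("AQUA stoichiometry follows the amount arithmetic", {
  sym <- tibble::tibble(
    peptide = "X",
    ac_light_intensity = 30, ac_standard_intensity = 60,
    unmod_light_intensity = 10, unmod_standard_intensity = 20,
    ac_spike_amount = 5, unmod_spike_amount = 5
  )
  expect_equal(aqua_stoichiometry(sym)$s_acp, 50)

  hand <- tibble::tibble(
    peptide = "Y",
    ac_light_intensity = 5, ac_standard_intensity = 100,
    unmod_light_intensity = 50, unmod_standard_intensity = 100,
    ac_spike_amount = 1, unmod_spike_amount = 100
  )
  # amounts 0.05 and 50 -> 100 * 0.05 / 50.05
  expect_equal(aqua_stoichiometry(hand)$s_acp, 100 * 0.05 / 50.05)

  bad <- dplyr::mutate(sym, ac_standard_intensity = 0)
  expect_error(aqua_stoichiometry(bad), class = "acstoich_domain_error")
})

test_that("initial stoichiometry and chemical degree reproduce print precision", {
  expect_equal(round_half_up(initial_stoichiometry(0.023, 80.8), 4), 0.0003)
  expect_equal(round_half_up(initial_stoichiometry(0.068, 11.3), 4), 0.0060)
  expect_equal(initial_stoichiometry(0.42, 1), 0.42)
  expect_error(initial_stoichiometry(0.1, 0.5), class = "acstoich_domain_error")

  expect_equal(round_half_up(chemical_acetylation_degree(0.023, 0.0003), 2), 0.02)
  expect_equal(round_half_up(chemical_acetylation_degree(0.181, 0.1055), 2), 0.08)
  expect_equal(chemical_acetylation_degree(0.3, 0.3), 0)
  expect_error(chemical_acetylation_degree(0.1, 0.2), class = "acstoich_domain_error")
})

test_that("detection limit is the median of the bottom decile", {
  expect_equal(detection_limit(1:100)$value, 5.5)
  expect_equal(detection_limit(1:100)$n_peptides_used, 10L)
  expect_equal(detection_limit(rep(7, 50))$value, 7)
  expect_equal(detection_limit(1:20)$value, 1.5)
  expect_error(detection_limit(1:9), class = "acstoich_insufficient_data")
  expect_error(detection_limit(c(1:10, 0)), class = "acstoich_domain_error")

  set.seed(21)
  for (i in 1:10) {
    x <- rlnorm(sample(10:200, 1), 10, 2)
    expect_lte(detection_limit(x)$value, median(x))
  }
})

test_that("minimum fold increase bounds the ratio from below", {
  lim <- detection_limit(rep(10, 10))
  expect_equal(minimum_fold_increase(700, lim), 70)
  expect_equal(minimum_fold_increase(10, lim), 1)
  expect_warning(low <- minimum_fold_increase(4, lim), "below 1")
  expect_equal(low, 0.4)
})

test_that("tryptic digest counting honours the K/R-not-P rule and length window", {
  expect_equal(count_observable_peptides("AAAAAAKRRRRRRR"), 1L)
  expect_equal(count_observable_peptides("ACDEFGHILMNQST"), 1L) # no cleavage site
  expect_equal(count_observable_peptides("MKPK"), 0L)
  expect_equal(count_observable_peptides("AAAAAAKPAAAAAK"), 1L) # KP block joins fragments
  expect_error(count_observable_peptides(""), class = "acstoich_domain_error")
})

test_that("iBAQ and I/iBAQ-A are intensity quotients with absent-not-zero scores", {
  expect_equal(ibaq(1000, 10), 100)
  expect_equal(ibaq(0, 5), 0)
  expect_error(ibaq(10, 0), class = "acstoich_domain_error")
  expect_equal(i_over_ibaq_a(100, 100), 1)
  expect_equal(i_over_ibaq_a(50, 100), 0.5)
  expect_true(is.na(i_over_ibaq_a(50, NA)))
})

test_that("sensitivity classification uses the 2-fold cutoff", {
  expect_equal(classify_sensitivity(c(1.5, 80.8, NA, 2)),
               c("insensitive", "sensitive", "no_ratio", "sensitive"))
})

test_that("estimate_stoichiometry combines bound, flag and minimum-ratio paths", {
  lim <- detection_limit(rep(10, 10))
  est <- estimate_stoichiometry(demo_sites(), demo_proteins(), lim,
                                natural_only = FALSE)
  est <- dplyr::arrange(est, protein_id)
  expect_equal(est$sensitivity_class, c("sensitive", "insensitive", "no_ratio",
                                        "insensitive"))
  expect_equal(est$bound_percent[1], 0.1)
  expect_equal(est$flag[2], ">1%")
  expect_true(is.na(est$bound_percent[2]))
  expect_equal(est$min_ratio[3], 70)
  expect_equal(est$bound_percent[3], 1 / 70)
  # I/iBAQ-A from the untreated channel; absent where protein unknown
  expect_equal(est$i_over_ibaq_a[1], 100 / 100)
  expect_true(is.na(est$i_over_ibaq_a[3]))

  natural <- estimate_stoichiometry(demo_sites(), demo_proteins(), lim,
                                    natural_only = TRUE)
  expect_equal(nrow(natural), 3)
})

test_that("stoichiometry fractions count flagged sites only in denominators", {
  est <- tibble::tibble(
    protein_id = paste0("P", 1:4), position = 1:4, peptide = "K(ac)",
    ratio = c(100, 25, 5, 1.2), min_ratio = NA_real_,
    sensitivity_class = c("sensitive", "sensitive", "sensitive", "insensitive"),
    bound_percent = c(0.01, 0.04, 0.2, NA), flag = c(NA, NA, NA, ">1%"),
    i_over_ibaq_a = NA_real_
  )
  class(est) <- c("stoich_estimates", class(est))
  fr <- stoichiometry_fractions(est, thresholds = c(0.001, 0.05, 10))
  expect_equal(fr$fraction, c(0, 0.5, 0.75))
})

test_that("AQUA report is internally consistent and matches published rows", {
  ref <- aqua_reference_sites()
  rep <- aqua_report(ref)
  # identities at full precision
  expect_equal(rep$s0 * rep$ratio, rep$s_acp)
  expect_equal(rep$s0 + rep$degree, rep$s_acp)
  # published columns reproduced on self-consistent rows
  sc <- dplyr::filter(rep, self_consistent)
  expect_gte(nrow(sc), 6)
  expect_equal(sc$s0_report, sc$s0_published)
  expect_equal(sc$degree_report, sc$degree_published)
})

test_that("tidy and glance summarise estimate tables", {
  lim <- detection_limit(rep(10, 10))
  est <- estimate_stoichiometry(demo_sites(), demo_proteins(), lim,
                                natural_only = FALSE)
  td <- tidy(est)
  expect_setequal(td$sensitivity_class, c("sensitive", "insensitive", "no_ratio"))
  gl <- glance(est)
  expect_equal(gl$n_sites, 4L)
  expect_equal(gl$n_insensitive, 2L)
  expect_equal(gl$detection_limit, 10)
})
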