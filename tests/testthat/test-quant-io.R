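test_that("site table reader parses rows and derives SILAC ratios", {
  path <- write_fixture(c(
    "protein_id\tposition\tpeptide\tlight_intensity\theavy_intensity",
    "P1\t12\tAAGFLLEK(ac)ELK\t808\t10",
    "P2\t3\tGATLYIP(ac)ALR\t500\t"
  ))
  sites <- read_site_table(path)
  expect_equal(nrow(sites), 2)
  expect_equal(sites$silac_ratio[1], 80.8)
  expect_true(is.na(sites$silac_ratio[2]))
  expect_true(is.na(sites$heavy_intensity[2]))
  expect_true(all(sites$naturally_occurring))
})

test_that("site table reader enforces the schema and row invariants", {
  no_pep <- write_fixture(c(
    "protein_id\tposition\tlight_intensity", "P1\t1\t10"
  ))
  expect_error(read_site_table(no_pep), "peptide", class = "acstoich_format_error")

  bad_rows <- write_fixture(c(
    "protein_id\tposition\tpeptide\tlight_intensity",
    "P1\t5\tAAK(ac)GLR\tnot_a_number",
    "P2\t0\tAAK(ac)GLR\t50",
    "P3\t9\tAAKGLR\t50",
    "P4\t9\tAAK(ac)GLR\t50"
  ))
  expect_warning(sites <- read_site_table(bad_rows), "3 invalid row")
  expect_equal(sites$protein_id, "P4")
  problems <- attr(sites, "problems")
  expect_equal(problems$row, c(1L, 2L, 3L))
  expect_match(problems$message[1], "^row 1: non-numeric")
  expect_match(problems$message[3], "\\(ac\\)")
})

test_that("column remapping and H/L orientation are applied at read time", {
  path <- write_fixture(c(
    "Protein\tPos\tModified sequence\tIntensity L\tRatio H/L",
    "P1\t12\tAAGFLLEK(ac)ELK\t808\t0.25"
  ))
  sites <- read_site_table(
    path,
    col_map = c(protein_id = "Protein", position = "Pos",
                peptide = "Modified sequence", light_intensity = "Intensity L",
                silac_ratio = "Ratio H/L"),
    ratio_orientation = "heavy_over_light"
  )
  expect_equal(sites$silac_ratio, 4)
})

test_that("protein table reader parses localizations and derives iBAQ", {
  path <- write_fixture(c(
    "protein_id\ttotal_intensity\tsilac_ratio\tlocalizations\tn_observable_peptides",
    "P1\t1000\t1.1\tmitochondrion\t10",
    "P2\t500\t\tmitochondrion;nucleus\t",
    "P3\t-5\t1\tcytoplasm\t2"
  ))
  expect_warning(prot <- read_protein_table(path), "1 invalid row")
  expect_equal(nrow(prot), 2)
  expect_equal(prot$ibaq[1], 100)
  expect_true(is.na(prot$silac_ratio[2]))
  expect_equal(strsplit(prot$localizations[2], ";")[[1]],
               c("mitochondrion", "nucleus"))
  expect_equal(attr(prot, "problems")$row, 3L)
})

test_that("protein reader derives observable-peptide counts from sequences", {
  path <- write_fixture(c(
    "protein_id\ttotal_intensity\tsequence",
    sprintf("P1\t700\t%s", paste0("AAAAAAK", "GGGGGGGGGGGGR"))
  ))
  prot <- read_protein_table(path)
  # AAAAAAK (7) and GGGGGGGGGGGGR (13) both inside the 7-30 window
  expect_equal(prot$n_observable_peptides, 2L)
  expect_equal(prot$ibaq, 350)
})

test_that("FASTA reader maps first header token to sequence and rejects duplicates", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1 some description", "MKR", ">P2", "ACDEF", "GHIKL"), path)
  seqs <- read_fasta(path)
  expect_equal(seqs, c(P1 = "MKR", P2 = "ACDEFGHIKL"))

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1", "MKR", ">P1", "MKK"), dup)
  expect_error(read_fasta(dup), "P1", class = "acstoich_format_error")

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty), class = "acstoich_format_error")
})

test_that("estimate tables round-trip losslessly through write/read", {
  limit <- detection_limit(rep(10, 10))
  est <- suppressWarnings(
    estimate_stoichiometry(demo_sites(), demo_proteins(), limit,
                           natural_only = FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_estimates(est, path)
  back <- read_estimates(path)
  expect_equal(as.data.frame(back), as.data.frame(est)[names(back)],
               tolerance = 1e-12)
  expect_equal(back$flag[back$protein_id == "P2"], ">1%")

  # empty table -> header-only file
  write_estimates(est[0, ], path)
  expect_equal(length(readLines(path)), 1L)
  expect_equal(nrow(read_estimates(path)), 0L)
})

test_that("AQUA and TMT readers validate their invariants", {
  aqua_path <- write_fixture(c(
    paste("peptide", "ac_light_intensity", "ac_standard_intensity",
          "unmod_light_intensity", "unmod_standard_intensity",
          "ac_spike_amount", "unmod_spike_amount", sep = "\t"),
    "PEP1\t5\t100\t50\t100\t1\t100",
    "PEP2\t0\t100\t50\t100\t1\t100"
  ))
  expect_warning(aqua <- read_aqua_table(aqua_path), "1 invalid row")
  expect_equal(aqua$peptide, "PEP1")

  tmt_path <- write_fixture(c(
    "peptide\tis_acetylated\tparent_purity\treporter_control\treporter_dose",
    "T1\tTRUE\t0.95\t100\t300",
    "T2\tFALSE\t1.5\t100\t100"
  ))
  expect_warning(tmt <- read_tmt_table(tmt_path), "1 invalid row")
  expect_equal(tmt$peptide, "T1")
  expect_true(tmt$is_acetylated)
})

test_that("annotation reader expands term sets and rejects empty ones", {
  path <- write_fixture(c(
    "protein_id\tterms",
    "P1\tGO:1;GO:2",
    "P2\t",
    "P3\tGO:2"
  ))
  expect_warning(ann <- read_annotation_table(path), "1 invalid row")
  expect_equal(nrow(ann), 3)
  expect_equal(sort(unique(ann$term)), c("GO:1", "GO:2"))
  expect_equal(attr(ann, "problems")$row, 2L)
})
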