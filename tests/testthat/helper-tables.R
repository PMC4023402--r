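# Small in-code fixtures: write a tab-separated table to a temp file.
write_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# A minimal hand-built site table covering the three sensitivity classes.
demo_sites <- function() {
  tibble::tibble(
    protein_id = c("P1", "P2", "P3", "P4"),
    position = c(12L, 30L, 7L, 44L),
    peptide = c("AAGFLLEK(ac)ELK", "GATLYIP(ac)ALR", "LIEPK(ac)GYR", "AND(ac)NESK"),
    light_intensity = c(1000, 600, 700, 240),
    heavy_intensity = c(100, 500, NA, 200),
    silac_ratio = c(10, 1.2, NA, 1.2),
    naturally_occurring = c(TRUE, TRUE, TRUE, FALSE)
  )
}

demo_proteins <- function() {
  tibble::tibble(
    protein_id = c("P1", "P2"),
    total_intensity = c(1000, 500),
    silac_ratio = c(1, 1),
    sequence = NA_character_,
    n_observable_peptides = c(10L, 5L),
    ibaq = c(100, 100),
    localizations = c("mitochondrion", "cytoplasm;nucleus")
  )
}
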