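make_panel_files <- function(dir, n_with_seed = 35L) {
  panel_names <- table1_fixture()$name
  set.seed(97)
  with_seed <- panel_names[seq_len(n_with_seed)]
  peps <- character(0); pdesc <- character(0)
  nucs <- character(0); ndesc <- character(0)
  for (i in seq_along(with_seed)) {
    nm <- with_seed[i]
    key <- gsub("[^A-Za-z0-9]", "", nm)
    roles <- switch(i %% 3 + 1,
                    c("mature", "precursor", "cdna"),
                    c("mature"),
                    c("precursor", "cdna"))
    if ("mature" %in% roles) {
      peps[paste0(key, "_mat")] <- random_pep(9)
      pdesc <- c(pdesc, paste0("role=mature name=", nm))
    }
    if ("precursor" %in% roles) {
      peps[paste0(key, "_prec")] <- paste0("M", random_pep(60))
      pdesc <- c(pdesc, paste0("role=precursor name=", nm))
    }
    if ("cdna" %in% roles) {
      nucs[paste0(key, "_cdna")] <- random_dna(180)
      ndesc <- c(ndesc, paste0("role=cdna name=", nm))
    }
  }
  pep_path <- file.path(dir, "seeds_pep.fasta")
  nuc_path <- file.path(dir, "seeds_cdna.fasta")
  write_fasta(peps, pep_path, descs = pdesc)
  write_fasta(nucs, nuc_path, descs = ndesc)
  panel <- data.frame(name = panel_names,
                      tier = ifelse(panel_names %in% with_seed,
                                    "SAME_SPECIES", "OTHER_SPECIES"),
                      citation = "synthetic")
  panel_path <- file.path(dir, "panel.tsv")
  write.table(panel, panel_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(fasta = c(pep_path, nuc_path), panel = panel_path)
}

test_that("a 43-name panel with 35 seeded members yields 35 qualified and 8 NO_SEED", {
  dir <- withr::local_tempdir()
  paths <- make_panel_files(dir)
  reg <- load_registry(paths$fasta, paths$panel)
  expect_length(reg$target_panel, 43)
  expect_length(reg$records, 35)
  expect_length(reg$no_seed, 8)
  expect_setequal(c(names(reg$records), reg$no_seed), reg$target_panel)
})

test_that("registry loading enforces unique names and known role tags", {
  dir <- withr::local_tempdir()
  panel <- data.frame(name = c("A", "A"), tier = "SAME_SPECIES")
  pp <- file.path(dir, "panel.tsv")
  write.table(panel, pp, sep = "\t", quote = FALSE, row.names = FALSE)
  fa <- file.path(dir, "s.fasta")
  write_fasta(c(x = "MKKR"), fa, descs = "role=precursor name=A")
  expect_error(load_registry(fa, pp), "duplicate")
  panel2 <- data.frame(name = "A", tier = "SAME_SPECIES")
  write.table(panel2, pp, sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta(c(x = "MKKR"), fa, descs = "role=propeptide name=A")
  expect_error(load_registry(fa, pp), "role")
})

test_that("a single mature-only record qualifies with precursor and cDNA absent", {
  dir <- withr::local_tempdir()
  pp <- file.path(dir, "panel.tsv")
  write.table(data.frame(name = "RYamide", tier = "SAME_SPECIES"), pp,
              sep = "\t", quote = FALSE, row.names = FALSE)
  fa <- file.path(dir, "s.fasta")
  write_fasta(c(ry_mat = "GSRYGKR"), fa, descs = "role=mature name=RYamide")
  reg <- load_registry(fa, pp)
  s <- reg$records[["RYamide"]]
  expect_length(s$mature_peptides, 1)
  expect_null(s$precursor)
  expect_null(s$cdna)
})

test_that("an empty panel yields an empty registry", {
  dir <- withr::local_tempdir()
  pp <- file.path(dir, "panel.tsv")
  write.table(data.frame(name = character(), tier = character()), pp,
              sep = "\t", quote = FALSE, row.names = FALSE)
  reg <- load_registry(character(0), pp)
  expect_length(reg$records, 0)
  expect_length(reg$target_panel, 0)
})

test_that("selection rules are a pure function of tier and available roles", {
  full <- seed_record("A", mature_peptides = c("GSRYGKR"),
                      precursor = pep_sequence("p", paste0("M", random_pep(50))),
                      cdna = nuc_sequence("c", random_dna(150)))
  r <- effective_rule(full)
  expect_setequal(r$rule_names, c("mature_exact", "precursor", "cdna"))
  expect_equal(r$precursor_cov, 0.70)
  expect_equal(r$cdna_cov, 0.60)

  other <- seed_record("B", precursor = pep_sequence("p", paste0("M", random_pep(50))),
                       provenance_tier = "OTHER_SPECIES")
  r2 <- effective_rule(other)
  expect_equal(r2$rule_names, "precursor")
  expect_equal(r2$precursor_cov, 0.50)
  expect_true(is.na(r2$cdna_cov))

  cdna_only <- seed_record("C", cdna = nuc_sequence("c", random_dna(120)))
  r3 <- effective_rule(cdna_only)
  expect_equal(r3$rule_names, "cdna")
  expect_equal(r3$cdna_cov, 0.60)
  expect_true(is.na(r3$precursor_cov))

  expect_error(effective_rule(seed_record("D", mature_peptides = list())),
               "NO_SEED")
})

test_that("registries round-trip losslessly through their on-disk form", {
  dir <- withr::local_tempdir()
  paths <- make_panel_files(dir)
  reg <- load_registry(paths$fasta, paths$panel)
  dir2 <- file.path(dir, "again")
  out <- write_registry(reg, dir2)
  reg2 <- load_registry(c(out$pep, out$nuc), out$panel)
  expect_equal(names(reg2$records), names(reg$records))
  expect_equal(reg2$target_panel, reg$target_panel)
  for (nm in names(reg$records)) {
    a <- reg$records[[nm]]; b <- reg2$records[[nm]]
    expect_equal(vapply(b$mature_peptides, `[[`, "", "seq"),
                 vapply(a$mature_peptides, `[[`, "", "seq"))
    expect_equal(b$precursor$seq, a$precursor$seq)
    expect_equal(b$cdna$seq, a$cdna$seq)
    expect_equal(b$provenance_tier, a$provenance_tier)
  }
})
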