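# helpers building deterministic seeds/models for the selection tiers
make_seed <- function(prec_len = 100L, mature = NULL, cdna_len = 0L,
                      tier = "SAME_SPECIES", seed = 1L) {
  set.seed(seed)
  body <- random_pep(prec_len - 1L)
  if (!is.null(mature)) {
    at <- 30L
    substr(body, at, at + nchar(mature) - 1L) <- mature
  }
  prec <- paste0("M", body)
  seed_record("NP", mature_peptides = if (is.null(mature)) list() else
                c(mature),
              precursor = pep_sequence("prec", prec),
              cdna = if (cdna_len > 0L)
                nuc_sequence("cdna", random_dna(cdna_len)) else NULL,
              provenance_tier = tier)
}

test_that("precursor coverage thresholds are inclusive at exactly 70% and reject one column less", {
  seed <- make_seed(prec_len = 100L)
  frag70 <- substring(seed$precursor$seq, 1, 70)
  frag69 <- substring(seed$precursor$seq, 1, 69)
  m70 <- gene_model("m70", "TRINITY", protein = frag70)
  m69 <- gene_model("m69", "TRINITY", protein = frag69)
  calls <- select_candidates(seed, list(m70, m69))
  expect_length(calls, 1)
  expect_equal(calls[[1]]$model$model_id, "m70")
  expect_equal(calls[[1]]$criterion, "PRECURSOR_COV_70")
  expect_equal(calls[[1]]$coverage, 0.70)
})

test_that("other-species seeds use the inclusive 50% precursor rule", {
  seed <- make_seed(prec_len = 120L, tier = "OTHER_SPECIES", seed = 2L)
  frag60 <- substring(seed$precursor$seq, 11, 70)   # 60 of 120 residues
  frag59 <- substring(seed$precursor$seq, 11, 69)
  calls <- select_candidates(seed, list(
    gene_model("m60", "TRINITY", protein = frag60),
    gene_model("m59", "TRINITY", protein = frag59)))
  expect_length(calls, 1)
  expect_equal(calls[[1]]$model$model_id, "m60")
  expect_equal(calls[[1]]$criterion, "OTHER_SPECIES_COV_50")
  expect_equal(calls[[1]]$coverage, 0.50)
})

test_that("cDNA coverage threshold is inclusive at exactly 60%", {
  seed <- make_seed(prec_len = 40L, cdna_len = 200L, seed = 3L)
  tx120 <- substring(seed$cdna$seq, 41, 160)   # 120/200 = 0.60
  tx119 <- substring(seed$cdna$seq, 41, 159)
  calls <- select_candidates(seed, list(
    gene_model("t120", "STRINGTIE", transcript = tx120),
    gene_model("t119", "STRINGTIE", transcript = tx119)))
  ids <- vapply(calls, function(c) c$model$model_id, "")
  expect_true("t120" %in% ids)
  expect_false("t119" %in% ids)
  call <- calls[[match("t120", ids)]]
  expect_equal(call$criterion, "CDNA_COV_60")
  expect_equal(call$coverage, 0.60)
})

test_that("criteria apply in priority order: mature > precursor > cDNA", {
  seed <- make_seed(prec_len = 100L, mature = "WQNDFRH", seed = 4L)
  # model containing both the mature peptide and 70% of the precursor
  both <- gene_model("both", "DRAFT",
                     protein = substring(seed$precursor$seq, 1, 75))
  calls <- select_candidates(seed, list(both))
  expect_length(calls, 1)
  expect_equal(calls[[1]]$criterion, "MATURE_EXACT")
})

test_that("selection is monotone in alignment coverage", {
  seed <- make_seed(prec_len = 100L, seed = 5L)
  called_at <- vapply(65:80, function(len) {
    m <- gene_model("m", "TRINITY",
                    protein = substring(seed$precursor$seq, 1, len))
    length(select_candidates(seed, list(m))) > 0
  }, TRUE)
  # once called, longer fragments stay called
  expect_false(any(diff(called_at) < 0))
  expect_true(called_at[[6]])    # len 70
  expect_false(called_at[[5]])   # len 69
})

test_that("models without transcript and protein are skipped with a warning", {
  seed <- make_seed(seed = 6L)
  expect_warning(calls <- select_candidates(seed, list(
    gene_model("empty", "TRINITY"))), "skipped")
  expect_length(calls, 0)
})

make_trick_fixture <- function(seed_val = 8L) {
  set.seed(seed_val)
  gen <- npannotate:::random_precursor("NP", 1L)
  prec <- gen$precursor
  cds <- paste0(npannotate:::reverse_translate(prec$seq), "TAA")
  tx <- npannotate:::frame_trick_transcript(cds, prec$seq, gen$matures)
  sr <- seed_record("NP", mature_peptides = gen$matures, precursor = prec,
                    cdna = nuc_sequence("c", cds))
  list(seed = sr, cds = cds, tx = tx, prec = prec)
}

test_that("frame rescue recovers the coding frame when the longest ORF is a decoy", {
  fx <- make_trick_fixture()
  model <- gene_model("trick", "TRINITY", transcript = fx$tx)
  # the longest-ORF deduction misses the mature peptide
  naive <- npannotate:::model_protein(model)
  expect_length(find_mature_exact(fx$seed$mature_peptides[[1]], naive), 0)
  r <- frame_rescue(fx$seed, model)
  expect_true(r$rescued)
  expect_equal(r$frame, 2L)
  expect_equal(r$evidence, "mature")
  expect_equal(r$protein$seq, fx$prec$seq)
})

test_that("a transcript whose longest ORF already qualifies is flagged no-rescue", {
  fx <- make_trick_fixture(9L)
  model <- gene_model("plain", "TRINITY", transcript = fx$cds)
  r <- frame_rescue(fx$seed, model)
  expect_false(r$rescued)
  expect_equal(r$frame, 1L)
})

test_that("a frameshift destroying the peptide in every frame yields no rescue", {
  set.seed(10)
  gen <- npannotate:::random_precursor("NP", 1L)
  prec <- gen$precursor
  cds <- npannotate:::reverse_translate(prec$seq)
  # delete one nucleotide inside the mature-coding region
  mat_pos <- find_mature_exact(gen$matures[[1]], prec)[[1]]$position
  cut <- (mat_pos + 2L) * 3L  # within the mature peptide's codons
  broken <- paste0(substring(cds, 1, cut), substring(cds, cut + 2, nchar(cds)),
                   "TAA")
  model <- gene_model("broken", "TRINITY", transcript = broken)
  r <- frame_rescue(gen2 <- seed_record("NP", mature_peptides = gen$matures,
                                        precursor = prec),
                    model)
  expect_null(r)
})

test_that("frame rescue never returns a frame lacking both evidence types", {
  set.seed(12)
  for (rep in 1:5) {
    gen <- npannotate:::random_precursor(paste0("NP", rep), 1L)
    cds <- paste0(npannotate:::reverse_translate(gen$precursor$seq), "TAA")
    tx <- npannotate:::frame_trick_transcript(cds, gen$precursor$seq,
                                              gen$matures)
    sr <- seed_record("NP", mature_peptides = gen$matures,
                      precursor = gen$precursor)
    r <- frame_rescue(sr, gene_model("m", "TRINITY", transcript = tx))
    if (is.null(r)) next
    aa <- translate_frame(tx, r$frame)
    has_mature <- any(vapply(sr$mature_peptides, function(m) {
      length(find_mature_exact(m, gsub("\\*", "X", aa))) > 0
    }, TRUE))
    aln <- local_align_protein(sr$precursor, r$protein)
    has_prec <- !is.null(aln) && aln$query_cov >= 0.70
    expect_true(has_mature || has_prec)
  }
})

test_that("processing annotation locates dibasic sites, flanks and amidation donors", {
  # KR | mature | GKR architecture: both sites flank, glycine donates amide
  prec <- pep_sequence("p", "MAAAKRGSRYGKRAAA")
  hits <- find_mature_exact("GSRYG", prec)
  ann <- annotate_processing(prec, hits)
  expect_equal(ann$sites$position, c(4L, 11L))
  expect_equal(ann$sites$site_type, c("KR", "KR"))
  expect_true(all(ann$sites$flanks_mature))
  expect_equal(ann$amidation, 10L)   # the G closing the mature span

  # no dibasic pair at all
  expect_equal(nrow(annotate_processing(pep_sequence("p", "MASTLQ"))$sites), 0)

  # RR at position 0, nothing flanking
  ann3 <- annotate_processing(pep_sequence("p", "RRMASTLQ"))
  expect_equal(ann3$sites$position, 0L)
  expect_equal(ann3$sites$site_type, "RR")
  expect_false(ann3$sites$flanks_mature)
  expect_length(ann3$amidation, 0)
})

test_that("curation reports render alignments with mature spans and survive ties", {
  set.seed(13)
  gen <- npannotate:::random_precursor("NP", 1L)
  sr <- seed_record("NP", mature_peptides = gen$matures,
                    precursor = gen$precursor)
  m1 <- gene_model("m1", "TRINITY", protein = gen$precursor$seq)
  calls <- select_candidates(sr, list(m1))
  rep1 <- curation_report(sr, calls)
  expect_true(any(grepl("curation report", rep1)))
  expect_true(any(grepl("=", rep1, fixed = TRUE)))  # mature span marked

  # three equal-length candidates: no crash, column count bounded
  ms <- lapply(1:3, function(i) {
    p <- gen$precursor$seq
    substr(p, 40, 40) <- "A"
    gene_model(paste0("mm", i), "TRINITY", protein = p)
  })
  calls3 <- select_candidates(sr, ms)
  rep3 <- curation_report(sr, calls3)
  expect_gt(length(rep3), 4)

  # overlapping-locus note for two models sharing exon space
  ex <- data.frame(scaffold = "sc1", start = 100L, end = 400L, strand = "+")
  mA <- gene_model("locA", "DRAFT", protein = gen$precursor$seq, exons = ex)
  mB <- gene_model("locB", "STRINGTIE", protein = gen$precursor$seq,
                   exons = ex)
  callsAB <- select_candidates(sr, list(mA, mB))
  repAB <- curation_report(sr, callsAB)
  expect_true(any(grepl("overlap one locus", repAB)))
})
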