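# build a scaffold with a planted CDS split over exons; returns everything
# needed for verification
plant_cds <- function(protein, exon_count = 1L, strand = "+", seed = 1L) {
  set.seed(seed)
  cds <- paste0(npannotate:::reverse_translate(protein), "TAA")
  gb <- npannotate:::build_gene_block(cds, exon_count)
  block <- gb$block; exons <- gb$exons
  if (strand == "-") {
    L <- nchar(block)
    block <- reverse_complement(block)
    exons <- data.frame(start = L - rev(exons$end), end = L - rev(exons$start))
  }
  lead <- random_dna(120)
  scaffold <- paste0(lead, block, random_dna(80))
  exons$start <- exons$start + nchar(lead)
  exons$end <- exons$end + nchar(lead)
  list(genome = c(sc1 = scaffold),
       aln = spliced_alignment("m1", "sc1", strand, exons),
       model = gene_model("m1", "TRINITY", transcript = cds,
                          protein = protein))
}

test_that("an exact single-exon gene is placed with the correct span and strand", {
  fx <- plant_cds(paste0("M", random_pep(40)), 1L, "+", seed = 201)
  a <- verify_locus(fx$model, fx$aln, fx$genome)
  expect_equal(a$status, "PLACED")
  expect_equal(a$scaffold, "sc1")
  expect_equal(a$span, c(min(fx$aln$exons$start), max(fx$aln$exons$end)))
  expect_equal(a$strand, "+")
})

test_that("placement is an exact biconditional of translation identity", {
  prot <- paste0("M", random_pep(40))
  fx <- plant_cds(prot, 1L, "+", seed = 202)
  scaffold <- fx$genome[["sc1"]]
  # scan CDS codons for one admitting both a synonymous and a
  # non-synonymous single-nucleotide edit
  syn <- NULL; nonsyn <- NULL; cstart <- NULL
  for (ci in 3:20) {
    cand_start <- fx$aln$exons$start[1] + 3L * ci
    codon <- substring(scaffold, cand_start + 1L, cand_start + 3L)
    aa0 <- Biostrings::GENETIC_CODE[[codon]]
    s <- NULL; ns <- NULL
    for (nt in c("A", "C", "G", "T")) {
      for (pos in 1:3) {
        cand <- codon
        substr(cand, pos, pos) <- nt
        if (cand == codon) next
        aa1 <- Biostrings::GENETIC_CODE[[cand]]
        if (aa1 == aa0 && is.null(s)) s <- cand
        if (aa1 != aa0 && aa1 != "*" && is.null(ns)) ns <- cand
      }
    }
    if (!is.null(s) && !is.null(ns)) {
      syn <- s; nonsyn <- ns; cstart <- cand_start
      break
    }
  }
  expect_false(is.null(cstart))
  edit_genome <- function(cand) {
    s <- scaffold
    substr(s, cstart + 1L, cstart + 3L) <- cand
    c(sc1 = s)
  }
  expect_equal(verify_locus(fx$model, fx$aln, edit_genome(syn))$status,
               "PLACED")
  a <- verify_locus(fx$model, fx$aln, edit_genome(nonsyn))
  expect_equal(a$status, "UNPLACED")
  expect_equal(a$reason, "translation-mismatch")
})

test_that("multi-exon minus-strand genes agree with an independent splice oracle", {
  prot <- paste0("M", random_pep(60))
  fx <- plant_cds(prot, 3L, "-", seed = 203)
  a <- verify_locus(fx$model, fx$aln, fx$genome)
  expect_equal(a$status, "PLACED")
  # independent splice-then-translate oracle via Biostrings
  scaffold <- fx$genome[["sc1"]]
  pieces <- substring(scaffold, fx$aln$exons$start + 1L, fx$aln$exons$end)
  spliced <- Biostrings::DNAString(paste(pieces, collapse = ""))
  spliced <- Biostrings::reverseComplement(spliced)
  oracle_aa <- as.character(Biostrings::translate(spliced))
  expect_equal(sub("\\*$", "", oracle_aa), prot)
})

test_that("strand round-trip: the same protein places on both orientations", {
  prot <- paste0("M", random_pep(30))
  for (strand in c("+", "-")) {
    fx <- plant_cds(prot, 2L, strand, seed = 204)
    expect_equal(verify_locus(fx$model, fx$aln, fx$genome)$status, "PLACED")
  }
})

test_that("bound violations and missing proteins are hard errors; phaseless exon sets are flagged", {
  fx <- plant_cds(paste0("M", random_pep(20)), 1L, "+", seed = 205)
  bad <- fx$aln
  bad$exons$end[1] <- nchar(fx$genome[["sc1"]]) + 10L
  expect_error(verify_locus(fx$model, bad, fx$genome), "bounds")
  no_prot <- gene_model("m2", "TRINITY")
  expect_error(verify_locus(no_prot, fx$aln, fx$genome), "protein")
  # total exon length not divisible by 3
  off <- fx$aln
  off$exons$end[1] <- off$exons$end[1] - 1L
  a <- verify_locus(fx$model, off, fx$genome)
  expect_equal(a$status, "UNPLACED")
  expect_equal(a$reason, "partial-exon")
})

test_that("classification partitions calls into placed and unplaced exactly once", {
  set.seed(206)
  fixtures <- lapply(1:7, function(i) {
    plant_cds(paste0("M", random_pep(25 + i)), (i %% 3) + 1L,
              if (i %% 2 == 0) "+" else "-", seed = 300 + i)
  })
  genome <- c()
  alns <- list(); calls <- list()
  for (i in seq_along(fixtures)) {
    fx <- fixtures[[i]]
    scn <- paste0("sc", i)
    genome[scn] <- fx$genome[["sc1"]]
    mid <- paste0("m", i)
    aln <- fx$aln; aln$model_id <- mid; aln$scaffold <- scn
    model <- fx$model; model$model_id <- mid
    if (i <= 5) alns[[length(alns) + 1L]] <- aln  # models 6,7 unmapped
    calls[[i]] <- npannotate:::new_candidate_call("NP", model,
                                                  "MATURE_EXACT",
                                                  NULL, 1, 1)
  }
  cls <- classify_models(calls, alns, genome)
  expect_length(cls$placed, 5)
  expect_length(cls$unplaced, 2)
  expect_setequal(vapply(cls$unplaced, `[[`, "", "reason"),
                  "no-mapping")
  # partition: every model classified exactly once
  ids <- c(vapply(cls$placed, `[[`, "", "model_id"),
           vapply(cls$unplaced, `[[`, "", "model_id"))
  expect_setequal(ids, paste0("m", 1:7))
  expect_length(ids, 7)
  # empty input
  empty <- classify_models(list(), alns, genome)
  expect_length(empty$placed, 0)
  expect_length(empty$unplaced, 0)
})

test_that("identical translations at two loci are both retained and flagged", {
  prot <- paste0("M", random_pep(30))
  fx <- plant_cds(prot, 1L, "+", seed = 207)
  sc <- fx$genome[["sc1"]]
  w <- fx$aln$exons$end[1] - fx$aln$exons$start[1]
  gene_seq <- substring(sc, fx$aln$exons$start[1] + 1L, fx$aln$exons$end[1])
  genome <- c(sc1 = paste0(sc, random_dna(50), gene_seq, random_dna(30)))
  aln2 <- spliced_alignment("m1", "sc1", "+", data.frame(
    start = nchar(sc) + 50L, end = nchar(sc) + 50L + w))
  call <- npannotate:::new_candidate_call("NP", fx$model, "MATURE_EXACT",
                                          NULL, 1, 1)
  cls <- classify_models(list(call), list(fx$aln, aln2), genome)
  expect_length(cls$placed, 2)
  expect_true(all(vapply(cls$placed, `[[`, TRUE, "multi_locus")))
  expect_length(cls$unplaced, 0)
})
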