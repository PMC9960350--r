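sample_gff_lines <- function() {
  c("##gff-version 3",
    "sc1\tdraft\tgene\t101\t500\t.\t+\t.\tID=G1;Name=geneA",
    "sc1\tdraft\tmRNA\t101\t500\t.\t+\t.\tID=G1-RA;Parent=G1",
    "sc1\tdraft\texon\t101\t250\t.\t+\t.\tID=G1-RA.e1;Parent=G1-RA",
    "sc1\tdraft\texon\t301\t500\t.\t+\t.\tID=G1-RA.e2;Parent=G1-RA",
    "sc1\tdraft\tCDS\t101\t250\t.\t+\t0\tID=G1-RA.c;Parent=G1-RA",
    "sc1\tdraft\tCDS\t301\t500\t.\t+\t0\tID=G1-RA.c;Parent=G1-RA",
    "sc2\tdraft\tgene\t51\t200\t.\t-\t.\tID=G2;note=has%2Cescape",
    "sc2\tdraft\tmRNA\t51\t200\t.\t-\t.\tID=G2-RA;Parent=G2",
    "sc2\tdraft\texon\t51\t200\t.\t-\t.\tID=G2-RA.e1;Parent=G2-RA")
}

test_that("GFF3 parse/write stabilises after one round trip and preserves escapes", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "draft.gff3")
  writeLines(sample_gff_lines(), p)
  g1 <- gff_read(p)
  expect_equal(nrow(g1), 9)
  w1 <- gff_write(g1, NULL)
  g2 <- npannotate:::gff_parse_lines(w1)
  w2 <- gff_write(g2, NULL)
  expect_identical(w2, w1)
  expect_true(any(grepl("has%2Cescape", w1, fixed = TRUE)))
  # malformed line reports its line number
  writeLines(c("##gff-version 3", "sc1\tonly\tthree"), p)
  expect_error(gff_read(p), "line 2")
})

test_that("randomly generated features survive parse(write(x)) field-by-field", {
  set.seed(401)
  n <- 200
  types <- c("gene", "mRNA", "exon", "CDS")
  df <- data.frame(
    seqid = paste0("sc", sample(1:9, n, TRUE)),
    source = "sim",
    type = sample(types, n, TRUE),
    start = sample(1:100000, n),
    end = 0L, score = ".",
    strand = sample(c("+", "-"), n, TRUE),
    phase = as.character(sample(c(".", "0", "1", "2"), n, TRUE)),
    stringsAsFactors = FALSE)
  df$end <- df$start + sample(50:5000, n)
  df$attributes <- lapply(seq_len(n), function(i) {
    at <- c(ID = paste0("f", i))
    if (i %% 2 == 0) at <- c(at, Parent = paste0("f", i - 1L))
    if (i %% 3 == 0) at <- c(at, note = paste0("v", i), zz = "9")
    at
  })
  class(df) <- c("gff", "data.frame")
  attr(df, "pragmas") <- "##gff-version 3"
  back <- gff_roundtrip(df)
  expect_equal(back$seqid, df$seqid)
  expect_equal(back$start, df$start)
  expect_equal(back$end, df$end)
  expect_equal(back$strand, df$strand)
  expect_equal(back$phase, df$phase)
  for (i in seq_len(n)) {
    a <- df$attributes[[i]]; b <- back$attributes[[i]]
    expect_setequal(names(b), names(a))
    expect_equal(b[names(a)], a[names(a)])
  }
})

test_that("the ID allocator runs an arithmetic step-100 progression and refuses collisions", {
  a <- id_allocator(existing_ids = "GBI_30200")
  expect_equal(alloc(a), "GBI_30000")
  expect_equal(alloc(a), "GBI_30100")
  expect_error(alloc(a), "collides")
})

make_assignment <- function(model_id, name, scaffold, start, end,
                            strand = "+", transcript = NULL,
                            protein = NULL, placed = TRUE) {
  model <- gene_model(model_id, "TRINITY", transcript = transcript,
                      protein = protein)
  call <- npannotate:::new_candidate_call(name, model, "MATURE_EXACT",
                                          NULL, 1, 1)
  if (placed) {
    a <- structure(list(model_id = model_id, status = "PLACED",
                        scaffold = scaffold, span = c(start, end),
                        strand = strand, reason = NA_character_,
                        exons = data.frame(start = start, end = end)),
                   class = "locus_assignment")
  } else {
    a <- npannotate:::unplaced(model_id, "translation-mismatch")
  }
  a$call <- call
  a
}

test_that("merging two placed and one unplaced model allocates GBI_30000/30100/30200", {
  set.seed(402)
  genome <- c(sc1 = random_dna(2000))
  draft <- c("##gff-version 3")
  placed <- list(
    make_assignment("t1", "NP1", "sc1", 100L, 400L, "+",
                    protein = paste0("M", random_pep(20))),
    make_assignment("t2", "NP2", "sc1", 900L, 1200L, "-",
                    protein = paste0("M", random_pep(20))))
  tx <- random_dna(240)
  unplaced <- list(
    make_assignment("t3", "NP3", NA, NA, NA, transcript = tx,
                    placed = FALSE))
  res <- merge_annotation(draft, genome, placed, unplaced)
  expect_equal(res$id_map$released_id, c("GBI_30000", "GBI_30100",
                                         "GBI_30200"))
  expect_equal(res$id_map$placement, c("placed", "placed",
                                       "unplaced-contig"))
  # the unplaced transcript appears exactly once as a new contig
  expect_true("GBI_30200" %in% names(res$fasta))
  expect_equal(res$fasta[["GBI_30200"]], tx)
  expect_equal(sum(names(res$fasta) == "GBI_30200"), 1)
  # every scaffold referenced by the GFF exists in the FASTA
  feature <- res$gff_lines[!startsWith(res$gff_lines, "#")]
  seqids <- unique(vapply(strsplit(feature, "\t"), `[[`, "", 1))
  expect_true(all(seqids %in% names(res$fasta)))
  # coordinate conversion: 0-based [100, 400) -> GFF 101..400
  gene_line <- grep("ID=GBI_30000;", res$gff_lines, value = TRUE)
  f <- strsplit(gene_line, "\t")[[1]]
  expect_equal(as.integer(f[4:5]), c(101L, 400L))
  # the augmented GFF round-trips
  rt <- gff_roundtrip(npannotate:::gff_parse_lines(res$gff_lines))
  expect_equal(nrow(rt), sum(!startsWith(res$gff_lines, "#")))
})

test_that("merging nothing reproduces the draft modulo the header note", {
  draft <- sample_gff_lines()
  genome <- c(sc1 = random_dna(600), sc2 = random_dna(300))
  res <- merge_annotation(draft, genome, list(), list())
  expect_equal(setdiff(res$gff_lines, draft),
               "## npannotate: neuropeptide annotations appended")
  expect_equal(res$gff_lines[-2], draft)   # draft lines byte-preserved
  expect_equal(res$fasta, toupper(genome))
  expect_equal(nrow(res$id_map), 0)
})

test_that("a placed model overlapping a draft gene on the same strand becomes an isoform", {
  set.seed(403)
  draft <- sample_gff_lines()
  genome <- c(sc1 = random_dna(600), sc2 = random_dna(300))
  placed <- list(make_assignment("t9", "AstB", "sc1", 150L, 420L, "+",
                                 protein = paste0("M", random_pep(15))))
  res <- merge_annotation(draft, genome, placed, list())
  expect_equal(res$id_map$released_id, "G1-RB")
  expect_equal(res$id_map$placement, "isoform")
  expect_true(any(grepl("ID=G1-RB;Parent=G1", res$gff_lines)))
  # opposite strand does not attach: new gene ID instead
  placed_minus <- list(make_assignment("t9", "AstB", "sc1", 150L, 420L, "-",
                                       protein = paste0("M", random_pep(15))))
  res2 <- merge_annotation(draft, genome, placed_minus, list())
  expect_equal(res2$id_map$released_id, "GBI_30000")
})

test_that("ID collisions with the draft are hard errors", {
  draft <- sample_gff_lines()
  draft[2] <- sub("ID=G1;", "ID=GBI_30000;", draft[2], fixed = TRUE)
  draft[3] <- sub("Parent=G1$", "Parent=GBI_30000", draft[3])
  genome <- c(sc1 = strrep("ACGT", 200), sc2 = strrep("ACGT", 100))
  placed <- list(make_assignment("t1", "NP", "sc2", 10L, 100L, "+",
                                 protein = "MKR"))
  expect_error(merge_annotation(draft, genome, placed, list()), "collides")
})
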