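# Synthetic-data generation: planted-gene genomes with controlled defects
# (frameshift, point mutation, misleading reading frames), matching seed
# sets and transcript sets, TPM matrices, and the transcribed published
# annotation ledger. Everything is deterministic given an RNG seed, so the
# whole pipeline is testable without any external download.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")

# EFLamide-like genomic fragment: a peptide present in the genome for which
# no transcript exists in any assembly (genomic-only negative control)
EFLAMIDE_FRAGMENT <- "KHQRNFLKGIRSISQIVYSARIVRNLGEFLGK"

#' Specification of one planted neuropeptide gene
#'
#' @param neuropeptide_name Name used for the seed and truth records.
#' @param precursor Optional `pep_sequence`; generated when `NULL`.
#' @param mature_peptides Optional character vector of mature peptides
#'   accompanying a supplied precursor.
#' @param n_mature Number of mature peptides carved into a generated
#'   precursor.
#' @param exon_count Exons for the genomic copy (1-4 typical).
#' @param strand `"+"` or `"-"`.
#' @param mutation `"NONE"`, `"FRAMESHIFT"` (1-nt deletion in the genomic
#'   copy; the transcript stays correct), or `"POINT"` (non-synonymous SNV
#'   in the genomic copy).
#' @param transcript_frame_trick Build the transcript so that its longest
#'   ORF lies in a different reading frame than the coding one (decoy ORF),
#'   exercising six-frame rescue.
#' @param sources Character subset of `c("D","S","T")`: which gene-model
#'   sets carry this gene's transcript.
#' @param genomic_only Plant the peptide in the genome with no transcript
#'   in any set (EFLamide-like negative control); implies an other-species
#'   precursor-only seed.
#' @return A `plant_spec`.
#' @export
plant_spec <- function(neuropeptide_name, precursor = NULL,
                       mature_peptides = NULL, n_mature = 1L,
                       exon_count = 1L, strand = "+",
                       mutation = c("NONE", "FRAMESHIFT", "POINT"),
                       transcript_frame_trick = FALSE,
                       sources = "T", genomic_only = FALSE) {
  mutation <- match.arg(mutation)
  stopifnot(exon_count >= 1L, strand %in% c("+", "-"),
            all(sources %in% c("D", "S", "T")))
  structure(list(neuropeptide_name = neuropeptide_name,
                 precursor = precursor,
                 mature_peptides = mature_peptides, n_mature = n_mature,
                 exon_count = exon_count, strand = strand,
                 mutation = mutation,
                 transcript_frame_trick = transcript_frame_trick,
                 sources = sources, genomic_only = genomic_only),
            class = "plant_spec")
}

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")
random_aa <- function(n, exclude = c("M")) {
  paste(sample(setdiff(AA20, exclude), n, TRUE), collapse = "")
}

# precursor with prohormone architecture: Met start, signal-like stretch,
# dibasic-flanked mature cores with an amidation donor glycine
random_precursor <- function(name, n_mature = 1L, mature_len = 8L) {
  matures <- replicate(n_mature, random_aa(mature_len, exclude = c("M", "K", "R", "G")))
  body <- paste0(vapply(matures, function(m) {
    paste0("KR", m, "GKR", random_aa(8L, exclude = "M"))
  }, ""), collapse = "")
  prec <- paste0("M", random_aa(18L, exclude = "M"), body,
                 random_aa(6L, exclude = "M"))
  list(precursor = pep_sequence(paste0(name, "_precursor"), prec),
       matures = lapply(seq_along(matures), function(i) {
         pep_sequence(sprintf("%s_mature%d", name, i), matures[i])
       }))
}

REV_CODON <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- split(names(gc), unname(gc))
    }
    tab
  }
})

# sample one synonymous codon per residue
reverse_translate <- function(pep) {
  tab <- REV_CODON()
  aa <- strsplit(pep, "", fixed = TRUE)[[1L]]
  paste(vapply(aa, function(a) {
    opts <- tab[[a]]
    opts[sample.int(length(opts), 1L)]
  }, ""), collapse = "")
}

# split a CDS into exon pieces and join with GT..AG introns; returns the
# gene block and 0-based exon offsets within it
build_gene_block <- function(cds, exon_count) {
  L <- nchar(cds)
  if (exon_count > 1L) {
    cuts <- sort(sample(seq(10L, L - 10L), exon_count - 1L))
    # avoid adjacent cuts closer than 10 nt
    while (any(diff(c(0L, cuts, L)) < 10L)) {
      cuts <- sort(sample(seq(10L, L - 10L), exon_count - 1L))
    }
  } else {
    cuts <- integer(0)
  }
  bounds <- c(0L, cuts, L)
  pieces <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1L])
  block <- ""
  exons <- data.frame(start = integer(0), end = integer(0))
  for (i in seq_along(pieces)) {
    s <- nchar(block)
    block <- paste0(block, pieces[i])
    exons <- rbind(exons, data.frame(start = s, end = nchar(block)))
    if (i < length(pieces)) {
      block <- paste0(block, "GT", random_nt(sample(50:90, 1L)), "AG")
    }
  }
  list(block = block, exons = exons)
}

apply_mutation <- function(block, exons, cds, mutation) {
  if (mutation == "NONE") return(list(block = block, exons = exons))
  # operate inside the first exon, away from the start codon
  e1 <- exons[1L, ]
  if (mutation == "FRAMESHIFT") {
    pos <- e1$start + 12L  # 0-based position of the deleted nucleotide
    block <- paste0(substring(block, 1L, pos),
                    substring(block, pos + 2L, nchar(block)))
    exons$end[1L] <- exons$end[1L] - 1L
    if (nrow(exons) > 1L) {
      exons$start[-1L] <- exons$start[-1L] - 1L
      exons$end[-1L] <- exons$end[-1L] - 1L
    }
    # keep total exon length divisible by 3 (a spliced aligner pins the CDS
    # length): the last exon absorbs one downstream nucleotide
    exons$end[nrow(exons)] <- exons$end[nrow(exons)] + 1L
  } else {  # POINT: non-synonymous substitution in codon 5
    codon_start <- e1$start + 12L  # codon 5 of the CDS, inside exon 1
    codon <- substring(block, codon_start + 1L, codon_start + 3L)
    aa0 <- Biostrings::GENETIC_CODE[[codon]]
    for (nt in c("A", "C", "G", "T")) {
      cand <- paste0(substring(codon, 1L, 1L), nt, substring(codon, 3L, 3L))
      aa1 <- Biostrings::GENETIC_CODE[[cand]]
      if (cand != codon && aa1 != aa0 && aa1 != "*") {
        block <- paste0(substring(block, 1L, codon_start + 1L), nt,
                        substring(block, codon_start + 3L, nchar(block)))
        break
      }
    }
  }
  list(block = block, exons = exons)
}

# decoy-framed transcript: the longest ORF is a decoy in frame +1 while the
# true precursor CDS sits in frame +2 behind an in-frame stop
frame_trick_transcript <- function(cds, precursor, matures, max_tries = 50L) {
  prec_len <- nchar(precursor)
  for (i in seq_len(max_tries)) {
    decoy <- paste0("M", random_aa(prec_len + 9L, exclude = c("M")))
    decoy_nt <- paste0(reverse_translate(decoy), "TAA")
    tx <- paste0(decoy_nt, "CTAA", cds)
    orfs <- six_frame_orfs(tx)
    frames <- vapply(orfs, function(o) o$frame, 0L)
    lens <- vapply(orfs, function(o) nchar(o$peptide$seq), 0L)
    if (length(orfs) == 0L) next
    longest <- orfs[[which.max(lens)]]
    f2 <- match(2L, frames)
    ok <- longest$frame == 1L &&
      identical(longest$peptide$seq, decoy) &&
      !is.na(f2) && identical(orfs[[f2]]$peptide$seq, precursor) &&
      !any(vapply(matures, function(m) {
        length(find_mature_exact(m, decoy)) > 0L
      }, TRUE))
    if (ok) return(tx)
  }
  stop("failed to construct a frame-trick transcript")
}

#' Generate a synthetic draft genome with planted neuropeptide genes
#'
#' Builds scaffolds carrying one gene per plant spec (known coordinates and
#' strand; 1-4 exons with canonical GT..AG introns), the matching seed
#' registry (mature peptides, precursor, cDNA per plant), and three gene
#' model sets mimicking a draft annotation (D: protein + exons), a
#' reference-mapping assembly (S: transcript + protein + exons) and a de
#' novo assembly (T: transcript only, protein left to longest-ORF
#' deduction). Mutant plants corrupt only the genomic copy; frame-trick
#' plants corrupt only the transcript's reading frame. Genomic-only plants
#' are written into a scaffold with no transcript anywhere.
#'
#' @param specs List of [plant_spec()]s.
#' @param scaffold_count Number of scaffolds to distribute genes over.
#' @param seed RNG seed; identical seeds give identical output.
#' @return List: `genome` (named scaffold strings), `truth` (data.frame of
#'   planted-gene coordinates and expectations), `truth_gff` (`gff`
#'   object), `models` (list `D`/`S`/`T` of `gene_model`s), `alignments`
#'   (list of `spliced_alignment`s, the spliced-aligner stand-in),
#'   `registry` (`seed_registry`), `specs`.
#' @export
generate_genome <- function(specs, scaffold_count = 4L, seed = 1L) {
  set.seed(seed)
  scaffolds <- stats::setNames(
    vapply(seq_len(scaffold_count), function(i) random_nt(400L), ""),
    sprintf("Scaffold%02d", seq_len(scaffold_count)))
  truth <- data.frame()
  models <- list(D = list(), S = list(), T = list())
  alignments <- list()
  seeds <- list()
  panel <- data.frame(name = character(), tier = character(),
                      citation = character(), stringsAsFactors = FALSE)

  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    nm <- sp$neuropeptide_name
    if (is.null(sp$precursor)) {
      gen <- random_precursor(nm, sp$n_mature)
    } else {
      mats <- lapply(seq_along(sp$mature_peptides), function(i) {
        pep_sequence(sprintf("%s_mature%d", nm, i), sp$mature_peptides[i])
      })
      gen <- list(precursor = sp$precursor, matures = mats)
    }
    prec <- gen$precursor
    matures <- gen$matures
    if (nchar(prec$seq) < max(c(0L, vapply(matures, function(m)
      nchar(m$seq), 0L)))) {
      stop("precursor shorter than a mature peptide for ", nm)
    }
    cds <- paste0(reverse_translate(prec$seq), "TAA")
    scn <- names(scaffolds)[(k - 1L) %% scaffold_count + 1L]

    if (sp$genomic_only) {
      frag_nt <- reverse_translate(prec$seq)
      offset <- nchar(scaffolds[[scn]])
      scaffolds[[scn]] <- paste0(scaffolds[[scn]], frag_nt,
                                 random_nt(300L))
      truth <- rbind(truth, data.frame(
        name = nm, scaffold = scn, start = offset,
        end = offset + nchar(frag_nt), strand = "+", mutation = "NONE",
        kind = "genomic_only", model_id = NA_character_,
        stringsAsFactors = FALSE))
      panel <- rbind(panel, data.frame(name = nm, tier = "OTHER_SPECIES",
                                       citation = "synthetic",
                                       stringsAsFactors = FALSE))
      seeds[[nm]] <- seed_record(nm, precursor = prec,
                                 provenance_tier = "OTHER_SPECIES",
                                 source_citation = "synthetic")
      next
    }

    gb <- build_gene_block(cds, sp$exon_count)
    mut <- apply_mutation(gb$block, gb$exons, cds, sp$mutation)
    block <- mut$block; exons <- mut$exons
    if (sp$strand == "-") {
      L <- nchar(block)
      block <- reverse_complement(block)
      exons <- data.frame(start = L - rev(exons$end),
                          end = L - rev(exons$start))
    }
    offset <- nchar(scaffolds[[scn]])
    scaffolds[[scn]] <- paste0(scaffolds[[scn]], block,
                               random_nt(sample(200:350, 1L)))
    exons$start <- exons$start + offset
    exons$end <- exons$end + offset

    model_id <- sprintf("%s_%s_m%02d",
                        c(D = "GBIDRAFT", S = "STRG", T = "TRINITY")[sp$sources[1L]],
                        gsub("[^A-Za-z0-9]", "", nm), k)
    tx_seq <- if (sp$transcript_frame_trick) {
      frame_trick_transcript(cds, prec$seq, matures)
    } else {
      cds
    }
    truth <- rbind(truth, data.frame(
      name = nm, scaffold = scn, start = min(exons$start),
      end = max(exons$end), strand = sp$strand, mutation = sp$mutation,
      kind = if (sp$transcript_frame_trick) "frame_trick" else "plain",
      model_id = model_id, stringsAsFactors = FALSE))

    for (src in sp$sources) {
      src_full <- c(D = "DRAFT", S = "STRINGTIE", T = "TRINITY")[[src]]
      m <- if (src == "T") {
        # de novo models carry no deduced protein: longest-ORF convention
        gene_model(model_id, src_full, transcript = tx_seq)
      } else {
        gene_model(model_id, src_full, transcript = cds,
                   protein = prec$seq,
                   exons = data.frame(scaffold = scn, start = exons$start,
                                      end = exons$end, strand = sp$strand,
                                      stringsAsFactors = FALSE))
      }
      models[[src]] <- c(models[[src]], list(m))
    }
    alignments[[length(alignments) + 1L]] <-
      spliced_alignment(model_id, scn, sp$strand,
                        exons[, c("start", "end")])

    panel <- rbind(panel, data.frame(name = nm, tier = "SAME_SPECIES",
                                     citation = "synthetic",
                                     stringsAsFactors = FALSE))
    seeds[[nm]] <- seed_record(nm, mature_peptides = matures,
                               precursor = prec,
                               cdna = nuc_sequence(paste0(nm, "_cdna"), cds),
                               source_citation = "synthetic")
  }

  registry <- structure(list(records = seeds, target_panel = panel$name,
                             no_seed = character(0), panel = panel),
                        class = "seed_registry")
  list(genome = scaffolds, truth = truth, truth_gff = truth_to_gff(truth),
       models = models, alignments = alignments, registry = registry,
       specs = specs)
}

truth_to_gff <- function(truth) {
  rows <- truth[truth$kind != "genomic_only", , drop = FALSE]
  if (nrow(rows) == 0L) return(gff_parse_lines(character(0)))
  lines <- vapply(seq_len(nrow(rows)), function(i) {
    g <- to_gff_coords(rows$start[i], rows$end[i])
    paste(rows$scaffold[i], "truth", "gene", g$start, g$end, ".",
          rows$strand[i], ".",
          sprintf("ID=truth_%s;Name=%s;mutation=%s",
                  gsub("[^A-Za-z0-9]", "", rows$name[i]), rows$name[i],
                  rows$mutation[i]),
          sep = "\t")
  }, "")
  gff_parse_lines(c("##gff-version 3", lines))
}

#' The default synthetic study conditions
#'
#' Eleven planted neuropeptide genes over four scaffolds: eight clean
#' plants mixing strands and 1-4 exons across the three annotation
#' sources, two frame-trick transcripts, one frameshifted genomic copy,
#' one non-synonymous genomic SNV, and one genomic-only fragment encoding
#' an EFLamide-like peptide.
#'
#' @return List of [plant_spec()]s.
#' @export
default_plant_specs <- function() {
  list(
    plant_spec("Proctolin-like-1", exon_count = 2L, strand = "+",
               sources = "T", transcript_frame_trick = TRUE),
    plant_spec("PDF-like", exon_count = 1L, strand = "-",
               sources = "T", transcript_frame_trick = TRUE),
    plant_spec("AstA-like", exon_count = 3L, strand = "+", n_mature = 2L,
               sources = c("D", "T")),
    plant_spec("AstB-like", exon_count = 2L, strand = "-", sources = "S"),
    plant_spec("Corazonin-like", exon_count = 1L, strand = "+",
               sources = "S"),
    plant_spec("CCAP-like", exon_count = 4L, strand = "-", sources = "D"),
    plant_spec("RYamide-like", exon_count = 2L, strand = "+", n_mature = 2L,
               sources = c("S", "T")),
    plant_spec("SIFamide-like", exon_count = 1L, strand = "-",
               sources = "D"),
    plant_spec("Sulfakinin-like", exon_count = 3L, strand = "+",
               sources = "T"),
    plant_spec("Natalisin-like", exon_count = 2L, strand = "+",
               mutation = "FRAMESHIFT", sources = "T"),
    plant_spec("CRFDH-like", exon_count = 1L, strand = "-",
               mutation = "POINT", sources = "T"),
    plant_spec("EFLamide-like",
               precursor = pep_sequence("EFLamide_fragment",
                                        EFLAMIDE_FRAGMENT),
               genomic_only = TRUE)
  )
}

#' The published 43-neuropeptide annotation ledger
#'
#' Transcription of the released cricket neuropeptide annotation table:
#' name, released gene-model IDs, genomic locus, and the annotation-method
#' letters (D = draft genome annotation, S = reference-mapping-based,
#' T = de novo assembly-based).
#'
#' @return An `annotation_table` data.frame with 43 rows and columns
#'   `name`, `ids`, `source_ids`, `locus`, `methods`.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "gbi_neuropeptide_table.tsv",
                      package = "npannotate", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          na.strings = NULL)
  df[is.na(df)] <- ""
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' Summary tallies of an annotation ledger
#'
#' @param table An `annotation_table` (see [table1_fixture()]).
#' @return List: `identified` (rows with at least one ID), `with_locus`,
#'   `without_locus` (identified minus with-locus), `by_method` (named
#'   counts of rows whose method set contains D, S, T).
#' @export
tally <- function(table) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0L) {
    return(list(identified = 0L, with_locus = 0L, without_locus = 0L,
                by_method = c(D = 0L, S = 0L, T = 0L)))
  }
  has_id <- nzchar(trimws(table$ids))
  has_locus <- has_id & nzchar(trimws(table$locus))
  letters_of <- function(s) strsplit(gsub("[ ,]+", ",", trimws(s)), ",")[[1L]]
  by_method <- vapply(c(D = "D", S = "S", T = "T"), function(l) {
    sum(vapply(table$methods, function(m) l %in% letters_of(m), TRUE))
  }, 0L)
  list(identified = sum(has_id),
       with_locus = sum(has_locus),
       without_locus = sum(has_id) - sum(has_locus),
       by_method = by_method)
}

#' Synthetic TPM matrix with planted expression archetypes
#'
#' Emulates a developmental whole-body RNA-seq series: each transcript
#' follows one of three archetype profiles (high at an early stage;
#' steadily increasing across post-embryonic development; a steep late
#' spike around molting/eclosion) with multiplicative log-normal noise.
#' Transcripts listed in `all_zero` get zero TPM throughout, mimicking
#' unexpressed splice variants.
#'
#' @param transcript_ids Character vector.
#' @param seed RNG seed.
#' @param n_samples Number of samples in the series (default 7).
#' @param all_zero IDs forced to all-zero rows.
#' @param noise_sd Log-scale noise standard deviation.
#' @return List: `tpm` ([expression_matrix()]), `archetype` (named integer,
#'   the planted pattern per transcript; 0 for all-zero rows).
#' @export
generate_tpm <- function(transcript_ids, seed = 1L, n_samples = 7L,
                         all_zero = character(0), noise_sd = 0.1) {
  set.seed(seed)
  t <- seq(0, 1, length.out = n_samples)
  shapes <- list(
    early = 80 * exp(-4 * t) + 2,
    increasing = 5 + 90 * t,
    spike = 5 + 95 * exp(-((t - 0.85) / 0.08)^2)
  )
  arch <- stats::setNames(integer(length(transcript_ids)), transcript_ids)
  m <- matrix(0, length(transcript_ids), n_samples,
              dimnames = list(transcript_ids,
                              sprintf("sample%02d", seq_len(n_samples))))
  j <- 0L
  for (id in transcript_ids) {
    if (id %in% all_zero) { arch[id] <- 0L; next }
    j <- j + 1L
    a <- (j - 1L) %% 3L + 1L
    arch[id] <- a
    m[id, ] <- shapes[[a]] * exp(stats::rnorm(n_samples, 0, noise_sd))
  }
  list(tpm = expression_matrix(m), archetype = arch)
}
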