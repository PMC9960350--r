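# Pipeline orchestration: seeds -> homology search -> tiered selection and
# frame rescue -> genome-level fallback search -> locus assignment ->
# annotation release -> expression validation -> tally. Stages log their
# input/output counts; no stage mutates its inputs.

#' Pipeline configuration
#'
#' Inputs may be in-memory objects (as produced by [generate_genome()]) or
#' file paths; paths are loaded up front and missing paths are reported
#' together.
#'
#' @param registry A `seed_registry`, or list(fasta = paths, panel = path).
#' @param models List with elements `D`, `S`, `T` of `gene_model` lists.
#' @param genome Named scaffold sequences, or a FASTA path.
#' @param draft_gff `gff` object, GFF3 path, or character lines.
#' @param alignments List of `spliced_alignment`s, or a GFF3 path of exon
#'   features (the spliced-aligner output).
#' @param tpm Optional [expression_matrix()] or TSV path.
#' @param thresholds Overrides for `precursor_cov` (0.70), `cdna_cov`
#'   (0.60), `other_species_cov` (0.50).
#' @param genome_min_score Minimum nucleotide alignment score for the
#'   genome-level fallback search.
#' @param id_start,id_step New-locus numbering (release IDs).
#' @param out_dir Output directory; created when needed.
#' @param seed RNG seed recorded in the config (the pipeline itself is
#'   deterministic; the seed feeds fixture generation when used upstream).
#' @return A `np_config` list.
#' @export
np_config <- function(registry, models, genome, draft_gff = character(0),
                      alignments = list(), tpm = NULL, thresholds = list(),
                      genome_min_score = 60, id_start = 30000L,
                      id_step = 100L, out_dir = NULL, seed = 1L) {
  missing <- character(0)
  need_path <- function(x, what) {
    if (is.character(x) && length(x) == 1L && !file.exists(x)) {
      missing <<- c(missing, paste0(what, ": ", x))
    }
  }
  if (!inherits(registry, "seed_registry")) {
    lapply(registry$fasta, need_path, "seed fasta")
    need_path(registry$panel, "panel")
  }
  if (is.character(genome) && length(genome) == 1L) need_path(genome, "genome")
  if (is.character(draft_gff) && length(draft_gff) == 1L &&
      grepl("\\.gff3?$", draft_gff)) need_path(draft_gff, "draft gff")
  if (is.character(alignments)) need_path(alignments, "alignments")
  if (is.character(tpm)) need_path(tpm, "tpm")
  if (length(missing) > 0L) {
    stop("missing input path(s):\n  ", paste(missing, collapse = "\n  "))
  }
  thr <- utils::modifyList(list(precursor_cov = 0.70, cdna_cov = 0.60,
                                other_species_cov = 0.50), thresholds)
  stopifnot(all(unlist(thr) > 0), all(unlist(thr) <= 1), id_start >= 0L)
  structure(list(registry = registry, models = models, genome = genome,
                 draft_gff = draft_gff, alignments = alignments, tpm = tpm,
                 thresholds = thr, genome_min_score = genome_min_score,
                 id_start = as.integer(id_start),
                 id_step = as.integer(id_step),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "np_config")
}

resolve_inputs <- function(config) {
  cfg <- config
  if (!inherits(cfg$registry, "seed_registry")) {
    cfg$registry <- load_registry(cfg$registry$fasta, cfg$registry$panel)
  }
  if (is.character(cfg$genome) && length(cfg$genome) == 1L) {
    recs <- read_fasta(cfg$genome, "nuc")
    cfg$genome <- vapply(recs, function(r) r$seq, "")
  }
  if (is.character(cfg$alignments)) {
    cfg$alignments <- unname(gff_spliced_alignments(cfg$alignments))
  }
  if (is.character(cfg$tpm) && length(cfg$tpm) == 1L) {
    cfg$tpm <- expression_matrix(cfg$tpm)
  }
  cfg
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full annotation pipeline
#'
#' Executes every stage in order: seed qualification, homology search with
#' tiered selection, six-frame ORF rescue of cDNA-only matches,
#' genome-level fallback search for seeds without transcript hits, locus
#' assignment by translation identity, GFF/FASTA release, optional
#' expression validation, and the final per-neuropeptide tally.
#'
#' @param config A [np_config()].
#' @return A `np_run` list: `calls`, `discrepancies`, `genomic_only`,
#'   `placed`, `unplaced`, `merged` (gff lines, fasta, id map),
#'   `validation`, `table` (per-neuropeptide ledger), `summary` (tallies).
#'   When `config$out_dir` is set, TSV/GFF3/FASTA artifacts are written
#'   there deterministically.
#' @export
np_run_all <- function(config) {
  stopifnot(inherits(config, "np_config"))
  cfg <- resolve_inputs(config)
  registry <- cfg$registry
  all_models <- c(cfg$models$D, cfg$models$S, cfg$models$T)
  stage_log("seeds", "%d panel members, %d qualified seeds, %d NO_SEED",
            length(registry$target_panel), length(registry$records),
            length(registry$no_seed))

  calls <- list(); discrepancies <- list(); genomic_only <- list()
  for (nm in registry$target_panel) {
    seedr <- registry$records[[nm]]
    if (is.null(seedr)) next  # NO_SEED and no other-species fallback given
    rules <- effective_rule(seedr, cfg$thresholds)
    seed_calls <- select_candidates(seedr, all_models, rules)
    # cDNA-level matches without mature-peptide support: try frame rescue
    for (i in seq_along(seed_calls)) {
      call <- seed_calls[[i]]
      if (call$criterion != "CDNA_COV_60") next
      if (is.null(call$model$transcript)) next
      resc <- frame_rescue(seedr, call$model, rules)
      if (is.null(resc)) {
        # cDNA homology without any qualifying frame: mutation-level
        # discrepancy between assembly and transcript (kept, flagged)
        discrepancies[[length(discrepancies) + 1L]] <-
          list(neuropeptide_name = nm, model_id = call$model$model_id,
               reason = "no reading frame carries the mature peptide")
      } else if (resc$rescued) {
        call$criterion <- "FRAME_RESCUED"
        call$rescued_frame <- resc$frame
        call$rescued_protein <- resc$protein
        call$model$protein <- resc$protein  # for locus verification
        seed_calls[[i]] <- call
      }
    }
    if (length(seed_calls) == 0L) {
      g <- genome_fallback(seedr, rules, cfg)
      if (!is.null(g)) {
        if (length(g$calls) > 0L) seed_calls <- g$calls
        else genomic_only[[length(genomic_only) + 1L]] <- g$report
      }
    }
    calls <- c(calls, seed_calls)
  }
  stage_log("select", "%d candidate calls, %d discrepancies, %d genomic-only",
            length(calls), length(discrepancies), length(genomic_only))

  # locus assignment: supplied spliced alignments plus the exon structures
  # that draft/reference-based models already carry
  alns <- cfg$alignments
  have <- vapply(alns, function(a) a$model_id, "")
  for (m in all_models) {
    if (!is.null(m$exons) && !m$model_id %in% have) {
      alns <- c(alns, list(spliced_alignment(
        m$model_id, m$exons$scaffold[1L], m$exons$strand[1L],
        m$exons[, c("start", "end")])))
      have <- c(have, m$model_id)
    }
  }
  cls <- classify_models(calls, alns, cfg$genome)
  stage_log("assign-locus", "%d placed, %d unplaced",
            length(cls$placed), length(cls$unplaced))

  allocator <- id_allocator(start = cfg$id_start, step = cfg$id_step)
  merged <- merge_annotation(cfg$draft_gff, cfg$genome, cls$placed,
                             cls$unplaced, allocator)
  stage_log("merge-gff", "%d new feature lines, %d contigs in release",
            length(merged$gff_lines), length(merged$fasta))

  validation <- NULL
  if (!is.null(cfg$tpm)) {
    validation <- zscore_rows(cfg$tpm)
    k <- min(3L, length(validation$retained))
    if (k >= 1L) validation <- cluster_patterns(validation, k = k)
    stage_log("validate-expr", "%d retained, %d all-zero dropped",
              length(validation$retained),
              length(validation$dropped_all_zero))
  }

  table <- run_table(registry, calls, cls, merged$id_map)
  summary <- tally(table)
  stage_log("tally", "identified %d / %d; with locus %d",
            summary$identified, length(registry$target_panel),
            summary$with_locus)

  run <- structure(list(calls = calls, discrepancies = discrepancies,
                        genomic_only = genomic_only,
                        placed = cls$placed, unplaced = cls$unplaced,
                        merged = merged, validation = validation,
                        table = table, summary = summary,
                        config = cfg),
                   class = "np_run")
  if (!is.null(cfg$out_dir)) write_run(run, cfg$out_dir)
  run
}

# fallback when no transcript-level candidate exists: align the seed cDNA
# against the genome (all loci kept), or, for precursor-only seeds, scan
# the six-frame translations of every scaffold. Gene models overlapping a
# hit locus are pulled into curation; hits without any model are reported
# as genomic-only evidence.
genome_fallback <- function(seedr, rules, cfg) {
  genome <- cfg$genome
  all_models <- c(cfg$models$D, cfg$models$S, cfg$models$T)
  if (!is.null(seedr$cdna)) {
    hits <- multi_locus_hits(seedr$cdna, genome,
                             min_score = cfg$genome_min_score)
    if (length(hits) == 0L) return(NULL)
    calls <- list()
    for (h in hits) {
      for (m in all_models) {
        if (is.null(m$exons)) next
        ov <- m$exons$scaffold == h$subject_id &
          m$exons$start < h$subject_span[2L] &
          m$exons$end > h$subject_span[1L]
        if (any(ov)) {
          calls[[length(calls) + 1L]] <- new_candidate_call(
            seedr$neuropeptide_name, m, "GENOME_BLASTN_LOCUS", h,
            coverage = h$query_cov, identity = h$identity_frac)
        }
      }
    }
    report <- list(neuropeptide_name = seedr$neuropeptide_name,
                   evidence = "cdna", hits = hits_table(hits),
                   status = "genome-hit-without-transcript")
    return(list(calls = calls, report = report))
  }
  if (!is.null(seedr$precursor)) {
    thr <- rules$precursor_cov
    best <- list()
    gseqs <- if (is.list(genome)) genome else as.list(genome)
    for (scn in names(gseqs)) {
      scaf <- if (is.list(genome)) genome_lookup(genome, scn) else gseqs[[scn]]
      for (f in c(1L, 2L, 3L, -1L, -2L, -3L)) {
        aa <- tryCatch(translate_frame(scaf, f), error = function(e) NULL)
        if (is.null(aa)) next
        aa <- gsub("*", "X", aa, fixed = TRUE)
        aln <- local_align_protein(seedr$precursor, aa)
        if (!is.null(aln) && aln$query_cov >= thr &&
            aln$identity_frac >= 0.9) {
          best[[length(best) + 1L]] <-
            data.frame(scaffold = scn, frame = f,
                       coverage = aln$query_cov,
                       identity = aln$identity_frac,
                       stringsAsFactors = FALSE)
        }
      }
    }
    if (length(best) == 0L) return(NULL)
    report <- list(neuropeptide_name = seedr$neuropeptide_name,
                   evidence = "precursor-six-frame",
                   hits = do.call(rbind, best),
                   status = "genome-hit-without-transcript")
    return(list(calls = list(), report = report))
  }
  NULL
}

run_table <- function(registry, calls, cls, id_map) {
  call_names <- vapply(calls, `[[`, "", "neuropeptide_name")
  placed_models <- vapply(cls$placed, `[[`, "", "model_id")
  rows <- lapply(registry$target_panel, function(nm) {
    idx <- which(call_names == nm)
    mids <- unique(vapply(calls[idx], function(c) c$model$model_id, ""))
    released <- id_map$released_id[match(mids, id_map$model_id)]
    ids <- ifelse(is.na(released), mids, released)
    pl <- cls$placed[vapply(cls$placed, function(p)
      p$call$neuropeptide_name == nm, TRUE)]
    locus <- if (length(pl) > 0L) {
      p <- pl[[1L]]
      g <- to_gff_coords(p$span[1L], p$span[2L])
      sprintf("%s:%d..%d(%s)", p$scaffold, g$start, g$end, p$strand)
    } else ""
    letters <- sort(unique(vapply(calls[idx], function(c)
      c$model$source_letter, "")))
    data.frame(name = nm, ids = paste(ids, collapse = ";"),
               source_ids = paste(mids, collapse = ";"),
               locus = locus,
               methods = paste(letters, collapse = ","),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(name = character(), ids = character(),
                     source_ids = character(), locus = character(),
                     methods = character(), stringsAsFactors = FALSE)
  }
  class(df) <- c("annotation_table", "data.frame")
  df
}

calls_table <- function(calls) {
  if (length(calls) == 0L) {
    return(data.frame(neuropeptide = character(), model_id = character(),
                      source = character(), criterion = character(),
                      coverage = numeric(), identity = numeric(),
                      rescued_frame = integer(), stringsAsFactors = FALSE))
  }
  data.frame(
    neuropeptide = vapply(calls, `[[`, "", "neuropeptide_name"),
    model_id = vapply(calls, function(c) c$model$model_id, ""),
    source = vapply(calls, function(c) c$model$source_letter, ""),
    criterion = vapply(calls, `[[`, "", "criterion"),
    coverage = round(vapply(calls, `[[`, 0, "coverage"), 4),
    identity = round(vapply(calls, `[[`, 0, "identity"), 4),
    rescued_frame = vapply(calls, function(c)
      as.integer(c$rescued_frame), 0L),
    stringsAsFactors = FALSE
  )
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(calls_table(run$calls), "calls.tsv")
  wt(assignments_table(c(run$placed, run$unplaced)), "assignments.tsv")
  wt(run$merged$id_map, "id_map.tsv")
  wt(run$table, "annotation_table.tsv")
  writeLines(run$merged$gff_lines, file.path(out_dir, "augmented.gff3"))
  write_fasta(run$merged$fasta, file.path(out_dir, "augmented.fasta"))
  if (length(run$genomic_only) > 0L) {
    gdf <- do.call(rbind, lapply(run$genomic_only, function(g) {
      data.frame(neuropeptide = g$neuropeptide_name, evidence = g$evidence,
                 status = g$status, stringsAsFactors = FALSE)
    }))
    wt(gdf, "genomic_only.tsv")
  }
  if (length(run$discrepancies) > 0L) {
    ddf <- do.call(rbind, lapply(run$discrepancies, function(d) {
      data.frame(neuropeptide = d$neuropeptide_name, model_id = d$model_id,
                 reason = d$reason, stringsAsFactors = FALSE)
    }))
    wt(ddf, "discrepancies.tsv")
  }
  if (!is.null(run$validation) && !is.null(run$validation$clusters)) {
    heatmap_export(run$validation, file.path(out_dir, "validation.tsv"))
  }
  s <- run$summary
  sm <- data.frame(metric = c("identified", "with_locus", "without_locus",
                              "method_D", "method_S", "method_T"),
                   value = c(s$identified, s$with_locus, s$without_locus,
                             s$by_method[["D"]], s$by_method[["S"]],
                             s$by_method[["T"]]))
  wt(sm, "summary.tsv")
  invisible(out_dir)
}
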