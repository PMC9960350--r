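# Tiered candidate selection, six-frame ORF rescue, prohormone processing
# annotation, and curation-support alignment reports.

MODEL_SOURCES <- c(DRAFT = "D", STRINGTIE = "S", TRINITY = "T")

#' Gene model from one of the three annotation sources
#'
#' @param model_id Identifier.
#' @param source One of `"DRAFT"` (draft genome annotation, letter D),
#'   `"STRINGTIE"` (reference-mapping-based, S), `"TRINITY"` (de novo
#'   assembly-based, T).
#' @param transcript Optional `nuc_sequence` (or string).
#' @param protein Optional deduced `pep_sequence` (or string).
#' @param exons Optional data.frame with columns `scaffold`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @return A `gene_model` object.
#' @export
gene_model <- function(model_id, source = c("DRAFT", "STRINGTIE", "TRINITY"),
                       transcript = NULL, protein = NULL, exons = NULL) {
  source <- match.arg(source)
  stopifnot(is.character(model_id), nzchar(model_id))
  if (!is.null(transcript) && !inherits(transcript, "nuc_sequence")) {
    transcript <- nuc_sequence(paste0(model_id, "_tx"), transcript)
  }
  if (!is.null(protein) && !inherits(protein, "pep_sequence")) {
    protein <- pep_sequence(paste0(model_id, "_pep"), protein)
  }
  structure(list(model_id = model_id, source = source,
                 source_letter = MODEL_SOURCES[[source]],
                 transcript = transcript, protein = protein, exons = exons),
            class = "gene_model")
}

# deduced protein of a model: its stated protein, else the longest
# M-started ORF of its transcript over all six frames (longest-ORF
# prediction, the convention of transcript ORF predictors)
model_protein <- function(model) {
  if (!is.null(model$protein)) return(model$protein)
  if (is.null(model$transcript)) return(NULL)
  orfs <- six_frame_orfs(model$transcript)
  if (length(orfs) == 0L) return(NULL)
  lens <- vapply(orfs, function(o) nchar(o$peptide$seq), 0L)
  orfs[[which.max(lens)]]$peptide
}

CALL_CRITERIA <- c("MATURE_EXACT", "PRECURSOR_COV_70", "CDNA_COV_60",
                   "OTHER_SPECIES_COV_50", "MOTIF", "GENOME_BLASTN_LOCUS",
                   "FRAME_RESCUED")

new_candidate_call <- function(neuropeptide_name, model, criterion, evidence,
                               coverage = NA_real_, identity = NA_real_,
                               rescued_frame = NA_integer_) {
  stopifnot(criterion %in% CALL_CRITERIA)
  structure(list(neuropeptide_name = neuropeptide_name, model = model,
                 criterion = criterion, evidence = evidence,
                 coverage = coverage, identity = identity,
                 rescued_frame = rescued_frame),
            class = "candidate_call")
}

#' Select candidate gene models for one neuropeptide seed
#'
#' Applies the tiered acceptance criteria given by the seed's selection
#' rules (see [effective_rule()]): an exact match of any mature peptide in
#' the model's deduced protein; precursor alignment covering at least 70%
#' of the seed precursor (50% for an other-species seed); cDNA alignment
#' covering at least 60% of the seed cDNA. A model is called once, under the
#' highest-priority criterion it meets (mature > precursor > cDNA); coverage
#' thresholds are inclusive.
#'
#' @param seed A `seed_record`.
#' @param models List of `gene_model`s.
#' @param rules Rule descriptor from [effective_rule()]; defaults to the
#'   seed's own rules.
#' @param scoring_protein,scoring_nuc Alignment scoring schemes.
#' @param min_score_protein,min_score_nuc Minimum raw alignment score for a
#'   coverage rule to be evaluated at all. Plays the role of the homology
#'   search's E-value cutoff: it keeps low-identity chance alignments
#'   between unrelated short proteins from entering the coverage test.
#' @return List of `candidate_call`s (possibly empty). Models lacking both
#'   transcript and protein are skipped with a warning.
#' @export
select_candidates <- function(seed, models, rules = effective_rule(seed),
                              scoring_protein = default_scoring("protein"),
                              scoring_nuc = default_scoring("nuc"),
                              min_score_protein = 50,
                              min_score_nuc = 60) {
  calls <- list()
  for (model in models) {
    if (is.null(model$transcript) && is.null(model$protein)) {
      warning("model ", model$model_id,
              " has neither transcript nor protein; skipped")
      next
    }
    prot <- model_protein(model)
    call <- NULL
    # priority 1: exact mature peptide
    if ("mature_exact" %in% rules$rule_names && !is.null(prot)) {
      for (mat in seed$mature_peptides) {
        hits <- find_mature_exact(mat, prot)
        if (length(hits) > 0L) {
          call <- new_candidate_call(seed$neuropeptide_name, model,
                                     "MATURE_EXACT", hits[[1L]],
                                     coverage = 1, identity = 1)
          break
        }
      }
    }
    # priority 2: precursor coverage
    if (is.null(call) && !is.null(seed$precursor) && !is.null(prot) &&
        !is.na(rules$precursor_cov)) {
      aln <- local_align_protein(seed$precursor, prot, scoring_protein)
      if (!is.null(aln) && aln$score >= min_score_protein &&
          aln$query_cov >= rules$precursor_cov) {
        crit <- if (seed$provenance_tier == "OTHER_SPECIES")
          "OTHER_SPECIES_COV_50" else "PRECURSOR_COV_70"
        call <- new_candidate_call(seed$neuropeptide_name, model, crit, aln,
                                   coverage = aln$query_cov,
                                   identity = aln$identity_frac)
      }
    }
    # priority 3: cDNA coverage
    if (is.null(call) && !is.null(seed$cdna) && !is.null(model$transcript) &&
        !is.na(rules$cdna_cov)) {
      aln <- local_align_nuc(seed$cdna, model$transcript, scoring_nuc,
                             both_strands = TRUE)
      if (!is.null(aln) && aln$score >= min_score_nuc &&
          aln$query_cov >= rules$cdna_cov) {
        call <- new_candidate_call(seed$neuropeptide_name, model,
                                   "CDNA_COV_60", aln,
                                   coverage = aln$query_cov,
                                   identity = aln$identity_frac)
      }
    }
    if (!is.null(call)) calls[[length(calls) + 1L]] <- call
  }
  calls
}

#' Six-frame ORF rescue of a cDNA-matched transcript
#'
#' When a transcript matches the seed at the cDNA level but its deduced
#' protein (the longest ORF) lacks the mature peptide, the transcript is
#' re-translated in all six frames and the frame whose translation contains
#' an exact mature-peptide match — or, failing that, a precursor alignment
#' meeting the rule threshold — is returned together with the longest
#' M-started ORF of that frame. When the longest-ORF frame itself already
#' qualifies, it is returned with `rescued = FALSE`. Frames are tried in the
#' order +1, +2, +3, -1, -2, -3, so ties resolve toward positive frames and
#' lower frame magnitude; mature-peptide evidence beats precursor-alignment
#' evidence across frames.
#'
#' @param seed A `seed_record`.
#' @param model A `gene_model` with a transcript.
#' @param rules Rule descriptor (for the precursor fallback threshold).
#' @param scoring_protein Protein scoring scheme.
#' @return `NULL` when no frame qualifies, else a list with `frame`,
#'   `protein` (`pep_sequence`, the longest M-started ORF of that frame),
#'   `rescued` (FALSE when the longest-ORF frame already qualified) and
#'   `evidence` (`"mature"` or `"precursor"`).
#' @export
frame_rescue <- function(seed, model, rules = effective_rule(seed),
                         scoring_protein = default_scoring("protein")) {
  stopifnot(!is.null(model$transcript))
  orfs <- six_frame_orfs(model$transcript)
  if (length(orfs) == 0L) return(NULL)
  frames <- vapply(orfs, function(o) o$frame, 0L)
  lens <- vapply(orfs, function(o) nchar(o$peptide$seq), 0L)
  longest_frame <- frames[which.max(lens)]

  qualify <- function(frame) {
    aa <- translate_frame(model$transcript, frame)
    aa_clean <- gsub("*", "X", aa, fixed = TRUE)  # motif never spans a stop
    for (mat in seed$mature_peptides) {
      if (length(find_mature_exact(mat, aa_clean)) > 0L) return("mature")
    }
    thr <- rules$precursor_cov
    idx <- match(frame, frames)
    if (!is.null(seed$precursor) && !is.na(thr) && !is.na(idx)) {
      aln <- local_align_protein(seed$precursor, orfs[[idx]]$peptide,
                                 scoring_protein)
      if (!is.null(aln) && aln$query_cov >= thr) return("precursor")
    }
    NULL
  }

  order_frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  evid <- list()
  for (f in intersect(order_frames, frames)) evid[[as.character(f)]] <- qualify(f)
  hit_frames <- as.integer(names(evid)[!vapply(evid, is.null, TRUE)])
  if (length(hit_frames) == 0L) return(NULL)
  # mature-exact evidence outranks precursor-alignment evidence
  mature_frames <- hit_frames[vapply(as.character(hit_frames),
                                     function(k) evid[[k]] == "mature", TRUE)]
  chosen <- if (length(mature_frames) > 0L) mature_frames[1L] else hit_frames[1L]
  if (longest_frame %in% (if (length(mature_frames) > 0L) mature_frames
                          else hit_frames)) {
    chosen <- longest_frame
    rescued <- FALSE
  } else {
    rescued <- TRUE
  }
  list(frame = chosen,
       protein = orfs[[match(chosen, frames)]]$peptide,
       rescued = rescued,
       evidence = evid[[as.character(chosen)]])
}

#' Annotate prohormone processing sites on a precursor
#'
#' Locates every dibasic convertase site (KR, KK, RR; overlapping pairs all
#' reported), marks sites flanking a mature-peptide match (within one
#' residue of either boundary), and flags C-terminal amidation donors: a
#' glycine immediately preceding a cleavage site that closes a mature match.
#' These annotations support curation; they never reject a candidate.
#'
#' @param precursor `pep_sequence` or string.
#' @param mature_hits List of `motif_hit`s from [find_mature_exact()].
#' @return A `processing_annotation`: `precursor_id`, `sites` data.frame
#'   (`position` 0-based index of the first residue of the pair,
#'   `site_type`, `flanks_mature`), and `amidation` (0-based positions of
#'   donor glycines).
#' @export
annotate_processing <- function(precursor, mature_hits = list()) {
  p <- as_seq_string(precursor)
  pid <- if (is.list(precursor)) precursor$id else "precursor"
  n <- nchar(p)
  pos <- integer(); typ <- character()
  if (n >= 2L) {
    pairs <- substring(p, seq_len(n - 1L), seq_len(n - 1L) + 1L)
    ix <- which(pairs %in% c("KR", "KK", "RR"))
    pos <- ix - 1L
    typ <- pairs[ix]
  }
  bounds <- lapply(mature_hits, function(h) {
    c(start = h$position, end = h$position + nchar(h$motif))
  })
  flanks <- vapply(pos, function(p0) {
    site <- c(p0, p0 + 2L)  # half-open span of the dibasic pair
    any(vapply(bounds, function(b) {
      abs(site[1L] - b["end"]) <= 1L || abs(site[2L] - b["start"]) <= 1L
    }, TRUE))
  }, TRUE)
  if (length(pos) == 0L) flanks <- logical(0)
  amid <- integer()
  for (i in seq_along(pos)) {
    p0 <- pos[i]
    if (p0 >= 1L && substring(p, p0, p0) == "G") {
      closes <- any(vapply(bounds, function(b) {
        b["end"] %in% c(p0 - 1L, p0)  # G may be part of the match or abut it
      }, TRUE))
      if (length(bounds) > 0L && closes) amid <- c(amid, p0 - 1L)
    }
  }
  structure(list(precursor_id = pid,
                 sites = data.frame(position = pos, site_type = typ,
                                    flanks_mature = flanks,
                                    stringsAsFactors = FALSE),
                 amidation = amid),
            class = "processing_annotation")
}

#' Plain-text curation report for one neuropeptide's candidates
#'
#' Builds a progressive (center-star) multiple alignment of the seed
#' precursor and the candidate proteins, marks the mature-peptide spans and
#' dibasic processing sites, and notes candidates sharing a genomic locus.
#' Advisory output for the human curator; never filters.
#'
#' @param seed A `seed_record`.
#' @param calls Non-empty list of `candidate_call`s.
#' @param width Wrap width for alignment blocks.
#' @return Character vector of report lines (class `curation_report`).
#' @export
curation_report <- function(seed, calls, width = 60L) {
  stopifnot(length(calls) >= 1L)
  seqs <- list()
  if (!is.null(seed$precursor)) {
    seqs[[paste0("seed|", seed$neuropeptide_name)]] <- seed$precursor$seq
  }
  for (call in calls) {
    prot <- model_protein(call$model)
    if (!is.null(call$rescued_frame) && !is.na(call$rescued_frame) &&
        !is.null(call$rescued_protein)) {
      prot <- call$rescued_protein
    }
    if (!is.null(prot)) seqs[[call$model$model_id]] <- gsub("*", "X",
                                                            prot$seq,
                                                            fixed = TRUE)
  }
  if (length(seqs) == 0L) stop("no sequences to align")
  aln <- center_star_align(seqs)
  lines <- c(sprintf("# curation report: %s", seed$neuropeptide_name),
             sprintf("# %d candidate(s); criteria: %s",
                     length(calls),
                     paste(vapply(calls, `[[`, "", "criterion"),
                           collapse = ", ")))
  shared <- shared_locus_note(calls)
  if (!is.null(shared)) lines <- c(lines, shared)
  mature <- vapply(seed$mature_peptides, as_seq_string, "")
  nc <- nchar(aln[[1L]])
  namew <- max(nchar(names(aln)))
  for (start in seq(1L, nc, by = width)) {
    stop_ <- min(start + width - 1L, nc)
    for (nm in names(aln)) {
      chunk <- substring(aln[[nm]], start, stop_)
      lines <- c(lines, sprintf("%-*s  %s", namew, nm, chunk))
      marks <- mark_line(aln[[nm]], mature)
      if (grepl("[^ ]", substring(marks, start, stop_))) {
        lines <- c(lines, sprintf("%-*s  %s", namew, "",
                                  substring(marks, start, stop_)))
      }
    }
    lines <- c(lines, "")
  }
  structure(lines, class = c("curation_report", "character"))
}

# progressive alignment around the longest sequence as center; pairwise
# global alignments are merged column-wise. Adequate for the <= ~20 short
# precursors a curation report compares.
center_star_align <- function(seqs) {
  if (length(seqs) == 1L) return(seqs)
  center_i <- which.max(nchar(unlist(seqs)))
  center <- seqs[[center_i]]
  others <- seqs[-center_i]
  pair_alns <- lapply(others, function(s) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(center), Biostrings::AAString(s),
      substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 0.5,
      type = "global")
    list(c = as.character(Biostrings::alignedPattern(pa)),
         s = as.character(Biostrings::alignedSubject(pa)))
  })
  # master gap pattern for the center: union of gap insertions
  center_cols <- lapply(pair_alns, function(a) {
    # map: for each center residue, gaps preceding it in this pairwise aln
    gaps_before(a$c)
  })
  n_res <- nchar(center)
  max_gaps <- Reduce(pmax, center_cols, rep(0L, n_res + 1L))
  master_center <- insert_gaps(center, max_gaps)
  out <- list()
  nm_center <- names(seqs)[center_i]
  out[[nm_center]] <- master_center
  for (i in seq_along(pair_alns)) {
    a <- pair_alns[[i]]
    have <- gaps_before(a$c)
    extra <- max_gaps - have
    out[[names(others)[i]]] <- insert_gaps(a$s, extra, template = a$c)
  }
  out[names(seqs)]
}

# number of gap characters before the 1st..nth residue and after the last
gaps_before <- function(aligned) {
  ch <- strsplit(aligned, "", fixed = TRUE)[[1L]]
  n_res <- sum(ch != "-")
  out <- integer(n_res + 1L)
  slot <- 1L
  for (c in ch) {
    if (c == "-") out[slot] <- out[slot] + 1L else slot <- slot + 1L
  }
  out
}

# insert gap runs into a plain sequence (template NULL) or an aligned string
# whose residue slots are defined by `template`'s non-gap positions
insert_gaps <- function(s, extra, template = NULL) {
  if (is.null(template)) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    pieces <- character(0)
    for (i in seq_along(ch)) {
      pieces <- c(pieces, strrep("-", extra[i]), ch[i])
    }
    paste0(paste(pieces, collapse = ""), strrep("-", extra[length(extra)]))
  } else {
    cch <- strsplit(template, "", fixed = TRUE)[[1L]]
    sch <- strsplit(s, "", fixed = TRUE)[[1L]]
    pieces <- character(0)
    slot <- 1L
    for (i in seq_along(cch)) {
      if (cch[i] != "-") {
        pieces <- c(pieces, strrep("-", extra[slot]), sch[i])
        slot <- slot + 1L
      } else {
        pieces <- c(pieces, sch[i])
      }
    }
    paste0(paste(pieces, collapse = ""), strrep("-", extra[slot]))
  }
}

mark_line <- function(aligned, mature) {
  plain <- gsub("-", "", aligned, fixed = TRUE)
  marks <- rep(" ", nchar(aligned))
  res_pos <- which(strsplit(aligned, "", fixed = TRUE)[[1L]] != "-")
  for (m in mature) {
    if (nchar(m) < 3L) next
    for (h in find_mature_exact(m, plain)) {
      span <- res_pos[(h$position + 1L):(h$position + nchar(m))]
      marks[span] <- "="
    }
  }
  ann <- annotate_processing(plain)
  for (p0 in ann$sites$position) {
    marks[res_pos[c(p0 + 1L, p0 + 2L)]] <- "^"
  }
  paste(marks, collapse = "")
}

shared_locus_note <- function(calls) {
  ex <- lapply(calls, function(c) c$model$exons)
  keep <- !vapply(ex, is.null, TRUE)
  if (sum(keep) < 2L) return(NULL)
  ex <- ex[keep]
  ids <- vapply(calls[keep], function(c) c$model$model_id, "")
  notes <- character(0)
  for (i in seq_len(length(ex) - 1L)) {
    for (j in seq(i + 1L, length(ex))) {
      a <- ex[[i]]; b <- ex[[j]]
      if (any(a$scaffold %in% b$scaffold)) {
        sc <- intersect(a$scaffold, b$scaffold)
        ai <- a[a$scaffold %in% sc, ]; bi <- b[b$scaffold %in% sc, ]
        if (min(ai$end) > max(bi$start) && min(bi$end) > max(ai$start) ||
            any(mapply(function(s, e) any(bi$start < e & bi$end > s),
                       ai$start, ai$end))) {
          notes <- c(notes, sprintf("# note: %s and %s overlap one locus",
                                    ids[i], ids[j]))
        }
      }
    }
  }
  if (length(notes) > 0L) unique(notes) else NULL
}
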