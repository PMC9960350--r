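# Locus assignment by translation identity: an accepted gene model is
# PLACED at a spliced genomic region iff translating that region reproduces
# the model's deduced protein exactly (no similarity slack). Spliced
# alignments (e.g. GMAP output) are consumed as input, never computed here.

#' Spliced alignment of a model's CDS to the genome
#'
#' @param model_id Model identifier.
#' @param scaffold Scaffold name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with `start`, `end`: 0-based half-open intervals
#'   on the forward strand, non-overlapping; sorted internally by `start`.
#' @return A `spliced_alignment`.
#' @export
spliced_alignment <- function(model_id, scaffold, strand, exons) {
  stopifnot(strand %in% c("+", "-"), all(exons$end > exons$start))
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] < exons$end[-nrow(exons)])) {
    stop("overlapping exons in spliced alignment for ", model_id)
  }
  structure(list(model_id = model_id, scaffold = scaffold, strand = strand,
                 exons = exons),
            class = "spliced_alignment")
}

genome_lookup <- function(genome, scaffold) {
  if (is.list(genome) && length(genome) > 0L &&
      inherits(genome[[1L]], "nuc_sequence")) {
    ids <- vapply(genome, function(r) r$id, "")
    i <- match(scaffold, ids)
    if (is.na(i)) return(NULL)
    genome[[i]]$seq
  } else {
    if (!scaffold %in% names(genome)) return(NULL)
    toupper(genome[[scaffold]])
  }
}

#' Verify a genomic locus by translation identity
#'
#' Splices the exon intervals out of the scaffold (5'->3': the concatenated
#' forward-strand sequence is reverse-complemented for minus-strand models),
#' translates frame +1, and compares to the model's deduced protein. A
#' trailing stop in the genomic translation is ignored (ORF predictors
#' usually omit it from deduced proteins). Identity places the model;
#' anything else leaves it unplaced with a reason.
#'
#' @param model A `gene_model` with a deduced protein.
#' @param aln A `spliced_alignment` for this model.
#' @param genome Named scaffold sequences (character vector or list of
#'   `nuc_sequence`).
#' @return A `locus_assignment`: `model_id`, `status` (`"PLACED"` /
#'   `"UNPLACED"`), and when placed `scaffold`, `span` (0-based half-open),
#'   `strand`; when unplaced a `reason` from `{no-mapping,
#'   translation-mismatch, partial-exon}`.
#' @export
verify_locus <- function(model, aln, genome) {
  prot <- model_protein(model)
  if (is.null(prot)) stop("model ", model$model_id, " has no deduced protein")
  scaf <- genome_lookup(genome, aln$scaffold)
  if (is.null(scaf)) stop("scaffold ", aln$scaffold, " absent from genome")
  if (any(aln$exons$end > nchar(scaf)) || any(aln$exons$start < 0L)) {
    stop("exon interval outside scaffold bounds for ", model$model_id)
  }
  total <- sum(aln$exons$end - aln$exons$start)
  if (total %% 3L != 0L) {
    return(unplaced(model$model_id, "partial-exon"))
  }
  spliced <- paste(substring(scaf, aln$exons$start + 1L, aln$exons$end),
                   collapse = "")
  if (aln$strand == "-") spliced <- reverse_complement(spliced)
  aa <- translate_frame(spliced, 1L)
  aa <- sub("\\*$", "", aa)
  target <- sub("\\*$", "", prot$seq)
  if (identical(aa, target)) {
    structure(list(model_id = model$model_id, status = "PLACED",
                   scaffold = aln$scaffold,
                   span = c(min(aln$exons$start), max(aln$exons$end)),
                   strand = aln$strand, reason = NA_character_,
                   exons = aln$exons),
              class = "locus_assignment")
  } else {
    unplaced(model$model_id, "translation-mismatch")
  }
}

unplaced <- function(model_id, reason) {
  stopifnot(reason %in% c("no-mapping", "translation-mismatch",
                          "partial-exon"))
  structure(list(model_id = model_id, status = "UNPLACED",
                 scaffold = NA_character_, span = c(NA_integer_, NA_integer_),
                 strand = NA_character_, reason = reason),
            class = "locus_assignment")
}

#' Classify called models as placed or unplaced
#'
#' Each unique called model is classified exactly once. Models lacking any
#' spliced alignment are unplaced with reason `"no-mapping"`. When a model
#' maps to several loci with identical translation, all placements are
#' retained and flagged `multi_locus` for curation (none is auto-chosen).
#'
#' @param calls List of `candidate_call`s.
#' @param alignments List of `spliced_alignment`s (several may share one
#'   `model_id`).
#' @param genome Named scaffold sequences.
#' @return List with `placed` (possibly >1 entry per multi-locus model) and
#'   `unplaced`; each entry carries the originating call as `$call`.
#' @export
classify_models <- function(calls, alignments, genome) {
  placed <- list(); unpl <- list()
  if (length(calls) == 0L) return(list(placed = placed, unplaced = unpl))
  # when several seeds call the same model, verify under the
  # best-supported call: exact mature evidence first, then identity
  prio <- c(MATURE_EXACT = 1, FRAME_RESCUED = 2, PRECURSOR_COV_70 = 3,
            OTHER_SPECIES_COV_50 = 3, CDNA_COV_60 = 4, MOTIF = 5,
            GENOME_BLASTN_LOCUS = 6)
  ord <- order(vapply(calls, function(c) prio[[c$criterion]], 0),
               -vapply(calls, function(c) {
                 if (is.na(c$identity)) 0 else c$identity
               }, 0))
  calls <- calls[ord]
  aln_ids <- vapply(alignments, function(a) a$model_id, "")
  seen <- character(0)
  for (call in calls) {
    mid <- call$model$model_id
    if (mid %in% seen) next  # classify each model exactly once
    seen <- c(seen, mid)
    alns <- alignments[aln_ids == mid]
    if (length(alns) == 0L) {
      a <- unplaced(mid, "no-mapping")
      a$call <- call
      unpl[[length(unpl) + 1L]] <- a
      next
    }
    results <- lapply(alns, function(a) verify_locus(call$model, a, genome))
    ok <- Filter(function(r) r$status == "PLACED", results)
    if (length(ok) > 0L) {
      for (r in ok) {
        r$call <- call
        r$multi_locus <- length(ok) > 1L
        placed[[length(placed) + 1L]] <- r
      }
    } else {
      r <- results[[1L]]
      r$call <- call
      unpl[[length(unpl) + 1L]] <- r
    }
  }
  list(placed = placed, unplaced = unpl)
}

#' Tabulate locus assignments
#'
#' @param assignments List of `locus_assignment`s (placed and/or unplaced).
#' @return data.frame with one row per assignment.
#' @export
assignments_table <- function(assignments) {
  if (length(assignments) == 0L) {
    return(data.frame(model_id = character(), status = character(),
                      scaffold = character(), start = integer(),
                      end = integer(), strand = character(),
                      reason = character(), stringsAsFactors = FALSE))
  }
  data.frame(
    model_id = vapply(assignments, `[[`, "", "model_id"),
    status = vapply(assignments, `[[`, "", "status"),
    scaffold = vapply(assignments, `[[`, "", "scaffold"),
    start = vapply(assignments, function(a) as.integer(a$span[1L]), 0L),
    end = vapply(assignments, function(a) as.integer(a$span[2L]), 0L),
    strand = vapply(assignments, `[[`, "", "strand"),
    reason = vapply(assignments, `[[`, "", "reason"),
    stringsAsFactors = FALSE
  )
}
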