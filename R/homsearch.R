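# Homology engine: local protein/nucleotide alignment (Smith-Waterman,
# affine gaps) with query-coverage metrics, exact mature-peptide matching,
# and all-loci genome scanning. This in-package aligner is the reference
# implementation used by the whole pipeline.

#' Default alignment scoring schemes
#'
#' Protein: BLOSUM62 with gap open 11 / extend 1 (BLASTP defaults).
#' Nucleotide: match +2 / mismatch -3 / gap open 5 / extend 2 (BLASTN-like).
#' `N` scores as a mismatch against every base including itself.
#'
#' @param type `"protein"` or `"nuc"`.
#' @return A list with `matrix` (integer substitution matrix with dimnames),
#'   `gap_open` and `gap_ext`.
#' @export
default_scoring <- function(type = c("protein", "nuc")) {
  type <- match.arg(type)
  if (type == "protein") {
    mat <- blosum62()
    list(matrix = mat, gap_open = 11, gap_ext = 1)
  } else {
    ab <- c("A", "C", "G", "T", "N")
    mat <- matrix(-3L, 5, 5, dimnames = list(ab, ab))
    diag(mat) <- 2L
    mat["N", "N"] <- -3L
    list(matrix = mat, gap_open = 5, gap_ext = 2)
  }
}

blosum62 <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      mat <<- env$BLOSUM62
    }
    mat
  }
})

encode_for <- function(s, mat, what) {
  ab <- rownames(mat)
  idx <- match(strsplit(s, "", fixed = TRUE)[[1L]], ab) - 1L
  if (anyNA(idx)) stop("character outside scoring alphabet in ", what)
  idx
}

sw_run <- function(qseq, sseq, scoring) {
  q <- encode_for(qseq, scoring$matrix, "query")
  s <- encode_for(sseq, scoring$matrix, "subject")
  .sw_align_cpp(q, s, scoring$matrix, scoring$gap_open, scoring$gap_ext,
                qseq, sseq)
}

make_alignment_result <- function(query_id, subject_id, raw, qlen, slen,
                                  strand = "+") {
  if (raw$score <= 0) return(NULL)  # no positive-scoring cell: no hit
  structure(list(
    query_id = query_id,
    subject_id = subject_id,
    score = raw$score,
    aligned_cols = raw$aligned_cols,
    identity_frac = raw$n_ident / raw$aligned_cols,
    query_cov = (raw$q_end - raw$q_start) / qlen,
    query_span = c(raw$q_start, raw$q_end),
    subject_span = c(raw$s_start, raw$s_end),
    strand = strand,
    q_aln = raw$q_aln,
    s_aln = raw$s_aln
  ), class = "alignment_result")
}

#' Optimal local protein alignment
#'
#' Smith-Waterman with affine gaps over a substitution matrix. Coverage is
#' reported as the aligned query-span length divided by the query length
#' (the BLAST `qcovs` convention), so it is always in `[0, 1]`.
#'
#' @param query,subject `pep_sequence` records (or plain strings; ids then
#'   default to "query"/"subject").
#' @param scoring Scoring list as from [default_scoring()].
#' @return An `alignment_result`, or `NULL` when no positive-scoring local
#'   alignment exists.
#' @export
local_align_protein <- function(query, subject,
                                scoring = default_scoring("protein")) {
  qid <- if (is.list(query)) query$id else "query"
  sid <- if (is.list(subject)) subject$id else "subject"
  qs <- as_seq_string(query); ss <- as_seq_string(subject)
  stopifnot(nchar(qs) > 0L, nchar(ss) > 0L)
  make_alignment_result(qid, sid, sw_run(qs, ss, scoring),
                        nchar(qs), nchar(ss))
}

#' Optimal local nucleotide alignment
#'
#' As [local_align_protein()] with match/mismatch scoring. With
#' `both_strands = TRUE` the reverse complement of the query is also tried
#' and the better-scoring orientation is reported with its strand flag;
#' subject coordinates always refer to the subject's forward strand.
#'
#' @param query,subject `nuc_sequence` records or strings.
#' @param scoring Scoring list as from [default_scoring("nuc")].
#' @param both_strands Search both query orientations.
#' @return An `alignment_result` (with `strand` field) or `NULL`.
#' @export
local_align_nuc <- function(query, subject, scoring = default_scoring("nuc"),
                            both_strands = FALSE) {
  qid <- if (is.list(query)) query$id else "query"
  sid <- if (is.list(subject)) subject$id else "subject"
  qs <- as_seq_string(query); ss <- as_seq_string(subject)
  stopifnot(nchar(qs) > 0L, nchar(ss) > 0L)
  fwd <- make_alignment_result(qid, sid, sw_run(qs, ss, scoring),
                               nchar(qs), nchar(ss))
  if (!both_strands) return(fwd)
  raw_rev <- sw_run(reverse_complement(qs), ss, scoring)
  rev <- make_alignment_result(qid, sid, raw_rev, nchar(qs), nchar(ss),
                               strand = "-")
  if (is.null(rev)) return(fwd)
  if (is.null(fwd) || rev$score > fwd$score) rev else fwd
}

#' Exact occurrences of a mature peptide within a protein
#'
#' Case-insensitive, overlapping occurrences are all reported.
#'
#' @param mature `pep_sequence` (length >= 3) or string.
#' @param protein `pep_sequence` or string.
#' @return List of `motif_hit` records (`subject_id`, `motif`, `position`
#'   0-based); empty list when absent.
#' @examples
#' length(find_mature_exact("AAA", pep_sequence("p", "AAAA")))  # 2
#' @export
find_mature_exact <- function(mature, protein) {
  m <- as_seq_string(mature)
  p <- as_seq_string(protein)
  stopifnot(nchar(m) >= 3L)
  sid <- if (is.list(protein)) protein$id else "subject"
  w <- nchar(m)
  n <- nchar(p)
  if (n < w) return(list())
  starts <- which(substring(p, seq_len(n - w + 1L),
                            seq_len(n - w + 1L) + w - 1L) == m)
  lapply(starts, function(i) {
    structure(list(subject_id = sid, motif = m, position = i - 1L),
              class = "motif_hit")
  })
}

#' All genome loci matching a nucleotide query
#'
#' Scans every scaffold on both strands and returns every local alignment
#' scoring at least `min_score`, not only the best: on long-read assemblies
#' the same gene may legitimately occur at several loci (segmental
#' duplication), and all of them go to curation. Found hits are masked and
#' the scaffold re-scanned until no qualifying alignment remains.
#'
#' @param query `nuc_sequence` or string.
#' @param genome Named list of `nuc_sequence` records, or named character
#'   vector of scaffold sequences.
#' @param min_score Minimum alignment score to report.
#' @param scoring Scoring list.
#' @param max_hits_per_scaffold Safety cap per scaffold/strand.
#' @return List of `alignment_result`s sorted by score (desc).
#' @export
multi_locus_hits <- function(query, genome, min_score = 60,
                             scoring = default_scoring("nuc"),
                             max_hits_per_scaffold = 10L) {
  stopifnot(length(genome) > 0L)
  qs <- as_seq_string(query)
  qid <- if (is.list(query) && !is.null(query$id)) query$id else "query"
  if (is.list(genome) && inherits(genome[[1L]], "nuc_sequence")) {
    seqs <- vapply(genome, function(r) r$seq, "")
    names(seqs) <- vapply(genome, function(r) r$id, "")
  } else {
    seqs <- toupper(unlist(genome))
  }
  # masking character: scores hugely negative against everything
  mat <- scoring$matrix
  mat <- rbind(cbind(mat, `#` = -1000L), `#` = -1000L)
  rownames(mat)[nrow(mat)] <- "#"
  colnames(mat)[ncol(mat)] <- "#"
  sc <- scoring; sc$matrix <- mat
  hits <- list()
  for (sid in names(seqs)) {
    for (strand in c("+", "-")) {
      subj <- seqs[[sid]]
      q <- if (strand == "+") qs else reverse_complement(qs)
      for (k in seq_len(max_hits_per_scaffold)) {
        raw <- sw_run_masked(q, subj, sc)
        if (raw$score < min_score) break
        res <- make_alignment_result(qid, sid, raw, nchar(qs), nchar(subj),
                                     strand = strand)
        if (strand == "-") {
          # report query span on the query's own forward strand
          res$query_span <- c(nchar(qs) - raw$q_end, nchar(qs) - raw$q_start)
        }
        hits[[length(hits) + 1L]] <- res
        substr(subj, raw$s_start + 1L, raw$s_end) <-
          strrep("#", raw$s_end - raw$s_start)
      }
    }
  }
  ord <- order(vapply(hits, function(h) h$score, 0), decreasing = TRUE)
  hits[ord]
}

sw_run_masked <- function(qseq, sseq, scoring) {
  q <- encode_for(qseq, scoring$matrix, "query")
  s <- encode_for(sseq, scoring$matrix, "subject")
  .sw_align_cpp(q, s, scoring$matrix, scoring$gap_open, scoring$gap_ext,
                qseq, sseq)
}

#' Tabulate alignment results
#'
#' BLAST outfmt-6-like table with query coverage appended.
#'
#' @param hits List of `alignment_result`s.
#' @return A data.frame, one row per hit.
#' @export
hits_table <- function(hits) {
  hits <- hits[!vapply(hits, is.null, TRUE)]
  if (length(hits) == 0L) {
    return(data.frame(query_id = character(), subject_id = character(),
                      identity = numeric(), aligned_cols = integer(),
                      q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      strand = character(), score = numeric(),
                      query_cov = numeric(), stringsAsFactors = FALSE))
  }
  data.frame(
    query_id = vapply(hits, `[[`, "", "query_id"),
    subject_id = vapply(hits, `[[`, "", "subject_id"),
    identity = vapply(hits, `[[`, 0, "identity_frac"),
    aligned_cols = vapply(hits, function(h) as.integer(h$aligned_cols), 0L),
    q_start = vapply(hits, function(h) as.integer(h$query_span[1L]), 0L),
    q_end = vapply(hits, function(h) as.integer(h$query_span[2L]), 0L),
    s_start = vapply(hits, function(h) as.integer(h$subject_span[1L]), 0L),
    s_end = vapply(hits, function(h) as.integer(h$subject_span[2L]), 0L),
    strand = vapply(hits, `[[`, "", "strand"),
    score = vapply(hits, `[[`, 0, "score"),
    query_cov = vapply(hits, `[[`, 0, "query_cov"),
    stringsAsFactors = FALSE
  )
}
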