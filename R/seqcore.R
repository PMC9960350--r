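#' @useDynLib npannotate, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

NUC_ALPHABET <- c("A", "C", "G", "T", "N")
PEP_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                  "M", "F", "P", "S", "T", "W", "Y", "V", "X", "*")

#' Nucleotide sequence record
#'
#' A validated nucleotide sequence over the alphabet `{A,C,G,T,N}`. Input is
#' case-insensitive and stored uppercase. Ambiguity codes other than `N` are
#' rejected: silently coercing them would hide corrupted input, and draft
#' assemblies use plain `ACGTN`.
#'
#' @param id Non-empty identifier string.
#' @param seq Nucleotide string, length >= 1.
#' @return An object of class `nuc_sequence` with fields `id` and `seq`.
#' @examples
#' nuc_sequence("tx1", "atgGCC")
#' @export
nuc_sequence <- function(id, seq) {
  x <- validate_seq(id, seq, NUC_ALPHABET, "nucleotide")
  structure(list(id = id, seq = x), class = "nuc_sequence")
}

#' Peptide sequence record
#'
#' A validated amino-acid sequence over the 20 standard residues plus `X`
#' (unknown) and `*` (stop).
#'
#' @param id Non-empty identifier string.
#' @param seq Amino-acid string, length >= 1.
#' @return An object of class `pep_sequence` with fields `id` and `seq`.
#' @examples
#' pep_sequence("proctolin_mature", "RYLPT")
#' @export
pep_sequence <- function(id, seq) {
  x <- validate_seq(id, seq, PEP_ALPHABET, "peptide")
  structure(list(id = id, seq = x), class = "pep_sequence")
}

validate_seq <- function(id, seq, alphabet, kind) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(seq), length(seq) == 1L)
  x <- toupper(seq)
  if (nchar(x) < 1L) stop("empty ", kind, " sequence for '", id, "'")
  bad <- setdiff(unique(strsplit(x, "", fixed = TRUE)[[1L]]), alphabet)
  if (length(bad) > 0L) {
    stop("invalid ", kind, " characters in '", id, "': ",
         paste(bad, collapse = ", "))
  }
  x
}

as_seq_string <- function(x) {
  if (inherits(x, "nuc_sequence") || inherits(x, "pep_sequence")) x$seq
  else if (is.character(x) && length(x) == 1L) toupper(x)
  else stop("expected a sequence record or a single string")
}

#' Reverse complement
#'
#' @param x A `nuc_sequence` or a plain nucleotide string.
#' @return A string: the reverse complement (`N` maps to `N`).
#' @examples
#' reverse_complement("ATGC")  # "GCAT"
#' @export
reverse_complement <- function(x) {
  s <- as_seq_string(x)
  comp <- chartr("ACGTN", "TGCAN", s)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

# genetic code lookup (standard table), built once from Biostrings
codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- Biostrings::GENETIC_CODE
    tab
  }
})

#' Translate one reading frame
#'
#' Translates a nucleotide sequence in one of the six reading frames using
#' the standard genetic code. Frames `+1..+3` offset into the forward strand;
#' frames `-1..-3` translate the reverse complement with the same offsets.
#' Codons containing `N` translate to `X`; a trailing partial codon is
#' dropped; stops appear as `*`.
#'
#' @param x A `nuc_sequence` or nucleotide string.
#' @param frame Integer in `c(1, 2, 3, -1, -2, -3)`.
#' @return Amino-acid string (possibly containing `*`).
#' @examples
#' translate_frame("ATGGCC", 1)   # "MA"
#' translate_frame("ATGGCC", -1)  # "GH"
#' @export
translate_frame <- function(x, frame) {
  s <- as_seq_string(x)
  if (!frame %in% c(1L, 2L, 3L, -1L, -2L, -3L)) {
    stop("frame must be one of +1,+2,+3,-1,-2,-3")
  }
  if (frame < 0) s <- reverse_complement(s)
  off <- abs(frame) - 1L
  n <- nchar(s) - off
  if (n < 3L) stop("degenerate input: no complete codon in frame ", frame)
  n_codon <- n %/% 3L
  starts <- off + 1L + 3L * (seq_len(n_codon) - 1L)
  codons <- substring(s, starts, starts + 2L)
  tab <- codon_table()
  aa <- unname(tab[codons])
  aa[is.na(aa)] <- "X"  # codons containing N
  paste(aa, collapse = "")
}

#' Longest methionine-started ORF in each of the six frames
#'
#' For each reading frame, reports the longest open reading frame that starts
#' at a methionine and contains no internal stop. Coordinates are 0-based
#' half-open offsets on the forward strand of the input, for all frames.
#' By default an ORF may run to the sequence edge without a terminating stop
#' (draft contigs are frequently truncated); set `require_stop = TRUE` to
#' demand a stop codon.
#'
#' @param x A `nuc_sequence` or nucleotide string.
#' @param min_len Minimum ORF length in residues (>= 1).
#' @param require_stop If `TRUE`, only ORFs ending at a stop codon qualify.
#' @return A list of `orf` records (`frame`, `start`, `end`, `peptide`),
#'   at most one per frame, ordered `+1,+2,+3,-1,-2,-3`; frames with no
#'   qualifying ORF are absent.
#' @examples
#' six_frame_orfs("ATGAAATAG")[[1]]$peptide  # "MK"
#' @export
six_frame_orfs <- function(x, min_len = 1L, require_stop = FALSE) {
  stopifnot(min_len >= 1L)
  s <- as_seq_string(x)
  L <- nchar(s)
  out <- list()
  for (frame in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    if (L - (abs(frame) - 1L) < 3L) next
    aa <- translate_frame(s, frame)
    best <- longest_m_orf(aa, min_len, require_stop)
    if (is.null(best)) next
    off <- abs(frame) - 1L
    # peptide occupies residues [p, p + w) of the frame translation;
    # nucleotide offsets on the translated strand:
    nt_start <- off + 3L * (best$pos - 1L)
    nt_end <- nt_start + 3L * best$len
    if (frame < 0) {
      fwd <- c(L - nt_end, L - nt_start)
    } else {
      fwd <- c(nt_start, nt_end)
    }
    out[[length(out) + 1L]] <- structure(
      list(frame = frame, start = fwd[1L], end = fwd[2L],
           peptide = pep_sequence(sprintf("orf_f%+d", frame), best$pep)),
      class = "orf")
  }
  out
}

# longest M-started stop-free stretch of a frame translation; returns
# 1-based residue position, length, and the peptide, or NULL
longest_m_orf <- function(aa, min_len, require_stop) {
  segs <- strsplit(aa, "*", fixed = TRUE)[[1L]]
  ends_with_stop <- substring(aa, nchar(aa), nchar(aa)) == "*"
  pos0 <- 1L
  best <- NULL
  for (i in seq_along(segs)) {
    seg <- segs[i]
    terminal <- (i == length(segs)) && !ends_with_stop
    if (nchar(seg) > 0L && !(require_stop && terminal)) {
      m <- regexpr("M", seg, fixed = TRUE)
      if (m > 0L) {
        len <- nchar(seg) - m + 1L
        if (len >= min_len && (is.null(best) || len > best$len)) {
          best <- list(pos = pos0 + m - 1L, len = len,
                       pep = substring(seg, m, nchar(seg)))
        }
      }
    }
    pos0 <- pos0 + nchar(seg) + 1L
  }
  best
}

#' Read a FASTA file of nucleotide or peptide sequences
#'
#' @param path FASTA file path.
#' @param type `"nuc"` or `"pep"`.
#' @return Named list of `nuc_sequence`/`pep_sequence` records; names are the
#'   first whitespace-delimited token of each header, the remainder of the
#'   header is kept as the `desc` attribute.
#' @export
read_fasta <- function(path, type = c("nuc", "pep")) {
  type <- match.arg(type)
  set <- if (type == "nuc") {
    Biostrings::readDNAStringSet(path)
  } else {
    Biostrings::readAAStringSet(path)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  recs <- lapply(seq_along(set), function(i) {
    r <- if (type == "nuc") nuc_sequence(ids[i], as.character(set[[i]]))
         else pep_sequence(ids[i], as.character(set[[i]]))
    attr(r, "desc") <- descs[i]
    r
  })
  names(recs) <- ids
  recs
}

#' Write sequences to FASTA (wrapped at 60 columns)
#'
#' @param seqs Named character vector, or list of sequence records.
#' @param path Output path.
#' @param descs Optional character vector of descriptions appended after the
#'   id, one per sequence.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, descs = NULL) {
  if (is.list(seqs)) {
    ids <- vapply(seqs, function(r) r$id, "")
    if (is.null(descs)) {
      descs <- vapply(seqs, function(r) {
        d <- attr(r, "desc")
        if (is.null(d)) "" else d
      }, "")
    }
    seqs <- vapply(seqs, function(r) r$seq, "")
    names(seqs) <- ids
  }
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    hdr <- names(seqs)[i]
    if (!is.null(descs) && nzchar(descs[i])) hdr <- paste(hdr, descs[i])
    writeLines(paste0(">", hdr), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}
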