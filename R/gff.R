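# Minimal deterministic GFF3 reader/writer. Coordinates are 1-based
# inclusive on disk (GFF dialect) and converted to the package's internal
# 0-based half-open convention only by the explicit helpers below.
# Attribute values are kept verbatim (URL escapes preserved); on output the
# ID, Parent and Name attributes come first, the rest alphabetically, which
# makes write(parse(write(x))) byte-identical to write(x).

#' Read a GFF3 file
#'
#' @param path GFF3 file path.
#' @return A `gff` object: data.frame with columns `seqid`, `source`,
#'   `type`, `start`, `end` (1-based inclusive), `score`, `strand`, `phase`
#'   and a list-column `attributes` of named character vectors; pragma
#'   lines are kept in `attr(, "pragmas")`.
#' @export
gff_read <- function(path) {
  lines <- readLines(path)
  gff_parse_lines(lines, path)
}

gff_parse_lines <- function(lines, origin = "<in-memory>") {
  pragmas <- lines[startsWith(lines, "##")]
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  rows <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad) > 0L) {
    stop("malformed GFF line ", rows[bad[1L]], " in ", origin,
         " (expected 9 tab-separated fields)")
  }
  n <- length(fields)
  df <- data.frame(
    seqid = vapply(fields, `[[`, "", 1L),
    source = vapply(fields, `[[`, "", 2L),
    type = vapply(fields, `[[`, "", 3L),
    start = as.integer(vapply(fields, `[[`, "", 4L)),
    end = as.integer(vapply(fields, `[[`, "", 5L)),
    score = vapply(fields, `[[`, "", 6L),
    strand = vapply(fields, `[[`, "", 7L),
    phase = vapply(fields, `[[`, "", 8L),
    stringsAsFactors = FALSE
  )
  if (n > 0L && (anyNA(df$start) || anyNA(df$end))) {
    stop("non-numeric coordinates in ", origin)
  }
  df$attributes <- lapply(fields, function(f) parse_attributes(f[9L]))
  class(df) <- c("gff", "data.frame")
  attr(df, "pragmas") <- if (length(pragmas) > 0L) pragmas else "##gff-version 3"
  df
}

parse_attributes <- function(s) {
  if (!nzchar(s) || s == ".") return(character(0))
  parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
  parts <- parts[nzchar(parts)]
  kv <- regmatches(parts, regexpr("=", parts, fixed = TRUE), invert = TRUE)
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, function(x) if (length(x) > 1L) x[2L] else "", "")
  stats::setNames(vals, keys)
}

format_attributes <- function(at) {
  if (length(at) == 0L) return(".")
  lead <- intersect(c("ID", "Parent", "Name"), names(at))
  rest <- sort(setdiff(names(at), lead))
  ord <- c(lead, rest)
  paste(paste0(ord, "=", at[ord]), collapse = ";")
}

#' Write a GFF3 file
#'
#' @param gff A `gff` object (see [gff_read()]).
#' @param path Output path; when `NULL` the lines are returned instead.
#' @return The written path (or the lines when `path` is `NULL`),
#'   invisibly.
#' @export
gff_write <- function(gff, path = NULL) {
  lines <- c(attr(gff, "pragmas"), gff_format_rows(gff))
  if (is.null(path)) return(invisible(lines))
  writeLines(lines, path)
  invisible(path)
}

gff_format_rows <- function(gff) {
  if (nrow(gff) == 0L) return(character(0))
  vapply(seq_len(nrow(gff)), function(i) {
    paste(gff$seqid[i], gff$source[i], gff$type[i], gff$start[i], gff$end[i],
          gff$score[i], gff$strand[i], gff$phase[i],
          format_attributes(gff$attributes[[i]]), sep = "\t")
  }, "")
}

#' Parse-write round trip of a GFF3 file
#'
#' Normalizes attribute order; a second round trip is byte-identical to the
#' first.
#'
#' @param gff A `gff` object or path to a GFF3 file.
#' @return The re-parsed `gff` object.
#' @export
gff_roundtrip <- function(gff) {
  if (is.character(gff)) gff <- gff_read(gff)
  gff_parse_lines(gff_write(gff, path = NULL))
}

# 0-based half-open -> GFF 1-based inclusive
to_gff_coords <- function(start0, end0) list(start = start0 + 1L, end = end0)
# GFF 1-based inclusive -> 0-based half-open
from_gff_coords <- function(start1, end1) list(start = start1 - 1L, end = end1)

#' Extract spliced-alignment exon tables from a GFF3 file
#'
#' Groups `exon` features by their `Parent` attribute; each group becomes
#' one spliced alignment of a transcript/CDS to the genome.
#'
#' @param gff A `gff` object or GFF3 path.
#' @return Named list of `spliced_alignment`s keyed by Parent ID.
#' @export
gff_spliced_alignments <- function(gff) {
  if (is.character(gff)) gff <- gff_read(gff)
  ex <- gff[gff$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0L) return(list())
  parents <- vapply(ex$attributes, function(a) {
    if ("Parent" %in% names(a)) a[["Parent"]] else NA_character_
  }, "")
  out <- list()
  for (pid in unique(parents[!is.na(parents)])) {
    rows <- ex[which(parents == pid), , drop = FALSE]
    out[[pid]] <- spliced_alignment(
      model_id = pid, scaffold = rows$seqid[1L], strand = rows$strand[1L],
      exons = data.frame(start = rows$start - 1L, end = rows$end,
                         stringsAsFactors = FALSE))
  }
  out
}
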