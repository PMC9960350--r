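# Releasing the augmented annotation: verified models are inserted into the
# draft GFF under newly allocated locus IDs; models without a genomic locus
# are appended to the genome FASTA as new contigs carrying a single-gene
# annotation. Original draft GFF lines are byte-preserved.

#' Locus-ID allocator
#'
#' Allocates release IDs `GBI_30000, GBI_30100, ...` (prefix, start and step
#' configurable; the step-100 series matches the released ID sequence).
#' Allocation refuses IDs already present in the draft annotation.
#'
#' @param start First locus number.
#' @param step Increment between loci.
#' @param prefix ID prefix.
#' @param existing_ids Character vector of IDs already in use.
#' @return An `id_allocator`; call `alloc(a)` for the next ID.
#' @export
id_allocator <- function(start = 30000L, step = 100L, prefix = "GBI_",
                         existing_ids = character(0)) {
  stopifnot(start >= 0L, step >= 1L)
  env <- new.env(parent = emptyenv())
  env$next_locus <- as.integer(start)
  env$step <- as.integer(step)
  env$prefix <- prefix
  env$existing <- unique(existing_ids)
  env$allocated <- character(0)
  structure(env, class = "id_allocator")
}

#' @rdname id_allocator
#' @param a An `id_allocator`.
#' @export
alloc <- function(a) {
  id <- sprintf("%s%05d", a$prefix, a$next_locus)
  if (id %in% a$existing) {
    stop("allocated ID ", id, " collides with an existing draft ID")
  }
  a$next_locus <- a$next_locus + a$step
  a$allocated <- c(a$allocated, id)
  id
}

gff_ids <- function(gff) {
  unlist(lapply(gff$attributes, function(a) {
    if ("ID" %in% names(a)) a[["ID"]] else NULL
  }), use.names = FALSE)
}

#' Merge verified neuropeptide models into the draft annotation
#'
#' Each placed model becomes gene + mRNA + exon + CDS features at its locus
#' under a freshly allocated release ID — unless its span overlaps an
#' existing draft gene on the same strand, in which case it is attached to
#' that gene as a new mRNA isoform (next `-R<letter>` suffix). Each
#' unplaced model becomes a new contig (named after its release ID) holding
#' its full transcript with a single-gene annotation spanning its CDS.
#' Original draft GFF lines are byte-preserved; a provenance comment is
#' appended to the header pragmas.
#'
#' @param draft_gff Path to the draft GFF3 (or a `gff` object).
#' @param draft_fasta Path to the draft genome FASTA (or named character
#'   vector of scaffolds).
#' @param placed,unplaced Lists of `locus_assignment`s from
#'   [classify_models()] (entries carry `$call`).
#' @param allocator An [id_allocator()].
#' @param out_gff,out_fasta Optional output paths; when given the augmented
#'   files are written there.
#' @return List: `gff_lines`, `fasta` (named character vector), `id_map`
#'   (data.frame model_id, released_id, placement).
#' @export
merge_annotation <- function(draft_gff, draft_fasta, placed, unplaced,
                             allocator = id_allocator(),
                             out_gff = NULL, out_fasta = NULL) {
  if (is.character(draft_gff) && length(draft_gff) == 1L &&
      file.exists(draft_gff)) {
    draft_lines <- readLines(draft_gff)
  } else if (inherits(draft_gff, "gff")) {
    draft_lines <- gff_write(draft_gff, path = NULL)
  } else {
    draft_lines <- draft_gff  # raw lines
  }
  gff <- gff_parse_lines(draft_lines)
  if (is.character(draft_fasta) && length(draft_fasta) == 1L &&
      file.exists(draft_fasta)) {
    recs <- read_fasta(draft_fasta, "nuc")
    fasta <- vapply(recs, function(r) r$seq, "")
  } else {
    fasta <- toupper(draft_fasta)
  }
  allocator$existing <- unique(c(allocator$existing, gff_ids(gff)))

  genes <- gff[gff$type == "gene", , drop = FALSE]
  new_lines <- character(0)
  id_map <- data.frame(model_id = character(), released_id = character(),
                       placement = character(), stringsAsFactors = FALSE)

  for (p in placed) {
    if (p$span[2L] > nchar(fasta[[p$scaffold]])) {
      stop("placed span for ", p$model_id, " exceeds scaffold ", p$scaffold)
    }
    host <- overlapping_gene(genes, p)
    if (!is.null(host)) {
      iso_id <- next_isoform_id(gff, host)
      new_lines <- c(new_lines,
                     model_feature_lines(p, gene_id = host, mrna_id = iso_id,
                                         new_gene = FALSE))
      id_map <- rbind(id_map, data.frame(model_id = p$model_id,
                                         released_id = iso_id,
                                         placement = "isoform",
                                         stringsAsFactors = FALSE))
    } else {
      gid <- alloc(allocator)
      new_lines <- c(new_lines,
                     model_feature_lines(p, gene_id = gid,
                                         mrna_id = paste0(gid, "-RA"),
                                         new_gene = TRUE))
      id_map <- rbind(id_map, data.frame(model_id = p$model_id,
                                         released_id = gid,
                                         placement = "placed",
                                         stringsAsFactors = FALSE))
    }
  }
  for (u in unplaced) {
    gid <- alloc(allocator)
    tx <- u$call$model$transcript
    if (is.null(tx)) stop("unplaced model ", u$model_id, " has no transcript")
    contig <- gid
    if (contig %in% names(fasta)) stop("contig name collision: ", contig)
    fasta[[contig]] <- tx$seq
    g <- to_gff_coords(0L, nchar(tx$seq))
    at_gene <- sprintf("ID=%s;Name=%s;note=unplaced neuropeptide contig",
                       gid, u$model_id)
    at_mrna <- sprintf("ID=%s-RA;Parent=%s;Name=%s", gid, gid, u$model_id)
    new_lines <- c(new_lines,
      paste(contig, "npannotate", "gene", g$start, g$end, ".", "+", ".",
            at_gene, sep = "\t"),
      paste(contig, "npannotate", "mRNA", g$start, g$end, ".", "+", ".",
            at_mrna, sep = "\t"),
      paste(contig, "npannotate", "exon", g$start, g$end, ".", "+", ".",
            sprintf("ID=%s-RA.exon1;Parent=%s-RA", gid, gid), sep = "\t"))
    id_map <- rbind(id_map, data.frame(model_id = u$model_id,
                                       released_id = gid,
                                       placement = "unplaced-contig",
                                       stringsAsFactors = FALSE))
  }

  header_at <- which(startsWith(draft_lines, "##"))
  lead <- header_at[header_at == seq_along(header_at)]  # leading pragma block
  note <- "## npannotate: neuropeptide annotations appended"
  if (length(lead) > 0L) {
    gff_lines <- append(draft_lines, note, after = max(lead))
  } else {
    gff_lines <- c("##gff-version 3", note, draft_lines)
  }
  gff_lines <- c(gff_lines, new_lines)

  if (!is.null(out_gff)) writeLines(gff_lines, out_gff)
  if (!is.null(out_fasta)) write_fasta(fasta, out_fasta)
  list(gff_lines = gff_lines, fasta = fasta, id_map = id_map)
}

overlapping_gene <- function(genes, p) {
  if (nrow(genes) == 0L) return(NULL)
  g <- to_gff_coords(p$span[1L], p$span[2L])
  hit <- which(genes$seqid == p$scaffold & genes$strand == p$strand &
               genes$start <= g$end & genes$end >= g$start)
  if (length(hit) == 0L) return(NULL)
  at <- genes$attributes[[hit[1L]]]
  if ("ID" %in% names(at)) at[["ID"]] else NULL
}

next_isoform_id <- function(gff, gene_id) {
  mrnas <- gff[gff$type == "mRNA", , drop = FALSE]
  existing <- unlist(lapply(mrnas$attributes, function(a) {
    if ("Parent" %in% names(a) && a[["Parent"]] == gene_id &&
        "ID" %in% names(a)) a[["ID"]] else NULL
  }))
  n <- length(existing)
  paste0(gene_id, "-R", LETTERS[n + 1L])
}

model_feature_lines <- function(p, gene_id, mrna_id, new_gene) {
  call <- p$call
  exons <- if (!is.null(p$exons)) p$exons else
    data.frame(start = p$span[1L], end = p$span[2L])
  g <- to_gff_coords(p$span[1L], p$span[2L])
  lines <- character(0)
  if (new_gene) {
    lines <- c(lines, paste(
      p$scaffold, "npannotate", "gene", g$start, g$end, ".", p$strand, ".",
      sprintf("ID=%s;Name=%s", gene_id, call$neuropeptide_name), sep = "\t"))
  }
  lines <- c(lines, paste(
    p$scaffold, "npannotate", "mRNA", g$start, g$end, ".", p$strand, ".",
    sprintf("ID=%s;Parent=%s;Name=%s;note=model %s criterion %s",
            mrna_id, gene_id, call$neuropeptide_name,
            call$model$model_id, call$criterion), sep = "\t"))
  phase_len <- 0L
  ord <- if (p$strand == "-") rev(seq_len(nrow(exons))) else seq_len(nrow(exons))
  k <- 0L
  for (i in ord) {
    k <- k + 1L
    e <- to_gff_coords(exons$start[i], exons$end[i])
    lines <- c(lines, paste(
      p$scaffold, "npannotate", "exon", e$start, e$end, ".", p$strand, ".",
      sprintf("ID=%s.exon%d;Parent=%s", mrna_id, k, mrna_id), sep = "\t"))
    phase <- (3L - phase_len %% 3L) %% 3L
    lines <- c(lines, paste(
      p$scaffold, "npannotate", "CDS", e$start, e$end, ".", p$strand, phase,
      sprintf("ID=%s.cds;Parent=%s", mrna_id, mrna_id), sep = "\t"))
    phase_len <- phase_len + (exons$end[i] - exons$start[i])
  }
  lines
}
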