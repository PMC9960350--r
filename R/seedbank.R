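# Registry of reference ("seed") neuropeptide sequences and their
# qualification status. A neuropeptide qualifies as a seed when at least one
# of a mature peptide, a precursor protein, or a cDNA is available; panel
# members with none are carried as explicit NO_SEED entries and fall back to
# other-species precursor search.

#' Seed record for one neuropeptide
#'
#' @param neuropeptide_name Canonical name, e.g. `"Proctolin"`.
#' @param mature_peptides List of `pep_sequence`s (possibly empty).
#' @param precursor Optional `pep_sequence`.
#' @param cdna Optional `nuc_sequence`.
#' @param provenance_tier `"SAME_SPECIES"` or `"OTHER_SPECIES"`. Seeds from
#'   other species use the relaxed 50% precursor-coverage selection rule.
#' @param source_citation Free-text provenance.
#' @return A `seed_record`.
#' @export
seed_record <- function(neuropeptide_name, mature_peptides = list(),
                        precursor = NULL, cdna = NULL,
                        provenance_tier = c("SAME_SPECIES", "OTHER_SPECIES"),
                        source_citation = "") {
  provenance_tier <- match.arg(provenance_tier)
  stopifnot(nzchar(neuropeptide_name))
  if (is.character(mature_peptides)) {
    mature_peptides <- lapply(seq_along(mature_peptides), function(i) {
      pep_sequence(sprintf("%s_mature%d", neuropeptide_name, i),
                   mature_peptides[i])
    })
  }
  structure(list(neuropeptide_name = neuropeptide_name,
                 mature_peptides = mature_peptides,
                 precursor = precursor, cdna = cdna,
                 provenance_tier = provenance_tier,
                 source_citation = source_citation),
            class = "seed_record")
}

seed_qualified <- function(seed) {
  length(seed$mature_peptides) > 0L || !is.null(seed$precursor) ||
    !is.null(seed$cdna)
}

#' Load a seed registry from FASTA files and a panel table
#'
#' Sequence roles are encoded in the FASTA description as
#' `role=mature|precursor|cdna` and records are tied to panel names by a
#' `name=<panel name>` tag. The panel table (TSV: columns `name`, `tier`,
#' `citation`) fixes the ordered list of neuropeptides under search; panel
#' members for which no sequence record exists are marked `NO_SEED`.
#'
#' @param seed_fasta_paths Character vector of FASTA paths. Nucleotide
#'   records (`role=cdna`) and peptide records may be mixed across files;
#'   each file must be alphabet-homogeneous and is auto-detected.
#' @param panel_table Path to the panel TSV, or a data.frame.
#' @return A `seed_registry`: `records` (named list of `seed_record`s),
#'   `target_panel` (ordered names), `no_seed` (names lacking sequences).
#' @export
load_registry <- function(seed_fasta_paths, panel_table) {
  panel <- if (is.data.frame(panel_table)) panel_table
           else utils::read.delim(panel_table, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "tier") %in% names(panel)))
  if (anyDuplicated(panel$name)) {
    stop("duplicate panel names: ",
         paste(unique(panel$name[duplicated(panel$name)]), collapse = ", "))
  }
  if (is.null(panel$citation)) panel$citation <- rep("", nrow(panel))
  recs <- list()
  for (path in seed_fasta_paths) {
    type <- sniff_fasta_type(path)
    for (rec in read_fasta(path, type)) {
      desc <- attr(rec, "desc")
      role <- desc_tag(desc, "role")
      nm <- desc_tag(desc, "name")
      if (is.na(role) || !role %in% c("mature", "precursor", "cdna")) {
        stop("unknown or missing role tag for '", rec$id, "' in ", path)
      }
      if (is.na(nm)) stop("missing name tag for '", rec$id, "' in ", path)
      if (!nm %in% panel$name) {
        stop("seed '", rec$id, "' names unknown neuropeptide '", nm, "'")
      }
      recs[[nm]] <- c(recs[[nm]], list(list(role = role, rec = rec)))
    }
  }
  records <- list()
  no_seed <- character(0)
  for (i in seq_len(nrow(panel))) {
    nm <- panel$name[i]
    tier <- toupper(panel$tier[i])
    stopifnot(tier %in% c("SAME_SPECIES", "OTHER_SPECIES"))
    parts <- recs[[nm]]
    if (is.null(parts)) {
      no_seed <- c(no_seed, nm)
      next
    }
    mats <- lapply(Filter(function(p) p$role == "mature", parts),
                   function(p) p$rec)
    precs <- Filter(function(p) p$role == "precursor", parts)
    cdnas <- Filter(function(p) p$role == "cdna", parts)
    records[[nm]] <- seed_record(
      neuropeptide_name = nm,
      mature_peptides = mats,
      precursor = if (length(precs) > 0L) precs[[1L]]$rec else NULL,
      cdna = if (length(cdnas) > 0L) cdnas[[1L]]$rec else NULL,
      provenance_tier = tier,
      source_citation = panel$citation[i])
  }
  structure(list(records = records, target_panel = panel$name,
                 no_seed = no_seed, panel = panel),
            class = "seed_registry")
}

# `name=` captures to end of line so panel names may contain spaces;
# it must therefore be the last tag on the header line
desc_tag <- function(desc, tag) {
  if (is.null(desc) || !nzchar(desc)) return(NA_character_)
  pat <- if (tag == "name") "\\bname=(.+)$" else paste0("\\b", tag, "=([^ ]+)")
  m <- regmatches(desc, regexec(pat, desc))[[1L]]
  if (length(m) < 2L) NA_character_ else trimws(m[2L])
}

sniff_fasta_type <- function(path) {
  lines <- readLines(path, n = 50L)
  body <- toupper(paste(lines[!startsWith(lines, ">")], collapse = ""))
  chars <- unique(strsplit(body, "", fixed = TRUE)[[1L]])
  if (all(chars %in% c("A", "C", "G", "T", "N"))) "nuc" else "pep"
}

#' Selection rules applicable to a seed
#'
#' Same-species seeds activate one rule per available role: exact mature
#' match, precursor alignment coverage >= 0.70, cDNA coverage >= 0.60.
#' Other-species seeds activate only precursor coverage >= 0.50.
#'
#' @param seed A qualified `seed_record`.
#' @param thresholds Named list overriding `precursor_cov` (0.70),
#'   `cdna_cov` (0.60), `other_species_cov` (0.50).
#' @return A list: `rule_names` (subset of `mature_exact`, `precursor`,
#'   `cdna`), `precursor_cov`, `cdna_cov` (NA when the rule is inactive).
#' @export
effective_rule <- function(seed, thresholds = list()) {
  if (!seed_qualified(seed)) {
    stop("no selection rule for NO_SEED neuropeptide '",
         seed$neuropeptide_name, "'")
  }
  thr <- utils::modifyList(list(precursor_cov = 0.70, cdna_cov = 0.60,
                                other_species_cov = 0.50), thresholds)
  if (seed$provenance_tier == "OTHER_SPECIES") {
    return(list(rule_names = "precursor",
                precursor_cov = thr$other_species_cov, cdna_cov = NA_real_))
  }
  rules <- character(0)
  if (length(seed$mature_peptides) > 0L) rules <- c(rules, "mature_exact")
  pc <- NA_real_; cc <- NA_real_
  if (!is.null(seed$precursor)) { rules <- c(rules, "precursor"); pc <- thr$precursor_cov }
  if (!is.null(seed$cdna)) { rules <- c(rules, "cdna"); cc <- thr$cdna_cov }
  list(rule_names = rules, precursor_cov = pc, cdna_cov = cc)
}

#' Serialize / restore a seed registry
#'
#' Writes the registry to a directory as one peptide FASTA, one nucleotide
#' FASTA and the panel TSV; [load_registry()] on those files restores it.
#'
#' @param registry A `seed_registry`.
#' @param dir Output directory (created if needed).
#' @return Invisible list of written paths (`pep`, `nuc`, `panel`); elements
#'   are omitted when there was nothing to write.
#' @export
write_registry <- function(registry, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  peps <- character(0); pdesc <- character(0)
  nucs <- character(0); ndesc <- character(0)
  for (seed in registry$records) {
    nm <- seed$neuropeptide_name
    for (m in seed$mature_peptides) {
      peps[m$id] <- m$seq
      pdesc <- c(pdesc, sprintf("role=mature name=%s", nm))
    }
    if (!is.null(seed$precursor)) {
      peps[seed$precursor$id] <- seed$precursor$seq
      pdesc <- c(pdesc, sprintf("role=precursor name=%s", nm))
    }
    if (!is.null(seed$cdna)) {
      nucs[seed$cdna$id] <- seed$cdna$seq
      ndesc <- c(ndesc, sprintf("role=cdna name=%s", nm))
    }
  }
  out <- list()
  if (length(peps) > 0L) {
    out$pep <- file.path(dir, "seeds_pep.fasta")
    write_fasta(peps, out$pep, descs = pdesc)
  }
  if (length(nucs) > 0L) {
    out$nuc <- file.path(dir, "seeds_cdna.fasta")
    write_fasta(nucs, out$nuc, descs = ndesc)
  }
  out$panel <- file.path(dir, "panel.tsv")
  utils::write.table(registry$panel, out$panel, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}
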