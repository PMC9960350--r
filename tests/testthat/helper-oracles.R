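# Independent oracles, deliberately implemented apart from the package:
# Biostrings-based translation, exhaustive ORF enumeration, a pure-R
# dynamic-programming local aligner (score only), and a naive agglomerative
# complete-linkage clusterer.

oracle_revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

oracle_translate <- function(s, frame) {
  if (frame < 0) s <- oracle_revcomp(s)
  off <- abs(frame) - 1L
  s <- substring(s, off + 1L, nchar(s))
  s <- substring(s, 1L, (nchar(s) %/% 3L) * 3L)
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     no.init.codon = TRUE,
                                     if.fuzzy.codon = "X"))
}

# every M...(stop|end) substring in every frame; longest per frame
oracle_orfs <- function(s, min_len = 1L, require_stop = FALSE) {
  out <- list()
  for (frame in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    if (nchar(s) - (abs(frame) - 1L) < 3L) next
    aa <- oracle_translate(s, frame)
    ch <- strsplit(aa, "", fixed = TRUE)[[1L]]
    best <- NULL
    for (i in which(ch == "M")) {
      j <- i
      while (j <= length(ch) && ch[j] != "*") j <- j + 1L
      terminated <- j <= length(ch)
      if (require_stop && !terminated) next
      pep <- paste(ch[i:(j - 1L)], collapse = "")
      if (nchar(pep) >= min_len &&
          (is.null(best) || nchar(pep) > nchar(best))) best <- pep
    }
    if (!is.null(best)) out[[as.character(frame)]] <- best
  }
  out
}

# pure-R affine-gap Smith-Waterman, score only (gap of length k costs
# open + k * ext)
oracle_sw_score <- function(q, s, mat, open, ext) {
  qc <- strsplit(q, "", fixed = TRUE)[[1L]]
  sc <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(qc); m <- length(sc)
  NEG <- -1e18
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(NEG, n + 1L, m + 1L)
  F_ <- matrix(NEG, n + 1L, m + 1L)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1L, j + 1L] <- max(H[i + 1L, j] - (open + ext),
                               E[i + 1L, j] - ext)
      F_[i + 1L, j + 1L] <- max(H[i, j + 1L] - (open + ext),
                                F_[i, j + 1L] - ext)
      h <- max(0,
               H[i, j] + mat[qc[i], sc[j]],
               E[i + 1L, j + 1L],
               F_[i + 1L, j + 1L])
      H[i + 1L, j + 1L] <- h
      if (h > best) best <- h
    }
  }
  best
}

# naive agglomerative complete-linkage clustering cut at k clusters
oracle_complete_linkage <- function(z, k) {
  n <- nrow(z)
  d <- as.matrix(stats::dist(z))
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq(i + 1L, length(clusters))) {
        dd <- max(d[clusters[[i]], clusters[[j]]])
        if (dd < bestd) { bestd <- dd; best <- c(i, j) }
      }
    }
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  labels <- integer(n)
  for (i in seq_along(clusters)) labels[clusters[[i]]] <- i
  labels
}

# partitions equal up to label renaming
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
random_pep <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"), n, TRUE),
        collapse = "")
}

blosum62_test <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env(); utils::data("BLOSUM62", package = "Biostrings",
                                  envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

nuc_mat_test <- function() {
  ab <- c("A", "C", "G", "T", "N")
  m <- matrix(-3L, 5, 5, dimnames = list(ab, ab))
  diag(m) <- 2L
  m["N", "N"] <- -3L
  m
}
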