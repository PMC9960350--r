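# Expression-based validation of annotated neuropeptides: per-transcript
# z-score normalisation of TPM values, exclusion of transcripts that are
# zero across all samples, and hierarchical clustering of the normalised
# profiles into expression patterns.

#' Construct / read an expression matrix
#'
#' @param tpm Numeric matrix (transcripts x samples) with dimnames, or a
#'   path to a TSV whose first column is the transcript ID and whose header
#'   row holds sample labels.
#' @return An `expression_matrix` (the validated numeric matrix).
#' @export
expression_matrix <- function(tpm) {
  if (is.character(tpm) && length(tpm) == 1L) {
    df <- utils::read.delim(tpm, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    tpm <- m
  }
  stopifnot(is.matrix(tpm), is.numeric(tpm))
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  if (is.null(rownames(tpm)) || is.null(colnames(tpm))) {
    stop("expression matrix needs transcript and sample names")
  }
  if (anyDuplicated(colnames(tpm))) stop("duplicate sample labels")
  structure(tpm, class = c("expression_matrix", class(tpm)))
}

#' Row-wise z-score normalisation with all-zero exclusion
#'
#' Transcripts whose TPM is zero in every sample are excluded (they cannot
#' be scaled and would distort the heatmap); rows that are constant but
#' non-zero are likewise excluded under the zero-variance guard. The
#' remaining rows are centred and scaled. By convention the population
#' standard deviation (denominator `n`) is used, matching common heatmap
#' z-scoring; `sd_type = "sample"` switches to `n - 1`.
#'
#' @param m An [expression_matrix()] (or coercible input).
#' @param sd_type `"population"` or `"sample"`.
#' @return A `validation_report`: `zmatrix`, `retained`,
#'   `dropped_all_zero`, `dropped_constant`.
#' @export
zscore_rows <- function(m, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (!inherits(m, "expression_matrix")) m <- expression_matrix(m)
  if (ncol(m) < 2L) stop("z-score undefined with a single sample")
  all_zero <- rownames(m)[rowSums(m != 0) == 0L]
  mu <- rowMeans(m)
  n <- ncol(m)
  ss <- rowSums((m - mu)^2)
  sdv <- if (sd_type == "population") sqrt(ss / n) else sqrt(ss / (n - 1L))
  constant <- setdiff(rownames(m)[sdv == 0], all_zero)
  retained <- setdiff(rownames(m), c(all_zero, constant))
  z <- (m[retained, , drop = FALSE] - mu[retained]) / sdv[retained]
  structure(list(zmatrix = z, retained = retained,
                 dropped_all_zero = all_zero, dropped_constant = constant,
                 clusters = NULL, n_patterns = NA_integer_),
            class = "validation_report")
}

#' Cluster z-scored expression profiles into patterns
#'
#' Complete-linkage hierarchical clustering on Euclidean distances between
#' z-scored rows, cut at `k` clusters. Deterministic given the input order.
#' The default `k = 3` reflects the coarse developmental patterns typically
#' distinguished (early-high, steadily increasing, late spike).
#'
#' @param report A `validation_report` from [zscore_rows()] (or a plain
#'   z-matrix).
#' @param k Target number of clusters.
#' @return The report with `clusters` (named integer vector, cluster labels
#'   renumbered in order of first appearance), `n_patterns = k`, and the
#'   `hclust` object as `attr(, "hclust")`; a bare matrix input returns the
#'   label vector.
#' @export
cluster_patterns <- function(report, k = 3L) {
  z <- if (inherits(report, "validation_report")) report$zmatrix else report
  stopifnot(is.matrix(z))
  if (k > nrow(z)) stop("k = ", k, " exceeds the ", nrow(z), " rows available")
  hc <- stats::hclust(stats::dist(z, method = "euclidean"),
                      method = "complete")
  raw <- stats::cutree(hc, k = k)
  labels <- match(raw, unique(raw[hc$order]))  # stable label order
  names(labels) <- rownames(z)
  if (!inherits(report, "validation_report")) return(labels)
  report$clusters <- labels
  report$n_patterns <- as.integer(k)
  attr(report, "hclust") <- hc
  report
}

#' Export the validation heatmap and its underlying table
#'
#' Writes a TSV of z-values ordered by cluster (then dendrogram order), and
#' optionally renders a heatmap image through pheatmap when that package is
#' available. Dropped transcripts never appear in either output.
#'
#' @param report A clustered `validation_report`.
#' @param tsv Output TSV path.
#' @param image Optional PNG path; ignored (with a message) when pheatmap
#'   is not installed.
#' @return Invisible list of written paths.
#' @export
heatmap_export <- function(report, tsv, image = NULL) {
  stopifnot(inherits(report, "validation_report"))
  if (length(report$retained) == 0L) stop("no retained transcripts")
  z <- report$zmatrix
  if (is.null(report$clusters)) report <- cluster_patterns(report)
  hc <- attr(report, "hclust")
  ord <- hc$order
  ord <- ord[order(report$clusters[ord], seq_along(ord))]  # cluster blocks
  z_ord <- z[ord, , drop = FALSE]
  df <- data.frame(transcript = rownames(z_ord),
                   cluster = unname(report$clusters[ord]),
                   z_ord, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- list(tsv = tsv)
  if (!is.null(image)) {
    if (requireNamespace("pheatmap", quietly = TRUE)) {
      grDevices::png(image, width = 800, height = 200 + 18 * nrow(z_ord))
      on.exit(grDevices::dev.off())
      pheatmap::pheatmap(z_ord, cluster_rows = FALSE, cluster_cols = FALSE,
                         main = "neuropeptide expression (z-scored TPM)")
      out$image <- image
    } else {
      message("pheatmap not installed; skipping image rendering")
    }
  }
  invisible(out)
}
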