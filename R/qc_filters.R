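## per-cell quality metrics, fixed-threshold filtering, division marker
## derivation and incongruent-gene scoring

#' Fixed quality-control thresholds
#'
#' Defaults follow the outlier cutoffs established for MERSCOPE somata:
#' at least 6 genes and 30 transcripts per soma, and fewer than 2% blank
#' barcodes. No volume floor is applied (the 3D segmentation's volume
#' distribution shows no clear lower threshold) and no upper transcript
#' cutoff (superseded by dedicated doublet detection).
#'
#' @param min_genes,min_transcripts,max_blank_fraction thresholds.
#' @return a list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 6, min_transcripts = 30,
                          max_blank_fraction = 0.02) {
  stopifnot(min_genes >= 0, min_transcripts >= 0, max_blank_fraction >= 0)
  structure(list(min_genes = min_genes, min_transcripts = min_transcripts,
                 max_blank_fraction = max_blank_fraction),
            class = "qc_thresholds")
}

#' Per-cell quality metrics
#'
#' @param m a [cell_matrix].
#' @param blanks per-cell blank counts; defaults to `cell_meta$n_blank`.
#' @return data.frame (one row per cell): `n_genes`, `n_transcripts`
#'   (both non-blank), `blank_fraction` = blanks / (blanks + non-blank),
#'   `density` = transcripts per um^3 (`NA` where volume is zero or
#'   unknown).
#' @export
compute_cell_metrics <- function(m, blanks = NULL) {
  if (is.null(blanks)) blanks <- m$cell_meta$n_blank %||% rep(0L, nrow(m$counts))
  n_tx <- as.integer(rowSums(m$counts))
  n_genes <- as.integer(rowSums(m$counts > 0))
  tot <- blanks + n_tx
  bf <- ifelse(tot > 0, blanks / tot, 0)
  vol <- m$cell_meta$volume_um3 %||% rep(NA_real_, nrow(m$counts))
  dens <- ifelse(!is.na(vol) & vol > 0, n_tx / vol, NA_real_)
  data.frame(cell_id = m$cell_meta$production_cell_id,
             n_genes = n_genes, n_transcripts = n_tx,
             blank_fraction = bf, density = dens,
             stringsAsFactors = FALSE)
}

#' Apply the fixed quality filter
#'
#' A cell is removed iff `n_genes < min_genes` OR
#' `n_transcripts < min_transcripts` OR
#' `blank_fraction >= max_blank_fraction`.
#'
#' @param metrics data.frame from [compute_cell_metrics()].
#' @param t a [qc_thresholds] object.
#' @return logical keep mask in cell order.
#' @export
apply_quality_filter <- function(metrics, t = qc_thresholds()) {
  !(metrics$n_genes < t$min_genes |
    metrics$n_transcripts < t$min_transcripts |
    metrics$blank_fraction >= t$max_blank_fraction)
}

## Wilcoxon rank-sum z-statistic of group vs rest for every gene
## (observations are the rows of the matrix, e.g. cluster medians)
rank_sum_z <- function(mat, in_group) {
  n1 <- sum(in_group); n2 <- sum(!in_group); n <- n1 + n2
  vapply(seq_len(ncol(mat)), function(j) {
    r <- rank(mat[, j])
    W <- sum(r[in_group]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    ties <- table(mat[, j])
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) return(0)
    (W - mu) / sqrt(sig2)
  }, 0)
}

#' Derive division-level marker genes from cluster medians
#'
#' One-vs-rest Wilcoxon rank-sum statistics are computed per gene for
#' every division, with clusters (rows of the median matrix) as the
#' observations, and the `top_n` genes by statistic (ties broken by gene
#' name) are reported per division.
#'
#' @param cluster_medians cluster x gene numeric matrix (rownames =
#'   clusters, colnames = genes).
#' @param division_of named character vector mapping cluster -> division.
#' @param top_n markers per division (default 10).
#' @return named list: division -> character vector of marker genes.
#' @export
derive_division_markers <- function(cluster_medians, division_of,
                                    top_n = 10L) {
  divs <- unique(division_of[rownames(cluster_medians)])
  if (length(divs) < 2L)
    stop_merscape("need at least two divisions",
                  class = "merscape_config_error")
  if (top_n > ncol(cluster_medians)) {
    warning("top_n exceeds gene panel size; returning all genes per division")
    top_n <- ncol(cluster_medians)
  }
  genes <- colnames(cluster_medians)
  out <- lapply(divs, function(dv) {
    z <- rank_sum_z(cluster_medians,
                    division_of[rownames(cluster_medians)] == dv)
    ord <- order(-z, genes)
    genes[ord][seq_len(top_n)]
  })
  names(out) <- divs
  out
}

#' Enumerate incongruent gene pairs across divisions
#'
#' Pairs every marker of one division with every marker of a different
#' division (mutually exclusive expression expected within a cell); an
#' optional allowlist removes pairs known to co-occur legitimately.
#'
#' @param markers named list from [derive_division_markers()].
#' @param allow data.frame with columns `gene1`, `gene2` of allowed
#'   co-occurrences (optional).
#' @return data.frame of class `incongruent_pairs`: `gene_a`, `gene_b`,
#'   `division_a`, `division_b` (unordered pairs, `division_a !=
#'   division_b`).
#' @export
incongruent_pairs <- function(markers, allow = NULL) {
  divs <- names(markers)
  rows <- list()
  for (i in seq_along(divs)) for (j in seq_along(divs)) {
    if (j <= i) next
    g <- expand.grid(gene_a = markers[[i]], gene_b = markers[[j]],
                     stringsAsFactors = FALSE)
    g <- g[g$gene_a != g$gene_b, , drop = FALSE]
    if (nrow(g)) {
      g$division_a <- divs[i]; g$division_b <- divs[j]
      rows[[length(rows) + 1L]] <- g
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(0), gene_b = character(0),
               division_a = character(0), division_b = character(0))
  if (!is.null(allow) && nrow(out)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    out <- out[!(key(out$gene_a, out$gene_b) %in%
                 key(allow$gene1, allow$gene2)), , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("incongruent_pairs", "data.frame")
  out
}

#' Incongruent-transcript percentage per cell
#'
#' For a cell labelled with division D, incongruent transcripts are
#' counts of genes that are markers of a different division and appear
#' in an incongruent pair against a D marker. The score is that count as
#' a percentage of the cell's total non-blank transcripts. Unlabelled or
#' zero-transcript cells return `NA`.
#'
#' @param m a [cell_matrix].
#' @param pairs an [incongruent_pairs] table.
#' @param division_label character vector, one division per cell.
#' @return numeric percentage per cell.
#' @export
incongruent_fraction <- function(m, pairs, division_label) {
  tot <- rowSums(m$counts)
  genes <- colnames(m$counts)
  out <- rep(NA_real_, nrow(m$counts))
  for (dv in unique(division_label)) {
    if (is.na(dv)) next
    ## genes paired against a marker of dv but belonging to another division
    foreign <- unique(c(pairs$gene_b[pairs$division_a == dv],
                        pairs$gene_a[pairs$division_b == dv]))
    foreign <- intersect(foreign, genes)
    sel <- which(!is.na(division_label) & division_label == dv)
    inc <- if (length(foreign))
      rowSums(m$counts[sel, foreign, drop = FALSE]) else rep(0, length(sel))
    out[sel] <- ifelse(tot[sel] > 0, 100 * inc / tot[sel], NA_real_)
  }
  out
}
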