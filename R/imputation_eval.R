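## imputation-accuracy scoring: COVET niche covariance representation
## and a multiscale structural similarity index over coarsened spatial
## kNN graphs (no cell-to-cell matching required)

#' COVET niche covariance per cell
#'
#' The niche of a cell is its `k` nearest spatial neighbours (excluding
#' the cell itself); it is summarized as the gene-gene shifted
#' covariance `mean_j (e_j - e_bar)(e_j - e_bar)^T` where `e_bar` is the
#' global dataset mean expression. The shift makes niches directly
#' comparable across the dataset.
#'
#' @param coords n x 2 (or 3) matrix of cell positions in um.
#' @param expr n x g expression matrix.
#' @param k niche size (default 8).
#' @param exclude_self drop the focal cell from its own niche (default
#'   TRUE, the COVET convention).
#' @return list of n symmetric g x g matrices.
#' @export
covet_niche <- function(coords, expr, k = 8L, exclude_self = TRUE) {
  coords <- as.matrix(coords); expr <- as.matrix(expr)
  n <- nrow(coords)
  if (n < k + 1L)
    stop_merscape("need at least k+1 cells", class = "merscape_config_error")
  e_bar <- colMeans(expr)
  nn <- FNN::get.knn(coords, k = if (exclude_self) k else k - 1L)$nn.index
  lapply(seq_len(n), function(i) {
    nbr <- if (exclude_self) nn[i, ] else c(i, nn[i, ])
    dev <- sweep(expr[nbr, , drop = FALSE], 2L, e_bar)
    crossprod(dev) / length(nbr)
  })
}

#' Coarsen a spatial graph by heavy-edge matching
#'
#' Greedy matching in node-index order: each unmatched node pairs with
#' its lowest-index unmatched neighbour; unmatched leftovers become
#' singleton supernodes. Pooled values are the mean over pooled members
#' and supernodes inherit the union of member adjacencies, so node
#' counts shrink to about `ceiling(n / 2)` per application (exactly so
#' when a perfect matching exists).
#'
#' @param graph an [igraph::graph].
#' @param values numeric per-node values.
#' @param coords optional per-node coordinates, pooled by mean too.
#' @return list(`graph` coarsened graph, `values`, `coords`,
#'   `membership` old-node -> supernode pooling operator).
#' @export
coarsen_graph <- function(graph, values, coords = NULL) {
  n <- igraph::vcount(graph)
  if (n == 0L)
    return(list(graph = graph, values = numeric(0), coords = coords,
                membership = integer(0)))
  adj <- igraph::as_adj_list(graph)
  match_of <- integer(n)  # 0 = unmatched
  grp <- 0L
  membership <- integer(n)
  for (i in seq_len(n)) {
    if (membership[i] != 0L) next
    grp <- grp + 1L
    membership[i] <- grp
    nbrs <- sort(as.integer(adj[[i]]))
    nbrs <- nbrs[membership[nbrs] == 0L & nbrs != i]
    if (length(nbrs)) membership[nbrs[1L]] <- grp
  }
  new_g <- igraph::simplify(igraph::contract(graph, membership))
  pooled <- as.numeric(tapply(values, membership, mean))
  new_coords <- if (!is.null(coords)) {
    cm <- apply(as.matrix(coords), 2L, function(cl) tapply(cl, membership, mean))
    matrix(cm, nrow = grp)
  } else NULL
  list(graph = new_g, values = pooled, coords = new_coords,
       membership = membership)
}

## 64-bin normalized histogram over a fixed range
norm_hist <- function(v, lo, hi, bins = 64L) {
  if (hi <= lo) return(c(1, rep(0, bins - 1L)))
  idx <- pmin(bins, 1L + floor((v - lo) / (hi - lo) * bins))
  tabulate(idx, nbins = bins) / length(v)
}

safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(if (isTRUE(all.equal(a, b))) 1 else 0)
  stats::cor(a, b)
}

#' Multiscale structural similarity of two spatial expression patterns
#'
#' Builds an independent `k = 8` spatial kNN graph per dataset (no cell
#' matching required; the datasets may differ in size and coordinates),
#' and compares the two value distributions at the original scale plus
#' `n_scales` graph coarsenings (each preceded by a one-step
#' neighbourhood blur). At each scale the luminance
#' `l = (2 mu_r mu_q + C1) / (mu_r^2 + mu_q^2 + C1)`, contrast
#' `c = (2 sd_r sd_q + C2) / (sd_r^2 + sd_q^2 + C2)` and structure
#' `s = cor(hist_r, hist_q)` (64-bin normalized histograms over the
#' pooled range) are multiplied; the final score is the mean over
#' scales. `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` with `L` the pooled
#' dynamic range of both datasets, which keeps the score symmetric.
#'
#' @param ref_coords,ref_values reference dataset: n x 2 coordinates and
#'   per-cell expression of one gene.
#' @param query_coords,query_values query dataset (possibly imputed).
#' @param k spatial neighbours (default 8).
#' @param n_scales coarsening steps beyond the original (default 4).
#' @return list of class `mssi_result`: `score`, `per_scale` data.frame
#'   (`scale`, `luminance`, `contrast`, `structure`, `score`,
#'   `n_ref`, `n_query`).
#' @export
mssi_score <- function(ref_coords, ref_values, query_coords, query_values,
                       k = 8L, n_scales = 4L) {
  prep <- function(coords, values) {
    coords <- as.matrix(coords)
    if (nrow(coords) < k + 1L)
      stop_merscape("each dataset needs at least k+1 cells",
                    class = "merscape_config_error")
    list(g = knn_graph(coords, k = k), v = as.numeric(values),
         xy = coords)
  }
  r <- prep(ref_coords, ref_values)
  q <- prep(query_coords, query_values)
  L <- max(c(r$v, q$v)) - min(c(r$v, q$v))
  if (L <= 0) L <- 1
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  blur <- function(s) {
    adj <- igraph::as_adj_list(s$g)
    s$v <- vapply(seq_along(s$v), function(i)
      mean(s$v[c(i, as.integer(adj[[i]]))]), 0)
    s
  }
  rows <- list()
  for (sc in 0:n_scales) {
    if (sc > 0L) {
      r <- blur(r); q <- blur(q)
      cr <- coarsen_graph(r$g, r$v, r$xy)
      r <- list(g = cr$graph, v = cr$values, xy = cr$coords)
      cq <- coarsen_graph(q$g, q$v, q$xy)
      q <- list(g = cq$graph, v = cq$values, xy = cq$coords)
    }
    mu_r <- mean(r$v); mu_q <- mean(q$v)
    sd_r <- stats::sd(r$v); sd_q <- stats::sd(q$v)
    if (is.na(sd_r)) sd_r <- 0
    if (is.na(sd_q)) sd_q <- 0
    l <- (2 * mu_r * mu_q + C1) / (mu_r^2 + mu_q^2 + C1)
    ct <- (2 * sd_r * sd_q + C2) / (sd_r^2 + sd_q^2 + C2)
    lo <- min(c(r$v, q$v)); hi <- max(c(r$v, q$v))
    s_term <- safe_cor(norm_hist(r$v, lo, hi), norm_hist(q$v, lo, hi))
    rows[[sc + 1L]] <- data.frame(scale = sc, luminance = l, contrast = ct,
                                  structure = s_term, score = l * ct * s_term,
                                  n_ref = length(r$v), n_query = length(q$v))
  }
  per_scale <- do.call(rbind, rows)
  structure(list(score = mean(per_scale$score), per_scale = per_scale),
            class = "mssi_result")
}

#' @export
print.mssi_result <- function(x, ...) {
  cat(sprintf("<mssi_result> score %.4f over %d scales\n", x$score,
              nrow(x$per_scale)))
  print(x$per_scale, row.names = FALSE)
  invisible(x)
}

#' MSSI for a panel of genes
#'
#' @param ref_coords,query_coords coordinate matrices.
#' @param ref_expr,query_expr cell x gene matrices sharing column names.
#' @param genes genes to score (default: shared columns).
#' @param ... passed to [mssi_score()].
#' @return data.frame(`gene`, `mssi`).
#' @export
mssi_panel <- function(ref_coords, ref_expr, query_coords, query_expr,
                       genes = NULL, ...) {
  if (is.null(genes))
    genes <- intersect(colnames(ref_expr), colnames(query_expr))
  data.frame(gene = genes,
             mssi = vapply(genes, function(g)
               mssi_score(ref_coords, ref_expr[, g], query_coords,
                          query_expr[, g], ...)$score, 0),
             row.names = NULL, stringsAsFactors = FALSE)
}
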