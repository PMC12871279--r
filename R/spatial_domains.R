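## spatial-domain preparation: 30 um grid aggregation, grid QC, spatial
## KNN graph, Leiden bootstrap stability, and domain-region concordance

#' Aggregate transcripts into a spatial grid
#'
#' Half-open square bins of `bin_um` micrometres from the section
#' origin; blanks are tallied separately per grid cell and excluded from
#' the counts.
#'
#' @param spots a [spot_table].
#' @param bin_um grid size in um (default 30).
#' @param origin `c(x, y)` um of the grid origin (default `c(0, 0)`).
#' @return an object of class `grid_matrix`: list(`counts` grid x gene
#'   matrix, `grid_meta` data.frame(`bin_x`, `bin_y`, `center_x`,
#'   `center_y`, `n_blank`), `bin_um`).
#' @export
aggregate_grid <- function(spots, bin_um = 30, origin = c(0, 0)) {
  if (bin_um <= 0)
    stop_merscape("bin_um must be > 0", class = "merscape_config_error")
  bx <- floor((spots$x - origin[1L]) / bin_um)
  by <- floor((spots$y - origin[2L]) / bin_um)
  key <- paste(bx, by)
  bins <- sort(unique(key))
  genes <- sort(unique(spots$gene[!spots$is_blank]))
  sel <- !spots$is_blank
  counts <- matrix(0L, length(bins), length(genes),
                   dimnames = list(bins, genes))
  if (any(sel)) {
    tab <- table(factor(key[sel], levels = bins),
                 factor(spots$gene[sel], levels = genes))
    counts[] <- as.integer(tab)
  }
  nb <- as.integer(table(factor(key[spots$is_blank], levels = bins)))
  xy <- do.call(rbind, strsplit(bins, " "))
  gm <- data.frame(bin_x = as.integer(xy[, 1L]), bin_y = as.integer(xy[, 2L]),
                   n_blank = nb)
  gm$center_x <- origin[1L] + (gm$bin_x + 0.5) * bin_um
  gm$center_y <- origin[2L] + (gm$bin_y + 0.5) * bin_um
  structure(list(counts = counts, grid_meta = gm, bin_um = bin_um),
            class = "grid_matrix")
}

#' Grid-level quality filter
#'
#' Retains grid cells with at least `min_genes` detected genes AND at
#' least `min_transcripts` transcripts AND a blank fraction strictly
#' below `max_blank_frac`.
#'
#' @param g a `grid_matrix` from [aggregate_grid()].
#' @param min_genes,min_transcripts,max_blank_frac thresholds (defaults
#'   60 / 300 / 0.03).
#' @return logical keep mask in grid order.
#' @export
grid_qc <- function(g, min_genes = 60, min_transcripts = 300,
                    max_blank_frac = 0.03) {
  n_genes <- rowSums(g$counts > 0)
  n_tx <- rowSums(g$counts)
  tot <- n_tx + g$grid_meta$n_blank
  bf <- ifelse(tot > 0, g$grid_meta$n_blank / tot, 0)
  n_genes >= min_genes & n_tx >= min_transcripts & bf < max_blank_frac
}

#' Spatial k-nearest-neighbour graph
#'
#' Each node is linked to its `k` nearest Euclidean neighbours
#' (deterministic tie-break by node index via FNN's ordering), then the
#' edge set is symmetrized by union, so every degree is >= `k`.
#'
#' @param coords numeric matrix of node coordinates.
#' @param k neighbours per node (default 8).
#' @return an [igraph::graph] with `nrow(coords)` vertices.
#' @export
knn_graph <- function(coords, k = 8L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n <= k) {
    warning("fewer than k+1 nodes; returning the complete graph")
    return(igraph::make_full_graph(n))
  }
  nn <- FNN::get.knn(coords, k = k)$nn.index
  el <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(g)
}

#' Adjusted Rand Index between two labelings
#' @param a,b label vectors of equal length.
#' @return ARI in `[-1, 1]`; 1 for identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

## entropy of a count vector (nats)
count_entropy <- function(cnt) {
  p <- cnt[cnt > 0] / sum(cnt)
  -sum(p * log(p))
}

#' Adjusted Mutual Information between two labelings
#'
#' Mutual information corrected by its expectation under the
#' hypergeometric model of random labelings with fixed marginals,
#' normalized by the mean of the two entropies.
#'
#' @param a,b label vectors of equal length.
#' @return AMI; 1 for identical partitions, ~0 for independent ones.
#' @export
adjusted_mutual_information <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  ai <- rowSums(tab); bj <- colSums(tab)
  ## observed MI
  mi <- 0
  for (i in seq_along(ai)) for (j in seq_along(bj)) {
    nij <- tab[i, j]
    if (nij > 0) mi <- mi + nij / n * log(nij * n / (ai[i] * bj[j]))
  }
  ## expected MI under the permutation model
  emi <- 0
  for (i in seq_along(ai)) for (j in seq_along(bj)) {
    lo <- max(ai[i] + bj[j] - n, 1)
    hi <- min(ai[i], bj[j])
    if (lo > hi) next
    for (nij in lo:hi) {
      t1 <- nij / n * log(nij * n / (ai[i] * bj[j]))
      lt2 <- lgamma(ai[i] + 1) + lgamma(bj[j] + 1) +
        lgamma(n - ai[i] + 1) + lgamma(n - bj[j] + 1) -
        lgamma(n + 1) - lgamma(nij + 1) - lgamma(ai[i] - nij + 1) -
        lgamma(bj[j] - nij + 1) - lgamma(n - ai[i] - bj[j] + nij + 1)
      emi <- emi + t1 * exp(lt2)
    }
  }
  h <- c(count_entropy(ai), count_entropy(bj))
  denom <- mean(h) - emi
  if (abs(denom) < 1e-15) return(1)
  unname((mi - emi) / denom)
}

#' Leiden clustering of an embedding
#'
#' k-nearest-neighbour graph (default 15 neighbours) on the embedding,
#' then Leiden with the modularity objective at the given resolution.
#'
#' @param embedding node x dim numeric matrix.
#' @param resolution Leiden resolution parameter.
#' @param k neighbours for the clustering graph (default 15).
#' @param seed RNG seed for the Leiden refinement.
#' @return integer cluster membership per node.
#' @export
leiden_cluster <- function(embedding, resolution = 1.0, k = 15L, seed = 0L) {
  g <- knn_graph(embedding, k = min(k, nrow(embedding) - 1L))
  with_seed(seed, {
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 3L)
    igraph::membership(cl)
  })
}

#' Bootstrap cluster-stability analysis
#'
#' For each resolution in the sweep, `n_boot` subsamples of `frac` of
#' the nodes are clustered with [leiden_cluster()]; every subsample pair
#' is scored by ARI and AMI on the intersection of their nodes, and the
#' number of clusters per run is recorded.
#'
#' @param embedding node x dim numeric matrix (an external spatial
#'   embedding, or e.g. a PCA of grid counts from [grid_pca_embedding()]).
#' @param resolutions numeric sweep (default `seq(0.2, 2.0, 0.1)`).
#' @param n_boot subsamples (default 25).
#' @param frac subsample fraction (default 0.8).
#' @param seed RNG seed; the whole analysis is deterministic given it.
#' @param k neighbours for the clustering graph (default 15).
#' @return a data.frame of class `stability_table`: `resolution`,
#'   `pair_i`, `pair_j`, `ami`, `ari`, `n_clusters_i`, `n_clusters_j`.
#' @export
cluster_stability <- function(embedding, resolutions = seq(0.2, 2.0, by = 0.1),
                              n_boot = 25L, frac = 0.8, seed = 0L, k = 15L) {
  if (!length(resolutions))
    stop_merscape("empty resolution sweep", class = "merscape_config_error")
  n <- nrow(embedding)
  m <- max(2L, floor(frac * n))
  rows <- list()
  with_seed(seed, {
    for (res in resolutions) {
      subs <- lapply(seq_len(n_boot), function(b) sort(sample.int(n, m)))
      labs <- lapply(seq_len(n_boot), function(b)
        leiden_cluster(embedding[subs[[b]], , drop = FALSE], resolution = res,
                       k = k, seed = sample.int(1e6, 1L)))
      nclus <- vapply(labs, function(l) length(unique(l)), 0L)
      for (i in seq_len(n_boot - 1L)) for (j in (i + 1L):n_boot) {
        common <- intersect(subs[[i]], subs[[j]])
        la <- labs[[i]][match(common, subs[[i]])]
        lb <- labs[[j]][match(common, subs[[j]])]
        rows[[length(rows) + 1L]] <- data.frame(
          resolution = res, pair_i = i, pair_j = j,
          ami = adjusted_mutual_information(la, lb),
          ari = adjusted_rand_index(la, lb),
          n_clusters_i = nclus[i], n_clusters_j = nclus[j])
      }
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("stability_table", "data.frame")
  out
}

#' PCA embedding of grid counts
#'
#' Built-in stand-in for an external spatially aware embedding so the
#' spatial-domain stage runs end-to-end: library-size + log1p
#' normalisation of the grid counts followed by PCA.
#'
#' @param g a `grid_matrix`.
#' @param n_pcs dimensions (default 10).
#' @return grid x `n_pcs` matrix.
#' @export
grid_pca_embedding <- function(g, n_pcs = 10L) {
  x <- g$counts
  ls <- rowSums(x); ls[ls == 0] <- 1
  xn <- log1p(x / ls * stats::median(rowSums(x)))
  stats::prcomp(xn, rank. = min(n_pcs, ncol(xn), nrow(xn) - 1L),
                center = TRUE)$x
}

#' Jaccard concordance between spatial domains and anatomical regions
#'
#' `J(d, r) = |types(d) n types(r)| / |types(d) u types(r)|` where
#' `types(d)` is the set of cell types observed in domain `d` and
#' `types(r)` the region-specific type set.
#'
#' @param domain_label character domain per cell.
#' @param region_sets named list: region -> character vector of
#'   region-specific cell types.
#' @param celltype character cell type per cell.
#' @return list(`jaccard` domain x region matrix, `overlap` matching
#'   matrix of intersection sizes).
#' @export
region_concordance <- function(domain_label, region_sets, celltype) {
  domains <- sort(unique(domain_label))
  J <- matrix(0, length(domains), length(region_sets),
              dimnames = list(domains, names(region_sets)))
  O <- J
  for (d in domains) {
    types_d <- unique(celltype[domain_label == d])
    for (r in names(region_sets)) {
      u <- union(types_d, region_sets[[r]])
      i <- intersect(types_d, region_sets[[r]])
      J[d, r] <- if (length(u)) length(i) / length(u) else 0
      O[d, r] <- length(i)
    }
  }
  list(jaccard = J, overlap = O)
}
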