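# Shared fixture builders, all generated in code at test time.

# minimal cell matrix with hand-set counts and blanks
toy_cell_matrix <- function(counts, n_blank = NULL, volume = NULL) {
  ids <- rownames(counts) %||% sprintf("c%02d", seq_len(nrow(counts)))
  cm_meta <- data.frame(production_cell_id = ids,
                        n_blank = n_blank %||% rep(0L, nrow(counts)),
                        stringsAsFactors = FALSE)
  if (!is.null(volume)) cm_meta$volume_um3 <- volume
  rownames(cm_meta) <- ids
  gm <- data.frame(name = colnames(counts), stringsAsFactors = FALSE)
  rownames(gm) <- colnames(counts)
  cell_matrix(counts, cm_meta, gm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two z-stacked Gaussian blobs rendered into a volume image
two_blob_image <- function(cx, n = 40, nz = 3, sigma2 = 8) {
  g <- expand.grid(y = seq_len(n), x = seq_len(n))
  plane <- matrix(0, n, n)
  for (c0 in cx)
    plane <- plane + matrix(exp(-((g$x - c0[1])^2 + (g$y - c0[2])^2) / sigma2),
                            n, n)
  v <- array(0, c(nz, n, n))
  for (z in seq_len(nz)) v[z, , ] <- plane
  volume_image(v, voxel_size = c(1, 1, 1))
}

# cell-matrix fixture with planted doublets: three disjoint expression
# programs; doublets are sums of two draws from different programs
planted_doublet_fixture <- function(seed = 1, n_per = 100, n_dbl = 30) {
  set.seed(seed)
  genes <- sprintf("G%02d", 1:30)
  prof <- list(A = c(rep(8, 10), rep(0.2, 20)),
               B = c(rep(0.2, 10), rep(8, 10), rep(0.2, 10)),
               C = c(rep(0.2, 20), rep(8, 10)))
  draw <- function(ty) rpois(30, prof[[ty]])
  singlets <- do.call(rbind, lapply(rep(names(prof), each = n_per), draw))
  pair_ty <- replicate(n_dbl, sample(names(prof), 2))
  dbl <- sapply(seq_len(n_dbl), function(i)
    draw(pair_ty[1, i]) + draw(pair_ty[2, i]))
  counts <- rbind(singlets, t(dbl))
  colnames(counts) <- genes
  rownames(counts) <- sprintf("c%03d", seq_len(nrow(counts)))
  list(cm = toy_cell_matrix(counts),
       truth = c(rep(FALSE, 3 * n_per), rep(TRUE, n_dbl)))
}

# naive independent DoubleMAD oracle (deliberately written differently)
naive_double_mad <- function(x) {
  x <- sort(x)
  med <- median(x)
  below <- x[x <= med]
  above <- x[x >= med]
  list(median = med,
       mad_low = median(sort(abs(below - med))),
       mad_high = median(sort(abs(above - med))))
}
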