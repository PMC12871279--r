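test_that("COVET matches the closed-form toy and the brute force", {
  # identical expression everywhere -> zero matrices
  set.seed(1)
  xy <- matrix(runif(40), 20, 2)
  same <- matrix(3, 20, 2)
  cv0 <- covet_niche(xy, same, k = 4)
  expect_true(all(vapply(cv0, function(m) max(abs(m)), 0) == 0))

  # 1D toy: cells at 0,1,2, values 1,3,5, k = 2 -> variances 2, 4, 2
  cv1 <- covet_niche(cbind(c(0, 1, 2), 0), matrix(c(1, 3, 5), 3, 1), k = 2)
  expect_equal(vapply(cv1, as.numeric, 0), c(2, 4, 2))

  # brute-force double loop on a <= 50 cell instance
  set.seed(3)
  n <- 40
  xy <- matrix(runif(2 * n), n, 2)
  ex <- matrix(rpois(n * 4, 5), n, 4)
  got <- covet_niche(xy, ex, k = 8)
  ebar <- colMeans(ex)
  d2 <- as.matrix(dist(xy)); diag(d2) <- Inf
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[1:8]
    ref <- Reduce(`+`, lapply(nb, function(j) tcrossprod(ex[j, ] - ebar))) / 8
    expect_lt(max(abs(got[[i]] - ref)), 1e-12)
    # symmetry + PSD
    expect_lt(max(abs(got[[i]] - t(got[[i]]))), 1e-12)
    expect_gte(min(eigen(got[[i]], symmetric = TRUE,
                         only.values = TRUE)$values), -1e-9)
  }
  # permuting cell order leaves each cell's matrix unchanged
  perm <- sample(n)
  got_p <- covet_niche(xy[perm, ], ex[perm, ], k = 8)
  expect_lt(max(abs(got[[perm[1]]] - got_p[[1]])), 1e-12)
  expect_error(covet_niche(xy[1:5, ], ex[1:5, ], k = 8),
               class = "merscape_config_error")
})

test_that("graph coarsening halves a path graph and keeps constants", {
  path8 <- igraph::make_ring(8, circular = FALSE)
  cg <- coarsen_graph(path8, values = rep(5, 8))
  expect_equal(igraph::vcount(cg$graph), 4L)
  expect_true(all(cg$values == 5))                 # constant stays constant
  expect_equal(length(cg$membership), 8L)

  # 4 applications of factor 2 on 64 nodes land near ceil chain = 4
  set.seed(5)
  g <- knn_graph(matrix(runif(128), 64, 2), k = 4)
  v <- rnorm(64)
  sizes <- integer(4)
  for (i in 1:4) {
    cg <- coarsen_graph(g, v)
    g <- cg$graph; v <- cg$values
    sizes[i] <- igraph::vcount(g)
  }
  # greedy maximal matching: each step shrinks to between n/2 (perfect
  # matching) and ~0.6 n (isolated leftovers stay singletons)
  expect_gte(sizes[1], 32L); expect_lte(sizes[1], 39L)
  expect_lte(sizes[4], 16L)
  expect_gte(sizes[4], 4L)

  e <- coarsen_graph(igraph::make_empty_graph(0, directed = FALSE),
                     values = numeric(0))
  expect_equal(igraph::vcount(e$graph), 0L)
})

test_that("MSSI is 1 on self, symmetric, and drops under permutation", {
  set.seed(6)
  xy <- matrix(runif(200), 100, 2)
  val <- rnorm(100, 5)
  self <- mssi_score(xy, val, xy, val)
  expect_lt(abs(self$score - 1), 1e-6)
  expect_equal(nrow(self$per_scale), 5L)           # original + 4 coarsenings

  perm <- mssi_score(xy, val, xy, sample(val))
  expect_lt(perm$score, self$score)
  # the distribution-based structure term is permutation-invariant at
  # the original scale (identical value histograms) but drops once
  # neighbourhood blurring and coarsening mix values spatially
  expect_equal(perm$per_scale$structure[1], 1)
  expect_lt(mean(perm$per_scale$structure[-1]),
            mean(self$per_scale$structure[-1]))

  # symmetry with different sizes and coordinates
  xy2 <- matrix(runif(160), 80, 2)
  val2 <- rnorm(80, 3)
  ab <- mssi_score(xy, val, xy2, val2)
  ba <- mssi_score(xy2, val2, xy, val)
  expect_lt(abs(ab$score - ba$score), 1e-9)

  # zero variance both sides, equal values -> stabilized score 1
  flat <- mssi_score(xy, rep(2, 100), xy2, rep(2, 80))
  expect_lt(abs(flat$score - 1), 1e-6)
  # zero variance on one side: contrast term < 1
  half <- mssi_score(xy, rep(2, 100), xy2, rnorm(80, 2))
  expect_lt(half$per_scale$contrast[1], 1)
})

test_that("the coarsening schedule applies 4 factor-2 reductions", {
  set.seed(7)
  xy <- matrix(runif(256), 128, 2)
  val <- rnorm(128)
  res <- mssi_score(xy, val, xy, val)
  n <- res$per_scale$n_ref
  expect_equal(length(n), 5L)
  expect_equal(n[1], 128L)
  # every step halves up to the unmatched-singleton slack
  ratio <- n[-1] / n[-5]
  expect_true(all(ratio >= 0.5 & ratio <= 0.62))
})

test_that("mssi_panel scores shared genes", {
  set.seed(8)
  xy <- matrix(runif(120), 60, 2)
  ex <- matrix(rnorm(120, 4), 60, 2, dimnames = list(NULL, c("g1", "g2")))
  tab <- mssi_panel(xy, ex, xy, ex)
  expect_equal(tab$gene, c("g1", "g2"))
  expect_true(all(abs(tab$mssi - 1) < 1e-6))
})
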