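test_that("double MAD matches hand computation and symmetry", {
  md <- double_mad(c(0.2, 0.4, 0.5, 0.6, 0.8))
  expect_equal(md$median, 0.5)
  expect_equal(md$mad_low, 0.1)
  expect_equal(md$mad_high, 0.1)

  cst <- double_mad(rep(0.3, 5))
  expect_equal(unlist(cst), c(median = 0.3, mad_low = 0, mad_high = 0))

  sym <- double_mad(c(-2, -1, 0, 1, 2))
  expect_equal(sym$mad_low, sym$mad_high)

  expect_error(double_mad(c(1, 2)), class = "merscape_config_error")
})

test_that("double MAD equals a brute-force oracle on skewed samples", {
  set.seed(100)
  for (i in 1:100) {
    x <- rgamma(500, shape = runif(1, 0.5, 3), rate = runif(1, 0.5, 2))
    got <- double_mad(x)
    ref <- naive_double_mad(x)
    expect_equal(got$median, ref$median, tolerance = 1e-12)
    expect_equal(got$mad_low, ref$mad_low, tolerance = 1e-12)
    expect_equal(got$mad_high, ref$mad_high, tolerance = 1e-12)
  }
})

test_that("threshold is equivariant under affine rescaling", {
  set.seed(12)
  x <- rgamma(300, 2, 3)
  thr <- function(v) {
    md <- double_mad(v)
    md$median - 3 * md$mad_low
  }
  a <- 2.5; b <- -0.7
  expect_equal(thr(a * x + b), a * thr(x) + b, tolerance = 1e-12)
})

test_that("bimodality detection flags the stated mixtures only", {
  set.seed(31)
  mix <- c(rnorm(1000, 0.3, 0.02), rnorm(1000, 0.7, 0.02))
  res <- detect_bimodality(mix)
  expect_true(res$bimodal)
  expect_lt(abs(res$local_min - 0.5), 0.05)

  uni <- rnorm(2000, 0.5, 0.05)
  expect_false(detect_bimodality(uni)$bimodal)

  skew97 <- c(rnorm(1940, 0.6, 0.02), rnorm(60, 0.35, 0.02))
  expect_false(detect_bimodality(skew97)$bimodal)  # minor mass < 10%

  expect_false(detect_bimodality(rep(0.5, 100))$bimodal)
})

test_that("supertype threshold handles unimodal and bimodal inputs", {
  uni <- supertype_threshold(c(0.2, 0.4, 0.5, 0.6, 0.8), label = "u")
  expect_equal(uni$threshold, 0.5 - 3 * 0.1)
  expect_equal(uni$n_removed, 0L)       # 0.2 is exactly at the cutoff
  expect_false(uni$bimodal)

  # near-equal masses and equal spreads so the two KDE peaks match in
  # height (the peak-gap criterion requires nearly equal peaks)
  set.seed(32)
  lower <- rnorm(500, 0.3, 0.03)
  upper <- rnorm(500, 0.65, 0.03)
  rep_b <- supertype_threshold(c(lower, upper), label = "b")
  expect_true(rep_b$bimodal)
  keep <- attr(rep_b, "keep")
  # the whole planted lower mode is removed, the upper mode retained
  expect_true(all(!keep[seq_along(lower)]))
  expect_gt(mean(keep[length(lower) + seq_along(upper)]), 0.95)
})

test_that("per-supertype filtering is group independent", {
  set.seed(33)
  sc <- generate_mapping_scores(n_supertypes = 4, n_cells_per = 300,
                                contaminant_frac = 0.12, seed = 5)
  out <- filter_mapped_cells(sc)
  expect_equal(nrow(out$report), 4L)
  # contaminants removed, main mode retained per supertype
  expect_gt(mean(!out$keep[sc$is_contaminant]), 0.9)
  expect_gt(mean(out$keep[!sc$is_contaminant]), 0.95)
  # thresholds computed independently: permuting group blocks preserves them
  for (st in unique(sc$supertype)) {
    sub <- sc[sc$supertype == st, ]
    solo <- supertype_threshold(sub$avg_correlation, label = st)
    expect_equal(out$report$threshold[out$report$supertype == st],
                 solo$threshold)
  }
  # tiny groups pass through unfiltered
  tiny <- data.frame(cell_id = 1:2, supertype = "T", avg_correlation = c(1, 0))
  out2 <- filter_mapped_cells(tiny)
  expect_true(all(out2$keep))
  expect_false(out2$report$filtered[1])
})

test_that("the adaptive filter is no harsher than a fixed 0.5 cutoff
           when all scores sit above 0.5", {
  set.seed(34)
  x <- runif(200, 0.55, 0.95)
  rep_x <- supertype_threshold(x)
  expect_gte(sum(attr(rep_x, "keep")), sum(x >= 0.5))
})

test_that("average nearest-neighbour distance per group", {
  two <- ann_distance(cbind(c(0, 7), c(0, 0)), c("a", "a"))
  expect_equal(unname(two["a"]), 7)
  col <- ann_distance(cbind(c(0, 1, 3), c(0, 0, 0)), rep("g", 3))
  expect_equal(unname(col["g"]), 4 / 3)
  dup <- ann_distance(cbind(c(0, 0, 5), c(0, 0, 0)), rep("g", 3))
  expect_equal(unname(dup["g"]), mean(c(0, 0, 5)))
  single <- ann_distance(cbind(1, 1), "s")
  expect_true(is.na(single["s"]))
})
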