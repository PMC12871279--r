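test_that("cell metrics follow the stated arithmetic", {
  counts <- rbind(c1 = c(A = 10L, B = 5L), c2 = c(A = 3L, B = 0L))
  m <- toy_cell_matrix(counts, n_blank = c(1L, 0L), volume = c(20, 0))
  met <- compute_cell_metrics(m)
  expect_equal(met$n_genes, c(2L, 1L))
  expect_equal(met$n_transcripts, c(15L, 3L))
  expect_equal(met$blank_fraction, c(1 / 16, 0))
  # 10+5 transcripts over 20 um^3 would be 0.75; here 15/20
  expect_equal(met$density[1], 15 / 20)
  expect_true(is.na(met$density[2]))  # zero volume -> undefined
})

test_that("fixed QC filter enforces the 6/30/2% rule with boundaries", {
  met <- data.frame(
    n_genes = c(5, 6, 50, 6, 6),
    n_transcripts = c(100, 30, 200, 29, 30),
    blank_fraction = c(0, 0.019, 0.025, 0, 0.02))
  keep <- apply_quality_filter(met, qc_thresholds())
  # 5 genes -> removed; boundary cell retained; 2.5% blanks -> removed;
  # 29 transcripts -> removed; exactly 2% blanks -> removed (>= rule)
  expect_equal(keep, c(FALSE, TRUE, FALSE, FALSE, FALSE))
})

test_that("the QC filter is monotone in its thresholds", {
  set.seed(4)
  met <- data.frame(n_genes = sample(0:20, 200, TRUE),
                    n_transcripts = sample(0:100, 200, TRUE),
                    blank_fraction = runif(200, 0, 0.05))
  base <- apply_quality_filter(met, qc_thresholds())
  relaxed <- list(qc_thresholds(min_genes = 3),
                  qc_thresholds(min_transcripts = 10),
                  qc_thresholds(max_blank_fraction = 0.04))
  for (t in relaxed) {
    keep <- apply_quality_filter(met, t)
    expect_true(all(keep[base]))  # lowering a threshold never removes more
  }
})

test_that("planted low-quality cells are recovered exactly", {
  cfg <- synth_config(n_cells = 60, extent_um = 250, low_quality_frac = 0.15,
                      blank_rate = 0.002, noise_rate_um2 = 0, seed = 21)
  sec <- generate_section(cfg)
  # ground-truth segmentation: assign each transcript to its true cell
  keepspot <- !is.na(sec$truth$spot_cell)
  asn <- data.frame(transcript_id = sec$spots$transcript_id[keepspot],
                    cell_id = sprintf("S1-0-%d", sec$truth$spot_cell[keepspot]),
                    tile_index = 0L)
  m <- assemble_cell_matrix(asn, sec$spots)
  keep <- apply_quality_filter(compute_cell_metrics(m))
  removed <- as.integer(sub("^S1-0-", "", m$cell_meta$production_cell_id[!keep]))
  expect_setequal(removed, sec$truth$low_quality)
})

test_that("division markers come out of the rank-sum screen", {
  set.seed(5)
  clusters <- paste0("cl", 1:12)
  division_of <- setNames(rep(c("A", "B", "C"), each = 4), clusters)
  genes <- c("gA1", "gA2", "gB1", "gB2", "gC1", "gC2", "flat")
  med <- matrix(rnorm(12 * 7, 1, 0.05), 12, 7,
                dimnames = list(clusters, genes))
  med[division_of == "A", c("gA1", "gA2")] <- 10
  med[division_of == "B", c("gB1", "gB2")] <- 10
  med[division_of == "C", c("gC1", "gC2")] <- 10
  med[, "flat"] <- 1  # constant gene: never a marker
  mk <- derive_division_markers(med, division_of, top_n = 2L)
  expect_setequal(mk$A, c("gA1", "gA2"))
  expect_setequal(mk$B, c("gB1", "gB2"))
  expect_setequal(mk$C, c("gC1", "gC2"))
  expect_warning(mk_all <- derive_division_markers(med, division_of,
                                                   top_n = 100L),
                 "panel")
  expect_equal(length(mk_all$A), 7L)
  # independent oracle on one division: wilcox.test statistic ordering
  w <- vapply(genes, function(g)
    suppressWarnings(stats::wilcox.test(med[division_of == "A", g],
                     med[division_of != "A", g],
                     alternative = "greater")$statistic), 0)
  expect_setequal(sub("\\.W$", "", names(sort(w, decreasing = TRUE))[1:2]),
                  mk$A)
})

test_that("incongruent fraction scores cross-division markers", {
  mk <- list(A = c("a1", "a2"), B = c("b1", "b2"))
  pairs <- incongruent_pairs(mk)
  expect_equal(nrow(pairs), 4L)
  expect_true(all(pairs$division_a != pairs$division_b))

  counts <- rbind(cellA = c(a1 = 8L, a2 = 0L, b1 = 2L, b2 = 0L),
                  cellPure = c(a1 = 5L, a2 = 5L, b1 = 0L, b2 = 0L),
                  cellEmpty = c(a1 = 0L, a2 = 0L, b1 = 0L, b2 = 0L))
  m <- toy_cell_matrix(counts)
  pct <- incongruent_fraction(m, pairs, c("A", "A", "A"))
  expect_equal(pct[1], 20)            # 2 foreign of 10
  expect_equal(pct[2], 0)             # only own markers
  expect_true(is.na(pct[3]))          # zero transcripts -> undefined
  expect_true(is.na(incongruent_fraction(m, pairs,
                                         c(NA, "A", "A"))[1]))
})
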