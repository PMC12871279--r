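test_that("read_spot_table parses the detected-transcripts dialect", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,global_x,global_y,global_z",
               "A,1,2,0", "A,2,2,0", "B,3,1,1", "Blank-1,0,0,0", "C,5,5,2"), p)
  st <- read_spot_table(p, dialect = "merscope_csv")
  expect_s3_class(st, "spot_table")
  expect_equal(nrow(st), 5L)
  expect_equal(sum(st$is_blank), 1L)
  expect_equal(st$gene[st$is_blank], "Blank-1")

  # header-only file: empty table, no error
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("gene,global_x,global_y,global_z", p2)
  expect_equal(nrow(read_spot_table(p2, "merscope_csv")), 0L)

  # missing gene column is a format error naming the column
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("global_x,global_y", "1,2"), p3)
  expect_error(read_spot_table(p3, "merscope_csv"), "gene",
               class = "merscape_format_error")

  # non-numeric coordinate names the row
  p4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,global_x,global_y,global_z", "A,1,2,0", "B,oops,2,0"), p4)
  expect_error(read_spot_table(p4, "merscope_csv"), "row 2",
               class = "merscape_parse_error")
})

test_that("blank flag follows the configurable pattern", {
  st <- spot_table(gene = c("blank-7", "Blank-1", "Gad1"), x = 1:3, y = 1:3)
  expect_equal(st$is_blank, c(TRUE, TRUE, FALSE))
  st2 <- spot_table(gene = c("NegCtrl-1", "Gad1"), x = 1:2, y = 1:2,
                    blank_pattern = "^NegCtrl")
  expect_equal(st2$is_blank, c(TRUE, FALSE))
})

test_that("assemble_cell_matrix counts, centroids and conservation", {
  st <- spot_table(gene = c("A", "A", "B", "B", "C", "A", "B", "C", "C", "C"),
                   x = c(0, 2, 1, 1, 1, 10, 10, 11, 5, 6),
                   y = rep(0, 10), z = rep(0.75, 10))
  asn <- data.frame(transcript_id = 1:7,
                    cell_id = c(rep("S1-1-1", 5), rep("S1-1-2", 2)),
                    tile_index = 1L)
  m <- assemble_cell_matrix(asn, st)
  expect_equal(sum(m$counts), 7)
  expect_equal(sum(m$gene_meta$total_unsegmented), 3)
  # conservation: counts + unsegmented = non-blank transcripts
  expect_equal(sum(m$counts) + sum(m$gene_meta$total_unsegmented), 10)
  # transcript centroid of cell 1: mean of (0,2,1,1,1) = 1
  expect_equal(m$cell_meta["S1-1-1", "tx_centroid_x"], 1)
  expect_equal(m$counts["S1-1-1", ], c(A = 2L, B = 2L, C = 1L))
  # unknown transcript reference
  bad <- data.frame(transcript_id = 99L, cell_id = "S1-1-9", tile_index = 1L)
  expect_error(assemble_cell_matrix(bad, st),
               class = "merscape_consistency_error")
})

test_that("polygon centroid is area weighted across planes", {
  # planes with areas 1 and 3 and centroids (0.5,0.5) and (4+?,...):
  sq <- function(x0, s) rbind(c(x0, 0), c(x0 + s, 0), c(x0 + s, s), c(x0, s))
  polys <- structure(list(planes = list(
    list(z = 0, vertices = sq(-0.5, 1), area = 1, centroid = c(0, 0.5)),
    list(z = 1, vertices = sq(4 - sqrt(3) / 2, sqrt(3)), area = 3,
         centroid = c(4, sqrt(3) / 2))),
    alpha_used = c(1, 1), alpha_scale = 0.75), class = "cell_polygons")
  g <- compute_geometry(polys, z_spacing = 1)
  expect_equal(g$centroid[1L], (1 * 0 + 3 * 4) / 4)  # x = 3.0
  expect_equal(g$area_um2, 3)
  expect_equal(g$volume_um3, 4)
})

test_that("cell matrix round-trips through the h5ad-style file", {
  counts <- matrix(c(0:11), 3, 4,
                   dimnames = list(paste0("S1-1-", 1:3), paste0("g", 1:4)))
  st <- spot_table(gene = "A", x = 1, y = 1, z = 0.2)
  poly <- build_cell_polygons(spot_table(gene = rep("A", 3), x = c(0, 1, 0),
                                         y = c(0, 0, 1), z = 0))
  m <- assemble_cell_matrix(
    data.frame(transcript_id = 1L, cell_id = "S1-1-1", tile_index = 1L),
    st, polygons = list(`S1-1-1` = poly), params = list(alpha = 0.75))
  f <- withr::local_tempfile(fileext = ".h5ad")
  write_cell_matrix(m, f)
  m2 <- read_cell_matrix(f)
  expect_equal(m2$counts, m$counts)
  expect_equal(m2$cell_meta, m$cell_meta)
  expect_equal(m2$gene_meta, m$gene_meta)
  # GeoJSON survives byte-identically
  expect_identical(m2$uns$polygons_geojson, m$uns$polygons_geojson)

  # direct container round trip including zero cells
  m0 <- toy_cell_matrix(matrix(integer(0), 0, 3,
                               dimnames = list(NULL, c("a", "b", "c"))))
  f0 <- withr::local_tempfile(fileext = ".h5ad")
  write_cell_matrix(m0, f0)
  m0b <- read_cell_matrix(f0)
  expect_equal(dim(m0b$counts), c(0L, 3L))
})
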