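test_that("make_tiles covers the extent in row-major order", {
  t1 <- make_tiles(c(0, 700, 0, 350), tile_size = 350, overlap = 0)
  expect_equal(nrow(t1), 2L)
  t2 <- make_tiles(c(0, 350, 0, 350), tile_size = 350, overlap = 0)
  expect_equal(nrow(t2), 1L)
  # ceil((700-350)/300)+1 = 3 per axis
  t3 <- make_tiles(c(0, 700, 0, 700), tile_size = 350, overlap = 50)
  expect_equal(nrow(t3), 9L)
  expect_equal(t3$xmin[1:3], c(0, 300, 350))  # last tile shifted to the edge
  # full coverage
  expect_true(all(t3$xmax - t3$xmin == 350))
  expect_equal(min(t3$xmin), 0); expect_equal(max(t3$xmax), 700)
  # smaller than one tile: single tile covering the extent
  t4 <- make_tiles(c(0, 100, 0, 80))
  expect_equal(nrow(t4), 1L)
  expect_equal(unlist(t4[1, c("xmax", "ymax")], use.names = FALSE), c(100, 80))
  expect_error(make_tiles(c(0, 1, 0, 1), tile_size = 10, overlap = 10),
               class = "merscape_config_error")
})

test_that("builtin segmenter labels blobs", {
  zero <- volume_image(array(0, c(3, 20, 20)))
  expect_equal(max(segment_tile(NULL, zero)$labels), 0L)

  # two well-separated blobs -> exactly 2 labels
  img <- two_blob_image(list(c(10, 20), c(30, 20)))
  lab <- segment_tile(NULL, img)
  expect_equal(max(lab$labels), 2L)

  # two touching blobs with distinct peaks -> still 2 labels
  img2 <- two_blob_image(list(c(16, 20), c(24, 20)))
  expect_equal(max(segment_tile(NULL, img2)$labels), 2L)

  expect_error(segment_tile(NULL, img, backend = "nope"),
               class = "merscape_config_error")
})

test_that("assign_transcripts maps voxels to production ids", {
  img <- two_blob_image(list(c(10, 20), c(30, 20)))
  lab <- segment_tile(NULL, img)
  st <- spot_table(gene = c("A", "B", "C"),
                   x = c(10, 30, 1), y = c(20, 20, 1), z = 1)
  asn <- assign_transcripts(st, lab, tile_index = 4L)
  expect_equal(nrow(asn), 3L)                     # conservation
  expect_true(is.na(asn$cell_id[3]))              # background voxel
  expect_match(asn$cell_id[1], "^S1-4-")
  expect_false(asn$cell_id[1] == asn$cell_id[2])
})

test_that("stitching merges above 50% sharing and not at exactly 50%", {
  # smaller cell: 10 transcripts, 6 shared with a 20-transcript cell
  a1 <- data.frame(transcript_id = 1:20, cell_id = "S1-1-1", tile_index = 1L)
  a2 <- data.frame(transcript_id = c(15:20, 101:104), cell_id = "S1-2-1",
                   tile_index = 2L)
  st <- stitch_and_merge(list(a1, a2))
  expect_equal(length(unique(st$cell_id)), 1L)     # merged into one cell
  expect_equal(sum(!is.na(st$cell_id)), 24L)

  # exactly 50% shared: no merge; contested transcripts to the newer tile
  b2 <- data.frame(transcript_id = c(16:20, 101:105), cell_id = "S1-2-1",
                   tile_index = 2L)
  st2 <- stitch_and_merge(list(a1, b2))
  expect_setequal(unique(st2$cell_id), c("S1-1-1", "S1-2-1"))
  expect_true(all(st2$cell_id[match(16:20, st2$transcript_id)] == "S1-2-1"))
  expect_equal(sum(st2$cell_id == "S1-1-1"), 15L)

  # disjoint tiles concatenate with disjoint ids
  c1 <- data.frame(transcript_id = 1:5, cell_id = "S1-1-1", tile_index = 1L)
  c2 <- data.frame(transcript_id = 6:9, cell_id = "S1-2-1", tile_index = 2L)
  st3 <- stitch_and_merge(list(c1, c2))
  expect_equal(sort(unique(st3$cell_id)), c("S1-1-1", "S1-2-1"))
  # at most one cell per transcript
  expect_equal(anyDuplicated(st3$transcript_id), 0L)
})

test_that("alpha-shape polygons: triangle, square, degenerate input", {
  tri <- build_cell_polygons(spot_table(gene = rep("A", 3), x = c(0, 1, 0),
                                        y = c(0, 0, 1), z = 0))
  expect_equal(length(tri$planes), 1L)
  expect_equal(tri$planes[[1]]$area, 0.5)

  sq <- build_cell_polygons(spot_table(
    gene = rep("A", 8),
    x = c(0, 1, 1, 0, .5, 1, .5, 0), y = c(0, 0, 1, 1, 0, .5, 1, .5), z = 0))
  expect_equal(length(sq$planes), 1L)
  expect_lte(sq$planes[[1]]$area, 1 + 1e-9)
  expect_true(polygon_is_simple(sq$planes[[1]]$vertices))

  col <- build_cell_polygons(spot_table(gene = rep("A", 4), x = 0:3,
                                        y = rep(0, 4), z = 0))
  expect_equal(length(col$planes), 0L)  # null boundary, no crash
  g <- compute_geometry(col)
  expect_equal(g$volume_um3, 0)
  expect_equal(g$area_um2, 0)
})

test_that("pseudo-3D geometry stacks plane areas", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  mk <- function(z, v, a) list(z = z, vertices = v, area = a,
                               centroid = polygon_centroid_(v))
  polygon_centroid_ <- function(v) colMeans(v)
  one <- structure(list(planes = list(mk(0, sq, 1)), alpha_used = 1,
                        alpha_scale = 0.75), class = "cell_polygons")
  expect_equal(compute_geometry(one, z_spacing = 1.5)$volume_um3, 1.5)
  expect_equal(compute_geometry(one, z_spacing = 1.5)$area_um2, 1)
  two <- structure(list(planes = list(mk(0, sq, 1), mk(1, sq, 1)),
                        alpha_used = c(1, 1), alpha_scale = 0.75),
                   class = "cell_polygons")
  expect_equal(compute_geometry(two, z_spacing = 1)$volume_um3, 2)
  mix <- structure(list(planes = list(mk(0, sq, 1), mk(1, 2 * sq, 3)),
                        alpha_used = c(1, 1), alpha_scale = 0.75),
                   class = "cell_polygons")
  expect_equal(compute_geometry(mix, z_spacing = 1)$area_um2, 3)
})

test_that("a cell split across tiles stitches to one cell end-to-end", {
  # one blob straddling the boundary of two overlapping tiles
  set.seed(7)
  n <- 60
  st <- spot_table(gene = rep("A", n), x = rnorm(n, 50, 3),
                   y = rnorm(n, 20, 3), z = 1)
  img <- bin_transcripts(st, dim_zyx = c(3, 40, 100), voxel_size = c(1, 1, 1))
  dens <- smooth_density(img, density_params(median_window_xy = 4))
  tiles <- make_tiles(c(0, 100, 0, 40), tile_size = 60, overlap = 20)
  per_tile <- lapply(seq_len(nrow(tiles)), function(ti) {
    rect <- as.numeric(tiles[ti, c("xmin", "xmax", "ymin", "ymax")])
    dt <- crop_volume(dens, rect)
    sel <- st$x >= rect[1] & st$x < rect[2] & st$y >= rect[3] & st$y < rect[4]
    assign_transcripts(st[sel, , drop = FALSE], segment_tile(NULL, dt),
                       tile_index = tiles$tile_index[ti])
  })
  merged <- stitch_and_merge(per_tile)
  got <- merged$cell_id[!is.na(merged$cell_id)]
  expect_equal(length(unique(got)), 1L)
  expect_equal(anyDuplicated(merged$transcript_id), 0L)
})
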