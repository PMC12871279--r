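fx <- generate_alignment_fixture(n_sections = 2, n_landmarks = 9,
                                 warp_amplitude = 0.05, seed = 11)
al <- parse_alignment(fx$quicknii_json, fx$visualign_json)

test_that("alignment files parse with matched sections", {
  expect_equal(length(al$anchors), 2L)
  expect_equal(length(al$landmarks), 2L)
  expect_equal(names(al$anchors), names(al$landmarks))
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(parse_alignment(bad), class = "merscape_parse_error")
  # VisuAlign section without a QuickNII anchor
  orphan <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(slices = list(list(filename = "nope.png",
                            markers = list(c(0, 0, 1, 1))))),
    orphan, auto_unbox = TRUE)
  expect_error(parse_alignment(fx$quicknii_json, orphan),
               class = "merscape_consistency_error")
  # missing markers array: empty landmark set + warning
  nomark <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(slices = list(list(filename = "section_01.png"))),
                       nomark, auto_unbox = TRUE)
  expect_warning(al2 <- parse_alignment(fx$quicknii_json, nomark), "markers")
  expect_equal(nrow(al2$landmarks[["section_01.png"]]$source), 0L)
})

test_that("QuickNII XML parses to the same anchors as JSON", {
  xml <- withr::local_tempfile(fileext = ".xml")
  a <- al$anchors[[1]]
  writeLines(sprintf(
    '<series><slice filename="%s" width="%g" height="%g" anchoring="%s"/></series>',
    names(al$anchors)[1], a$width, a$height,
    paste(c(a$o, a$u, a$v), collapse = "&amp;")), xml)
  ax <- parse_alignment(xml)
  expect_equal(ax$anchors[[1]]$matrix, a$matrix)
})

test_that("landmark warp is exact on markers and linear maps", {
  lm <- al$landmarks[[1]]
  expect_lt(max(abs(warp_points(lm$source, lm) - lm$target)), 1e-9)
  # identity landmarks -> identity warp
  id <- list(source = lm$source, target = lm$source)
  set.seed(1)
  pts <- cbind(runif(40, 10, 390), runif(40, 10, 290))
  expect_lt(max(abs(warp_points(pts, id) - pts)), 1e-9)
  # forced linear map: (0,0),(1,0),(0,1) -> doubled triangle
  lm2 <- list(source = rbind(c(0, 0), c(1, 0), c(0, 1)),
              target = rbind(c(0, 0), c(2, 0), c(0, 2)))
  expect_equal(as.numeric(warp_points(cbind(0.25, 0.25), lm2)), c(0.5, 0.5))
  # the planted warp is affine, so interpolation reproduces it analytically
  for (s in 1:2)
    expect_lt(max(abs(warp_points(pts, al$landmarks[[s]]) -
                      fx$truth[[s]]$warp(pts))), 1e-6)
  # collinear markers: identity with warning
  lc <- list(source = rbind(c(0, 0), c(1, 0), c(2, 0)),
             target = rbind(c(0, 0), c(1, 0), c(2, 0)))
  expect_warning(wc <- warp_points(pts, lc), "identity|collinear")
  expect_equal(wc, pts)
})

test_that("anchor transform is o + x u + y v on normalized coordinates", {
  anchor <- list(o = c(10, 5, 0), u = c(20, 0, 0), v = c(0, 0, -20),
                 width = 100, height = 100,
                 matrix = rbind(c(20, 0, 0), c(0, 0, -20), c(10, 5, 0)))
  expect_equal(as.numeric(to_ccf(cbind(50, 50), anchor)), c(20, 5, -10))
  expect_equal(as.numeric(to_ccf(cbind(0, 0), anchor)), c(10, 5, 0))  # o
  # identity atlas matrix leaves the anchor output unchanged
  expect_equal(to_ccf(cbind(30, 70), anchor),
               to_ccf(cbind(30, 70), anchor, atlas_matrix = diag(4)))
})

test_that("region annotation floors to 25 um voxels", {
  vol <- list(labels = array(0L, c(4, 4, 4)), voxel_um = 25)
  vol$labels[2, 2, 2] <- 42L
  expect_equal(annotate_regions(cbind(30, 30, 30), vol), 42L)
  expect_equal(annotate_regions(cbind(-1, 0, 0), vol), 0L)     # outside
  vol$labels[2, 1, 1] <- 7L
  expect_equal(annotate_regions(cbind(25, 0, 0), vol), 7L)     # boundary
})

test_that("identity stack reproduces inputs and voxel lookups agree", {
  fx0 <- generate_alignment_fixture(n_sections = 1, warp_amplitude = 0,
                                    seed = 3)
  al0 <- parse_alignment(fx0$quicknii_json, fx0$visualign_json)
  a0 <- al0$anchors[[1]]
  al0$anchors[[1]] <- list(o = c(0, 0, 0), u = c(a0$width, 0, 0),
                           v = c(0, a0$height, 0),
                           width = a0$width, height = a0$height,
                           matrix = rbind(c(a0$width, 0, 0),
                                          c(0, a0$height, 0), c(0, 0, 0)))
  set.seed(2)
  pts <- cbind(runif(100, 1, 399), runif(100, 1, 299))
  res <- register_section(pts, al0, names(al0$anchors)[1])
  expect_lt(max(abs(res$ccf[, 1:2] - pts)), 1e-9)
  expect_true(all(res$ccf[, 3] == 0))

  # region assignment equals direct voxel lookup on 1000 random points
  vol <- fx0$volume
  set.seed(4)
  d <- dim(vol$labels)
  p3 <- cbind(runif(1000, -10, d[1] * 25 + 10),
              runif(1000, -10, d[2] * 25 + 10),
              runif(1000, -10, d[3] * 25 + 10))
  got <- as.integer(annotate_regions(p3, vol))
  direct <- vapply(seq_len(1000), function(i) {
    ix <- floor(p3[i, ] / 25) + 1
    if (any(ix < 1) || any(ix > d)) 0L
    else vol$labels[ix[1], ix[2], ix[3]]
  }, 0L)
  expect_equal(got, direct)
})
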