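## atlas registration: parse QuickNII/VisuAlign alignment files, apply
## the landmark warp, the section-to-atlas affine, and region annotation

#' Parse QuickNII + VisuAlign alignment files
#'
#' QuickNII files (JSON or XML) provide one anchor per section: the
#' anchoring vectors `o`, `u`, `v` (equivalently a 3x3 affine mapping
#' normalized section coordinates to 3D atlas coordinates) plus image
#' dimensions. VisuAlign JSON provides per-section landmark pairs
#' (source and target marker positions in image coordinates). Sections
#' are matched by name; a VisuAlign section without a QuickNII anchor is
#' a consistency error, a section without a markers array yields an
#' empty landmark set (no warp) with a warning.
#'
#' @param quicknii_path QuickNII JSON (fields `slices`/`sections` with
#'   `filename`/`name`, `anchoring` (9 numbers: o, u, v), `width`,
#'   `height`) or XML (elements `slice` with attributes `filename`,
#'   `anchoring`, `width`, `height`).
#' @param visualign_path VisuAlign JSON (fields `slices` with
#'   `filename`/`name`, `markers` = list of `[sx, sy, tx, ty]`) or
#'   `NULL` for no non-linear correction.
#' @return list(`anchors`, `landmarks`): named lists keyed by section
#'   name. Each anchor is list(`o`, `u`, `v`, `width`, `height`,
#'   `matrix` 3x3 rbind(u, v, o)); each landmark set is list(`source`,
#'   `target` n x 2 matrices, `width`, `height`).
#' @export
parse_alignment <- function(quicknii_path, visualign_path = NULL) {
  anchors <- if (grepl("\\.xml$", quicknii_path, ignore.case = TRUE))
    parse_quicknii_xml(quicknii_path) else parse_quicknii_json(quicknii_path)
  landmarks <- list()
  if (!is.null(visualign_path)) {
    va <- try(jsonlite::fromJSON(visualign_path, simplifyVector = FALSE),
              silent = TRUE)
    if (inherits(va, "try-error"))
      stop_merscape("cannot parse VisuAlign JSON: ", visualign_path,
                    class = "merscape_parse_error")
    for (sl in (va$slices %||% va$sections %||% list())) {
      nm <- sl$filename %||% sl$name
      if (is.null(anchors[[nm]]))
        stop_merscape("VisuAlign section '", nm, "' has no QuickNII anchor",
                      class = "merscape_consistency_error")
      mk <- sl$markers
      if (is.null(mk) || !length(mk)) {
        warning("section '", nm, "' has no markers; no warp will be applied")
        landmarks[[nm]] <- list(source = matrix(0, 0, 2),
                                target = matrix(0, 0, 2),
                                width = anchors[[nm]]$width,
                                height = anchors[[nm]]$height)
        next
      }
      mkm <- do.call(rbind, lapply(mk, function(v) as.numeric(unlist(v))))
      landmarks[[nm]] <- list(source = mkm[, 1:2, drop = FALSE],
                              target = mkm[, 3:4, drop = FALSE],
                              width = sl$width %||% anchors[[nm]]$width,
                              height = sl$height %||% anchors[[nm]]$height)
    }
  }
  list(anchors = anchors, landmarks = landmarks)
}

parse_quicknii_json <- function(path) {
  js <- try(jsonlite::fromJSON(path, simplifyVector = FALSE), silent = TRUE)
  if (inherits(js, "try-error"))
    stop_merscape("cannot parse QuickNII JSON: ", path,
                  class = "merscape_parse_error")
  out <- list()
  for (sl in (js$slices %||% js$sections %||% list())) {
    nm <- sl$filename %||% sl$name
    a <- as.numeric(unlist(sl$anchoring))
    out[[nm]] <- anchor_from_vec(a, as.numeric(sl$width),
                                 as.numeric(sl$height))
  }
  out
}

parse_quicknii_xml <- function(path) {
  doc <- try(xml2::read_xml(path), silent = TRUE)
  if (inherits(doc, "try-error"))
    stop_merscape("cannot parse QuickNII XML: ", path,
                  class = "merscape_parse_error")
  out <- list()
  for (sl in xml2::xml_find_all(doc, ".//slice")) {
    nm <- xml2::xml_attr(sl, "filename")
    a <- as.numeric(strsplit(xml2::xml_attr(sl, "anchoring"),
                             "[&,; ]+")[[1]])
    a <- a[!is.na(a)]
    out[[nm]] <- anchor_from_vec(a,
                                 as.numeric(xml2::xml_attr(sl, "width")),
                                 as.numeric(xml2::xml_attr(sl, "height")))
  }
  out
}

anchor_from_vec <- function(a, width, height) {
  if (length(a) != 9L || any(!is.finite(a)))
    stop_merscape("anchoring must be 9 finite numbers",
                  class = "merscape_parse_error")
  if (!is_number(width) || !is_number(height) || width <= 0 || height <= 0)
    stop_merscape("image dimensions must be positive",
                  class = "merscape_parse_error")
  o <- a[1:3]; u <- a[4:6]; v <- a[7:9]
  list(o = o, u = u, v = v, width = width, height = height,
       matrix = rbind(u, v, o))
}

## barycentric coordinates of points wrt one triangle (rows of tri)
barycentric <- function(pts, tri) {
  d <- rbind(tri[2L, ] - tri[1L, ], tri[3L, ] - tri[1L, ])
  den <- d[1L, 1L] * d[2L, 2L] - d[2L, 1L] * d[1L, 2L]
  px <- pts[, 1L] - tri[1L, 1L]; py <- pts[, 2L] - tri[1L, 2L]
  w2 <- (px * d[2L, 2L] - py * d[2L, 1L]) / den
  w3 <- (py * d[1L, 1L] - px * d[1L, 2L]) / den
  cbind(1 - w2 - w3, w2, w3)
}

point_segment_dist <- function(pts, a, b) {
  ab <- b - a
  t <- ((pts[, 1L] - a[1L]) * ab[1L] + (pts[, 2L] - a[2L]) * ab[2L]) /
    sum(ab^2)
  t <- pmin(1, pmax(0, t))
  dx <- a[1L] + t * ab[1L] - pts[, 1L]
  dy <- a[2L] + t * ab[2L] - pts[, 2L]
  sqrt(dx^2 + dy^2)
}

#' Non-linear landmark warp of 2D points
#'
#' Delaunay-triangulates the source markers; each point inside the
#' triangulation is expressed in barycentric coordinates of its
#' containing triangle and those weights are applied to the paired
#' target markers. Points outside the triangulation use the affine
#' extension of the nearest triangle (distance to the triangle's
#' edges). Degenerate (collinear or < 3) markers give the identity warp
#' with a warning.
#'
#' @param points n x 2 matrix of coordinates (same frame as the source
#'   markers).
#' @param lm landmark set from [parse_alignment()] (or any
#'   list(`source`, `target`) of paired n x 2 matrices).
#' @return n x 2 matrix of corrected coordinates.
#' @export
warp_points <- function(points, lm) {
  points <- as.matrix(points)
  src <- lm$source; tgt <- lm$target
  if (is.null(src) || nrow(src) < 3L) {
    if (!is.null(src) && nrow(src) > 0L)
      warning("fewer than 3 landmarks; applying identity warp")
    return(points)
  }
  dt <- delaunay_tris(src[, 1L], src[, 2L])
  if (is.null(dt)) {
    warning("degenerate (collinear) landmarks; applying identity warp")
    return(points)
  }
  ## map deldir's deduplicated points back to marker rows
  row_of <- match(paste(dt$pts[, 1L], dt$pts[, 2L]),
                  paste(src[, 1L], src[, 2L]))
  out <- matrix(NA_real_, nrow(points), 2L)
  n_tri <- nrow(dt$tris)
  bary <- lapply(seq_len(n_tri), function(t3)
    barycentric(points, dt$pts[dt$tris[t3, ], , drop = FALSE]))
  ## minimal barycentric coordinate per triangle: >= 0 means inside
  minw <- vapply(bary, function(w) pmin(w[, 1L], w[, 2L], w[, 3L]),
                 numeric(nrow(points)))
  minw <- matrix(minw, nrow = nrow(points))
  best <- max.col(minw, ties.method = "first")
  inside <- minw[cbind(seq_len(nrow(points)), best)] >= -1e-9
  apply_tri <- function(i, t3) {
    w <- bary[[t3]][i, , drop = FALSE]
    tv <- tgt[row_of[dt$tris[t3, ]], , drop = FALSE]
    w %*% tv
  }
  for (i in which(inside)) out[i, ] <- apply_tri(i, best[i])
  out_idx <- which(!inside)
  if (length(out_idx)) {
    ## nearest triangle by edge distance; then its affine extension
    dmin <- matrix(Inf, length(out_idx), n_tri)
    for (t3 in seq_len(n_tri)) {
      tri <- dt$pts[dt$tris[t3, ], , drop = FALSE]
      p <- points[out_idx, , drop = FALSE]
      dmin[, t3] <- pmin(point_segment_dist(p, tri[1L, ], tri[2L, ]),
                         point_segment_dist(p, tri[2L, ], tri[3L, ]),
                         point_segment_dist(p, tri[1L, ], tri[3L, ]))
    }
    nearest <- max.col(-dmin, ties.method = "first")
    for (ii in seq_along(out_idx))
      out[out_idx[ii], ] <- apply_tri(out_idx[ii], nearest[ii])
  }
  out
}

#' Transform corrected section coordinates to 3D atlas coordinates
#'
#' Coordinates are normalized by the image width/height to `[0, 1]`,
#' the homogeneous vector `(x_norm, y_norm, 1)` is multiplied by the
#' anchor matrix `rbind(u, v, o)` (giving `o + x_norm u + y_norm v`),
#' and the result is optionally passed through a 4x4 homogeneous atlas
#' matrix to voxel-scaled, origin-aligned coordinates.
#'
#' @param coords2d n x 2 corrected image coordinates.
#' @param anchor a section anchor from [parse_alignment()].
#' @param atlas_matrix 4x4 homogeneous transform (default identity).
#' @return n x 3 matrix of atlas coordinates.
#' @export
to_ccf <- function(coords2d, anchor, atlas_matrix = diag(4)) {
  coords2d <- as.matrix(coords2d)
  h <- cbind(coords2d[, 1L] / anchor$width, coords2d[, 2L] / anchor$height,
             rep(1, nrow(coords2d)))
  xyz <- h %*% anchor$matrix
  hz <- cbind(xyz, 1) %*% t(atlas_matrix)
  hz[, 1:3, drop = FALSE] / hz[, 4L]
}

#' Annotation volume lookup
#'
#' Voxel index = `floor(coord / voxel_um)` per axis (0-based, half-open
#' voxels); coordinates outside the volume map to label 0 ("outside").
#'
#' @param coords3d n x 3 atlas coordinates in um.
#' @param vol list(`labels` 3D integer array indexed `[x, y, z]`,
#'   `voxel_um` voxel size (default 25), optional `region_names` named
#'   map label -> region name).
#' @return integer region label per cell (with a `region` attribute of
#'   names when `region_names` is present).
#' @export
annotate_regions <- function(coords3d, vol) {
  coords3d <- as.matrix(coords3d)
  voxel <- vol$voxel_um %||% 25
  d <- dim(vol$labels)
  idx <- floor(coords3d / voxel)
  ok <- idx[, 1L] >= 0 & idx[, 1L] < d[1L] &
        idx[, 2L] >= 0 & idx[, 2L] < d[2L] &
        idx[, 3L] >= 0 & idx[, 3L] < d[3L]
  lab <- integer(nrow(coords3d))
  lab[ok] <- vol$labels[idx[ok, , drop = FALSE] + 1L]
  if (!is.null(vol$region_names))
    attr(lab, "region") <- unname(vol$region_names[as.character(lab)])
  lab
}

#' Full registration of cell centroids to the atlas
#'
#' Convenience wrapper: landmark warp (when landmarks exist), anchor
#' affine, atlas matrix, and region annotation for one section.
#'
#' @param coords2d n x 2 cell centroids in image coordinates.
#' @param alignment result of [parse_alignment()].
#' @param section section name.
#' @param vol annotation volume (see [annotate_regions()]), optional.
#' @param atlas_matrix 4x4 homogeneous transform (default identity).
#' @return list(`ccf` n x 3 coordinates, `region` labels or `NULL`).
#' @export
register_section <- function(coords2d, alignment, section, vol = NULL,
                             atlas_matrix = diag(4)) {
  anchor <- alignment$anchors[[section]]
  if (is.null(anchor))
    stop_merscape("no anchor for section '", section, "'",
                  class = "merscape_consistency_error")
  lm <- alignment$landmarks[[section]]
  corrected <- if (!is.null(lm) && nrow(lm$source) >= 3L)
    warp_points(coords2d, lm) else as.matrix(coords2d)
  ccf <- to_ccf(corrected, anchor, atlas_matrix)
  list(ccf = ccf,
       region = if (!is.null(vol)) annotate_regions(ccf, vol) else NULL)
}
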