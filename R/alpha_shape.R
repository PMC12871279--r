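## alpha-shape cell boundaries: per z-plane 2D alpha shapes of the
## transcript positions of a cell, stacked into a pseudo-3D boundary

## Delaunay triangles via deldir; returns matrix of vertex indices
## (rows = triangles) or NULL for degenerate input.
delaunay_tris <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3L) return(NULL)
  d <- try(suppressMessages(deldir::deldir(pts[, 1L], pts[, 2L])),
           silent = TRUE)
  if (inherits(d, "try-error")) return(NULL)
  tl <- try(deldir::triang.list(d), silent = TRUE)
  if (inherits(tl, "try-error") || !length(tl)) return(NULL)
  tris <- do.call(rbind, lapply(tl, function(t3) t3$ptNum))
  tris <- tris[!is.na(rowSums(tris)), , drop = FALSE]
  if (!nrow(tris)) return(NULL)
  list(tris = tris, pts = pts)
}

circumradius <- function(p1, p2, p3) {
  a <- sqrt(sum((p2 - p3)^2)); b <- sqrt(sum((p1 - p3)^2))
  cc <- sqrt(sum((p1 - p2)^2))
  ar <- abs((p2[1L] - p1[1L]) * (p3[2L] - p1[2L]) -
            (p3[1L] - p1[1L]) * (p2[2L] - p1[2L])) / 2
  if (ar < 1e-12) return(Inf)
  a * b * cc / (4 * ar)
}

## keep triangles with circumradius <= r; classify the boundary
alpha_complex <- function(dt, r) {
  cr <- apply(dt$tris, 1L, function(tr)
    circumradius(dt$pts[tr[1L], ], dt$pts[tr[2L], ], dt$pts[tr[3L], ]))
  dt$tris[cr <= r, , drop = FALSE]
}

## boundary edges = edges used by exactly one kept triangle
boundary_edges <- function(tris) {
  if (is.null(tris) || !nrow(tris)) return(NULL)
  e <- rbind(tris[, c(1L, 2L)], tris[, c(2L, 3L)], tris[, c(1L, 3L)])
  e <- t(apply(e, 1L, sort))
  key <- paste(e[, 1L], e[, 2L])
  e[!(key %in% key[duplicated(key)]), , drop = FALSE]
}

## do the boundary edges form exactly one simple closed cycle?
single_closed_cycle <- function(be) {
  if (is.null(be) || nrow(be) < 3L) return(FALSE)
  verts <- unique(as.vector(be))
  deg <- table(as.vector(be))
  if (any(deg != 2L)) return(FALSE)
  if (length(verts) != nrow(be)) return(FALSE)
  ## connectivity: walk the cycle from the first edge
  length(trace_cycle(be)) == length(verts)
}

## walk a degree-2 edge set into an ordered vertex cycle
trace_cycle <- function(be) {
  adj <- split(c(be[, 2L], be[, 1L]), c(be[, 1L], be[, 2L]))
  start <- be[1L, 1L]
  cyc <- start
  prev <- NA_integer_
  cur <- start
  repeat {
    nb <- adj[[as.character(cur)]]
    nxt <- nb[is.na(prev) | nb != prev][1L]
    if (is.na(nxt) || nxt == start) break
    cyc <- c(cyc, nxt)
    prev <- cur
    cur <- nxt
    if (length(cyc) > 2L * nrow(be)) break  # safety
  }
  cyc
}

## connected components of triangles sharing edges; returns component id
tri_components <- function(tris) {
  n <- nrow(tris)
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- rbind(
    data.frame(k = ekey(tris[, 1L], tris[, 2L]), t = seq_len(n)),
    data.frame(k = ekey(tris[, 2L], tris[, 3L]), t = seq_len(n)),
    data.frame(k = ekey(tris[, 1L], tris[, 3L]), t = seq_len(n)))
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  for (grp in split(edges$t, edges$k)) {
    if (length(grp) > 1L) {
      r <- find(grp[1L])
      for (j in grp[-1L]) comp[find(j)] <- r
    }
  }
  vapply(seq_len(n), find, 0L)
}

## 2D alpha shape of one plane's points at circumradius cutoff r:
## largest-area single closed polygon, or NULL
alpha_shape_polygon <- function(dt, r) {
  kept <- alpha_complex(dt, r)
  if (!nrow(kept)) return(NULL)
  comp <- tri_components(kept)
  polys <- lapply(unique(comp), function(ci) {
    be <- boundary_edges(kept[comp == ci, , drop = FALSE])
    if (!single_closed_cycle(be)) return(NULL)
    v <- dt$pts[trace_cycle(be), , drop = FALSE]
    list(vertices = v, area = polygon_area(v))
  })
  polys <- Filter(Negate(is.null), polys)
  if (!length(polys)) return(NULL)
  polys[[which.max(vapply(polys, function(p) p$area, 0))]]
}

## TRUE if the alpha shape at cutoff r is exactly one closed polygon
is_single_polygon <- function(dt, r) {
  kept <- alpha_complex(dt, r)
  if (!nrow(kept)) return(FALSE)
  if (length(unique(tri_components(kept))) != 1L) return(FALSE)
  single_closed_cycle(boundary_edges(kept))
}

#' Alpha-shape boundary stack for one cell
#'
#' On each z-plane with at least three non-collinear transcript
#' positions, the alpha parameter is searched by bisection (30
#' iterations over circumradius cutoffs in `[0, diameter]`, ties toward
#' smaller alpha) for the maximum alpha — equivalently the minimum
#' circumradius cutoff — whose alpha shape is a single closed polygon.
#' That alpha is then multiplied by `alpha_scale` (default 0.75),
#' loosening the shape toward biologically realistic outlines; if the
#' scaled alpha yields several components, the largest-area component is
#' kept. Planes with fewer than three usable points contribute no
#' polygon; a cell with no usable plane gets a null boundary.
#'
#' @param spots_of_cell [spot_table] rows belonging to one cell.
#' @param alpha_scale scale applied to the searched alpha (default 0.75).
#' @param n_iter bisection iterations (default 30).
#' @return an object of class `cell_polygons`: list(`planes` = list of
#'   list(`z`, `vertices`, `area`, `centroid`), `alpha_used` (per-plane
#'   alpha actually applied, as 1/circumradius), `alpha_scale`).
#' @export
build_cell_polygons <- function(spots_of_cell, alpha_scale = 0.75,
                                n_iter = 30L) {
  planes <- list()
  alpha_used <- numeric(0)
  for (zv in sort(unique(spots_of_cell$z))) {
    sel <- spots_of_cell$z == zv
    dt <- delaunay_tris(spots_of_cell$x[sel], spots_of_cell$y[sel])
    if (is.null(dt)) next
    diam <- max(dist(dt$pts))
    lo <- 0; hi <- diam
    if (!is_single_polygon(dt, hi)) next  # degenerate triangulation
    for (i in seq_len(n_iter)) {
      mid <- (lo + hi) / 2
      if (is_single_polygon(dt, mid)) hi <- mid else lo <- mid
    }
    r_min <- hi
    r_used <- if (alpha_scale > 0) r_min / alpha_scale else r_min
    poly <- alpha_shape_polygon(dt, r_used)
    if (is.null(poly)) poly <- alpha_shape_polygon(dt, diam)
    if (is.null(poly)) next
    planes[[length(planes) + 1L]] <-
      list(z = zv, vertices = poly$vertices, area = poly$area,
           centroid = polygon_centroid(poly$vertices))
    alpha_used <- c(alpha_used, if (r_used > 0) 1 / r_used else Inf)
  }
  structure(list(planes = planes, alpha_used = alpha_used,
                 alpha_scale = alpha_scale),
            class = "cell_polygons")
}

#' @export
print.cell_polygons <- function(x, ...) {
  cat(sprintf("<cell_polygons> %d plane(s), alpha_scale %.2f\n",
              length(x$planes), x$alpha_scale))
  invisible(x)
}

#' Pseudo-3D geometry of a polygon stack
#'
#' Volume is the sum of plane areas times the z spacing; the reported 2D
#' area is the maximum single-plane polygon area; the centroid is the
#' area-weighted mean of per-plane polygon centroids (z included).
#'
#' @param polys a [cell_polygons] stack.
#' @param z_spacing plane spacing in um.
#' @return list(`volume_um3`, `area_um2`, `centroid` = `c(x, y, z)`).
#' @export
compute_geometry <- function(polys, z_spacing = 1.5) {
  if (!length(polys$planes))
    return(list(volume_um3 = 0, area_um2 = 0,
                centroid = c(NA_real_, NA_real_, NA_real_)))
  areas <- vapply(polys$planes, function(p) p$area, 0)
  cents <- t(vapply(polys$planes, function(p) c(p$centroid, p$z),
                    numeric(3L)))
  w <- if (sum(areas) > 0) areas / sum(areas) else rep(1 / length(areas),
                                                       length(areas))
  list(volume_um3 = sum(areas) * z_spacing,
       area_um2 = max(areas),
       centroid = as.numeric(colSums(cents * w)))
}

#' Is a polygon ring simple (non-self-intersecting)?
#'
#' Brute-force segment intersection check used by the test-suite
#' invariants; adjacent segments sharing an endpoint are allowed.
#' @param v n x 2 vertex matrix (unclosed ring).
#' @return logical.
#' @export
polygon_is_simple <- function(v) {
  n <- nrow(v)
  if (n < 3L) return(FALSE)
  seg <- cbind(v, v[c(2:n, 1L), , drop = FALSE])
  inter <- function(a, b) {
    d1 <- a[3:4] - a[1:2]; d2 <- b[3:4] - b[1:2]
    den <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
    if (abs(den) < 1e-14) return(FALSE)
    t <- ((b[1L] - a[1L]) * d2[2L] - (b[2L] - a[2L]) * d2[1L]) / den
    u <- ((b[1L] - a[1L]) * d1[2L] - (b[2L] - a[2L]) * d1[1L]) / den
    t > 1e-12 && t < 1 - 1e-12 && u > 1e-12 && u < 1 - 1e-12
  }
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through the closure
      if (inter(seg[i, ], seg[j, ])) return(FALSE)
    }
  }
  TRUE
}
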