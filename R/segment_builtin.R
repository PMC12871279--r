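## built-in per-tile segmenter: Otsu threshold + Euclidean distance
## transform + watershed seeded on density maxima. This is the offline
## stand-in for an external volumetric Cellpose backend.

#' Otsu threshold of an image
#' @param values numeric vector/array.
#' @param n_bins histogram bins.
#' @return scalar threshold.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  v <- as.vector(values)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1L])
  h <- tabulate(pmin(n_bins, 1L + floor((v - rng[1L]) / diff(rng) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  rng[1L] + k / n_bins * diff(rng)
}

## 1D squared Euclidean distance transform (Felzenszwalb-Huttenlocher)
edt1d <- function(f) {
  n <- length(f)
  d <- numeric(n); v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
      if (is.nan(s)) s <- -Inf  # two infinite parabolas: drop the older
      if (s <= z[k]) {
        k <- k - 1L
        if (k == 0L) { s <- -Inf; break }
      } else break
    }
    k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Euclidean distance transform of a 3D mask
#'
#' Distance (in voxel units, anisotropy via `spacing`) from each TRUE
#' voxel to the nearest FALSE voxel.
#'
#' @param mask logical 3D array `[z, y, x]`.
#' @param spacing voxel spacing `(z, y, x)`.
#' @return numeric array of distances.
#' @export
distance_transform <- function(mask, spacing = c(1, 1, 1)) {
  d <- dim(mask)
  f <- array(ifelse(mask, Inf, 0), d)
  for (axis in 1:3) {
    if (d[axis] == 1L) next
    sp2 <- spacing[axis]^2
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(f, perm)
    m <- matrix(a, nrow = dim(a)[1L])
    for (j in seq_len(ncol(m))) {
      col <- m[, j]
      if (all(is.infinite(col)) || all(col == 0)) next
      m[, j] <- edt1d(col / sp2) * sp2
    }
    a[] <- m
    f <- aperm(a, order(perm))
  }
  sqrt(f)
}

## linear-index neighbour offsets (26-connectivity) with border masks
neighbour_shifts <- function(d) {
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  iz <- rep(seq_len(d[1L]), times = d[2L] * d[3L])
  iy <- rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L])
  ix <- rep(seq_len(d[3L]), each = d[1L] * d[2L])
  list(offs = offs, iz = iz, iy = iy, ix = ix)
}

## local maxima (26-neighbourhood, plateaus allowed) above a threshold
local_maxima3d <- function(values, threshold) {
  d <- dim(values)
  ns <- neighbour_shifts(d)
  is_max <- values > threshold
  for (o in seq_len(nrow(ns$offs))) {
    zz <- ns$iz + ns$offs$dz[o]; yy <- ns$iy + ns$offs$dy[o]
    xx <- ns$ix + ns$offs$dx[o]
    ok <- zz >= 1L & zz <= d[1L] & yy >= 1L & yy <= d[2L] &
          xx >= 1L & xx <= d[3L]
    nb <- rep(-Inf, length(ns$iz))
    nb[ok] <- values[cbind(zz[ok], yy[ok], xx[ok])]
    is_max <- is_max & (as.vector(values) >= nb)
  }
  array(is_max, d)
}

## connected-component labelling of a mask (26-connectivity), BFS
label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  ns <- neighbour_shifts(d)
  nxt <- 0L
  todo <- which(mask)
  for (s in todo) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s; lab[s] <- nxt
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      cz <- ((cur - 1L) %% d[1L]) + 1L
      cy <- (((cur - 1L) %/% d[1L]) %% d[2L]) + 1L
      cx <- ((cur - 1L) %/% (d[1L] * d[2L])) + 1L
      for (o in seq_len(nrow(ns$offs))) {
        zz <- cz + ns$offs$dz[o]; yy <- cy + ns$offs$dy[o]
        xx <- cx + ns$offs$dx[o]
        ok <- zz >= 1L & zz <= d[1L] & yy >= 1L & yy <= d[2L] &
              xx >= 1L & xx <= d[3L]
        if (!any(ok)) next
        lin <- (xx[ok] - 1L) * d[1L] * d[2L] + (yy[ok] - 1L) * d[1L] + zz[ok]
        new <- lin[mask[lin] & lab[lin] == 0L]
        if (length(new)) { lab[new] <- nxt; queue <- c(queue, new) }
      }
      queue <- unique(queue)
    }
  }
  lab
}

## seeded watershed: flood foreground outward from the seed labels in
## synchronous rounds; each unlabeled voxel takes the label of its
## highest-priority (deepest distance-transform) labeled neighbour
watershed_flood <- function(priority, seeds, mask, max_pass = 10000L) {
  d <- dim(priority)
  lab <- seeds
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  remaining <- which(mask & lab == 0L)
  if (!length(remaining)) return(lab)
  for (pass in seq_len(max_pass)) {
    cz <- ((remaining - 1L) %% d[1L]) + 1L
    cy <- (((remaining - 1L) %/% d[1L]) %% d[2L]) + 1L
    cx <- ((remaining - 1L) %/% (d[1L] * d[2L])) + 1L
    best <- integer(length(remaining))
    best_p <- rep(-Inf, length(remaining))
    for (o in seq_len(nrow(offs))) {
      zz <- cz + offs$dz[o]; yy <- cy + offs$dy[o]; xx <- cx + offs$dx[o]
      ok <- zz >= 1L & zz <= d[1L] & yy >= 1L & yy <= d[2L] &
            xx >= 1L & xx <= d[3L]
      if (!any(ok)) next
      lin <- (xx[ok] - 1L) * d[1L] * d[2L] + (yy[ok] - 1L) * d[1L] + zz[ok]
      l <- lab[lin]
      p <- priority[lin]
      upd <- l > 0L & p > best_p[ok]
      if (any(upd)) {
        iok <- which(ok)[upd]
        best[iok] <- l[upd]
        best_p[iok] <- p[upd]
      }
    }
    hit <- best > 0L
    if (!any(hit)) break
    lab[remaining[hit]] <- best[hit]
    remaining <- remaining[!hit]
    if (!length(remaining)) break
  }
  lab
}

#' Segment one tile into a label volume
#'
#' The `"builtin"` backend thresholds the smoothed density image (Otsu),
#' computes the Euclidean distance transform of the foreground, seeds on
#' 26-neighbourhood local maxima of the density, and floods a watershed
#' on the distance transform. It is a deterministic test stand-in for an
#' external volumetric Cellpose backend (`backend = "cellpose"` is a
#' pluggable hook and errors if the external tool is unavailable).
#'
#' @param dapi [volume_image] nuclear stain (may be `NULL`; only the
#'   geometry is used by the builtin backend).
#' @param density [volume_image] smoothed density stain on the same grid.
#' @param backend `"builtin"` or `"cellpose"`.
#' @return a `label_volume`: list(labels [z,y,x] integer array, origin,
#'   voxel_size); 0 = background, labels compacted to 1..K.
#' @export
segment_tile <- function(dapi, density, backend = "builtin") {
  if (!is.null(dapi) &&
      (!all(dim(dapi$values) == dim(density$values)) ||
       any(abs(dapi$voxel_size - density$voxel_size) > 1e-9)))
    stop_merscape("dapi and density geometries differ",
                  class = "merscape_config_error")
  if (identical(backend, "cellpose"))
    stop_merscape("cellpose backend not available in this installation; ",
                  "use backend = 'builtin'", class = "merscape_config_error")
  if (!identical(backend, "builtin"))
    stop_merscape("unknown segmentation backend: ", backend,
                  class = "merscape_config_error")
  v <- density$values
  if (all(v == 0)) {
    return(structure(list(labels = array(0L, dim(v)), origin = density$origin,
                          voxel_size = density$voxel_size),
                     class = "label_volume"))
  }
  thr <- otsu_threshold(v[v > 0])
  mask <- v > thr
  seeds_mask <- local_maxima3d(v, thr) & mask
  seeds <- label_components(seeds_mask)
  dt <- distance_transform(mask)
  lab <- watershed_flood(dt, seeds, mask)
  ## compact label ids
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids)) lab[] <- match(lab, c(0L, ids), nomatch = 1L) - 1L
  structure(list(labels = array(as.integer(lab), dim(v)),
                 origin = density$origin, voxel_size = density$voxel_size),
            class = "label_volume")
}
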