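## the automated four-step pipeline: segmentation -> low-quality
## filtering -> doublet flagging -> mapping-score filtering. Filters
## annotate boolean columns rather than deleting cells, so diagnostics
## stay reproducible from one artifact; rows are dropped only on export.

#' Crop a volume image to an axis-aligned x/y rectangle
#' @param img a [volume_image] (or `label_volume`).
#' @param rect `c(xmin, xmax, ymin, ymax)` in um.
#' @return the cropped image with an adjusted origin.
#' @export
crop_volume <- function(img, rect) {
  vs <- img$voxel_size; org <- img$origin
  d <- dim(img$values %||% img$labels)
  ix <- pmax(1L, pmin(d[3L], 1L + floor((c(rect[1L], rect[2L] - 1e-9) - org[1L]) / vs[1L])))
  iy <- pmax(1L, pmin(d[2L], 1L + floor((c(rect[3L], rect[4L] - 1e-9) - org[2L]) / vs[2L])))
  vals <- (img$values %||% img$labels)[, iy[1L]:iy[2L], ix[1L]:ix[2L],
                                       drop = FALSE]
  new_origin <- c(org[1L] + (ix[1L] - 1L) * vs[1L],
                  org[2L] + (iy[1L] - 1L) * vs[2L], org[3L])
  if (!is.null(img$values))
    volume_image(vals, new_origin, vs)
  else structure(list(labels = vals, origin = new_origin, voxel_size = vs),
                 class = "label_volume")
}

#' Run the automated processing pipeline on one section
#'
#' Stages, in order: (1) density-stain construction, tiling, per-tile
#' segmentation, transcript assignment and stitching, alpha-shape
#' boundaries, cell-matrix assembly; (2) per-cell QC metrics and the
#' fixed low-quality filter; (3) doublet scoring and quantile
#' thresholding; (4) adaptive filtering of label-transfer mapping
#' scores when provided. Every filter is recorded as a boolean
#' `keep_*` column in `cell_meta`; [export_cells()] drops flagged rows.
#'
#' @param spots a [spot_table] for one section.
#' @param dapi optional [volume_image]; when `NULL` only the density
#'   stain drives the builtin segmenter.
#' @param mapping_scores optional data.frame(`cell_id`, `supertype`,
#'   `avg_correlation`) from an external label-transfer tool.
#' @param voxel_um density grid resolution (default 2).
#' @param z_spacing_um imaging-plane spacing (default 1.5).
#' @param tile_size,overlap tiling in um (defaults 350 / 50).
#' @param qc a [qc_thresholds] object.
#' @param density_p a [density_params] object.
#' @param seed RNG seed for the doublet scorer.
#' @param backend segmentation backend (default `"builtin"`).
#' @return list(`cells` [cell_matrix] with flag columns, `assignments`,
#'   `metrics`, `doublets`, `mapping`, `log` per-stage removal counts).
#' @export
run_pipeline <- function(spots, dapi = NULL, mapping_scores = NULL,
                         voxel_um = 2, z_spacing_um = 1.5,
                         tile_size = 350, overlap = 50,
                         qc = qc_thresholds(), density_p = density_params(),
                         seed = 0L, backend = "builtin") {
  log <- list()
  ## ---- stage 1: segmentation ----
  if (!is.null(dapi)) {
    ## bin on the imaging (DAPI) grid so stains and density align
    d <- dim(dapi$values)
    voxel_um <- dapi$voxel_size[1L]
    z_spacing_um <- dapi$voxel_size[3L]
    origin <- dapi$origin
    dims <- d
    ext <- c(origin[1L], origin[1L] + d[3L] * voxel_um,
             origin[2L], origin[2L] + d[2L] * dapi$voxel_size[2L])
  } else {
    origin <- c(0, 0, 0)
    ext <- c(0, max(spots$x) + voxel_um, 0, max(spots$y) + voxel_um)
    zmax <- max(spots$z) + z_spacing_um / 2
    dims <- c(max(1L, ceiling(zmax / z_spacing_um)),
              ceiling((ext[4L]) / voxel_um), ceiling((ext[2L]) / voxel_um))
  }
  binned <- bin_transcripts(spots, origin = origin, dim_zyx = dims,
                            voxel_size = c(voxel_um, voxel_um, z_spacing_um))
  density <- smooth_density(binned, density_p)
  tiles <- make_tiles(ext, tile_size = tile_size, overlap = overlap)
  per_tile <- lapply(seq_len(nrow(tiles)), function(ti) {
    rect <- as.numeric(tiles[ti, c("xmin", "xmax", "ymin", "ymax")])
    dens_t <- crop_volume(density, rect)
    dapi_t <- if (!is.null(dapi)) crop_volume(dapi, rect) else NULL
    labs <- segment_tile(dapi_t, dens_t, backend = backend)
    in_tile <- spots$x >= rect[1L] & spots$x < rect[2L] &
               spots$y >= rect[3L] & spots$y < rect[4L]
    assign_transcripts(spots[in_tile, , drop = FALSE], labs,
                       tile_index = tiles$tile_index[ti])
  })
  assignments <- stitch_and_merge(per_tile)
  log$n_transcripts <- nrow(spots)
  log$n_assigned <- sum(!is.na(assignments$cell_id))

  ## snap z to plane centers so per-plane polygons see co-planar points
  spots_plane <- spots
  spots_plane$z <- (floor(spots$z / z_spacing_um) + 0.5) * z_spacing_um
  cell_of <- assignments$cell_id[match(spots$transcript_id,
                                       assignments$transcript_id)]
  polys <- list()
  for (cc in sort(unique(cell_of[!is.na(cell_of)]))) {
    sel <- which(!is.na(cell_of) & cell_of == cc & !spots$is_blank)
    if (length(sel) >= 3L)
      polys[[cc]] <- build_cell_polygons(spots_plane[sel, , drop = FALSE])
  }
  cells <- assemble_cell_matrix(assignments, spots, polygons = polys,
                                params = list(z_spacing_um = z_spacing_um,
                                              voxel_um = voxel_um,
                                              tile_size = tile_size,
                                              overlap = overlap,
                                              backend = backend,
                                              seed = seed))
  log$n_cells <- nrow(cells$counts)

  ## ---- stage 2: low-quality filtering ----
  metrics <- compute_cell_metrics(cells)
  keep_qc <- apply_quality_filter(metrics, qc)
  cells$cell_meta$keep_qc <- keep_qc
  log$removed_qc <- sum(!keep_qc)

  ## ---- stage 3: doublet flagging ----
  doublets <- NULL
  keep_doublet <- rep(TRUE, nrow(cells$counts))
  if (nrow(cells$counts) >= 50L) {
    scores <- score_doublets(cells, seed = seed)
    call <- call_doublets(scores)
    keep_doublet <- !call$is_doublet
    doublets <- list(scores = scores, threshold = call$threshold)
  } else {
    warning("fewer than 50 cells; doublet stage skipped")
  }
  cells$cell_meta$keep_doublet <- keep_doublet
  log$removed_doublet <- sum(!keep_doublet)

  ## ---- stage 4: mapping-score filtering ----
  mapping <- NULL
  keep_map <- rep(TRUE, nrow(cells$counts))
  if (!is.null(mapping_scores)) {
    idx <- match(cells$cell_meta$production_cell_id, mapping_scores$cell_id)
    ms <- mapping_scores[idx[!is.na(idx)], , drop = FALSE]
    ## only cells passing the earlier stages enter the adaptive filter
    upstream <- keep_qc & keep_doublet
    sel <- which(!is.na(idx) & upstream)
    ms_sel <- mapping_scores[idx[sel], , drop = FALSE]
    if (nrow(ms_sel) >= 3L) {
      fm <- filter_mapped_cells(ms_sel)
      keep_map[sel] <- fm$keep
      mapping <- fm$report
    }
  }
  cells$cell_meta$keep_mapping <- keep_map
  log$removed_mapping <- sum(!keep_map)
  log$n_final <- sum(keep_qc & keep_doublet & keep_map)

  list(cells = cells, assignments = assignments, metrics = metrics,
       doublets = doublets, mapping = mapping, log = log)
}

#' Export only the cells passing every recorded filter
#' @param cells a [cell_matrix] with `keep_*` columns in `cell_meta`.
#' @return a filtered [cell_matrix].
#' @export
export_cells <- function(cells) {
  flags <- grep("^keep_", names(cells$cell_meta), value = TRUE)
  keep <- Reduce(`&`, cells$cell_meta[flags], rep(TRUE, nrow(cells$counts)))
  cell_matrix(cells$counts[keep, , drop = FALSE],
              cells$cell_meta[keep, , drop = FALSE],
              cells$gene_meta, cells$uns)
}
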