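## core data model: cell-by-gene matrices with metadata, h5ad-style I/O

#' Construct a cell-by-gene matrix container
#'
#' Holds segmented transcript counts (cells x genes, non-negative
#' integers), per-cell metadata (centroids, volume, area, ids), per-gene
#' metadata, and an unstructured slot carrying cell boundary polygons
#' (GeoJSON), segmentation parameters and the package version.
#'
#' @param counts integer matrix, cells in rows (rownames = production
#'   cell ids), genes in columns (colnames = gene names).
#' @param cell_meta data.frame with one row per cell.
#' @param gene_meta data.frame with one row per gene.
#' @param uns named list of unstructured metadata.
#' @return an object of class `cell_matrix`.
#' @export
cell_matrix <- function(counts, cell_meta, gene_meta, uns = list()) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (nrow(counts) != nrow(cell_meta) || ncol(counts) != nrow(gene_meta))
    stop_merscape("counts dimensions do not match metadata",
                  class = "merscape_consistency_error")
  if (nrow(counts) && any(counts < 0))
    stop_merscape("negative counts", class = "merscape_consistency_error")
  if (anyDuplicated(cell_meta$production_cell_id))
    stop_merscape("production_cell_id not unique",
                  class = "merscape_consistency_error")
  structure(list(counts = counts, cell_meta = cell_meta,
                 gene_meta = gene_meta, uns = uns),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> %d cells x %d genes, %d transcripts segmented\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' Assemble a cell-by-gene matrix from assignments, spots and polygons
#'
#' Collects per-cell counts from a stitched assignment table. Blank
#' codewords are carried through assignment (they feed per-cell QC via
#' the `n_blank` column) but excluded from the counts matrix. Geometry
#' (volume, 2D area, polygon centroid) is taken from the per-cell
#' boundary stacks when provided.
#'
#' @param assignments assignment table from [stitch_and_merge()] or
#'   [assign_transcripts()]: columns `transcript_id`, `cell_id`,
#'   `tile_index`.
#' @param spots the [spot_table] the assignments refer to.
#' @param polygons named list of [cell_polygons] keyed by cell id
#'   (optional).
#' @param params named list of run parameters echoed into `uns`;
#'   `params$z_spacing_um` (default 1.5) sets the plane spacing used for
#'   volumes.
#' @return a [cell_matrix].
#' @export
assemble_cell_matrix <- function(assignments, spots, polygons = list(),
                                 params = list()) {
  z_spacing <- params$z_spacing_um %||% 1.5
  idx <- match(assignments$transcript_id, spots$transcript_id)
  if (anyNA(idx))
    stop_merscape("assignment references unknown transcript id ",
                  assignments$transcript_id[which(is.na(idx))[1L]],
                  class = "merscape_consistency_error")
  cell_of <- rep(NA_character_, nrow(spots))
  cell_of[idx] <- as.character(assignments$cell_id)

  genes <- sort(unique(spots$gene[!spots$is_blank]))
  cells <- sort(unique(cell_of[!is.na(cell_of)]))
  counts <- matrix(0L, length(cells), length(genes),
                   dimnames = list(cells, genes))
  seg <- !is.na(cell_of) & !spots$is_blank
  if (any(seg)) {
    tab <- table(factor(cell_of[seg], levels = cells),
                 factor(spots$gene[seg], levels = genes))
    counts[] <- as.integer(tab)
  }

  ## per-cell metadata
  nb <- as.integer(table(factor(cell_of[!is.na(cell_of) & spots$is_blank],
                                levels = cells)))
  cen <- function(v) {
    s <- vapply(cells, function(cc) mean(v[seg & cell_of == cc]), 0)
    s[is.nan(s)] <- NA_real_
    s
  }
  geom <- lapply(cells, function(cc) {
    p <- polygons[[cc]]
    if (is.null(p)) list(volume_um3 = NA_real_, area_um2 = NA_real_,
                         centroid = c(NA_real_, NA_real_, NA_real_))
    else compute_geometry(p, z_spacing = z_spacing)
  })
  cell_meta <- data.frame(
    production_cell_id = cells,
    original_cell_id = sub("^.*-", "", cells),
    tx_centroid_x = cen(spots$x), tx_centroid_y = cen(spots$y),
    tx_centroid_z = cen(spots$z),
    poly_centroid_x = vapply(geom, function(g) g$centroid[1L], 0),
    poly_centroid_y = vapply(geom, function(g) g$centroid[2L], 0),
    poly_centroid_z = vapply(geom, function(g) g$centroid[3L], 0),
    volume_um3 = vapply(geom, function(g) g$volume_um3, 0),
    area_um2 = vapply(geom, function(g) g$area_um2, 0),
    n_blank = nb,
    stringsAsFactors = FALSE
  )
  rownames(cell_meta) <- cells

  unseg <- !spots$is_blank & is.na(cell_of)
  gene_meta <- data.frame(
    name = genes,
    n_cells_expressing = as.integer(colSums(counts > 0)),
    total_segmented = as.integer(colSums(counts)),
    total_unsegmented = as.integer(table(factor(spots$gene[unseg],
                                                levels = genes))),
    stringsAsFactors = FALSE
  )
  rownames(gene_meta) <- genes

  uns <- list(
    polygons_geojson = polygons_to_geojson(polygons),
    params = params,
    version = as.character(utils::packageVersion("merscape"))
  )
  cell_matrix(counts, cell_meta, gene_meta, uns)
}

#' Serialize per-cell polygon stacks as a GeoJSON FeatureCollection
#'
#' One feature per cell; the geometry is a `MultiPolygon` with one ring
#' per z-plane, and properties carry the cell id, the plane z values and
#' the alpha parameters used.
#'
#' @param polygons named list of [cell_polygons].
#' @return a single GeoJSON string.
#' @export
polygons_to_geojson <- function(polygons) {
  feats <- lapply(names(polygons), function(cc) {
    p <- polygons[[cc]]
    rings <- lapply(p$planes, function(pl) {
      v <- pl$vertices
      v <- rbind(v, v[1L, , drop = FALSE])  # close the ring
      list(lapply(seq_len(nrow(v)), function(i) c(v[i, 1L], v[i, 2L])))
    })
    list(type = "Feature",
         geometry = list(type = "MultiPolygon", coordinates = rings),
         properties = list(cell_id = cc,
                           z = vapply(p$planes, function(pl) pl$z, 0),
                           alpha_used = p$alpha_used %||% NA,
                           alpha_scale = p$alpha_scale %||% NA))
  })
  as.character(jsonlite::toJSON(
    list(type = "FeatureCollection", features = feats),
    auto_unbox = TRUE, digits = NA, null = "null"))
}

## ---- h5ad-style on-disk representation (rhdf5) ----

h5_set_attr <- function(fid, obj, name, value) {
  h5obj <- rhdf5::H5Oopen(fid, obj)
  on.exit(rhdf5::H5Oclose(h5obj))
  rhdf5::h5writeAttribute(value, h5obj, name, asScalar = length(value) == 1L)
}

h5_write_df <- function(fid, path, df, index_col) {
  rhdf5::h5createGroup(fid, path)
  rhdf5::h5write(rownames(df), fid, paste0(path, "/_index"))
  for (cn in names(df)) rhdf5::h5write(df[[cn]], fid, paste0(path, "/", cn))
  h5_set_attr(fid, path, "encoding-type", "dataframe")
  h5_set_attr(fid, path, "encoding-version", "0.2.0")
  h5_set_attr(fid, path, "_index", "_index")
  h5_set_attr(fid, path, "column-order", names(df))
}

#' Write a cell matrix to an h5ad-style HDF5 file
#'
#' The on-disk layout follows the anndata convention: `X` (cells x genes
#' counts, C order), `obs`, `var` (dataframe groups keyed by `_index`)
#' and `uns` (polygons GeoJSON, parameters, code version). The file
#' round-trips exactly through [read_cell_matrix()].
#'
#' @param m a [cell_matrix].
#' @param path output path (overwritten).
#' @export
write_cell_matrix <- function(m, path) {
  if (file.exists(path)) unlink(path)
  ok <- try(rhdf5::h5createFile(path), silent = TRUE)
  if (inherits(ok, "try-error") || !file.exists(path))
    stop_merscape("cannot write to ", path, class = "merscape_io_error")
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  fid <- rhdf5::H5Fopen(path)
  ## transpose so a C-order (python) reader sees cells x genes
  rhdf5::h5write(t(m$counts), fid, "X")
  h5_set_attr(fid, "X", "encoding-type", "array")
  h5_set_attr(fid, "X", "encoding-version", "0.2.0")
  h5_write_df(fid, "obs", m$cell_meta, "production_cell_id")
  h5_write_df(fid, "var", m$gene_meta, "name")
  rhdf5::h5createGroup(fid, "uns")
  rhdf5::h5write(m$uns$polygons_geojson %||% "", fid, "uns/polygons_geojson")
  rhdf5::h5write(as.character(jsonlite::toJSON(m$uns$params %||% list(),
                                               auto_unbox = TRUE, digits = NA)),
                 fid, "uns/params_json")
  rhdf5::h5write(m$uns$version %||% "", fid, "uns/version")
  h5_set_attr(fid, "/", "encoding-type", "anndata")
  h5_set_attr(fid, "/", "encoding-version", "0.1.0")
  invisible(path)
}

h5_read_df <- function(path, group) {
  ls <- rhdf5::h5ls(path)
  cols <- ls$name[ls$group == paste0("/", group)]
  idx <- as.character(rhdf5::h5read(path, paste0(group, "/_index")))
  out <- list()
  for (cn in setdiff(cols, "_index")) {
    v <- rhdf5::h5read(path, paste0(group, "/", cn))
    out[[cn]] <- if (is.array(v)) as.vector(v) else v
  }
  df <- as.data.frame(out, stringsAsFactors = FALSE, optional = TRUE)
  if (nrow(df) == 0L && length(idx)) df <- data.frame(row.names = idx)
  rownames(df) <- idx
  df
}

#' Read a cell matrix written by [write_cell_matrix()]
#' @param path h5ad-style HDF5 file.
#' @return a [cell_matrix].
#' @export
read_cell_matrix <- function(path) {
  if (!file.exists(path))
    stop_merscape("file not found: ", path, class = "merscape_io_error")
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  X <- rhdf5::h5read(path, "X")
  obs <- h5_read_df(path, "obs")
  var <- h5_read_df(path, "var")
  counts <- t(X)
  dimnames(counts) <- list(rownames(obs), rownames(var))
  uns <- list(
    polygons_geojson = as.character(rhdf5::h5read(path, "uns/polygons_geojson")),
    params = jsonlite::fromJSON(as.character(rhdf5::h5read(path, "uns/params_json")),
                                simplifyVector = TRUE),
    version = as.character(rhdf5::h5read(path, "uns/version"))
  )
  ## preserve canonical column order where present
  cm_cols <- c("production_cell_id", "original_cell_id", "tx_centroid_x",
               "tx_centroid_y", "tx_centroid_z", "poly_centroid_x",
               "poly_centroid_y", "poly_centroid_z", "volume_um3",
               "area_um2", "n_blank")
  if (all(cm_cols %in% names(obs))) obs <- obs[c(cm_cols, setdiff(names(obs), cm_cols))]
  gm_cols <- c("name", "n_cells_expressing", "total_segmented",
               "total_unsegmented")
  if (all(gm_cols %in% names(var))) var <- var[c(gm_cols, setdiff(names(var), gm_cols))]
  cell_matrix(counts, obs, var, uns)
}
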