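## transcript-to-cell assignment within tiles and the overlap merge rule
## used when stitching tiles back together

#' Assign transcripts to segmented labels
#'
#' Each transcript receives the label of its containing voxel (half-open
#' bins); label 0 or out-of-volume positions are unassigned. Cell ids
#' are globally unique production ids `"{section}-{tile}-{label}"`.
#'
#' @param spots a [spot_table].
#' @param labels a `label_volume` from [segment_tile()].
#' @param tile_index integer index of the tile (part of the cell id).
#' @return assignment table: data.frame(`transcript_id`, `cell_id`
#'   (`NA` = unassigned), `tile_index`), one row per transcript.
#' @export
assign_transcripts <- function(spots, labels, tile_index = 1L) {
  d <- dim(labels$labels)
  vs <- labels$voxel_size
  org <- labels$origin
  n <- nrow(spots)
  cell <- rep(NA_character_, n)
  if (n) {
    ix <- floor((spots$x - org[1L]) / vs[1L])
    iy <- floor((spots$y - org[2L]) / vs[2L])
    iz <- floor((spots$z - org[3L]) / vs[3L])
    ok <- ix >= 0 & ix < d[3L] & iy >= 0 & iy < d[2L] & iz >= 0 & iz < d[1L]
    lab <- integer(n)
    lab[ok] <- labels$labels[cbind(iz[ok] + 1L, iy[ok] + 1L, ix[ok] + 1L)]
    hit <- ok & lab > 0L
    cell[hit] <- sprintf("%s-%d-%d", spots$section_id[hit], tile_index,
                         lab[hit])
  }
  data.frame(transcript_id = spots$transcript_id, cell_id = cell,
             tile_index = rep(as.integer(tile_index), n),
             stringsAsFactors = FALSE)
}

#' Stitch per-tile assignments with the overlap merge rule
#'
#' Tiles are processed in increasing `tile_index` (deterministic
#' row-major order); the tile processed later is the "newer" one. For
#' each pair of cells sharing transcripts in an overlap, let
#' `s = shared / size(smaller cell)` (size = transcript count, ties
#' broken by lexicographic cell id). If `s > 0.5` (strictly) the smaller
#' cell's id is replaced by the larger cell's id; otherwise every
#' contested transcript is assigned to the newer tile's cell. The result
#' has at most one cell per transcript.
#'
#' @param per_tile list of assignment tables from [assign_transcripts()],
#'   one per tile.
#' @return a single assignment table covering every transcript seen in
#'   any tile, one row per transcript.
#' @export
stitch_and_merge <- function(per_tile) {
  ord <- order(vapply(per_tile, function(a) a$tile_index[1L] %||% 0L, 0L))
  per_tile <- per_tile[ord]
  assign_cell <- character(0)   # keyed by transcript id
  assign_tile <- integer(0)
  members <- list()             # cell id -> character vector of tids
  seen <- character(0)          # all transcript ids ever seen (as names)

  for (tab in per_tile) {
    tile <- tab$tile_index[1L] %||% 0L
    tids_all <- as.character(tab$transcript_id)
    seen <- union(seen, tids_all)
    keep <- !is.na(tab$cell_id)
    if (!any(keep)) next
    cells_new <- split(tids_all[keep], tab$cell_id[keep])
    for (nc in sort(names(cells_new))) {
      s_n <- cells_new[[nc]]
      cur_id <- nc
      repeat {
        prev <- assign_cell[s_n]
        prev <- prev[!is.na(prev) & prev != cur_id]
        if (!length(prev)) break
        other <- names(sort(table(prev), decreasing = TRUE))[1L]
        s_e <- members[[other]]
        shared <- intersect(s_n, s_e)
        ## smaller cell by transcript count, ties by lexicographic id
        n_pair <- c(length(s_n), length(s_e))
        ids <- c(cur_id, other)
        smaller <- if (n_pair[1L] != n_pair[2L]) which.min(n_pair)
                   else which.min(rank(ids, ties.method = "first"))
        s_frac <- length(shared) / n_pair[smaller]
        if (s_frac > 0.5) {
          larger_id <- ids[3L - smaller]
          if (smaller == 1L) {
            ## new cell absorbed into the existing one
            cur_id <- larger_id
            s_n <- union(members[[larger_id]], s_n)
          } else {
            ## existing cell absorbed into the new one
            s_n <- union(s_n, s_e)
            assign_cell[s_e] <- cur_id
            assign_tile[s_e] <- tile
            members[[other]] <- NULL
          }
        } else {
          ## contested transcripts go to the newer (current) tile's cell
          members[[other]] <- setdiff(s_e, shared)
          if (!length(members[[other]])) members[[other]] <- NULL
          assign_cell[shared] <- cur_id
          assign_tile[shared] <- tile
        }
      }
      members[[cur_id]] <- unique(c(members[[cur_id]], s_n))
      assign_cell[s_n] <- cur_id
      assign_tile[s_n] <- tile
    }
  }
  out_cell <- assign_cell[seen]
  out_tile <- assign_tile[seen]
  out_tile[is.na(out_tile)] <- 0L
  data.frame(transcript_id = as.integer(seen),
             cell_id = ifelse(is.na(out_cell), NA_character_,
                              unname(out_cell)),
             tile_index = unname(out_tile), stringsAsFactors = FALSE)
}
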