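## section tiling for memory-bounded, parallelizable segmentation

#' Tile a section extent into overlapping squares
#'
#' Covers the extent with `tile_size` x `tile_size` um tiles advancing
#' by `tile_size - overlap`, in deterministic row-major order from the
#' minimum corner (x fastest). The last tile per axis is shifted back so
#' it ends exactly at the extent edge; an extent smaller than one tile
#' yields a single tile covering the extent.
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` in um.
#' @param tile_size tile edge length, um (default 350).
#' @param overlap overlap width between adjacent tiles, um (default 50).
#' @return a data.frame of class `tile_set`: `tile_index`, `xmin`,
#'   `xmax`, `ymin`, `ymax`.
#' @export
make_tiles <- function(extent, tile_size = 350, overlap = 50) {
  if (!(tile_size > overlap && overlap >= 0))
    stop_merscape("need tile_size > overlap >= 0",
                  class = "merscape_config_error")
  stride <- tile_size - overlap
  axis_starts <- function(lo, hi) {
    w <- hi - lo
    if (w <= tile_size) return(list(starts = lo, size = w))
    n <- ceiling((w - tile_size) / stride) + 1
    s <- lo + (seq_len(n) - 1) * stride
    s <- pmin(s, hi - tile_size)
    list(starts = s, size = tile_size)
  }
  ax <- axis_starts(extent[1L], extent[2L])
  ay <- axis_starts(extent[3L], extent[4L])
  g <- expand.grid(x = ax$starts, y = ay$starts)  # x fastest = row-major
  out <- data.frame(tile_index = seq_len(nrow(g)),
                    xmin = g$x, xmax = g$x + ax$size,
                    ymin = g$y, ymax = g$y + ay$size)
  class(out) <- c("tile_set", "data.frame")
  attr(out, "tile_size") <- tile_size
  attr(out, "overlap") <- overlap
  out
}
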