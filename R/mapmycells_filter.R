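## adaptive filtering of label-transfer mapping scores: DoubleMAD
## thresholds per cell type with bimodality handling, and the
## nearest-neighbour spatial diagnostic

#' DoubleMAD parameters
#' @param k_mad multiplier on the lower MAD (default 3).
#' @return list of class `double_mad_params`.
#' @export
double_mad_params <- function(k_mad = 3) {
  stopifnot(k_mad > 0)
  structure(list(k_mad = k_mad, side = "low"), class = "double_mad_params")
}

#' Bimodality-detection parameters
#'
#' A mapping-score distribution counts as bimodal when its kernel
#' density estimate has exactly two modes, the minor mode carries at
#' least `min_minor_mass` of the total density, the local minimum lies
#' within `min_window` of the median, and the normalized KDE-height
#' difference between the two peaks is below `max_peak_gap`.
#'
#' @param min_minor_mass minimum minor-mode density share (default 0.10).
#' @param min_window half-width of the median window for the local
#'   minimum, in correlation units (default 0.05).
#' @param max_peak_gap maximum normalized peak-height difference
#'   (default 0.05, strictly below).
#' @param min_valley_depth the KDE height at the between-modes minimum
#'   must fall below `(1 - min_valley_depth)` times the smaller peak
#'   (default 0.1); guards against discretization wiggles at a flat
#'   mode top that would otherwise satisfy all three criteria.
#' @return list of class `bimodality_params`.
#' @export
bimodality_params <- function(min_minor_mass = 0.10, min_window = 0.05,
                              max_peak_gap = 0.05, min_valley_depth = 0.1) {
  stopifnot(min_minor_mass > 0, min_minor_mass < 1,
            min_window > 0, min_window < 1,
            max_peak_gap > 0, max_peak_gap < 1,
            min_valley_depth >= 0, min_valley_depth < 1)
  structure(list(min_minor_mass = min_minor_mass, min_window = min_window,
                 max_peak_gap = max_peak_gap,
                 min_valley_depth = min_valley_depth),
            class = "bimodality_params")
}

#' Double median absolute deviation
#'
#' Separate deviations below and above the median, robust for skewed
#' distributions: `mad_low` is the median of `|x - median|` over values
#' `<= median`, `mad_high` the analogue over values `>= median` (the
#' median belongs to both sides).
#'
#' @param values numeric vector, length >= 3.
#' @return list(`median`, `mad_low`, `mad_high`).
#' @export
double_mad <- function(values) {
  if (length(values) < 3L)
    stop_merscape("double_mad needs at least 3 values",
                  class = "merscape_config_error")
  med <- stats::median(values)
  list(median = med,
       mad_low = stats::median(abs(values[values <= med] - med)),
       mad_high = stats::median(abs(values[values >= med] - med)))
}

#' Detect bimodality of a score distribution
#'
#' Gaussian KDE with Silverman bandwidth on a 512-point grid over the
#' data range; modes are strict local maxima of the KDE. See
#' [bimodality_params()] for the three criteria.
#'
#' @param values numeric vector, length >= 50.
#' @param p a [bimodality_params] object.
#' @return list(`bimodal` logical, `local_min` score value of the
#'   between-modes minimum (or `NA`)).
#' @export
detect_bimodality <- function(values, p = bimodality_params()) {
  not_bimodal <- list(bimodal = FALSE, local_min = NA_real_)
  if (length(values) < 50L || stats::sd(values) == 0) return(not_bimodal)
  kde <- try(stats::density(values, bw = "nrd0", n = 512L,
                            from = min(values), to = max(values)),
             silent = TRUE)
  if (inherits(kde, "try-error")) return(not_bimodal)
  y <- kde$y; x <- kde$x
  n <- length(y)
  int <- 2:(n - 1L)
  peaks <- int[y[int] > y[int - 1L] & y[int] >= y[int + 1L]]
  ## collapse plateau duplicates
  if (length(peaks) > 1L) peaks <- peaks[c(TRUE, diff(peaks) > 1L)]
  if (length(peaks) != 2L) return(not_bimodal)
  ## local minimum between the two modes
  seg <- peaks[1L]:peaks[2L]
  vmin <- seg[which.min(y[seg])]
  med <- stats::median(values)
  if (abs(x[vmin] - med) > p$min_window) return(not_bimodal)
  ## density mass split at the local minimum
  dx <- x[2L] - x[1L]
  mass <- c(sum(y[1:vmin]), sum(y[vmin:n])) * dx
  if (min(mass) / sum(mass) < p$min_minor_mass) return(not_bimodal)
  ## normalized peak-height gap
  h <- y[peaks]
  if (abs(h[1L] - h[2L]) / max(h) >= p$max_peak_gap) return(not_bimodal)
  ## the valley must dip below the smaller peak
  if (y[vmin] > (1 - p$min_valley_depth) * min(h)) return(not_bimodal)
  list(bimodal = TRUE, local_min = x[vmin])
}

#' Adaptive threshold for one cell type's mapping scores
#'
#' If the distribution is bimodal the lower mode is discarded: the
#' median and lower MAD are recomputed on values above the local
#' minimum. The threshold is `median_used - k_mad * mad_low_used`
#' (default `median - 3 * MAD_low`); values strictly below it are
#' flagged for removal.
#'
#' @param values numeric mapping scores of one cell type.
#' @param dm a [double_mad_params] object.
#' @param bp a [bimodality_params] object.
#' @param label cell-type label echoed into the report.
#' @return a one-row data.frame of class `threshold_report`: `supertype`,
#'   `median`, `mad_low`, `mad_high`, `threshold`, `bimodal`,
#'   `local_min`, `n_kept`, `n_removed`, plus a `keep` attribute with
#'   the logical mask in input order.
#' @export
supertype_threshold <- function(values, dm = double_mad_params(),
                                bp = bimodality_params(), label = "") {
  if (length(values) < 3L)
    stop_merscape("supertype_threshold needs at least 3 values",
                  class = "merscape_config_error")
  bi <- detect_bimodality(values, bp)
  use <- values
  if (bi$bimodal) {
    sub <- values[values > bi$local_min]
    if (length(sub) >= 3L) use <- sub
    else {
      warning("fewer than 3 values above the local minimum; ",
              "falling back to the full distribution")
      bi$bimodal <- FALSE
    }
  }
  md <- double_mad(use)
  thr <- md$median - dm$k_mad * md$mad_low
  ## strictly-below rule with a tolerance so that a value exactly at the
  ## cutoff survives floating-point round-off in median - k * MAD
  keep <- (thr - values) <= 1e-12 * max(1, abs(thr))
  rep <- data.frame(supertype = label, median = md$median,
                    mad_low = md$mad_low, mad_high = md$mad_high,
                    threshold = thr, bimodal = bi$bimodal,
                    local_min = bi$local_min,
                    n_kept = sum(keep), n_removed = sum(!keep),
                    stringsAsFactors = FALSE)
  class(rep) <- c("threshold_report", "data.frame")
  attr(rep, "keep") <- keep
  rep
}

#' Filter mapped cells per cell type
#'
#' Groups per-cell mapping scores by supertype, derives one adaptive
#' threshold per group with [supertype_threshold()], and concatenates
#' the per-group verdicts into a keep mask in input order. Groups with
#' fewer than 3 cells are kept unfiltered and flagged in the report.
#'
#' @param scores data.frame with columns `cell_id`, `supertype`,
#'   `avg_correlation`.
#' @param dm,bp parameter objects.
#' @return list(`keep` logical mask in input order, `report` data.frame
#'   with one row per supertype plus a `filtered` column).
#' @export
filter_mapped_cells <- function(scores, dm = double_mad_params(),
                                bp = bimodality_params()) {
  keep <- rep(TRUE, nrow(scores))
  reports <- list()
  for (st in sort(unique(scores$supertype))) {
    sel <- which(scores$supertype == st)
    if (length(sel) < 3L) {
      reports[[st]] <- data.frame(
        supertype = st, median = NA_real_, mad_low = NA_real_,
        mad_high = NA_real_, threshold = NA_real_, bimodal = FALSE,
        local_min = NA_real_, n_kept = length(sel), n_removed = 0L,
        filtered = FALSE, stringsAsFactors = FALSE)
      next
    }
    rep_st <- supertype_threshold(scores$avg_correlation[sel], dm, bp,
                                  label = st)
    keep[sel] <- attr(rep_st, "keep")
    rep_st$filtered <- TRUE
    reports[[st]] <- as.data.frame(rep_st)
  }
  report <- do.call(rbind, reports)
  rownames(report) <- NULL
  list(keep = keep, report = report)
}

#' Average nearest-neighbour distance within groups
#'
#' For each cell, the Euclidean distance to the nearest other cell of
#' the same group; the group value is the mean. Singleton groups are
#' undefined (`NA`). Poorly mapped cells lack the strong regional
#' localization of real cell types, so their groups show larger values.
#'
#' @param positions numeric matrix (n x 2 or n x 3) of centroids in um.
#' @param group character/factor group label per cell.
#' @return named numeric vector: mean NN distance per group.
#' @export
ann_distance <- function(positions, group) {
  positions <- as.matrix(positions)
  vapply(split(seq_len(nrow(positions)), group), function(sel) {
    if (length(sel) < 2L) return(NA_real_)
    nn <- FNN::get.knn(positions[sel, , drop = FALSE], k = 1L)$nn.dist
    mean(nn[, 1L])
  }, 0)
}
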