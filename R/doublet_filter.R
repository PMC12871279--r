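## doublet flagging: pluggable singlet/doublet scorer + quantile
## threshold on the score difference

#' Score cells as singlets or doublets
#'
#' The `"builtin"` backend simulates artificial doublets by summing the
#' count profiles of random cell pairs, embeds observed and artificial
#' profiles in a PCA-reduced, library-size + log1p normalized space, and
#' classifies each observed cell by a k-nearest-neighbour vote against
#' the pooled set (observed = singlet votes, artificial = doublet
#' votes). Probabilities are vote fractions; the run is deterministic
#' given `seed`. An external deep-learning scorer (Solo) can stand
#' behind the `"solo"` backend but is not bundled.
#'
#' @param m a [cell_matrix] for one section.
#' @param backend `"builtin"` (or `"solo"`, external hook).
#' @param seed integer seed for the artificial-doublet draw.
#' @param n_artificial number of artificial doublets (default = twice
#'   the number of cells, so that simulated doublets dominate the
#'   neighbourhoods of real ones).
#' @param k neighbours in the vote (default 15).
#' @param n_pcs PCA dimensions (default 10).
#' @return data.frame of class `doublet_scores`: `cell_id`, `singlet_p`,
#'   `doublet_p`, `dif` = `doublet_p - singlet_p` (the sign convention
#'   is such that doublet-like cells score high; see [call_doublets()]).
#' @export
score_doublets <- function(m, backend = "builtin", seed = 0L,
                           n_artificial = NULL, k = 15L, n_pcs = 10L) {
  if (identical(backend, "solo"))
    stop_merscape("solo backend not available in this installation; ",
                  "use backend = 'builtin'", class = "merscape_config_error")
  if (!identical(backend, "builtin"))
    stop_merscape("unknown doublet backend: ", backend,
                  class = "merscape_config_error")
  n <- nrow(m$counts)
  if (n < 50L)
    stop_merscape("builtin doublet scorer needs >= 50 cells per section",
                  class = "merscape_config_error")
  if (is.null(n_artificial)) n_artificial <- 2L * n
  with_seed(seed, {
    i1 <- sample.int(n, n_artificial, replace = TRUE)
    i2 <- sample.int(n, n_artificial, replace = TRUE)
    same <- i1 == i2
    i2[same] <- (i2[same] %% n) + 1L
    art <- m$counts[i1, , drop = FALSE] + m$counts[i2, , drop = FALSE]
    norm <- function(x) {
      ls <- rowSums(x)
      ls[ls == 0] <- 1
      log1p(x / ls * stats::median(rowSums(m$counts)))
    }
    all_mat <- rbind(norm(m$counts), norm(art))
    pcs <- stats::prcomp(all_mat, rank. = min(n_pcs, ncol(all_mat), nrow(all_mat) - 1L),
                         center = TRUE, scale. = FALSE)$x
    ## library size is the main doublet signal that normalisation removes;
    ## reinstate it as an extra embedding axis on the PC scale
    libs <- log1p(c(rowSums(m$counts), rowSums(art)))
    libs <- (libs - mean(libs)) / max(stats::sd(libs), 1e-12)
    pcs <- cbind(pcs, libs * stats::sd(pcs[, 1L]))
    obs <- pcs[seq_len(n), , drop = FALSE]
    nn <- FNN::get.knnx(pcs, obs, k = k + 1L)$nn.index
    doublet_p <- vapply(seq_len(n), function(i) {
      nb <- setdiff(nn[i, ], i)[seq_len(k)]  # exclude self-match
      mean(nb > n)
    }, 0)
    out <- data.frame(cell_id = m$cell_meta$production_cell_id,
                      singlet_p = 1 - doublet_p, doublet_p = doublet_p,
                      dif = doublet_p - (1 - doublet_p),
                      stringsAsFactors = FALSE)
    class(out) <- c("doublet_scores", "data.frame")
    out
  })
}

#' Quantile-based doublet threshold and flags
#'
#' The dif distribution of the predicted doublets (cells whose doublet
#' probability exceeds their singlet probability) defines the cutoff
#' `threshold = q0.9(dif) - q0.1(dif)` with linear-interpolation
#' quantiles; all cells with `dif` strictly above the threshold are
#' flagged as doublets. With `convention = "singlet_minus_doublet"` the
#' dif sign (and the flagging side) is inverted.
#'
#' @param scores a `doublet_scores` data.frame from [score_doublets()].
#' @param convention `"doublet_minus_singlet"` (default) or
#'   `"singlet_minus_doublet"`.
#' @return list(`threshold`, `is_doublet` logical mask in cell order,
#'   `n_predicted` size of the predicted-doublet set).
#' @export
call_doublets <- function(scores,
                          convention = c("doublet_minus_singlet",
                                         "singlet_minus_doublet")) {
  convention <- match.arg(convention)
  dif <- scores$doublet_p - scores$singlet_p
  if (convention == "singlet_minus_doublet") dif <- -dif
  ## ties (doublet_p == singlet_p) count as predicted so that a fully
  ## degenerate dif distribution still yields the threshold 0, no flags
  predicted <- scores$doublet_p >= scores$singlet_p
  if (sum(predicted) < 2L) {
    warning("fewer than two predicted doublets; threshold undefined, no flags")
    return(list(threshold = NA_real_,
                is_doublet = rep(FALSE, nrow(scores)),
                n_predicted = sum(predicted)))
  }
  q <- stats::quantile(dif[predicted], c(0.1, 0.9), type = 7, names = FALSE)
  thr <- q[2L] - q[1L]
  flag <- if (convention == "doublet_minus_singlet") dif > thr else dif < -thr
  list(threshold = thr, is_doublet = flag, n_predicted = sum(predicted))
}
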