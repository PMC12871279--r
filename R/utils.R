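## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a locally-seeded RNG
#'
#' Saves and restores the global RNG state, so generators are pure
#' functions of their seed and never perturb user code.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

stop_merscape <- function(..., class) {
  stop(structure(class = c(class, "merscape_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## Shoelace area of a closed ring given as an n x 2 matrix (first != last ok).
polygon_area <- function(v) {
  n <- nrow(v)
  if (is.null(n) || n < 3L) return(0)
  i2 <- c(2:n, 1L)
  abs(sum(v[, 1L] * v[i2, 2L] - v[i2, 1L] * v[, 2L])) / 2
}

## Area-weighted centroid of a simple polygon ring (n x 2 matrix).
polygon_centroid <- function(v) {
  n <- nrow(v)
  if (n < 3L) return(colMeans(v))
  i2 <- c(2:n, 1L)
  cr <- v[, 1L] * v[i2, 2L] - v[i2, 1L] * v[, 2L]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(v))
  cx <- sum((v[, 1L] + v[i2, 1L]) * cr) / (6 * a)
  cy <- sum((v[, 2L] + v[i2, 2L]) * cr) / (6 * a)
  c(cx, cy)
}
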