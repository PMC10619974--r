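#' @keywords internal
"_PACKAGE"

# Shared internal helpers: seeded RNG scoping, seed splitting, small checks.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded simulator calls do not
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

#' Derive a child seed from a master seed
#'
#' Deterministic seed-splitting scheme used throughout the pipeline so that
#' any plane/block can be regenerated in isolation from the master seed and
#' its indices. A multiplicative hash keeps children well separated and
#' below 2^31.
#'
#' @param master integer master seed.
#' @param ... one or more non-negative integer indices (plane, block, ...).
#' @return integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(42, 1, 3)
child_seed <- function(master, ...) {
  idx <- c(as.numeric(master), vapply(list(...), as.numeric, numeric(1)))
  h <- 0
  for (v in idx) {
    # 64-bit-safe modular hash in double precision (all values < 2^53)
    h <- ((h * 69069) %% 2147483647 + (v + 1) * 40503) %% 2147483647
    h <- (h * 2654435761) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Linear interpolation of a polyline (n x 2 matrix, columns x/z in mm) at
# arc lengths `s` (recycled modulo total length when wrap = TRUE).
polyline_interp <- function(points, s, wrap = FALSE) {
  seg_len <- sqrt(rowSums(diff(points)^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  if (wrap) s <- s %% total
  s <- pmin(pmax(s, 0), total)
  x <- stats::approx(cum, points[, 1], xout = s, ties = "ordered")$y
  z <- stats::approx(cum, points[, 2], xout = s, ties = "ordered")$y
  cbind(x = x, z = z)
}

polyline_length <- function(points) {
  if (nrow(points) < 2L) return(0)
  sum(sqrt(rowSums(diff(points)^2)))
}

# Unit tangent of a polyline at arc lengths s (finite difference).
polyline_tangent <- function(points, s) {
  total <- polyline_length(points)
  h <- max(total * 1e-4, 1e-6)
  p1 <- polyline_interp(points, pmax(s - h, 0))
  p2 <- polyline_interp(points, pmin(s + h, total))
  d <- p2 - p1
  n <- sqrt(rowSums(d^2))
  n[n == 0] <- 1
  d / n
}
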