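#' Symmetric one-dimensional simulation grid
#'
#' Builds a fixed grid of nodes spanning `[-half_length, half_length]`,
#' centred on the Hh source midpoint at x = 0.  The node count is odd so a
#' node sits exactly at x = 0 and the grid is mirror-symmetric.
#'
#' @param half_length Spatial extent to each side of x = 0 (um).
#' @param dx Node spacing (um); `2 * half_length / dx` must be an even
#'   integer (within floating tolerance).
#' @param omega Width of the Hh source (um); nodes with `|x| <= omega / 2`
#'   are flagged in `source_mask`.
#' @return An object of class `ocellar_grid`: list with `half_length`,
#'   `dx`, `n_points`, `x` (node coordinates) and `source_mask`.
#' @export
#' @examples
#' g <- grid1d(100, 1, omega = 30)
#' sum(g$source_mask)  # nodes inside the source
grid1d <- function(half_length, dx, omega) {
  if (half_length <= 0 || dx <= 0 || omega <= 0)
    stop("half_length, dx and omega must be positive")
  n_half <- half_length / dx
  if (abs(n_half - round(n_half)) > 1e-8)
    stop("half_length must be an integer multiple of dx")
  n_half <- round(n_half)
  x <- seq(-n_half, n_half) * dx
  structure(list(half_length = half_length, dx = dx,
                 n_points = length(x), x = x,
                 source_mask = abs(x) <= omega / 2 + 1e-12),
            class = "ocellar_grid")
}

#' @export
print.ocellar_grid <- function(x, ...) {
  cat(sprintf("1D grid: %d nodes, dx = %g um, x in [%g, %g], %d source nodes\n",
              x$n_points, x$dx, -x$half_length, x$half_length,
              sum(x$source_mask)))
  invisible(x)
}
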