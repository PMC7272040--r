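#' Extract an elevation profile from a gridded DEM
#'
#' Samples a digital elevation model along the straight segment between two
#' map coordinates at a fixed planar step, using bilinear interpolation, and
#' returns the cross-section as a [reef_profile()]. This is how virtual
#' transects are overlaid on a reconstructed reef surface.
#'
#' @param dem A list with `x` (eastings, ascending), `y` (northings,
#'   ascending) and `z` (elevation matrix, `length(x)` rows by `length(y)`
#'   columns, following the [graphics::image()] convention). `NA` cells are
#'   treated as no-data.
#' @param from,to Numeric `c(easting, northing)` endpoints, inside the grid.
#' @param step Sampling step along the segment (m, > 0).
#' @return A [reef_profile()] whose `x` is distance along the segment.
#' @export
#' @examples
#' dem <- list(x = 0:10, y = 0:10, z = outer(0:10, 0:10, function(e, n) 0.1 * e))
#' sample_transect_from_dem(dem, c(0, 5), c(10, 5), step = 0.5)
sample_transect_from_dem <- function(dem, from, to, step) {
  check_scalar_pos(step, "step")
  if (length(from) != 2L || length(to) != 2L) {
    stop_invalid("`from` and `to` must each be c(easting, northing).")
  }
  seg <- sqrt(sum((to - from)^2))
  if (seg <= 0) stop_invalid("endpoints are coincident.")
  for (p in list(from, to)) {
    if (p[1] < min(dem$x) || p[1] > max(dem$x) ||
        p[2] < min(dem$y) || p[2] > max(dem$y)) {
      stop("endpoint (", p[1], ", ", p[2], ") lies outside the DEM grid.",
           call. = FALSE)
    }
  }
  d <- seq(0, seg, by = step)
  if (d[length(d)] < seg - 1e-12) d <- c(d, seg)
  ex <- from[1] + (to[1] - from[1]) * d / seg
  ny <- from[2] + (to[2] - from[2]) * d / seg
  z <- bilinear_eval(dem, ex, ny)
  if (anyNA(z)) {
    bad <- which(is.na(z))[1]
    stop("no-data cell on the transect path at (easting ",
         signif(ex[bad], 6), ", northing ", signif(ny[bad], 6), ").",
         call. = FALSE)
  }
  reef_profile(d, z, resolution = step)
}

bilinear_eval <- function(dem, ex, ny) {
  ix <- pmin(pmax(findInterval(ex, dem$x), 1L), length(dem$x) - 1L)
  iy <- pmin(pmax(findInterval(ny, dem$y), 1L), length(dem$y) - 1L)
  x0 <- dem$x[ix]; x1 <- dem$x[ix + 1L]
  y0 <- dem$y[iy]; y1 <- dem$y[iy + 1L]
  tx <- (ex - x0) / (x1 - x0)
  ty <- (ny - y0) / (y1 - y0)
  z00 <- dem$z[cbind(ix, iy)]
  z10 <- dem$z[cbind(ix + 1L, iy)]
  z01 <- dem$z[cbind(ix, iy + 1L)]
  z11 <- dem$z[cbind(ix + 1L, iy + 1L)]
  (1 - tx) * (1 - ty) * z00 + tx * (1 - ty) * z10 +
    (1 - tx) * ty * z01 + tx * ty * z11
}
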