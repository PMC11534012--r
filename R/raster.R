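#' Planar raster container
#'
#' A minimal single-band raster on a regular planar grid in metres. Values
#' are stored in a matrix indexed `[ix, iy]` with the centre of pixel
#' `(ix, iy)` at `((ix - 0.5) * res, (iy - 0.5) * res)` relative to `origin`.
#' x increases eastward, y northward.
#'
#' @param values numeric matrix of cell values.
#' @param res cell size in metres.
#' @param origin length-2 numeric, planar coordinates of the grid's
#'   lower-left corner.
#' @return An object of class `wq_raster`.
#' @export
wq_raster <- function(values, res = 10, origin = c(0, 0)) {
  stopifnot(is.matrix(values), res > 0, length(origin) == 2)
  structure(list(values = values, res = res, origin = as.numeric(origin)),
            class = "wq_raster")
}

#' @export
print.wq_raster <- function(x, ...) {
  cat(sprintf("<wq_raster %d x %d @ %g m, range [%g, %g]>\n",
              nrow(x$values), ncol(x$values), x$res,
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' @export
dim.wq_raster <- function(x) dim(x$values)

# Planar coordinates of every pixel centre, as an n x 2 matrix (x, y),
# in column-major matrix order (ix varies fastest).
pixel_centers <- function(r) {
  nx <- nrow(r$values); ny <- ncol(r$values)
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  cbind(x = r$origin[1] + (ix - 0.5) * r$res,
        y = r$origin[2] + (iy - 0.5) * r$res)
}

#' Pixel indices whose centres lie within a closed disc
#'
#' Disc membership follows the centre-of-pixel convention: a pixel belongs
#' to the disc iff its centre is at distance <= `radius_m` from `(x, y)`.
#'
#' @param r a [wq_raster()].
#' @param x,y disc centre in planar metres.
#' @param radius_m disc radius in metres.
#' @return Integer matrix with columns `ix`, `iy` (possibly 0 rows).
#' @export
disc_pixels <- function(r, x, y, radius_m) {
  nx <- nrow(r$values); ny <- ncol(r$values)
  # candidate window to avoid scanning the full grid
  ix0 <- max(1L, floor((x - radius_m - r$origin[1]) / r$res - 0.5) + 1L)
  ix1 <- min(nx, ceiling((x + radius_m - r$origin[1]) / r$res + 0.5))
  iy0 <- max(1L, floor((y - radius_m - r$origin[2]) / r$res - 0.5) + 1L)
  iy1 <- min(ny, ceiling((y + radius_m - r$origin[2]) / r$res + 0.5))
  if (ix0 > ix1 || iy0 > iy1) {
    return(cbind(ix = integer(0), iy = integer(0)))
  }
  ix <- rep(ix0:ix1, times = iy1 - iy0 + 1L)
  iy <- rep(iy0:iy1, each = ix1 - ix0 + 1L)
  cx <- r$origin[1] + (ix - 0.5) * r$res
  cy <- r$origin[2] + (iy - 0.5) * r$res
  keep <- (cx - x)^2 + (cy - y)^2 <= radius_m^2
  cbind(ix = ix[keep], iy = iy[keep])
}

# Shift a logical mask matrix by (dx, dy) pixels; cells shifted in from
# outside are FALSE. dx moves +x (increasing row index), dy moves +y.
shift_mask <- function(m, dx, dy) {
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(FALSE, nx, ny)
  sx <- seq_len(nx) - dx   # source indices
  sy <- seq_len(ny) - dy
  okx <- sx >= 1 & sx <= nx
  oky <- sy >= 1 & sy <= ny
  if (any(okx) && any(oky)) {
    out[okx, oky] <- m[sx[okx], sy[oky]]
  }
  out
}
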