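# Shared helpers: angle arithmetic, geometry, interpolation.

#' Wrap angles in degrees to the principal interval (-180, 180]
#'
#' All phase arithmetic in the package is done in phase-degrees on this
#' interval; the wrap is applied after phase subtraction and before halving
#' when opposite stimulus directions are combined.
#'
#' @param x numeric vector or matrix of angles in degrees.
#' @return object of the same shape with values in (-180, 180].
#' @export
wrap_degrees <- function(x) {
  w <- x - 360 * floor(x / 360 + 0.5)
  # floor-based wrap yields [-180, 180); move -180 to +180
  w[w == -180] <- 180
  w
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Disk-shaped pixel mask
#'
#' Convenience constructor for circular regions of interest.
#'
#' @param nrow,ncol map dimensions in pixels.
#' @param radius disk radius in pixels.
#' @param center numeric length-2 (row, col); defaults to the map center.
#' @return logical matrix of dimension `nrow` x `ncol`.
#' @export
disk_mask <- function(nrow, ncol, radius, center = NULL) {
  if (is.null(center)) center <- c((nrow + 1) / 2, (ncol + 1) / 2)
  r <- matrix(seq_len(nrow), nrow, ncol)
  c <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  (r - center[1])^2 + (c - center[2])^2 <= radius^2
}

#' Rectangular pixel mask
#'
#' @param nrow,ncol map dimensions in pixels.
#' @param rows,cols integer ranges (inclusive) of rows and columns to include.
#' @return logical matrix of dimension `nrow` x `ncol`.
#' @export
rect_mask <- function(nrow, ncol, rows, cols) {
  m <- matrix(FALSE, nrow, ncol)
  m[rows, cols] <- TRUE
  m
}

# Bilinear interpolation of matrix `z` at fractional (row, col) positions.
# Points whose 2x2 support exits the matrix give NA.
bilinear <- function(z, row, col) {
  nr <- nrow(z); nc <- ncol(z)
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0; fc <- col - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 + 1 <= nr & c0 + 1 <= nc
  out <- rep(NA_real_, length(row))
  if (any(ok)) {
    r0 <- r0[ok]; c0 <- c0[ok]; fr <- fr[ok]; fc <- fc[ok]
    i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
    i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
    out[ok] <- z[i00] * (1 - fr) * (1 - fc) + z[i10] * fr * (1 - fc) +
      z[i01] * (1 - fr) * fc + z[i11] * fr * fc
  }
  out
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}
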