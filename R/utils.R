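#' @include AllClasses.R
NULL

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' von Neumann mask for horizontal kernels
#'
#' Logical 3 x 3 x cin x cout array that is `TRUE` at the four nearest
#' neighbors (up, down, left, right) and `FALSE` elsewhere; horizontal
#' kernels are constrained to this support at all times.
#'
#' @param cin,cout kernel channel dimensions.
#' @return logical array.
#' @export
horizontalMask <- function(cin = 1L, cout = 1L) {
  m <- array(FALSE, c(3, 3, cin, cout))
  m[1, 2, , ] <- TRUE; m[3, 2, , ] <- TRUE
  m[2, 1, , ] <- TRUE; m[2, 3, , ] <- TRUE
  m
}

#' Clipped linear activation
#'
#' Element-wise clamp to \[0, 1\]; the interneuron nonlinearity of the
#' recurrent pathway.
#'
#' @param x numeric array.
#' @return `x` clamped to \[0, 1\], same shape.
#' @export
thetaClip <- function(x) pmin(pmax(x, 0), 1)

#' Saturating gate nonlinearity
#'
#' `phiGate(x) = 100 |x| / sqrt(1 + (100 x)^2)`: zero at zero, monotone in
#' `|x|`, saturating at 1.  Applied to the sensory input and to the gate maps,
#' it ensures that enhanced activity can only propagate where the
#' scale-selection pathway is active.  `bump = TRUE` selects the alternative
#' non-monotone reading `100 |x| / (1 + (100 x)^2)`, kept for comparison.
#'
#' @param x numeric array.
#' @param bump logical, use the non-monotone variant.
#' @return gated values, same shape as `x`.
#' @export
phiGate <- function(x, bump = FALSE) {
  out <- .cpp_phi(as.numeric(x), bump)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

# Next multiple of 3^nScales.
paddedSize <- function(n, nScales) {
  m <- 3L^nScales
  as.integer(ceiling(n / m) * m)
}

#' Zero-pad an image on the right/bottom to a processable size
#'
#' Layer `l` of the network runs at resolution H/3^l, so the canvas side must
#' be a multiple of 3^`nScales`; images are zero-padded right and bottom
#' (e.g. 108 to 162, 594 to 648 for four scales).
#'
#' @param image H x W x 3 array.
#' @param nScales number of scales the network uses.
#' @return padded array.
#' @export
padImage <- function(image, nScales = 4L) {
  h <- paddedSize(dim(image)[1], nScales)
  w <- paddedSize(dim(image)[2], nScales)
  if (h == dim(image)[1] && w == dim(image)[2]) return(image)
  out <- array(0, c(h, w, dim(image)[3]))
  out[seq_len(dim(image)[1]), seq_len(dim(image)[2]), ] <- image
  out
}

# Expand a grid-level array (G x G x C) to pixels (3G x 3G x C).
expandCells <- function(grid, cellPx = 3L) {
  grid[rep(seq_len(nrow(grid)), each = cellPx),
       rep(seq_len(ncol(grid)), each = cellPx), , drop = FALSE]
}

# Pixel rows/cols of a cell block (1-based, cellPx = 3).
cellPixels <- function(cell, cellPx = 3L) {
  list(rows = ((cell[1] - 1L) * cellPx + 1L):(cell[1] * cellPx),
       cols = ((cell[2] - 1L) * cellPx + 1L):(cell[2] * cellPx))
}
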