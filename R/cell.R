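#' Create a lattice cell
#'
#' A triclinic unit cell given by its edge lengths (angstrom) and angles
#' (degrees). The orthogonalization convention used throughout the package is
#' the standard crystallographic one: \strong{a} along x, \strong{b} in the
#' xy-plane, right-handed.
#'
#' @param a,b,c Cell lengths in angstrom, all positive.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class \code{"lattice_cell"} with elements
#'   \code{a,b,c,alpha,beta,gamma}, the orthogonalization matrix \code{ortho}
#'   (columns are the cell vectors in Cartesian angstrom), its inverse
#'   \code{frac}, and \code{volume} in cubic angstrom.
#' @examples
#' cl <- lattice_cell(10, 12, 8, 90, 104, 90)
#' cl$volume
#' @export
lattice_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a, b, c); ang <- c(alpha, beta, gamma)
  if (any(!is.finite(len)) || any(len <= 0))
    stop("cell lengths must be positive and finite")
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  # volume by the triclinic closed form
  arg <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (arg <= 0) stop("cell angles give a non-positive-definite metric")
  vol <- a * b * c * sqrt(arg)
  cz <- sqrt(arg) / sg
  ortho <- matrix(c(
    a, 0, 0,
    b * cg, b * sg, 0,
    c * cb, c * (ca - cb * cg) / sg, c * cz
  ), nrow = 3)
  structure(list(
    a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
    ortho = ortho, frac = solve(ortho), volume = vol
  ), class = "lattice_cell")
}

#' @export
print.lattice_cell <- function(x, ...) {
  cat(sprintf("cell  a=%.4f b=%.4f c=%.4f  alpha=%.3f beta=%.3f gamma=%.3f  V=%.3f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Metric tensor of a cell
#'
#' @param cell A \code{lattice_cell}.
#' @return 3x3 real-space metric tensor G (angstrom^2); positive definite for
#'   any valid cell.
#' @export
cell_metric <- function(cell) crossprod(cell$ortho)

# fractional -> Cartesian for a matrix with rows = points
frac_to_cart <- function(cell, xf) {
  xf <- rbind(xf)
  t(cell$ortho %*% t(xf))
}

cart_to_frac <- function(cell, xc) {
  xc <- rbind(xc)
  t(cell$frac %*% t(xc))
}

#' Scale a cell isotropically
#'
#' Multiplies all three cell lengths by \code{s}, keeping the angles.
#'
#' @param cell A \code{lattice_cell}.
#' @param s Positive scale factor applied to each length.
#' @return A new \code{lattice_cell}.
#' @export
cell_scale <- function(cell, s) {
  lattice_cell(cell$a * s, cell$b * s, cell$c * s,
               cell$alpha, cell$beta, cell$gamma)
}
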