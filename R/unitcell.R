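#' Triclinic unit cell (P1)
#'
#' Constructs a unit cell from lengths (Angstrom) and angles (degrees).
#' Only space group P1 is supported throughout the package; all symmetry
#' beyond Friedel pairing is out of scope.
#'
#' @param a,b,c Cell edge lengths in Angstrom (> 0).
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell`.
#' @examples
#' cell <- unit_cell(18, 15, 12)
#' cell_volume(cell)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  if (any(c(a, b, c) <= 0)) stop("cell lengths must be positive")
  ang <- c(alpha, beta, gamma)
  if (any(ang <= 0 | ang >= 180)) stop("cell angles must lie in (0, 180)")
  cell <- structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma),
    class = "unit_cell")
  if (cell_volume(cell) <= 0) stop("degenerate cell: volume <= 0")
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.1f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, cell_volume(x)))
  invisible(x)
}

#' Unit cell volume in cubic Angstrom
#' @param cell A `unit_cell`.
#' @return Volume in Angstrom^3.
#' @export
cell_volume <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta  * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  arg <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  cell$a * cell$b * cell$c * sqrt(max(arg, 0))
}

#' Orthogonalization matrix (fractional -> Cartesian)
#'
#' Standard PDB convention: `a` along x, `b` in the xy plane.
#'
#' @param cell A `unit_cell`.
#' @return 3x3 matrix `M` such that `xyz = M %*% frac`.
#' @export
cell_orth_matrix <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta  * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  sg <- sin(cell$gamma * pi / 180)
  v <- cell_volume(cell) / (cell$a * cell$b * cell$c)
  matrix(c(
    cell$a, cell$b * cg, cell$c * cb,
    0,      cell$b * sg, cell$c * (ca - cb * cg) / sg,
    0,      0,           cell$c * v / sg),
    nrow = 3, byrow = TRUE)
}

#' Fractionalization matrix (Cartesian -> fractional)
#' @param cell A `unit_cell`.
#' @return 3x3 matrix, inverse of [cell_orth_matrix()].
#' @export
cell_frac_matrix <- function(cell) solve(cell_orth_matrix(cell))

#' Resolution (d-spacing) of reflections
#'
#' @param cell A `unit_cell`.
#' @param hkl Integer matrix with three columns (h, k, l), one row per
#'   reflection, or a length-3 vector.
#' @return Numeric vector of d-spacings in Angstrom.
#' @export
d_spacing <- function(cell, hkl) {
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3)
  # reciprocal basis: rows of t(inv(orth)) are a*, b*, c*
  bstar <- t(cell_frac_matrix(cell))
  svec <- hkl %*% t(bstar)          # scattering vectors, |s| = 1/d
  1 / sqrt(rowSums(svec^2))
}
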