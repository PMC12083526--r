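#' Reflection dataset
#'
#' A set of P1-unique reflections with amplitudes, sigmas and optional
#' phases. Friedel mates are implicit: only one hemisphere is stored and
#' map synthesis completes the sphere by conjugation.
#'
#' @param hkl Integer matrix with columns h, k, l (no duplicates, no 000).
#' @param f Amplitudes (>= 0).
#' @param sigf Sigmas (>= 0); may be all zero for calculated sets.
#' @param phase Phases in degrees, or `NULL`/`NA` when unknown.
#' @param cell A [unit_cell()].
#' @param role One of `"observed-dark"`, `"observed-light"`,
#'   `"calculated-dark"`, `"calculated-light"`, `"difference"`,
#'   `"extrapolated"`, `"plain"`.
#' @return Object of class `reflection_set` with fields `data`
#'   (data.frame h,k,l,f,sigf,phase,d), `cell`, `d_min`, `d_max`, `role`.
#' @export
reflection_set <- function(hkl, f, sigf = NULL, phase = NULL, cell,
                           role = "plain") {
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3)
  storage.mode(hkl) <- "integer"
  n <- nrow(hkl)
  if (is.null(sigf)) sigf <- rep(0, n)
  if (is.null(phase)) phase <- rep(NA_real_, n)
  stopifnot(length(f) == n, length(sigf) == n, length(phase) == n)
  if (any(f < -1e-9)) stop("amplitudes must be >= 0")
  if (any(rowSums(abs(hkl)) == 0)) stop("the (0,0,0) reflection is not allowed")
  key <- paste(hkl[, 1], hkl[, 2], hkl[, 3])
  if (anyDuplicated(key)) stop("duplicate (h,k,l) entries")
  d <- d_spacing(cell, hkl)
  data <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                     f = pmax(f, 0), sigf = sigf, phase = phase, d = d)
  structure(list(data = data, cell = cell,
                 d_min = min(d), d_max = max(d), role = role),
            class = "reflection_set")
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("<reflection_set> %d reflections, role=%s, d %.2f-%.2f A, phases: %s\n",
              nrow(x$data), x$role, x$d_min, x$d_max,
              if (all(is.na(x$data$phase))) "absent" else "present"))
  invisible(x)
}

#' Unique P1 reflection indices to a resolution limit
#'
#' One reflection per Friedel pair, chosen on the hemisphere
#' l > 0, or (l = 0, k > 0), or (l = k = 0, h > 0).
#'
#' @param cell A `unit_cell`.
#' @param d_min High-resolution limit in Angstrom.
#' @param d_max Optional low-resolution limit (default `Inf`).
#' @return Integer matrix of (h, k, l).
#' @export
unique_hkl <- function(cell, d_min, d_max = Inf) {
  stopifnot(d_min > 0)
  hmax <- ceiling(cell$a / d_min); kmax <- ceiling(cell$b / d_min)
  lmax <- ceiling(cell$c / d_min)
  g <- expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = 0:lmax)
  hkl <- as.matrix(g)
  hemi <- hkl[, 3] > 0 | (hkl[, 3] == 0 & hkl[, 2] > 0) |
    (hkl[, 3] == 0 & hkl[, 2] == 0 & hkl[, 1] > 0)
  hkl <- hkl[hemi, , drop = FALSE]
  d <- d_spacing(cell, hkl)
  hkl <- hkl[d >= d_min & d <= d_max, , drop = FALSE]
  if (!nrow(hkl)) stop("no reflections between d_min and d_max for this cell")
  hkl
}

#' Structure factors by direct summation (P1)
#'
#' Computes complex structure factors
#' \deqn{F(h) = \sum_j occ_j f_j(s) e^{-B_j s^2} e^{2\pi i h\cdot x_j}}
#' with \eqn{s^2 = 1/(4d^2)}, over all unique reflections with
#' \eqn{d \ge d_{min}}, and returns amplitudes plus phases. Friedel mates
#' are related by complex conjugation and are not stored.
#'
#' @param model An [atom_model()].
#' @param d_min High-resolution limit in Angstrom.
#' @param mode Form-factor mode, `"cromer_mann"` or `"toy"`.
#' @param hkl Optional explicit index matrix (overrides the d_min sphere).
#' @param role Role tag for the returned set.
#' @return A `reflection_set` with phases (degrees) and zero sigmas.
#' @export
calc_structure_factors <- function(model, d_min, mode = "cromer_mann",
                                   hkl = NULL, role = "calculated-dark") {
  if (!nrow(model$atoms)) stop("model has no atoms")
  if (is.null(hkl)) {
    if (d_min > max(model$cell$a, model$cell$b, model$cell$c))
      stop("d_min exceeds the cell: empty reflection set")
    hkl <- unique_hkl(model$cell, d_min)
  }
  fc <- .complex_sf(model, hkl, mode)
  reflection_set(hkl, f = Mod(fc), sigf = rep(0, nrow(hkl)),
                 phase = Arg(fc) * 180 / pi, cell = model$cell, role = role)
}

# complex structure factors for an explicit hkl list (vectorised over
# reflections x atoms; fine for toy systems of tens of atoms)
.complex_sf <- function(model, hkl, mode = "cromer_mann") {
  at <- model$atoms
  known <- c("H", "C", "N", "O", "P", "S")
  bad <- which(!(toupper(at$element) %in% known))
  if (length(bad))
    stop("unknown element symbol '", at$element[bad[1]], "' for atom ",
         at$resi[bad[1]], " ", at$atom[bad[1]])
  d <- d_spacing(model$cell, hkl)
  s2 <- 1 / (4 * d^2)
  frac <- frac_coords(model)
  phase <- 2 * pi * (hkl %*% t(frac))          # nrefl x natom
  # per-element form factors, shared across atoms of the same element
  elems <- toupper(at$element)
  fmat <- matrix(0, nrow(hkl), nrow(at))
  for (e in unique(elems)) {
    fe <- form_factor(e, s2, mode)
    fmat[, elems == e] <- fe
  }
  coef <- fmat * exp(-outer(s2, at$b)) *
    matrix(at$occ, nrow(hkl), nrow(at), byrow = TRUE)
  as.vector((coef * exp(1i * phase)) %*% rep(1, nrow(at)))
}

# merge two reflection sets on (h,k,l); returns indices into each
.common_hkl <- function(a, b) {
  ka <- paste(a$data$h, a$data$k, a$data$l)
  kb <- paste(b$data$h, b$data$k, b$data$l)
  ia <- which(ka %in% kb)
  ib <- match(ka[ia], kb)
  list(ia = ia, ib = ib)
}
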