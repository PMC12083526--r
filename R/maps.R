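#' Real-space density map on a P1 grid
#'
#' @param values 3D numeric array (nx, ny, nz); voxel (1,1,1) sits at the
#'   cell origin, fractional spacing 1/nx etc.
#' @param cell A [unit_cell()].
#' @param provenance One of `"observed-DED"`, `"calculated-DED"`,
#'   `"extrapolated"`, `"plain"`.
#' @return Object of class `density_map` with `values`, `cell`,
#'   `map_sigma` (RMS of voxel values) and `provenance`.
#' @export
density_map <- function(values, cell, provenance = "plain") {
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (any(dim(values) < 2)) stop("grid must have >= 2 points per axis")
  structure(list(values = values, cell = cell,
                 map_sigma = sqrt(mean(values^2)),
                 provenance = provenance),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density_map> %dx%dx%d grid, sigma=%.4g, provenance=%s\n",
              d[1], d[2], d[3], x$map_sigma, x$provenance))
  invisible(x)
}

# grid dimensions giving spacing <= d_min/3 (the common oversampling
# default) and honouring the Nyquist requirement for the index range
.default_grid <- function(cell, d_min, oversample = 3) {
  n <- ceiling(oversample * c(cell$a, cell$b, cell$c) / d_min)
  pmax(n, 4L)
}

#' Fourier synthesis of a density map
#'
#' Inverse Fourier synthesis over the P1 cell,
#' \deqn{\rho(x) = (1/V) \sum_h F_h e^{-2\pi i h \cdot x},}
#' with Friedel completion (the conjugate mate of every stored reflection
#' is added automatically) and the (0,0,0) term omitted, so the map has
#' zero mean. Implemented with an FFT; the grid must satisfy Nyquist for
#' every stored index.
#'
#' @param rs A `reflection_set` whose entries all carry phases.
#' @param grid Integer vector (nx, ny, nz); defaults to spacing
#'   `d_min/3` along each axis.
#' @param provenance Provenance tag for the returned map.
#' @return A [density_map()] in electrons/Angstrom^3 (for absolute-scale
#'   amplitudes); `map_sigma` is the RMS voxel value.
#' @export
synthesize_map <- function(rs, grid = NULL, provenance = "plain") {
  dat <- rs$data
  if (anyNA(dat$phase)) {
    bad <- which(is.na(dat$phase))
    stop("reflections without phases: ",
         paste(sprintf("(%d,%d,%d)", dat$h[bad], dat$k[bad], dat$l[bad])[
           seq_len(min(5, length(bad)))], collapse = " "),
         if (length(bad) > 5) " ..." else "")
  }
  if (is.null(grid)) grid <- .default_grid(rs$cell, min(dat$d))
  grid <- as.integer(grid)
  hm <- c(max(abs(dat$h)), max(abs(dat$k)), max(abs(dat$l)))
  if (any(grid < 2 * hm + 1))
    stop("grid too coarse for the stored indices (Nyquist violation)")
  arr <- array(0 + 0i, dim = grid)
  fc <- dat$f * exp(1i * dat$phase * pi / 180)
  idx <- function(h, n) (h %% n) + 1L
  i1 <- cbind(idx(dat$h, grid[1]), idx(dat$k, grid[2]), idx(dat$l, grid[3]))
  i2 <- cbind(idx(-dat$h, grid[1]), idx(-dat$k, grid[2]), idx(-dat$l, grid[3]))
  arr[i1] <- arr[i1] + fc
  arr[i2] <- arr[i2] + Conj(fc)
  rho <- Re(stats::fft(arr)) / cell_volume(rs$cell)
  density_map(rho, rs$cell, provenance = provenance)
}

#' Observed difference electron density (DED) map
#'
#' Composes the full observed-DED route: scale the light data onto the
#' dark data, form filtered difference amplitudes, optionally apply
#' per-reflection weights, take phases from the dark-model structure
#' factors, and synthesize the map.
#'
#' @param light,dark Observed `reflection_set`s.
#' @param dark_model The dark-state [atom_model()] supplying phases.
#' @param snr_min,d_low Filters passed to [difference_amplitudes()].
#' @param weights Optional [compute_qweights()] result (or numeric vector
#'   aligned with the difference set) multiplied into the amplitudes.
#' @param grid Optional grid dimensions.
#' @param mode Form-factor mode for the phasing model.
#' @param scale If `FALSE`, skip [scale_to_reference()] (data already scaled).
#' @return A `density_map` tagged `"observed-DED"`.
#' @export
ded_map <- function(light, dark, dark_model, snr_min = 3, d_low = 10,
                    weights = NULL, grid = NULL, mode = "cromer_mann",
                    scale = TRUE) {
  if (scale) light <- scale_to_reference(light, dark)
  diff <- difference_amplitudes(light, dark, snr_min = snr_min, d_low = d_low)
  if (!is.null(weights)) {
    w <- if (inherits(weights, "qweights")) weights$w else weights
    stopifnot(length(w) == nrow(diff$data))
    diff$data$f <- diff$data$f * w
  }
  diff <- .phase_from_model(diff, dark_model, mode)
  synthesize_map(diff, grid = grid, provenance = "observed-DED")
}

# attach phases computed from a model to a (difference) set
.phase_from_model <- function(rs, model, mode = "cromer_mann") {
  hkl <- as.matrix(rs$data[, c("h", "k", "l")])
  if (!nrow(hkl)) stop("cannot phase an empty reflection set")
  fc <- .complex_sf(model, hkl, mode)
  rs$data$phase <- Arg(fc) * 180 / pi
  rs
}

#' Zero out voxels below a sigma level
#'
#' Voxels with `|value| < level_sigma * map_sigma` are set to zero; the
#' rest are untouched. The original `map_sigma` is retained so repeated
#' thresholding refers to the same contour scale.
#'
#' @param map A `density_map`.
#' @param level_sigma Threshold in map-sigma units (>= 0).
#' @return The thresholded `density_map`.
#' @export
threshold_map <- function(map, level_sigma) {
  stopifnot(level_sigma >= 0)
  v <- map$values
  v[abs(v) < level_sigma * map$map_sigma] <- 0
  out <- map
  out$values <- v        # keep original map_sigma for contour reference
  out
}
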