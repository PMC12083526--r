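#' UV/Vis absorption spectrum
#'
#' @param wavelength Wavelength grid in nm, strictly increasing.
#' @param absorbance Absorbance values (AU), same length.
#' @param delay Optional pump-probe delay in seconds.
#' @param crystal Optional crystal identifier.
#' @param power Optional pump power (GW/cm^2).
#' @return Object of class `spectrum`.
#' @export
spectrum <- function(wavelength, absorbance, delay = NA_real_,
                     crystal = NA_character_, power = NA_real_) {
  stopifnot(length(wavelength) == length(absorbance))
  if (is.unsorted(wavelength, strictly = TRUE))
    stop("wavelengths must be strictly increasing")
  structure(list(wavelength = wavelength, absorbance = absorbance,
                 delay = delay, crystal = crystal, power = power),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %.0f-%.0f nm%s\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              if (!is.na(x$delay)) sprintf(", delay %.3g s", x$delay) else ""))
  invisible(x)
}

#' Savitzky-Golay smoothing
#'
#' Replaces each point by the center value of a local least-squares
#' polynomial fit. Defaults mirror the standard spectral-smoothing
#' choice: a 21-point window with a third-degree polynomial. Near the
#' edges the window shrinks symmetrically (the polynomial order is
#' reduced only where fewer points than `order + 1` remain).
#'
#' @param spec A [spectrum()] (or any numeric vector via `$absorbance`).
#' @param window Odd window length in points (> order).
#' @param order Polynomial degree.
#' @return The smoothed `spectrum`.
#' @export
smooth_sg <- function(spec, window = 21, order = 3) {
  stopifnot(window %% 2 == 1, window > order)
  y <- spec$absorbance
  n <- length(y)
  if (n < window) stop("spectrum shorter than the smoothing window")
  h <- (window - 1) / 2
  # precompute the center-evaluation row for each half-width
  rows <- list()
  center_row <- function(hh, p) {
    x <- (-hh):hh
    V <- outer(x, 0:p, `^`)
    solve(crossprod(V), t(V))[1, ]          # row giving the constant term
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    hh <- min(h, i - 1, n - i)
    p <- min(order, 2 * hh)                  # shrink order at extreme edges
    key <- paste(hh, p)
    if (is.null(rows[[key]])) rows[[key]] <- center_row(hh, p)
    out[i] <- sum(rows[[key]] * y[(i - hh):(i + hh)])
  }
  spec$absorbance <- out
  spec
}

#' Rayleigh scattering correction
#'
#' Fits `b * lambda^-4 + c` over an absorption-free window (default
#' 700-800 nm) and subtracts the `b * lambda^-4` term across the whole
#' spectrum. The fitted `(b, c)` are attached as attribute
#' `"scatter_fit"`.
#'
#' @param spec A [spectrum()].
#' @param fit_window Length-2 nm range free of chromophore absorption.
#' @return The corrected `spectrum` with attribute `scatter_fit`.
#' @export
subtract_scattering <- function(spec, fit_window = c(700, 800)) {
  wl <- spec$wavelength
  inw <- wl >= fit_window[1] & wl <= fit_window[2]
  if (sum(inw) < 3) stop("scattering fit window lies outside the spectrum grid")
  x4 <- wl^-4
  fit <- stats::lm.fit(cbind(x4[inw], 1), spec$absorbance[inw])
  b <- unname(fit$coefficients[1]); cst <- unname(fit$coefficients[2])
  spec$absorbance <- spec$absorbance - b * x4
  attr(spec, "scatter_fit") <- c(b = b, c = cst)
  spec
}

#' Trapezoidal band integration
#'
#' @param spec A [spectrum()].
#' @param lo,hi Band limits in nm (`hi > lo`, both within the grid).
#' @return Integral of absorbance over \[lo, hi\] in AU nm.
#' @export
integrate_band <- function(spec, lo, hi) {
  if (hi <= lo) stop("band limits must satisfy hi > lo")
  wl <- spec$wavelength
  if (lo < min(wl) || hi > max(wl)) stop("band limits outside the wavelength grid")
  keep <- wl >= lo & wl <= hi
  x <- wl[keep]; y <- spec$absorbance[keep]
  # clip exactly to the band edges by linear interpolation
  if (x[1] > lo) {
    y0 <- stats::approx(wl, spec$absorbance, xout = lo)$y
    x <- c(lo, x); y <- c(y0, y)
  }
  if (x[length(x)] < hi) {
    y1 <- stats::approx(wl, spec$absorbance, xout = hi)$y
    x <- c(x, hi); y <- c(y, y1)
  }
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Normalized, standardized kinetic trace from a spectral series
#'
#' For each (delay, transient, dark) triple: form the difference
#' spectrum, smooth it (Savitzky-Golay), integrate the radical band
#' (default 580-640 nm), and normalize by the scattering-corrected
#' dark-state band integral (default 456-490 nm) of the same crystal —
#' this cancels the per-crystal optical path length. Repeated delays are
#' averaged; the assembled trace is finally standardized to a maximum of
#' one.
#'
#' @param series List of entries, each a list with fields `delay`
#'   (seconds), `transient` and `dark` ([spectrum()]s on one grid).
#' @param band Difference-band limits in nm.
#' @param norm_band Dark normalization band in nm.
#' @param sg_window,sg_order Savitzky-Golay parameters.
#' @param scatter_window Scattering-fit window in nm.
#' @param standardize Divide by the trace maximum (default `TRUE`).
#' @return A [time_trace()] ready for [fit_trace()].
#' @export
build_difference_trace <- function(series, band = c(580, 640),
                                   norm_band = c(456, 490),
                                   sg_window = 21, sg_order = 3,
                                   scatter_window = c(700, 800),
                                   standardize = TRUE) {
  delays <- vapply(series, `[[`, numeric(1), "delay")
  vals <- vapply(series, function(e) {
    stopifnot(identical(e$transient$wavelength, e$dark$wavelength))
    diff <- e$dark
    diff$absorbance <- e$transient$absorbance - e$dark$absorbance
    diff <- smooth_sg(diff, sg_window, sg_order)
    num <- integrate_band(diff, band[1], band[2])
    dk <- subtract_scattering(e$dark, scatter_window)
    den <- integrate_band(dk, norm_band[1], norm_band[2])
    if (den <= 0) stop("non-positive dark normalizer for crystal ",
                       e$dark$crystal)
    num / den
  }, numeric(1))
  agg <- tapply(vals, delays, mean)
  tt <- as.numeric(names(agg)); vv <- as.numeric(agg)
  o <- order(tt)
  tt <- tt[o]; vv <- vv[o]
  if (standardize) {
    m <- max(vv)
    if (m > 0) vv <- vv / m
  }
  time_trace(tt, vv, label = "normalized difference band")
}

#' Pairwise Pearson correlation between difference spectra
#'
#' Shared implementation with [feature_correlation_map()]; spectra are
#' smoothed before correlation.
#'
#' @param diff_spectra List of difference [spectrum()]s on one grid.
#' @param sg_window,sg_order Savitzky-Golay parameters (set
#'   `sg_window = 0` to skip smoothing).
#' @return Symmetric correlation matrix.
#' @export
spectra_correlation_map <- function(diff_spectra, sg_window = 21,
                                    sg_order = 3) {
  vecs <- lapply(diff_spectra, function(s) {
    if (sg_window > 0) s <- smooth_sg(s, sg_window, sg_order)
    s$absorbance
  })
  feature_correlation_map(vecs)
}

#' Molar extinction coefficient table for the flavin two-state system
#'
#' Defaults are the reported coefficients for oxidized FAD and the
#' neutral semiquinone radical FADH at 450 and 635 nm, in 1/(M cm):
#' FAD_ox 11204 (450 nm) and 0 (635 nm); FADH 3833 (450 nm) and
#' 4958 (635 nm).
#'
#' @param eps_ox_450,eps_ox_635,eps_sq_450,eps_sq_635 Coefficients
#'   (>= 0).
#' @return Object of class `extinction_table` (2x2 matrix, rows =
#'   wavelengths 450/635, columns = species ox/sq).
#' @export
extinction_table <- function(eps_ox_450 = 11204, eps_ox_635 = 0,
                             eps_sq_450 = 3833, eps_sq_635 = 4958) {
  m <- matrix(c(eps_ox_450, eps_ox_635, eps_sq_450, eps_sq_635), 2, 2,
              dimnames = list(c("450", "635"), c("ox", "sq")))
  if (any(m < 0)) stop("extinction coefficients must be >= 0")
  structure(m, class = c("extinction_table", "matrix"))
}

#' Two-state Lambert-Beer deconvolution
#'
#' Solves the 2x2 linear system
#' \eqn{A_\lambda = \ell\,(\epsilon_{ox,\lambda} c_{ox} +
#' \epsilon_{sq,\lambda} c_{sq})} at 450 and 635 nm for the two
#' concentrations. Negative solutions are returned as-is but flagged
#' with a warning.
#'
#' @param A450,A635 Absorbances (AU).
#' @param path_cm Optical path length in cm (> 0).
#' @param table An [extinction_table()].
#' @return Named vector `c(c_ox, c_sq)` in molar units.
#' @export
lambert_beer_deconvolve <- function(A450, A635, path_cm = 1,
                                    table = extinction_table()) {
  stopifnot(path_cm > 0)
  M <- unclass(table)
  if (abs(det(M)) < 1e-12 * max(abs(M))^2)
    stop("extinction table is singular at this wavelength pair")
  conc <- solve(path_cm * M, c(A450, A635))
  names(conc) <- c("c_ox", "c_sq")
  if (any(conc < -1e-12)) warning("negative concentration solution")
  conc
}
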