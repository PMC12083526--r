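#' Scale one observed dataset onto a reference
#'
#' Linear+Wilson scaling in the style of SCALEIT: finds `(k, B_rel)`
#' minimizing the sigma-weighted squared amplitude difference
#' \deqn{\sum_h w_h (|F_{ref}| - k e^{-B_{rel} s^2} |F_{mov}|)^2}
#' over the common reflections, with \eqn{w_h = 1/(\sigma_{ref}^2 +
#' \sigma_{mov}^2)} (unit weights when all sigmas are zero), then applies
#' the factor to the moving set's amplitudes and sigmas.
#'
#' @param moving,reference `reflection_set`s sharing >= 10 reflections.
#' @return The moving set with scaled amplitudes/sigmas; the fitted scale
#'   is attached as attribute `"scale"` (`k`, `B_rel`).
#' @export
scale_to_reference <- function(moving, reference) {
  cm <- .common_hkl(moving, reference)
  if (length(cm$ia) < 10)
    stop("insufficient overlap: fewer than 10 common reflections")
  fm <- moving$data$f[cm$ia]
  fr <- reference$data$f[cm$ib]
  s2 <- 1 / (4 * moving$data$d[cm$ia]^2)
  w <- 1 / (reference$data$sigf[cm$ib]^2 + moving$data$sigf[cm$ia]^2)
  if (all(!is.finite(w))) w <- rep(1, length(fm))
  w[!is.finite(w)] <- max(w[is.finite(w)])

  kopt <- function(B) {
    e <- exp(-B * s2)
    sum(w * fr * fm * e) / sum(w * (fm * e)^2)
  }
  obj <- function(B) {
    k <- kopt(B)
    sum(w * (fr - k * exp(-B * s2) * fm)^2)
  }
  op <- stats::optimize(obj, interval = c(-200, 200), tol = 1e-10)
  B_rel <- op$minimum
  k <- kopt(B_rel)
  fac <- k * exp(-B_rel * s2)

  out <- moving
  out$data <- moving$data[cm$ia, , drop = FALSE]
  out$data$f <- fm * fac
  out$data$sigf <- moving$data$sigf[cm$ia] * fac
  rownames(out$data) <- NULL
  out$d_min <- min(out$data$d); out$d_max <- max(out$data$d)
  attr(out, "scale") <- c(k = k, B_rel = B_rel)
  out
}

#' Filtered difference amplitudes between scaled light and dark data
#'
#' Returns the isomorphous difference set
#' \eqn{\Delta F = |F_{o,l}| - |F_{o,dark}|} with
#' \eqn{\sigma_{\Delta F} = \sqrt{\sigma_l^2 + \sigma_{dark}^2}},
#' restricted to common reflections that (a) lie below the low-resolution
#' cutoff (`d < d_low`, default 10 Angstrom, which keeps high-intensity
#' low-resolution terms from dominating the maps), and (b) have amplitude
#' signal-to-noise `f/sigf > snr_min` (default 3) in both parents.
#' Reflections with zero sigma count as infinite signal-to-noise.
#'
#' @param light,dark Observed `reflection_set`s (light already scaled to
#'   dark; see [scale_to_reference()]).
#' @param snr_min Minimum amplitude SNR required in both parents.
#' @param d_low Low-resolution cutoff in Angstrom.
#' @return A `reflection_set` with role `"difference"`. `f` holds the
#'   signed difference amplitude (may be negative); `sigf` the propagated
#'   sigma. Emits a warning when nothing survives the filters.
#' @export
difference_amplitudes <- function(light, dark, snr_min = 3, d_low = 10) {
  stopifnot(snr_min >= 0, d_low > 0)
  cm <- .common_hkl(light, dark)
  dl <- light$data[cm$ia, , drop = FALSE]
  dd <- dark$data[cm$ib, , drop = FALSE]
  snr <- function(f, s) ifelse(s > 0, f / s, Inf)
  keep <- dl$d < d_low &
    snr(dl$f, dl$sigf) > snr_min & snr(dd$f, dd$sigf) > snr_min
  if (!any(keep)) {
    warning("no reflections survive the SNR/resolution filters; empty difference set")
    keep[which.max(dl$d)] <- TRUE   # keep one entry so the object is valid
    out <- .make_diff(dl[keep, ], dd[keep, ], light$cell)
    out$data <- out$data[0, ]
    return(out)
  }
  .make_diff(dl[keep, , drop = FALSE], dd[keep, , drop = FALSE], light$cell)
}

.make_diff <- function(dl, dd, cell) {
  out <- reflection_set(as.matrix(dl[, c("h", "k", "l")]),
                        f = rep(0, nrow(dl)), sigf = sqrt(dl$sigf^2 + dd$sigf^2),
                        phase = NULL, cell = cell, role = "difference")
  out$data$f <- dl$f - dd$f       # signed: bypass the >=0 amplitude check
  out
}
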