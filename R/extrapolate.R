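#' Bayesian (q-) weights for a difference set
#'
#' The Ren/Srajer-style per-reflection weight
#' \deqn{w_h = 1/\left(1 + \sigma^2_{\Delta F,h}/\langle\sigma^2_{\Delta F}\rangle
#'   + \Delta F_h^2/\langle\Delta F^2\rangle\right)}
#' which down-weights both noisy and outlier difference amplitudes.
#' Raw weights lie in (0, 1]; because their mean is well below 1, users
#' feeding them into extrapolation typically renormalize to unit mean so
#' the N scale of the occupancy analysis is preserved
#' (`normalize = "mean"`, the [residual_density_scan()] default).
#'
#' @param diff A difference `reflection_set`.
#' @param normalize `"none"` (raw weights in (0,1]) or `"mean"`
#'   (rescaled to mean 1).
#' @return Object of class `qweights` with field `w` aligned to `diff`.
#' @export
compute_qweights <- function(diff, normalize = c("none", "mean")) {
  normalize <- match.arg(normalize)
  dF <- diff$data$f
  sg <- diff$data$sigf
  if (all(dF == 0) && all(sg == 0)) {
    warning("all-zero difference amplitudes and sigmas: uniform weights")
    w <- rep(1, length(dF))
  } else {
    ms2 <- mean(sg^2)
    mf2 <- mean(dF^2)
    w <- 1 / (1 + (if (ms2 > 0) sg^2 / ms2 else 0) +
                (if (mf2 > 0) dF^2 / mf2 else 0))
  }
  if (normalize == "mean") w <- w / mean(w)
  structure(list(w = w, n = length(w), normalize = normalize),
            class = "qweights")
}

#' Structure-factor extrapolation
#'
#' Linearly amplifies weighted difference amplitudes by a factor `N` on
#' top of the calculated dark structure factors, deconvoluting a
#' partially occupied state:
#' scalar mode \eqn{|F_{ext}| = N w \Delta F + |F_{c,dark}|} with
#' \eqn{\sigma_{ext} = N w \sigma_{\Delta F}} and dark phases; vectorial
#' mode \eqn{F_{ext} = N w \Delta F e^{i\alpha_{dark}} + F_{c,dark}} as a
#' complex sum, returning the updated amplitude and phase. Negative
#' scalar amplitudes are clipped to zero and counted (attribute
#' `"n_clipped"`).
#'
#' @param diff Difference `reflection_set` (signed `f`).
#' @param dark_calc Calculated dark set with phases, on the same indices
#'   (a superset is fine).
#' @param N Extrapolation factor (>= 0; `N = 2/alpha` targets occupancy
#'   `alpha`).
#' @param mode `"scalar"` or `"vectorial"`.
#' @param weights Optional [compute_qweights()] object or numeric vector
#'   aligned with `diff`; default unit weights.
#' @param dark_obs Optional observed dark set; when supplied with
#'   `base = "obs"`, observed dark amplitudes replace `|F_c,dark|` in
#'   scalar mode.
#' @param base `"calc"` (default) or `"obs"`.
#' @return A `reflection_set` with role `"extrapolated"`.
#' @export
extrapolate <- function(diff, dark_calc, N, mode = c("scalar", "vectorial"),
                        weights = NULL, dark_obs = NULL, base = c("calc", "obs")) {
  mode <- match.arg(mode); base <- match.arg(base)
  stopifnot(N >= 0)
  if (all(is.na(dark_calc$data$phase))) stop("dark_calc lacks phases")
  cm <- .common_hkl(diff, dark_calc)
  if (length(cm$ia) < nrow(diff$data))
    stop("dark_calc does not cover all difference reflections")
  dd <- diff$data[cm$ia, , drop = FALSE]
  dc <- dark_calc$data[cm$ib, , drop = FALSE]
  w <- if (is.null(weights)) rep(1, nrow(dd))
       else if (inherits(weights, "qweights")) weights$w[cm$ia]
       else weights[cm$ia]
  fbase <- dc$f
  if (base == "obs") {
    if (is.null(dark_obs)) stop("base = 'obs' requires dark_obs")
    co <- .common_hkl(diff, dark_obs)
    if (length(co$ia) < nrow(diff$data)) stop("dark_obs does not cover diff")
    fbase <- dark_obs$data$f[co$ib][match(cm$ia, co$ia)]
  }
  hkl <- as.matrix(dd[, c("h", "k", "l")])
  if (mode == "scalar") {
    fext <- N * w * dd$f + fbase
    ncl <- sum(fext < 0)
    fext <- pmax(fext, 0)
    out <- reflection_set(hkl, f = fext, sigf = N * w * dd$sigf,
                          phase = dc$phase, cell = diff$cell,
                          role = "extrapolated")
    attr(out, "n_clipped") <- ncl
  } else {
    # vectorial: difference vector along the dark phase added to the full
    # complex dark structure factor
    ph <- dc$phase * pi / 180
    fvec <- (N * w * dd$f + dc$f) * exp(1i * ph)
    out <- reflection_set(hkl, f = Mod(fvec), sigf = N * w * dd$sigf,
                          phase = Arg(fvec) * 180 / pi, cell = diff$cell,
                          role = "extrapolated")
    attr(out, "n_clipped") <- 0L
  }
  attr(out, "N") <- N
  attr(out, "mode") <- mode
  out
}

#' Residual negative density versus extrapolation factor
#'
#' For each `N` on the grid, builds the q-weighted scalar extrapolated
#' map (dark phases) and integrates the negative density above the
#' `level_sigma` contour within the marker region, recording its
#' magnitude. At low `N` the dark-state contribution dominates and the
#' residual stays near zero; once `N` exceeds `2/alpha` the amplified
#' difference terms over-subtract the departing atoms and the residual
#' grows steadily — the inflection between the two regimes estimates the
#' activated fraction (see [estimate_occupancy()]).
#'
#' The marker voxel set follows the stated region-selection rule: voxels
#' within `radius` of the selected atoms where the (q-weighted) DED map
#' shows significant signal, i.e. beyond `level_sigma` DED map-sigmas.
#' `marker_mode = "ded_negative"` (default) keeps only the negative DED
#' voxels — the departing density whose over-subtraction marks
#' over-extrapolation; `"ded_both"` keeps both signs; `"sphere"` keeps
#' the whole sphere. The negative extrapolated density is integrated
#' raw within that fixed set. Subtracting the calculated dark-model map
#' first (`subtrahend = "dark_calc"`) is available for comparison, but
#' note that it makes the residual exactly linear in `N` and therefore
#' destroys the inflection.
#'
#' @param diff Difference `reflection_set`.
#' @param dark_calc Calculated dark set with phases covering `diff`.
#' @param dark_model Dark [atom_model()] (grid/marker reference).
#' @param marker A [region_mask()] (used as-is) or a selection string
#'   evaluated on `dark_model`.
#' @param N_grid Extrapolation factors; default 21 log-spaced in \[2, 40\]
#'   (covers occupancies 0.05-1).
#' @param weights Optional weights; default mean-normalized q-weights.
#' @param grid Map grid dimensions (default from the data resolution).
#' @param level_sigma DED contour defining "significant signal" for the
#'   marker restriction.
#' @param radius Marker radius when `marker` is a selection string.
#' @param marker_mode `"ded_negative"`, `"ded_both"` or `"sphere"`.
#' @param subtrahend `"none"` (default) or `"dark_calc"`.
#' @return Object of class `occupancy_scan`: data.frame `scan`
#'   (N, drho_res), the marker, and `N_star`/`alpha`/`se` filled by
#'   [estimate_occupancy()].
#' @export
residual_density_scan <- function(diff, dark_calc, dark_model, marker,
                                  N_grid = exp(seq(log(2), log(40), length.out = 21)),
                                  weights = NULL, grid = NULL, level_sigma = 3,
                                  radius = 2.0,
                                  marker_mode = c("ded_negative", "ded_both", "sphere"),
                                  subtrahend = c("none", "dark_calc")) {
  subtrahend <- match.arg(subtrahend)
  marker_mode <- match.arg(marker_mode)
  if (length(N_grid) < 5) stop("N_grid needs >= 5 values")
  if (is.unsorted(N_grid, strictly = TRUE)) stop("N_grid must be strictly increasing")
  if (any(N_grid < 1)) stop("all N must be >= 1")
  if (is.null(weights)) weights <- compute_qweights(diff, normalize = "mean")
  if (is.null(grid)) grid <- .default_grid(diff$cell, min(diff$data$d))
  if (!inherits(marker, "region_mask")) {
    marker <- region_mask(dark_model, marker, grid = grid, radius = radius)
    if (marker_mode != "sphere") {
      wded <- diff
      wded$data$f <- wded$data$f * weights$w
      wded <- .phase_from_model(wded, dark_model)
      dmap <- synthesize_map(wded, grid = grid, provenance = "observed-DED")
      sig <- if (marker_mode == "ded_negative")
        dmap$values <= -level_sigma * dmap$map_sigma
      else abs(dmap$values) >= level_sigma * dmap$map_sigma
      if (dmap$map_sigma == 0 || !any(marker$voxels & sig)) {
        warning("no ", level_sigma, "-sigma DED signal within the marker; ",
                "scan returned with zero residuals")
        return(structure(list(scan = data.frame(N = N_grid,
                                                drho_res = rep(0, length(N_grid))),
                              marker = marker, level_sigma = level_sigma,
                              N_star = NA_real_, alpha = NA_real_,
                              se = NA_real_),
                         class = "occupancy_scan"))
      }
      marker$voxels <- marker$voxels & sig
    }
  }
  dark_map <- if (subtrahend == "dark_calc")
    synthesize_map(dark_calc, grid = grid) else NULL
  drho <- vapply(N_grid, function(N) {
    ext <- extrapolate(diff, dark_calc, N = N, mode = "scalar",
                       weights = weights)
    m <- synthesize_map(ext, grid = grid, provenance = "extrapolated")
    if (!is.null(dark_map)) {
      m$values <- m$values - dark_map$values
      m$map_sigma <- sqrt(mean(m$values^2))
    }
    abs(integrate_region(m, marker, sign = "negative", threshold = FALSE))
  }, numeric(1))
  if (all(drho == 0))
    warning("no negative density within the marker at any N")
  structure(list(scan = data.frame(N = N_grid, drho_res = drho),
                 marker = marker, level_sigma = level_sigma,
                 N_star = NA_real_, alpha = NA_real_, se = NA_real_),
            class = "occupancy_scan")
}

#' @export
print.occupancy_scan <- function(x, ...) {
  cat(sprintf("<occupancy_scan> %d N values in [%.2f, %.2f]",
              nrow(x$scan), min(x$scan$N), max(x$scan$N)))
  if (!is.na(x$N_star))
    cat(sprintf("; N* = %.2f (alpha = %.3f +/- %.3f)",
                x$N_star, x$alpha, 2 / x$N_star^2 * x$se))
  cat("\n")
  invisible(x)
}

#' Occupancy from the inflection of the residual-density scan
#'
#' Fits a continuous two-segment model with a grid-searched breakpoint;
#' the breakpoint `N*` marks the transition between the dark-dominated
#' (flat) and difference-dominated (rising) regimes, and the activated
#' fraction follows the difference-map convention `alpha = 2/N*`.
#'
#' Beyond the onset the residual grows superlinearly (the
#' over-subtracted region both deepens and widens with `N`), so with the
#' default `transform = "sqrt"` the model is fitted to
#' `sqrt(drho_res)`, which linearizes the rising regime; the left
#' segment is held flat (zero slope, matching the dark-dominated
#' regime), and when the scan shows a genuine flat regime (first point
#' below 10 percent of the maximum) the fit is restricted to the onset
#' half of the rise (values below half maximum), where the
#' linearization is accurate. `transform = "none"` fits the classic
#' free-slope two-line model to the raw values and recovers an exact
#' piecewise-linear scan's breakpoint exactly. The breakpoint standard
#' error comes from the residual-sum-of-squares profile.
#'
#' @param scan An [residual_density_scan()] result (>= 5 points spanning
#'   both regimes).
#' @param transform `"sqrt"` (default) or `"none"`.
#' @return The scan with `N_star`, `alpha` and `se` (breakpoint standard
#'   error) filled in.
#' @export
estimate_occupancy <- function(scan, transform = c("sqrt", "none")) {
  stopifnot(inherits(scan, "occupancy_scan"))
  transform <- match.arg(transform)
  N <- scan$scan$N; y0 <- scan$scan$drho_res
  n <- length(N)
  if (n < 5) stop("scan needs >= 5 points")
  if (max(abs(y0)) == 0) stop("no inflection detectable: scan is identically zero")

  if (transform == "sqrt") {
    z <- sqrt(y0)
    two_regime <- z[1] <= 0.1 * max(z)
    keep <- if (two_regime) z <= 0.5 * max(z) else rep(TRUE, n)
    if (sum(keep) < 6) keep <- seq_len(n) <= 6
    Nk <- N[keep]; zk <- z[keep]
    rss_at <- function(c0) {
      X <- cbind(1, pmax(Nk - c0, 0))
      sum(stats::lm.fit(X, zk)$residuals^2)
    }
  } else {
    Nk <- N; zk <- y0
    two_regime <- TRUE
    rss_at <- function(c0) {
      X <- cbind(1, pmin(Nk - c0, 0), pmax(Nk - c0, 0))
      sum(stats::lm.fit(X, zk)$residuals^2)
    }
  }
  nk <- length(Nk)
  rss_line <- sum(stats::lm.fit(cbind(1, Nk), zk)$residuals^2)
  zscale <- max(abs(zk))
  if (transform == "none" && rss_line <= 1e-18 * zscale^2)
    stop("no inflection detectable: scan is linear in N")
  cand <- seq(Nk[1], Nk[nk - 1], length.out = 200)
  rss <- vapply(cand, rss_at, numeric(1))
  best <- which.min(rss)
  lo <- cand[max(1, best - 2)]; hi <- cand[min(length(cand), best + 2)]
  op <- stats::optimize(rss_at, c(lo, hi))
  N_star <- op$minimum; rss2 <- op$objective
  if (rss2 > rss[best]) { N_star <- cand[best]; rss2 <- rss[best] }
  # a scan rising from the very first N is a saturated (edge) breakpoint,
  # not a missing one; the no-inflection guard applies otherwise
  check_line <- transform == "none" || two_regime
  if (check_line && rss_line > 1e-18 * zscale^2 &&
      (rss_line - rss2) / rss_line < 0.10)
    stop("no inflection detectable: breakpoint fit barely improves on a line")
  s2 <- rss2 / max(nk - 4, 1)
  ok <- cand[rss <= rss2 + s2]
  se <- if (length(ok) > 1) (max(ok) - min(ok)) / 2 else (N[n] - N[1]) / n
  scan$N_star <- N_star
  scan$alpha <- min(2 / N_star, 1)
  scan$se <- se
  scan
}
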