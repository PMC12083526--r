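#' Kinetic time trace
#'
#' @param time Time points in seconds, strictly increasing, all > 0
#'   (a leading 0 is tolerated and kept).
#' @param value Trace values (arbitrary units).
#' @param sigma Optional per-point uncertainties.
#' @param label Trace label.
#' @return Object of class `time_trace`.
#' @export
time_trace <- function(time, value, sigma = NULL, label = "") {
  stopifnot(length(time) == length(value))
  if (is.unsorted(time, strictly = TRUE)) stop("time must be strictly increasing")
  if (any(time < 0)) stop("times must be >= 0")
  if (!is.null(sigma)) stopifnot(length(sigma) == length(time), all(sigma >= 0))
  structure(list(time = time, value = value, sigma = sigma, label = label),
            class = "time_trace")
}

#' @export
print.time_trace <- function(x, ...) {
  cat(sprintf("<time_trace> '%s': %d points, t = %.3g..%.3g s\n",
              x$label, length(x$time), min(x$time), max(x$time)))
  invisible(x)
}

#' First-order (single-exponential) kinetic model
#'
#' \eqn{A(t) = A_\infty (1 - e^{-t/\tau})}.
#'
#' @param t Time in seconds.
#' @param A_inf Plateau amplitude.
#' @param tau Time constant in seconds (> 0).
#' @return Model value(s).
#' @export
eval_first_order <- function(t, A_inf, tau) {
  if (tau <= 0) stop("tau must be > 0")
  A_inf * (1 - exp(-t / tau))
}

#' Two-step sequential kinetic model (rise-then-decay)
#'
#' Intermediate population of a sequential A -> B -> C scheme:
#' \deqn{y(t) = baseline + A \frac{\tau_2}{\tau_2 - \tau_1}
#'   \left(e^{-t/\tau_2} - e^{-t/\tau_1}\right)}
#' rising with the fast constant `tau1` and decaying with the slow
#' `tau2` (`tau1 < tau2` by convention). The degenerate `tau1 == tau2`
#' limit `A (t/tau) e^{-t/tau}` is available via `degenerate = TRUE`.
#'
#' @param t Time in seconds.
#' @param A Amplitude.
#' @param tau1,tau2 Rise and decay time constants in seconds (> 0).
#' @param baseline Additive offset (default 0).
#' @param degenerate Allow the `tau1 == tau2` limiting form.
#' @return Model value(s).
#' @export
eval_two_step <- function(t, A, tau1, tau2, baseline = 0, degenerate = FALSE) {
  if (tau1 <= 0 || tau2 <= 0) stop("tau1 and tau2 must be > 0")
  if (tau1 == tau2) {
    if (!degenerate) stop("tau1 == tau2 is degenerate; set degenerate = TRUE for the limiting form")
    return(baseline + A * (t / tau1) * exp(-t / tau1))
  }
  baseline + A * (tau2 / (tau2 - tau1)) * (exp(-t / tau2) - exp(-t / tau1))
}

# linear-subproblem design matrices: given taus, amplitude/baseline enter
# linearly, so profile them out by weighted least squares
.fo_curve <- function(t, tau) 1 - exp(-t / tau)
.ts_curve <- function(t, tau1, tau2) exp(-t / tau2) - exp(-t / tau1)

.wls <- function(X, y, w) {
  Xw <- X * sqrt(w); yw <- y * sqrt(w)
  fit <- stats::lm.fit(Xw, yw)
  list(coef = fit$coefficients, rss = sum(fit$residuals^2))
}

#' Fit a kinetic model to a time trace
#'
#' Weighted least squares in linear value space on the (typically
#' log-spaced) time grid. Amplitude-like parameters are profiled out
#' analytically; the time constants are located by a log-spaced grid
#' search spanning the data's time range followed by Nelder-Mead
#' polishing (multi-start, deterministic). Weights are `1/sigma^2` when
#' the trace carries uncertainties, else 1. Repeated time points are
#' averaged before fitting.
#'
#' @param trace A [time_trace()] (>= 4 points for first-order, >= 6 for
#'   two-step).
#' @param model `"first_order"` or `"two_step"`.
#' @param init Optional named initialization (`tau`, or `tau1`/`tau2`);
#'   added to the start list.
#' @return Object of class `kinetic_fit`: `model`, `par` (named:
#'   first-order `A_inf`, `tau`; two-step `A`, `tau1`, `tau2`,
#'   `baseline`), `se`, `rss`, `fitted`, `status`
#'   (`"ok"` or `"degenerate"`), `trace`.
#' @export
fit_trace <- function(trace, model = c("first_order", "two_step"),
                      init = NULL) {
  model <- match.arg(model)
  t <- trace$time; y <- trace$value
  # average repeats (possible after delay-grid assembly upstream)
  if (anyDuplicated(t)) {
    y <- tapply(y, t, mean); t <- as.numeric(names(y)); y <- as.numeric(y)
  }
  pos <- t > 0
  w <- if (!is.null(trace$sigma)) {
    s <- trace$sigma; s[s <= 0] <- min(s[s > 0], 1)
    1 / s^2
  } else rep(1, length(t))
  npt <- length(t)
  if (model == "first_order" && npt < 4) stop("need >= 4 points for a first-order fit")
  if (model == "two_step" && npt < 6) stop("need >= 6 points for a two-step fit")
  tmin <- min(t[pos]); tmax <- max(t)
  ltau_lo <- log(tmin / 30); ltau_hi <- log(tmax * 30)
  status <- "ok"

  if (model == "first_order") {
    rss_of <- function(ltau) {
      X <- cbind(.fo_curve(t, exp(ltau)))
      .wls(X, y, w)$rss
    }
    grid <- seq(ltau_lo, ltau_hi, length.out = 60)
    if (!is.null(init$tau)) grid <- c(log(init$tau), grid)
    r0 <- vapply(grid, rss_of, numeric(1))
    starts <- grid[order(r0)][1:3]
    best <- NULL
    for (s0 in starts) {
      dg <- diff(range(grid)) / length(grid)
      op <- stats::optim(s0, rss_of, method = "Brent",
                         lower = max(ltau_lo, s0 - 2 * dg),
                         upper = min(ltau_hi, s0 + 2 * dg))
      if (is.null(best) || op$value < best$value) best <- op
    }
    # never return worse than the best grid candidate (covers any init)
    if (best$value > min(r0))
      best <- list(par = grid[which.min(r0)], value = min(r0))
    tau <- exp(best$par)
    co <- .wls(cbind(.fo_curve(t, tau)), y, w)
    par <- c(A_inf = unname(co$coef[1]), tau = tau)
    fitted <- eval_first_order(t, par["A_inf"], par["tau"])
    if (best$par <= ltau_lo + 1e-6 || best$par >= ltau_hi - 1e-6)
      status <- "degenerate"
    if (status == "degenerate" && best$par <= ltau_lo + 1e-6)
      par["A_inf"] <- unname(co$coef[1])   # plateau ~ trace level
    modelfun <- function(p) eval_first_order(t, p[1], p[2])
  } else {
    rss_ts <- function(lt) {
      t1 <- exp(min(lt)); t2 <- exp(max(lt))
      if (t2 / t1 < 1 + 1e-8) t2 <- t1 * (1 + 1e-8)
      X <- cbind(.ts_curve(t, t1, t2), 1)
      .wls(X, y, w)$rss
    }
    g <- seq(ltau_lo, ltau_hi, length.out = 18)
    cand <- as.matrix(expand.grid(g, g))
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    if (!is.null(init$tau1) && !is.null(init$tau2))
      cand <- rbind(c(log(init$tau1), log(init$tau2)), cand)
    r0 <- apply(cand, 1, rss_ts)
    starts <- cand[order(r0)[1:4], , drop = FALSE]
    best <- NULL
    for (si in seq_len(nrow(starts))) {
      op <- stats::optim(starts[si, ], rss_ts, method = "Nelder-Mead",
                         control = list(reltol = 1e-12, maxit = 2000))
      if (is.null(best) || op$value < best$value) best <- op
    }
    t1 <- exp(min(best$par)); t2 <- exp(max(best$par))
    if (t2 / t1 < 1 + 1e-8) t2 <- t1 * (1 + 1e-8)
    co <- .wls(cbind(.ts_curve(t, t1, t2), 1), y, w)
    C <- unname(co$coef[1]); b0 <- unname(co$coef[2])
    A <- C * (t2 - t1) / t2          # amplitude convention of eval_two_step
    par <- c(A = A, tau1 = t1, tau2 = t2, baseline = b0)
    fitted <- eval_two_step(t, A, t1, t2, b0)
    modelfun <- function(p) eval_two_step(t, p[1], p[2], p[3], p[4])
  }

  rss <- sum(w * (y - fitted)^2)
  se <- .fit_se(par, modelfun, y, w, rss)
  structure(list(model = model, par = par, se = se, rss = rss,
                 time = t, value = y, fitted = fitted, status = status,
                 trace = trace),
            class = "kinetic_fit")
}

# parameter standard errors from the numerical Jacobian of the model
.fit_se <- function(par, modelfun, y, w, rss) {
  p <- as.numeric(par); np <- length(p); n <- length(y)
  J <- matrix(0, n, np)
  for (j in seq_len(np)) {
    h <- max(abs(p[j]) * 1e-6, 1e-12)
    pp <- p; pp[j] <- pp[j] + h
    pm <- p; pm[j] <- pm[j] - h
    J[, j] <- (modelfun(pp) - modelfun(pm)) / (2 * h)
  }
  s2 <- rss / max(n - np, 1)
  V <- tryCatch(solve(crossprod(J * sqrt(w))) * s2,
                error = function(e) matrix(NA_real_, np, np))
  se <- sqrt(pmax(diag(V), 0))
  names(se) <- names(par)
  se
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> %s (%s)\n", x$model, x$status))
  for (nm in names(x$par))
    cat(sprintf("  %-9s %.6g +/- %.3g\n", nm, x$par[nm], x$se[nm]))
  cat(sprintf("  RSS %.6g over %d points\n", x$rss, length(x$time)))
  invisible(x)
}
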