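# Seeded generators for every pipeline input: toy crystals, perturbed
# light states, mixed noisy reflection datasets, kinetic time series of
# datasets, and spectral series. All randomness is local (Mersenne
# Twister via a saved/restored .Random.seed) so generators never disturb
# the caller's RNG stream and are bit-reproducible for a given seed.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# place an atom at `dist` from `from` toward `dir`
.place <- function(from, toward, dist) {
  u <- toward - from
  from + dist * u / sqrt(sum(u^2))
}

#' Deterministic toy crystal
#'
#' Builds a ~30-atom model in an 18 x 15 x 12 Angstrom P1 cell: a
#' three-residue peptide-like fragment whose central residue is an
#' Asn-analog side chain (rotatable chi1/chi2 axes, see
#' [asn_chi_axes()]), a flat fused 10-atom ring mimicking an
#' isoalloxazine, and six solvent oxygens. The heavy-atom geometry is
#' fixed; the seed only jitters the solvent positions (within 0.3
#' Angstrom) and B-factors, so the model diffracts meaningfully to
#' ~1.6 Angstrom for any seed.
#'
#' @param seed Integer seed.
#' @return An [atom_model()]; the Asn-analog is residue 2, the ring
#'   residue 10, waters residues 20-25.
#' @export
make_toy_crystal <- function(seed = 1) {
  cell <- unit_cell(18, 15, 12)
  A <- function(element, resi, resn, atom, xyz, b)
    data.frame(element = element, resi = resi, resn = resn, atom = atom,
               x = xyz[1], y = xyz[2], z = xyz[3], occ = 1, b = b)
  rows <- list()
  add <- function(...) rows[[length(rows) + 1]] <<- A(...)

  # residue 1 (Gly-like)
  n1  <- c(4.80, 8.60, 6.60)
  ca1 <- .place(n1, c(6.2, 8.9, 6.9), 1.46)
  c1  <- .place(ca1, c(7.0, 8.1, 6.3), 1.52)
  o1  <- .place(c1, c(6.6, 7.0, 5.9), 1.23)
  add("N", 1, "GLY", "N", n1, 12); add("C", 1, "GLY", "CA", ca1, 12)
  add("C", 1, "GLY", "C", c1, 12); add("O", 1, "GLY", "O", o1, 12)
  # residue 2 (Asn-analog with chi1/chi2)
  n2  <- .place(c1, c(7.9, 8.4, 6.1), 1.33)
  ca2 <- .place(n2, c(9.0, 7.6, 6.0), 1.46)
  cb2 <- .place(ca2, c(9.5, 6.9, 7.3), 1.53)
  cg2 <- .place(cb2, c(10.6, 6.1, 7.45), 1.52)
  od1 <- .place(cg2, c(10.9, 6.3, 8.6), 1.23)
  nd2 <- .place(cg2, c(11.3, 5.3, 6.6), 1.33)
  c2  <- .place(ca2, c(10.0, 8.6, 5.6), 1.52)
  o2  <- .place(c2, c(9.9, 9.8, 5.9), 1.23)
  add("N", 2, "ASN", "N", n2, 12); add("C", 2, "ASN", "CA", ca2, 12)
  add("C", 2, "ASN", "CB", cb2, 14); add("C", 2, "ASN", "CG", cg2, 14)
  add("O", 2, "ASN", "OD1", od1, 15); add("N", 2, "ASN", "ND2", nd2, 15)
  add("C", 2, "ASN", "C", c2, 12); add("O", 2, "ASN", "O", o2, 12)
  # residue 3 (Ala-like)
  n3  <- .place(c2, c(11.2, 8.4, 5.2), 1.33)
  ca3 <- .place(n3, c(12.3, 9.2, 5.6), 1.46)
  cb3 <- .place(ca3, c(12.8, 10.0, 6.9), 1.53)
  c3  <- .place(ca3, c(13.5, 8.4, 5.1), 1.52)
  o3  <- .place(c3, c(13.6, 7.2, 5.3), 1.23)
  add("N", 3, "ALA", "N", n3, 12); add("C", 3, "ALA", "CA", ca3, 12)
  add("C", 3, "ALA", "CB", cb3, 14); add("C", 3, "ALA", "C", c3, 12)
  add("O", 3, "ALA", "O", o3, 12)
  # residue 10: flat fused two-ring system (isoalloxazine mimic), z = 2.8
  bond <- 1.40
  cxA <- c(4.3, 3.5); cxB <- c(4.3 + 2 * bond * cos(pi / 6), 3.5)
  hexA <- t(vapply(seq(30, 330, by = 60) * pi / 180,
                   function(a) cxA + bond * c(cos(a), sin(a)), numeric(2)))
  hexB <- t(vapply(seq(30, 330, by = 60) * pi / 180,
                   function(a) cxB + bond * c(cos(a), sin(a)), numeric(2)))
  ring <- unique(round(rbind(hexA, hexB), 6))
  stopifnot(nrow(ring) == 10)
  for (i in seq_len(nrow(ring))) {
    el <- if (i %in% c(1, 6)) "N" else "C"   # two ring nitrogens
    add(el, 10, "FLV", sprintf("%s%d", el, i), c(ring[i, ], 2.8), 10)
  }
  # solvent
  wsites <- rbind(c(2, 12, 9.5), c(15, 12, 3), c(9, 2.5, 9.5),
                  c(15, 3, 9), c(2.5, 5.5, 2), c(12, 13, 10))
  atoms <- .with_seed(seed, {
    for (i in seq_len(nrow(wsites))) {
      add("O", 19 + i, "HOH", "O", wsites[i, ] + stats::runif(3, -0.3, 0.3), 20)
    }
    df <- do.call(rbind, rows)
    df$b <- df$b + stats::runif(nrow(df), -1, 1)
    df
  })
  atom_model(atoms, cell)
}

#' Light-state perturbation specification
#'
#' @param rotations List of `list(axis = rotation_axis(...), angle =
#'   degrees)` entries applied in order (or a [rotation_axes()] plus an
#'   `angles` vector via [apply_perturbation()]).
#' @param displacements Optional named list mapping atom labels to
#'   length-3 Cartesian displacement vectors.
#' @param disorder Optional list with `atoms` (labels) and either
#'   `occ = 0` (atoms vanish in the light state) or `delta_b` (B-factor
#'   increase).
#' @return Object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(rotations = list(), displacements = NULL,
                              disorder = NULL) {
  structure(list(rotations = rotations, displacements = displacements,
                 disorder = disorder),
            class = "perturbation_spec")
}

#' Apply a perturbation to a model
#'
#' Rotations are applied in declared order, displacements next, disorder
#' last.
#'
#' @param model Base (dark) [atom_model()].
#' @param spec A [perturbation_spec()].
#' @return The perturbed (light-state) `atom_model`.
#' @export
apply_perturbation <- function(model, spec) {
  stopifnot(inherits(spec, "perturbation_spec"))
  for (r in spec$rotations)
    model <- .rotate_atoms(model, r$axis, r$angle)
  if (!is.null(spec$displacements)) {
    labs <- atom_labels(model)
    for (nm in names(spec$displacements)) {
      i <- match(nm, labs)
      if (is.na(i)) stop("displacement for unknown atom: ", nm)
      model$atoms[i, c("x", "y", "z")] <-
        model$atoms[i, c("x", "y", "z")] + spec$displacements[[nm]]
    }
  }
  if (!is.null(spec$disorder)) {
    idx <- select_atoms(model, spec$disorder$atoms)
    if (!is.null(spec$disorder$occ)) model$atoms$occ[idx] <- spec$disorder$occ
    if (!is.null(spec$disorder$delta_b))
      model$atoms$b[idx] <- model$atoms$b[idx] + spec$disorder$delta_b
  }
  model
}

#' The standard Asn-analog chi2 light-state perturbation
#'
#' Rotates the toy crystal's Asn-analog chi2 axis by `angle` degrees
#' (default -86.4, the magnitude of the dark-to-light switch the toy
#' emulates).
#'
#' @param angle Rotation in degrees.
#' @param resi Residue carrying the Asn-analog (default 2).
#' @return A [perturbation_spec()].
#' @export
toy_chi2_perturbation <- function(angle = -86.4, resi = 2) {
  ax <- asn_chi_axes(resi)[[2]]
  perturbation_spec(rotations = list(list(axis = ax, angle = angle)))
}

#' Simulate a dark/light pair of observed reflection datasets
#'
#' Partial occupancy is modeled in structure-factor space (the
#' space-averaged crystal): \eqn{F_{mix} = (1-\alpha) F_{dark} + \alpha
#' F_{light}} per reflection. Observed amplitudes are \eqn{|F| (1 +
#' \epsilon)} with \eqn{\epsilon \sim N(0, noise\_frac)}, clipped at
#' zero; sigmas are `noise_frac * |F|`.
#'
#' @param dark,light [atom_model()]s on the same cell.
#' @param alpha Activated fraction in \[0, 1\].
#' @param noise_frac Fractional amplitude noise (>= 0).
#' @param seed Integer seed.
#' @param d_min Resolution limit in Angstrom.
#' @param mode Form-factor mode.
#' @return List with `dark_obs` and `light_obs` `reflection_set`s (and
#'   `hkl`, the shared index matrix).
#' @export
simulate_dataset <- function(dark, light, alpha, noise_frac = 0.01,
                             seed = 1, d_min = 1.8, mode = "cromer_mann") {
  stopifnot(alpha >= 0, alpha <= 1, noise_frac >= 0)
  hkl <- unique_hkl(dark$cell, d_min)
  fd <- .complex_sf(dark, hkl, mode)
  fl <- .complex_sf(light, hkl, mode)
  fmix <- (1 - alpha) * fd + alpha * fl
  .with_seed(seed, {
    mk <- function(fc, role) {
      amp <- Mod(fc)
      obs <- pmax(amp * (1 + stats::rnorm(length(amp), 0, noise_frac)), 0)
      reflection_set(hkl, f = obs, sigf = noise_frac * amp,
                     cell = dark$cell, role = role)
    }
    list(dark_obs = mk(fd, "observed-dark"),
         light_obs = mk(fmix, "observed-light"),
         hkl = hkl)
  })
}

#' The pump-probe delay grid
#'
#' The named snapshot delays (10 ns ... 233 ms) padded with log-spaced
#' fillers up to `n` points, optionally extended to a later last delay.
#'
#' @param n Total number of delays (>= 12).
#' @param t_max Last delay in seconds (default 0.233).
#' @return Sorted numeric vector of delays in seconds.
#' @export
default_delay_grid <- function(n = 19, t_max = 0.233) {
  named <- c(1e-8, 1e-7, 1e-6, 3e-5, 1e-3, 7e-3, 1e-2, 3.3e-2, 6.6e-2,
             1e-1, 1.33e-1, 2.33e-1)
  named <- named[named <= t_max]
  if (n <= length(named)) return(utils::head(named, n))
  fill <- exp(seq(log(1e-8), log(t_max), length.out = n))
  out <- named
  for (f in fill) {
    if (length(out) >= n) break
    if (min(abs(log(f / out))) > 0.2) out <- c(out, f)
  }
  extra <- setdiff(fill, out)
  while (length(out) < n && length(extra)) {
    out <- c(out, extra[1]); extra <- extra[-1]
  }
  sort(utils::head(out, n))
}

#' Kinetic scenario for a simulated time series
#'
#' @param loci Named list; each element is `list(model = "first_order",
#'   tau = s)` or `list(model = "two_step", tau1 = s, tau2 = s)` plus a
#'   `perturbation` ([perturbation_spec()]).
#' @param delays Delay grid in seconds (positive increasing).
#' @param alpha_max Global maximum activated fraction in (0, 1].
#' @param noise_frac Fractional amplitude noise.
#' @param seed Mandatory integer seed.
#' @return Object of class `kinetic_scenario`.
#' @export
kinetic_scenario <- function(loci, delays = default_delay_grid(),
                             alpha_max = 0.2, noise_frac = 0.02, seed) {
  if (missing(seed)) stop("a seed is mandatory for kinetic scenarios")
  stopifnot(alpha_max > 0, alpha_max <= 1, all(delays > 0),
            !is.unsorted(delays, strictly = TRUE))
  if (length(loci) > 3) stop("at most 3 loci are supported (2^k state mixing)")
  structure(list(loci = loci, delays = delays, alpha_max = alpha_max,
                 noise_frac = noise_frac, seed = seed),
            class = "kinetic_scenario")
}

# per-locus activated fraction at time t (first-order monotone rise, or
# unimodal two-step normalized to peak at alpha_max)
.locus_alpha <- function(locus, t, alpha_max) {
  if (locus$model == "first_order") {
    alpha_max * (1 - exp(-t / locus$tau))
  } else {
    t1 <- locus$tau1; t2 <- locus$tau2
    tmaxv <- (t1 * t2 / (t2 - t1)) * log(t2 / t1)
    peak <- eval_two_step(tmaxv, 1, t1, t2)
    alpha_max * eval_two_step(t, 1, t1, t2) / peak
  }
}

#' Simulate a time series of light-triggered reflection datasets
#'
#' Per delay, each locus carries an activated fraction from its kinetic
#' model. Loci activate independently, so the crystal is a mixture over
#' the `2^k` combinations of locus states; the composite structure
#' factor is the correspondingly weighted sum of the combination models'
#' structure factors (structure-factor-space mixing). Observed
#' amplitudes get seeded fractional Gaussian noise per delay.
#'
#' @param scenario A [kinetic_scenario()].
#' @param dark Dark [atom_model()].
#' @param d_min Resolution limit.
#' @param mode Form-factor mode.
#' @return List with `delays`, `dark_obs` (one shared noisy dark set),
#'   `light_obs` (list of sets per delay), `alphas` (matrix delay x
#'   locus).
#' @export
simulate_timeseries <- function(scenario, dark, d_min = 1.8,
                                mode = "cromer_mann") {
  loci <- scenario$loci
  k <- length(loci)
  # locus atom sets must not overlap (combination models would conflict)
  moved <- lapply(loci, function(lc) {
    sp <- lc$perturbation
    c(unlist(lapply(sp$rotations, function(r) r$axis$moving)),
      names(sp$displacements),
      if (!is.null(sp$disorder)) sp$disorder$atoms)
  })
  if (k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k)
      if (length(intersect(moved[[i]], moved[[j]])))
        stop("overlapping locus atom sets: ", names(loci)[i], " / ", names(loci)[j])
  }
  hkl <- unique_hkl(dark$cell, d_min)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  fcomb <- lapply(seq_len(nrow(combos)), function(ci) {
    m <- dark
    for (li in seq_len(k)) if (combos[ci, li])
      m <- apply_perturbation(m, loci[[li]]$perturbation)
    .complex_sf(m, hkl, mode)
  })
  alphas <- vapply(loci, function(lc)
    .locus_alpha(lc, scenario$delays, scenario$alpha_max),
    numeric(length(scenario$delays)))
  alphas <- matrix(alphas, nrow = length(scenario$delays),
                   dimnames = list(NULL, names(loci)))
  nf <- scenario$noise_frac
  fd <- fcomb[[1]]
  .with_seed(scenario$seed, {
    noisy <- function(fc, role) {
      amp <- Mod(fc)
      obs <- pmax(amp * (1 + stats::rnorm(length(amp), 0, nf)), 0)
      reflection_set(hkl, f = obs, sigf = nf * amp, cell = dark$cell,
                     role = role)
    }
    dark_obs <- noisy(fd, "observed-dark")
    light_obs <- lapply(seq_along(scenario$delays), function(ti) {
      wts <- vapply(seq_len(nrow(combos)), function(ci) {
        prod(ifelse(unlist(combos[ci, ]), alphas[ti, ], 1 - alphas[ti, ]))
      }, numeric(1))
      fmix <- Reduce(`+`, Map(`*`, fcomb, wts))
      noisy(fmix, "observed-light")
    })
    list(delays = scenario$delays, dark_obs = dark_obs,
         light_obs = light_obs, alphas = alphas, hkl = hkl)
  })
}

#' Simulate a pump-probe in crystallo spectral series
#'
#' The dark spectrum is an oxidized-flavin Gaussian band (450 nm center)
#' plus a Rayleigh `b * lambda^-4` baseline. The transient at delay `t`
#' converts a fraction `c_max * (1 - exp(-t/tau_s))` of the oxidized
#' band into a semiquinone band centered at 600 nm (spanning the
#' 580-640 nm integration window), with relative band amplitudes taken
#' from the extinction table. Each delay uses a fresh crystal with a
#' random optical path factor applied to both members of the pair (the
#' nuisance the dark-band normalization is designed to cancel); noise is
#' additive Gaussian with sd = `noise` x the full-conversion difference
#' band amplitude of that crystal.
#'
#' @param tau_s First-order protonation time constant in seconds.
#' @param delays Delay grid in seconds.
#' @param path_cm Base optical path in cm.
#' @param noise Noise level (fraction of the difference-band signal).
#' @param seed Integer seed.
#' @param table An [extinction_table()].
#' @param path_range Range of per-crystal path factors (default
#'   `c(0.5, 2)`).
#' @param c_max Maximum converted fraction (default 0.2).
#' @param wavelength Wavelength grid in nm.
#' @return List of entries `list(delay, transient, dark)` suitable for
#'   [build_difference_trace()].
#' @export
simulate_spectra_series <- function(tau_s, delays, path_cm = 0.02,
                                    noise = 0.05, seed = 1,
                                    table = extinction_table(),
                                    path_range = c(0.5, 2),
                                    c_max = 0.2,
                                    wavelength = seq(350, 800, by = 1)) {
  M <- unclass(table)
  gauss <- function(center, sd) exp(-(wavelength - center)^2 / (2 * sd^2))
  eps_ox <- M["450", "ox"] * gauss(450, 28)
  eps_sq <- M["450", "sq"] * gauss(450, 28) + M["635", "sq"] * gauss(600, 30)
  conc <- 1 / (M["450", "ox"] * path_cm)   # dark A450 ~ 1 AU at unit path factor
  b_scatter <- 0.15 * 450^4                # ~0.15 AU of scatter at 450 nm
  scatter <- b_scatter * wavelength^-4
  .with_seed(seed, {
    lapply(delays, function(t) {
      g <- stats::runif(1, path_range[1], path_range[2])
      conv <- c_max * (1 - exp(-t / tau_s))
      a_dark <- g * (path_cm * conc * eps_ox + scatter)
      a_tr <- g * (path_cm * conc * ((1 - conv) * eps_ox + conv * eps_sq) +
                     scatter)
      sig <- noise * g * path_cm * conc * c_max * M["635", "sq"]
      a_dark <- a_dark + stats::rnorm(length(wavelength), 0, sig)
      a_tr <- a_tr + stats::rnorm(length(wavelength), 0, sig)
      list(delay = t,
           transient = spectrum(wavelength, a_tr, delay = t),
           dark = spectrum(wavelength, a_dark, delay = t))
    })
  })
}
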