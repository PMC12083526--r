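# shared noisy mixed dataset at the standard activated fraction
mix_sim <- simulate_dataset(toy_dark, toy_light, alpha = 0.2,
                            noise_frac = 0.01, seed = 1, d_min = 1.8)
mix_diff <- difference_amplitudes(
  scale_to_reference(mix_sim$light_obs, mix_sim$dark_obs), mix_sim$dark_obs)
dark_calc_18 <- calc_structure_factors(toy_dark, min(mix_diff$data$d))

test_that("q-weights follow the closed formula and down-weight outliers", {
  hkl <- unique_hkl(toy_dark$cell, 5)[1:20, ]
  set.seed(5)
  dF <- rnorm(20, 0, 2); sg <- runif(20, 0.5, 2)
  diff <- reflection_set(hkl, abs(dF), sg, cell = toy_dark$cell,
                         role = "difference")
  diff$data$f <- dF
  w <- compute_qweights(diff)
  wref <- 1 / (1 + sg^2 / mean(sg^2) + dF^2 / mean(dF^2))
  expect_equal(w$w, wref, tolerance = 1e-12)
  expect_true(all(w$w > 0 & w$w <= 1))

  # homogeneous set -> equal weights
  dh <- diff; dh$data$f <- rep(2, 20); dh$data$sigf <- rep(0.5, 20)
  expect_equal(diff(range(compute_qweights(dh)$w)), 0, tolerance = 1e-14)

  # one large outlier gets the smallest weight
  do <- diff
  do$data$f[1] <- 10 * sqrt(mean(dF^2))
  wo <- compute_qweights(do)$w
  expect_true(all(wo[1] < wo[-1]))

  dz <- diff; dz$data$f <- rep(0, 20); dz$data$sigf <- rep(0, 20)
  expect_warning(wz <- compute_qweights(dz), "uniform weights")
  expect_true(all(wz$w == 1))

  expect_equal(mean(compute_qweights(diff, normalize = "mean")$w), 1,
               tolerance = 1e-12)
})

test_that("extrapolation: identity at dF=0, hand formula, affinity in N", {
  zero <- mix_diff
  zero$data$f <- 0 * zero$data$f
  for (mode in c("scalar", "vectorial")) {
    ext <- extrapolate(zero, dark_calc_18, N = 7, mode = mode)
    cm <- trsfx:::.common_hkl(ext, dark_calc_18)
    expect_equal(ext$data$f, dark_calc_18$data$f[cm$ib], tolerance = 1e-10)
  }

  # N = 2, w = 1, fully converted noise-free pair: 2|Fl| - 2|Fd| + |Fc,dark|
  pure_diff <- difference_amplitudes(toy_sim_pure$light_obs,
                                     toy_sim_pure$dark_obs, snr_min = 0)
  dc <- calc_structure_factors(toy_dark, min(pure_diff$data$d))
  ext <- extrapolate(pure_diff, dc, N = 2, mode = "scalar")
  cm <- trsfx:::.common_hkl(pure_diff, dc)
  l <- trsfx:::.common_hkl(pure_diff, toy_sim_pure$light_obs)
  d <- trsfx:::.common_hkl(pure_diff, toy_sim_pure$dark_obs)
  byhand <- pmax(2 * toy_sim_pure$light_obs$data$f[l$ib] -
                   2 * toy_sim_pure$dark_obs$data$f[d$ib] +
                   dc$data$f[cm$ib], 0)
  expect_equal(ext$data$f, byhand, tolerance = 1e-9)

  # scalar amplitudes affine in N; N=0 w=1 returns F_c,dark
  e0 <- extrapolate(mix_diff, dark_calc_18, N = 0, mode = "scalar")
  e1 <- extrapolate(mix_diff, dark_calc_18, N = 1, mode = "scalar")
  e2 <- extrapolate(mix_diff, dark_calc_18, N = 2, mode = "scalar")
  cm <- trsfx:::.common_hkl(mix_diff, dark_calc_18)
  expect_equal(e0$data$f, dark_calc_18$data$f[cm$ib], tolerance = 1e-12)
  unc <- e2$data$f > 0 & e1$data$f > 0      # away from the clipping fork
  expect_equal((e2$data$f - e1$data$f)[unc], (e1$data$f - e0$data$f)[unc],
               tolerance = 1e-9)

  # scalar and vectorial agree here (difference applied along dark phase)
  ev <- extrapolate(mix_diff, dark_calc_18, N = 2, mode = "vectorial")
  expect_equal(ev$data$f[e2$data$f > 0], e2$data$f[e2$data$f > 0],
               tolerance = 1e-9)

  nop <- dark_calc_18; nop$data$phase <- NA_real_
  expect_error(extrapolate(mix_diff, nop, N = 2), "phases")
})

test_that("vectorial extrapolation at N=2/alpha approaches the light state", {
  diff <- mix_diff
  w <- compute_qweights(diff, normalize = "mean")
  ext <- extrapolate(diff, dark_calc_18, N = 2 / 0.2, mode = "vectorial",
                     weights = w)
  grid <- dim(toy_ded_pure$values)
  m_ext <- synthesize_map(ext, grid = grid)
  m_dark <- synthesize_map(dark_calc_18, grid = grid)
  light_calc <- calc_structure_factors(toy_light, min(diff$data$d))
  m_light <- synthesize_map(light_calc, grid = grid)
  mask <- region_mask(toy_dark, "resi 2 and name CB,CG,OD1,ND2",
                      grid = grid, radius = 2.5)
  cc <- function(a, b) cor(a$values[mask$voxels], b$values[mask$voxels])
  expect_gt(cc(m_ext, m_light), cc(m_dark, m_light))
})

test_that("residual-density scan: null input, monotone tail, two regimes", {
  zero <- mix_diff
  zero$data$f <- 0 * zero$data$f
  zero$data$sigf <- 0 * zero$data$sigf
  expect_warning(
    expect_warning(s0 <- residual_density_scan(zero, dark_calc_18, toy_dark,
                                               marker = "resi 2 and name CG,OD1,ND2"),
                   "uniform weights|zero residuals"),
    "uniform weights|zero residuals")
  expect_true(all(s0$scan$drho_res == 0))
  expect_error(estimate_occupancy(s0), "identically zero")

  scan <- residual_density_scan(mix_diff, dark_calc_18, toy_dark,
                                marker = "resi 2 and name CG,OD1,ND2")
  y <- scan$scan$drho_res; N <- scan$scan$N
  # beyond the true 2/alpha = 10 the magnitude is non-decreasing
  tail <- y[N > 10]
  expect_true(all(diff(tail) >= -1e-9))
  # two-regime shape: two-segment fit halves the one-line residual
  rss1 <- sum(lm.fit(cbind(1, N), y)$residuals^2)
  rss2 <- min(vapply(seq(N[2], N[20], length.out = 100), function(c0)
    sum(lm.fit(cbind(1, pmin(N - c0, 0), pmax(N - c0, 0)), y)$residuals^2),
    numeric(1)))
  expect_lt(rss2, 0.5 * rss1)
})

test_that("occupancy estimation: exact breakpoint, recovery, saturation", {
  mk <- function(df) structure(list(scan = df, marker = NULL, level_sigma = 3,
                                    N_star = NA_real_, alpha = NA_real_,
                                    se = NA_real_), class = "occupancy_scan")
  N <- seq(2, 40, length.out = 21)
  exact <- mk(data.frame(N = N, drho_res = ifelse(N < 10, 1, 1 + 0.5 * (N - 10))))
  est <- estimate_occupancy(exact, transform = "none")
  expect_equal(est$N_star, 10, tolerance = 1e-3)
  expect_equal(est$alpha, 0.2, tolerance = 1e-3)

  lin <- mk(data.frame(N = N, drho_res = 2 + 0.3 * N))
  expect_error(estimate_occupancy(lin, transform = "none"), "no inflection")

  scan <- residual_density_scan(mix_diff, dark_calc_18, toy_dark,
                                marker = "resi 2 and name CG,OD1,ND2")
  a <- estimate_occupancy(scan)
  expect_gt(a$alpha, 0.15); expect_lt(a$alpha, 0.25)
  expect_gt(a$se, 0)

  # fully converted crystal: N* ~ 2 (alpha saturates at 1)
  sim1 <- simulate_dataset(toy_dark, toy_light, alpha = 1, noise_frac = 0.01,
                           seed = 2, d_min = 1.8)
  d1 <- difference_amplitudes(scale_to_reference(sim1$light_obs, sim1$dark_obs),
                              sim1$dark_obs)
  s1 <- estimate_occupancy(residual_density_scan(d1, dark_calc_18, toy_dark,
                                                 marker = "resi 2 and name CG,OD1,ND2"))
  expect_lt(abs(s1$N_star - 2), 0.2 * 2 + 0.45)   # within ~20% of N*=2
  expect_gt(s1$alpha, 0.8)
})

test_that("occupancy recovery across the alpha range (seeded medians)", {
  for (alpha in c(0.1, 0.2, 0.5, 1.0)) {
    rec <- vapply(1:3, function(s) {
      sim <- simulate_dataset(toy_dark, toy_light, alpha = alpha,
                              noise_frac = 0.01, seed = s, d_min = 1.8)
      d <- difference_amplitudes(
        scale_to_reference(sim$light_obs, sim$dark_obs), sim$dark_obs)
      sc <- residual_density_scan(d, dark_calc_18, toy_dark,
                                  marker = "resi 2 and name CG,OD1,ND2")
      estimate_occupancy(sc)$alpha
    }, numeric(1))
    expect_lt(abs(median(rec) - alpha) / alpha, 0.25)
  }
})
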