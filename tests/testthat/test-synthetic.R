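test_that("toy crystal: determinism, manifest, reflection count", {
  a <- make_toy_crystal(5)
  b <- make_toy_crystal(5)
  expect_identical(a, b)
  c_ <- make_toy_crystal(6)
  expect_false(identical(a$atoms, c_$atoms))    # seed moves solvent/B only
  expect_identical(a$atoms[a$atoms$resi < 20, c("x", "y", "z")],
                   c_$atoms[c_$atoms$resi < 20, c("x", "y", "z")])

  expect_identical(nrow(a$atoms), 33L)
  expect_identical(sum(a$atoms$resi == 2), 8L)          # Asn-analog residue
  expect_identical(sum(a$atoms$resi == 10), 10L)        # ring
  expect_identical(sum(a$atoms$resn == "HOH"), 6L)
  expect_true(all(c("2 CA", "2 CB", "2 CG", "2 OD1", "2 ND2") %in%
                    atom_labels(a)))

  rs <- calc_structure_factors(a, 1.8)
  expect_gt(nrow(rs$data), 400)
})

test_that("perturbations: identity, inverse, rotation-matrix prediction", {
  empty <- apply_perturbation(toy_dark, perturbation_spec())
  expect_identical(empty, toy_dark)

  ax <- asn_chi_axes(2)[[2]]
  there <- apply_perturbation(toy_dark, perturbation_spec(
    rotations = list(list(axis = ax, angle = 37))))
  back <- apply_perturbation(there, perturbation_spec(
    rotations = list(list(axis = ax, angle = -37))))
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(toy_dark$atoms[, c("x", "y", "z")]),
               tolerance = 1e-9)

  # displacement of the rotated atoms matches an explicit Rodrigues matrix
  labs <- atom_labels(toy_dark)
  xyz <- as.matrix(toy_dark$atoms[, c("x", "y", "z")])
  p <- xyz[match("2 CB", labs), ]
  u <- xyz[match("2 CG", labs), ] - p; u <- u / sqrt(sum(u^2))
  th <- -86.4 * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  for (lab in c("2 OD1", "2 ND2")) {
    pred <- unname(drop(R %*% (xyz[match(lab, labs), ] - p)) + p)
    got <- unlist(toy_light$atoms[match(lab, labs), c("x", "y", "z")],
                  use.names = FALSE)
    expect_equal(got, pred, tolerance = 1e-9)
  }

  dis <- apply_perturbation(toy_dark, perturbation_spec(
    disorder = list(atoms = "resi 3", occ = 0)))
  expect_true(all(dis$atoms$occ[dis$atoms$resi == 3] == 0))
})

test_that("simulate_dataset: mixing limits and seeded noise", {
  s0 <- simulate_dataset(toy_dark, toy_light, alpha = 0, noise_frac = 0,
                         seed = 1, d_min = 2.2)
  expect_equal(s0$light_obs$data$f, s0$dark_obs$data$f, tolerance = 1e-12)

  s1 <- simulate_dataset(toy_dark, toy_light, alpha = 1, noise_frac = 0,
                         seed = 1, d_min = 2.2)
  fl <- calc_structure_factors(toy_light, 2.2, hkl = s1$hkl)
  expect_equal(s1$light_obs$data$f, fl$data$f, tolerance = 1e-10)

  sa <- simulate_dataset(toy_dark, toy_light, 0.3, 0.02, seed = 9, d_min = 2.2)
  sb <- simulate_dataset(toy_dark, toy_light, 0.3, 0.02, seed = 9, d_min = 2.2)
  expect_identical(sa$light_obs$data$f, sb$light_obs$data$f)
  expect_identical(sa$dark_obs$data$sigf, 0.02 * Mod(trsfx:::.complex_sf(
    toy_dark, sa$hkl)))
})

test_that("cross-module: occupancy recovered from a simulated pair", {
  sim <- simulate_dataset(toy_dark, toy_light, alpha = 0.2, noise_frac = 0.01,
                          seed = 4, d_min = 1.8)
  d <- difference_amplitudes(scale_to_reference(sim$light_obs, sim$dark_obs),
                             sim$dark_obs)
  dc <- calc_structure_factors(toy_dark, min(d$data$d))
  sc <- estimate_occupancy(residual_density_scan(
    d, dc, toy_dark, marker = "resi 2 and name CG,OD1,ND2"))
  expect_lt(abs(sc$alpha - 0.2) / 0.2, 0.25)
})

test_that("timeseries: infinite tau reproduces dark, activation shapes hold", {
  sc <- kinetic_scenario(
    loci = list(chi2 = list(model = "first_order", tau = 1e12,
                            perturbation = toy_chi2_perturbation())),
    delays = default_delay_grid(8), alpha_max = 0.2, noise_frac = 0,
    seed = 2)
  ts <- simulate_timeseries(sc, toy_dark, d_min = 2.2)
  for (i in seq_along(ts$delays))
    expect_equal(ts$light_obs[[i]]$data$f, ts$dark_obs$data$f,
                 tolerance = 1e-9)

  # monotone first-order activation; unimodal two-step activation
  sc2 <- kinetic_scenario(
    loci = list(
      chi2 = list(model = "first_order", tau = 0.0439,
                  perturbation = toy_chi2_perturbation()),
      helix = list(model = "two_step", tau1 = 59e-6, tau2 = 15e-3,
                   perturbation = perturbation_spec(
                     disorder = list(atoms = "resi 3", occ = 0)))),
    delays = default_delay_grid(19), alpha_max = 0.2, noise_frac = 0.02,
    seed = 3)
  ts2 <- simulate_timeseries(sc2, toy_dark, d_min = 2.2)
  a <- ts2$alphas
  expect_false(is.unsorted(a[, "chi2"]))
  pk <- which.max(a[, "helix"])
  expect_false(is.unsorted(a[seq_len(pk), "helix"]))
  expect_false(is.unsorted(rev(a[pk:nrow(a), "helix"])))
  expect_equal(max(a), 0.2, tolerance = 0.02)

  # overlapping loci are rejected
  bad <- kinetic_scenario(
    loci = list(
      a = list(model = "first_order", tau = 1, perturbation = toy_chi2_perturbation()),
      b = list(model = "first_order", tau = 1, perturbation = toy_chi2_perturbation())),
    delays = default_delay_grid(8), alpha_max = 0.2, noise_frac = 0, seed = 1)
  expect_error(simulate_timeseries(bad, toy_dark, d_min = 2.2), "overlapping")
})

test_that("timeseries kinetics are recoverable from integrated DED traces", {
  tau_true <- 0.0439
  taus <- vapply(1:8, function(s) {
    sc <- kinetic_scenario(
      loci = list(chi2 = list(model = "first_order", tau = tau_true,
                              perturbation = toy_chi2_perturbation())),
      delays = default_delay_grid(15, t_max = 0.5), alpha_max = 0.3,
      noise_frac = 0.01, seed = s)
    ts <- simulate_timeseries(sc, toy_dark, d_min = 2.2)
    maps <- lapply(ts$light_obs, function(lo)
      ded_map(lo, ts$dark_obs, toy_dark, scale = FALSE))
    mask <- region_mask(toy_dark, "resi 2 and name CG,OD1,ND2",
                        grid = dim(maps[[1]]$values), radius = 2.0)
    tr <- ded_trace(maps, mask, ts$delays, sign = "negative",
                    level_sigma = 3)
    tr$value <- -tr$value            # rising positive signal
    fit_trace(tr, "first_order")$par[["tau"]]
  }, numeric(1))
  expect_lt(abs(median(taus) - tau_true) / tau_true, 0.15)
})

test_that("two-locus series carries at least two SVD components", {
  sc <- kinetic_scenario(
    loci = list(
      chi2 = list(model = "first_order", tau = 0.0439,
                  perturbation = toy_chi2_perturbation()),
      helix = list(model = "two_step", tau1 = 59e-6, tau2 = 15e-3,
                   perturbation = perturbation_spec(
                     disorder = list(atoms = "resi 3", occ = 0)))),
    delays = default_delay_grid(19), alpha_max = 0.3, noise_frac = 0.02,
    seed = 11)
  ts <- simulate_timeseries(sc, toy_dark, d_min = 2.2)
  maps <- lapply(ts$light_obs, function(lo)
    ded_map(lo, ts$dark_obs, toy_dark, scale = FALSE))
  mask <- region_mask(toy_dark, "resi 2-3", grid = dim(maps[[1]]$values),
                      radius = 2.5)
  res <- svd_decompose(maps, mask, times = ts$delays)

  # noise-only reference series sets the floor
  sc0 <- kinetic_scenario(
    loci = list(chi2 = list(model = "first_order", tau = 1e12,
                            perturbation = toy_chi2_perturbation())),
    delays = default_delay_grid(19), alpha_max = 0.3, noise_frac = 0.02,
    seed = 11)
  ts0 <- simulate_timeseries(sc0, toy_dark, d_min = 2.2)
  maps0 <- lapply(ts0$light_obs, function(lo)
    ded_map(lo, ts0$dark_obs, toy_dark, scale = FALSE))
  floor_sv <- max(svd_decompose(maps0, mask)$sv)
  expect_gt(res$sv[2], floor_sv)
})

test_that("spectra generator: zero-delay null and nuisance robustness", {
  ser <- simulate_spectra_series(0.05, c(1e-9, 0.1), noise = 0, seed = 1,
                                 path_range = c(1, 1))
  expect_equal(ser[[1]]$transient$absorbance, ser[[1]]$dark$absorbance,
               tolerance = 1e-6)
  expect_gt(max(ser[[2]]$transient$absorbance - ser[[2]]$dark$absorbance),
            0.01)
})
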