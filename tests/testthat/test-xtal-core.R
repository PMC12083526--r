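test_that("unit cell validates inputs and computes triclinic geometry", {
  expect_error(unit_cell(-1, 2, 3), "positive")
  expect_error(unit_cell(1, 2, 3, alpha = 200), "angles")
  cell <- unit_cell(10, 12, 14, 80, 95, 103)
  expect_gt(cell_volume(cell), 0)
  expect_equal(cell_orth_matrix(cell) %*% cell_frac_matrix(cell), diag(3),
               tolerance = 1e-12)
  # d-spacing against the explicit reciprocal metric
  hkl <- rbind(c(1, 0, 0), c(2, -3, 1), c(0, 0, 4))
  G <- t(cell_orth_matrix(cell)) %*% cell_orth_matrix(cell)
  dref <- apply(hkl, 1, function(h) 1 / sqrt(drop(h %*% solve(G) %*% h)))
  expect_equal(d_spacing(cell, hkl), dref, tolerance = 1e-12)
})

test_that("atom model enforces its invariants", {
  at <- toy_dark$atoms
  bad <- at; bad$occ[1] <- 1.5
  expect_error(atom_model(bad, toy_dark$cell), "occupanc")
  bad <- at; bad$b[2] <- -1
  expect_error(atom_model(bad, toy_dark$cell), "B-factors")
  bad <- at; bad$resi[2] <- bad$resi[1]; bad$atom[2] <- bad$atom[1]
  expect_error(atom_model(bad, toy_dark$cell), "duplicate")
})

test_that("structure factors: origin atom, shift theorem, unknown element", {
  cell <- unit_cell(10, 10, 10)
  one <- atom_model(data.frame(element = "C", resi = 1, resn = "X",
                               atom = "C1", x = 0, y = 0, z = 0,
                               occ = 1, b = 0), cell)
  rs <- calc_structure_factors(one, 3)
  expect_true(all(abs(rs$data$phase) < 1e-9))

  # translating every atom shifts phases by -360 h.t, leaves amplitudes
  t_frac <- c(0.21, -0.13, 0.07)
  shifted <- toy_small
  shifted$atoms[, c("x", "y", "z")] <-
    as.matrix(toy_small$atoms[, c("x", "y", "z")]) +
    matrix(cell_orth_matrix(cell <- toy_small$cell) %*% t_frac,
           nrow(toy_small$atoms), 3, byrow = TRUE)
  a <- calc_structure_factors(toy_small, 2.5)
  b <- calc_structure_factors(shifted, 2.5)
  expect_equal(a$data$f, b$data$f, tolerance = 1e-9)
  # F(h) picks up exp(2*pi*i h.t): phases move by +360 h.t (equivalently
  # -360 h.t for the conjugate convention); check modulo 360
  dphi <- (b$data$phase - a$data$phase -
             360 * (as.matrix(a$data[, c("h", "k", "l")]) %*% t_frac)) %% 360
  expect_true(all(pmin(dphi, 360 - dphi) < 1e-6))

  bad <- toy_small
  bad$atoms$element[3] <- "Xx"
  expect_error(calc_structure_factors(bad, 2.5), "Xx")
  expect_error(calc_structure_factors(bad, 2.5), "1 C")  # names the atom
  expect_error(calc_structure_factors(toy_small, 100), "d_min")
})

test_that("structure factors match the brute-force direct sum", {
  for (mode in c("cromer_mann", "toy")) {
    rs <- calc_structure_factors(toy_small, 2.0, mode = mode)
    fb <- brute_sf(toy_small, as.matrix(rs$data[, c("h", "k", "l")]), mode)
    expect_lt(max(abs(Mod(fb) - rs$data$f) / pmax(rs$data$f, 1e-12)), 1e-6)
  }
})

test_that("Parseval consistency between reflections and map", {
  rs <- calc_structure_factors(toy_dark, 2.5)
  m <- synthesize_map(rs)
  lhs <- 2 * sum(rs$data$f^2)            # both Friedel mates
  rhs <- cell_volume(toy_dark$cell)^2 * mean(m$values^2)
  expect_rel(lhs, rhs, 1e-6)
})

test_that("scaling: identity, pure scale, generate-then-recover", {
  rs <- toy_sim_pure$dark_obs
  rs$data$sigf <- 0.01 * rs$data$f
  s1 <- scale_to_reference(rs, rs)
  sc <- attr(s1, "scale")
  expect_equal(unname(sc["k"]), 1, tolerance = 1e-8)
  expect_equal(unname(sc["B_rel"]), 0, tolerance = 1e-6)

  doubled <- rs
  doubled$data$f <- 2 * rs$data$f
  s2 <- scale_to_reference(doubled, rs)
  expect_equal(unname(attr(s2, "scale")["k"]), 0.5, tolerance = 1e-8)
  expect_equal(s2$data$f, rs$data$f, tolerance = 1e-8)

  moved <- rs
  s2v <- 1 / (4 * rs$data$d^2)
  moved$data$f <- rs$data$f / (0.7 * exp(-12 * s2v))
  moved$data$sigf <- rs$data$sigf / (0.7 * exp(-12 * s2v))
  s3 <- scale_to_reference(moved, rs)
  expect_rel(unname(attr(s3, "scale")["k"]), 0.7, 0.01)
  expect_lt(abs(unname(attr(s3, "scale")["B_rel"]) - 12), 0.5)

  few <- rs; few$data <- few$data[1:5, ]
  expect_error(scale_to_reference(few, rs), "insufficient overlap")
})

test_that("difference amplitudes apply the SNR and low-resolution filters", {
  rs <- toy_sim_pure$dark_obs
  rs$data$sigf <- rep(1, nrow(rs$data))
  d0 <- difference_amplitudes(rs, rs, snr_min = 0, d_low = 10)
  expect_true(all(d0$data$f == 0))
  expect_equal(nrow(d0$data), sum(rs$data$d < 10))

  # toy set straddling both filters, checked against plain enumeration
  cell <- unit_cell(30, 30, 30)
  hkl <- unique_hkl(cell, 5)
  set.seed(42)
  fl <- runif(nrow(hkl), 1, 100); fd <- runif(nrow(hkl), 1, 100)
  sl <- runif(nrow(hkl), 1, 20); sd_ <- runif(nrow(hkl), 1, 20)
  light <- reflection_set(hkl, fl, sl, cell = cell, role = "observed-light")
  dark <- reflection_set(hkl, fd, sd_, cell = cell, role = "observed-dark")
  dd <- difference_amplitudes(light, dark, snr_min = 3, d_low = 10)
  d <- d_spacing(cell, hkl)
  nref <- sum(d < 10 & fl / sl > 3 & fd / sd_ > 3)
  expect_identical(nrow(dd$data), as.integer(nref))
  # a reflection at d = 12 A is excluded at d_low = 10
  d12 <- which(d > 10)[1]
  expect_false(paste(hkl[d12, ], collapse = " ") %in%
                 paste(dd$data$h, dd$data$k, dd$data$l))
  expect_equal(dd$data$sigf,
               sqrt(sl^2 + sd_^2)[d < 10 & fl / sl > 3 & fd / sd_ > 3])

  expect_warning(nothing <- difference_amplitudes(light, dark, snr_min = 1e9),
                 "no reflections survive")
  expect_identical(nrow(nothing$data), 0L)
})

test_that("map synthesis: single-wave, zero set, direct-sum oracle", {
  cell <- unit_cell(10, 10, 10)
  one <- reflection_set(c(1, 0, 0), f = 5, phase = 0, cell = cell)
  m <- synthesize_map(one, grid = c(16, 4, 4))
  V <- cell_volume(cell)
  expect_equal(max(m$values), 2 * 5 / V, tolerance = 1e-10)
  expect_equal(min(m$values), -2 * 5 / V, tolerance = 1e-10)
  expect_equal(m$values[1, 1, 1], 2 * 5 / V, tolerance = 1e-10)

  z <- reflection_set(rbind(c(1, 0, 0), c(0, 2, 1)), f = c(0, 0),
                      phase = c(0, 0), cell = cell)
  mz <- synthesize_map(z, grid = c(8, 8, 8))
  expect_true(all(mz$values == 0))
  expect_identical(mz$map_sigma, 0)

  rs <- calc_structure_factors(toy_dark, 6.0)
  m8 <- synthesize_map(rs, grid = c(8, 8, 8))
  expect_lt(max(abs(m8$values - brute_map(rs, c(8, 8, 8)))), 1e-8)
  expect_lt(abs(mean(m8$values)), 1e-12)   # (0,0,0) omitted -> zero mean

  nop <- rs; nop$data$phase[3] <- NA
  expect_error(synthesize_map(nop), "without phases")
  expect_error(synthesize_map(rs, grid = c(4, 4, 4)), "Nyquist")
})

test_that("observed DED maps: null, antisymmetry, peak location, linearity", {
  sim <- toy_sim_pure
  null <- ded_map(sim$dark_obs, sim$dark_obs, toy_dark)
  expect_lt(null$map_sigma, 1e-10)

  # antisymmetry holds for data already on a common scale
  ab <- ded_map(sim$light_obs, sim$dark_obs, toy_dark, scale = FALSE)
  ba <- ded_map(sim$dark_obs, sim$light_obs, toy_dark, scale = FALSE)
  expect_equal(ab$values, -ba$values, tolerance = 1e-8)
  expect_identical(ab$provenance, "observed-DED")

  # strongest negative peak near a departing atom, positive near arriving
  g <- dim(ab$values)
  M <- cell_orth_matrix(toy_dark$cell)
  vox_xyz <- function(w) as.numeric(M %*% ((w - 1) / g))
  labs <- atom_labels(toy_dark)
  moved <- c("2 OD1", "2 ND2")
  dk <- as.matrix(toy_dark$atoms[match(moved, labs), c("x", "y", "z")])
  lt <- as.matrix(toy_light$atoms[match(moved, labs), c("x", "y", "z")])
  wmin <- which(ab$values == min(ab$values), arr.ind = TRUE)[1, ]
  wmax <- which(ab$values == max(ab$values), arr.ind = TRUE)[1, ]
  expect_lt(min(sqrt(rowSums(sweep(dk, 2, vox_xyz(wmin))^2))), 0.5)
  expect_lt(min(sqrt(rowSums(sweep(lt, 2, vox_xyz(wmax))^2))), 0.5)

  # small-displacement linearity: alpha-mixture map ~ alpha x pure map
  light_small <- apply_perturbation(toy_dark, toy_chi2_perturbation(-15))
  pure <- simulate_dataset(toy_dark, light_small, 1, 0, 1, d_min = 1.8)
  mp <- ded_map(pure$light_obs, pure$dark_obs, toy_dark)
  for (alpha in c(0.1, 0.5)) {
    mix <- simulate_dataset(toy_dark, light_small, alpha, 0, 1, d_min = 1.8)
    mm <- ded_map(mix$light_obs, mix$dark_obs, toy_dark)
    slope <- sum(mm$values * mp$values) / sum(mp$values^2)
    expect_rel(slope, alpha, 0.05)
  }
})
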