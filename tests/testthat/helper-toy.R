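# Shared fixtures, computed once per test run. Everything is generated in
# code from seeds; nothing is read from disk.

toy_dark <- make_toy_crystal(1)
toy_light <- apply_perturbation(toy_dark, toy_chi2_perturbation(-86.4))

# noise-free, fully converted dataset pair and its observed DED map
toy_sim_pure <- simulate_dataset(toy_dark, toy_light, alpha = 1,
                                 noise_frac = 0, seed = 1, d_min = 1.8)
toy_ded_pure <- ded_map(toy_sim_pure$light_obs, toy_sim_pure$dark_obs,
                        toy_dark)

# a tiny 5-atom model for brute-force oracles
toy_small <- local({
  m <- toy_dark
  m$atoms <- m$atoms[1:5, ]
  m
})

# direct-summation structure-factor oracle (scalar loop, no shortcuts)
brute_sf <- function(model, hkl, mode = "cromer_mann") {
  frac <- frac_coords(model)
  d <- d_spacing(model$cell, hkl)
  vapply(seq_len(nrow(hkl)), function(i) {
    s2 <- 1 / (4 * d[i]^2)
    acc <- 0 + 0i
    for (j in seq_len(nrow(model$atoms))) {
      f <- form_factor(model$atoms$element[j], s2, mode)
      acc <- acc + model$atoms$occ[j] * f * exp(-model$atoms$b[j] * s2) *
        exp(2i * pi * sum(hkl[i, ] * frac[j, ]))
    }
    acc
  }, complex(1))
}

# direct Fourier-summation map oracle over an explicit grid
brute_map <- function(rs, grid) {
  V <- cell_volume(rs$cell)
  fc <- rs$data$f * exp(1i * rs$data$phase * pi / 180)
  h <- rs$data$h; k <- rs$data$k; l <- rs$data$l
  v <- array(0, grid)
  for (ix in seq_len(grid[1])) for (iy in seq_len(grid[2]))
    for (iz in seq_len(grid[3])) {
      x <- c(ix - 1, iy - 1, iz - 1) / grid
      s <- sum(fc * exp(-2i * pi * (h * x[1] + k * x[2] + l * x[3])))
      v[ix, iy, iz] <- 2 * Re(s) / V     # Friedel mate doubles the real part
    }
  v
}

expect_rel <- function(x, y, tol) expect_lt(abs(x - y) / abs(y), tol)
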