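single_state <- function(energy = 12000, strength = 1) {
  # minimal hand-built exciton_states object for lineshape tests
  structure(
    list(
      energies = energy,
      coefficients = matrix(1),
      state_dipoles = matrix(c(sqrt(strength), 0, 0), 1),
      dipole_strengths = strength,
      band = rep("b850", length(energy)),
      k = rep(NA_integer_, length(energy)),
      basis = tibble::tibble(
        index = 1, type = "le", site_id = 1, unit = 0,
        role = "alpha", donor = NA, acceptor = NA, label = "LE_alpha_u0"
      ),
      dipoles = matrix(c(sqrt(strength), 0, 0), 1),
      site_energies = energy,
      n_le = 1L, n_ct = 0L, n_units = 1L
    ),
    class = "exciton_states"
  )
}

multi_state <- function(energies, strengths) {
  st <- single_state()
  st$energies <- energies
  st$dipole_strengths <- strengths
  st$band <- rep("b850", length(energies))
  st$k <- rep(NA_integer_, length(energies))
  st
}

test_that("a single Lorentzian is normalised and peaks where it should", {
  st <- single_state(12000, strength = 1)
  wide <- seq(2000, 40000, by = 2)
  sp <- lorentzian_spectrum(st,
    hwhm_low_band = 150, global_shift = -1000, grid = wide
  )
  expect_equal(attr(sp, "normalization"), 1, tolerance = 0.01)
  expect_false(attr(sp, "grid_warning"))
  pk <- peak_positions(sp)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$wavenumber, 11000, tolerance = 2)

  # halving the width doubles the peak height (D / (pi * Gamma))
  sp2 <- lorentzian_spectrum(st,
    hwhm_low_band = 75, global_shift = -1000, grid = wide
  )
  expect_equal(max(sp2$intensity) / max(sp$intensity), 2, tolerance = 0.01)

  # a clipped grid raises the normalization flag
  clipped <- lorentzian_spectrum(st,
    hwhm_low_band = 150, global_shift = 0,
    grid = seq(11800, 12200, by = 1)
  )
  expect_true(attr(clipped, "grid_warning"))
})

test_that("well-separated equal states give two equal maxima", {
  st <- multi_state(c(11000, 13000), c(1, 1))
  sp <- lorentzian_spectrum(st,
    hwhm_low_band = 100, global_shift = 0,
    grid = seq(9000, 15000, by = 1)
  )
  pk <- peak_positions(sp)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$height[1], pk$height[2], tolerance = 1e-3)
  expect_setequal(round(pk$wavenumber), c(11000, 13000))

  # merged peaks at sub-width separation give one maximum
  stm <- multi_state(c(12000, 12050), c(1, 1))
  spm <- lorentzian_spectrum(stm,
    hwhm_low_band = 100, global_shift = 0,
    grid = seq(9000, 15000, by = 1)
  )
  expect_equal(nrow(peak_positions(spm)), 1)

  # empty state list -> no peaks
  st0 <- multi_state(12000, 0)
  expect_equal(nrow(peak_positions(lorentzian_spectrum(st0,
    grid = seq(9000, 15000, 1), global_shift = 0
  ))), 0)
})

test_that("the global shift translates the spectrum rigidly", {
  st <- multi_state(c(12000, 12600), c(1, 0.5))
  g <- seq(8000, 16000, by = 1)
  s0 <- lorentzian_spectrum(st, global_shift = 0, grid = g)
  s1 <- lorentzian_spectrum(st, global_shift = -1247, grid = g - 1247)
  expect_equal(s1$intensity, s0$intensity, tolerance = 1e-12)
})

test_that("spectrum averaging is the linear pointwise mean", {
  st <- multi_state(c(12000, 12600), c(1, 0.5))
  g <- seq(9000, 15000, by = 2)
  s1 <- lorentzian_spectrum(st, global_shift = 0, grid = g)
  expect_equal(average_spectra(list(s1, s1))$intensity, s1$intensity)

  st2 <- multi_state(c(11500, 13200), c(0.7, 0.9))
  s2 <- lorentzian_spectrum(st2, global_shift = 0, grid = g)
  avg <- average_spectra(list(s1, s2))
  expect_equal(avg$intensity, (s1$intensity + s2$intensity) / 2)

  s3 <- lorentzian_spectrum(st2, global_shift = 0, grid = g + 1)
  expect_error(average_spectra(list(s1, s3)), "grid")
})

test_that("per-frame averaging and the averaged Hamiltonian peak together", {
  ring <- build_ideal_ring(
    include_b800 = FALSE,
    site_energies = c(alpha = 13639, beta = 13693, b800 = 0)
  )
  ens <- sample_ensemble(
    ring, disorder_model(sigma_by_role = c(alpha = 290, beta = 297, b800 = 0)),
    n_frames = 50, seed = 17
  )
  hams <- per_frame_hamiltonians(ens, v1 = 149, v2 = 281)
  g <- seq(9000, 16000, by = 2)
  per_frame <- average_spectra(lapply(hams, function(h) {
    lorentzian_spectrum(diagonalize_hamiltonian(h),
      hwhm_low_band = 280, global_shift = 0, grid = g
    )
  }))
  havg <- symmetry_average(hams)
  avg_h <- lorentzian_spectrum(diagonalize_hamiltonian(havg),
    hwhm_low_band = 280, global_shift = 0, grid = g
  )
  p1 <- peak_positions(per_frame)$wavenumber[1]
  p2 <- peak_positions(avg_h)$wavenumber[1]
  expect_lt(abs(p1 - p2), 280) # agree within one HWHM
})

test_that("site-energy corrections shift the diagonal and only the diagonal", {
  h <- build_nn_ring_hamiltonian("LL")
  expect_equal(apply_site_corrections(h, c(alpha = 0, beta = 0))$matrix, h$matrix)

  # a uniform correction shifts every eigenvalue by exactly that amount
  hc <- apply_site_corrections(h, c(alpha = 50, beta = 50))
  expect_equal(
    diagonalize_hamiltonian(hc)$energies,
    diagonalize_hamiltonian(h)$energies + 50,
    tolerance = 1e-9
  )

  # the acetyl-torsion correction reproduces the closed-form increment
  hcorr <- apply_site_corrections(h, c(alpha = 220, beta = 120))
  inc <- ek1(assign_k(diagonalize_hamiltonian(hcorr))) -
    ek1(assign_k(diagonalize_hamiltonian(h)))
  inc_oracle <- two_band_k1(13639 + 220, 13693 + 120, 149, 281) -
    two_band_k1(13639, 13693, 149, 281)
  expect_equal(inc, inc_oracle, tolerance = 1e-8)
  expect_error(apply_site_corrections(h, c(gamma = 10)), "unknown role")
})

test_that("coupling-class scaling is exact, monotone in effect and linear", {
  h <- build_nn_ring_hamiltonian("PucD")
  expect_equal(scale_coupling_class(h, "intra_chain", 1)$matrix, h$matrix)

  sweep <- scale_coupling_sweep(h, factors = seq(1, 0.65, by = -0.05))
  expect_true(all(diff(sweep$e_k1) > 0)) # blue shift as V2 drops

  # scaling both classes with eps_a = eps_b scales the splitting
  hu <- build_nn_ring_hamiltonian(
    eps_alpha = 13500, eps_beta = 13500, v1 = 200, v2 = 300
  )
  hs <- scale_coupling_class(
    scale_coupling_class(hu, "intra_chain", 0.5), "inter_chain", 0.5
  )
  e0 <- diagonalize_hamiltonian(hu)$energies - 13500
  es <- diagonalize_hamiltonian(hs)$energies - 13500
  expect_equal(es, 0.5 * e0, tolerance = 1e-9)

  expect_error(scale_coupling_class(h, "intra_chain", 0), "positive")
})

test_that("the double-ring fixture shows two bands; dropping the 18-ring leaves one", {
  ring <- build_ideal_ring()
  h <- assemble_hamiltonian(ring, couple_frame(ring))
  st <- diagonalize_hamiltonian(h)
  g <- seq(9000, 16000, by = 2)
  sp <- lorentzian_spectrum(st,
    hwhm_low_band = 150, hwhm_high_band = 180,
    global_shift = 0, grid = g
  )
  pk <- peak_positions(sp, prominence = 0.05)
  expect_gte(nrow(pk), 2)

  b800 <- ring[ring$role == "b800", ]
  h8 <- assemble_hamiltonian(b800, couple_frame(b800))
  sp8 <- lorentzian_spectrum(diagonalize_hamiltonian(h8),
    hwhm_low_band = 150, hwhm_high_band = 180, global_shift = 0, grid = g
  )
  expect_equal(nrow(peak_positions(sp8, prominence = 0.05)), 1)
})
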