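test_that("ideal ring has the right site count and exact C_n symmetry", {
  ring <- build_ideal_ring()
  expect_equal(nrow(ring), 27)
  expect_equal(sum(ring$role == "alpha"), 9)
  expect_equal(sum(ring$role == "beta"), 9)
  expect_equal(sum(ring$role == "b800"), 9)

  # the generating 40-degree rotation permutes sites exactly
  rot <- transform_frame(ring, angle_deg = 40)
  for (u in 0:8) {
    for (r in c("alpha", "beta", "b800")) {
      src <- rot[rot$unit == u & rot$role == r, ]
      tgt <- ring[ring$unit == (u + 1) %% 9 & ring$role == r, ]
      expect_lt(max(abs(
        c(src$x, src$y, src$z) - c(tgt$x, tgt$y, tgt$z)
      )), 1e-10)
      expect_lt(max(abs(
        c(src$mux, src$muy, src$muz) - c(tgt$mux, tgt$muy, tgt$muz)
      )), 1e-10)
    }
  }

  # sites two apart on the 18-ring are related by a 40-degree rotation
  b850 <- ring[ring$role != "b800", ]
  p1 <- as.numeric(b850[1, c("x", "y", "z")])
  p3 <- as.numeric(b850[3, c("x", "y", "z")])
  th <- 40 * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
    byrow = TRUE
  )
  expect_lt(max(abs(drop(R %*% p1) - p3)), 1e-10)
})

test_that("degenerate ring sizes and invalid parameters are handled", {
  expect_equal(nrow(build_ideal_ring(n_units = 1)), 3)
  expect_error(build_ideal_ring(dipole_magnitude = 0), "dipole_magnitude")
  expect_error(build_ideal_ring(dipole_magnitude = -1), "dipole_magnitude")
  expect_error(build_ideal_ring(n_units = 0), "n_units")
  expect_error(disorder_model(corr_intra = 0.8, corr_inter = 0.5), "exceed 1")
  expect_error(disorder_model(sigma_by_role = c(alpha = -1, beta = 1, b800 = 1)))
})

test_that("zero disorder reproduces the base frame; sampling is deterministic", {
  ring <- build_ideal_ring()
  ens <- sample_ensemble(ring, disorder_model(
    sigma_by_role = c(alpha = 0, beta = 0, b800 = 0)
  ), n_frames = 3, seed = 7)
  for (f in 1:3) {
    fr <- dplyr::select(ens[ens$frame == f, ], -"frame")
    expect_equal(as.data.frame(fr), as.data.frame(ring), tolerance = 1e-12)
  }
  e1 <- sample_ensemble(ring, disorder_model(orient_jitter_deg = 5), 4, seed = 11)
  e2 <- sample_ensemble(ring, disorder_model(orient_jitter_deg = 5), 4, seed = 11)
  expect_identical(e1, e2)
})

test_that("sampled site energies reproduce the planted mean and spread", {
  ring <- build_ideal_ring()
  dis <- disorder_model(sigma_by_role = c(alpha = 290, beta = 297, b800 = 312))
  ens <- sample_ensemble(ring, dis, n_frames = 2000, seed = 3)
  ea <- ens$site_energy[ens$role == "alpha"]
  expect_lt(abs(stats::sd(ea) - 290) / 290, 0.05)
  # mean convergence within 3 standard errors already at 50 frames
  ens50 <- sample_ensemble(ring, dis, n_frames = 50, seed = 5)
  for (r in c("alpha", "beta", "b800")) {
    e <- ens50$site_energy[ens50$role == r]
    se <- dis$sigma_by_role[[r]] / sqrt(length(e))
    expect_lt(abs(mean(e) - ring$site_energy[ring$role == r][1]), 3 * se)
  }
})

test_that("jitter correlations behave as configured", {
  ring <- build_ideal_ring()
  # perfect intra correlation: alpha/beta partners rotate identically
  ens <- sample_ensemble(
    ring,
    disorder_model(orient_jitter_deg = 8, corr_intra = 1),
    n_frames = 10, seed = 2
  )
  base_dir <- atan2(ring$muy, ring$mux)
  for (f in unique(ens$frame)) {
    fr <- ens[ens$frame == f, ]
    dirs <- atan2(fr$muy, fr$mux)
    dang <- (dirs - base_dir + pi) %% (2 * pi) - pi
    for (u in 0:8) {
      expect_equal(
        dang[fr$role == "alpha" & fr$unit == u],
        dang[fr$role == "beta" & fr$unit == u],
        tolerance = 1e-10
      )
    }
  }

  # with corr_intra = 1 and corr_inter = 0 the inter-chain orientation
  # factor fluctuates more than the intra-chain one
  d <- descriptor_distributions(sample_ensemble(
    ring, disorder_model(orient_jitter_deg = 4, corr_intra = 1, corr_inter = 0),
    n_frames = 120, seed = 4
  ))
  s <- attr(d, "summary")
  expect_gt(
    s$kappa_sd[s$class == "inter_chain"],
    s$kappa_sd[s$class == "intra_chain"]
  )
})

test_that("CT manifold enumerates both transfer directions per adjacent pair", {
  ring <- build_ideal_ring()
  ct <- make_ct_manifold(ring, seed = 1)
  expect_equal(nrow(ct$states), 36) # 18 adjacent pairs x 2 directions
  expect_true(all(paste(ct$states$acceptor, ct$states$donor) %in%
    paste(ct$states$donor, ct$states$acceptor)))

  # deterministic energies: mean + alignment shift when sd = 0
  ct0 <- make_ct_manifold(ring, energy_mean = 16000, energy_sd = 0, seed = 1)
  expect_true(all(ct0$states$energy == 16000 - 1008))
  # default placement keeps the shifted CT manifold above the LE energies
  expect_true(all(ct$states$energy >= max(ring$site_energy)))

  # non-adjacent pairs in a user coupling table are rejected
  b850 <- ring[ring$role != "b800", ]
  bad <- tibble::tibble(
    site_id = b850$site_id[1], donor = b850$site_id[1],
    acceptor = b850$site_id[5], v = 100
  )
  expect_error(make_ct_manifold(ring, coupling_table = bad), "non-adjacent")
})

test_that("planted regression data have the promised signal structure", {
  coeffs <- c(2500, -1800, 900, 600)
  d0 <- plant_regression_data(4, coeffs, noise_sd = 0, n_samples = 60, seed = 1)
  fit0 <- suppressWarnings(fit_bond_length_regression(d0)) # exact fit by design
  expect_equal(fit0$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(fit0$coefficients), coeffs, tolerance = 1e-8)

  sd6 <- noise_sd_for_r2(coeffs, bond_sd = 0.015, r2 = 0.6)
  d6 <- plant_regression_data(4, coeffs,
    noise_sd = sd6, n_samples = 1000, seed = 2
  )
  fit6 <- fit_bond_length_regression(d6)
  expect_lt(abs(fit6$r_squared - 0.6), 0.05)

  # row order is irrelevant
  dperm <- d6[sample.int(nrow(d6)), ]
  fitp <- fit_bond_length_regression(dperm)
  expect_equal(fitp$coefficients, fit6$coefficients, tolerance = 1e-10)
})

test_that("ensemble manifest round-trips generator parameters", {
  f <- withr::local_tempfile(fileext = ".cfg")
  params <- list(n_frames = 50, seed = 123, sigma_alpha = 276.5, label = "LL")
  write_ensemble_manifest(params, f)
  back <- read_ensemble_manifest(f)
  expect_equal(back$n_frames, 50)
  expect_equal(back$sigma_alpha, 276.5)
  expect_equal(back$label, "LL")
})
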