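test_that("Hamiltonian assembly produces the documented block structure", {
  # minimal dimer
  dimer <- build_ideal_ring(n_units = 1, include_b800 = FALSE)
  h2 <- assemble_hamiltonian(
    dimer,
    tibble::tibble(i = dimer$site_id[1], j = dimer$site_id[2], v_total = 100)
  )
  expect_equal(dim(h2$matrix), c(2, 2))
  expect_equal(h2$matrix[1, 2], 100)
  expect_equal(h2$matrix[2, 1], 100)

  # 18 LE + 36 CT -> 54 x 54 symmetric with zero CT-CT couplings
  ring <- build_ideal_ring(include_b800 = FALSE)
  cpl <- nn_couplings(ring, v1 = 266, v2 = 298)
  ct <- make_ct_manifold(ring, energy_mean = 16000, seed = 1)
  h <- assemble_hamiltonian(ring, cpl, ct)
  expect_equal(dim(h$matrix), c(54, 54))
  expect_equal(h$matrix, t(h$matrix))
  ct_block <- h$matrix[19:54, 19:54]
  expect_equal(ct_block - diag(diag(ct_block)), matrix(0, 36, 36))

  # an empty CT manifold is the same as omitting it
  h_no <- assemble_hamiltonian(ring, cpl)
  expect_equal(h$matrix[1:18, 1:18], h_no$matrix)

  bad <- tibble::tibble(i = 999, j = 1, v_total = 10)
  expect_error(assemble_hamiltonian(ring, bad), "unknown site")
})

test_that("diagonalization matches closed forms and conserves dipole strength", {
  # diagonal Hamiltonian: states are the sites
  ring <- build_ideal_ring(include_b800 = FALSE)
  h0 <- assemble_hamiltonian(
    ring,
    tibble::tibble(i = integer(), j = integer(), v_total = numeric())
  )
  st0 <- diagonalize_hamiltonian(h0)
  expect_equal(st0$energies, sort(ring$site_energy))

  # homodimer (eps, eps, V): split eps +/- V, in-phase state carries all
  # strength for parallel dipoles
  dimer <- tibble::tibble(
    site_id = 1:2, unit = 0L, role = c("alpha", "beta"),
    x = c(0, 9), y = 0, z = 0, mux = 0, muy = 6.3, muz = 0,
    site_energy = 13500
  )
  hd <- assemble_hamiltonian(dimer, tibble::tibble(i = 1, j = 2, v_total = 200))
  std <- diagonalize_hamiltonian(hd)
  expect_equal(std$energies, c(13300, 13700))
  expect_equal(std$dipole_strengths[2], 2 * 6.3^2, tolerance = 1e-9)
  expect_equal(std$dipole_strengths[1], 0, tolerance = 1e-9)

  # 18-site nearest-neighbour ring vs the analytic two-band dispersion
  for (cx in c("HL", "LL", "PucD")) {
    p <- dplyr::filter(lh2_site_parameters(), complex == cx)
    val <- function(nm) p$value[p$parameter == nm]
    st <- diagonalize_hamiltonian(build_nn_ring_hamiltonian(cx))
    expect_lt(
      max(abs(st$energies -
        two_band_energies(val("alpha"), val("beta"), val("V1ab"), val("V2ab")))),
      1e-8
    )
  }

  # completeness: total dipole strength equals the site total
  ring27 <- build_ideal_ring()
  h27 <- assemble_hamiltonian(ring27, couple_frame(ring27))
  st27 <- diagonalize_hamiltonian(h27)
  expect_equal(
    sum(st27$dipole_strengths),
    sum(ring27$mux^2 + ring27$muy^2 + ring27$muz^2),
    tolerance = 1e-6
  )

  hbad <- h27
  hbad$matrix[1, 2] <- hbad$matrix[1, 2] + 1
  expect_error(diagonalize_hamiltonian(hbad), "not symmetric")
})

test_that("symmetry averaging commutes with the ring rotation and recovers means", {
  # a single symmetric frame is a fixed point
  h <- build_nn_ring_hamiltonian("LL")
  havg <- symmetry_average(h)
  expect_equal(havg$matrix, h$matrix, tolerance = 1e-12)

  # disordered ensemble: averaged diagonal recovers the planted means
  ring <- build_ideal_ring(site_energies = c(
    alpha = 13639, beta = 13693, b800 = 13735
  ))
  dis <- disorder_model(sigma_by_role = c(alpha = 290, beta = 297, b800 = 312))
  ens <- sample_ensemble(ring, dis, n_frames = 50, seed = 21)
  hams <- per_frame_hamiltonians(
    dplyr::filter(ens, role != "b800"),
    v1 = 149, v2 = 281
  )
  havg <- symmetry_average(hams)

  # exactly one distinct diagonal value per site class after averaging
  d <- diag(havg$matrix)
  expect_equal(length(unique(round(d, 9))), 2) # alpha and beta classes
  alpha_mean <- d[havg$basis$role == "alpha"][1]
  se <- 290 / sqrt(50 * 9)
  expect_lt(abs(alpha_mean - 13639), 3 * se)

  # commutation with the C9 permutation
  p <- excitonring:::rotation_permutation(havg$basis, 9)
  P <- diag(18)[p, ]
  expect_lt(max(abs(P %*% havg$matrix - havg$matrix %*% P)), 1e-9)

  # full 27-site average has exactly 3 distinct diagonal values
  hams27 <- per_frame_hamiltonians(ens, v1 = 149, v2 = 281)
  havg27 <- symmetry_average(hams27)
  expect_equal(length(unique(round(diag(havg27$matrix), 9))), 3)

  h2 <- build_nn_ring_hamiltonian("HL")
  h2$basis$label[1] <- "mismatch"
  expect_error(symmetry_average(list(h, h2)), "same basis")
})

test_that("k assignment follows the ring convention and degrades under disorder", {
  st <- assign_k(diagonalize_hamiltonian(build_nn_ring_hamiltonian("HL")))
  # all 18 labels defined, one per mode
  expect_setequal(st$k, c(-8:9))
  # dark k = 0 singlet lowest, bright k = +/-1 pair just above
  expect_equal(st$k[1], 0)
  expect_setequal(st$k[2:3], c(1, -1))
  # the two non-degenerate states carry k = 0 and k = 9
  expect_setequal(st$k[c(1, 18)], c(0, 9))

  # site-localized states (V = 0) have undefined labels
  ring <- build_ideal_ring(include_b800 = FALSE)
  h0 <- assemble_hamiltonian(
    ring,
    tibble::tibble(i = integer(), j = integer(), v_total = numeric())
  )
  st0 <- assign_k(diagonalize_hamiltonian(h0))
  expect_true(all(is.na(st0$k)))

  # rigidly rotating the ring by one unit leaves |k| labels unchanged
  rot <- transform_frame(ring, angle_deg = 40)
  strot <- assign_k(diagonalize_hamiltonian(
    assemble_hamiltonian(rot, nn_couplings(rot, v1 = 266, v2 = 298))
  ))
  expect_equal(abs(strot$k), abs(st$k))
})

test_that("exciton width matches the closed-form dispersion", {
  # uniform ring (single site energy, V1 = V2 = V): width = 4 V cos(pi/9)
  V <- 250
  h <- build_nn_ring_hamiltonian(
    eps_alpha = 13500, eps_beta = 13500, v1 = V, v2 = V
  )
  st <- assign_k(diagonalize_hamiltonian(h))
  expect_equal(exciton_width(st), 4 * V * cos(pi / 9), tolerance = 1e-8)

  # scaling all couplings scales the width linearly when eps_a = eps_b
  h2 <- build_nn_ring_hamiltonian(
    eps_alpha = 13500, eps_beta = 13500, v1 = 0.5 * V, v2 = 0.5 * V
  )
  st2 <- assign_k(diagonalize_hamiltonian(h2))
  expect_equal(exciton_width(st2), 0.5 * exciton_width(st), tolerance = 1e-8)

  # Table-parameter rings against the frozen two-band oracle
  expect_equal(
    exciton_width(assign_k(diagonalize_hamiltonian(
      build_nn_ring_hamiltonian("HL")
    ))),
    two_band_width(13527, 13556, 266, 298),
    tolerance = 1e-8
  )
})

test_that("bright/dark census matches the symmetric-ring selection rules", {
  st <- diagonalize_hamiltonian(build_nn_ring_hamiltonian("HL"))
  cen <- bright_dark_census(st)
  expect_equal(cen$n_dark, 14)
  expect_equal(cen$n_bright, 4)
  expect_equal(cen$n_degenerate_pairs, 8)
  expect_equal(cen$n_singlets, 2)

  # static disorder redistributes strength into formerly dark states
  ring <- build_ideal_ring(include_b800 = FALSE)
  ens <- sample_ensemble(
    ring, disorder_model(sigma_by_role = c(alpha = 276, beta = 279, b800 = 326)),
    n_frames = 1, seed = 13
  )
  fr <- dplyr::select(ens, -"frame")
  std <- diagonalize_hamiltonian(
    assemble_hamiltonian(fr, nn_couplings(fr, v1 = 266, v2 = 298))
  )
  expect_gt(bright_dark_census(std)$n_bright, cen$n_bright)
})

test_that("the low-light k = +/-1 exciton is blue-shifted relative to high-light", {
  e_hl <- ek1(assign_k(diagonalize_hamiltonian(build_nn_ring_hamiltonian("HL"))))
  e_ll <- ek1(assign_k(diagonalize_hamiltonian(build_nn_ring_hamiltonian("LL"))))
  expect_gt(e_ll, e_hl)
})

test_that("CT mixing shifts match second-order perturbation in the weak regime", {
  ring <- build_ideal_ring(include_b800 = FALSE)
  cpl <- nn_couplings(ring, v1 = 266, v2 = 298)
  h_le <- assemble_hamiltonian(ring, cpl)

  # zero LE-CT coupling -> zero shift
  ct0 <- make_ct_manifold(ring,
    energy_mean = 17000, le_ct_coupling = 0, seed = 1
  )
  sh0 <- ct_shift(assemble_hamiltonian(ring, cpl, ct0), h_le)
  expect_lt(max(abs(sh0$shift)), 1e-9)

  # gap 10x coupling: exact vs perturbative within 5%
  gap <- 5000 # above the exciton band top
  vc <- 300 # CT gap to band edge ~ 10x later; use a clearly weak coupling
  ct <- make_ct_manifold(ring,
    energy_mean = max(ring$site_energy) + gap + 1008,
    le_ct_coupling = vc, seed = 2
  )
  sh <- ct_shift(assemble_hamiltonian(ring, cpl, ct), h_le)
  expect_false(any(sh$ambiguous))
  big <- abs(sh$shift) > 1
  expect_lt(max(abs(sh$shift[big] - sh$shift_pt2[big]) / abs(sh$shift[big])), 0.05)
  # CT states sit above: the low excitons shift down
  expect_lt(sh$shift[1], 0)

  # lowering the CT energies deepens the k = +/-1 downshift
  shift_k1 <- function(mean_e) {
    ctx <- make_ct_manifold(ring,
      energy_mean = mean_e, le_ct_coupling = vc, seed = 2
    )
    s <- ct_shift(assemble_hamiltonian(ring, cpl, ctx), h_le)
    mean(s$shift[2:3])
  }
  shifts <- vapply(c(21000, 19500, 18500), shift_k1, numeric(1))
  expect_true(all(diff(shifts) < 0)) # more negative as CT comes down
})
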