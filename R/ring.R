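#' Build an ideal C_n-symmetric LH2-like double ring
#'
#' Constructs an idealised nonameric (by default) LH2 pigment frame: an
#' inner ring of `2 * n_units` alternating alpha/beta pigments (the
#' B850-like 18-ring) and an outer ring of `n_units` pigments (the
#' B800-like 9-ring), with exact n-fold rotational symmetry about z.
#' Transition dipoles lie in the ring plane, near-tangential, with
#' alternating tilt offsets and antiparallel alternation between alpha
#' and beta pigments so that nearest-neighbour point-dipole couplings are
#' positive and of the order of a few hundred cm^-1.
#'
#' The returned basis order is fixed throughout the package: B850 sites
#' unit-major (alpha before beta), then B800 sites.
#'
#' @param n_units Number of protomer units (9 for LH2).
#' @param radius_b850,radius_b800 Ring radii in Angstrom.
#' @param z_b800 Axial displacement of the B800 ring, Angstrom.
#' @param dipole_magnitude Transition dipole magnitude, Debye.
#' @param site_offset_deg Angular half-offset of alpha (-) and beta (+)
#'   pigments from their unit axis, degrees. The default makes intra-unit
#'   pairs closer (hence more strongly coupled) than inter-unit pairs.
#' @param dipole_tilt_deg Alternating in-plane tilt of the B850 dipoles
#'   away from the tangent, degrees.
#' @param site_energies Named vector of site energies (cm^-1) for roles
#'   `alpha`, `beta`, `b800`; defaults to the HL complex averages.
#' @param include_b800 Keep the 9-ring? Set `FALSE` for pure 18-ring
#'   models.
#'
#' @return A tibble with one row per pigment site and columns `site_id`,
#'   `unit` (0-based), `role`, `x`, `y`, `z` (Angstrom), `mux`, `muy`,
#'   `muz` (Debye) and `site_energy` (cm^-1).
#' @examples
#' ring <- build_ideal_ring()
#' nrow(ring) # 27 sites
#' @export
build_ideal_ring <- function(n_units = 9,
                             radius_b850 = 26,
                             radius_b800 = 31,
                             z_b800 = 16.5,
                             dipole_magnitude = 6.3,
                             site_offset_deg = 9,
                             dipole_tilt_deg = 10,
                             site_energies = c(alpha = 13527, beta = 13556, b800 = 13783),
                             include_b800 = TRUE) {
  if (n_units < 1) stop("`n_units` must be >= 1", call. = FALSE)
  if (radius_b850 <= 0 || radius_b800 <= 0) {
    stop("ring radii must be positive", call. = FALSE)
  }
  if (dipole_magnitude <= 0) {
    stop("invalid parameter: `dipole_magnitude` must be positive", call. = FALSE)
  }
  if (!all(PIGMENT_ROLES %in% names(site_energies))) {
    stop("`site_energies` must name alpha, beta and b800", call. = FALSE)
  }

  deg <- pi / 180
  units <- seq_len(n_units) - 1L
  phi <- 2 * pi * units / n_units

  # B850 ring: alpha at phi - offset, beta at phi + offset.
  theta_a <- phi - site_offset_deg * deg
  theta_b <- phi + site_offset_deg * deg
  # In-plane dipole direction angles: alpha near +tangent, beta
  # antiparallel (near -tangent), each tilted by +/- dipole_tilt_deg.
  dir_a <- theta_a + pi / 2 + dipole_tilt_deg * deg
  dir_b <- theta_b + 3 * pi / 2 - dipole_tilt_deg * deg

  b850 <- tibble::tibble(
    unit = rep(units, each = 2L),
    role = rep(c("alpha", "beta"), times = n_units),
    theta = as.vector(rbind(theta_a, theta_b)),
    dir = as.vector(rbind(dir_a, dir_b)),
    x = radius_b850 * cos(.data$theta),
    y = radius_b850 * sin(.data$theta),
    z = 0
  )

  frame <- b850
  if (include_b800) {
    b800 <- tibble::tibble(
      unit = units,
      role = "b800",
      theta = phi,
      dir = phi + pi / 2,
      x = radius_b800 * cos(phi),
      y = radius_b800 * sin(phi),
      z = z_b800
    )
    frame <- dplyr::bind_rows(frame, b800)
  }

  frame |>
    dplyr::mutate(
      site_id = dplyr::row_number(),
      mux = dipole_magnitude * cos(.data$dir),
      muy = dipole_magnitude * sin(.data$dir),
      muz = 0,
      site_energy = unname(site_energies[.data$role])
    ) |>
    dplyr::select(
      "site_id", "unit", "role", "x", "y", "z",
      "mux", "muy", "muz", "site_energy"
    )
}

# Internal: sanity-check a pigment frame tibble.
validate_frame <- function(frame) {
  needed <- c(
    "site_id", "unit", "role", "x", "y", "z",
    "mux", "muy", "muz", "site_energy"
  )
  missing <- setdiff(needed, names(frame))
  if (length(missing) > 0) {
    stop("frame is missing columns: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(frame$site_id)) {
    stop("`site_id` must be unique within a frame", call. = FALSE)
  }
  if (!all(frame$role %in% PIGMENT_ROLES)) {
    stop("unknown pigment role(s): ",
      paste(setdiff(unique(frame$role), PIGMENT_ROLES), collapse = ", "),
      call. = FALSE
    )
  }
  mu <- sqrt(frame$mux^2 + frame$muy^2 + frame$muz^2)
  if (any(mu <= 0)) stop("all transition dipoles must be non-zero", call. = FALSE)
  invisible(frame)
}

# Internal: number of protomer units in a frame.
frame_n_units <- function(frame) max(frame$unit) + 1L

# Internal: B850 sites of a frame in ring order (unit-major,
# alpha before beta), i.e. consecutive rows are ring neighbours.
b850_ring <- function(frame) {
  frame |>
    dplyr::filter(.data$role %in% c("alpha", "beta")) |>
    dplyr::arrange(.data$unit, match(.data$role, c("alpha", "beta")))
}

#' Static-disorder and jitter model for ring ensembles
#'
#' Describes per-role Gaussian site-energy disorder, in-plane
#' orientational jitter of the transition dipoles with controllable
#' correlation between bonded B850 neighbours, and radial positional
#' jitter. The orientational correlations emulate the tethering effect of
#' the hydrogen-bond network: when a pigment is H-bonded to the
#' neighbouring protomer its orientational fluctuations stay correlated
#' with that neighbour, which narrows the distribution of the pairwise
#' orientation factor kappa.
#'
#' Correlation is realised by shared Gaussian draws: alpha and beta of
#' the same unit share a weight-`sqrt(corr_intra)` component, beta of
#' unit u and alpha of unit u+1 share a weight-`sqrt(corr_inter)`
#' component, and the remainder is private. This requires
#' `corr_intra + corr_inter <= 1`.
#'
#' @param sigma_by_role Named vector of site-energy standard deviations
#'   (cm^-1) for `alpha`, `beta`, `b800`; defaults to the HL complex.
#' @param orient_jitter_deg Standard deviation of the in-plane dipole
#'   rotation, degrees.
#' @param radial_jitter_A Standard deviation of the radial center
#'   displacement, Angstrom.
#' @param corr_intra,corr_inter Correlation of the jitter angles of
#'   intra-unit (alpha-beta) and inter-unit (beta-alpha') B850 partners,
#'   each in `[0, 1]` with `corr_intra + corr_inter <= 1`.
#'
#' @return An object of class `disorder_model`.
#' @examples
#' disorder_model(orient_jitter_deg = 8, corr_intra = 0.8)
#' @export
disorder_model <- function(sigma_by_role = c(alpha = 276, beta = 279, b800 = 326),
                           orient_jitter_deg = 0,
                           radial_jitter_A = 0,
                           corr_intra = 0,
                           corr_inter = 0) {
  if (!all(PIGMENT_ROLES %in% names(sigma_by_role))) {
    stop("`sigma_by_role` must name alpha, beta and b800", call. = FALSE)
  }
  if (any(sigma_by_role < 0)) stop("disorder sigmas must be >= 0", call. = FALSE)
  if (orient_jitter_deg < 0 || radial_jitter_A < 0) {
    stop("jitter widths must be >= 0", call. = FALSE)
  }
  if (corr_intra < 0 || corr_intra > 1 || corr_inter < 0 || corr_inter > 1) {
    stop("correlations must lie in [0, 1]", call. = FALSE)
  }
  if (corr_intra + corr_inter > 1 + 1e-12) {
    stop("`corr_intra` + `corr_inter` must not exceed 1 in the shared-draw model",
      call. = FALSE
    )
  }
  structure(
    list(
      sigma_by_role = sigma_by_role[PIGMENT_ROLES],
      orient_jitter_deg = orient_jitter_deg,
      radial_jitter_A = radial_jitter_A,
      corr_intra = corr_intra,
      corr_inter = corr_inter
    ),
    class = "disorder_model"
  )
}

#' @export
print.disorder_model <- function(x, ...) {
  cat("<disorder_model>\n")
  cat("  sigma (cm^-1): ",
    paste(names(x$sigma_by_role), round(x$sigma_by_role, 1),
      sep = "=", collapse = ", "
    ), "\n",
    sep = ""
  )
  cat("  orientation jitter:", x$orient_jitter_deg, "deg;  radial jitter:",
    x$radial_jitter_A, "A\n")
  cat("  corr_intra:", x$corr_intra, " corr_inter:", x$corr_inter, "\n")
  invisible(x)
}

#' Sample a disordered ensemble of ring frames
#'
#' Draws `n_frames` independent realizations of a base frame under a
#' [disorder_model()]: site energies from role-specific Gaussians,
#' in-plane dipole rotations with the configured bond correlations, and
#' radial center displacements. A single RNG stream seeded once drives
#' all draws; within each frame the order is: site energies (site
#' order), shared intra-unit draws, shared inter-unit draws, private
#' B850 orientation draws, B800 orientation draws, radial draws. The
#' output is therefore bit-reproducible for a given seed.
#'
#' @param frame Base frame from [build_ideal_ring()] (or a read
#'   structure).
#' @param disorder A [disorder_model()].
#' @param n_frames Number of realizations (the reference workflow uses
#'   50 trajectory frames).
#' @param seed Integer seed.
#'
#' @return A tibble of `n_frames * nrow(frame)` rows: the frame columns
#'   plus a leading `frame` index.
#' @examples
#' ring <- build_ideal_ring()
#' ens <- sample_ensemble(ring, disorder_model(), n_frames = 5, seed = 1)
#' @export
sample_ensemble <- function(frame, disorder, n_frames = 50, seed = 1) {
  validate_frame(frame)
  stopifnot(inherits(disorder, "disorder_model"))
  if (n_frames < 1) stop("`n_frames` must be >= 1", call. = FALSE)

  n_units <- frame_n_units(frame)
  ring <- b850_ring(frame)
  n_sites <- nrow(frame)
  sig <- disorder$sigma_by_role[frame$role]
  jit <- disorder$orient_jitter_deg
  a <- sqrt(disorder$corr_intra)
  b <- sqrt(disorder$corr_inter)
  cpriv <- sqrt(max(0, 1 - disorder$corr_intra - disorder$corr_inter))
  is_b850 <- frame$role %in% c("alpha", "beta")
  radial <- cbind(frame$x, frame$y, 0)
  rnorm_len <- sqrt(rowSums(radial^2))
  radial <- radial / ifelse(rnorm_len > 0, rnorm_len, 1)

  withr::with_seed(seed, {
    frames <- purrr::map(seq_len(n_frames), function(f) {
      out <- frame
      out$site_energy <- frame$site_energy + stats::rnorm(n_sites) * sig

      s_u <- stats::rnorm(n_units) # shared within a unit (intra bond)
      r_u <- stats::rnorm(n_units) # shared across units (inter bond)
      p_ring <- stats::rnorm(2L * n_units)
      p_b800 <- stats::rnorm(n_units)
      dr <- stats::rnorm(n_sites) * disorder$radial_jitter_A

      # standardized jitter per B850 site, ring order
      zu <- numeric(2L * n_units)
      for (u in seq_len(n_units) - 1L) {
        ia <- 2L * u + 1L
        ib <- 2L * u + 2L
        u_prev <- (u - 1L) %% n_units
        zu[ia] <- a * s_u[u + 1L] + b * r_u[u_prev + 1L] + cpriv * p_ring[ia]
        zu[ib] <- a * s_u[u + 1L] + b * r_u[u + 1L] + cpriv * p_ring[ib]
      }
      ang <- numeric(n_sites)
      ang[match(ring$site_id, frame$site_id)] <- jit * zu
      ang[!is_b850] <- jit * p_b800[frame$unit[!is_b850] + 1L]

      rad <- ang * pi / 180
      mux <- out$mux * cos(rad) - out$muy * sin(rad)
      muy <- out$mux * sin(rad) + out$muy * cos(rad)
      out$mux <- mux
      out$muy <- muy
      out$x <- out$x + dr * radial[, 1]
      out$y <- out$y + dr * radial[, 2]
      dplyr::bind_cols(tibble::tibble(frame = f), out)
    })
  })
  dplyr::bind_rows(frames)
}

#' Synthetic charge-transfer manifold for the B850 ring
#'
#' Generates the CT states that mix into the B850 exciton manifold: for
#' every pair of adjacent pigments in the 18-ring both transfer
#' directions (alpha -> beta and beta -> alpha) are created, giving
#' `2 * (2 * n_units)` states (36 for the nonameric ring). CT energies
#' are drawn from a Gaussian and then lowered by `alignment_shift`, the
#' a-posteriori correction that aligns the CT-capable electronic
#'-structure level with the one used for the local excitations. Each CT
#' state couples to the local excitations of its donor and acceptor
#' sites.
#'
#' @param frame A pigment frame containing an 18-site B850 subring.
#' @param energy_mean Mean CT energy (cm^-1) before the alignment shift;
#'   defaults to 2500 cm^-1 above the highest site energy so that the
#'   shifted CT manifold stays above the local excitations.
#' @param energy_sd Gaussian spread of the CT energies, cm^-1.
#' @param le_ct_coupling Mean LE-CT coupling magnitude, cm^-1.
#' @param coupling_sd Gaussian spread of the LE-CT couplings, cm^-1.
#' @param coupling_table Optional tibble `(site_id, donor, acceptor, v)`
#'   overriding the generated couplings; referencing a non-adjacent
#'   donor/acceptor pair is an error.
#' @param alignment_shift Additive alignment of the CT energies, cm^-1
#'   (default -1008).
#' @param seed Integer seed.
#'
#' @return An object of class `ct_manifold`: a list with tibbles
#'   `states` (`ct_index`, `donor`, `acceptor`, `energy`) and
#'   `couplings` (`ct_index`, `site_id`, `v`).
#' @examples
#' ct <- make_ct_manifold(build_ideal_ring(), seed = 1)
#' nrow(ct$states) # 36
#' @export
make_ct_manifold <- function(frame,
                             energy_mean = NULL,
                             energy_sd = 0,
                             le_ct_coupling = 250,
                             coupling_sd = 0,
                             coupling_table = NULL,
                             alignment_shift = -1008,
                             seed = 1) {
  validate_frame(frame)
  ring <- b850_ring(frame)
  n_ring <- nrow(ring)
  if (n_ring < 2) stop("frame has no 18-site B850 subring", call. = FALSE)
  if (is.null(energy_mean)) energy_mean <- max(frame$site_energy) + 2500

  nxt <- c(seq_len(n_ring)[-1], 1L)
  edges <- tibble::tibble(
    i = ring$site_id,
    j = ring$site_id[nxt]
  )
  states <- tibble::tibble(
    donor = c(edges$i, edges$j),
    acceptor = c(edges$j, edges$i)
  ) |>
    dplyr::arrange(match(.data$donor, ring$site_id), match(.data$acceptor, ring$site_id)) |>
    dplyr::mutate(ct_index = dplyr::row_number(), .before = 1)

  withr::with_seed(seed, {
    states$energy <- energy_mean + stats::rnorm(nrow(states)) * energy_sd +
      alignment_shift
    couplings <- tibble::tibble(
      ct_index = rep(states$ct_index, each = 2L),
      site_id = as.vector(rbind(states$donor, states$acceptor))
    )
    couplings$v <- le_ct_coupling + stats::rnorm(nrow(couplings)) * coupling_sd
  })

  if (!is.null(coupling_table)) {
    key_adj <- c(paste(edges$i, edges$j), paste(edges$j, edges$i))
    bad <- !(paste(coupling_table$donor, coupling_table$acceptor) %in% key_adj)
    if (any(bad)) {
      stop("coupling table references non-adjacent pair(s): ",
        paste(unique(paste0(
          "(", coupling_table$donor[bad], ",",
          coupling_table$acceptor[bad], ")"
        )), collapse = ", "),
        call. = FALSE
      )
    }
    idx <- match(
      paste(coupling_table$donor, coupling_table$acceptor),
      paste(states$donor, states$acceptor)
    )
    couplings <- tibble::tibble(
      ct_index = idx,
      site_id = coupling_table$site_id,
      v = coupling_table$v
    )
  }

  structure(
    list(states = states, couplings = couplings, alignment_shift = alignment_shift),
    class = "ct_manifold"
  )
}

#' @export
print.ct_manifold <- function(x, ...) {
  cat("<ct_manifold> ", nrow(x$states), " CT states, ",
    nrow(x$couplings), " LE-CT couplings\n",
    sep = ""
  )
  cat("  energy range (cm^-1): ",
    paste(round(range(x$states$energy), 1), collapse = " .. "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Plant a linear bond-length / excitation-energy data set
#'
#' Generates synthetic training data for the bond-length regression of
#' site energies: bond lengths fluctuate independently around a common
#' mean and the excitation energy is an exact linear function of them
#' plus Gaussian noise. The generating parameters are attached as
#' attributes so recovery can be tested.
#'
#' @param n_bonds Number of bond-length descriptors.
#' @param coeffs Regression coefficients, cm^-1 per Angstrom (recycled
#'   or length `n_bonds`).
#' @param noise_sd Residual standard deviation, cm^-1.
#' @param n_samples Number of rows (must exceed `n_bonds`).
#' @param seed Integer seed.
#' @param intercept Intercept, cm^-1.
#' @param bond_mean,bond_sd Mean and SD of each bond length, Angstrom.
#'
#' @return A tibble with columns `bond_01` ... and `energy`; attributes
#'   `coeffs`, `intercept` and `noise_sd` hold the generating truth.
#' @seealso [noise_sd_for_r2()] to target a planted R^2;
#'   [fit_bond_length_regression()] for the fit.
#' @examples
#' d <- plant_regression_data(4, coeffs = c(2000, -1500, 800, 400),
#'                            noise_sd = 0, n_samples = 50, seed = 1)
#' @export
plant_regression_data <- function(n_bonds,
                                  coeffs,
                                  noise_sd,
                                  n_samples,
                                  seed = 1,
                                  intercept = 13500,
                                  bond_mean = 1.42,
                                  bond_sd = 0.015) {
  if (n_samples <= n_bonds) stop("`n_samples` must exceed `n_bonds`", call. = FALSE)
  coeffs <- rep_len(coeffs, n_bonds)
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(n_samples * n_bonds, bond_mean, bond_sd),
      nrow = n_samples
    )
    energy <- intercept + drop(x %*% coeffs) +
      stats::rnorm(n_samples) * noise_sd
  })
  colnames(x) <- sprintf("bond_%02d", seq_len(n_bonds))
  out <- dplyr::bind_cols(tibble::as_tibble(x), tibble::tibble(energy = energy))
  attr(out, "coeffs") <- coeffs
  attr(out, "intercept") <- intercept
  attr(out, "noise_sd") <- noise_sd
  out
}

#' Residual SD that yields a target planted R-squared
#'
#' For independent bond lengths with common standard deviation
#' `bond_sd`, the signal variance of the planted linear model is
#' `sum(coeffs^2) * bond_sd^2`; the residual SD giving population
#' R-squared `r2` follows from `r2 = var_signal / (var_signal + sd^2)`.
#'
#' @param coeffs Planted regression coefficients, cm^-1 per Angstrom.
#' @param bond_sd Bond-length standard deviation, Angstrom.
#' @param r2 Target population R-squared in (0, 1).
#' @return Residual standard deviation, cm^-1.
#' @examples
#' noise_sd_for_r2(c(2000, -1500), 0.015, r2 = 0.6)
#' @export
noise_sd_for_r2 <- function(coeffs, bond_sd, r2) {
  if (r2 <= 0 || r2 >= 1) stop("`r2` must lie in (0, 1)", call. = FALSE)
  var_signal <- sum(coeffs^2) * bond_sd^2
  sqrt(var_signal * (1 - r2) / r2)
}
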