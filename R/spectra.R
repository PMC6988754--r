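#' Lorentzian absorption spectrum from exciton states
#'
#' Convolves the exciton stick spectrum with Lorentzian lineshapes,
#' `I(v) = sum_s D_s (1/pi) G_s / ((v - E_s - shift)^2 + G_s^2)`,
#' where `D_s` is the dipole strength and the half-width at
#' half-maximum `G_s` is assigned per band: B850-dominated states get
#' the low-energy-band width, B800- and CT-dominated states the
#' high-energy-band width (or a fixed energy cutoff via `band_split`).
#' A rigid `global_shift` aligns the computed energies with experiment.
#' All broadening sources are lumped into the single lineshape.
#'
#' @param states An `exciton_states` object.
#' @param hwhm_low_band,hwhm_high_band Lorentzian HWHMs, cm^-1
#'   (reference values: 150 for the high-light complex, 280 for the
#'   low-light forms' low band, 180 for the high band).
#' @param global_shift Rigid shift applied to all state energies, cm^-1.
#' @param grid Wavenumber grid, cm^-1 (strictly increasing).
#' @param band_split Optional energy cutoff (cm^-1, on the unshifted
#'   scale): states below it get the low-band width, above it the
#'   high-band width. When `NULL` the per-state band labels are used.
#' @return A `spectrum_model` tibble `(wavenumber, wavelength,
#'   intensity)` with attributes recording the widths, the shift and a
#'   normalization check (`normalization` = integral / total dipole
#'   strength; `grid_warning` is set when it deviates by more than 1%,
#'   i.e. the grid clips the Lorentzian tails).
#' @examples
#' st <- diagonalize_hamiltonian(build_nn_ring_hamiltonian("HL"))
#' sp <- lorentzian_spectrum(st)
#' @export
lorentzian_spectrum <- function(states,
                                hwhm_low_band = 150,
                                hwhm_high_band = 180,
                                global_shift = -1247,
                                grid = seq(9000, 15000, by = 1),
                                band_split = NULL) {
  stopifnot(inherits(states, "exciton_states"))
  if (any(diff(grid) <= 0)) stop("`grid` must be strictly increasing", call. = FALSE)
  if (hwhm_low_band <= 0 || hwhm_high_band <= 0) {
    stop("HWHMs must be positive", call. = FALSE)
  }

  e <- states$energies
  d <- states$dipole_strengths
  if (is.null(band_split)) {
    low <- states$band == "b850"
  } else {
    low <- e < band_split
  }
  gam <- ifelse(low, hwhm_low_band, hwhm_high_band)

  centers <- e + global_shift
  intensity <- rep(0, length(grid))
  for (s in seq_along(e)) {
    if (d[s] == 0) next
    intensity <- intensity +
      d[s] * (gam[s] / pi) / ((grid - centers[s])^2 + gam[s]^2)
  }

  out <- tibble::tibble(
    wavenumber = grid,
    wavelength = 1e7 / grid,
    intensity = intensity
  )
  total_d <- sum(d)
  integral <- sum((intensity[-1] + intensity[-length(intensity)]) / 2 * diff(grid))
  normalization <- if (total_d > 0) integral / total_d else 1
  attr(out, "hwhm_low_band") <- hwhm_low_band
  attr(out, "hwhm_high_band") <- hwhm_high_band
  attr(out, "global_shift") <- global_shift
  attr(out, "normalization") <- normalization
  attr(out, "grid_warning") <- abs(normalization - 1) > 0.01
  class(out) <- c("spectrum_model", class(out))
  out
}

#' Pointwise average of spectra
#'
#' Averages per-frame spectra on a common grid (the route used when
#' disorder is treated frame-by-frame instead of through the averaged
#' Hamiltonian). Averaging is linear and grid mismatches are an error.
#'
#' @param spectra A list of `spectrum_model` objects sharing a grid.
#' @return A `spectrum_model`.
#' @export
average_spectra <- function(spectra) {
  stopifnot(length(spectra) >= 1)
  g <- spectra[[1]]$wavenumber
  for (sp in spectra) {
    if (!isTRUE(all.equal(sp$wavenumber, g))) {
      stop("all spectra must share the same wavenumber grid", call. = FALSE)
    }
  }
  out <- spectra[[1]]
  out$intensity <- Reduce(`+`, lapply(spectra, function(sp) sp$intensity)) /
    length(spectra)
  out
}

#' Locate spectral peaks
#'
#' Local maxima of the intensity above a relative prominence threshold,
#' sorted by height. Two Lorentzians closer than their width merge into
#' a single reported maximum.
#'
#' @param spectrum A `spectrum_model`.
#' @param prominence Minimum height relative to the global maximum.
#' @return A tibble `(wavenumber, wavelength, height)`.
#' @examples
#' st <- diagonalize_hamiltonian(build_nn_ring_hamiltonian("HL"))
#' peak_positions(lorentzian_spectrum(st))
#' @export
peak_positions <- function(spectrum, prominence = 0.01) {
  y <- spectrum$intensity
  n <- length(y)
  if (n < 3 || max(y) <= 0) {
    return(tibble::tibble(
      wavenumber = numeric(), wavelength = numeric(), height = numeric()
    ))
  }
  mid <- 2:(n - 1)
  is_peak <- y[mid] > y[mid - 1] & y[mid] >= y[mid + 1] &
    y[mid] >= prominence * max(y)
  idx <- mid[is_peak]
  tibble::tibble(
    wavenumber = spectrum$wavenumber[idx],
    wavelength = spectrum$wavelength[idx],
    height = y[idx]
  ) |>
    dplyr::arrange(dplyr::desc(.data$height))
}

#' Apply role-wise site-energy corrections
#'
#' Increments the LE diagonal of a Hamiltonian by a per-role shift,
#' leaving all couplings untouched. This implements the acetyl-torsion
#' correction experiment: the out-of-plane rotation of the acetyl group
#' seen in the crystal forms (but planarized by the classical force
#' field) blue-shifts the site energies by about +220 cm^-1 (alpha) and
#' +120 cm^-1 (beta) without significantly affecting the couplings.
#'
#' @param h An `exciton_hamiltonian`.
#' @param delta_by_role Named numeric vector of shifts (cm^-1) by role.
#' @return The corrected `exciton_hamiltonian`.
#' @examples
#' h <- apply_site_corrections(
#'   build_nn_ring_hamiltonian("LL"),
#'   c(alpha = 220, beta = 120)
#' )
#' @export
apply_site_corrections <- function(h, delta_by_role = c(alpha = 220, beta = 120)) {
  stopifnot(inherits(h, "exciton_hamiltonian"))
  unknown <- setdiff(names(delta_by_role), PIGMENT_ROLES)
  if (length(unknown) > 0) {
    stop("unknown role(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  le <- seq_len(h$n_le)
  delta <- delta_by_role[h$basis$role[le]]
  delta[is.na(delta)] <- 0
  diag(h$matrix)[le] <- diag(h$matrix)[le] + delta
  h$site_energies <- diag(h$matrix)[le]
  h
}

# Internal: logical mask of LE-LE elements belonging to a coupling class.
coupling_class_mask <- function(h, class) {
  le <- h$basis[seq_len(h$n_le), ]
  n_units <- h$n_units
  n <- nrow(h$matrix)
  mask <- matrix(FALSE, n, n)
  for (a in seq_len(h$n_le - 1)) {
    for (b in (a + 1):h$n_le) {
      ra <- le$role[a]
      rb <- le$role[b]
      if (!all(c(ra, rb) %in% c("alpha", "beta"))) next
      same_unit <- le$unit[a] == le$unit[b]
      intra <- same_unit && ra != rb
      inter <- (ra == "beta" && rb == "alpha" && le$unit[b] == (le$unit[a] + 1L) %% n_units) ||
        (rb == "beta" && ra == "alpha" && le$unit[a] == (le$unit[b] + 1L) %% n_units)
      hit <- (class == "intra_chain" && intra) || (class == "inter_chain" && inter)
      if (hit) mask[a, b] <- mask[b, a] <- TRUE
    }
  }
  mask
}

#' Scale one coupling class of a Hamiltonian
#'
#' Multiplies all matrix elements of the chosen nearest-neighbour B850
#' coupling class (`intra_chain` V2 or `inter_chain` V1) by a factor,
#' preserving symmetry. Reducing the intra-chain coupling mimics a
#' larger orientational freedom of the pigment pair within a unit and
#' blue-shifts the k = +/-1 exciton.
#'
#' @param h An `exciton_hamiltonian`.
#' @param class `"intra_chain"` or `"inter_chain"`.
#' @param factor Positive scale factor.
#' @return The scaled `exciton_hamiltonian`.
#' @examples
#' h <- scale_coupling_class(build_nn_ring_hamiltonian("PucD"),
#'   "intra_chain",
#'   factor = 0.7
#' )
#' @export
scale_coupling_class <- function(h, class = c("intra_chain", "inter_chain"), factor) {
  stopifnot(inherits(h, "exciton_hamiltonian"))
  class <- match.arg(class)
  if (factor <= 0) stop("`factor` must be positive", call. = FALSE)
  mask <- coupling_class_mask(h, class)
  h$matrix[mask] <- h$matrix[mask] * factor
  h
}

#' Sweep a coupling-class scale factor
#'
#' Recomputes the k = +/-1 exciton energy (and the exciton width) for a
#' set of scale factors applied to one coupling class — the numerical
#' experiment that asks how much the intra-chain coupling must drop for
#' the low-energy band to shift into the B800 region.
#'
#' @param h Base `exciton_hamiltonian`.
#' @param factors Numeric vector of scale factors.
#' @param class Coupling class to scale.
#' @return A tibble `(factor, e_k1, width)`, energies in cm^-1.
#' @examples
#' scale_coupling_sweep(build_nn_ring_hamiltonian("PucD"),
#'   factors = seq(1, 0.65, by = -0.05)
#' )
#' @export
scale_coupling_sweep <- function(h, factors, class = "intra_chain") {
  purrr::map(factors, function(f) {
    st <- assign_k(diagonalize_hamiltonian(scale_coupling_class(h, class, f)))
    tibble::tibble(
      factor = f,
      e_k1 = mean(st$energies[!is.na(st$k) & abs(st$k) == 1L]),
      width = exciton_width(st)
    )
  }) |>
    dplyr::bind_rows()
}
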