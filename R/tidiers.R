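#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an exciton Hamiltonian into its matrix elements
#'
#' @param x An `exciton_hamiltonian`.
#' @param ... Unused.
#' @return A tibble `(i, j, label_i, label_j, value)` of the non-zero
#'   upper-triangle elements (diagonal included), cm^-1.
#' @method tidy exciton_hamiltonian
#' @export
tidy.exciton_hamiltonian <- function(x, ...) {
  idx <- which(upper.tri(x$matrix, diag = TRUE) & x$matrix != 0, arr.ind = TRUE)
  tibble::tibble(
    i = idx[, 1],
    j = idx[, 2],
    label_i = x$basis$label[idx[, 1]],
    label_j = x$basis$label[idx[, 2]],
    value = x$matrix[idx]
  ) |>
    dplyr::arrange(.data$i, .data$j)
}

#' One-row summary of an exciton Hamiltonian
#'
#' @param x An `exciton_hamiltonian`.
#' @param ... Unused.
#' @return A tibble with `n_le`, `n_ct`, the LE diagonal mean and the
#'   largest off-diagonal coupling.
#' @method glance exciton_hamiltonian
#' @export
glance.exciton_hamiltonian <- function(x, ...) {
  le <- seq_len(x$n_le)
  off <- x$matrix[le, le]
  diag(off) <- 0
  tibble::tibble(
    n_le = x$n_le,
    n_ct = x$n_ct,
    mean_site_energy = mean(diag(x$matrix)[le]),
    max_coupling = max(abs(off))
  )
}

#' Tidy exciton states into a state table
#'
#' @param x An `exciton_states` object.
#' @param threshold_rel Bright threshold relative to the maximum dipole
#'   strength.
#' @param ... Unused.
#' @return A tibble `(state, energy, k, band, dipole_strength, bright)`.
#' @method tidy exciton_states
#' @export
tidy.exciton_states <- function(x, threshold_rel = 1e-6, ...) {
  tibble::tibble(
    state = seq_along(x$energies),
    energy = x$energies,
    k = x$k,
    band = x$band,
    dipole_strength = x$dipole_strengths,
    bright = x$dipole_strengths > threshold_rel * max(x$dipole_strengths)
  )
}

#' One-row summary of exciton states
#'
#' @param x An `exciton_states` object.
#' @param ... Passed to [bright_dark_census()].
#' @return A tibble with state counts, the bright/dark census, the
#'   total dipole strength and (when k labels exist) the exciton width.
#' @method glance exciton_states
#' @export
glance.exciton_states <- function(x, ...) {
  cen <- bright_dark_census(x, ...)
  width <- if (any(!is.na(x$k) & abs(x$k) == 1L) &&
    any(!is.na(x$k) & abs(x$k) == 8L)) {
    exciton_width(x)
  } else {
    NA_real_
  }
  tibble::tibble(
    n_states = length(x$energies),
    n_bright = cen$n_bright,
    n_dark = cen$n_dark,
    n_degenerate_pairs = cen$n_degenerate_pairs,
    total_dipole_strength = sum(x$dipole_strengths),
    exciton_width = width
  )
}

#' Tidy a bond-length regression
#'
#' @param x A `bond_regression`.
#' @param ... Unused.
#' @return A tibble `(term, estimate, std_error)` including the
#'   intercept.
#' @method tidy bond_regression
#' @export
tidy.bond_regression <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std_error = s[, "Std. Error"]
  )
}

#' One-row summary of a bond-length regression
#'
#' @param x A `bond_regression`.
#' @param ... Unused.
#' @return A tibble with `r_squared`, `sigma` (residual SD, cm^-1) and
#'   `n_samples`.
#' @method glance bond_regression
#' @export
glance.bond_regression <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared,
    sigma = summary(x$fit)$sigma,
    n_samples = x$n_samples
  )
}
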