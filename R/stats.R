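#' Bond-length linear regression of site energies
#'
#' Ordinary least squares of the excitation energy on macrocycle bond
#' lengths. The conjugation pattern of the macrocycle makes bond
#' lengths the dominant structural determinant of the Q_y energy, so a
#' plain linear model on all ring bond lengths already explains most of
#' the variability; the fitted model can then predict energies for
#' structures not used in the fit (crystal or optimized geometries).
#' Rank deficiency fails loudly, naming the collinear columns.
#'
#' @param table A data frame whose last column (or a column named
#'   `energy`) is the response and all remaining numeric columns are
#'   bond-length descriptors (Angstrom).
#' @return An object of class `bond_regression`: the underlying `lm`
#'   fit plus `coefficients` (cm^-1 per Angstrom), `intercept`,
#'   `r_squared` and `n_samples`.
#' @examples
#' d <- plant_regression_data(4, c(2000, -1500, 800, 400),
#'   noise_sd = 20, n_samples = 200, seed = 1
#' )
#' fit <- fit_bond_length_regression(d)
#' fit$r_squared
#' @export
fit_bond_length_regression <- function(table) {
  stopifnot(is.data.frame(table))
  ycol <- if ("energy" %in% names(table)) "energy" else names(table)[ncol(table)]
  xcols <- setdiff(names(table), ycol)
  if (nrow(table) <= length(xcols) + 1) {
    stop("need more samples than descriptors", call. = FALSE)
  }
  fit <- stats::lm(
    stats::reformulate(xcols, response = ycol),
    data = table
  )
  co <- stats::coef(fit)
  if (anyNA(co)) {
    stop("rank-deficient design; collinear column(s): ",
      paste(names(co)[is.na(co)], collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      fit = fit,
      coefficients = co[-1],
      intercept = unname(co[1]),
      r_squared = summary(fit)$r.squared,
      n_samples = nrow(table),
      descriptors = xcols
    ),
    class = "bond_regression"
  )
}

#' @export
print.bond_regression <- function(x, ...) {
  cat("<bond_regression> ", length(x$coefficients), " bond descriptors, n = ",
    x$n_samples, ", R^2 = ", round(x$r_squared, 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Predict a site energy from bond lengths
#'
#' Applies a fitted [fit_bond_length_regression()] model to one set of
#' bond lengths: intercept plus dot product.
#'
#' @param model A `bond_regression`.
#' @param bond_lengths Numeric vector matching the model's descriptor
#'   count (Angstrom).
#' @return Predicted excitation energy, cm^-1.
#' @export
predict_site_energy <- function(model, bond_lengths) {
  stopifnot(inherits(model, "bond_regression"))
  if (length(bond_lengths) != length(model$coefficients)) {
    stop("expected ", length(model$coefficients), " bond lengths, got ",
      length(bond_lengths),
      call. = FALSE
    )
  }
  model$intercept + sum(model$coefficients * bond_lengths)
}

#' Group-wise statistics with t-based 95% confidence intervals
#'
#' Mean, sample standard deviation (n - 1 denominator) and a Student-t
#' 95% confidence interval of the mean for each group of records — the
#' summary used for class-wise coupling comparisons across complexes.
#'
#' @param records A data frame.
#' @param value Name of the numeric column to summarise.
#' @param group Name(s) of the grouping column(s).
#' @param conf_level Confidence level.
#' @return A tibble with one row per group: `mean`, `sd`, `ci_low`,
#'   `ci_high`, `n`.
#' @examples
#' cpl <- couple_frame(build_ideal_ring()) |> dplyr::filter(class != "other")
#' class_statistics(cpl, "v_total", "class")
#' @export
class_statistics <- function(records, value, group, conf_level = 0.95) {
  stopifnot(value %in% names(records), all(group %in% names(records)))
  out <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::summarise(
      mean = mean(.data[[value]]),
      sd = stats::sd(.data[[value]]),
      n = dplyr::n(),
      .groups = "drop"
    )
  if (any(out$n < 2)) {
    stop("every group needs at least 2 records for a confidence interval",
      call. = FALSE
    )
  }
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = out$n - 1)
  out |>
    dplyr::mutate(
      ci_low = .data$mean - tcrit * .data$sd / sqrt(.data$n),
      ci_high = .data$mean + tcrit * .data$sd / sqrt(.data$n)
    ) |>
    dplyr::relocate("ci_low", "ci_high", .after = "sd")
}

#' Classical per-residue environment contribution ledger
#'
#' First-order classical estimate of how much each environment residue
#' shifts a pigment's excitation energy, emulating the switch-off
#' analysis (zeroing a residue's charges and polarizabilities and
#' recomputing the excitation). The pigment enters through its
#' ground-to-excited difference charges; at first order the shift from
#' residue R is the Coulomb interaction
#' `delta_eps_R = sum_a sum_k dq_a q_k / r_ak`, so per-residue shifts
#' add up exactly to the total environment shift. With
#' `polarizable = TRUE` the induced-dipole response of the residues'
#' polarizable sites (energy `-1/2 sum mu . E`) is included and the
#' ledger becomes the difference full-minus-switched-off, which is no
#' longer exactly additive. This is a classical estimate of signs and
#' distance trends, not of the quantum-mechanical magnitudes.
#'
#' @param pigment_diff_charges Tibble `(x, y, z, dq)`: atomic difference
#'   charges (excited minus ground), e.
#' @param environment_residues Tibble `(residue, x, y, z, q)` with an
#'   optional `alpha` column (Angstrom^3) for the polarizable mode.
#' @param polarizable Include the induced-dipole response?
#' @return A tibble `(residue, delta_eps)` in cm^-1, one signed shift
#'   per residue, plus the total in attribute `total`.
#' @examples
#' dq <- tibble::tibble(x = c(0, 1), y = 0, z = 0, dq = c(-0.1, 0.1))
#' env <- tibble::tibble(residue = "TYR44", x = 5, y = 0, z = 0, q = 0.5)
#' contribution_ledger(dq, env)
#' @export
contribution_ledger <- function(pigment_diff_charges, environment_residues,
                                polarizable = FALSE) {
  need <- c("x", "y", "z", "dq")
  if (!all(need %in% names(pigment_diff_charges))) {
    stop("difference-charge table needs columns x, y, z, dq", call. = FALSE)
  }
  if (!all(c("residue", "x", "y", "z", "q") %in% names(environment_residues))) {
    stop("environment table needs columns residue, x, y, z, q", call. = FALSE)
  }
  dq <- dplyr::rename(pigment_diff_charges, q = "dq")

  env_energy <- function(env) {
    # electrostatic: sum_a sum_k dq_a q_k / r_ak
    e_stat <- if (nrow(env) == 0) 0 else {
      transition_charge_coupling(dq, env[, c("x", "y", "z", "q")])
    }
    e_pol <- 0
    if (polarizable && "alpha" %in% names(env) && any(env$alpha > 0)) {
      pol <- env[env$alpha > 0, c("x", "y", "z", "alpha")]
      mu <- solve_induced_dipoles(pol, dq)
      Edq <- charge_field(dq, pol)
      e_pol <- -0.5 * CM1_PER_E2_ANG * sum(mu * Edq)
    }
    e_stat + e_pol
  }

  full <- env_energy(environment_residues)
  residues <- unique(environment_residues$residue)
  shifts <- vapply(residues, function(r) {
    if (polarizable) {
      off <- environment_residues[environment_residues$residue != r, ]
      full - env_energy(off)
    } else {
      env_energy(environment_residues[environment_residues$residue == r, ])
    }
  }, numeric(1))
  out <- tibble::tibble(residue = residues, delta_eps = unname(shifts))
  attr(out, "total") <- full
  out
}
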