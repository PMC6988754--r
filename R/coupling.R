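# Internal: point-dipole coupling from raw vectors (mu in D, r in A).
pd_coupling_vec <- function(mu1, mu2, rvec) {
  r <- sqrt(sum(rvec^2))
  if (r == 0) stop("zero distance between pigment centers", call. = FALSE)
  kap <- orientation_factor(mu1, mu2, rvec)
  m1 <- sqrt(sum(mu1^2))
  m2 <- sqrt(sum(mu2^2))
  CM1_PER_D2_ANG3 * kap * m1 * m2 / r^3
}

# Internal: coerce a site argument (one-row frame tibble / named list)
# to list(mu, pos).
as_site <- function(site) {
  if (is.data.frame(site)) {
    stopifnot(nrow(site) == 1)
    site <- as.list(site)
  }
  list(
    mu = c(site$mux, site$muy, site$muz),
    pos = c(site$x, site$y, site$z)
  )
}

#' Point-dipole excitonic coupling
#'
#' Forster-style estimate
#' `V = C * kappa * |mu_i| * |mu_j| / r^3` with
#' `C = 5034.12 cm^-1 D^-2 A^3`, dipoles in Debye and the center-center
#' distance in Angstrom. Symmetric under exchanging the two sites.
#'
#' @param site_i,site_j One-row pigment frame tibbles (or named lists
#'   with `x, y, z, mux, muy, muz`).
#' @return Coupling in cm^-1.
#' @examples
#' ring <- build_ideal_ring()
#' point_dipole_coupling(ring[1, ], ring[2, ])
#' @export
point_dipole_coupling <- function(site_i, site_j) {
  a <- as_site(site_i)
  b <- as_site(site_j)
  pd_coupling_vec(a$mu, b$mu, b$pos - a$pos)
}

#' Two-point transition charges for a pigment
#'
#' The minimal classical stand-in for a transition density: a +q/-q pair
#' along the transition-dipole axis, with `q = |mu| / separation`
#' (converted from Debye), so the pair reproduces the site's transition
#' dipole exactly.
#'
#' @param site One-row pigment frame tibble.
#' @param separation Charge separation along the dipole axis, Angstrom.
#' @return A tibble `(x, y, z, q)` with charges in units of e.
#' @examples
#' transition_charges(build_ideal_ring()[1, ])
#' @export
transition_charges <- function(site, separation = 0.87) {
  s <- as_site(site)
  m <- sqrt(sum(s$mu^2))
  if (m <= 0) stop("site has zero transition dipole", call. = FALSE)
  muh <- s$mu / m
  q <- m * DEBYE_E_ANG / separation
  tibble::tibble(
    x = s$pos[1] + c(-0.5, 0.5) * separation * muh[1],
    y = s$pos[2] + c(-0.5, 0.5) * separation * muh[2],
    z = s$pos[3] + c(-0.5, 0.5) * separation * muh[3],
    q = c(-q, q)
  )
}

#' Coulomb coupling between two transition-charge sets
#'
#' The bare Coulomb interaction `sum_ab q_a q_b / r_ab` between the
#' transition charges of two pigments, converted to cm^-1. Approaches
#' the point-dipole coupling in the far field and is symmetric under
#' exchanging the two sets.
#'
#' @param tq_i,tq_j Tibbles `(x, y, z, q)` (charges in e, positions in
#'   Angstrom) belonging to distinct pigments.
#' @return Coupling in cm^-1.
#' @examples
#' ring <- build_ideal_ring()
#' transition_charge_coupling(
#'   transition_charges(ring[1, ]),
#'   transition_charges(ring[2, ])
#' )
#' @export
transition_charge_coupling <- function(tq_i, tq_j) {
  pi_ <- as.matrix(tq_i[, c("x", "y", "z")])
  pj_ <- as.matrix(tq_j[, c("x", "y", "z")])
  d2 <- outer(rowSums(pi_^2), rowSums(pj_^2), `+`) - 2 * pi_ %*% t(pj_)
  d <- sqrt(pmax(d2, 0))
  if (any(d < 1e-9)) {
    stop("coincident positions across the two charge sets", call. = FALSE)
  }
  CM1_PER_E2_ANG * sum(outer(tq_i$q, tq_j$q) / d)
}

# Internal: electric field of point charges at given points, e / A^2.
charge_field <- function(charges, points) {
  pts <- as.matrix(points[, c("x", "y", "z")])
  src <- as.matrix(charges[, c("x", "y", "z")])
  q <- charges$q
  E <- matrix(0, nrow = nrow(pts), ncol = 3)
  for (a in seq_along(q)) {
    dv <- sweep(pts, 2, src[a, ])
    r3 <- rowSums(dv^2)^1.5
    if (any(r3 < 1e-18)) {
      stop("field requested at a source-charge position", call. = FALSE)
    }
    E <- E + q[a] * dv / r3
  }
  E
}

# Internal: field at points from point dipoles mu (e*A) at dip_pos.
dipole_field <- function(mu, dip_pos, points, alphas = NULL, thole_a = NULL) {
  E <- matrix(0, nrow = nrow(points), ncol = 3)
  for (k in seq_len(nrow(dip_pos))) {
    dv <- sweep(points, 2, dip_pos[k, ])
    r2 <- rowSums(dv^2)
    ok <- r2 > 1e-18
    if (!any(ok)) next
    r <- sqrt(r2[ok])
    rh <- dv[ok, , drop = FALSE] / r
    mdotr <- drop(rh %*% mu[k, ])
    l3 <- 1
    l5 <- 1
    if (!is.null(thole_a)) {
      s <- (alphas[k] * alphas)^(1 / 6)
      u <- r / s[ok]
      e <- exp(-thole_a * u^3)
      l3 <- 1 - e
      l5 <- 1 - (1 + thole_a * u^3) * e
    }
    E[ok, ] <- E[ok, ] +
      (3 * l5 * mdotr * rh - l3 * matrix(mu[k, ], nrow = sum(ok), ncol = 3, byrow = TRUE)) / r^3
  }
  E
}

#' Self-consistent induced point dipoles
#'
#' Solves the mutual-polarization fixed point
#' `mu_k = alpha_k * (E_sources(r_k) + sum_{l != k} E_dipole(mu_l, r_k))`
#' for a set of isotropic polarizable sites in the field of source
#' charges, by damped Jacobi iteration (successive over-relaxation).
#' Optionally applies exponential Thole-style short-range damping to the
#' dipole-dipole tensor for numerical stability with closely spaced
#' synthetic sites.
#'
#' @param pol_sites Tibble `(x, y, z, alpha)` with polarizabilities in
#'   Angstrom^3 (an optional `q` column of static charges is ignored by
#'   the solver itself).
#' @param field_sources Tibble `(x, y, z, q)` of source charges, e.
#' @param tol Convergence threshold on the largest dipole change, Debye.
#' @param max_iter Iteration cap.
#' @param omega Over-relaxation factor in (0, 1].
#' @param thole Logical; apply Thole damping.
#' @param thole_a Damping strength when `thole = TRUE`.
#' @return An n x 3 matrix of induced dipoles in e * Angstrom, with the
#'   iteration count in attribute `iterations`.
#' @examples
#' pol <- tibble::tibble(x = 0, y = 0, z = 0, alpha = 1.5)
#' src <- tibble::tibble(x = 5, y = 0, z = 0, q = 1)
#' solve_induced_dipoles(pol, src) # a single site: mu = alpha * E
#' @export
solve_induced_dipoles <- function(pol_sites, field_sources,
                                  tol = 1e-8, max_iter = 500, omega = 0.7,
                                  thole = FALSE, thole_a = 0.39) {
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)
  if (any(pol_sites$alpha < 0)) stop("polarizabilities must be >= 0", call. = FALSE)
  pos <- as.matrix(pol_sites[, c("x", "y", "z")])
  alpha <- pol_sites$alpha
  n <- nrow(pos)
  E0 <- charge_field(field_sources, pol_sites)
  mu <- alpha * E0 # first-order start
  ta <- if (thole) thole_a else NULL
  last_res <- Inf
  for (it in seq_len(max_iter)) {
    Eind <- dipole_field(mu, pos, pos, alphas = alpha, thole_a = ta)
    mu_new <- (1 - omega) * mu + omega * alpha * (E0 + Eind)
    res <- max(abs(mu_new - mu)) / DEBYE_E_ANG
    if (!is.finite(res) || res > 1e6) {
      stop("induced-dipole iteration diverged (singular response?); residual = ",
        format(res),
        call. = FALSE
      )
    }
    mu <- mu_new
    last_res <- res
    if (res < tol) {
      attr(mu, "iterations") <- it
      return(mu)
    }
  }
  stop("induced-dipole solver did not converge in ", max_iter,
    " iterations; last residual = ", format(last_res), " D",
    call. = FALSE
  )
}

#' Polarizable-environment screening term of a coupling
#'
#' The environment contribution to an excitonic coupling: the dipoles
#' induced in the polarizable sites by the transition of pigment j
#' interact with the transition field of pigment i,
#' `v_env = - sum_k mu_ind_k(tq_j) . E_i(r_k)` (the negative sign is the
#' interaction energy of a dipole in a field; with a polarizable medium
#' between two pigments it opposes the bare Coulomb term, i.e. screens
#' it). Reciprocity (i <-> j symmetry) holds through the symmetric
#' linear response and is verified numerically rather than assumed.
#'
#' @param tq_i,tq_j Transition-charge tibbles of the two pigments.
#' @param pol_sites Polarizable sites `(x, y, z, alpha)`.
#' @param ... Passed to [solve_induced_dipoles()].
#' @return Screening contribution in cm^-1 (0 for an empty environment).
#' @export
environment_screening <- function(tq_i, tq_j, pol_sites, ...) {
  if (is.null(pol_sites) || nrow(pol_sites) == 0) {
    return(0)
  }
  mu <- solve_induced_dipoles(pol_sites, tq_j, ...)
  Ei <- charge_field(tq_i, pol_sites)
  -CM1_PER_E2_ANG * sum(mu * Ei)
}

#' Pairwise couplings of a frame
#'
#' Batch driver: computes the Coulomb coupling for every pigment pair
#' of a frame within a center-center distance cutoff, by the
#' point-dipole or the transition-charge route, optionally adding the
#' polarizable-environment screening term, and classifies each pair as
#' `intra_chain`, `inter_chain` or `other`. Records are ordered by
#' `(i, j)`.
#'
#' @param frame A pigment frame tibble.
#' @param method `"point_dipole"` or `"transition_charge"`.
#' @param pol_sites Optional polarizable environment `(x, y, z, alpha)`.
#' @param cutoff Distance cutoff, Angstrom.
#' @param separation Charge separation for the transition-charge route.
#' @return A tibble `(i, j, class, distance, v_coul, v_env, v_total)`,
#'   energies in cm^-1.
#' @examples
#' couple_frame(build_ideal_ring()) |> dplyr::filter(class != "other")
#' @export
couple_frame <- function(frame,
                         method = c("point_dipole", "transition_charge"),
                         pol_sites = NULL,
                         cutoff = 25,
                         separation = 0.87) {
  method <- match.arg(method)
  validate_frame(frame)
  pairs <- classify_pairs(frame)
  pos <- as.matrix(frame[, c("x", "y", "z")])
  mu <- as.matrix(frame[, c("mux", "muy", "muz")])
  ii <- match(pairs$i, frame$site_id)
  jj <- match(pairs$j, frame$site_id)
  dvec <- pos[jj, , drop = FALSE] - pos[ii, , drop = FALSE]
  dist <- sqrt(rowSums(dvec^2))
  keep <- dist <= cutoff
  pairs <- pairs[keep, ]
  if (nrow(pairs) == 0) {
    return(tibble::tibble(
      i = integer(), j = integer(), class = character(),
      distance = numeric(), v_coul = numeric(), v_env = numeric(),
      v_total = numeric()
    ))
  }
  ii <- ii[keep]
  jj <- jj[keep]
  dvec <- dvec[keep, , drop = FALSE]
  dist <- dist[keep]

  tq <- NULL
  if (method == "transition_charge" || !is.null(pol_sites)) {
    tq <- lapply(
      seq_len(nrow(frame)),
      function(s) transition_charges(frame[s, ], separation)
    )
  }
  v_coul <- vapply(seq_len(nrow(pairs)), function(p) {
    if (method == "point_dipole") {
      pd_coupling_vec(mu[ii[p], ], mu[jj[p], ], dvec[p, ])
    } else {
      transition_charge_coupling(tq[[ii[p]]], tq[[jj[p]]])
    }
  }, numeric(1))
  v_env <- rep(0, nrow(pairs))
  if (!is.null(pol_sites) && nrow(pol_sites) > 0) {
    v_env <- vapply(seq_len(nrow(pairs)), function(p) {
      environment_screening(tq[[ii[p]]], tq[[jj[p]]], pol_sites)
    }, numeric(1))
  }
  pairs |>
    dplyr::mutate(
      distance = dist, v_coul = v_coul, v_env = v_env,
      v_total = v_coul + v_env
    ) |>
    dplyr::arrange(.data$i, .data$j)
}
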