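#' Assemble a Frenkel (LE + CT) exciton Hamiltonian
#'
#' Builds the block Hamiltonian of the coupled pigment system: the
#' locally-excited (LE) block carries the site energies on the diagonal
#' and the excitonic couplings off-diagonal; an optional charge-transfer
#' manifold adds CT diagonal energies (already containing their
#' alignment shift) and LE-CT couplings. CT-CT couplings are zero by
#' construction, matching the block structure of the model.
#'
#' Basis order is fixed: B850 sites unit-major (alpha before beta),
#' then B800 sites, then CT states.
#'
#' @param frame A pigment frame tibble (site energies and transition
#'   dipoles).
#' @param couplings Tibble with columns `i`, `j` and `v_total` (or `v`),
#'   cm^-1, e.g. from [couple_frame()].
#' @param ct_manifold Optional [make_ct_manifold()] object.
#' @return An object of class `exciton_hamiltonian`: list with the
#'   symmetric `matrix` (cm^-1), the `basis` tibble, the LE site
#'   `dipoles` (n_le x 3, Debye), `n_le` and `n_ct`.
#' @examples
#' ring <- build_ideal_ring()
#' h <- assemble_hamiltonian(ring, couple_frame(ring))
#' @export
assemble_hamiltonian <- function(frame, couplings, ct_manifold = NULL) {
  validate_frame(frame)
  vcol <- if ("v_total" %in% names(couplings)) "v_total" else "v"
  if (!all(c("i", "j", vcol) %in% names(couplings))) {
    stop("`couplings` needs columns i, j and v_total (or v)", call. = FALSE)
  }

  ordered <- dplyr::bind_rows(
    b850_ring(frame),
    dplyr::filter(frame, .data$role == "b800") |> dplyr::arrange(.data$unit)
  )
  n_le <- nrow(ordered)
  basis <- tibble::tibble(
    index = seq_len(n_le),
    type = "le",
    site_id = ordered$site_id,
    unit = ordered$unit,
    role = ordered$role,
    donor = NA_integer_,
    acceptor = NA_integer_,
    label = paste0("LE_", ordered$role, "_u", ordered$unit)
  )

  n_ct <- if (is.null(ct_manifold)) 0L else nrow(ct_manifold$states)
  n <- n_le + n_ct
  H <- matrix(0, n, n)
  diag(H)[seq_len(n_le)] <- ordered$site_energy

  le_of <- stats::setNames(seq_len(n_le), basis$site_id)
  bad <- !(couplings$i %in% basis$site_id) | !(couplings$j %in% basis$site_id)
  if (any(bad)) {
    stop("couplings reference unknown site id(s): ",
      paste(unique(c(couplings$i[bad], couplings$j[bad])), collapse = ", "),
      call. = FALSE
    )
  }
  ii <- le_of[as.character(couplings$i)]
  jj <- le_of[as.character(couplings$j)]
  if (any(ii == jj)) stop("self-couplings are not allowed", call. = FALSE)
  H[cbind(ii, jj)] <- couplings[[vcol]]
  H[cbind(jj, ii)] <- couplings[[vcol]]

  if (n_ct > 0) {
    st <- ct_manifold$states
    ct_idx <- n_le + seq_len(n_ct)
    diag(H)[ct_idx] <- st$energy
    u_of <- stats::setNames(ordered$unit, ordered$site_id)
    basis <- dplyr::bind_rows(basis, tibble::tibble(
      index = ct_idx,
      type = "ct",
      site_id = NA_integer_,
      unit = unname(u_of[as.character(st$donor)]),
      role = NA_character_,
      donor = st$donor,
      acceptor = st$acceptor,
      label = paste0("CT_", st$donor, "to", st$acceptor)
    ))
    cp <- ct_manifold$couplings
    if (!all(cp$site_id %in% basis$site_id[seq_len(n_le)])) {
      stop("CT couplings reference unknown LE site id(s)", call. = FALSE)
    }
    ri <- le_of[as.character(cp$site_id)]
    ci <- n_le + cp$ct_index
    H[cbind(ri, ci)] <- cp$v
    H[cbind(ci, ri)] <- cp$v
  }

  structure(
    list(
      matrix = H, basis = basis,
      dipoles = as.matrix(ordered[, c("mux", "muy", "muz")]),
      site_energies = ordered$site_energy,
      n_le = n_le, n_ct = n_ct,
      n_units = frame_n_units(frame)
    ),
    class = "exciton_hamiltonian"
  )
}

#' @export
print.exciton_hamiltonian <- function(x, ...) {
  cat("<exciton_hamiltonian> ", x$n_le, " LE + ", x$n_ct, " CT states\n", sep = "")
  d <- diag(x$matrix)[seq_len(x$n_le)]
  cat("  LE diagonal (cm^-1): ",
    paste(round(range(d), 1), collapse = " .. "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Nearest-neighbour B850 ring Hamiltonian from tabulated parameters
#'
#' Convenience constructor for the 18-site nearest-neighbour model of
#' the B850 ring: alternating alpha/beta site energies and alternating
#' intra-chain (`v2`) / inter-chain (`v1`) couplings on an ideal
#' C9-symmetric geometry (used for the transition dipoles). Pass a
#' complex name to take all four parameters from
#' [lh2_site_parameters()].
#'
#' @param complex `"HL"`, `"LL"` or `"PucD"`; when given, overrides the
#'   four numeric parameters.
#' @param eps_alpha,eps_beta Site energies, cm^-1.
#' @param v1,v2 Inter-chain and intra-chain nearest-neighbour couplings,
#'   cm^-1.
#' @param n_units Number of protomer units.
#' @param ct_manifold Optional CT manifold.
#' @return An `exciton_hamiltonian` over the 18 LE sites (+ CT).
#' @examples
#' h <- build_nn_ring_hamiltonian("HL")
#' @export
build_nn_ring_hamiltonian <- function(complex = NULL,
                                      eps_alpha = 13527, eps_beta = 13556,
                                      v1 = 266, v2 = 298,
                                      n_units = 9,
                                      ct_manifold = NULL) {
  if (!is.null(complex)) {
    p <- complex_parameters(complex)
    eps_alpha <- p$eps[["alpha"]]
    eps_beta <- p$eps[["beta"]]
    v1 <- p$v1
    v2 <- p$v2
  }
  frame <- build_ideal_ring(
    n_units = n_units,
    site_energies = c(alpha = eps_alpha, beta = eps_beta, b800 = 0),
    include_b800 = FALSE
  )
  assemble_hamiltonian(frame, nn_couplings(frame, v1 = v1, v2 = v2),
    ct_manifold = ct_manifold
  )
}

#' Nearest-neighbour coupling records for a ring frame
#'
#' Builds the coupling table containing only the two nearest-neighbour
#' B850 classes, with fixed values `v1` (inter-chain) and `v2`
#' (intra-chain).
#'
#' @param frame A pigment frame tibble.
#' @param v1,v2 Couplings in cm^-1.
#' @return A tibble `(i, j, class, v_total)`.
#' @export
nn_couplings <- function(frame, v1, v2) {
  classify_pairs(frame) |>
    dplyr::filter(.data$class != "other") |>
    dplyr::mutate(v_total = ifelse(.data$class == "intra_chain", v2, v1))
}

# Internal: permutation vector sending every basis element to its image
# under the elementary ring rotation (unit u -> u + 1).
rotation_permutation <- function(basis, n_units) {
  le <- basis[basis$type == "le", ]
  site_map <- stats::setNames(integer(nrow(le)), le$site_id)
  for (r in seq_len(nrow(le))) {
    tgt <- which(le$role == le$role[r] & le$unit == (le$unit[r] + 1L) %% n_units)
    site_map[as.character(le$site_id[r])] <- le$site_id[tgt]
  }
  p <- integer(nrow(basis))
  for (r in seq_len(nrow(basis))) {
    if (basis$type[r] == "le") {
      tgt <- which(basis$type == "le" &
        basis$site_id == site_map[as.character(basis$site_id[r])])
    } else {
      d2 <- site_map[as.character(basis$donor[r])]
      a2 <- site_map[as.character(basis$acceptor[r])]
      tgt <- which(basis$type == "ct" & basis$donor == d2 & basis$acceptor == a2)
    }
    if (length(tgt) != 1) {
      stop("basis is not closed under the ring rotation", call. = FALSE)
    }
    p[r] <- tgt
  }
  p
}

#' Symmetry-averaged exciton Hamiltonian
#'
#' Averages a set of per-frame Hamiltonians over the frames and over
#' all C_n symmetry-equivalent matrix elements, producing the
#' Hamiltonian of the (average) perfectly homogeneous ring. With static
#' disorder this is the canonical object on which the exciton width is
#' defined: disorder removes the ring quantum numbers per frame, but the
#' symmetry-averaged matrix commutes exactly with the ring rotation, so
#' its states are again labelled by k.
#'
#' @param hamiltonians A single `exciton_hamiltonian` or a list of them
#'   sharing the same basis.
#' @param n_units Ring symmetry order; defaults to the value stored in
#'   the Hamiltonians.
#' @return An `exciton_hamiltonian` that commutes with the C_n rotation
#'   permutation.
#' @examples
#' h <- build_nn_ring_hamiltonian("HL")
#' havg <- symmetry_average(h) # already symmetric: unchanged
#' @export
symmetry_average <- function(hamiltonians, n_units = NULL) {
  if (inherits(hamiltonians, "exciton_hamiltonian")) {
    hamiltonians <- list(hamiltonians)
  }
  h1 <- hamiltonians[[1]]
  if (is.null(n_units)) n_units <- h1$n_units
  labels <- h1$basis$label
  for (h in hamiltonians) {
    if (!identical(h$basis$label, labels)) {
      stop("all Hamiltonians must share the same basis", call. = FALSE)
    }
  }
  if ((h1$n_le %% n_units) != 0) {
    stop("`n_units` must divide the number of LE sites", call. = FALSE)
  }

  M <- Reduce(`+`, lapply(hamiltonians, function(h) h$matrix)) /
    length(hamiltonians)
  p <- rotation_permutation(h1$basis, n_units)
  acc <- M
  cur <- M
  n <- nrow(M)
  for (g in seq_len(n_units - 1)) {
    nxt <- matrix(0, n, n)
    nxt[p, p] <- cur
    cur <- nxt
    acc <- acc + cur
  }
  out <- h1
  out$matrix <- acc / n_units
  out$site_energies <- diag(out$matrix)[seq_len(out$n_le)]
  out
}

#' Diagonalize an exciton Hamiltonian
#'
#' Computes eigen-energies (ascending), orthonormal coefficients, state
#' transition dipoles `mu_state = sum_i c_i mu_i` (CT basis functions
#' carry zero dipole) and dipole strengths `|mu_state|^2`. Each state is
#' assigned a band by its dominant basis weight: `b850`, `b800` or
#' `ct`.
#'
#' @param h An `exciton_hamiltonian`.
#' @return An object of class `exciton_states`: list with `energies`
#'   (cm^-1), `coefficients` (columns = states), `state_dipoles`
#'   (Debye), `dipole_strengths` (D^2), `band`, `k` (NA until
#'   [assign_k()]), plus the basis and site dipoles.
#' @examples
#' st <- diagonalize_hamiltonian(build_nn_ring_hamiltonian("HL"))
#' range(st$energies)
#' @export
diagonalize_hamiltonian <- function(h) {
  stopifnot(inherits(h, "exciton_hamiltonian"))
  if (max(abs(h$matrix - t(h$matrix))) > 1e-9) {
    stop("Hamiltonian matrix is not symmetric", call. = FALSE)
  }
  e <- eigen((h$matrix + t(h$matrix)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  energies <- e$values[ord]
  C <- e$vectors[, ord, drop = FALSE]

  le_rows <- seq_len(h$n_le)
  state_dipoles <- t(C[le_rows, , drop = FALSE]) %*% h$dipoles
  strengths <- rowSums(state_dipoles^2)

  w_ct <- if (h$n_ct > 0) colSums(C[-le_rows, , drop = FALSE]^2) else rep(0, ncol(C))
  b800_rows <- which(h$basis$role == "b800")
  w_b800 <- if (length(b800_rows) > 0) {
    colSums(C[b800_rows, , drop = FALSE]^2)
  } else {
    rep(0, ncol(C))
  }
  band <- ifelse(w_ct > 0.5, "ct", ifelse(w_b800 > 0.5, "b800", "b850"))

  structure(
    list(
      energies = energies,
      coefficients = C,
      state_dipoles = state_dipoles,
      dipole_strengths = strengths,
      band = band,
      k = rep(NA_integer_, length(energies)),
      basis = h$basis,
      dipoles = h$dipoles,
      site_energies = h$site_energies,
      n_le = h$n_le, n_ct = h$n_ct, n_units = h$n_units
    ),
    class = "exciton_states"
  )
}

#' @export
print.exciton_states <- function(x, ...) {
  cat("<exciton_states> ", length(x$energies), " states (",
    x$n_le, " LE + ", x$n_ct, " CT basis)\n",
    sep = ""
  )
  cat("  energies (cm^-1): ",
    paste(round(range(x$energies), 1), collapse = " .. "), "\n",
    sep = ""
  )
  if (!all(is.na(x$k))) {
    cat("  k assigned; exciton width: ", round(exciton_width(x), 1),
      " cm^-1\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Assign ring quantum numbers k to exciton states
#'
#' Labels each state by the B850 ring Fourier mode carrying the largest
#' share of its coefficient power. For a 2n-site ring the labels run
#' over `-(n-1) .. n` (k = -8 .. 9 for the nonameric ring); the +/-k
#' members of a degenerate pair receive opposite signs. A state whose
#' best +/-k mode pair holds less than half of its total power (strong
#' disorder, or B800/CT-dominated states) keeps `NA`.
#'
#' The quantum number is measured in the gauge where neighbouring
#' transition dipoles are phase-aligned: when adjacent ring dipoles are
#' antiparallel (the head-to-tail alternation of the alpha/beta
#' pigments) the coefficient pattern is de-alternated before the
#' Fourier analysis. With positive nearest-neighbour couplings this
#' places the dark k = 0 singlet at the bottom of the manifold, the
#' optically active k = +/-1 pair just above it and the weakly allowed
#' k = +/-8 pair at the top, matching the standard ring-aggregate
#' convention.
#'
#' @param states An `exciton_states` object whose basis contains the
#'   B850 ring.
#' @param min_power Power threshold below which the label is undefined.
#' @return The `exciton_states` object with `k` filled in.
#' @examples
#' st <- assign_k(diagonalize_hamiltonian(build_nn_ring_hamiltonian("HL")))
#' table(abs(st$k))
#' @export
assign_k <- function(states, min_power = 0.5) {
  stopifnot(inherits(states, "exciton_states"))
  ring_rows <- which(states$basis$type == "le" &
    states$basis$role %in% c("alpha", "beta"))
  n_ring <- length(ring_rows)
  if (n_ring < 2) stop("basis contains no B850 ring", call. = FALSE)
  s <- seq_len(n_ring) - 1
  modes <- seq_len(n_ring) - 1 # 0 .. 2n-1
  Fm <- exp(-2i * pi * outer(modes, s) / n_ring) / sqrt(n_ring)

  # Forster-phase gauge: de-alternate the coefficients when adjacent
  # ring dipoles point head-to-head (mean neighbour dot product < 0).
  mu_ring <- states$dipoles[seq_len(n_ring), , drop = FALSE]
  nn_dot <- sum(mu_ring * mu_ring[c(2:n_ring, 1), ])
  gauge <- if (nn_dot < 0) (-1)^s else rep(1, n_ring)

  n_states <- length(states$energies)
  kk <- rep(NA_integer_, n_states)
  for (t in seq_len(n_states)) {
    c_ring <- gauge * states$coefficients[ring_rows, t]
    pw <- Mod(Fm %*% c_ring)^2 # power per mode, sums to |c_ring|^2
    # combine +k and -k (mode m and 2n - m)
    half <- n_ring / 2
    cand <- 0:half
    tot <- vapply(cand, function(k) {
      if (k == 0 || k == half) pw[k + 1] else pw[k + 1] + pw[n_ring - k + 1]
    }, numeric(1))
    best <- cand[which.max(tot)]
    if (max(tot) >= min_power) kk[t] <- best
  }
  # sign the degenerate pairs: first member +k, partner -k
  for (k in setdiff(unique(kk[!is.na(kk)]), c(0L, as.integer(n_ring / 2)))) {
    idx <- which(kk == k)
    if (length(idx) == 2) kk[idx[2]] <- -k
  }
  states$k <- kk
  states
}

#' Exciton width of the B850 ring
#'
#' The energy difference between the k = +/-8 and the k = +/-1 exciton
#' pairs of the 18-meric ring (pair means; for the symmetric ring the
#' pair members are exactly degenerate, so only disorder handling
#' distinguishes the conventions).
#'
#' @param states An `exciton_states` object with k labels assigned (see
#'   [assign_k()]).
#' @return Width in cm^-1.
#' @examples
#' st <- assign_k(diagonalize_hamiltonian(build_nn_ring_hamiltonian("HL")))
#' exciton_width(st)
#' @export
exciton_width <- function(states) {
  stopifnot(inherits(states, "exciton_states"))
  n_ring <- sum(states$basis$type == "le" &
    states$basis$role %in% c("alpha", "beta"))
  k_top <- as.integer(n_ring / 2) - 1L # 8 for the 18-ring
  e1 <- states$energies[!is.na(states$k) & abs(states$k) == 1L]
  e8 <- states$energies[!is.na(states$k) & abs(states$k) == k_top]
  if (length(e1) == 0 || length(e8) == 0) {
    stop("k = +/-1 and k = +/-", k_top,
      " labels are required; run assign_k() (disorder too strong?)",
      call. = FALSE
    )
  }
  mean(e8) - mean(e1)
}

#' Bright/dark census of exciton states
#'
#' Counts optically bright states (dipole strength above a relative
#' threshold), dark states, exactly degenerate pairs (within an energy
#' tolerance) and non-degenerate singlets. For the perfectly symmetric
#' 18-ring with in-plane near-tangential dipoles the selection rules
#' leave only the k = +/-1 and k = +/-8 pairs bright: 4 bright and 14
#' dark states, organised as 8 degenerate pairs plus 2 singlets.
#'
#' @param states An `exciton_states` object.
#' @param threshold_rel Bright threshold relative to the maximum dipole
#'   strength.
#' @param degeneracy_tol Energy tolerance (cm^-1) for pair counting.
#' @return A list with `n_bright`, `n_dark`, `n_degenerate_pairs`,
#'   `n_singlets` and the logical `bright` vector.
#' @examples
#' st <- diagonalize_hamiltonian(build_nn_ring_hamiltonian("HL"))
#' bright_dark_census(st)
#' @export
bright_dark_census <- function(states, threshold_rel = 1e-6, degeneracy_tol = 1e-4) {
  stopifnot(inherits(states, "exciton_states"))
  d <- states$dipole_strengths
  bright <- d > threshold_rel * max(d)
  e <- states$energies
  n <- length(e)
  pairs <- 0L
  used <- rep(FALSE, n)
  for (s in seq_len(n - 1)) {
    if (!used[s] && !used[s + 1] && abs(e[s + 1] - e[s]) <= degeneracy_tol) {
      pairs <- pairs + 1L
      used[s] <- used[s + 1] <- TRUE
    }
  }
  list(
    n_bright = sum(bright),
    n_dark = sum(!bright),
    n_degenerate_pairs = pairs,
    n_singlets = sum(!used),
    bright = bright
  )
}

#' CT-induced shifts of the exciton states
#'
#' Quantifies how the charge-transfer manifold reshapes the LE exciton
#' states: both Hamiltonians are diagonalized, each LE-only state is
#' matched to the CT-including state of maximal eigenvector overlap on
#' the LE block (ties broken by energy proximity), and the exact shift
#' is reported next to the second-order perturbative estimate
#' `sum_m |sum_i c_i V_im|^2 / (E_s - eps_m)` (negative below the CT
#' manifold: CT coupling pushes the low excitons down).
#'
#' @param h_with_ct `exciton_hamiltonian` including the CT manifold.
#' @param h_without_ct The same LE block without CT states.
#' @return A tibble `(state, energy_le, energy_with_ct, shift,
#'   shift_pt2, overlap, ambiguous)`; `ambiguous` flags matches with
#'   overlap below 0.5.
#' @examples
#' ring <- build_ideal_ring(include_b800 = FALSE)
#' cpl <- nn_couplings(ring, v1 = 266, v2 = 298)
#' ct <- make_ct_manifold(ring, energy_mean = 16000, seed = 1)
#' ct_shift(
#'   assemble_hamiltonian(ring, cpl, ct),
#'   assemble_hamiltonian(ring, cpl)
#' )
#' @export
ct_shift <- function(h_with_ct, h_without_ct) {
  stopifnot(
    inherits(h_with_ct, "exciton_hamiltonian"),
    inherits(h_without_ct, "exciton_hamiltonian")
  )
  if (h_with_ct$n_le != h_without_ct$n_le ||
    !identical(
      h_with_ct$basis$label[seq_len(h_with_ct$n_le)],
      h_without_ct$basis$label[seq_len(h_without_ct$n_le)]
    )) {
    stop("the two Hamiltonians must share the LE basis", call. = FALSE)
  }
  s0 <- diagonalize_hamiltonian(h_without_ct)
  s1 <- diagonalize_hamiltonian(h_with_ct)
  n_le <- h_with_ct$n_le
  le_rows <- seq_len(n_le)

  V <- h_with_ct$matrix[le_rows, -le_rows, drop = FALSE]
  eps_ct <- diag(h_with_ct$matrix)[-le_rows]

  ov <- abs(t(s1$coefficients[le_rows, , drop = FALSE]) %*% s0$coefficients)
  out <- purrr::map(seq_len(n_le), function(s) {
    o <- ov[, s]
    best <- which(o == max(o))
    if (length(best) > 1) {
      best <- best[which.min(abs(s1$energies[best] - s0$energies[s]))]
    }
    v_eff <- drop(crossprod(s0$coefficients[, s], V))
    tibble::tibble(
      state = s,
      energy_le = s0$energies[s],
      energy_with_ct = s1$energies[best],
      shift = s1$energies[best] - s0$energies[s],
      shift_pt2 = sum(v_eff^2 / (s0$energies[s] - eps_ct)),
      overlap = max(o),
      ambiguous = max(o) < 0.5
    )
  })
  dplyr::bind_rows(out)
}
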