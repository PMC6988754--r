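# Independent analytic oracles used to check the numerical machinery.

# Bloch two-band dispersion of the alternating nearest-neighbour ring:
# unit cell (alpha, beta), eigenvalues ebar +/- sqrt(delta^2 + |v2 + v1 e^{i theta}|^2)
# at theta = 2 pi m / n_units. Returns all 2*n_units energies, ascending.
two_band_energies <- function(eps_a, eps_b, v1, v2, n_units = 9) {
  theta <- 2 * pi * (seq_len(n_units) - 1) / n_units
  ebar <- (eps_a + eps_b) / 2
  delta <- (eps_a - eps_b) / 2
  gap <- sqrt(delta^2 + v1^2 + v2^2 + 2 * v1 * v2 * cos(theta))
  sort(c(ebar - gap, ebar + gap))
}

# k = +/-1 energy and exciton width from the same closed form.
two_band_k1 <- function(eps_a, eps_b, v1, v2, n_units = 9) {
  theta1 <- 2 * pi / n_units
  (eps_a + eps_b) / 2 -
    sqrt(((eps_a - eps_b) / 2)^2 + v1^2 + v2^2 + 2 * v1 * v2 * cos(theta1))
}

two_band_width <- function(eps_a, eps_b, v1, v2, n_units = 9) {
  theta1 <- 2 * pi / n_units
  2 * sqrt(((eps_a - eps_b) / 2)^2 + v1^2 + v2^2 + 2 * v1 * v2 * cos(theta1))
}

# Rigid-body transform of a pigment frame (Rodrigues rotation + shift).
transform_frame <- function(frame, axis = c(0, 0, 1), angle_deg = 0,
                            translation = c(0, 0, 0)) {
  axis <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(
    0, -axis[3], axis[2],
    axis[3], 0, -axis[1],
    -axis[2], axis[1], 0
  ), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  pos <- as.matrix(frame[, c("x", "y", "z")]) %*% t(R)
  mu <- as.matrix(frame[, c("mux", "muy", "muz")]) %*% t(R)
  frame$x <- pos[, 1] + translation[1]
  frame$y <- pos[, 2] + translation[2]
  frame$z <- pos[, 3] + translation[3]
  frame$mux <- mu[, 1]
  frame$muy <- mu[, 2]
  frame$muz <- mu[, 3]
  frame
}

# Mean k = +/-1 energy of an exciton_states object.
ek1 <- function(states) {
  mean(states$energies[!is.na(states$k) & abs(states$k) == 1L])
}

# Build one 18-site nearest-neighbour Hamiltonian per ensemble frame.
per_frame_hamiltonians <- function(ensemble, v1, v2) {
  lapply(
    split(ensemble, ensemble$frame),
    function(fr) {
      fr <- dplyr::select(fr, -"frame")
      excitonring::assemble_hamiltonian(
        fr, excitonring::nn_couplings(fr, v1 = v1, v2 = v2)
      )
    }
  )
}
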