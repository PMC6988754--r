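#' Macrocycle center from the four nitrogen positions
#'
#' The effective center of a (bacterio)chlorin macrocycle, defined as
#' the arithmetic mean of the four pyrrole nitrogen positions.
#'
#' @param n_positions A 4 x 3 numeric matrix of nitrogen coordinates,
#'   Angstrom.
#' @return A length-3 numeric vector, Angstrom.
#' @examples
#' macrocycle_center(rbind(c(1, 1, 0), c(-1, 1, 0), c(-1, -1, 0), c(1, -1, 0)))
#' @export
macrocycle_center <- function(n_positions) {
  n_positions <- as.matrix(n_positions)
  if (!is.numeric(n_positions) || nrow(n_positions) != 4 || ncol(n_positions) != 3) {
    stop("`n_positions` must be a 4 x 3 numeric matrix", call. = FALSE)
  }
  colMeans(n_positions)
}

#' Orientation factor kappa of a pigment pair
#'
#' The Forster orientation factor
#' `kappa = mu1.mu2 - 3 (mu1.r)(mu2.r)` with all three vectors
#' normalised internally. Bounded by `[-2, 2]`, symmetric under swapping
#' the dipoles, and invariant to flipping the separation vector.
#'
#' @param mu1,mu2 Transition dipole vectors (any magnitude > 0).
#' @param r_vec Separation vector between the two centers (non-zero).
#' @return Dimensionless scalar in `[-2, 2]`.
#' @examples
#' orientation_factor(c(0, 0, 1), c(0, 0, 1), c(1, 0, 0)) # parallel, perp to r: 1
#' orientation_factor(c(1, 0, 0), c(1, 0, 0), c(1, 0, 0)) # collinear: -2
#' @export
orientation_factor <- function(mu1, mu2, r_vec) {
  nr <- sqrt(sum(r_vec^2))
  if (nr == 0) stop("zero separation between pigment centers", call. = FALSE)
  n1 <- sqrt(sum(mu1^2))
  n2 <- sqrt(sum(mu2^2))
  if (n1 == 0 || n2 == 0) stop("transition dipoles must be non-zero", call. = FALSE)
  m1 <- mu1 / n1
  m2 <- mu2 / n2
  rh <- r_vec / nr
  sum(m1 * m2) - 3 * sum(m1 * rh) * sum(m2 * rh)
}

#' Signed dihedral (torsion) angle of four points
#'
#' IUPAC convention: a planar cis arrangement gives 0 degrees, trans
#' gives 180 degrees, and the sign follows the right-hand rule about the
#' central bond. Values lie in `(-180, 180]`. Reversing the atom order
#' leaves the value unchanged; mirroring the structure negates it.
#'
#' @param p1,p2,p3,p4 Length-3 coordinate vectors, Angstrom.
#' @return Angle in degrees.
#' @examples
#' dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)) # cis: 0
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (sum(b1^2) == 0 || sum(b2^2) == 0 || sum(b3^2) == 0) {
    stop("consecutive points must not coincide", call. = FALSE)
  }
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) {
    stop("undefined torsion: three consecutive points are colinear", call. = FALSE)
  }
  b2h <- b2 / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2h)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Internal: 3-vector cross product.
cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

#' Heavy-atom hydrogen-bond distance
#'
#' Euclidean distance between the donor and acceptor heavy atoms
#' (e.g. the acetyl oxygen and a tyrosine OH or tryptophan NE1), the
#' standard proxy when hydrogen positions are not resolved.
#'
#' @param donor_heavy,acceptor_heavy Length-3 coordinate vectors,
#'   Angstrom.
#' @return Distance in Angstrom.
#' @examples
#' hbond_distance(c(0, 0, 0), c(3, 4, 0)) # 5
#' @export
hbond_distance <- function(donor_heavy, acceptor_heavy) {
  sqrt(sum((donor_heavy - acceptor_heavy)^2))
}

#' Classify B850 pigment pairs of a frame
#'
#' Enumerates all pigment pairs of a frame and labels the two
#' nearest-neighbour B850 classes: `intra_chain` (alpha and beta of the
#' same unit) and `inter_chain` (beta of unit u with alpha of unit u+1,
#' modulo the ring); every other pair is `other`.
#'
#' @param frame A pigment frame tibble.
#' @return A tibble with one row per unordered pair: `i`, `j` (site
#'   ids), `class`.
#' @examples
#' classify_pairs(build_ideal_ring()) |> dplyr::count(class)
#' @export
classify_pairs <- function(frame) {
  validate_frame(frame)
  n_units <- frame_n_units(frame)
  idx <- utils::combn(seq_len(nrow(frame)), 2)
  a <- frame[idx[1, ], c("site_id", "unit", "role")]
  b <- frame[idx[2, ], c("site_id", "unit", "role")]
  cls <- rep("other", ncol(idx))
  intra <- a$unit == b$unit &
    ((a$role == "alpha" & b$role == "beta") | (a$role == "beta" & b$role == "alpha"))
  inter <- (a$role == "beta" & b$role == "alpha" & b$unit == (a$unit + 1L) %% n_units) |
    (b$role == "beta" & a$role == "alpha" & a$unit == (b$unit + 1L) %% n_units)
  cls[intra] <- "intra_chain"
  cls[inter] <- "inter_chain"
  tibble::tibble(i = a$site_id, j = b$site_id, class = cls)
}

#' Pairwise distance and orientation-factor distributions over an ensemble
#'
#' For every frame of an ensemble and every symmetry-equivalent pigment
#' pair of the requested classes, computes the center-center distance
#' and the orientation factor kappa, together with per-class summary
#' statistics. This is the descriptor pair used to rationalise why the
#' inter-chain coupling collapses when the hydrogen bond tethering a
#' pigment to the neighbouring unit is lost: the distance distribution
#' barely moves while the kappa distribution broadens.
#'
#' @param ensemble Long tibble from [sample_ensemble()] (a single frame
#'   tibble is also accepted).
#' @param pair_classes Character vector of classes to keep, from
#'   `c("inter_chain", "intra_chain", "other")`.
#' @return A tibble `(frame, i, j, class, distance, kappa)` with a
#'   `summary` attribute holding per-class mean and SD of both
#'   descriptors.
#' @examples
#' ens <- sample_ensemble(build_ideal_ring(), disorder_model(), 3, seed = 1)
#' d <- descriptor_distributions(ens)
#' attr(d, "summary")
#' @export
descriptor_distributions <- function(ensemble,
                                     pair_classes = c("inter_chain", "intra_chain")) {
  known <- c("inter_chain", "intra_chain", "other")
  if (!all(pair_classes %in% known)) {
    stop("unknown pair class(es): ",
      paste(setdiff(pair_classes, known), collapse = ", "),
      call. = FALSE
    )
  }
  if (!"frame" %in% names(ensemble)) {
    ensemble <- dplyr::bind_cols(tibble::tibble(frame = 1L), ensemble)
  }
  if (nrow(ensemble) == 0) stop("ensemble is empty", call. = FALSE)

  frames <- dplyr::group_split(ensemble, .data$frame)
  pairs <- classify_pairs(dplyr::select(frames[[1]], -"frame")) |>
    dplyr::filter(.data$class %in% pair_classes)

  rows <- purrr::map(frames, function(fr) {
    pos <- as.matrix(fr[, c("x", "y", "z")])
    mu <- as.matrix(fr[, c("mux", "muy", "muz")])
    ii <- match(pairs$i, fr$site_id)
    jj <- match(pairs$j, fr$site_id)
    dvec <- pos[jj, , drop = FALSE] - pos[ii, , drop = FALSE]
    dist <- sqrt(rowSums(dvec^2))
    kap <- vapply(seq_len(nrow(pairs)), function(p) {
      orientation_factor(mu[ii[p], ], mu[jj[p], ], dvec[p, ])
    }, numeric(1))
    tibble::tibble(
      frame = fr$frame[1], i = pairs$i, j = pairs$j,
      class = pairs$class, distance = dist, kappa = kap
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "summary") <- out |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      n = dplyr::n(),
      distance_mean = mean(.data$distance),
      distance_sd = stats::sd(.data$distance),
      kappa_mean = mean(.data$kappa),
      kappa_sd = stats::sd(.data$kappa),
      .groups = "drop"
    )
  out
}

#' Histogram table of a descriptor column
#'
#' Fixed-width binning returning a plain table `(bin_left, bin_right,
#' count)`; counts sum to the number of observations.
#'
#' @param descriptors Tibble from [descriptor_distributions()].
#' @param var Column to bin (`"distance"` or `"kappa"`).
#' @param bins Number of bins.
#' @return A tibble `(class, bin_left, bin_right, count)`.
#' @examples
#' ens <- sample_ensemble(build_ideal_ring(),
#'   disorder_model(orient_jitter_deg = 5), 10, seed = 1)
#' descriptor_histogram(descriptor_distributions(ens), "kappa", bins = 10)
#' @export
descriptor_histogram <- function(descriptors, var = c("distance", "kappa"), bins = 20) {
  var <- match.arg(var)
  x <- descriptors[[var]]
  brk <- seq(min(x), max(x), length.out = bins + 1)
  brk[1] <- brk[1] - 1e-9
  descriptors |>
    dplyr::mutate(bin = cut(.data[[var]], breaks = brk, labels = FALSE)) |>
    dplyr::group_by(.data$class, .data$bin) |>
    dplyr::summarise(count = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(
      bin_left = brk[.data$bin],
      bin_right = brk[.data$bin + 1]
    ) |>
    dplyr::select("class", "bin_left", "bin_right", "count")
}
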