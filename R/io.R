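#' Write / read a pigment site table
#'
#' Plain tab-separated representation of a frame: one row per site with
#' columns `site_id`, `unit`, `role`, `x`, `y`, `z`, `mux`, `muy`,
#' `muz`, `site_energy`. Values are written with full precision, so the
#' round trip is exact.
#'
#' @param frame A pigment frame tibble.
#' @param path File path.
#' @return `write_site_table()` returns `path` invisibly;
#'   `read_site_table()` returns the frame tibble.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_site_table(build_ideal_ring(), f)
#' ring <- read_site_table(f)
#' @export
write_site_table <- function(frame, path) {
  validate_frame(frame)
  utils::write.table(format_columns(frame), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

# Internal: full-precision column-wise formatting for TSV output.
format_columns <- function(df, digits = 17) {
  as.data.frame(lapply(df, function(col) {
    if (is.double(col)) {
      format(col, digits = digits, scientific = FALSE, trim = TRUE)
    } else {
      col
    }
  }), check.names = FALSE)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  out <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  out$site_id <- as.integer(out$site_id)
  out$unit <- as.integer(out$unit)
  validate_frame(out)
  out
}

# Default residue / atom naming for synthetic ring PDB files.
ring_selection_rules <- function(residues = c(alpha = "BCA", beta = "BCB", b800 = "B80"),
                                 n_atoms = c("N1", "N2", "N3", "N4"),
                                 dipole_atoms = c("N1", "N3"),
                                 dipole_magnitude = NULL) {
  list(
    residues = residues, n_atoms = n_atoms,
    dipole_atoms = dipole_atoms, dipole_magnitude = dipole_magnitude
  )
}

#' Write a pigment frame as a PDB file
#'
#' Each pigment becomes one HETATM residue of four macrocycle-nitrogen
#' pseudo-atoms arranged so that their mean is the pigment center and
#' the `N1 -> N3` axis is the transition-dipole direction (the
#' N_B -> N_D convention of the real macrocycle). The dipole magnitude
#' (Debye) is stored in the occupancy column and the protomer unit index
#' in the B-factor column. Coordinates carry the standard 1e-3 Angstrom
#' PDB precision.
#'
#' @param frame A pigment frame tibble.
#' @param path Output path.
#' @param rules Naming rules from `ring_selection_rules()`.
#' @param arm Half-extent of the nitrogen pseudo-square, Angstrom.
#' @return `path`, invisibly.
#' @export
write_ring_pdb <- function(frame, path, rules = ring_selection_rules(), arm = 1.5) {
  validate_frame(frame)
  pos <- as.matrix(frame[, c("x", "y", "z")])
  mu <- as.matrix(frame[, c("mux", "muy", "muz")])
  mu_len <- sqrt(rowSums(mu^2))
  muh <- mu / mu_len
  # in-plane perpendicular; fall back to x for axial dipoles
  perp <- cbind(-muh[, 2], muh[, 1], 0)
  bad <- rowSums(perp^2) < 1e-12
  perp[bad, ] <- rep(c(1, 0, 0), each = sum(bad))
  perp <- perp / sqrt(rowSums(perp^2))

  n <- nrow(frame)
  xyz <- matrix(NA_real_, nrow = 4L * n, ncol = 3)
  xyz[seq(1, 4 * n, by = 4), ] <- pos - arm * muh
  xyz[seq(2, 4 * n, by = 4), ] <- pos - arm * perp
  xyz[seq(3, 4 * n, by = 4), ] <- pos + arm * muh
  xyz[seq(4, 4 * n, by = 4), ] <- pos + arm * perp

  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(xyz)),
    type = rep("HETATM", 4L * n),
    resno = rep(frame$site_id, each = 4L),
    resid = rep(unname(rules$residues[frame$role]), each = 4L),
    chain = rep("A", 4L * n),
    elety = rep(rules$n_atoms, times = n),
    o = rep(round(mu_len, 2), each = 4L),
    b = rep(frame$unit, each = 4L)
  )
  invisible(path)
}

#' Read a pigment structure from a PDB file
#'
#' Builds one pigment site per selected residue: the center is the mean
#' of the four macrocycle nitrogen positions and the dipole direction
#' runs between the two configured nitrogen atoms (`N1 -> N3` for
#' synthetic files; use e.g. `NB -> ND` for real bacteriochlorophyll
#' entries via `rules`). The dipole magnitude is taken from the
#' occupancy column when available, otherwise from
#' `rules$dipole_magnitude`.
#'
#' @param path PDB file path.
#' @param rules Selection rules from `ring_selection_rules()`:
#'   role-named residue names, the four nitrogen atom names, the two
#'   atoms defining the dipole axis, and an optional fixed dipole
#'   magnitude (Debye).
#' @param site_energies Optional named vector of site energies per role
#'   (cm^-1) to attach; defaults to the HL averages.
#' @return A pigment frame tibble.
#' @export
read_ring_pdb <- function(path, rules = ring_selection_rules(),
                          site_energies = c(alpha = 13527, beta = 13556, b800 = 13783)) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  keep <- at$resid %in% rules$residues
  if (!any(keep)) {
    stop("no pigment residues matching ",
      paste(rules$residues, collapse = "/"), " found in ", path,
      call. = FALSE
    )
  }
  at <- at[keep, ]
  role_of <- stats::setNames(names(rules$residues), rules$residues)

  sites <- split(at, paste(at$chain, at$resno))
  rows <- lapply(sites, function(res) {
    nmask <- res$elety %in% rules$n_atoms
    if (sum(nmask) != 4) {
      missing <- setdiff(rules$n_atoms, res$elety)
      stop("residue ", res$resid[1], " ", res$resno[1],
        " lacks macrocycle N atom(s): ", paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    nn <- res[nmask, ]
    center <- macrocycle_center(as.matrix(nn[, c("x", "y", "z")]))
    p1 <- nn[match(rules$dipole_atoms[1], nn$elety), c("x", "y", "z")]
    p2 <- nn[match(rules$dipole_atoms[2], nn$elety), c("x", "y", "z")]
    axis <- as.numeric(p2) - as.numeric(p1)
    axis <- axis / sqrt(sum(axis^2))
    mag <- rules$dipole_magnitude
    if (is.null(mag)) {
      occ <- suppressWarnings(as.numeric(res$o[1]))
      mag <- if (is.finite(occ) && occ > 0) occ else 6.3
    }
    role <- role_of[[res$resid[1]]]
    tibble::tibble(
      site_id = as.integer(res$resno[1]),
      unit = as.integer(round(suppressWarnings(as.numeric(res$b[1])))),
      role = role,
      x = center[1], y = center[2], z = center[3],
      mux = mag * axis[1], muy = mag * axis[2], muz = mag * axis[3],
      site_energy = unname(site_energies[role])
    )
  })
  out <- dplyr::bind_rows(rows) |> dplyr::arrange(.data$site_id)
  if (any(!is.finite(out$unit))) out$unit[!is.finite(out$unit)] <- 0L
  validate_frame(out)
  out
}

#' Write / read an ensemble manifest
#'
#' Records the generator parameters and the seed of a synthetic
#' ensemble as plain `key = value` lines so a run can be reproduced
#' bit-for-bit.
#'
#' @param params Named list of scalar parameters (numbers or strings).
#' @param path File path.
#' @return `write_ensemble_manifest()` returns `path` invisibly;
#'   `read_ensemble_manifest()` returns a named list (numeric where
#'   possible).
#' @examples
#' f <- tempfile(fileext = ".cfg")
#' write_ensemble_manifest(list(n_frames = 50, seed = 1, sigma_alpha = 276), f)
#' read_ensemble_manifest(f)
#' @export
write_ensemble_manifest <- function(params, path) {
  stopifnot(is.list(params), !is.null(names(params)))
  lines <- vapply(names(params), function(k) {
    v <- params[[k]]
    paste0(k, " = ", paste(format(v, digits = 17, trim = TRUE), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ensemble_manifest
#' @export
read_ensemble_manifest <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "\\s*=\\s*")
  out <- lapply(kv, function(p) {
    vals <- strsplit(p[2], ",")[[1]]
    num <- suppressWarnings(as.numeric(vals))
    if (any(is.na(num))) vals else num
  })
  stats::setNames(out, vapply(kv, `[[`, character(1), 1))
}

#' Write / read a dense Hamiltonian matrix
#'
#' Tab-separated dense matrix with a header line of basis labels.
#'
#' @param h An `exciton_hamiltonian`.
#' @param path File path.
#' @return `write_hamiltonian_matrix()` returns `path` invisibly;
#'   `read_hamiltonian_matrix()` returns a labelled numeric matrix.
#' @export
write_hamiltonian_matrix <- function(h, path) {
  stopifnot(inherits(h, "exciton_hamiltonian"))
  m <- h$matrix
  dimnames(m) <- list(h$basis$label, h$basis$label)
  utils::write.table(format(m, digits = 17, trim = TRUE), path,
    sep = "\t", quote = FALSE, col.names = NA
  )
  invisible(path)
}

#' @rdname write_hamiltonian_matrix
#' @export
read_hamiltonian_matrix <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  storage.mode(m) <- "double"
  m
}

#' Write a spectrum table
#'
#' Tab-separated `(wavenumber_cm1, wavelength_nm, intensity)`.
#'
#' @param spectrum A `spectrum_model`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.table(
    format_columns(spectrum[, c("wavenumber", "wavelength", "intensity")],
      digits = 12
    ),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Write a coupling table
#'
#' Tab-separated `(frame, i, j, class, v_coul, v_env, v_total)`.
#'
#' @param couplings Tibble from [couple_frame()] (optionally with a
#'   `frame` column).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_couplings <- function(couplings, path) {
  if (!"frame" %in% names(couplings)) {
    couplings <- dplyr::bind_cols(tibble::tibble(frame = 1L), couplings)
  }
  utils::write.table(format_columns(couplings, digits = 12), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
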