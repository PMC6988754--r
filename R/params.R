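#' Average excitonic parameters of the three LH2 complexes
#'
#' Returns the MD-averaged site energies of the three inequivalent
#' bacteriochlorophylls and the two largest couplings of the 18-meric
#' (B850-like) ring for the high-light (`HL`), low-light (`LL`) and
#' homology-modelled PucD (`PucD`) forms of LH2, together with the
#' standard deviations over 50 trajectory frames. `V1ab` couples the
#' alpha/beta pigments of adjacent protomer units (inter-chain), `V2ab`
#' those of the same unit (intra-chain).
#'
#' These values serve as default inputs for the nearest-neighbour ring
#' Hamiltonians ([build_nn_ring_hamiltonian()]) and for the disorder
#' widths of the synthetic ensemble generator ([disorder_model()]).
#'
#' @return A tibble with columns `complex`, `parameter` (one of
#'   `"alpha"`, `"beta"`, `"b800"`, `"V1ab"`, `"V2ab"`), `value` and `sd`,
#'   all energies in cm^-1.
#' @examples
#' lh2_site_parameters()
#' @export
lh2_site_parameters <- function() {
  tibble::tribble(
    ~complex, ~parameter, ~value, ~sd,
    "HL",   "alpha", 13527, 276,
    "HL",   "beta",  13556, 279,
    "HL",   "b800",  13783, 326,
    "HL",   "V1ab",    266,  55,
    "HL",   "V2ab",    298,  35,
    "LL",   "alpha", 13639, 290,
    "LL",   "beta",  13693, 297,
    "LL",   "b800",  13735, 312,
    "LL",   "V1ab",    149,  89,
    "LL",   "V2ab",    281,  37,
    "PucD", "alpha", 13790, 266,
    "PucD", "beta",  13715, 286,
    "PucD", "b800",  13767, 328,
    "PucD", "V1ab",    127,  74,
    "PucD", "V2ab",    285,  35
  )
}

# Internal: fetch one complex's parameters as a named list.
complex_parameters <- function(complex = c("HL", "LL", "PucD")) {
  complex <- match.arg(complex)
  p <- dplyr::filter(lh2_site_parameters(), .data$complex == !!complex)
  list(
    eps = stats::setNames(p$value[match(PIGMENT_ROLES, p$parameter)], PIGMENT_ROLES),
    sigma = stats::setNames(p$sd[match(PIGMENT_ROLES, p$parameter)], PIGMENT_ROLES),
    v1 = p$value[p$parameter == "V1ab"],
    v2 = p$value[p$parameter == "V2ab"],
    v1_sd = p$sd[p$parameter == "V1ab"],
    v2_sd = p$sd[p$parameter == "V2ab"]
  )
}
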