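# Electrostatic unit conversions (CODATA 2018).
#
# e^2 / (4 pi eps0) = 14.399645 eV * Angstrom; 1 eV = 8065.543937 cm^-1.
# Hence two unit charges 1 Angstrom apart interact by 116140.97 cm^-1
# (and by one Hartree, 219474.63 cm^-1, at 1 bohr).
# 1 Debye = 0.20819433 e * Angstrom, so the dipole-dipole prefactor in
# V = C * kappa * mu1 * mu2 / r^3 (mu in D, r in Angstrom) is
# C = 116140.97 * 0.20819433^2 = 5034.1166 cm^-1 D^-2 Angstrom^3.

CM1_PER_E2_ANG <- 116140.97320979
DEBYE_E_ANG <- 0.20819433270936
CM1_PER_D2_ANG3 <- CM1_PER_E2_ANG * DEBYE_E_ANG^2

PIGMENT_ROLES <- c("alpha", "beta", "b800")
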