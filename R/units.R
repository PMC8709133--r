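# Internal unit constants. All lengths are micrometres, energies keV,
# densities g/cm^3 and specific energies Gy throughout the package; these
# constants are the single place where the conversions live.

# one keV in joule (exact, from the 2019 SI elementary charge)
.J_PER_KEV <- 1.602176634e-16

# specific energy in Gy for 1 keV deposited in 1 g
.GY_PER_KEV_PER_G <- .J_PER_KEV * 1e3

# gram per um^3 for a density of 1 g/cm^3
.G_PER_UM3 <- 1e-12

# energy density in keV/um^3 equivalent to 1 Gy in a 1 g/cm^3 medium:
# 1e-15 kg/um^3 * 1 J/kg / (J per keV)
.KEV_PER_UM3_PER_GY <- 1e-15 / .J_PER_KEV
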