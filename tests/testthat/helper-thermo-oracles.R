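# Independent closed-form oracles for the statistical-thermodynamics
# pieces, coded here from scratch so the package path is cross-checked.

kB <- 1.380649e-23; hP <- 6.62607015e-34; cc <- 2.99792458e10
NA_ <- 6.02214076e23; Rj <- 8.31446261815324

# pure harmonic-oscillator per-mode entropy, cal/(mol K)
ho_entropy <- function(nu, T) {
  x <- hP * cc * nu / (kB * T)
  Rj * (x / (exp(x) - 1) - log(1 - exp(-x))) / 4184 * 1000
}

# free-rotor per-mode entropy with the damped moment, cal/(mol K)
fr_entropy <- function(nu, T, B_av = 1e-44) {
  mu <- hP / (8 * pi^2 * cc * nu)
  mu_eff <- mu * B_av / (mu + B_av)
  Rj * (0.5 + log(sqrt(8 * pi^3 * mu_eff * kB * T) / hP)) / 4184 * 1000
}
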