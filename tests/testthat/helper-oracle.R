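# Independent fixed-step RK4 integrator of the reaction network, kept
# deliberately separate from the package's lsoda-based path. State order:
# AS, HNO, ONOO, FlBA, FlOH, nuc, adduct, N2O, NO2, O2 (all M).
oracle_rhs <- function(y, kAS, kO2, kFlBA, kdim, knuc, clamp = TRUE) {
  r_as <- kAS * y[1]
  r_o2 <- kO2 * y[10] * y[2]
  r_nuc <- knuc * y[6] * y[2]
  r_dim <- kdim * y[2]^2
  r_pr <- kFlBA * y[4] * y[3]
  c(-r_as, r_as - r_o2 - r_nuc - 2 * r_dim, r_o2 - r_pr,
    -r_pr, r_pr, -r_nuc, r_nuc, r_dim, r_pr, if (clamp) 0 else -r_o2)
}

oracle_rk4 <- function(y0, T, dt, ...) {
  y <- y0
  for (s in seq_len(round(T / dt))) {
    k1 <- oracle_rhs(y, ...)
    k2 <- oracle_rhs(y + dt / 2 * k1, ...)
    k3 <- oracle_rhs(y + dt / 2 * k2, ...)
    k4 <- oracle_rhs(y + dt * k3, ...)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  names(y) <- c("AS", "HNO", "ONOO", "FlBA", "FlOH",
                "nuc", "adduct", "N2O", "NO2", "O2")
  y
}

oracle_state0 <- function(AS0 = 20e-6, FlBA0 = 25e-6, O2 = 225e-6, nuc = 0) {
  c(AS0, 0, 0, FlBA0, 0, nuc, 0, 0, 0, O2)
}

# reference assay parameters shared across tests
ref_conditions <- function(...) experiment_conditions(...)
ref_rates <- function(...) rate_constants(...)
noiseless_optics <- function(...) optics_model(noise_sd = 0, ...)
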