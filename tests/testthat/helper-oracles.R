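# Independent oracles, deliberately coded without the package's solution
# paths: a brute-force scan for the point-AIS fold and a hand-rolled RK4
# shooting solver for the extended-AIS boundary-value problem.

# Fold of Ra*G*(ENa - V_half)*exp((V - V_half)/k) = V - Vs: the threshold is
# the largest Vs admitting a solution, i.e. max over V of
# V - A*exp((V - V_half)/k).
oracle_point_fold <- function(k, V_half, ENa, Ra_MOhm, G_nS,
                              dV = 1e-4) {
  A <- Ra_MOhm * G_nS * 1e-3 * (ENa - V_half)   # mV
  V <- seq(V_half - 15 * k, V_half + 5 * k, by = dV)
  max(V - A * exp((V - V_half) / k))
}

# Shooting solution of V'' = -C exp((V - V_half)/k) on the AIS, integrated
# backward from the end (V'(L) = 0) with classical fixed-step RK4, plus a
# linear resistive stretch of length delta to the soma. The threshold is
# the maximum of the implied somatic potential over the end voltage.
oracle_bvp_threshold <- function(k, V_half, ENa, Ri, d_um, delta, L, g,
                                 n_steps = 800) {
  d <- d_um * 1e-6
  ra <- 4 * (Ri * 1e-2) / (pi * d^2)                 # Ohm/m
  C <- pi * d * g * ra * (ENa - V_half) * 1e-12      # mV/um^2
  h <- -L / n_steps                                  # integrate L -> 0
  shoot <- function(V_end) {
    y <- c(V_end, 0)
    f <- function(y) c(y[2], -C * exp((y[1] - V_half) / k))
    for (i in seq_len(n_steps)) {
      k1 <- f(y)
      k2 <- f(y + h / 2 * k1)
      k3 <- f(y + h / 2 * k2)
      k4 <- f(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    y[1] - delta * y[2]
  }
  stats::optimize(shoot, c(V_half - 40, V_half + 25), maximum = TRUE,
                  tol = 1e-10)$objective
}

# shared small helpers
paper_mem <- function() passive_membrane(Cm = 0.9, Rm = 15000, Ri = 100,
                                         EL = -75)
unit_axon <- function() cable_geometry(d = 1, dS = 100)
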