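#' Nav channel parameters for the threshold theory
#'
#' The analytical theory characterizes AIS Nav channels by a Boltzmann
#' activation curve: slope factor `k`, half-activation voltage `V_half`,
#' and reversal potential `ENa`. The driving force is approximated by
#' (ENa − V_half) throughout the closed forms.
#'
#' @param k Boltzmann slope factor (mV); must be > 0.
#' @param V_half half-activation voltage (mV).
#' @param ENa Na reversal potential (mV); must exceed `V_half`.
#' @return An object of class `nav_theory_params`.
#' @export
nav_theory_params <- function(k = 5, V_half = -35, ENa = 70) {
  if (k <= 0) stop("k must be > 0 (mV)")
  if (ENa <= V_half) stop("ENa must exceed V_half")
  structure(list(k = k, V_half = V_half, ENa = ENa),
            class = "nav_theory_params")
}

#' AIS geometry
#'
#' @param delta AIS start position Δ, distance from soma (µm), >= 0.
#' @param L AIS length (µm), > 0.
#' @param d AIS diameter (µm), > 0.
#' @param g Nav surface conductance density (S/m²), optional.
#' @param G total Nav conductance (nS), optional. When both `g` and `G` are
#'   given they must satisfy G = g·π·d·L; when only one is given the other
#'   is filled in.
#' @return An object of class `ais_geometry` with derived field `x_half`
#'   (AIS midpoint, µm).
#' @export
ais_geometry <- function(delta = 5, L = 30, d = 1, g = NULL, G = NULL) {
  if (delta < 0) stop("delta must be >= 0 (µm)")
  if (L <= 0) stop("L must be > 0 (µm)")
  if (d <= 0) stop("d must be > 0 (µm)")
  # g [S/m²] x lateral area [µm² = 1e-12 m²] -> S; report nS
  area_factor <- pi * d * L * 1e-3   # nS per (S/m²)
  if (!is.null(g) && !is.null(G)) {
    if (abs(G - g * area_factor) > 1e-9 * abs(G))
      stop("inconsistent g and G: G must equal g*pi*d*L")
  } else if (!is.null(g)) {
    G <- g * area_factor
  } else if (!is.null(G)) {
    g <- G / area_factor
  }
  structure(list(delta = delta, L = L, d = d, g = g, G = G,
                 x_half = delta + L / 2),
            class = "ais_geometry")
}

# f(z) = (1+rho) z tanh z + rho z^2 (1 - tanh^2 z) - 1, whose root gives the
# fold of the rescaled boundary-value problem U'' + e^U = 0
.bifurcation_f <- function(z, rho) {
  t <- tanh(z)
  (1 + rho) * z * t + rho * z^2 * (1 - t^2) - 1
}

.bifurcation_fprime <- function(z, rho) {
  t <- tanh(z)
  s <- 1 - t^2
  (1 + rho) * (t + z * s) + 2 * rho * z * s * (1 - z * t)
}

#' Fold bifurcation of the rescaled extended-AIS cable equation
#'
#' The steady-state cable equation of an AIS with exponential Nav current,
#' with all leak and time-dependent terms dropped, rescales to
#' U'' + e^U = 0 on (0, 1) with U'(1) = 0 and a Robin condition at the
#' proximal end set by the ratio Δ/L. Its solutions are
#' U(y) = ln(2z²) − 2·ln cosh(z(y − 1)); the somatic value at which the
#' solution branch folds (spike initiation) satisfies
#' (1 + Δ/L)·z·tanh z + (Δ/L)·z²·(1 − tanh²z) = 1.
#'
#' @param ratio Δ/L, the AIS start distance in units of AIS length (>= 0).
#'   `0` is an AIS abutting the soma; `Inf` recovers the point-AIS limit.
#' @return A list with:
#'   \describe{
#'     \item{z}{root of the bifurcation condition (z·tanh z = 1 at ratio 0).}
#'     \item{c1}{the solution-family constant, c1 = 2z.}
#'     \item{U0}{rescaled somatic threshold,
#'       ln(2z²) − 2·ln cosh z − 2·(Δ/L)·z·tanh z (≈ −0.13 at ratio 0).}
#'     \item{U1}{rescaled AIS-end threshold, ln(2z²) (≈ 1.06 at ratio 0).}
#'     \item{ratio}{the input ratio.}
#'   }
#'   Note e^U1 = c1²/2, so the amplitude constant c1²·/2 ≈ 2.88 and
#'   2·e^U1 = 4z² ≈ 5.8.
#' @examples
#' b <- solve_bifurcation(0)
#' b$U0   # about -0.13
#' @export
solve_bifurcation <- function(ratio = 0) {
  if (is.na(ratio) || ratio < 0) stop("ratio must be >= 0")
  if (is.infinite(ratio)) {
    # point-AIS limit: z -> 0, U0 -> ln 2 - ln(1 + 2 rho) - 1 -> -Inf,
    # but F -> 0; represent the limit explicitly
    return(list(z = 0, c1 = 0, U0 = -Inf, U1 = -Inf, ratio = Inf))
  }
  root <- stats::uniroot(.bifurcation_f, c(1e-8, 10), rho = ratio,
                         tol = 1e-13)$root
  # Newton polish to machine-level residual
  for (i in 1:4) {
    root <- root - .bifurcation_f(root, ratio) / .bifurcation_fprime(root, ratio)
  }
  if (abs(.bifurcation_f(root, ratio)) > 1e-12)
    stop("bifurcation root finding did not converge")
  z <- root
  U1 <- log(2 * z^2)
  U0 <- U1 - 2 * log(cosh(z)) - 2 * ratio * z * tanh(z)
  list(z = z, c1 = 2 * z, U0 = U0, U1 = U1, ratio = ratio)
}

#' Corrective term F for the midpoint-equivalent point AIS
#'
#' The threshold of an extended AIS differs from that of a point AIS with
#' the same total conductance placed at the midpoint x_1/2 = Δ + L/2 by
#' k·F(Δ/L), with F(ratio) = U0(ratio) + 1 + ln(ratio + 1/2). F decreases
#' monotonically from about 0.17 at ratio 0 to 0 in the point limit.
#'
#' @inheritParams solve_bifurcation
#' @return Dimensionless corrective term (vectorized over `ratio`).
#' @export
corrective_term_F <- function(ratio) {
  vapply(ratio, function(r) {
    if (is.infinite(r)) return(0)
    b <- solve_bifurcation(r)
    b$U0 + 1 + log(r + 0.5)
  }, numeric(1))
}

# dimensionless Ra*G product from interface units (MOhm, nS)
.RaG <- function(Ra_MOhm, G_nS) Ra_MOhm * G_nS * 1e-3

#' Does the point-AIS fold bifurcation exist?
#'
#' With the full Boltzmann Nav current I(V) = Ra·G·m∞(V)·(ENa − V), the
#' axonal fixed-point equation V = Vs + I(V) only loses solutions by a fold
#' if the current curve somewhere has unit slope. For a very proximal AIS
#' (small Ra·G) there is no fold and the somatic potential transitions
#' smoothly ("no kink"); the threshold is then undefined.
#'
#' @param nav a [nav_theory_params()].
#' @param Ra axial resistance soma→AIS (MΩ).
#' @param G total available Nav conductance (nS).
#' @return Logical.
#' @export
point_ais_bifurcation_exists <- function(nav, Ra, G) {
  A <- .RaG(Ra, G)
  dIdV <- function(V) {
    u <- (V - nav$V_half) / nav$k
    minf <- 1 / (1 + exp(-u))
    # d/dV [A m_inf (ENa - V)]
    A * (minf * (1 - minf) / nav$k * (nav$ENa - V) - minf)
  }
  Vgrid <- seq(nav$V_half - 30 * nav$k, nav$ENa - 1e-6, length.out = 2000)
  any(dIdV(Vgrid) >= 1)
}

#' Spike threshold with a point AIS
#'
#' Somatic and AIS threshold for all Nav conductance clustered at one
#' axonal site with axial resistance `Ra` to the soma. With the driving
#' force approximated as (ENa − V_half) the fold of
#' Ra·G·(ENa − V_half)·e^((V − V_half)/k) = V − Vs gives
#' Vs = V_half − k − k·ln(Ra·G·(ENa − V_half)/k); the AIS-site threshold is
#' exactly k above it.
#'
#' @inheritParams point_ais_bifurcation_exists
#' @param exact_driving_force if `TRUE`, solve the fold numerically with
#'   the full Boltzmann current I = Ra·G·m∞(V)·(ENa − V) instead of the
#'   exponential approximation.
#' @return A list with `Vs_soma`, `Vs_ais` (mV).
#' @export
point_ais_threshold <- function(nav, Ra, G, exact_driving_force = FALSE) {
  if (Ra <= 0) stop("Ra must be > 0 (MΩ)")
  if (G <= 0) stop("G must be > 0 (nS)")
  if (!point_ais_bifurcation_exists(nav, Ra, G)) {
    stop(structure(
      class = c("aisx_no_bifurcation", "error", "condition"),
      list(message = sprintf(
             "no fold bifurcation for Ra*G = %.3g MOhm*nS: AIS too proximal or conductance too low, threshold undefined",
             Ra * G),
           call = sys.call(-1))))
  }
  A <- .RaG(Ra, G)
  if (!exact_driving_force) {
    Va <- nav$V_half - nav$k * log(A * (nav$ENa - nav$V_half) / nav$k)
    return(list(Vs_soma = Va - nav$k, Vs_ais = Va))
  }
  # exact fold: dI/dV = 1 at the tangency below the current maximum
  I <- function(V) {
    A * (nav$ENa - V) / (1 + exp(-(V - nav$V_half) / nav$k))
  }
  dIdV1 <- function(V) {
    u <- (V - nav$V_half) / nav$k
    minf <- 1 / (1 + exp(-u))
    A * (minf * (1 - minf) / nav$k * (nav$ENa - V) - minf) - 1
  }
  Vgrid <- seq(nav$V_half - 30 * nav$k, nav$ENa - 1e-6, length.out = 4000)
  vals <- dIdV1(Vgrid)
  ix <- which(vals[-1] * vals[-length(vals)] < 0)[1]  # lowest tangency
  Vstar <- stats::uniroot(dIdV1, c(Vgrid[ix], Vgrid[ix + 1]),
                          tol = 1e-12)$root
  list(Vs_soma = Vstar - I(Vstar), Vs_ais = Vstar)
}

#' Spike threshold with a spatially extended AIS
#'
#' Analytical somatic threshold for an AIS of length L starting at distance
#' Δ from the soma, with uniform Nav density g:
#' Vs = V_half + k·U0(Δ/L) − k·ln(r_a·(ENa − V_half)/k) − k·ln(π·d·g)
#'      − 2k·ln L,
#' evaluated in SI units so the logarithm arguments are dimensionless.
#' Also returns the midpoint-equivalent point-AIS threshold (same total
#' conductance at x_1/2) and their difference k·F(Δ/L).
#'
#' @inheritParams point_ais_bifurcation_exists
#' @param mem a [passive_membrane()] (supplies Ri for r_a).
#' @param geom an [ais_geometry()] with `g` set.
#' @return A list with `Vs_soma`, `Vs_ais_end`, `Vs_point_equiv` (midpoint
#'   rule, mV), `kF` (mV), `z`, `U0`, `ratio`.
#' @export
extended_ais_threshold <- function(nav, mem, geom) {
  stopifnot(inherits(geom, "ais_geometry"))
  if (is.null(geom$g)) stop("geometry must carry a Nav density g")
  ratio <- geom$delta / geom$L
  b <- solve_bifurcation(ratio)
  # SI: ra [Ohm/m], d [m], g [S/m^2], L [m]
  d_m <- geom$d * 1e-6
  L_m <- geom$L * 1e-6
  ra_si <- 4 * (mem$Ri * 1e-2) / (pi * d_m^2)
  drive <- (nav$ENa - nav$V_half) / nav$k
  log_arg <- log(pi * d_m * geom$g * L_m^2 * ra_si * drive)
  Vs <- nav$V_half + nav$k * (b$U0 - log_arg)
  V_end <- nav$V_half + nav$k * (b$U1 - log_arg)
  # equivalent point AIS: total conductance G at the midpoint
  G_S <- geom$G * 1e-9
  x_m <- geom$x_half * 1e-6
  Vs_pt <- nav$V_half - nav$k - nav$k * log(ra_si * x_m * G_S * drive)
  list(Vs_soma = Vs, Vs_ais_end = V_end, Vs_point_equiv = Vs_pt,
       kF = Vs - Vs_pt, z = b$z, U0 = b$U0, ratio = ratio)
}

#' Threshold shift from ratios of AIS parameters
#'
#' The separable logarithmic threshold formula
#' Vs = const − k·ln g − k·ln L − k·ln x_1/2 + k·ln d gives, between two
#' configurations, ΔVs = −k·[ln(g'/g) + ln(L'/L) + ln(x'/x) − ln(d'/d)].
#'
#' @param k Nav activation slope (mV).
#' @param g_ratio,L_ratio,x_ratio,d_ratio ratios final/initial of Nav
#'   density, AIS length, AIS midpoint position, and AIS diameter.
#' @return Threshold shift ΔVs (mV).
#' @examples
#' threshold_shift_geometry(x_ratio = 30 / 25)  # about -0.9 mV
#' @export
threshold_shift_geometry <- function(k = 5, g_ratio = 1, L_ratio = 1,
                                     x_ratio = 1, d_ratio = 1) {
  if (any(c(g_ratio, L_ratio, x_ratio, d_ratio) <= 0))
    stop("ratios must be > 0")
  -k * (log(g_ratio) + log(L_ratio) + log(x_ratio) - log(d_ratio))
}

#' Predicted threshold shift from measured AIS geometry change
#'
#' Applies ΔVs = −k·[ln(L_f/L_i) + ln(x_f/x_i)] to an initial/final pair of
#' AIS length and midpoint position, assuming constant Nav density and
#' diameter (the structural-plasticity prediction).
#'
#' @param L_i,x_i initial AIS length and midpoint position (µm).
#' @param L_f,x_f final AIS length and midpoint position (µm).
#' @param k Nav activation slope (mV).
#' @return Threshold shift (mV).
#' @examples
#' predict_geometry_shift(9.6, 13.3, 19.5, 18.4)  # about -5.2 mV
#' @export
predict_geometry_shift <- function(L_i, x_i, L_f, x_f, k = 5) {
  if (any(c(L_i, x_i, L_f, x_f) <= 0)) stop("lengths must be > 0")
  -k * (log(L_f / L_i) + log(x_f / x_i))
}

#' Somatic threshold shift from a current at the AIS
#'
#' A static current I injected on the axon hyperpolarizes (I < 0) or
#' depolarizes the AIS relative to the soma by Ra·I through resistive
#' coupling, shifting the somatic threshold by −Ra·I while leaving the
#' AIS-site threshold unchanged (injection at the AIS start). The effective
#' site is capped at the AIS end: beyond it the voltage gradient between
#' soma and AIS no longer grows.
#'
#' @param mem a [passive_membrane()].
#' @param geom_axon a [cable_geometry()] for the axon.
#' @param I current (pA; negative = hyperpolarizing).
#' @param site injection distance from the soma (µm).
#' @param ais_end AIS end position Δ + L (µm); the site is clipped to it.
#' @return A list with `dVs_soma` and `dVs_ais` (mV) and the effective `Ra`
#'   (MΩ).
#' @export
threshold_shift_from_current <- function(mem, geom_axon, I, site,
                                         ais_end = site) {
  x_eff <- min(site, ais_end)
  Ra <- axial_resistance(mem, geom_axon, x_eff)
  list(dVs_soma = -Ra * I * 1e-3, dVs_ais = 0, Ra = Ra)
}

#' Effective axial resistance with a shunting conductance at the AIS
#'
#' Inserting a conductance g* at the AIS is equivalent to placing it in
#' parallel with the axial resistance: Ra_eff = 1/(1/Ra + g*). Negligible
#' when g* ≪ 1/Ra.
#'
#' @param Ra axial resistance (MΩ).
#' @param g_shunt shunt conductance (nS), >= 0.
#' @return Effective resistance (MΩ).
#' @export
effective_Ra <- function(Ra, g_shunt) {
  if (any(g_shunt < 0)) stop("g_shunt must be >= 0")
  1 / (1 / Ra + g_shunt * 1e-3)
}

#' Threshold shift from the distal axonal load
#'
#' The distal axon acts as a conductance 1/R_distal at the AIS end with
#' reversal at rest, raising the somatic threshold by
#' ΔV = (Ra_end/R_distal)·(Va − EL), with R_distal = r_a·λ for a
#' semi-infinite unmyelinated axon. Myelination multiplying Rm by
#' `myelin_factor` scales λ (hence R_distal) by its square root, halving
#' the shift for the typical factor of 4.
#'
#' @param mem a [passive_membrane()].
#' @param geom_axon a [cable_geometry()] for the distal axon.
#' @param Ra_end axial resistance from soma to the AIS end (MΩ).
#' @param Va spike threshold at the AIS end (mV).
#' @param myelin_factor multiplicative increase of Rm beyond the AIS
#'   (>= 1; 1 = unmyelinated).
#' @return A list with `dV` (mV) and `R_distal` (MΩ).
#' @export
distal_load_threshold_shift <- function(mem, geom_axon, Ra_end, Va,
                                        myelin_factor = 1) {
  if (myelin_factor < 1) stop("myelin_factor must be >= 1")
  mem2 <- passive_membrane(mem$Cm, mem$Rm * myelin_factor, mem$Ri, mem$EL)
  R_distal <- axial_resistance_per_um(mem2, geom_axon) *
    space_constant(mem2, geom_axon)
  list(dV = Ra_end / R_distal * (Va - mem$EL), R_distal = R_distal)
}

#' Electrically equivalent axon diameter for a given soma diameter
#'
#' Requiring somatic (∝ dS⁻²) and axonal (∝ da^(−3/2)) resistances to scale
#' together gives the power law da ∝ dS^(4/3). The returned law is anchored
#' so that it passes through (`anchor_dS`, `anchor_d`).
#'
#' @param dS soma diameter(s) (µm).
#' @param anchor_dS,anchor_d anchor point (µm); defaults to a 30 µm soma
#'   with a 1 µm axon.
#' @return Axon diameter(s) (µm).
#' @export
electrical_equivalence_scaling <- function(dS, anchor_dS = 30, anchor_d = 1) {
  if (any(dS <= 0)) stop("dS must be > 0")
  anchor_d * (dS / anchor_dS)^(4 / 3)
}

#' AIS length/position scaling with diameter
#'
#' Electrical equivalence keeps AIS position and length constant in units
#' of the space constant, which scales as sqrt(d): returns the length
#' scale factor for a diameter change.
#'
#' @param d new diameter (µm).
#' @param ref_d reference diameter (µm).
#' @return Scale factor sqrt(d/ref_d).
#' @export
ais_length_scale <- function(d, ref_d = 1) sqrt(d / ref_d)

#' Numerical threshold of an extended AIS with axonal currents
#'
#' Solves the steady-state AIS cable equation
#' V'' = −π·d·g·r_a·(ENa − V_half)·e^((V − V_half)/k) − r_a·i
#' numerically by backward shooting from the AIS end, with boundary
#' conditions V'(end) = r_a·I_end and a linear (resistive) proximal stretch
#' of length Δ to the clamped soma. The somatic threshold is the largest
#' somatic potential admitting a steady solution (the fold), found as the
#' maximum of the implied somatic potential over the AIS-end voltage.
#' Covers the cases without closed form: current injected at the AIS end
#' and current distributed uniformly over the AIS.
#'
#' @inheritParams extended_ais_threshold
#' @param I_end current injected at the AIS end (pA; negative =
#'   hyperpolarizing).
#' @param I_uniform total current spread uniformly over the AIS (pA).
#' @return A list with `Vs_soma` (mV), `V_end` (AIS-end voltage at
#'   threshold, mV), and `Vs_linear` (the linearized approximation
#'   Vs(no current) − Ra_end·I_end, mV; `NA` when `I_uniform` is used).
#' @export
bvp_threshold <- function(nav, mem, geom, I_end = 0, I_uniform = 0) {
  stopifnot(inherits(geom, "ais_geometry"))
  d_m <- geom$d * 1e-6
  L_m <- geom$L * 1e-6
  ra_si <- 4 * (mem$Ri * 1e-2) / (pi * d_m^2)     # Ohm/m
  Cexp <- pi * d_m * geom$g * ra_si * (nav$ENa - nav$V_half)  # mV/m^2
  i_lin <- ra_si * (I_uniform * 1e-12) / L_m       # V/m^2 = mV/m^2 * 1e3?
  # ra_si [Ohm/m] * I [A] / L [m] -> V/m^2; convert to mV/m^2
  i_lin <- i_lin * 1e3
  um2 <- 1e-12                                     # (m/µm)^2
  deriv <- function(x, y, parms) {
    # y[1] = V (mV), y[2] = dV/dx (mV/µm); x in µm along the AIS
    dV2 <- -(Cexp * exp((y[1] - nav$V_half) / nav$k) + i_lin) * um2
    list(c(y[2], dV2))
  }
  slope_end <- ra_si * (I_end * 1e-12) * 1e3 * 1e-6  # mV/µm
  implied_Vs <- function(V_end) {
    out <- deSolve::ode(y = c(V = V_end, dV = slope_end),
                        times = seq(geom$L, 0, length.out = 101),
                        func = deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-10)
    V0 <- out[nrow(out), "V"]
    dV0 <- out[nrow(out), "dV"]
    unname(V0 - geom$delta * dV0)
  }
  opt <- stats::optimize(implied_Vs, interval = c(nav$V_half - 8 * nav$k,
                                                  nav$V_half + 4 * nav$k),
                         maximum = TRUE, tol = 1e-9)
  Vs_lin <- if (I_uniform == 0) {
    base <- extended_ais_threshold(nav, mem, geom)$Vs_soma
    Ra_end <- axial_resistance(mem, cable_geometry(d = geom$d),
                               geom$delta + geom$L)
    base - Ra_end * I_end * 1e-3
  } else NA_real_
  list(Vs_soma = opt$objective, V_end = opt$maximum, Vs_linear = Vs_lin)
}
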