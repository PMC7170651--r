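#' Passive membrane parameters
#'
#' Bundles the specific membrane and cytoplasm constants from which all
#' passive cable quantities derive.
#'
#' @param Cm specific membrane capacitance (µF/cm²).
#' @param Rm specific membrane resistance (Ω·cm²).
#' @param Ri intracellular (axial) resistivity (Ω·cm).
#' @param EL leak reversal potential (mV).
#'
#' @return An object of class `passive_membrane`.
#' @examples
#' passive_membrane() # the default cortical-like parameter set
#' @export
passive_membrane <- function(Cm = 0.9, Rm = 15000, Ri = 100, EL = -75) {
  if (!is.numeric(Cm) || Cm <= 0) stop("Cm must be > 0 (µF/cm²)")
  if (!is.numeric(Rm) || Rm <= 0) stop("Rm must be > 0 (Ω·cm²)")
  if (!is.numeric(Ri) || Ri <= 0) stop("Ri must be > 0 (Ω·cm)")
  structure(list(Cm = Cm, Rm = Rm, Ri = Ri, EL = EL),
            class = "passive_membrane")
}

#' Cable geometry
#'
#' @param d axon diameter (µm).
#' @param dS soma diameter (µm), optional; `NA` when the model has no
#'   explicit soma.
#'
#' @return An object of class `cable_geometry`.
#' @export
cable_geometry <- function(d = 1, dS = NA_real_) {
  if (!is.numeric(d) || d <= 0) stop("axon diameter d must be > 0 (µm)")
  if (!is.na(dS) && dS <= 0) stop("soma diameter dS must be > 0 (µm)")
  structure(list(d = d, dS = dS), class = "cable_geometry")
}

# unit helpers: interface units are µm / MΩ / GΩ; formulas are evaluated in
# cm and Ω (Rm is Ω·cm², Ri is Ω·cm) and converted at the boundary
.um_to_cm <- 1e-4

#' Axonal space constant
#'
#' Steady-state space constant of an infinite passive cylinder,
#' lambda = sqrt(Rm·d/(4·Ri)).
#'
#' @inheritParams axial_resistance
#' @return Length in µm.
#' @examples
#' space_constant(passive_membrane(), cable_geometry(d = 1)) # ~612 µm
#' @export
space_constant <- function(mem, geom) {
  stopifnot(inherits(mem, "passive_membrane"), inherits(geom, "cable_geometry"))
  lambda_cm <- sqrt(mem$Rm * (geom$d * .um_to_cm) / (4 * mem$Ri))
  lambda_cm / .um_to_cm
}

#' Axial resistance per unit length
#'
#' r_a = 4·Ri/(π·d²) for a cylinder of diameter d.
#'
#' @inheritParams axial_resistance
#' @return Resistance per length in MΩ/µm.
#' @export
axial_resistance_per_um <- function(mem, geom) {
  stopifnot(inherits(mem, "passive_membrane"), inherits(geom, "cable_geometry"))
  ra_ohm_per_cm <- 4 * mem$Ri / (pi * (geom$d * .um_to_cm)^2)
  ra_ohm_per_cm * .um_to_cm / 1e6
}

#' Axial resistance of a length of axon
#'
#' R_a = r_a · x, the resistance of the cytoplasmic path along a cylinder.
#'
#' @param mem a [passive_membrane()].
#' @param geom a [cable_geometry()].
#' @param x distance along the axon (µm).
#' @return Resistance in MΩ.
#' @examples
#' # 100 µm of 1-µm axon at Ri = 100 Ω·cm is about 127 MΩ
#' axial_resistance(passive_membrane(), cable_geometry(d = 1), 100)
#' @export
axial_resistance <- function(mem, geom, x) {
  if (any(x < 0)) stop("x must be >= 0 (µm)")
  axial_resistance_per_um(mem, geom) * x
}

#' Membrane resistance of an axonal segment
#'
#' R = Rm/(π·d·x): the transmembrane resistance of a cylinder of length x.
#' Much larger than the axial resistance over the same stretch for thin
#' proximal axons, which is why leak can be neglected in the threshold
#' theory.
#'
#' @inheritParams axial_resistance
#' @return Resistance in GΩ.
#' @export
membrane_resistance_segment <- function(mem, geom, x) {
  if (any(x <= 0)) stop("x must be > 0 (µm)")
  r_ohm <- mem$Rm / (pi * (geom$d * .um_to_cm) * (x * .um_to_cm))
  r_ohm / 1e9
}

#' Somatic membrane resistance
#'
#' Membrane resistance of a spherical soma, R_soma = Rm/(π·dS²).
#'
#' @inheritParams axial_resistance
#' @param dS soma diameter (µm).
#' @return Resistance in MΩ.
#' @examples
#' soma_resistance(passive_membrane(), dS = 100) # 47.7 MΩ
#' @export
soma_resistance <- function(mem, dS) {
  stopifnot(inherits(mem, "passive_membrane"))
  if (any(dS <= 0)) stop("dS must be > 0 (µm)")
  r_ohm <- mem$Rm / (pi * (dS * .um_to_cm)^2)
  r_ohm / 1e6
}

# distal resistance seen from x: semi-infinite by default, or a finite
# sealed-end axon of total length `axon_length` (coth correction)
.distal_resistance <- function(mem, geom, x, axon_length = Inf) {
  ra <- axial_resistance_per_um(mem, geom)
  lambda <- space_constant(mem, geom)
  if (is.infinite(axon_length)) return(ra * lambda)
  if (any(axon_length <= x)) stop("axon_length must exceed x")
  ra * lambda / tanh((axon_length - x) / lambda)
}

#' Input resistance with a sealed proximal end
#'
#' Input resistance at distance `x` from a sealed end (no current through
#' the origin; the small-soma limit). The proximal segment has resistance
#' r_a·λ/tanh(x/λ) and combines in parallel with the distal axon (r_a·λ for
#' a semi-infinite cable), giving R(x) = r_a·λ/(1 + tanh(x/λ)).
#'
#' @inheritParams axial_resistance
#' @param axon_length total axon length in µm (default infinite); when
#'   finite the distal branch uses the sealed-end coth correction.
#' @return A list with `R` (MΩ, exact), `R_taylor` (MΩ, the small-x
#'   expansion r_a·(λ − x)), `R_proximal` and `R_distal` (MΩ).
#' @export
input_resistance_sealed <- function(mem, geom, x, axon_length = Inf) {
  if (any(x < 0)) stop("x must be >= 0 (µm)")
  ra <- axial_resistance_per_um(mem, geom)
  lambda <- space_constant(mem, geom)
  Rdist <- .distal_resistance(mem, geom, x, axon_length)
  Rprox <- ifelse(x == 0, Inf, ra * lambda / tanh(x / lambda))
  list(R = 1 / (1 / Rprox + 1 / Rdist),
       R_taylor = ra * (lambda - x),
       R_proximal = Rprox,
       R_distal = Rdist)
}

#' Input resistance with a killed proximal end
#'
#' Input resistance at distance `x` from a killed end (open membrane held at
#' rest; the infinitely large soma limit). The proximal resistance is
#' r_a·λ·tanh(x/λ), approximately r_a·x for x ≪ λ, so the input resistance
#' grows with distance from the soma.
#'
#' @inheritParams input_resistance_sealed
#' @return A list with `R` (MΩ, exact), `R_taylor` (MΩ, r_a·x·(1 − x/λ)),
#'   `R_proximal` and `R_distal` (MΩ).
#' @export
input_resistance_killed <- function(mem, geom, x, axon_length = Inf) {
  if (any(x < 0)) stop("x must be >= 0 (µm)")
  ra <- axial_resistance_per_um(mem, geom)
  lambda <- space_constant(mem, geom)
  Rdist <- .distal_resistance(mem, geom, x, axon_length)
  Rprox <- ra * lambda * tanh(x / lambda)
  list(R = 1 / (1 / Rprox + 1 / Rdist),
       R_taylor = ra * x * (1 - x / lambda),
       R_proximal = Rprox,
       R_distal = Rdist)
}

#' Input resistance with a finite soma
#'
#' Interpolates between the killed-end and sealed-end limits: the proximal
#' path is the axial resistance to the soma in series with the somatic
#' membrane resistance, in parallel with the distal axon:
#' 1/R = 1/(r_a·x + R_soma) + 1/(r_a·λ).
#'
#' @inheritParams input_resistance_sealed
#' @param dS soma diameter (µm).
#' @return A list with `R` (MΩ), `R_proximal`, `R_distal`, `R_soma` (MΩ).
#' @export
input_resistance_finite_soma <- function(mem, geom, x, dS, axon_length = Inf) {
  if (any(x < 0)) stop("x must be >= 0 (µm)")
  ra <- axial_resistance_per_um(mem, geom)
  Rsoma <- soma_resistance(mem, dS)
  Rdist <- .distal_resistance(mem, geom, x, axon_length)
  Rprox <- ra * x + Rsoma
  list(R = 1 / (1 / Rprox + 1 / Rdist),
       R_proximal = Rprox,
       R_distal = Rdist,
       R_soma = Rsoma)
}

#' Table of passive input resistances along the axon
#'
#' Convenience wrapper evaluating the three boundary-condition variants on a
#' grid of distances.
#'
#' @inheritParams input_resistance_finite_soma
#' @param x numeric vector of distances (µm).
#' @return A data.frame with columns `x_um`, `R_sealed_MOhm`,
#'   `R_killed_MOhm`, `R_finite_MOhm`.
#' @export
passive_resistance_table <- function(mem, geom, x, dS = geom$dS,
                                     axon_length = Inf) {
  data.frame(
    x_um = x,
    R_sealed_MOhm = input_resistance_sealed(mem, geom, x, axon_length)$R,
    R_killed_MOhm = input_resistance_killed(mem, geom, x, axon_length)$R,
    R_finite_MOhm = if (is.na(dS)) NA_real_ else
      input_resistance_finite_soma(mem, geom, x, dS, axon_length)$R
  )
}
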