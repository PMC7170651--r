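#' A cylindrical cable section
#'
#' @param name unique section name.
#' @param length section length (µm).
#' @param diameter constant diameter (µm).
#' @param dx target compartment length (µm); the section is split into
#'   `round(length/dx)` equal compartments (at least one).
#' @param parent `"soma"` or the name of an earlier section; sections
#'   attach at the distal end of their parent.
#' @param kind `"axon"` or `"dendrite"`; controls which channel densities
#'   apply and whether AIS distances are measured along it.
#' @param on_axon_path whether path distance from the soma through this
#'   section counts as axonal distance (defaults to `kind == "axon"`; set
#'   for an axon-bearing dendrite stem).
#' @return An object of class `cable_section`.
#' @export
section <- function(name, length, diameter, dx = 10, parent = "soma",
                    kind = c("axon", "dendrite"),
                    on_axon_path = (kind[1] == "axon")) {
  kind <- match.arg(kind)
  if (length <= 0 || diameter <= 0 || dx <= 0)
    stop("length, diameter and dx must be > 0")
  structure(list(name = name, length = length, diameter = diameter,
                 dx = dx, parent = parent, kind = kind,
                 on_axon_path = on_axon_path),
            class = "cable_section")
}

#' A branched neuron model
#'
#' Assembles a spherical, isopotential soma, a tree of cylindrical
#' sections, passive parameters, channel specifications and (optionally)
#' an AIS marking into a simulatable model.
#'
#' @param soma_diameter soma diameter (µm; sphere, one compartment with
#'   membrane area π·dS²).
#' @param sections list of [section()]s; parents must precede children.
#' @param passive a [passive_membrane()].
#' @param channels named list of [channel_spec()]s (may be empty for a
#'   passive model).
#' @param ais an [ais_geometry()] marking which axonal compartments (by
#'   path distance from the soma) carry AIS densities, or `NULL`.
#' @param point_ais optional point AIS: `list(position = µm, G = named nS
#'   per channel name)`; the named channels get their total conductance
#'   placed in the single axonal compartment containing `position`.
#' @param myelin_beyond distance (µm) beyond which axonal membrane is
#'   myelinated (Rm ×`myelin_factor`, Cm /`myelin_factor`), or `NULL`.
#' @param myelin_factor myelination factor (default 4).
#' @param g_L_soma_extra additional somatic leak density (S/m², reversal
#'   EL); used for leak-sensitivity protocols.
#' @return An object of class `neuron_model`.
#' @export
neuron_model <- function(soma_diameter, sections, passive,
                         channels = list(), ais = NULL, point_ais = NULL,
                         myelin_beyond = NULL, myelin_factor = 4,
                         g_L_soma_extra = 0) {
  stopifnot(inherits(passive, "passive_membrane"))
  nm <- vapply(sections, function(s) s$name, character(1))
  if (anyDuplicated(nm)) stop("section names must be unique")
  for (i in seq_along(sections)) {
    p <- sections[[i]]$parent
    if (p != "soma" && !(p %in% nm[seq_len(i - 1)]))
      stop("parent of section '", nm[i], "' must be 'soma' or an earlier section")
  }
  structure(list(soma_diameter = soma_diameter, sections = sections,
                 passive = passive, channels = channels, ais = ais,
                 point_ais = point_ais, myelin_beyond = myelin_beyond,
                 myelin_factor = myelin_factor,
                 g_L_soma_extra = g_L_soma_extra),
            class = "neuron_model")
}

#' Discretize a neuron model into compartments
#'
#' Converts the section tree into flat per-compartment arrays (capacitance,
#' leak, axial coupling, per-channel maximal conductances) ready for the
#' implicit solver. The soma is compartment 1 (the tree root); its axial
#' resistance to each child is the child's first half-compartment only.
#'
#' @param model a [neuron_model()].
#' @return An object of class `compiled_model`: per-compartment vectors and
#'   a `comp` data.frame (`section`, `region`, `path_mid` = distance of the
#'   compartment midpoint from the soma, µm).
#' @export
compile_model <- function(model) {
  stopifnot(inherits(model, "neuron_model"))
  mem <- model$passive
  um2_to_cm2 <- 1e-8
  um2_to_m2 <- 1e-12

  sec_names <- c("soma", vapply(model$sections, `[[`, "", "name"))
  comp_sec <- "soma"; comp_len <- NA_real_; comp_diam <- model$soma_diameter
  comp_mid <- 0; comp_area <- pi * model$soma_diameter^2
  parent <- -1L              # 0-based parent of soma
  half_res <- 0              # MΩ, distal-half axial resistance of each comp
  sec_last <- c(soma = 1L)   # last compartment index (1-based) per section
  sec_end_dist <- c(soma = 0)
  on_path <- TRUE

  for (s in model$sections) {
    ncomp <- max(1L, as.integer(round(s$length / s$dx)))
    len <- s$length / ncomp
    ra <- axial_resistance_per_um(mem, cable_geometry(d = s$diameter)) # MΩ/µm
    base_dist <- sec_end_dist[[s$parent]]
    mids <- base_dist + (seq_len(ncomp) - 0.5) * len
    idx0 <- length(comp_sec)
    comp_sec <- c(comp_sec, rep(s$name, ncomp))
    comp_len <- c(comp_len, rep(len, ncomp))
    comp_diam <- c(comp_diam, rep(s$diameter, ncomp))
    comp_mid <- c(comp_mid, mids)
    comp_area <- c(comp_area, rep(pi * s$diameter * len, ncomp))
    on_path <- c(on_path, rep(s$on_axon_path, ncomp))
    parent <- c(parent,
                as.integer(sec_last[[s$parent]] - 1L),
                idx0 + seq_len(ncomp - 1L) - 1L)
    half_res <- c(half_res, rep(ra * len / 2, ncomp))
    sec_last[s$name] <- idx0 + ncomp
    sec_end_dist[s$name] <- base_dist + s$length
  }

  n <- length(comp_sec)
  kind_of <- c(soma = "soma",
               stats::setNames(vapply(model$sections, `[[`, "", "kind"),
                               vapply(model$sections, `[[`, "", "name")))
  region <- unname(kind_of[comp_sec])
  region[1] <- "soma"
  distal_half <- rep(FALSE, n)
  if (!is.null(model$ais)) {
    a <- model$ais
    sel <- region == "axon" & on_path &
      comp_mid >= a$delta & comp_mid <= a$delta + a$L
    if (!any(sel)) stop("AIS interval contains no axonal compartment")
    region[sel] <- "ais"
    distal_half <- sel & comp_mid >= a$delta + a$L / 2
  }

  # axial coupling conductance comp<->parent (µS = 1/MΩ);
  # soma contributes no half-resistance (isopotential sphere boundary)
  g_ax <- numeric(n)
  for (i in 2:n) {
    p <- parent[i] + 1L
    rp <- if (p == 1L) 0 else half_res[p]
    g_ax[i] <- 1 / (rp + half_res[i])
  }

  area_cm2 <- comp_area * um2_to_cm2
  rm_fac <- rep(1, n); cm_fac <- rep(1, n)
  if (!is.null(model$myelin_beyond)) {
    my <- (region %in% c("axon")) & on_path & comp_mid > model$myelin_beyond
    rm_fac[my] <- model$myelin_factor
    cm_fac[my] <- 1 / model$myelin_factor
  }
  cm <- mem$Cm * cm_fac * area_cm2 * 1e3          # nF
  gl <- area_cm2 / (mem$Rm * rm_fac) * 1e6        # µS
  gl[1] <- gl[1] + model$g_L_soma_extra * comp_area[1] * um2_to_m2 * 1e6

  # channel conductances per compartment
  channels_c <- list()
  for (cn in names(model$channels)) {
    ch <- model$channels[[cn]]
    gbar <- numeric(n)
    for (rg in names(ch$density_map)) {
      dens <- ch$density_map[[rg]]
      tgt <- if (rg == "ais_distal_half") distal_half else region == rg
      gbar[tgt] <- gbar[tgt] + dens * comp_area[tgt] * um2_to_m2 * 1e6
    }
    if (!is.null(model$point_ais) && cn %in% names(model$point_ais$G)) {
      ic <- which(region %in% c("axon", "ais") & on_path)
      ic <- ic[which.min(abs(comp_mid[ic] - model$point_ais$position))]
      gbar[ic] <- gbar[ic] + model$point_ais$G[[cn]] * 1e-3   # nS -> µS
    }
    channels_c[[cn]] <- list(
      E = ch$E_rev, gbar = gbar,
      gates = lapply(ch$gates, function(g)
        list(V_half = g$V_half, k_slope = g$k_slope, tau_star = g$tau_star,
             exponent = g$exponent, is_inactivation = g$is_inactivation,
             fixed_tau = g$fixed_tau)))
  }

  structure(list(
    n = n, parent = parent, cm = cm, g_ax = g_ax, gl = gl, EL = mem$EL,
    channels = channels_c,
    comp = data.frame(section = comp_sec, region = region,
                      path_mid = comp_mid, diameter = comp_diam,
                      length_um = comp_len, area_um2 = comp_area,
                      on_axon_path = on_path),
    model = model), class = "compiled_model")
}

#' Index of the compartment at a given axonal distance
#'
#' @param cmodel a [compiled_model()].
#' @param x distance from the soma along the axonal path (µm); `0` returns
#'   the soma.
#' @param section restrict the lookup to a named section (needed distal to
#'   a branch point).
#' @return 1-based compartment index.
#' @export
comp_at <- function(cmodel, x, section = NULL) {
  if (x == 0) return(1L)
  sel <- cmodel$comp$on_axon_path & cmodel$comp$region != "soma"
  if (!is.null(section)) sel <- sel & cmodel$comp$section == section
  ix <- which(sel)
  ix[which.min(abs(cmodel$comp$path_mid[ix] - x))]
}

#' Index of the distal AIS end compartment
#'
#' @param cmodel a [compiled_model()].
#' @return 1-based compartment index of the most distal AIS compartment
#'   (or, for a point AIS, the compartment holding the point conductance).
#' @export
ais_end_comp <- function(cmodel) {
  ia <- which(cmodel$comp$region == "ais")
  if (length(ia) > 0) return(ia[which.max(cmodel$comp$path_mid[ia])])
  pa <- cmodel$model$point_ais
  if (!is.null(pa)) return(comp_at(cmodel, pa$position))
  stop("model has no AIS")
}

#' The biophysical neuron model
#'
#' Spherical soma (30 µm), 6 µm × 1000 µm dendrite, 1 µm × 500 µm
#' unmyelinated axon whose proximal stretch carries the AIS (default
#' 5–35 µm) with high Nav/Kv1 densities; lower densities elsewhere.
#' Morphological variants cover a thicker axon with an electrically
#' equivalent soma, a longer axon, a myelinated distal axon, distal
#' branching with a configurable diameter exponent, and an axon borne on a
#' dendritic stem.
#'
#' @param ais an [ais_geometry()]; its `g` is the AIS Nav density and its
#'   `d` must equal `axon_diameter`.
#' @param g_k_ais AIS Kv1 density (S/m²).
#' @param g_hyper_ais density (S/m²) of a static hyperpolarizing
#'   conductance (reversal −90 mV) on the distal half of the AIS (0 = none).
#' @param kv7_kinetic if `TRUE` use the kinetic Kv7 gate instead of the
#'   static conductance for `g_hyper_ais`.
#' @param soma_diameter,axon_diameter,axon_length,dend_diameter,dend_length
#'   morphology (µm).
#' @param variant one of `"default"`, `"big_axon"` (3 µm axon, soma and
#'   AIS rescaled for electrical equivalence), `"long_axon"` (1000 µm),
#'   `"myelinated"` (Rm ×4, Cm /4 beyond the AIS end), `"branched_32"` /
#'   `"branched_52"` (distal branch point with diameter exponent 3/2 or
#'   5/2), `"axon_dendrite"` (2 µm stem splitting per the 3/2 rule, one
#'   daughter carrying the axon).
#' @param g_L_soma_extra extra somatic leak density (S/m²).
#' @param point_ais optional point AIS override: `list(position = µm,
#'   G_na = nS, G_k = nS)`; suppresses the extended AIS marking.
#' @param dx_fine,dx_coarse,fine_extent discretization (µm): compartment
#'   size on the proximal axon (out to `fine_extent` or the AIS end + 15,
#'   whichever is larger) and elsewhere.
#' @return A [neuron_model()].
#' @export
build_biophysical_neuron <- function(ais = ais_geometry(delta = 5, L = 30,
                                                        d = 1, g = 3500),
                                     g_k_ais = 1500, g_hyper_ais = 0,
                                     kv7_kinetic = FALSE,
                                     soma_diameter = 30, axon_diameter = 1,
                                     axon_length = 500,
                                     dend_diameter = 6, dend_length = 1000,
                                     variant = "default",
                                     g_L_soma_extra = 0, point_ais = NULL,
                                     dx_fine = 1, dx_coarse = 10,
                                     fine_extent = 100) {
  variant <- match.arg(variant, c("default", "big_axon", "long_axon",
                                  "myelinated", "branched_32", "branched_52",
                                  "axon_dendrite"))
  mem <- passive_membrane()
  myelin_beyond <- NULL
  if (variant == "big_axon") {
    sc <- ais_length_scale(3, 1)
    axon_diameter <- 3
    soma_diameter <- 30 * 3^(3 / 4)
    ais <- ais_geometry(delta = ais$delta * sc, L = ais$L * sc, d = 3,
                        g = ais$g)
  }
  if (variant == "long_axon") axon_length <- 1000
  if (variant == "myelinated") myelin_beyond <- ais$delta + ais$L

  if (!is.null(point_ais)) {
    pa <- list(position = point_ais$position,
               G = c(Nav_AIS = point_ais$G_na, Kv1 = point_ais$G_k))
    ais_mark <- NULL
  } else {
    pa <- NULL
    ais_mark <- ais
    if (abs(ais$d - axon_diameter) > 1e-9)
      stop("ais$d must equal axon_diameter")
  }

  fine_len <- max(fine_extent,
                  if (!is.null(ais_mark)) ais_mark$delta + ais_mark$L + 15
                  else pa$position + 15)
  fine_len <- min(fine_len, axon_length)

  secs <- list(
    section("dend", dend_length, dend_diameter, dx = dx_coarse,
            parent = "soma", kind = "dendrite"))
  if (variant == "axon_dendrite") {
    # axon-bearing dendrite: 2 µm stem, Rall 3/2 split after 7 µm
    d_daughter <- 2 / 2^(2 / 3)
    secs <- c(secs, list(
      section("stem", 7, 2, dx = 1, parent = "soma", kind = "dendrite",
              on_axon_path = TRUE),
      section("dend2", 300, d_daughter, dx = dx_coarse, parent = "stem",
              kind = "dendrite"),
      section("axon_prox", fine_len, axon_diameter, dx = dx_fine,
              parent = "stem", kind = "axon"),
      section("axon_dist", axon_length - fine_len, axon_diameter,
              dx = dx_coarse, parent = "axon_prox", kind = "axon")))
  } else if (variant %in% c("branched_32", "branched_52")) {
    p <- if (variant == "branched_32") 3 / 2 else 5 / 2
    d_br <- axon_diameter / 2^(1 / p)
    branch_at <- max(100, fine_len)
    secs <- c(secs, list(
      section("axon_prox", branch_at, axon_diameter, dx = dx_fine,
              parent = "soma", kind = "axon"),
      section("axon_br1", axon_length - branch_at, d_br, dx = dx_coarse,
              parent = "axon_prox", kind = "axon"),
      section("axon_br2", axon_length - branch_at, d_br, dx = dx_coarse,
              parent = "axon_prox", kind = "axon", on_axon_path = FALSE)))
  } else {
    secs <- c(secs, list(
      section("axon_prox", fine_len, axon_diameter, dx = dx_fine,
              parent = "soma", kind = "axon")))
    if (axon_length > fine_len)
      secs <- c(secs, list(
        section("axon_dist", axon_length - fine_len, axon_diameter,
                dx = dx_coarse, parent = "axon_prox", kind = "axon")))
  }

  ch <- build_paper_channels(g_na_ais = if (!is.null(ais)) ais$g else 3500,
                             g_k_ais = g_k_ais)
  if (g_hyper_ais > 0) {
    ch$Kv7 <- if (kv7_kinetic)
      channel_spec("Kv7",
                   list(gating_variable("q", -30, 9, 100)),
                   E_rev = -90,
                   density_map = c(ais_distal_half = g_hyper_ais))
    else
      static_conductance(c(ais_distal_half = g_hyper_ais))
  }

  neuron_model(soma_diameter, secs, mem, ch, ais = ais_mark,
               point_ais = pa, myelin_beyond = myelin_beyond,
               g_L_soma_extra = g_L_soma_extra)
}

#' The reduced point-Nav cable model
#'
#' A 50 µm spherical soma on a 1 µm × 300 µm passive axon with all Nav
#' conductance at one axonal site: a single non-inactivating activation
#' gate with fixed time constant (150 µs at 23 °C, Q10-corrected to
#' 53.6 µs), V_half = −35 mV, k = 5 mV, ENa = 70 mV; no K channels. Used
#' in somatic voltage clamp, where the soma size is immaterial.
#'
#' @param G total Nav conductance (nS; the reference range is 200–600).
#' @param position AIS position Δ (µm from the soma).
#' @param dx compartment size (µm).
#' @return A [neuron_model()].
#' @export
build_simplified_neuron <- function(G = 400, position = 10, dx = 1) {
  mem <- passive_membrane()
  nav <- channel_spec(
    "Nav_point",
    list(gating_variable("m", -35, 5, q10_correct(0.150), fixed_tau = TRUE)),
    E_rev = 70, density_map = c())
  neuron_model(
    soma_diameter = 50,
    sections = list(section("axon", 300, 1, dx = dx, parent = "soma",
                            kind = "axon")),
    passive = mem, channels = list(Nav_point = nav),
    point_ais = list(position = position, G = c(Nav_point = G)))
}

#' A passive soma + axon model
#'
#' @param soma_diameter soma diameter (µm; 1 for the sealed-end-like small
#'   soma, 100 for the large soma).
#' @param axon_length axon length (µm).
#' @param axon_diameter axon diameter (µm).
#' @param dx compartment size (µm).
#' @return A [neuron_model()] with no channels.
#' @export
build_passive_neuron <- function(soma_diameter = 100, axon_length = 2000,
                                 axon_diameter = 1, dx = 2) {
  neuron_model(
    soma_diameter = soma_diameter,
    sections = list(section("axon", axon_length, axon_diameter, dx = dx,
                            parent = "soma", kind = "axon")),
    passive = passive_membrane(), channels = list())
}
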