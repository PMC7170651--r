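mem <- paper_mem()

test_that("model construction validates the section tree and AIS placement", {
  expect_error(neuron_model(30, list(section("a", 10, 1, parent = "b")),
                            mem), "earlier section")
  expect_error(
    compile_model(neuron_model(
      30, list(section("axon", 50, 1, dx = 1)), mem,
      ais = ais_geometry(delta = 100, L = 30, d = 1, g = 3500))),
    "no axonal compartment")
})

test_that("default biophysical model discretizes to the reference layout", {
  cmp <- compile_model(build_biophysical_neuron())
  expect_equal(cmp$comp$region[1], "soma")
  expect_equal(cmp$comp$area_um2[1], pi * 30^2)
  ais <- which(cmp$comp$region == "ais")
  expect_length(ais, 30)  # 5..35 µm at 1 µm resolution
  expect_equal(range(cmp$comp$path_mid[ais]), c(5.5, 34.5))
  # total AIS Nav conductance = g pi d L
  G_ais <- sum(cmp$channels$Nav_AIS$gbar) * 1e3  # µS -> nS
  expect_equal(G_ais, 3500 * pi * 1 * 30 * 1e-3, tolerance = 1e-9)
  # AIS Kv1 density on top of the default layout
  expect_equal(sum(cmp$channels$Kv1$gbar[ais]) * 1e3,
               1500 * pi * 30 * 1e-3, tolerance = 1e-9)
  # tree invariant: parents precede children
  expect_true(all(cmp$parent < seq_len(cmp$n) - 1L))
})

test_that("passive tree preserves the resting equilibrium to 1e-9 mV", {
  cmp <- compile_model(build_passive_neuron(100, 2000, 1, dx = 2))
  out <- run_sim(cmp, t_stop = 10, dt = 0.1,
                 probes = c(soma = 1L, mid = comp_at(cmp, 1000)))
  expect_lt(max(abs(out$V - mem$EL)), 1e-9)
})

test_that("steady-state leak currents balance the injected current", {
  cmp <- compile_model(build_passive_neuron(100, 2000, 1, dx = 2))
  out <- run_sim(cmp, t_stop = 400, dt = 0.1,
                 stim = list(stim_step(comp_at(cmp, 100), 100, 0, Inf)),
                 probes = c(soma = 1L), record_every = 400)
  V <- out$state$V
  leak_total <- sum(cmp$gl * (V - cmp$EL))   # µS * mV = nA
  expect_equal(leak_total, 0.1, tolerance = 1e-3)
})

test_that("large-soma passive model matches the finite-soma closed form within 2%", {
  cmp <- compile_model(build_passive_neuron(100, 2000, 1, dx = 2))
  geo <- cable_geometry(d = 1)
  # proximal distances (the regime the closed forms address; the neglected
  # proximal leak grows the discrepancy beyond ~2% distally)
  for (x in c(20, 50, 100)) {
    ic <- comp_at(cmp, x)
    xm <- cmp$comp$path_mid[ic]
    out <- run_sim(cmp, t_stop = 300, dt = 0.1,
                   stim = list(stim_step(ic, 100, 0, Inf)),
                   probes = c(site = ic), record_every = 100)
    Rsim <- unname(out$V[nrow(out$V), 1] - mem$EL) / 0.1
    Rth <- input_resistance_finite_soma(mem, geo, xm, dS = 100,
                                        axon_length = 2000)$R
    expect_equal(Rsim, Rth, tolerance = 0.02)
  }
})

test_that("small-soma passive model has decreasing input resistance", {
  cmp <- compile_model(build_passive_neuron(1, 2000, 1, dx = 2))
  R <- vapply(c(20, 100, 300), function(x) {
    ic <- comp_at(cmp, x)
    out <- run_sim(cmp, t_stop = 300, dt = 0.1,
                   stim = list(stim_step(ic, 10, 0, Inf)),
                   probes = c(site = ic), record_every = 100)
    (out$V[nrow(out$V), 1] - mem$EL) / 0.01
  }, 0)
  expect_true(all(diff(R) < 0))
})

test_that("early-time responses: linear proximal profile, axon charges faster than soma", {
  cmp <- compile_model(build_passive_neuron(100, 2000, 1, dx = 2))
  site <- comp_at(cmp, 75)
  prox <- which(cmp$comp$region == "axon" &
                  cmp$comp$path_mid < cmp$comp$path_mid[site])
  out <- run_sim(cmp, t_stop = 0.3, dt = 0.005,
                 stim = list(stim_step(site, 100, 0, Inf)),
                 probes = c(soma = 1L, site = site))
  # at t = 300 µs the axonal site leads the soma by >= 10x
  dep <- out$V[nrow(out$V), ] - mem$EL
  expect_gt(dep[["site"]] / dep[["soma"]], 10)
  # spatial profile between soma and site is linear (R^2 > 0.999)
  Vx <- out$state$V[prox]
  fit <- summary(lm(Vx ~ cmp$comp$path_mid[prox]))
  expect_gt(fit$r.squared, 0.999)
})

test_that("simplified model rests at EL and carries a single fixed-tau gate", {
  m <- build_simplified_neuron(G = 400, position = 15)
  expect_length(m$channels$Nav_point$gates, 1)
  expect_true(m$channels$Nav_point$gates[[1]]$fixed_tau)
  expect_equal(m$channels$Nav_point$gates[[1]]$tau_star, 0.05357,
               tolerance = 1e-3)
  cmp <- compile_model(m)
  out <- run_sim(cmp, t_stop = 10, dt = 0.05,
                 probes = c(soma = 1L, ais = ais_end_comp(cmp)))
  # rest sits slightly above EL: the non-inactivating point conductance
  # passes a small standing current (G m_inf(-75) (ENa - V) ~ 20 pA)
  expect_lt(max(out$V - mem$EL), 4)
  expect_gte(min(out$V - mem$EL), 0)
  # with a vanishing conductance the rest is EL exactly
  cmp0 <- compile_model(build_simplified_neuron(G = 1e-6, position = 15))
  out0 <- run_sim(cmp0, t_stop = 5, dt = 0.05, probes = c(soma = 1L))
  expect_lt(max(abs(out0$V - mem$EL)), 1e-6)
  # the point conductance sits in one compartment
  expect_equal(sum(cmp$channels$Nav_point$gbar > 0), 1L)
  expect_equal(sum(cmp$channels$Nav_point$gbar), 0.4)  # 400 nS in µS
})

test_that("holding-potential initialization is self-consistent after release", {
  cmp <- compile_model(build_biophysical_neuron())
  ss <- steady_state_init(cmp, hold_V = -75)
  out <- run_sim(cmp, t_stop = 20, dt = 0.01, state = ss$state,
                 stim = list(stim_step(1, ss$holding_pA, 0, Inf)),
                 probes = c(soma = 1L))
  expect_lt(max(abs(out$V[, 1] + 75)), 0.05)
  # free relaxation of a passive model lands on EL
  cmp2 <- compile_model(build_passive_neuron(100, 500, 1, dx = 5))
  ss2 <- steady_state_init(cmp2)
  expect_equal(ss2$V_rest, mem$EL, tolerance = 1e-6)
  expect_equal(ss2$holding_pA, 0)
})

test_that("a standing hyperpolarizing AIS current lowers the AIS resting potential", {
  cmp <- compile_model(build_biophysical_neuron(
    point_ais = list(position = 25, G_na = 350, G_k = 150)))
  site <- comp_at(cmp, 25)
  ss <- steady_state_init(cmp, hold_V = -75,
                          stim = list(stim_step(site, -200, 0, Inf)))
  expect_lt(ss$state$V[site], -76)
  # and the drop matches Ohm across the proximal axon within 10%
  dV_pred <- axial_resistance(mem, cable_geometry(1), 25) * -200 * 1e-3
  expect_equal(ss$state$V[site] - (-75), dV_pred, tolerance = 0.1)
})

test_that("suprathreshold spikes initiate at the AIS with fast axonal upstroke", {
  cmp <- compile_model(build_biophysical_neuron())
  ss <- steady_state_init(cmp, hold_V = -75)
  ae <- ais_end_comp(cmp)
  for (amp in c(1000, 1500, 2500)) {
    out <- run_sim(cmp, t_stop = 15, dt = 0.005, state = ss$state,
                   stim = list(stim_step(1, ss$holding_pA, 0, Inf),
                               stim_step(1, amp, 0.5, 15)),
                   probes = c(soma = 1L, ais = ae), record_currents = TRUE)
    t_ais <- out$t[which(out$V[, "ais"] >= -20)[1]]
    t_soma <- out$t[which(out$V[, "soma"] >= -20)[1]]
    expect_lt(t_ais, t_soma)  # axonal initiation
    expect_gt(max(diff(out$V[, "ais"])) / 0.005, 1000)  # dV/dt > 1000 V/s
    # Na+/K+ current separation at the AIS
    ina <- out$currents$Nav_AIS[, "ais"]
    ik <- out$currents$Kv1[, "ais"]
    pk <- which.max(abs(ina))
    expect_lt(abs(ik[pk]) / abs(ina[pk]), 0.2)
  }
})

test_that("morphology variants build with the intended passive changes", {
  my <- compile_model(build_biophysical_neuron(variant = "myelinated"))
  beyond <- my$comp$region == "axon" & my$comp$path_mid > 35 &
    my$comp$on_axon_path
  base <- compile_model(build_biophysical_neuron())
  expect_equal(my$gl[beyond], base$gl[beyond] / 4)
  expect_equal(my$cm[beyond], base$cm[beyond] / 4)
  big <- build_biophysical_neuron(variant = "big_axon")
  expect_equal(big$soma_diameter, 30 * 3^(3 / 4))
  expect_equal(big$ais$L, 30 * sqrt(3))
  br <- compile_model(build_biophysical_neuron(variant = "branched_52"))
  expect_true(all(c("axon_br1", "axon_br2") %in% br$comp$section))
  d_br <- unique(br$comp$diameter[br$comp$section == "axon_br1"])
  expect_equal(2 * d_br^(5 / 2), 1)  # d_main^p = d1^p + d2^p with d_main = 1
  ad <- compile_model(build_biophysical_neuron(variant = "axon_dendrite"))
  expect_true("stem" %in% ad$comp$section)
  expect_equal(max(ad$comp$path_mid[ad$comp$region == "ais"]) -
                 min(ad$comp$path_mid[ad$comp$region == "ais"]), 29,
               tolerance = 0.1)
})

test_that("voltage clamp holds the soma and reports the electrode current", {
  cmp <- compile_model(build_passive_neuron(100, 500, 1, dx = 5))
  out <- run_sim(cmp, t_stop = 100, dt = 0.05, clamp_V = -65,
                 probes = c(soma = 1L))
  expect_true(all(abs(out$V[-1, 1] + 65) < 1e-9))
  # steady clamp current ~ (V - EL) / R_input at the soma
  R_in <- input_resistance_finite_soma(mem, cable_geometry(1), 0, 100,
                                       axon_length = 500)$R
  expect_equal(out$I_clamp[length(out$I_clamp)], 10 / R_in,
               tolerance = 0.02)
})

test_that("Crank-Nicolson and backward Euler agree on a passive transient", {
  cmp <- compile_model(build_passive_neuron(100, 500, 1, dx = 5))
  st <- list(stim_step(comp_at(cmp, 50), 100, 0.2, Inf))
  be <- run_sim(cmp, t_stop = 5, dt = 0.01, stim = st,
                probes = c(soma = 1L), theta = 1)
  cn <- run_sim(cmp, t_stop = 5, dt = 0.01, stim = st,
                probes = c(soma = 1L), theta = 0.5)
  expect_lt(max(abs(be$V - cn$V)), 0.02)
})

test_that("integrate_model attaches default probes and the compiled model", {
  out <- integrate_model(build_simplified_neuron(), t_stop = 2, dt = 0.02)
  expect_named(as.data.frame(out$V), c("soma", "ais_end"))
  expect_s3_class(attr(out, "cmodel"), "compiled_model")
})
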