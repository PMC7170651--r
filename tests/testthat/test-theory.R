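nav <- nav_theory_params()
mem <- paper_mem()
geo <- unit_axon()

test_that("bifurcation solver reproduces the analytical constants", {
  b <- solve_bifurcation(0)
  expect_equal(b$z * tanh(b$z), 1, tolerance = 1e-12)
  expect_equal(b$z, 1.1996787, tolerance = 1e-6)
  expect_equal(b$c1, 2 * b$z)
  expect_equal(b$U0, -0.1295876, tolerance = 1e-6)
  expect_equal(b$U1, log(2 * b$z^2))
  # AIS end threshold sits about 1.2 k above the somatic threshold
  expect_equal(b$U1 - b$U0, 1.19, tolerance = 0.005)
})

test_that("general bifurcation reduces to the soma-adjacent case and to the point limit", {
  expect_equal(solve_bifurcation(0)$U0, solve_bifurcation(1e-12)$U0,
               tolerance = 1e-9)
  expect_equal(corrective_term_F(0), 0.17727, tolerance = 1e-4)
  expect_lt(corrective_term_F(100), 0.01)
  expect_equal(corrective_term_F(Inf), 0)
  Fs <- corrective_term_F(seq(0, 10, by = 0.25))
  expect_true(all(diff(Fs) < 0))  # monotone decrease
})

test_that("point-AIS threshold matches the brute-force fold oracle", {
  set.seed(42)
  for (i in 1:20) {
    Ra <- runif(1, 5, 120)
    G <- runif(1, 100, 800)
    got <- point_ais_threshold(nav, Ra, G)$Vs_soma
    expect_equal(got, oracle_point_fold(5, -35, 70, Ra, G),
                 tolerance = 1e-4)
  }
  # logarithmic additivity: doubling G lowers threshold by k ln 2
  v1 <- point_ais_threshold(nav, 30, 200)$Vs_soma
  v2 <- point_ais_threshold(nav, 30, 400)$Vs_soma
  expect_equal(v1 - v2, 5 * log(2), tolerance = 1e-12)
  # AIS threshold is exactly k above the somatic threshold
  p <- point_ais_threshold(nav, 31.8, 350)
  expect_equal(p$Vs_ais - p$Vs_soma, 5)
})

test_that("no-bifurcation regime is reported as a typed condition", {
  expect_error(point_ais_threshold(nav, Ra = 0.5, G = 10),
               class = "aisx_no_bifurcation")
  expect_true(point_ais_bifurcation_exists(nav, 30, 350))
  expect_false(point_ais_bifurcation_exists(nav, 0.5, 10))
})

test_that("exact driving force gives a nearby but distinct threshold", {
  appr <- point_ais_threshold(nav, 30, 350)$Vs_soma
  exact <- point_ais_threshold(nav, 30, 350, exact_driving_force = TRUE)$Vs_soma
  expect_lt(abs(appr - exact), 2)
  expect_gt(abs(appr - exact), 1e-6)
})

test_that("extended-AIS threshold agrees with the RK4 shooting oracle", {
  set.seed(7)
  for (i in 1:10) {
    delta <- runif(1, 0, 40)
    L <- runif(1, 10, 60)
    g <- runif(1, 1000, 8000)
    geom <- ais_geometry(delta = delta, L = L, d = 1, g = g)
    got <- extended_ais_threshold(nav, mem, geom)$Vs_soma
    want <- oracle_bvp_threshold(5, -35, 70, 100, 1, delta, L, g)
    expect_equal(got, want, tolerance = 0.01)
  }
})

test_that("extended AIS at the soma vs equivalent point AIS: 0.87k offset", {
  geom <- ais_geometry(delta = 0, L = 30, d = 1, g = 3500)
  ext <- extended_ais_threshold(nav, mem, geom)$Vs_soma
  pt <- point_ais_threshold(nav, axial_resistance(mem, geo, 30),
                            geom$G)$Vs_soma
  expect_equal(ext - pt, 0.87 * 5, tolerance = 0.01)
  # equivalently: same threshold as the point AIS moved to ~0.42 L
  x_eq <- 30 * exp((pt - ext) / 5)
  expect_equal(x_eq / 30, 0.42, tolerance = 0.005)
})

test_that("midpoint-equivalent correction is k*F(delta/L), bounded by 0.9 mV", {
  for (ratio in c(0, 0.1, 0.5, 1, 2, 5, 10, 20)) {
    L <- 20
    geom <- ais_geometry(delta = ratio * L, L = L, d = 1, g = 3500)
    th <- extended_ais_threshold(nav, mem, geom)
    expect_equal(th$kF, 5 * corrective_term_F(ratio), tolerance = 1e-9)
    expect_lte(abs(th$kF), 0.9)
  }
  # compressing/extending about a fixed midpoint at fixed G barely moves Vs
  x_half <- 25
  Ls <- seq(10, 2 * x_half, by = 5)
  Vs <- vapply(Ls, function(L) extended_ais_threshold(
    nav, mem, ais_geometry(delta = x_half - L / 2, L = L, d = 1,
                           G = 350))$Vs_soma, 0)
  expect_lt(diff(range(Vs)), 0.9)
})

test_that("threshold is monotone in each AIS factor", {
  th <- function(delta, L, g, d = 1) extended_ais_threshold(
    nav, passive_membrane(), ais_geometry(delta, L, d, g = g))$Vs_soma
  gs <- vapply(seq(1000, 8000, length.out = 8), function(g)
    th(10, 30, g), 0)
  expect_true(all(diff(gs) < 0))
  Ls <- vapply(seq(10, 60, length.out = 8), function(L) th(10, L, 3500), 0)
  expect_true(all(diff(Ls) < 0))
  xs <- vapply(seq(5, 50, length.out = 8), function(delta)
    th(delta, 30, 3500), 0)
  expect_true(all(diff(xs) < 0))
  # increasing diameter at fixed density and geometry raises threshold
  ds <- vapply(c(0.5, 1, 2, 3), function(d) th(10, 30, 3500, d = d), 0)
  expect_true(all(diff(ds) > 0))
})

test_that("geometric shift formula reproduces the worked examples", {
  expect_equal(threshold_shift_geometry(x_ratio = 30 / 25), -0.912,
               tolerance = 1e-3)
  expect_equal(threshold_shift_geometry(L_ratio = 50 / 40,
                                        x_ratio = 50 / 40),
               -2.231, tolerance = 1e-3)
  expect_equal(threshold_shift_geometry(d_ratio = 3,
                                        L_ratio = sqrt(3),
                                        x_ratio = 1),
               5 / 2 * log(3), tolerance = 1e-12)
  expect_equal(predict_geometry_shift(10, 20, 10, 20), 0)
  expect_equal(predict_geometry_shift(9.6, 13.3, 19.5, 18.4), -5.166,
               tolerance = 1e-3)
  expect_equal(predict_geometry_shift(19.2, 10.4, 15.7, 7.85), 2.414,
               tolerance = 1e-3)
  expect_error(threshold_shift_geometry(g_ratio = 0), "> 0")
})

test_that("axonal current shifts the somatic threshold by -Ra*I", {
  expect_equal(threshold_shift_from_current(mem, geo, 0, 30)$dVs_soma, 0)
  # site capped at the AIS end: moving the AIS end from 55 to 65 µm with a
  # current that hyperpolarizes the end by 3 mV raises threshold ~0.5 mV
  I <- -3 / (axial_resistance(mem, geo, 55) * 1e-3)
  s55 <- threshold_shift_from_current(mem, geo, I, 55, ais_end = 55)
  s65 <- threshold_shift_from_current(mem, geo, I, 65, ais_end = 65)
  expect_equal(s55$dVs_soma, 3)
  expect_equal(s65$dVs_soma - s55$dVs_soma, 10 / 55 * 3, tolerance = 1e-9)
  # beyond the AIS end the effect saturates
  s_beyond <- threshold_shift_from_current(mem, geo, I, 120, ais_end = 65)
  expect_equal(s_beyond$dVs_soma, s65$dVs_soma)
  expect_equal(s55$dVs_ais, 0)
})

test_that("a shunting conductance acts in parallel with Ra", {
  expect_equal(effective_Ra(40, 0), 40)
  expect_equal(effective_Ra(40, 1 / 40 * 1e3), 20)
  # negligible threshold effect when g_shunt << 1/Ra
  Ra <- 30
  g_small <- 0.05 / Ra * 1e3 * 0.9
  v0 <- point_ais_threshold(nav, Ra, 350)$Vs_soma
  v1 <- point_ais_threshold(nav, effective_Ra(Ra, g_small), 350)$Vs_soma
  expect_lt(abs(v1 - v0), 0.05 * 5)
})

test_that("distal axonal load raises threshold; myelination halves it", {
  Ra_end <- axial_resistance(mem, geo, 75)
  un <- distal_load_threshold_shift(mem, geo, Ra_end, Va = -55)
  expect_equal(un$R_distal, 779.8, tolerance = 1e-3)
  expect_equal(un$dV, 2.45, tolerance = 0.01)
  my <- distal_load_threshold_shift(mem, geo, Ra_end, Va = -55,
                                    myelin_factor = 4)
  expect_equal(my$dV, un$dV / 2)
  expect_equal(distal_load_threshold_shift(mem, geo, Ra_end, Va = -75)$dV, 0)
})

test_that("electrical equivalence scaling is a 4/3 power law", {
  expect_equal(electrical_equivalence_scaling(30), 1)
  expect_equal(electrical_equivalence_scaling(60) /
                 electrical_equivalence_scaling(30), 2^(4 / 3))
  # exponent recovered from any two points
  e <- log(electrical_equivalence_scaling(77) /
             electrical_equivalence_scaling(11)) / log(77 / 11)
  expect_equal(e, 4 / 3, tolerance = 1e-12)
  expect_equal(ais_length_scale(3), sqrt(3))
  res <- table3_equivalence_residuals()
  expect_true(all(is.finite(res$log_residual)))
  expect_equal(nrow(res), 4)
})

test_that("numerical BVP handles end-injected and uniform currents", {
  geom <- ais_geometry(delta = 10, L = 30, d = 1, g = 3500)
  base <- extended_ais_threshold(nav, mem, geom)$Vs_soma
  b0 <- bvp_threshold(nav, mem, geom)
  expect_equal(b0$Vs_soma, base, tolerance = 1e-5)
  bh <- bvp_threshold(nav, mem, geom, I_end = -100)
  expect_gt(bh$Vs_soma, base)        # hyperpolarizing current raises it
  expect_gt(bh$Vs_linear, base)      # linearized estimate agrees in sign
  expect_lt(abs(bh$Vs_soma - bh$Vs_linear), 3)  # reported side by side
  bu <- bvp_threshold(nav, mem, geom, I_uniform = -100)
  expect_gt(bu$Vs_soma, base)
  expect_true(is.na(bu$Vs_linear))
})

test_that("ais_geometry validates and completes g/G", {
  g1 <- ais_geometry(delta = 5, L = 30, d = 1, g = 3500)
  expect_equal(g1$G, 3500 * pi * 30 * 1e-3)
  expect_equal(g1$x_half, 20)
  g2 <- ais_geometry(delta = 5, L = 30, d = 1, G = g1$G)
  expect_equal(g2$g, 3500)
  expect_error(ais_geometry(delta = 5, L = 30, d = 1, g = 3500, G = 999),
               "inconsistent")
  expect_error(ais_geometry(delta = -1, L = 30, d = 1), ">= 0")
})
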