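# Single-compartment neuron: Nernst relation, Ca-channel gating, calcium
# pool, and the membrane-potential update.

test_that("Nernst potential matches closed-form values and monotonicity", {
  # equal concentrations (after unit conversion) -> zero potential
  expect_equal(nernst_potential(2e6, 2, 294), 0)
  # (RT/2F) ln(1e5) at 294 K
  expect_equal(nernst_potential(20, 2, 294),
               1000 * 8.314 * 294 / (2 * 96485) * log(1e5),
               tolerance = 1e-12)
  expect_equal(nernst_potential(20, 2, 294), 145.8, tolerance = 1e-3)
  # tenfold higher Ca_i scales by ratio of logarithms
  expect_equal(nernst_potential(200, 2, 294) / nernst_potential(20, 2, 294),
               log(1e4) / log(1e5), tolerance = 1e-12)
  # strictly decreasing in Ca_i
  ca <- 10^seq(0, 6, length.out = 25)
  expect_true(all(diff(nernst_potential(ca, 2, 294)) < 0))
  expect_error(nernst_potential(0, 2), "positive")
  expect_error(nernst_potential(10, -1), "positive")
})

test_that("steady-state activation is the standard logistic", {
  expect_equal(steady_state_activation(-40, -40, 7.5), 0.5)
  expect_equal(steady_state_activation(-47.5, -40, 7.5), 1 / (1 + exp(1)))
  expect_equal(steady_state_activation(-60, -40, 7.5),
               1 / (1 + exp(20 / 7.5)))
  v <- seq(-90, 10, by = 1)
  m <- steady_state_activation(v)
  expect_true(all(diff(m) > 0))
  expect_true(all(m > 0 & m < 1))
})

test_that("gate update is exponential relaxation and stays bracketed", {
  expect_equal(step_activation(0.3, 0.3, 50, 1), 0.3)
  expect_equal(step_activation(0, 1, 50, 1), 1 - exp(-0.02))
  # 50 steps of 1 ms compound to one 50 ms relaxation
  m <- 0
  for (i in 1:50) m <- step_activation(m, 1, 50, 1)
  expect_equal(m, 1 - exp(-1), tolerance = 1e-12)
  # bracketing for random inputs
  set.seed(1)
  for (i in 1:50) {
    m0 <- runif(1); mi <- runif(1)
    m1 <- step_activation(m0, mi, 50, runif(1, 0.1, 10))
    expect_gte(m1, min(m0, mi)); expect_lte(m1, max(m0, mi))
  }
})

test_that("channel current is Ohmic with the unit contract", {
  a <- membrane_area(10)
  expect_equal(a, pi * 1e-6, tolerance = 1e-12)
  expect_equal(channel_current(0.35, 1, a, -60, -60), 0)
  # default leak, 10 mV driving force: ~ +0.011 nA
  expect_equal(channel_current(0.35, 1, a, -50, -60), 0.011, tolerance = 0.01)
  # linear in the control factor
  expect_equal(channel_current(1, 0.8, a, -30, -10),
               2 * channel_current(1, 0.4, a, -30, -10))
})

test_that("calcium pool integrates inflow minus clearance with a floor", {
  expect_equal(step_calcium(0.1, 0, Ca_i_min = 0.1), 0.1)
  # pure clearance over one time constant
  expect_equal(step_calcium(400.1, 0, tau_Ca_clr = 400, Ca_i_min = 0.1,
                            dt = 400),
               0.1 + 400 * exp(-1), tolerance = 1e-9)
  # constant inflow equilibrates at Ca_min + inflow * tau
  p <- neuron_parameters()
  I_Ca <- -0.02
  inflow <- p$B * p$B_scale * 0.02
  ca <- 0.1
  for (i in 1:20000) {
    ca <- step_calcium(ca, I_Ca, p$B, p$tau_Ca_clr, p$Ca_i_min, 1, p$B_scale)
  }
  expect_equal(ca, p$Ca_i_min + inflow * p$tau_Ca_clr, tolerance = 1e-6)
  # outward current does not deplete below the clearance path
  expect_gte(step_calcium(5, +1, dt = 1), step_calcium(5, 0, dt = 1) - 1e-12)
})

test_that("membrane step relaxes to conductance-weighted equilibrium", {
  p <- neuron_parameters()
  # at leak equilibrium with no other channels, V is unchanged
  expect_equal(step_membrane_potential(-60, 0, 150, p, I_stim = 0, dt = 1),
               -60)
  # passive steady state under current injection: I / g_leak above rest
  g_leak_tot <- p$g_leak * p$area        # mS
  v <- -60
  for (i in 1:200) {
    v <- step_membrane_potential(v, 0, 150, p, I_stim = 0.01, dt = 1)
  }
  expect_equal(v, -60 + 0.01 / (g_leak_tot * 1000), tolerance = 1e-6)
  expect_equal(v, -60 + 9.1, tolerance = 0.02)
})

test_that("one exponential-Euler step equals the analytic RC solution", {
  p <- neuron_parameters(g_Ca_max = 1e-12)   # effectively passive
  tau <- p$C_m * p$area / (p$g_leak * p$area)    # ~2.857 ms
  g_extra <- 0.5 * p$area                        # constant extra conductance
  v_inf <- (p$g_leak * p$area * (-60) + g_extra * (-10)) /
    (p$g_leak * p$area + g_extra)
  tau2 <- p$C_m * p$area / (p$g_leak * p$area + g_extra)
  v1 <- step_membrane_potential(-60, 0, 150, p, g_extra = g_extra,
                                E_extra = -10, dt = 1)
  expect_equal(v1, v_inf + (-60 - v_inf) * exp(-1 / tau2), tolerance = 1e-12)
})

test_that("passive step response matches the analytic exponential", {
  # RC compartment: simulate with the network engine, Ca channel disabled
  p <- neuron_parameters(g_Ca_max = 1e-15)
  spec <- network_spec(data.frame(name = "n"),
                       data.frame(pre = character(), post = character()),
                       neuron_params = p)
  prot <- stimulus_protocol(tonic_current("n", 0, 100, 0.01))
  tau <- p$C_m / p$g_leak                      # ms, density form
  dV <- 0.01 / (p$g_leak * p$area * 1000)      # steady-state depolarisation
  analytic <- function(t) -60 + dV * (1 - exp(-t / tau))
  # 1 ms steps: within 1% of the analytic curve at full depolarisation
  r1 <- simulate_network(spec, prot, duration = 100, dt = 1)
  expect_lt(abs(r1$V[101, 1] - analytic(100)) / dV, 0.01)
  # small steps: matches to high accuracy (exponential Euler is exact for
  # piecewise-constant conductance, up to stimulus-grid alignment)
  r2 <- simulate_network(spec, prot, duration = 100, dt = 0.01)
  expect_lt(abs(r2$V[nrow(r2$V), 1] - analytic(100)) / dV, 1e-6)
})

test_that("initial state is rest-consistent and E_Ca tracks the Nernst relation", {
  p <- neuron_parameters()
  s0 <- initial_neuron_state(p)
  expect_equal(s0$V_m, p$V_leak_eq)
  expect_equal(s0$m, steady_state_activation(p$V_leak_eq, p$V_mid, p$S_Ca))
  expect_equal(s0$E_Ca, nernst_potential(p$Ca_i_init, p$Ca_e, p$temperature))
  # during simulation, recorded E_Ca-consistency: recompute from Ca trace
  spec <- network_spec(data.frame(name = "n"),
                       data.frame(pre = character(), post = character()))
  prot <- stimulus_protocol(tonic_current("n", 100, 3000, 0.02))
  r <- simulate_network(spec, prot, duration = 5000, record_state = TRUE)
  expect_true(all(r$Ca >= p$Ca_i_min))
  expect_true(all(r$m >= 0 & r$m <= 1))
})

test_that("gate and concentration bounds hold under random pulse protocols", {
  set.seed(42)
  spec <- network_spec(data.frame(name = "n"),
                       data.frame(pre = character(), post = character()))
  for (i in 1:5) {
    prot <- stimulus_protocol(
      poisson_pulse_train("n", MSI = runif(1, 100, 1000),
                          window = c(0, 10000),
                          width = runif(1, 10, 300),
                          amplitude = runif(1, -0.05, 0.08)),
      rng_seed = i)
    r <- simulate_network(spec, prot, duration = 10000, record_state = TRUE)
    expect_true(all(r$m >= 0 & r$m <= 1))
    expect_true(all(r$Ca >= neuron_parameters()$Ca_i_min))
    expect_true(all(is.finite(r$V)))
  }
})

test_that("parameter validation rejects non-physical values", {
  expect_error(neuron_parameters(diameter = -1), "positive")
  expect_error(neuron_parameters(S_Ca = 0), "positive")
  expect_error(neuron_parameters(Ca_i_init = 0.01), "Ca_i_min")
})

test_that("neuron parameters round-trip through the plain-text config", {
  p <- neuron_parameters(g_leak = 0.4, tau_m = 60)
  f <- tempfile(fileext = ".yaml")
  write_params(p, f)
  q <- read_params(f)
  expect_s3_class(q, "neuron_parameters")
  expect_equal(q[names(q) != "area"], p[names(p) != "area"])
})
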