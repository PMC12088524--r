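# Network assembly, stimulus protocols, and the integrator.

test_that("network validation names offending cells", {
  expect_error(network_spec(data.frame(name = c("a", "a")),
                            data.frame(pre = "a", post = "a")),
               "duplicate")
  expect_error(network_spec(data.frame(name = "a"),
                            data.frame(pre = "a", post = "ghost")),
               "ghost")
  expect_error(network_spec(data.frame(name = "a"),
                            data.frame(pre = "a", post = "a")),
               "self-connection")
})

test_that("an empty network simulates to empty flat traces", {
  spec <- network_spec(data.frame(name = character()),
                       data.frame(pre = character(), post = character()))
  r <- simulate_network(spec, NULL, duration = 100)
  expect_equal(ncol(r$V), 0)
  expect_equal(length(r$time), 101)
})

test_that("the hemisegmental oscillator blueprint builds as specified", {
  bp <- hemisegmental_oscillator()
  net <- build_network(bp$spec)
  expect_equal(net$n_cells, 5)     # 3-cell core + 2 command neurons
  expect_equal(net$n_conns, 6)
  # reciprocal E<->I with identical parameters for both excitors
  atlas <- circuit_atlas(bp)
  ei <- atlas$connections
  expect_setequal(ei$polarity[ei$pre == "I"], "inhibitory")
  expect_setequal(ei$polarity[ei$post == "I"], "excitatory")
})

test_that("Poisson pulse trains have exponential interval statistics", {
  # mean count over a long window ~ D / MSI
  counts <- vapply(1:20, function(s)
    length(poisson_pulse_times(1000, c(0, 1e6), seed = s)), numeric(1))
  expect_true(all(abs(counts - 1000) < 3 * sqrt(1000)))
  # rate scaling: MSI 3000 vs 1000 over same window
  c3 <- mean(vapply(1:20, function(s)
    length(poisson_pulse_times(3000, c(0, 1e6), seed = s)), numeric(1)))
  expect_equal(c3 / mean(counts), 1 / 3, tolerance = 0.1)
  # empty window
  expect_length(poisson_pulse_times(1000, c(500, 500), 1), 0)
  expect_error(poisson_pulse_times(-1, c(0, 100), 1), "positive")
  # deterministic given the seed
  expect_identical(poisson_pulse_times(500, c(0, 1e5), 42),
                   poisson_pulse_times(500, c(0, 1e5), 42))
})

test_that("stimulus bookkeeping: delivered integral equals amp * width * count", {
  bp <- hemisegmental_oscillator()
  net <- build_network(bp$spec)
  prot <- stimulus_protocol(
    poisson_pulse_train("C_B", 500, c(0, 50000), width = 100,
                        amplitude = 0.01), rng_seed = 9)
  comp <- larvaCPG:::.compile_protocol(prot, net, 60000, 1)
  n_pulses <- length(comp$pulse_times$C_B)
  expect_gt(n_pulses, 50)
  delivered <- sum(comp$stim$mat) * 1      # nA * ms
  expect_equal(delivered, 0.01 * 100 * n_pulses, tolerance = 1e-10)
})

test_that("per-cell stimulus streams are independent", {
  bp <- abdominal_chain()
  net <- build_network(bp$spec)
  p1 <- stimulus_protocol(poisson_pulse_train(c("C_F", "C_B"), 1000,
                                              c(0, 1e5)), rng_seed = 1)
  c1 <- larvaCPG:::.compile_protocol(p1, net, 1e5, 1)
  # restricting the episode to one cell leaves that cell's train unchanged
  p2 <- stimulus_protocol(poisson_pulse_train("C_F", 1000, c(0, 1e5)),
                          rng_seed = 1)
  c2 <- larvaCPG:::.compile_protocol(p2, net, 1e5, 1)
  expect_identical(c1$pulse_times$C_F, c2$pulse_times$C_F)
  expect_false(identical(c1$pulse_times$C_F, c1$pulse_times$C_B))
})

test_that("ramp episodes deliver the analytic line on the grid", {
  spec <- network_spec(data.frame(name = "n"),
                       data.frame(pre = character(), post = character()))
  net <- build_network(spec)
  prot <- stimulus_protocol(ramp_stimulus("n", 1000, 5000, -0.001))
  comp <- larvaCPG:::.compile_protocol(prot, net, 6000, 1)
  tt <- 0:5999
  expected <- ifelse(tt >= 1000 & tt < 5000, -0.001 / 1000 * (tt - 1000), 0)
  expect_equal(comp$stim$mat[, 1], expected, tolerance = 1e-12)
  # slope 0 -> all-zero episode
  p0 <- stimulus_protocol(ramp_stimulus("n", 0, 5000, 0))
  expect_true(all(larvaCPG:::.compile_protocol(p0, net, 6000, 1)$stim$mat == 0))
})

test_that("simulation is bit-reproducible for identical seeds", {
  bp <- hemisegmental_oscillator()
  prot <- stimulus_protocol(poisson_pulse_train("C_B", 800, c(0, 20000)),
                            rng_seed = 5)
  r1 <- simulate_network(bp, prot, duration = 20000)
  r2 <- simulate_network(bp, prot, duration = 20000)
  expect_identical(r1$V, r2$V)
  r3 <- simulate_network(bp, stimulus_protocol(
    poisson_pulse_train("C_B", 800, c(0, 20000)), rng_seed = 6),
    duration = 20000)
  expect_false(identical(r1$V, r3$V))
})

test_that("compiled and reference engines agree", {
  bp <- hemisegmental_oscillator()
  prot <- stimulus_protocol(tonic_current("C_B", 500, 8000, 0.06))
  r_cpp <- simulate_network(bp, prot, duration = 8000, engine = "cpp",
                            record_state = TRUE)
  r_ref <- simulate_network(bp, prot, duration = 8000, engine = "r",
                            record_state = TRUE)
  expect_equal(r_cpp$V, r_ref$V, tolerance = 1e-10)
  expect_equal(r_cpp$Ca, r_ref$Ca, tolerance = 1e-10)
  expect_equal(r_cpp$m_syn, r_ref$m_syn, tolerance = 1e-10)
})

test_that("opto channels act only inside their scheduled window", {
  bp <- hemisegmental_oscillator(opto_g = 0.8)
  prot0 <- stimulus_protocol(tonic_current("C_B", 500, 20000, 0.06))
  prot1 <- stimulus_protocol(tonic_current("C_B", 500, 20000, 0.06),
                             opto_window("I", 10000, 15000))
  r0 <- simulate_network(bp, prot0, duration = 20000, record = "I")
  r1 <- simulate_network(bp, prot1, duration = 20000, record = "I")
  expect_identical(r0$V[r0$time < 10000, ], r1$V[r1$time < 10000, ])
  # the chloride conductance pulls the inhibitor toward -70 mV against its
  # synaptic drive while the window is open, and only then
  win <- r1$time > 11000 & r1$time < 15000
  expect_lt(mean(r1$V[win, ]), mean(r0$V[win, ]) - 8)
  post <- r1$time > 17000
  expect_equal(mean(r1$V[post, ]), mean(r0$V[post, ]), tolerance = 0.05)
  expect_error(
    simulate_network(hemisegmental_oscillator(), prot1, duration = 1000),
    "without an opto channel")
})

test_that("recordings export and re-import as delimited text", {
  bp <- hemisegmental_oscillator()
  r <- simulate_network(bp, NULL, duration = 500, record = c("E_F", "I"))
  f <- tempfile(fileext = ".tsv")
  write_recording(r, f)
  d <- read_traces(f)
  expect_equal(names(d), c("time", "E_F", "I"))
  expect_equal(d$E_F, unname(r$V[, "E_F"]), tolerance = 1e-9)
  expect_error(read_traces({
    f2 <- tempfile(); writeLines("a\tb\n1\t2", f2); f2
  }), "time")
})

test_that("storage decimation subsamples without changing integration", {
  bp <- hemisegmental_oscillator()
  prot <- stimulus_protocol(tonic_current("C_B", 500, 5000, 0.06))
  r1 <- simulate_network(bp, prot, duration = 5000)
  r5 <- simulate_network(bp, prot, duration = 5000, record_every = 5L)
  expect_equal(r5$time, r1$time[seq(1, 5001, by = 5)])
  expect_equal(r5$V, r1$V[seq(1, 5001, by = 5), ], tolerance = 1e-12)
})
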