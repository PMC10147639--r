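test_that("phase drift matches closed-form single-neuron cases", {
  cfg <- sim_config(noise_variance = 0)
  st <- network_state(0, matrix(0, 1, 1), "excitatory", 1.5)
  expect_equal(phase_drift(st, 0, cfg), 3.0)

  # at theta = -pi (the wrapped image of pi) the excitable term vanishes
  st$phases <- -pi
  expect_equal(phase_drift(st, 0, cfg), 2.0)
  st$excitabilities <- 77
  expect_equal(phase_drift(st, 0, cfg), 2.0)

  # two in-phase neurons exert no coupling on each other
  st2 <- network_state(c(0.3, 0.3), matrix(c(0, 1, 1, 0), 2),
                       "excitatory", c(1.5, 1.5))
  d <- phase_drift(st2, c(0, 0), cfg)
  expect_equal(d[1], d[2])
  expect_equal(d, phase_drift(network_state(c(0.3, 0.3),
                                            matrix(0, 2, 2), "excitatory",
                                            c(1.5, 1.5)), c(0, 0), cfg))
})

test_that("drift is invariant under 2*pi phase shifts and errors on bad input", {
  cfg <- sim_config()
  st <- tiny_ei_state()
  base <- phase_drift(st, numeric(6), cfg)
  st_shift <- st
  st_shift$phases <- wrap_phase(st$phases + 2 * pi)
  expect_equal(phase_drift(st_shift, numeric(6), cfg), base)
  expect_error(phase_drift(st, numeric(3), cfg), "length")
})

test_that("noise-free inter-spike interval converges to pi/sqrt(eta)", {
  # closed-form period of the theta-neuron; checked at two step sizes
  eta <- 1.5
  expected <- pi / sqrt(eta)
  for (case in list(list(dt = 0.01, tol = 0.01), list(dt = 0.001, tol = 0.001))) {
    cfg <- sim_config(g = 0, dt = case$dt, noise_variance = 0)
    st <- network_state(0, matrix(0, 1, 1), "excitatory", eta)
    sim <- simulate_network(st, 40, cfg, record_every = 0)
    isi <- first_neuron_isi(sim$raster)
    expect_gt(length(isi), 10)
    expect_lt(abs(mean(isi) - expected) / expected, case$tol)
  }
})

test_that("compiled integrator agrees with the R reference scheme (noise-free)", {
  st <- tiny_ei_state()
  cfg <- sim_config(noise_variance = 0)
  cur <- c(3, 0, 0, 0, 0, 0)
  res <- step_network(st, cur, cfg, rule = NULL, n_steps = 25L)
  ref <- r_heun_steps(st, cur, cfg, 25L)
  expect_equal(res$state$phases, ref$phases, tolerance = 1e-12)
})

test_that("one noise-free step is first-order consistent with the drift", {
  st <- tiny_ei_state()
  for (dt in c(1e-3, 1e-4, 1e-5)) {
    cfg <- sim_config(dt = dt, noise_variance = 0)
    res <- step_network(st, numeric(6), cfg)
    expect_equal(res$state$phases,
                 wrap_phase(st$phases + phase_drift(st, numeric(6), cfg) * dt),
                 tolerance = 10 * dt)
  }
})

test_that("identical neurons at identical phases stay identical", {
  N <- 5
  w <- matrix(0.4, N, N); diag(w) <- 0
  st <- network_state(rep(1.2, N), w, "excitatory", rep(1.5, N))
  cfg <- sim_config(noise_variance = 0)
  res <- step_network(st, numeric(N), cfg, n_steps = 500L)
  expect_equal(max(res$state$phases) - min(res$state$phases), 0)
})

test_that("spikes coincide with wrap events through +pi", {
  st <- network_state(3.0, matrix(0, 1, 1), "excitatory", 1.5)
  cfg <- sim_config(g = 0, noise_variance = 0)
  out <- step_network(st, 0, cfg, n_steps = 200L)
  spikes <- out$spikes
  # re-integrate step by step and compare wrap times
  s <- st
  wraps <- c()
  for (k in 1:200) {
    prev <- s$phases
    one <- step_network(s, 0, cfg)
    s <- one$state
    if (s$phases < prev) wraps <- c(wraps, k)
  }
  expect_equal(nrow(spikes), length(wraps))
  expect_true(all(spikes$neuron == 1L))
})

test_that("init_network respects sizes, signs and determinism", {
  cfg <- sim_config()
  set.seed(7)
  st <- init_network(100, 20, "ei", cfg)
  expect_equal(sum(st$types == "excitatory"), 80)
  expect_equal(sum(st$types == "inhibitory"), 20)
  expect_true(all(st$weights[, 1:80] >= 0 & st$weights[, 1:80] <= 1))
  expect_true(all(st$weights[, 81:100] >= -1 & st$weights[, 81:100] <= 0))
  expect_true(all(diag(st$weights) == 0))
  expect_true(all(st$phases >= -pi & st$phases < pi))

  set.seed(7)
  st2 <- init_network(100, 20, "ei", cfg)
  expect_identical(st, st2)

  set.seed(1)
  expect_equal(init_network(1, 0, "ei", cfg)$weights, matrix(0, 1, 1))
  expect_error(init_network(10, 2, "excitatory_only", cfg), "n_inhibitory")

  set.seed(3)
  stu <- init_network(10, 0, "unlabelled", cfg)
  expect_true(any(stu$weights < 0) && any(stu$weights > 0))
  expect_true(all(abs(stu$weights) <= 1))
})

test_that("noise-free multi-step runs are deterministic", {
  st <- tiny_ei_state()
  cfg <- sim_config(noise_variance = 0)
  r1 <- simulate_network(st, 5, cfg, record_every = 0)
  r2 <- simulate_network(st, 5, cfg, record_every = 0)
  expect_identical(r1$state$phases, r2$state$phases)
})

test_that("state invariants are enforced", {
  expect_error(network_state(c(0, 0), matrix(0.5, 2, 2),
                             c("inhibitory", "inhibitory"), c(1, 1)),
               "bounds")
  st <- tiny_ei_state()
  st$phases[1] <- 10
  expect_error(validate_network_state(st), "phases")
  expect_error(sim_config(dt = -1), "dt")
  expect_error(sim_config(noise_variance = -0.1), "noise_variance")
})
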