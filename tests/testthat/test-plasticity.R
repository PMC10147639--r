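test_that("kernel closed-form values and periodicity", {
  expect_equal(kernel_lambda0(0), 1)
  expect_equal(kernel_lambda0(pi), -1)
  expect_equal(kernel_lambda0(pi / 2), 0)

  # direct evaluation of the two-branch form
  expect_equal(kernel_lambda1(0), 1 - exp(-2 * pi))
  expect_equal(kernel_lambda1(-pi), exp(-10 * pi) - 1)
  expect_equal(kernel_lambda1(0.3), kernel_lambda1(0.3 + 2 * pi))
  expect_equal(kernel_lambda1(-2.2), kernel_lambda1(-2.2 - 6 * pi))

  # the kernel is even: both branches agree on mirrored arguments
  x <- seq(0.01, 3.1, by = 0.17)
  expect_equal(kernel_lambda1(x), kernel_lambda1(-x))
})

test_that("kernel branch joins are continuous and lobes have 5:1 widths", {
  h <- 1e-10
  expect_lt(abs(kernel_lambda1(h) - kernel_lambda1(-h)), 1e-9)
  expect_lt(abs(kernel_lambda1(pi - h) - kernel_lambda1(-pi + h)), 1e-9)

  # e-fold widths measured from the dominant exponentials of each lobe:
  # potentiation term drops by e over 0.1 rad, depression term over 0.5 rad
  pot <- function(x) exp(-x / 0.1)
  dep <- function(x) -exp((x - pi) / 0.5)
  w_pot <- uniroot(function(x) pot(x) - pot(0) / exp(1), c(0, 1),
                   tol = 1e-12)$root
  w_dep <- uniroot(function(x) dep(pi - x) - dep(pi) / exp(1), c(0, 2),
                   tol = 1e-12)$root
  expect_equal(w_dep / w_pot, 5, tolerance = 1e-9)

  # extrema of the two kernels agree to within 2e-3
  grid <- seq(-pi, pi, length.out = 20001)
  expect_lt(abs(max(kernel_lambda1(grid)) - max(kernel_lambda0(grid))), 2e-3)
  expect_lt(abs(min(kernel_lambda1(grid)) - min(kernel_lambda0(grid))), 2e-3)
  expect_lt(abs(grid[which.max(kernel_lambda1(grid))]), 1e-3)
})

test_that("weight derivative honours soft bounds and gating", {
  rule <- plasticity_rule(dale_mode = "ei")
  expect_equal(weight_derivative(0, 0.1, rule = rule), 0)
  expect_equal(weight_derivative(1, 0.1, rule = rule), 0)
  # fast gate applies only to excitatory-excitatory synapses
  slow <- weight_derivative(0.5, 0, pre_stimulated = FALSE, rule = rule)
  fast <- weight_derivative(0.5, 0, pre_stimulated = TRUE, rule = rule)
  expect_equal(fast / slow, (1e-5 + 0.1) / 1e-5)
  ei_slow <- weight_derivative(0.5, 0, pre_type = "excitatory",
                               post_type = "inhibitory",
                               pre_stimulated = TRUE, rule = rule)
  expect_equal(ei_slow, slow)
  # inhibitory pre-synaptic weight in phase is driven towards zero
  d_inh <- weight_derivative(-0.5, 0, pre_type = "inhibitory",
                             post_type = "excitatory", rule = rule)
  expect_gt(d_inh, 0)
  # and towards -1 in anti-phase
  d_inh_ap <- weight_derivative(-0.5, pi, pre_type = "inhibitory",
                                post_type = "excitatory", rule = rule)
  expect_lt(d_inh_ap, 0)
  expect_error(weight_derivative(1.5, 0, rule = rule), "kappa")
  expect_error(weight_derivative(0.5, 0, pre_type = "inhibitory", rule = rule),
               "kappa")
})

test_that("unlabelled weights relax exponentially to the kernel value", {
  rule <- plasticity_rule(kernel = "cosine", eps_slow = 1e-3,
                          dale_mode = "unlabelled")
  dtheta <- 0.8
  k0 <- -0.4
  # closed-form solution of dk/dt = eps (-k + Lambda0)
  t_end <- 500
  expected <- cos(dtheta) + (k0 - cos(dtheta)) * exp(-1e-3 * t_end)
  # numerical Euler integration with the package derivative
  k <- k0
  dt <- 0.05
  for (i in seq_len(t_end / dt))
    k <- k + dt * weight_derivative(k, dtheta, rule = rule)
  # first-order Euler discretisation error at this step size
  expect_equal(k, expected, tolerance = 1e-3)
})

test_that("update_weights potentiates in phase and depresses in anti-phase", {
  rule <- plasticity_rule(eps_slow = 1e-3, dale_mode = "ei")
  N <- 4
  w <- matrix(0.5, N, N); diag(w) <- 0
  st <- network_state(rep(0.2, N), w, "excitatory", rep(1.5, N))
  up <- update_weights(st, numeric(N), rule, dt = 0.01)
  off <- upper.tri(w) | lower.tri(w)
  expect_true(all(up$weights[off] > 0.5))

  st$phases <- c(0, 0, pi - 0.01, pi - 0.01)
  up2 <- update_weights(st, numeric(N), rule, dt = 0.01)
  expect_true(all(up2$weights[1:2, 3:4] < 0.5))
  expect_true(all(up2$weights[3:4, 1:2] < 0.5))
  expect_true(all(up2$weights[1, 2] > 0.5))

  # unstimulated slow update obeys the factored derivative bound
  delta <- abs(up$weights - w)[off]
  expect_true(all(delta <= 1e-3 * 0.01 * 0.25 * max(abs(kernel_lambda1(seq(-pi, pi, 0.01)))) + 1e-15))
})

test_that("compiled weight update matches the R reference elementwise", {
  for (mode in c("ei", "unlabelled")) {
    set.seed(11)
    st <- if (mode == "ei") init_network(8, 3, "ei")
          else init_network(8, 0, "unlabelled")
    rule <- plasticity_rule(
      kernel = if (mode == "unlabelled") "cosine" else "asymmetric_exponential",
      eps_slow = 1e-2, eps_fast = 0.2, dale_mode = mode)
    cfg <- sim_config(noise_variance = 0)
    cur <- c(3, 3, 0, 0, 0, 0, 0, 0)
    out <- step_network(st, cur, cfg, rule, n_steps = 1L)
    # reference: advance phases with the R scheme, then one R weight step
    ref_state <- r_heun_steps(st, cur, cfg, 1L)
    ref <- update_weights(ref_state, cur, rule, cfg$dt)
    expect_equal(out$state$weights, ref$weights, tolerance = 2e-5)
  }
})

test_that("E-E weight pairs symmetrise under the unstimulated rule", {
  rule <- plasticity_rule(eps_slow = 5e-3, dale_mode = "ei")
  w <- matrix(c(0, 0.8, 0.2, 0), 2, 2)
  st <- network_state(c(0.1, 0.4), w, "excitatory", c(1.5, 1.5))
  gaps <- numeric(200)
  for (i in 1:200) {
    st <- update_weights(st, c(0, 0), rule, dt = 1)
    gaps[i] <- abs(st$weights[1, 2] - st$weights[2, 1])
  }
  expect_true(all(diff(gaps) <= 1e-12))
  expect_lt(gaps[200], abs(0.8 - 0.2))
})

test_that("plasticity rule validates its rates", {
  expect_error(plasticity_rule(eps_slow = 0.5, eps_fast = 0.1), "rates")
  expect_error(plasticity_rule(eps_slow = 0, eps_fast = 0.1), "rates")
  expect_silent(plasticity_rule(eps_slow = 1e-3, eps_fast = 0.1))
})
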