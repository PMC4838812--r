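test_that("a fixed seed makes simulations bit-identical", {
  m <- wendling_model(B = 40)
  for (sch in c("euler_classical", "rk4_classical", "euler_sde")) {
    s1 <- simulate(m, seed = 5, scheme = sch, h = 1e-3, duration = 1)
    s2 <- simulate(m, seed = 5, scheme = sch, h = 1e-3, duration = 1)
    expect_identical(s1$y_out, s2$y_out)
  }
  # a seeded call must not disturb the caller's RNG stream
  set.seed(99); before <- stats::rnorm(1)
  set.seed(99); invisible(simulate(m, seed = 5, duration = 0.1))
  expect_identical(stats::rnorm(1), before)
})

test_that("with no noise the dynamics rest at a stable fixed point", {
  m <- wendling_model(B = 45, input_variance = 0)
  s0 <- refine_equilibrium(m, equilibrium_state(m, nullcline_roots(m)[1]))
  for (sch in c("euler_classical", "rk4_classical")) {
    sim <- simulate(m, scheme = sch, h = 1e-3, duration = 10, init = s0)
    expect_lt(max(abs(sim$y_out - output_full(s0))), 1e-6)
    expect_lt(max(abs(attr(sim, "final_state") - s0)), 1e-6)
  }
})

test_that("stochastic Euler reduces to classical Euler at the reference step", {
  m <- wendling_model(B = 40)
  s1 <- simulate(m, seed = 7, scheme = "euler_classical", h = 1e-3,
                 duration = 10)
  s2 <- simulate(m, seed = 7, scheme = "euler_sde", h = 1e-3, duration = 10)
  expect_lt(max(abs(s1$y_out - s2$y_out)), 1e-10)
})

test_that("full and reduced systems produce identical output trajectories", {
  m <- wendling_model(B = 40)
  for (sch in c("euler_classical", "rk4_classical", "euler_sde")) {
    sf <- simulate(m, seed = 3, scheme = sch, h = 1e-3, duration = 10,
                   system = "full")
    sr <- simulate(m, seed = 3, scheme = sch, h = 1e-3, duration = 10,
                   system = "reduced")
    expect_lt(max(abs(sf$y_out - sr$y_out)), 1e-9)
  }
})

test_that("classical output variance scales with the step size", {
  m <- wendling_model(B = 40)
  v <- sapply(c(1e-3, 1e-4), function(h) output_variance(
    simulate(m, seed = 2, scheme = "rk4_classical", h = h, duration = 6),
    discard = 1))
  expect_gt(v[1] / v[2], 5)     # a decade of h loses about a decade of power
  expect_lt(v[1] / v[2], 20)
})

test_that("corrected-scheme variance is stable across step sizes", {
  m <- wendling_model(B = 40)
  v <- sapply(c(1e-3, 1e-5), function(h) output_variance(
    simulate(m, seed = 2, scheme = "euler_sde", h = h, duration = 6),
    discard = 1))
  expect_gt(v[2] / v[1], 0.5)
  expect_lt(v[2] / v[1], 1.2)
})

test_that("divergence aborts with a step-numbered diagnostic", {
  m <- wendling_model(B = 40)
  expect_error(simulate(m, seed = 1, scheme = "euler_classical", h = 0.5,
                        duration = 500),
               "non-finite state at step")
})

test_that("integrator configuration is validated", {
  m <- wendling_model()
  expect_error(simulate(m, duration = 0), "duration")
  expect_error(simulate(m, h = 0), "h must be")
  expect_error(simulate(m, init = rep(0, 3)), "length 10")
  expect_error(simulate(m, system = "reduced", init = rep(0, 10)),
               "length 8")
})

test_that("record_states keeps the full trajectory", {
  m <- wendling_model(B = 40)
  sim <- simulate(m, seed = 1, h = 1e-3, duration = 0.1,
                  record_states = TRUE)
  st <- attr(sim, "states")
  expect_equal(dim(st), c(101L, 10L))
  expect_equal(st[101, ], attr(sim, "final_state"))
  expect_equal(sim$y_out, st[, 2] - st[, 3] - st[, 4])
})

test_that("output_variance uses the population convention", {
  expect_equal(output_variance(rep(3, 10)), 0)
  expect_equal(output_variance(rep(c(0, 1), 50)), 0.25)
  expect_error(output_variance(numeric(0)), "empty")
  m <- wendling_model(B = 40)
  sim <- simulate(m, seed = 1, duration = 1)
  expect_error(output_variance(sim, discard = 2), "empty")
})
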