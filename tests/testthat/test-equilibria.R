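test_that("nullcline solver recovers every published equilibrium", {
  ref <- reference_equilibria()
  for (B in unique(ref$B)) {
    want <- ref[ref$B == B, ]
    eq <- equilibria(phase_model(B), input_mean = 90)
    expect_equal(nrow(eq), nrow(want))
    expect_lt(max(abs(eq$y_out - want$y_out)), 0.005)
    for (col in c("y0", "y1", "y2", "y3", "y4"))
      expect_lt(max(abs(eq[[col]] - want[[col]])), 0.005)
    expect_equal(eq$stability, want$stability)
  }
})

test_that("nullcline roots satisfy the fixed-point equations tightly", {
  for (B in c(45, 38, 8)) {
    m <- phase_model(B)
    for (rt in nullcline_roots(m, input_mean = 90)) {
      s <- equilibrium_state(m, rt, input_mean = 90)
      expect_lt(abs(output_full(s) - rt), 1e-9)
      expect_lt(max(abs(drift_full(s, m, input_rate = 90))), 1e-9)
    }
  }
})

test_that("a bracket far above saturation contains no roots", {
  expect_length(nullcline_roots(phase_model(45), bracket = c(100, 200)), 0)
})

test_that("nullcline_roots validates its arguments", {
  m <- phase_model(45)
  expect_error(nullcline_roots(m, grid = 0), "grid")
  expect_error(nullcline_roots(m, bracket = c(3, 1)), "bracket")
})

test_that("analytic Jacobian matches finite differences of the drift", {
  set.seed(33)
  m <- wendling_model(B = 12, G = 25)
  for (k in 1:5) {
    s <- stats::runif(10, -2, 2)
    J <- jacobian_matrix(m, s, "full")
    Jfd <- fd_jacobian(m, s, "full")
    expect_lt(max(abs(J - Jfd)) / max(abs(Jfd)), 1e-6)
    z <- stats::runif(8, -2, 2)
    J8 <- jacobian_matrix(m, z, "reduced")
    J8fd <- fd_jacobian(m, z, "reduced")
    expect_lt(max(abs(J8 - J8fd)) / max(abs(J8fd)), 1e-6)
  }
})

test_that("eigenvalues come in conjugate pairs and include the double -b", {
  ref <- reference_equilibria()
  for (i in seq_len(nrow(ref))) {
    m <- phase_model(ref$B[i])
    s <- equilibrium_state(m, nullcline_roots(m)[
      which.min(abs(nullcline_roots(m) - ref$y_out[i]))])
    ev <- eigen(jacobian_matrix(m, s, "full"), only.values = TRUE)$values
    # conjugate symmetry (real matrix)
    expect_lt(max(abs(sort(Im(ev)) + rev(sort(Im(ev))))), 1e-8)
    # the decoupled redundant PSP pair contributes -b twice (a double
    # root splits by ~sqrt(machine eps) in a dense eigensolver)
    expect_equal(sum(abs(ev + 50) < 1e-3), 2)
  }
})

test_that("full spectrum equals reduced spectrum plus the double -b", {
  for (B in c(45, 37, 8)) {
    m <- phase_model(B)
    for (rt in nullcline_roots(m)) {
      s <- equilibrium_state(m, rt)
      z <- full_to_reduced(s, m, tol = 1e-8)
      ev_full <- eigen(jacobian_matrix(m, s, "full"),
                       only.values = TRUE)$values
      ev_red <- eigen(jacobian_matrix(m, z, "reduced"),
                      only.values = TRUE)$values
      expect_spectrum_close(ev_full, c(ev_red, -50, -50), 1e-6, relative = TRUE)
    }
  }
})

test_that("stability classification follows the eigenvalue real parts", {
  expect_equal(classify_stability(c(-1, -2, -3)), "stable")
  expect_equal(classify_stability(complex(real = c(-50, 20.3),
                                          imaginary = c(0, 89.2))),
               "unstable")
  expect_equal(classify_stability(c(-1, 1e-9)), "marginal")
  expect_error(classify_stability(numeric(0)), "empty")
  expect_error(classify_stability(c(-1), tol = -1), "tol")
})
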