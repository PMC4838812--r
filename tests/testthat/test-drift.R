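test_that("every published point is a rounded true equilibrium", {
  # The raw drift at a 3-decimal-rounded state is amplified by the a^2,
  # b^2, g^2 coefficients (up to ~1e3 mV/s^2 here), so the meaningful
  # check is that Newton refinement from each printed seed lands on an
  # exact fixed point within print rounding of the seed.
  ref <- reference_equilibria()
  for (i in seq_len(nrow(ref))) {
    m <- phase_model(ref$B[i])
    seed_state <- ref_state(ref[i, ])
    s <- refine_equilibrium(m, seed_state, input_rate = 90)
    expect_lt(max(abs(drift_full(s, m, 90))), 1e-9)
    expect_lt(max(abs(s - seed_state)), 2e-3)
    expect_lt(abs(output_full(s) - ref$y_out[i]), 5e-4)
  }
})

test_that("zero state with zero input exposes the drift structure", {
  m <- wendling_model()
  d <- drift_full(rep(0, 10), m, input_rate = 0)
  expect_equal(d[1:5], rep(0, 5))
  expect_equal(d[6], m$A * m$a * sigmoid(0))
  dr <- drift_reduced(rep(0, 8), m, input_rate = 0)
  expect_equal(dr[1:4], rep(0, 4))
})

test_that("drift agrees with an independent transcription of the equations", {
  set.seed(11)
  m <- wendling_model(B = 38, G = 15)
  for (k in 1:20) {
    y <- stats::runif(10, -5, 5)
    p <- stats::runif(1, 0, 200)
    a <- drift_full(y, m, p)
    b <- oracle_drift_full(y, m, p)
    expect_lt(max(abs(a - b) / pmax(abs(b), 1)), 1e-12)
    z <- stats::runif(8, -5, 5)
    ar <- drift_reduced(z, m, p)
    br <- oracle_drift_reduced(z, m, p)
    expect_lt(max(abs(ar - br) / pmax(abs(br), 1)), 1e-12)
  }
})

test_that("output projections follow the pyramidal membrane sum", {
  expect_equal(output_full(c(0, 6.097, 5.882, 0.339, rep(0, 6))), -0.124)
  expect_equal(output_full(rep(0, 10)), 0)
  expect_equal(output_full(c(0, 1, 1, 0, rep(0, 6))), 0)
  expect_equal(output_reduced(rep(0, 8)), 0)
  m <- wendling_model()
  set.seed(4)
  for (k in 1:10) {
    s <- random_consistent_full_state(m)
    expect_equal(output_reduced(full_to_reduced(s, m), C4 = m$C4),
                 output_full(s))
  }
})

test_that("full/reduced state maps round-trip and reject inconsistent states", {
  m <- wendling_model()
  expect_equal(full_to_reduced(rep(0, 10), m), rep(0, 8))
  expect_equal(reduced_to_full(rep(0, 8), m), rep(0, 10))
  set.seed(21)
  for (k in 1:20) {
    s <- random_consistent_full_state(m)
    expect_lt(max(abs(reduced_to_full(full_to_reduced(s, m), m) - s)), 1e-12)
  }
  bad <- rep(1, 10)                    # y2 != C4 * y4
  expect_error(full_to_reduced(bad, m), "not reducible")
  # printed Phase-1 point: old y2 = C4 * old y4 holds to print rounding
  ref <- reference_equilibria()[1, ]
  expect_lt(abs(ref$y2 - 33.75 * ref$y4), 0.02)
  expect_silent(full_to_reduced(ref_state(ref), m, tol = 0.02))
})

test_that("the reduced image of a published equilibrium is also at rest", {
  ref <- reference_equilibria()
  m <- phase_model(45)
  s <- refine_equilibrium(m, ref_state(ref[1, ]), input_rate = 90)
  z <- full_to_reduced(s, m, tol = 1e-8)
  expect_lt(max(abs(drift_reduced(z, m, input_rate = 90))), 1e-9)
})

test_that("drift rejects malformed states", {
  m <- wendling_model()
  expect_error(drift_full(rep(0, 9), m))
  expect_error(drift_reduced(rep(0, 10), m))
})
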