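mk_counts <- function(counts, basis = "ZZZ", shots = sum(counts), seed = 0L) {
  full <- stats::setNames(integer(8), vapply(0:7, function(i) {
    paste0(bitwAnd(bitwShiftR(i, 2:0), 1L), collapse = "")
  }, character(1)))
  full[names(counts)] <- as.integer(counts)
  structure(
    list(counts = full, shots = as.integer(shots), seed = seed, basis = basis),
    class = "shot_counts"
  )
}

test_that("parity expectation from counts matches hand-computed cases", {
  expect_equal(expectation_from_counts(mk_counts(c("000" = 1000)), "ZZZ")$value, 1)
  expect_equal(
    expectation_from_counts(mk_counts(c("000" = 500, "111" = 500)), "ZZZ")$value, 0
  )
  est <- expectation_from_counts(mk_counts(c("000" = 600, "111" = 400)), "ZZZ")
  expect_equal(est$value, 0.2)
  expect_equal(est$stderr, sqrt((1 - 0.2^2) / 1000))
  # single-qubit parity on the rightmost qubit
  expect_equal(
    expectation_from_counts(mk_counts(c("000" = 500, "111" = 500)), "IIZ")$value, 0
  )
  # support restricted to qubits 0 and 2: "110" has one support 1-bit
  expect_equal(
    expectation_from_counts(mk_counts(c("110" = 300, "000" = 700)), "ZIZ")$value,
    (700 - 300) / 1000
  )
})

test_that("estimates from counts refuse a mismatched measurement basis", {
  zc <- mk_counts(c("000" = 1000), basis = "ZZZ")
  expect_error(expectation_from_counts(zc, "XIX"), "basis mismatch")
  xc <- mk_counts(c("000" = 1000), basis = "XZX")
  expect_equal(expectation_from_counts(xc, "XIX")$value, 1)
  expect_error(expectation_from_counts(xc, "ZZZ"), "basis mismatch")
})

test_that("pauli_observable validates labels and derives support", {
  obs <- pauli_observable("ZIZ")
  expect_identical(obs$support, c(0L, 2L))
  expect_error(pauli_observable("ZY?"), "over \\{I, Z, X\\}")
  expect_error(pauli_observable("ZZ"), "3 characters")
})

test_that("exact expectations reproduce the trace oracle on encoded states", {
  for (t in c(0, 0.035, 0.5, 0.8, 1)) {
    rho <- run_circuit(build_circuit(angle_from_similarity(t)), mode = "exact")$rho
    expect_equal(exact_expectation(rho, "III")$value, 1, tolerance = 1e-12)
    expect_equal(exact_expectation(rho, "ZZZ")$value, 2 * t - 1, tolerance = 1e-12)
    # single- and two-qubit Z marginals of the GHZ-like state
    for (lbl in c("IIZ", "IZI", "ZII")) {
      expect_equal(exact_expectation(rho, lbl)$value, 2 * t - 1, tolerance = 1e-12)
    }
    for (lbl in c("ZIZ", "ZZI", "IZZ")) {
      expect_equal(exact_expectation(rho, lbl)$value, 1, tolerance = 1e-12)
    }
    # X observables vanish identically: destructive-interference diagnostic
    for (lbl in c("IIX", "IXI", "XII", "XIX", "XXI", "IXX")) {
      expect_equal(exact_expectation(rho, lbl)$value, 0, tolerance = 1e-12)
    }
    # cross-check every label against the independent element-sum oracle
    for (lbl in c("ZZZ", "IIZ", "ZIZ", "XIX", "IXI")) {
      expect_equal(exact_expectation(rho, lbl)$value, o_expect(rho, lbl),
        tolerance = 1e-12)
    }
  }
})

test_that("counts-based estimates converge to exact values with shots", {
  t <- 0.3
  p <- 0.02
  circ <- build_circuit(angle_from_similarity(t))
  rho <- run_circuit(circ, noise = noise_spec(p), mode = "exact")$rho
  exact <- exact_expectation(rho, "ZZZ")$value
  cts <- sample_counts(rho, shots = 100000, seed = 5)
  est <- expectation_from_counts(cts, "ZZZ")
  expect_lt(abs(est$value - exact), 5 * est$stderr)
})

test_that("probability deltas divide counts correctly and sum to zero", {
  ideal <- mk_counts(c("000" = 1000))
  noisy <- mk_counts(c("000" = 900, "001" = 100))
  pd <- probability_deltas(ideal, noisy)
  expect_equal(nrow(pd), 8)
  expect_equal(pd$delta[pd$outcome == "000"], 0.1)
  expect_equal(pd$delta[pd$outcome == "001"], -0.1)
  expect_equal(sum(pd$delta), 0)
  expect_equal(sum(pd$p_ideal), 1)
  expect_equal(sum(pd$p_noisy), 1)
  same <- probability_deltas(ideal, ideal)
  expect_true(all(same$delta == 0))
  xbasis <- mk_counts(c("000" = 100), basis = "XZZ")
  expect_error(probability_deltas(ideal, xbasis), "Z-basis")
})

test_that("product approximation composes, clips, and flags itself", {
  expect_equal(product_approx_zzz(list(ZIZ = 1, IZI = 1))$value, 1)
  expect_equal(product_approx_zzz(list(ZIZ = -0.9, IZI = -0.9))$value, 0.81)
  est <- product_approx_zzz(list(ZIZ = -1.3, IZI = 1))
  expect_equal(est$value, -1) # projected onto [-1, 1]
  expect_true(est$approximate)
  expect_error(product_approx_zzz(list(IZI = 1)), "requires estimates")
  # alternative three-factor composition
  expect_equal(
    product_approx_zzz(list(IIZ = 0.9, IZI = 0.9, ZIZ = 0.9),
      composition = "triple"
    )$value,
    0.9^3
  )
  expect_error(
    product_approx_zzz(list(ZIZ = 1, IZI = 1), composition = "triple"),
    "IIZ"
  )
})
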