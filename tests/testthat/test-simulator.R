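test_that("gate application preserves state structure and known identities", {
  circ <- build_circuit(angle_from_similarity(0.3))
  rho <- run_circuit(circ, mode = "exact")$rho
  # identity rotation leaves any state unchanged
  expect_equal(apply_gate(rho, list(name = "ry", theta = 0, qubits = 0L)), rho)
  # CNOT is an involution
  cx <- list(name = "cx", qubits = c(0L, 1L))
  expect_lt(max(Mod(apply_gate(apply_gate(rho, cx), cx) - rho)), 1e-12)
  expect_error(apply_gate(rho, list(name = "swap", qubits = c(0L, 1L))), "unknown gate")
})

test_that("RY(pi/2) + CNOT fan-out prepares the balanced GHZ state", {
  rho <- matrix(0 + 0i, 8, 8)
  rho[1, 1] <- 1
  rho <- apply_gate(rho, list(name = "ry", theta = pi / 2, qubits = 0L))
  rho <- apply_gate(rho, list(name = "cx", qubits = c(0L, 1L)))
  rho <- apply_gate(rho, list(name = "cx", qubits = c(0L, 2L)))
  v <- o_ideal_vec(0.5)
  expect_lt(max(Mod(rho - outer(v, v))), 1e-12)
})

test_that("depolarizing channel limits: p=0 identity, p=1 maximally mixed", {
  circ <- build_circuit(angle_from_similarity(0.7))
  rho <- run_circuit(circ, mode = "exact")$rho
  expect_equal(depolarize(rho, 0:2, 0), rho)
  mixed <- depolarize(rho, 0:2, 1)
  expect_equal(Re(diag(mixed)), rep(1 / 8, 8))
  expect_lt(max(Mod(mixed - diag(8) / 8)), 1e-12)
  expect_error(depolarize(rho, 0:2, 1.2), "\\[0, 1\\]")
})

test_that("single-qubit depolarization shrinks <Z> by (1 - p)", {
  rho0 <- matrix(0 + 0i, 8, 8)
  rho0[1, 1] <- 1 # |000>
  for (p in c(0.1, 0.5, 0.9)) {
    for (q in 0:2) {
      rho <- depolarize(rho0, q, p)
      lbl <- paste(replace(rep("I", 3), q + 1, "Z"), collapse = "")
      expect_equal(exact_expectation(rho, lbl)$value, 1 - p, tolerance = 1e-12)
      validate_density_matrix(rho)
    }
  }
})

test_that("depolarize agrees with the Pauli-sum oracle on arbitrary subsets", {
  circ <- build_circuit(angle_from_similarity(0.3))
  rho <- run_circuit(circ, mode = "exact")$rho
  for (qs in list(0L, 1L, c(0L, 1L), c(0L, 2L), c(1L, 2L), 0:2)) {
    expect_lt(max(Mod(depolarize(rho, qs, 0.07) - o_depol(rho, qs, 0.07))), 1e-12)
  }
})

test_that("every simulation step keeps the state a valid density matrix", {
  for (t in c(0, 0.5, 1)) {
    for (p in c(0, 0.05, 0.3)) {
      circ <- build_circuit(angle_from_similarity(t))
      res <- run_circuit(circ, noise = if (p > 0) noise_spec(p) else NULL,
        mode = "exact")
      expect_silent(validate_density_matrix(res$rho))
    }
  }
  expect_error(
    validate_density_matrix(diag(8) + 0i), "trace"
  )
  bad <- diag(c(1.5, -0.5, rep(0, 6))) + 0i
  expect_error(validate_density_matrix(bad), "negative eigenvalue")
})

test_that("noisy <ZZZ> follows the closed form (1-p)^2 (2T-1) and the oracle", {
  for (t in c(0, 0.035, 0.25, 0.5, 0.75, 1)) {
    for (p in c(0, 0.001, 0.01, 0.05, 0.1, 0.2)) {
      circ <- build_circuit(angle_from_similarity(t))
      rho <- run_circuit(circ, noise = if (p > 0) noise_spec(p) else NULL,
        mode = "exact")$rho
      zzz <- exact_expectation(rho, "ZZZ")$value
      expect_equal(zzz, (1 - p)^2 * (2 * t - 1), tolerance = 1e-10)
      expect_lt(max(Mod(rho - o_run(t, p))), 1e-10)
    }
  }
})

test_that("the three-qubit-arity channel matches the global-depolarization oracle", {
  for (t in c(0.035, 0.5, 1)) {
    for (p in c(0.01, 0.1)) {
      circ <- build_circuit(angle_from_similarity(t))
      rho <- run_circuit(circ, noise = noise_spec(p, arity = "three_qubit"),
        mode = "exact")$rho
      expect_lt(max(Mod(rho - o_run(t, p, arity = "three_qubit"))), 1e-10)
      # a k-qubit depolarizing event still shrinks ZZZ by exactly (1 - p)
      expect_equal(exact_expectation(rho, "ZZZ")$value,
        (1 - p)^2 * (2 * t - 1), tolerance = 1e-10)
    }
  }
})

test_that("noiseless shot sampling is deterministic and concentrated", {
  circ1 <- build_circuit(angle_from_similarity(1))
  r1 <- run_circuit(circ1, mode = "shots", shots = 1000, seed = 11)
  expect_identical(unname(r1$counts$counts["000"]), 1000L)
  expect_identical(sum(r1$counts$counts), 1000L)

  circ <- build_circuit(angle_from_similarity(0.5))
  a <- run_circuit(circ, mode = "shots", shots = 1000, seed = 7)$counts
  b <- run_circuit(circ, mode = "shots", shots = 1000, seed = 7)$counts
  expect_identical(a$counts, b$counts)
  # only the two correlated outcomes carry probability
  off <- setdiff(names(a$counts), c("000", "111"))
  expect_true(all(a$counts[off] == 0L))
})

test_that("sampling the maximally mixed state is uniform within 4 sd", {
  mixed <- diag(8) / 8 + 0i
  shots <- 40000L
  cts <- sample_counts(mixed, shots = shots, seed = 3)
  expected <- shots / 8
  sd <- sqrt(shots * (1 / 8) * (7 / 8))
  expect_true(all(abs(cts$counts - expected) < 4 * sd))
})

test_that("noiseless shot distribution passes a chi-square test vs the ideal", {
  t <- 0.3
  circ <- build_circuit(angle_from_similarity(t))
  pvals <- vapply(1:5, function(s) {
    cts <- run_circuit(circ, mode = "shots", shots = 10000, seed = s)$counts
    obs <- c(cts$counts[["000"]], cts$counts[["111"]])
    suppressWarnings(
      stats::chisq.test(obs, p = c(t, 1 - t))$p.value
    )
  }, numeric(1))
  expect_true(all(pvals > 0.01))
})

test_that("sampling refuses a meaningfully negative diagonal", {
  bad <- diag(c(1.1, -0.1, rep(0, 6))) + 0i
  expect_error(sample_counts(bad, 100, seed = 1), "negative probability")
})

test_that("counts serialize to JSON with seed, basis and bit-order provenance", {
  circ <- build_circuit(angle_from_similarity(0.5))
  cts <- run_circuit(circ, mode = "shots", shots = 1000, seed = 42)$counts
  parsed <- jsonlite::fromJSON(counts_to_json(cts))
  expect_equal(parsed$shots, 1000)
  expect_equal(parsed$seed, 42)
  expect_equal(parsed$basis, "ZZZ")
  expect_match(parsed$bit_order, "qubit 0")
  expect_equal(sum(unlist(parsed$counts)), 1000)
})
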