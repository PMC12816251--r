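test_that("angle anchors: T=1 -> 0, T=0 -> pi, T=0.5 -> pi/2", {
  expect_equal(angle_from_similarity(1)$theta, 0)
  expect_equal(angle_from_similarity(0)$theta, pi)
  expect_equal(angle_from_similarity(0.5)$theta, pi / 2)
})

test_that("T -> theta -> T round trip is the identity on a dense grid", {
  grid <- seq(0, 1, length.out = 1001)
  back <- vapply(
    grid, function(t) similarity_from_angle(angle_from_similarity(t)),
    numeric(1)
  )
  expect_true(all(abs(back - grid) < 1e-12))
})

test_that("theta is strictly decreasing in T and stays in [0, pi]", {
  grid <- seq(0, 1, length.out = 101)
  thetas <- vapply(grid, function(t) angle_from_similarity(t)$theta, numeric(1))
  expect_true(all(diff(thetas) < 0))
  expect_true(all(thetas >= 0 & thetas <= pi))
})

test_that("angle maps reject out-of-domain inputs", {
  expect_error(angle_from_similarity(-0.01), "\\[0, 1\\]")
  expect_error(angle_from_similarity(1.01), "\\[0, 1\\]")
  expect_error(similarity_from_angle(-0.1), "\\[0, pi\\]")
  expect_error(similarity_from_angle(pi + 0.1), "\\[0, pi\\]")
})

test_that("circuit structure: one RY on q0, CNOT fan-out, full measurement", {
  circ <- build_circuit(angle_from_similarity(0.5))
  names <- vapply(circ$gates, `[[`, character(1), "name")
  expect_identical(names, c("ry", "cx", "cx", "measure"))
  expect_equal(circ$gates[[1]]$theta, pi / 2)
  expect_identical(circ$gates[[1]]$qubits, 0L)
  expect_identical(circ$gates[[2]]$qubits, c(0L, 1L))
  expect_identical(circ$gates[[3]]$qubits, c(0L, 2L))
  expect_identical(circ$gates[[4]]$qubits, 0:2)
  # identity rotation at T = 1
  expect_equal(build_circuit(angle_from_similarity(1))$gates[[1]]$theta, 0)
})

test_that("X-basis measurement appends Hadamards on the flagged qubits only", {
  circ <- build_circuit(angle_from_similarity(0.3), measure_basis = "XZX")
  hs <- Filter(function(g) g$name == "h", circ$gates)
  expect_identical(vapply(hs, `[[`, integer(1), "qubits"), c(0L, 2L))
  expect_error(build_circuit(angle_from_similarity(0.3), "XY?"), "over \\{Z, X\\}")
})

test_that("ideal state puts sqrt(T) on 000 and sqrt(1-T) on 111", {
  amps <- ideal_state(angle_from_similarity(0.5))
  expect_equal(unname(amps), c(1 / sqrt(2), 0, 0, 0, 0, 0, 0, 1 / sqrt(2)))
  amps1 <- ideal_state(angle_from_similarity(1))
  expect_equal(unname(amps1), c(1, rep(0, 7)))
  for (t in c(0, 0.035, 0.3, 0.8, 1)) {
    a <- ideal_state(angle_from_similarity(t))
    expect_equal(sum(a^2), 1)
    expect_equal(unname(a^2)[1], t)
    expect_equal(unname(a^2)[8], 1 - t)
    expect_equal(unname(a)[2:7], rep(0, 6))
  }
})

test_that("exact circuit evolution reproduces the ideal state", {
  for (t in c(0, 0.035, 0.25, 0.5, 0.9, 1)) {
    circ <- build_circuit(angle_from_similarity(t))
    rho <- run_circuit(circ, mode = "exact")$rho
    v <- o_ideal_vec(t)
    expect_lt(max(Mod(rho - outer(v, v))), 1e-12)
  }
})

test_that("circuit JSON serialization carries gates and conventions", {
  circ <- build_circuit(angle_from_similarity(0.5), measure_basis = "ZZX")
  parsed <- jsonlite::fromJSON(circuit_to_json(circ), simplifyVector = FALSE)
  expect_equal(parsed$n_qubits, 3)
  expect_equal(parsed$theta, pi / 2)
  expect_equal(parsed$measure_basis, "ZZX")
  expect_match(parsed$bit_order, "qubit 0")
  expect_identical(
    vapply(parsed$gates, `[[`, character(1), "name"),
    c("ry", "cx", "cx", "h", "measure")
  )
})
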