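# Exact 8x8 density-matrix simulation of the 3-qubit encoding circuit.
# Basis index i in 0:7 carries qubit 0 in its most significant bit, so the
# outcome label for index i is the 3-character binary string with qubit 0
# leftmost (matching basis_labels()).

dm_dim <- 8L

#' Depolarizing noise specification
#'
#' Depolarizing noise with probability `p` replaces the state on the affected
#' qubits by the maximally mixed state; it shrinks every nontrivial Pauli
#' expectation on those qubits by `(1 - p)`. By default the channel acts on
#' the two qubits of each CNOT, after that gate. The `"three_qubit"` arity
#' applies a global 3-qubit channel after each CNOT instead (both readings of
#' "depolarizing errors on CX gates" are supported; the choice is a flag).
#'
#' @param p Depolarizing probability in `[0, 1]`.
#' @param arity `"two_qubit"` (channel on the CNOT's qubit pair, default) or
#'   `"three_qubit"` (global channel on all three qubits).
#' @param apply_after Gate-name filter; the channel fires after each matching
#'   gate. Default `"cx"`.
#' @return Object of class `"noise_spec"`.
#' @export
noise_spec <- function(p, arity = c("two_qubit", "three_qubit"),
                       apply_after = "cx") {
  stopifnot(is.numeric(p), length(p) == 1L, is.finite(p))
  if (p < 0 || p > 1) stop("depolarizing probability must lie in [0, 1]")
  arity <- match.arg(arity)
  structure(
    list(p = as.numeric(p), arity = arity, apply_after = apply_after),
    class = "noise_spec"
  )
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf(
    "<depolarizing noise: p = %g, %s channel after each '%s'>\n",
    x$p, x$arity, x$apply_after
  ))
  invisible(x)
}

#' Validate a density matrix
#'
#' Checks Hermiticity, unit trace and positive semi-definiteness (within
#' `tol`). Eigenvalues in `[-tol, 0)` are numerical noise and are accepted;
#' anything more negative is an error.
#'
#' @param rho 8x8 complex matrix.
#' @param tol Numerical tolerance (default `1e-10`).
#' @return `rho`, invisibly, if valid; otherwise an error.
#' @export
validate_density_matrix <- function(rho, tol = 1e-10) {
  stopifnot(is.matrix(rho), all(dim(rho) == dm_dim))
  if (max(Mod(rho - Conj(t(rho)))) > tol) {
    stop("density matrix is not Hermitian within tolerance ", tol)
  }
  tr <- Re(sum(diag(rho)))
  if (abs(tr - 1) > tol) {
    stop("density matrix trace is ", tr, ", not 1 within tolerance ", tol)
  }
  ev <- eigen((rho + Conj(t(rho))) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    stop("density matrix has negative eigenvalue ", min(ev))
  }
  invisible(rho)
}

# |000><000| initial state
initial_density <- function() {
  rho <- matrix(0 + 0i, dm_dim, dm_dim)
  rho[1, 1] <- 1 + 0i
  rho
}

# Single-qubit operators promoted to the 3-qubit register (qubit 0 = leftmost
# factor in the Kronecker product, i.e. most significant bit).
single_qubit_full <- function(u, qubit) {
  id <- diag(2)
  facs <- list(id, id, id)
  facs[[qubit + 1L]] <- u
  kronecker(kronecker(facs[[1]], facs[[2]]), facs[[3]])
}

ry_matrix <- function(theta) {
  matrix(c(
    cos(theta / 2), sin(theta / 2),
    -sin(theta / 2), cos(theta / 2)
  ), 2, 2)
}

hadamard_matrix <- function() matrix(c(1, 1, 1, -1), 2, 2) / sqrt(2)

# CNOT as an 8x8 permutation: flip `target` bit when `control` bit is 1
cnot_matrix <- function(control, target) {
  u <- matrix(0, dm_dim, dm_dim)
  for (i in 0:(dm_dim - 1L)) {
    cbit <- bitwAnd(bitwShiftR(i, 2L - control), 1L)
    j <- if (cbit == 1L) bitwXor(i, bitwShiftL(1L, 2L - target)) else i
    u[j + 1L, i + 1L] <- 1
  }
  u
}

gate_unitary <- function(gate) {
  switch(gate$name,
    ry = single_qubit_full(ry_matrix(gate$theta), gate$qubits[1]),
    h = single_qubit_full(hadamard_matrix(), gate$qubits[1]),
    cx = cnot_matrix(gate$qubits[1], gate$qubits[2]),
    stop("unknown gate: ", gate$name)
  )
}

#' Apply a gate to a density matrix
#'
#' Unitary conjugation `rho' = U rho U^dagger` for the gates of the encoding
#' circuit (`ry` on one qubit, `cx`, `h`). Trace and Hermiticity are
#' preserved exactly by construction.
#'
#' @param rho 8x8 density matrix.
#' @param gate A gate entry `list(name, theta?, qubits)` as in a
#'   `"circuit_spec"`.
#' @export
apply_gate <- function(rho, gate) {
  u <- gate_unitary(gate)
  u %*% rho %*% Conj(t(u))
}

# Partial trace of an 8x8 matrix over a subset of qubits; returns the reduced
# matrix on the remaining qubits (in their original order).
partial_trace <- function(rho, qubits) {
  keep <- setdiff(0:2, qubits)
  dk <- 2L^length(keep)
  out <- matrix(0 + 0i, dk, dk)
  bit <- function(i, q) bitwAnd(bitwShiftR(i, 2L - q), 1L)
  idx_of <- function(bits_keep, bits_tr) {
    i <- 0L
    for (k in seq_along(keep)) i <- i + bitwShiftL(bits_keep[k], 2L - keep[k])
    for (k in seq_along(qubits)) i <- i + bitwShiftL(bits_tr[k], 2L - qubits[k])
    i
  }
  nk <- length(keep)
  nt <- length(qubits)
  for (a in 0:(dk - 1L)) {
    for (b in 0:(dk - 1L)) {
      abits <- if (nk) vapply(seq_len(nk), function(k) bitwAnd(bitwShiftR(a, nk - k), 1L), integer(1)) else integer(0)
      bbits <- if (nk) vapply(seq_len(nk), function(k) bitwAnd(bitwShiftR(b, nk - k), 1L), integer(1)) else integer(0)
      acc <- 0 + 0i
      for (m in 0:(2L^nt - 1L)) {
        mbits <- vapply(seq_len(nt), function(k) bitwAnd(bitwShiftR(m, nt - k), 1L), integer(1))
        acc <- acc + rho[idx_of(abits, mbits) + 1L, idx_of(bbits, mbits) + 1L]
      }
      out[a + 1L, b + 1L] <- acc
    }
  }
  out
}

# Re-tensor a reduced state on `keep` qubits with I/2^k on `qubits`,
# restoring the original qubit ordering.
retensor_mixed <- function(reduced, qubits) {
  keep <- setdiff(0:2, qubits)
  out <- matrix(0 + 0i, dm_dim, dm_dim)
  nk <- length(keep)
  nt <- length(qubits)
  idx_of <- function(bits_keep, bits_tr) {
    i <- 0L
    for (k in seq_along(keep)) i <- i + bitwShiftL(bits_keep[k], 2L - keep[k])
    for (k in seq_along(qubits)) i <- i + bitwShiftL(bits_tr[k], 2L - qubits[k])
    i
  }
  mix <- 1 / 2^nt
  for (a in 0:(2L^nk - 1L)) {
    for (b in 0:(2L^nk - 1L)) {
      abits <- if (nk) vapply(seq_len(nk), function(k) bitwAnd(bitwShiftR(a, nk - k), 1L), integer(1)) else integer(0)
      bbits <- if (nk) vapply(seq_len(nk), function(k) bitwAnd(bitwShiftR(b, nk - k), 1L), integer(1)) else integer(0)
      val <- (if (nk) reduced[a + 1L, b + 1L] else reduced[1, 1]) * mix
      for (m in 0:(2L^nt - 1L)) {
        mbits <- vapply(seq_len(nt), function(k) bitwAnd(bitwShiftR(m, nt - k), 1L), integer(1))
        out[idx_of(abits, mbits) + 1L, idx_of(bbits, mbits) + 1L] <- val
      }
    }
  }
  out
}

#' Apply a depolarizing channel to selected qubits
#'
#' `rho' = (1 - p) * rho + p * (Tr_q rho) (x) I/2^k` where the identity mix
#' sits on the depolarized qubits `q` and the partial trace keeps the rest.
#' With `p = 1` and all three qubits this yields the maximally mixed state
#' (all diagonal entries 1/8). Trace is preserved exactly.
#'
#' @param rho 8x8 density matrix.
#' @param qubits Qubit indices in `{0, 1, 2}` the channel acts on.
#' @param p Depolarizing probability in `[0, 1]`.
#' @export
depolarize <- function(rho, qubits, p) {
  stopifnot(is.numeric(p), length(p) == 1L)
  if (p < 0 || p > 1) stop("depolarizing probability must lie in [0, 1]")
  qubits <- sort(unique(as.integer(qubits)))
  if (!all(qubits %in% 0:2)) stop("qubits must be a subset of {0, 1, 2}")
  if (p == 0) {
    return(rho)
  }
  (1 - p) * rho + p * retensor_mixed(partial_trace(rho, qubits), qubits)
}

#' Sample measurement counts from a density matrix
#'
#' Multinomial draw over the 8 computational-basis probabilities (the diagonal
#' of `rho`), reproducible for a fixed seed. Diagonal entries in
#' `[-1e-10, 0)` are clipped to 0 and the distribution renormalized; larger
#' negativity is an error.
#'
#' @param rho 8x8 density matrix (already rotated into the measurement basis).
#' @param shots Number of measurement repetitions (>= 1).
#' @param seed Integer RNG seed, recorded in the result.
#' @param basis 3-character basis tag stored with the counts (default
#'   `"ZZZ"`).
#' @return Object of class `"shot_counts"`: list with `counts` (named integer
#'   vector over all 8 labels), `shots`, `seed`, `basis`.
#' @export
sample_counts <- function(rho, shots, seed, basis = "ZZZ") {
  stopifnot(shots >= 1L)
  probs <- Re(diag(rho))
  if (min(probs) < -1e-10) {
    stop("density-matrix diagonal has negative probability ", min(probs))
  }
  probs <- pmax(probs, 0)
  probs <- probs / sum(probs)
  draw <- with_seed(seed, stats::rmultinom(1, size = shots, prob = probs)[, 1])
  structure(
    list(
      counts = stats::setNames(as.integer(draw), basis_labels()),
      shots = as.integer(shots), seed = as.integer(seed), basis = basis
    ),
    class = "shot_counts"
  )
}

#' @export
print.shot_counts <- function(x, ...) {
  cat(sprintf(
    "<shot counts: %d shots, basis %s, seed %d>\n", x$shots, x$basis, x$seed
  ))
  nz <- x$counts[x$counts > 0]
  for (lbl in names(nz)) cat(sprintf("  |%s>  %d\n", lbl, nz[[lbl]]))
  invisible(x)
}

#' Serialize shot counts to JSON
#'
#' @param counts A `"shot_counts"` object.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @export
counts_to_json <- function(counts, path = NULL) {
  stopifnot(inherits(counts, "shot_counts"))
  obj <- list(
    basis = counts$basis, shots = counts$shots, seed = counts$seed,
    bit_order = "leftmost = qubit 0",
    counts = as.list(counts$counts)
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) {
    return(as.character(json))
  }
  writeLines(json, path)
  invisible(path)
}

#' Run the encoding circuit, exactly or with shot sampling
#'
#' Evolves `|000><000|` through the circuit's gates in order. After each gate
#' whose name matches `noise$apply_after`, the depolarizing channel fires on
#' that gate's qubit pair (`two_qubit` arity) or on all three qubits
#' (`three_qubit`). Measurement-basis rotations (`h` gates appended by
#' [build_circuit()]) evolve the state but attract no noise by default. In
#' `"shots"` mode outcomes are sampled from the final diagonal with the given
#' seed; `"exact"` mode returns the density matrix only.
#'
#' @param circuit A `"circuit_spec"` from [build_circuit()].
#' @param noise A [noise_spec()] or `NULL` for a noiseless run.
#' @param mode `"exact"` or `"shots"`.
#' @param shots Shot count for `"shots"` mode (default 1000).
#' @param seed RNG seed for `"shots"` mode.
#' @return List with `rho` (final 8x8 density matrix) and `counts`
#'   (a `"shot_counts"`, or `NULL` in exact mode).
#' @examples
#' circ <- build_circuit(angle_from_similarity(0.5))
#' run_circuit(circ, noise = noise_spec(0.01), mode = "exact")$rho[1, 1]
#' @export
run_circuit <- function(circuit, noise = NULL, mode = c("exact", "shots"),
                        shots = 1000L, seed = 1L) {
  stopifnot(inherits(circuit, "circuit_spec"))
  mode <- match.arg(mode)
  if (!is.null(noise)) stopifnot(inherits(noise, "noise_spec"))
  rho <- initial_density()
  for (gate in circuit$gates) {
    if (gate$name == "measure") next
    rho <- apply_gate(rho, gate)
    if (!is.null(noise) && gate$name %in% noise$apply_after && noise$p > 0) {
      qs <- if (noise$arity == "three_qubit") 0:2 else gate$qubits
      rho <- depolarize(rho, qs, noise$p)
    }
    validate_density_matrix(rho, tol = 1e-8)
  }
  counts <- NULL
  if (mode == "shots") {
    counts <- sample_counts(rho, shots = shots, seed = seed,
      basis = circuit$measure_basis)
  }
  list(rho = rho, counts = counts)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}
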