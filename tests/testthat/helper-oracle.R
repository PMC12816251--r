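# Brute-force 8x8 matrix oracle, written independently of the package
# internals: gates are built from projector algebra, the depolarizing channel
# from its full Pauli-conjugation sum (including Y), and traces from
# element-wise sums. Qubit 0 is the leftmost Kronecker factor, matching the
# package's outcome-label convention.

o_id <- diag(2)
o_x <- matrix(c(0, 1, 1, 0), 2, 2)
o_y <- matrix(c(0, 1i, -1i, 0), 2, 2)
o_z <- diag(c(1, -1))
o_h <- matrix(c(1, 1, 1, -1), 2, 2) / sqrt(2)

o_kron3 <- function(a, b, c) kronecker(kronecker(a, b), c)

o_embed1 <- function(u, q) {
  f <- list(o_id, o_id, o_id)
  f[[q + 1]] <- u
  o_kron3(f[[1]], f[[2]], f[[3]])
}

# CNOT as |0><0|_c (x) I + |1><1|_c (x) X_t
o_cnot <- function(ctrl, tgt) {
  p0 <- diag(c(1, 0))
  p1 <- diag(c(0, 1))
  f0 <- list(o_id, o_id, o_id)
  f0[[ctrl + 1]] <- p0
  f1 <- list(o_id, o_id, o_id)
  f1[[ctrl + 1]] <- p1
  f1[[tgt + 1]] <- o_x
  o_kron3(f0[[1]], f0[[2]], f0[[3]]) + o_kron3(f1[[1]], f1[[2]], f1[[3]])
}

o_ry <- function(th) {
  matrix(c(cos(th / 2), sin(th / 2), -sin(th / 2), cos(th / 2)), 2, 2)
}

o_conj <- function(u, rho) u %*% rho %*% Conj(t(u))

# k-qubit depolarizing channel via the Pauli-twirl identity:
# Tr_q(rho) (x) I/2^k == 4^-k * sum over all k-qubit Paulis P of P rho P
o_depol <- function(rho, qubits, p) {
  paulis <- list(o_id, o_x, o_y, o_z)
  k <- length(qubits)
  combos <- as.matrix(expand.grid(rep(list(1:4), k)))
  total <- matrix(0 + 0i, 8, 8)
  for (r in seq_len(nrow(combos))) {
    f <- list(o_id, o_id, o_id)
    for (j in seq_len(k)) f[[qubits[j] + 1]] <- paulis[[combos[r, j]]]
    pm <- o_kron3(f[[1]], f[[2]], f[[3]])
    total <- total + o_conj(pm, rho)
  }
  (1 - p) * rho + (p / 4^k) * total
}

# Full circuit: RY(theta) on q0, CNOT 0->1, CNOT 0->2, depolarizing after
# each CNOT on its qubit pair (or all three qubits).
o_run <- function(t, p, arity = "two_qubit") {
  th <- 2 * acos(sqrt(t))
  rho <- matrix(0 + 0i, 8, 8)
  rho[1, 1] <- 1
  rho <- o_conj(o_embed1(o_ry(th), 0), rho)
  for (ct in list(c(0, 1), c(0, 2))) {
    rho <- o_conj(o_cnot(ct[1], ct[2]), rho)
    if (p > 0) {
      rho <- o_depol(rho, if (arity == "two_qubit") ct else 0:2, p)
    }
  }
  rho
}

o_pauli_mat <- function(label) {
  m <- list(I = o_id, Z = o_z, X = o_x, Y = o_y)
  ch <- strsplit(label, "")[[1]]
  o_kron3(m[[ch[1]]], m[[ch[2]]], m[[ch[3]]])
}

# Tr(rho O) as an element-wise sum, avoiding the package's matrix product
o_expect <- function(rho, label) {
  val <- sum(rho * t(o_pauli_mat(label)))
  stopifnot(abs(Im(val)) < 1e-10)
  Re(val)
}

# ideal amplitudes straight from the encoded-state formula
o_ideal_vec <- function(t) {
  v <- numeric(8)
  v[1] <- sqrt(t)
  v[8] <- sqrt(1 - t)
  v
}

aspirin_smiles <- "CC(=O)OC1=CC=CC=C1C(=O)O"
butane_smiles <- "CCCC"
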