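#' Map a similarity value to the encoding rotation angle
#'
#' The similarity `T` in `[0, 1]` is stored as the probability of the `|0>`
#' branch of a single-qubit RY rotation: `cos^2(theta/2) = T`, hence
#' `theta = 2*acos(sqrt(T))`. `theta` runs from `pi` (T = 0) down to 0 (T = 1);
#' at `T = 0.5` the rotation is `pi/2` and the state is a balanced
#' superposition.
#'
#' @param t Similarity in `[0, 1]`.
#' @return An object of class `"encoding_angle"`: list with `theta` (radians,
#'   in `[0, pi]`) and `source_t`.
#' @examples
#' angle_from_similarity(0.5)$theta # pi/2
#' @export
angle_from_similarity <- function(t) {
  stopifnot(is.numeric(t), length(t) == 1L, is.finite(t))
  if (t < 0 || t > 1) stop("similarity must lie in [0, 1], got ", t)
  structure(
    list(theta = 2 * acos(sqrt(t)), source_t = as.numeric(t)),
    class = "encoding_angle"
  )
}

#' Recover the similarity encoded by a rotation angle
#'
#' Inverse of [angle_from_similarity()]: `T = cos^2(theta/2)`.
#'
#' @param theta Angle in radians, in `[0, pi]`.
#' @return Similarity in `[0, 1]`.
#' @export
similarity_from_angle <- function(theta) {
  if (inherits(theta, "encoding_angle")) theta <- theta$theta
  stopifnot(is.numeric(theta), length(theta) == 1L, is.finite(theta))
  if (theta < 0 || theta > pi) stop("theta must lie in [0, pi], got ", theta)
  cos(theta / 2)^2
}

#' @export
print.encoding_angle <- function(x, ...) {
  cat(sprintf(
    "<encoding angle: theta = %.6g rad (%.4g*pi), T = %.6g>\n",
    x$theta, x$theta / pi, x$source_t
  ))
  invisible(x)
}

#' Build the 3-qubit similarity-encoding circuit
#'
#' The circuit applies `RY(theta)` on qubit 0 and fans out two CNOTs
#' (control 0, targets 1 and 2), preparing the GHZ-like state
#' `sqrt(T)|000> + sqrt(1-T)|111>`. Measuring a qubit in the X basis is
#' realized by appending a Hadamard on that qubit before the computational
#' measurement.
#'
#' Outcome labels read left-to-right as qubit 0, qubit 1, qubit 2 in every
#' serialized artifact (for this permutation-symmetric state the two common
#' conventions coincide on `"000"`/`"111"`, but parity bookkeeping needs one
#' fixed rule).
#'
#' @param angle An `"encoding_angle"` from [angle_from_similarity()], or a
#'   bare numeric angle in `[0, pi]`.
#' @param measure_basis 3-character string over `{"Z","X"}`, one per qubit
#'   (position 1 = qubit 0). Default `"ZZZ"`.
#' @return An object of class `"circuit_spec"`: list with `gates` (list of
#'   `list(name, theta?, qubits)`), `n_qubits = 3`, `measure_basis`.
#' @examples
#' build_circuit(angle_from_similarity(0.5))
#' @export
build_circuit <- function(angle, measure_basis = "ZZZ") {
  if (is.numeric(angle)) {
    angle <- structure(
      list(theta = angle, source_t = similarity_from_angle(angle)),
      class = "encoding_angle"
    )
  }
  stopifnot(inherits(angle, "encoding_angle"))
  if (!is.character(measure_basis) || nchar(measure_basis) != 3L ||
    !all(strsplit(measure_basis, "")[[1]] %in% c("Z", "X"))) {
    stop("measure_basis must be a 3-character string over {Z, X}")
  }
  gates <- list(
    list(name = "ry", theta = angle$theta, qubits = 0L),
    list(name = "cx", qubits = c(0L, 1L)),
    list(name = "cx", qubits = c(0L, 2L))
  )
  for (q in which(strsplit(measure_basis, "")[[1]] == "X") - 1L) {
    gates[[length(gates) + 1L]] <- list(name = "h", qubits = q)
  }
  gates[[length(gates) + 1L]] <- list(name = "measure", qubits = 0:2)
  structure(
    list(
      gates = gates, n_qubits = 3L, measure_basis = measure_basis,
      theta = angle$theta, source_t = angle$source_t,
      bit_order = "leftmost = qubit 0"
    ),
    class = "circuit_spec"
  )
}

#' @export
print.circuit_spec <- function(x, ...) {
  cat(sprintf(
    "3-qubit similarity-encoding circuit (T = %.6g, theta = %.6g rad)\n",
    x$source_t, x$theta
  ))
  for (g in x$gates) {
    cat(sprintf(
      "  %-7s q%s%s\n", g$name, paste(g$qubits, collapse = ",q"),
      if (!is.null(g$theta)) sprintf("  (theta = %.6g)", g$theta) else ""
    ))
  }
  cat(sprintf(
    "  measure basis %s; outcome labels: %s\n", x$measure_basis, x$bit_order
  ))
  invisible(x)
}

#' Serialize a circuit to JSON
#'
#' Gate names `"ry"`, `"cx"`, `"h"`, `"measure"` with qubit indices, suitable
#' for export to standard circuit toolkits.
#'
#' @param circuit A `"circuit_spec"`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @export
circuit_to_json <- function(circuit, path = NULL) {
  stopifnot(inherits(circuit, "circuit_spec"))
  obj <- list(
    n_qubits = circuit$n_qubits,
    source_t = circuit$source_t,
    theta = circuit$theta,
    measure_basis = circuit$measure_basis,
    bit_order = circuit$bit_order,
    gates = lapply(circuit$gates, function(g) {
      out <- list(name = g$name, qubits = I(g$qubits))
      if (!is.null(g$theta)) out$theta <- g$theta
      out
    })
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) {
    return(as.character(json))
  }
  writeLines(json, path)
  invisible(path)
}

#' Ideal (noiseless) state amplitudes of the encoding circuit
#'
#' The noiseless circuit output is `sqrt(T)|000> + sqrt(1-T)|111>`: amplitudes
#' are real and non-negative (an RY rotation on `|0>` introduces no phases),
#' and all weight sits on the two perfectly correlated outcomes.
#'
#' @inheritParams build_circuit
#' @return Named numeric vector of 8 amplitudes, names `"000"` ... `"111"`.
#' @export
ideal_state <- function(angle) {
  if (is.numeric(angle)) angle <- angle_from_similarity(similarity_from_angle(angle))
  stopifnot(inherits(angle, "encoding_angle"))
  t <- angle$source_t
  amps <- stats::setNames(numeric(8), basis_labels())
  amps["000"] <- sqrt(t)
  amps["111"] <- sqrt(1 - t)
  amps
}

# 3-bit outcome labels, leftmost character = qubit 0
basis_labels <- function() {
  vapply(0:7, function(i) {
    paste0(bitwAnd(bitwShiftR(i, 2:0), 1L), collapse = "")
  }, character(1))
}
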