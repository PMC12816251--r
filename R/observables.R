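#' Three-qubit Pauli observable
#'
#' A tensor product of I, Z, X factors, written as a 3-character label with
#' the leftmost character acting on qubit 0 (e.g. `"ZZZ"`, `"IIZ"`, `"XIX"`).
#' On the encoded GHZ-like state, `<ZZZ> = 2T - 1`, so the similarity is
#' recovered as `T = (1 + <ZZZ>)/2`; all single- and two-qubit X observables
#' are identically zero on the ideal state for every `T` (destructive
#' interference), which makes them a noise diagnostic.
#'
#' @param label 3-character string over `{"I", "Z", "X"}`.
#' @return Object of class `"pauli_observable"`: list with `label`, `support`
#'   (0-based qubit indices of non-identity factors) and `matrix` (8x8).
#' @export
pauli_observable <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  chars <- strsplit(label, "")[[1]]
  if (length(chars) != 3L || !all(chars %in% c("I", "Z", "X"))) {
    stop("observable label must be 3 characters over {I, Z, X}, got '", label, "'")
  }
  pauli1 <- list(
    I = diag(2),
    Z = matrix(c(1, 0, 0, -1), 2, 2),
    X = matrix(c(0, 1, 1, 0), 2, 2)
  )
  m <- kronecker(kronecker(pauli1[[chars[1]]], pauli1[[chars[2]]]), pauli1[[chars[3]]])
  structure(
    list(label = label, support = which(chars != "I") - 1L, matrix = m),
    class = "pauli_observable"
  )
}

as_observable <- function(obs) {
  if (inherits(obs, "pauli_observable")) obs else pauli_observable(obs)
}

new_estimate <- function(value, stderr, shots, source, observable,
                         approximate = FALSE) {
  structure(
    list(
      value = value, stderr = stderr, shots = shots, source = source,
      observable = observable, approximate = approximate
    ),
    class = "observable_estimate"
  )
}

#' @export
print.observable_estimate <- function(x, ...) {
  cat(sprintf(
    "<%s> = %.6g%s  [%s%s%s]\n", x$observable, x$value,
    if (x$source == "counts") sprintf(" +/- %.3g", x$stderr) else "",
    x$source,
    if (x$source == "counts") sprintf(", %d shots", x$shots) else "",
    if (isTRUE(x$approximate)) ", approximate" else ""
  ))
  invisible(x)
}

#' Pauli expectation value from measurement counts
#'
#' `<O> = (1/S) * sum_i s_i C_i` where `C_i` is the count of outcome `i`,
#' `S` the total shots, and the sign `s_i = (-1)^(number of 1-bits of outcome
#' i on the observable's support)` — the parity convention under which
#' `<ZZZ>` equals P(even parity) - P(odd parity) and evaluates to `2T - 1` on
#' the encoded state. The standard error is the binomial error of a +/-1
#' estimator, `sqrt((1 - value^2)/S)`.
#'
#' The counts' measurement basis must supply each non-identity factor of the
#' observable (X factors require an X-basis measurement on that qubit);
#' mixing Z counts into X estimates is refused.
#'
#' @param counts A `"shot_counts"` from [sample_counts()] or [run_circuit()].
#' @param obs A [pauli_observable()] or its label.
#' @return An `"observable_estimate"` with `source = "counts"`.
#' @examples
#' cts <- structure(list(
#'   counts = c("000" = 600, "111" = 400), shots = 1000L,
#'   seed = 0L, basis = "ZZZ"
#' ), class = "shot_counts")
#' expectation_from_counts(cts, "ZZZ")$value # 0.2
#' @export
expectation_from_counts <- function(counts, obs) {
  stopifnot(inherits(counts, "shot_counts"))
  obs <- as_observable(obs)
  if (counts$shots <= 0L) stop("counts have zero shots")
  obs_chars <- strsplit(obs$label, "")[[1]]
  basis_chars <- strsplit(counts$basis, "")[[1]]
  active <- obs_chars != "I"
  if (any(obs_chars[active] != basis_chars[active])) {
    stop(sprintf(
      "basis mismatch: observable %s needs per-qubit bases %s but counts were measured in %s",
      obs$label, obs$label, counts$basis
    ))
  }
  labels <- names(counts$counts)
  signs <- vapply(labels, function(lbl) {
    bits <- as.integer(strsplit(lbl, "")[[1]])
    (-1)^sum(bits[obs$support + 1L])
  }, numeric(1))
  value <- sum(signs * counts$counts) / counts$shots
  stderr <- sqrt(max(0, 1 - value^2) / counts$shots)
  new_estimate(value, stderr, counts$shots, "counts", obs$label)
}

#' Exact Pauli expectation value from a density matrix
#'
#' The trace rule `<O> = Tr(rho O)`; the imaginary part (zero up to roundoff
#' for Hermitian inputs) is discarded after a tolerance check.
#'
#' @param rho 8x8 density matrix.
#' @param obs A [pauli_observable()] or its label.
#' @return An `"observable_estimate"` with `source = "exact"`, `stderr = 0`.
#' @export
exact_expectation <- function(rho, obs) {
  obs <- as_observable(obs)
  val <- sum(diag(rho %*% obs$matrix))
  if (abs(Im(val)) > 1e-10) {
    stop("expectation value has non-negligible imaginary part: ", Im(val))
  }
  new_estimate(Re(val), 0, NA_integer_, "exact", obs$label)
}

#' Ideal-vs-noisy outcome probability differences
#'
#' Converts two Z-basis count sets into per-outcome probabilities
#' `P(q) = C(q)/C_total` and their differences
#' `delta(q) = P_ideal(q) - P_noisy(q)`, over all 8 outcomes (including
#' zero-count ones). The deltas sum to zero since both distributions are
#' normalized.
#'
#' @param ideal,noisy `"shot_counts"` objects measured in the Z basis.
#' @return A data.frame with columns `outcome`, `p_ideal`, `p_noisy`, `delta`.
#' @export
probability_deltas <- function(ideal, noisy) {
  stopifnot(inherits(ideal, "shot_counts"), inherits(noisy, "shot_counts"))
  if (ideal$basis != "ZZZ" || noisy$basis != "ZZZ") {
    stop("probability deltas are defined for Z-basis counts")
  }
  if (ideal$shots <= 0L || noisy$shots <= 0L) stop("counts have zero shots")
  labels <- basis_labels()
  p_ideal <- as.numeric(ideal$counts[labels]) / ideal$shots
  p_noisy <- as.numeric(noisy$counts[labels]) / noisy$shots
  data.frame(
    outcome = labels, p_ideal = p_ideal, p_noisy = p_noisy,
    delta = p_ideal - p_noisy, stringsAsFactors = FALSE
  )
}

#' Product approximation of the three-qubit parity
#'
#' Reconstructs `<ZZZ>` from separately measured Z-basis observables under an
#' independence assumption, then projects onto the physically allowed range
#' `[-1, 1]`. The default composition multiplies the disjoint-support pair
#' `<ZIZ> * <IZI>` (their supports tile all three qubits); the alternative
#' `"triple"` composition multiplies `<IIZ> * <IZI> * <ZIZ>`. The result is
#' flagged `approximate`.
#'
#' @param z_estimates Named list of `"observable_estimate"` objects (or bare
#'   numerics), with names among `"IIZ"`, `"IZI"`, `"ZIZ"`.
#' @param composition `"pair"` (default) or `"triple"`.
#' @return An `"observable_estimate"` for `ZZZ` with `approximate = TRUE`.
#' @examples
#' product_approx_zzz(list(ZIZ = -0.9, IZI = -0.9))$value # 0.81
#' @export
product_approx_zzz <- function(z_estimates, composition = c("pair", "triple")) {
  composition <- match.arg(composition)
  need <- if (composition == "pair") c("ZIZ", "IZI") else c("IIZ", "IZI", "ZIZ")
  missing <- setdiff(need, names(z_estimates))
  if (length(missing)) {
    stop(
      "product approximation (", composition, ") requires estimates for: ",
      paste(missing, collapse = ", ")
    )
  }
  val_of <- function(e) if (inherits(e, "observable_estimate")) e$value else as.numeric(e)
  raw <- prod(vapply(z_estimates[need], val_of, numeric(1)))
  new_estimate(
    value = min(1, max(-1, raw)), stderr = NA_real_, shots = NA_integer_,
    source = "counts", observable = "ZZZ", approximate = TRUE
  )
}
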