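#' Error-mitigation configuration
#'
#' Exponential rescaling multiplies a noisy expectation value by `e^epsilon`
#' to approximate its noiseless value, then clips to the physical range
#' `[-1, 1]`. Three policies set the exponent:
#' \describe{
#'   \item{`from_noise_p`}{`epsilon = p`, the per-gate error chance itself
#'     (the simplest reading of "scale factor e^0.015 for a 1.5% chance of
#'     error"); default.}
#'   \item{`calibrated`}{`epsilon = -n_gates * log(1 - p)`, the closed-form
#'     inverse of the default depolarizing channel — exact recovery in
#'     exact-expectation mode, see [calibrated_epsilon()].}
#'   \item{`fixed`}{a user-supplied exponent.}
#' }
#'
#' @param epsilon Non-negative exponent (required for `"fixed"`, ignored
#'   otherwise).
#' @param policy One of `"from_noise_p"`, `"calibrated"`, `"fixed"`.
#' @param clip Clip the rescaled expectation to `[-1, 1]`? Default `TRUE`.
#' @return Object of class `"mitigation_config"`.
#' @export
mitigation_config <- function(policy = c("from_noise_p", "calibrated", "fixed"),
                              epsilon = NULL, clip = TRUE) {
  policy <- match.arg(policy)
  if (policy == "fixed") {
    stopifnot(is.numeric(epsilon), length(epsilon) == 1L, is.finite(epsilon))
    if (epsilon < 0) stop("epsilon must be >= 0")
  } else if (!is.null(epsilon)) {
    warning("epsilon is ignored unless policy = 'fixed'")
  }
  structure(
    list(policy = policy, epsilon = epsilon, clip = isTRUE(clip)),
    class = "mitigation_config"
  )
}

# Resolve the exponent a config implies for a given noise model.
resolve_epsilon <- function(config, noise = NULL, n_noisy_gates = 2L) {
  switch(config$policy,
    fixed = config$epsilon,
    from_noise_p = if (is.null(noise)) 0 else noise$p,
    calibrated = if (is.null(noise)) 0 else calibrated_epsilon(noise, n_noisy_gates)
  )
}

#' Rescale a noisy expectation value
#'
#' `<ZZZ>_mitigated = <ZZZ>_noisy * e^epsilon`, clipped to `[-1, 1]` when the
#' config asks for it. With `epsilon = 0` the value is unchanged.
#'
#' @param zzz_noisy Noisy expectation value in `[-1, 1]`.
#' @param epsilon Non-negative exponent, or a [mitigation_config()] with
#'   policy `"fixed"`.
#' @param clip Clip to `[-1, 1]`? Default `TRUE`.
#' @return The mitigated expectation value.
#' @examples
#' mitigate_expectation(0.96, 0.01) # 0.96 * exp(0.01)
#' @export
mitigate_expectation <- function(zzz_noisy, epsilon, clip = TRUE) {
  if (inherits(epsilon, "mitigation_config")) {
    clip <- epsilon$clip
    epsilon <- resolve_epsilon(epsilon)
  }
  stopifnot(is.numeric(zzz_noisy), length(zzz_noisy) == 1L)
  if (abs(zzz_noisy) > 1 + 1e-12) {
    stop("noisy expectation must lie in [-1, 1], got ", zzz_noisy)
  }
  if (epsilon < 0) stop("epsilon must be >= 0")
  out <- zzz_noisy * exp(epsilon)
  if (clip) out <- min(1, max(-1, out))
  out
}

#' Similarity from a three-qubit parity expectation
#'
#' `T = (1 + <ZZZ>)/2`: linear, mapping `<ZZZ> = -1` to 0 and `+1` to 1.
#'
#' @param zzz Expectation value in `[-1, 1]`.
#' @param clip Clip slightly out-of-range inputs to `[-1, 1]` first
#'   (default `TRUE`); with `clip = FALSE` an out-of-range input is an error.
#' @return Similarity in `[0, 1]`.
#' @export
similarity_from_zzz <- function(zzz, clip = TRUE) {
  stopifnot(is.numeric(zzz), length(zzz) == 1L, is.finite(zzz))
  if (abs(zzz) > 1) {
    if (!clip) stop("expectation value outside [-1, 1]: ", zzz)
    zzz <- min(1, max(-1, zzz))
  }
  (1 + zzz) / 2
}

#' Absolute similarity error against the classical baseline
#'
#' `epsilon = |s_base - s_estimated|`, the absolute deviation of an estimated
#' similarity from the classical (noise-free) baseline.
#'
#' @param s_base Baseline similarity in `[0, 1]`.
#' @param s_estimated Estimated (noisy or mitigated) similarity in `[0, 1]`.
#' @return Non-negative error.
#' @export
error_metric <- function(s_base, s_estimated) {
  stopifnot(
    is.numeric(s_base), is.numeric(s_estimated),
    s_base >= 0, s_base <= 1, s_estimated >= 0, s_estimated <= 1
  )
  abs(s_base - s_estimated)
}

#' Percent error reduction achieved by mitigation
#'
#' `epsilon_r = 100 * (epsilon_unmitigated - epsilon_mitigated) /
#' epsilon_unmitigated`; negative when mitigation worsens the error. When the
#' unmitigated error is exactly zero the reduction is undefined: `NA` is
#' returned (with 0 conventionally reported when both errors are zero —
#' mitigation changed nothing there).
#'
#' @param eps_unmitigated Unmitigated error (>= 0).
#' @param eps_mitigated Mitigated error (>= 0).
#' @return Percent reduction, or `NA` when undefined.
#' @examples
#' error_reduction(0.020, 0.005) # 75
#' @export
error_reduction <- function(eps_unmitigated, eps_mitigated) {
  stopifnot(
    is.numeric(eps_unmitigated), is.numeric(eps_mitigated),
    eps_unmitigated >= 0, eps_mitigated >= 0
  )
  if (eps_unmitigated == 0) {
    return(if (eps_mitigated == 0) 0 else NA_real_)
  }
  100 * (eps_unmitigated - eps_mitigated) / eps_unmitigated
}

#' Closed-form mitigation exponent for the depolarizing channel
#'
#' Each depolarizing event with probability `p` shrinks a traceless Pauli
#' expectation by `(1 - p)`; after `n_noisy_gates` such events the total
#' attenuation is `(1 - p)^n`. The exponent inverting it exactly is
#' `epsilon = -n * log(1 - p)`, so mitigation recovers the noiseless
#' expectation (and hence the encoded similarity) exactly in
#' exact-expectation mode.
#'
#' @param noise A [noise_spec()] (or a bare probability `p`).
#' @param n_noisy_gates Number of noise events in the circuit (default 2, one
#'   per CNOT).
#' @return The calibrated exponent (>= 0).
#' @examples
#' calibrated_epsilon(0.01) # -2 * log(0.99)
#' @export
calibrated_epsilon <- function(noise, n_noisy_gates = 2L) {
  p <- if (inherits(noise, "noise_spec")) noise$p else as.numeric(noise)
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0)
  if (p >= 1) stop("calibrated exponent diverges at p = 1")
  -n_noisy_gates * log(1 - p)
}
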