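#' Estimate a quantum-encoded Tanimoto similarity under noise
#'
#' The central estimator of the package. A classical similarity `T` (direct
#' value, [similarity_from_pair()] record, or SMILES pair) is encoded into the
#' 3-qubit GHZ-like state `sqrt(T)|000> + sqrt(1-T)|111>` via an RY rotation
#' and two CNOTs, evolved exactly as a density matrix under depolarizing noise
#' on the entangling gates, read out through the three-qubit parity `<ZZZ>`
#' (exactly, or estimated from seeded measurement shots), mitigated by
#' exponential rescaling, and decoded back to a similarity
#' `T = (1 + <ZZZ>)/2`.
#'
#' @param t The similarity to encode: a numeric in `[0, 1]`, or a
#'   `"similarity_record"` from [similarity_from_pair()] /
#'   [direct_similarity()].
#' @param noise_p Depolarizing probability per entangling gate, in `[0, 1]`.
#'   May also be a full [noise_spec()] via `noise`.
#' @param noise A [noise_spec()]; overrides `noise_p` when given.
#' @param mode `"shots"` (sample measurement outcomes; default) or `"exact"`
#'   (noise-free expectation values from the density matrix, no sampling).
#' @param shots Measurement shots per simulation in `"shots"` mode
#'   (default 1000).
#' @param seed Integer RNG seed for shot sampling; recorded in the result.
#' @param mitigation A [mitigation_config()]; default rescales by
#'   `e^p` (`from_noise_p` policy).
#' @return An object of class `"quantum_similarity"`; see
#'   [print.quantum_similarity()], [coef.quantum_similarity()],
#'   [as.data.frame.quantum_similarity()], [simulate.quantum_similarity()].
#'   Key fields: `t_base`, `t_noisy`, `t_mitigated`, `zzz_noisy`,
#'   `zzz_mitigated`, `eps_unmitigated`, `eps_mitigated`,
#'   `eps_reduction_pct`, plus the retained intermediate artifacts
#'   (`circuit`, `rho_noisy`, `counts_ideal`, `counts_noisy`).
#' @examples
#' fit <- quantum_similarity(0.5, noise_p = 0.01, mode = "exact")
#' coef(fit)
#' @export
quantum_similarity <- function(t, noise_p = 0, noise = NULL,
                               mode = c("shots", "exact"), shots = 1000L,
                               seed = 1L,
                               mitigation = mitigation_config()) {
  mode <- match.arg(mode)
  record <- if (inherits(t, "similarity_record")) {
    t
  } else {
    direct_similarity(t)
  }
  stopifnot(inherits(mitigation, "mitigation_config"))
  if (is.null(noise)) {
    noise <- if (noise_p > 0) noise_spec(noise_p) else NULL
  }
  t_base <- record$t_value

  angle <- angle_from_similarity(t_base)
  circuit <- build_circuit(angle, measure_basis = "ZZZ")

  run_ideal <- run_circuit(circuit,
    noise = NULL, mode = mode,
    shots = shots, seed = seed
  )
  run_noisy <- if (is.null(noise)) {
    # derive a distinct sampling stream for the "noisy" arm even when p = 0
    run_circuit(circuit, noise = NULL, mode = mode, shots = shots,
      seed = seed + 1L)
  } else {
    run_circuit(circuit, noise = noise, mode = mode, shots = shots,
      seed = seed + 1L)
  }

  est_noisy <- if (mode == "exact") {
    exact_expectation(run_noisy$rho, "ZZZ")
  } else {
    expectation_from_counts(run_noisy$counts, "ZZZ")
  }

  epsilon <- resolve_epsilon(mitigation, noise, n_noisy_gates = 2L)
  zzz_mitigated <- mitigate_expectation(est_noisy$value, epsilon,
    clip = mitigation$clip)
  clipped <- abs(est_noisy$value * exp(epsilon)) > 1 && mitigation$clip

  t_noisy <- similarity_from_zzz(est_noisy$value)
  t_mitigated <- similarity_from_zzz(zzz_mitigated)

  eps_unmit <- error_metric(t_base, t_noisy)
  eps_mit <- error_metric(t_base, t_mitigated)

  structure(
    list(
      record = record, t_base = t_base, theta = angle$theta,
      circuit = circuit, noise = noise, mitigation = mitigation,
      epsilon = epsilon, mode = mode, shots = as.integer(shots),
      seed = as.integer(seed),
      rho_ideal = run_ideal$rho, rho_noisy = run_noisy$rho,
      counts_ideal = run_ideal$counts, counts_noisy = run_noisy$counts,
      estimate_noisy = est_noisy,
      zzz_noisy = est_noisy$value, zzz_mitigated = zzz_mitigated,
      t_noisy = t_noisy, t_mitigated = t_mitigated,
      eps_unmitigated = eps_unmit, eps_mitigated = eps_mit,
      eps_reduction_pct = error_reduction(eps_unmit, eps_mit),
      clipped = clipped
    ),
    class = "quantum_similarity"
  )
}

#' @export
print.quantum_similarity <- function(x, digits = 4, ...) {
  cat("Quantum-encoded Tanimoto similarity\n")
  cat(sprintf("  pair: %s  (%s)\n", x$record$label, x$record$method))
  cat(sprintf(
    "  encoding: theta = %.*g rad; backend: %s%s\n", digits, x$theta, x$mode,
    if (x$mode == "shots") sprintf(" (%d shots, seed %d)", x$shots, x$seed) else ""
  ))
  cat(sprintf(
    "  noise: %s; mitigation: %s (epsilon = %.*g)\n",
    if (is.null(x$noise)) "none" else sprintf(
      "depolarizing p = %g (%s)", x$noise$p, x$noise$arity
    ),
    x$mitigation$policy, digits, x$epsilon
  ))
  cat(sprintf(
    "  T  baseline %.*g | noisy %.*g | mitigated %.*g\n",
    digits, x$t_base, digits, x$t_noisy, digits, x$t_mitigated
  ))
  invisible(x)
}

#' @export
summary.quantum_similarity <- function(object, ...) {
  structure(object, class = c("summary.quantum_similarity", class(object)))
}

#' @export
print.summary.quantum_similarity <- function(x, digits = 4, ...) {
  NextMethod()
  cat(sprintf(
    "  <ZZZ>  noisy %.*g%s | mitigated %.*g%s\n",
    digits, x$zzz_noisy,
    if (x$estimate_noisy$source == "counts") {
      sprintf(" +/- %.2g", x$estimate_noisy$stderr)
    } else "",
    digits, x$zzz_mitigated,
    if (x$clipped) " (clipped to [-1,1])" else ""
  ))
  cat(sprintf(
    "  error  unmitigated %.*g | mitigated %.*g | reduction %s%%\n",
    digits, x$eps_unmitigated, digits, x$eps_mitigated,
    if (is.na(x$eps_reduction_pct)) "NA" else
      format(round(x$eps_reduction_pct, 2))
  ))
  if (!is.null(x$counts_noisy)) {
    nz <- x$counts_noisy$counts[x$counts_noisy$counts > 0]
    cat("  noisy counts: ", paste(sprintf("|%s> %d", names(nz), nz),
      collapse = ", "
    ), "\n", sep = "")
  }
  invisible(x)
}

#' Extract the similarity estimates
#'
#' @param object A `"quantum_similarity"` fit.
#' @param ... Unused.
#' @return Named vector `c(baseline, noisy, mitigated)`.
#' @export
coef.quantum_similarity <- function(object, ...) {
  c(
    baseline = object$t_base, noisy = object$t_noisy,
    mitigated = object$t_mitigated
  )
}

#' One-row summary in the standard report column order
#'
#' @param x A `"quantum_similarity"` fit.
#' @param row.names,optional,... Passed through / unused.
#' @export
as.data.frame.quantum_similarity <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  data.frame(
    error_pct = 100 * (if (is.null(x$noise)) 0 else x$noise$p),
    pair = x$record$label,
    baseline = x$t_base,
    unmitigated = x$t_noisy,
    mitigated = x$t_mitigated,
    eps_unmitigated = x$eps_unmitigated,
    eps_mitigated = x$eps_mitigated,
    eps_reduction_pct = x$eps_reduction_pct,
    stringsAsFactors = FALSE, row.names = row.names
  )
}

#' Re-sample the measurement stage of a fitted estimate
#'
#' Redraws the measurement shots from the fitted noisy state `nsim` times
#' (fresh seeds derived from `seed`) and recomputes the noisy and mitigated
#' similarity estimates, exposing their sampling variability.
#'
#' @param object A `"quantum_similarity"` fit (any mode; resampling always
#'   uses the stored noisy density matrix).
#' @param nsim Number of resamples.
#' @param seed Base seed for the resampling streams.
#' @param ... Unused.
#' @return A data.frame with columns `sim`, `seed`, `zzz_noisy`, `t_noisy`,
#'   `t_mitigated`.
#' @export
simulate.quantum_similarity <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- object$seed
  rows <- lapply(seq_len(nsim), function(i) {
    s <- seed + i
    cts <- sample_counts(object$rho_noisy, shots = object$shots, seed = s)
    est <- expectation_from_counts(cts, "ZZZ")
    zm <- mitigate_expectation(est$value, object$epsilon,
      clip = object$mitigation$clip)
    data.frame(
      sim = i, seed = s, zzz_noisy = est$value,
      t_noisy = similarity_from_zzz(est$value),
      t_mitigated = similarity_from_zzz(zm)
    )
  })
  do.call(rbind, rows)
}

#' Sweep noise levels for a set of molecule pairs
#'
#' Runs [quantum_similarity()] over the full grid of pairs x error rates and
#' collects one row per combination in the standard report column order
#' (error level, pair, baseline, unmitigated, mitigated, unmitigated error,
#' mitigated error, percent error reduction). Rows are sorted by rate, then
#' pair label.
#'
#' @param pairs List of similarities to encode: numerics in `[0, 1]` and/or
#'   `"similarity_record"` objects. A bare numeric vector is accepted.
#' @param error_rates Depolarizing probabilities to sweep. The default grid
#'   `c(0.001, 0.01, 0.015, 0.05, 0.1)` covers the standard benchmark levels;
#'   see [log_error_grid()] for a log-dense alternative.
#' @param ... Passed to [quantum_similarity()] (`mode`, `shots`, `seed`,
#'   `mitigation`, ...).
#' @param seed Base seed; each grid cell runs on its own derived stream.
#' @return Object of class `"noise_sweep"`: a data.frame with the columns
#'   above plus a `config` attribute (seed, shots, mode, mitigation policy,
#'   noise arity).
#' @examples
#' sw <- noise_sweep(list(1.0, 0.035), error_rates = c(0.01, 0.1), mode = "exact")
#' print(sw)
#' @export
noise_sweep <- function(pairs, error_rates = c(0.001, 0.01, 0.015, 0.05, 0.1),
                        ..., seed = 1L) {
  if (is.numeric(pairs)) pairs <- as.list(pairs)
  stopifnot(length(pairs) >= 1L, length(error_rates) >= 1L)
  if (any(error_rates < 0 | error_rates >= 1)) {
    stop("error rates must lie in [0, 1)")
  }
  records <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    if (inherits(p, "similarity_record")) p else
      direct_similarity(p, label = sprintf("t=%g", p))
  })
  fits <- list()
  rows <- list()
  k <- 0L
  for (ri in seq_along(error_rates)) {
    for (pi in seq_along(records)) {
      k <- k + 1L
      fit <- quantum_similarity(records[[pi]],
        noise_p = error_rates[ri],
        seed = seed + 97L * k, ...
      )
      fits[[k]] <- fit
      rows[[k]] <- as.data.frame(fit)
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$error_pct, tab$pair), , drop = FALSE]
  rownames(tab) <- NULL
  mode <- fits[[1]]$mode
  structure(tab,
    config = list(
      seed = as.integer(seed), shots = fits[[1]]$shots, mode = mode,
      mitigation_policy = fits[[1]]$mitigation$policy,
      noise_arity = if (is.null(fits[[1]]$noise)) "two_qubit" else
        fits[[1]]$noise$arity,
      error_rates = error_rates,
      pairs = vapply(records, function(r) r$label, character(1))
    ),
    fits = fits,
    class = c("noise_sweep", "data.frame")
  )
}

#' @export
print.noise_sweep <- function(x, digits = 4, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "Noise sweep: %d pairs x %d error rates (%s mode%s, mitigation '%s')\n",
    length(cfg$pairs), length(cfg$error_rates), cfg$mode,
    if (cfg$mode == "shots") sprintf(", %d shots, seed %d", cfg$shots, cfg$seed) else "",
    cfg$mitigation_policy
  ))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(col) round(col, digits))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Log-spaced error-rate grid
#'
#' @param from,to Range endpoints (default `1e-3` to `1e-1`).
#' @param n Number of points.
#' @return Numeric vector of `n` log-spaced rates.
#' @export
log_error_grid <- function(from = 1e-3, to = 1e-1, n = 20L) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Plot a noise sweep
#'
#' Unmitigated and mitigated similarity against the error rate (log x-axis),
#' one panel-free overlay per pair, with the classical baseline as a dashed
#' reference.
#'
#' @param x A `"noise_sweep"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.noise_sweep <- function(x, ...) {
  df <- as.data.frame(x)
  pairs <- unique(df$pair)
  cols <- grDevices::hcl.colors(max(2L, length(pairs)), "Dark 2")
  rng <- range(df$unmitigated, df$mitigated, df$baseline)
  graphics::plot(NA,
    xlim = range(df$error_pct / 100), ylim = rng, log = "x",
    xlab = "depolarizing error rate", ylab = "Tanimoto similarity", ...
  )
  for (i in seq_along(pairs)) {
    d <- df[df$pair == pairs[i], ]
    d <- d[order(d$error_pct), ]
    graphics::lines(d$error_pct / 100, d$unmitigated, col = cols[i], lty = 1)
    graphics::points(d$error_pct / 100, d$unmitigated, col = cols[i], pch = 1)
    graphics::lines(d$error_pct / 100, d$mitigated, col = cols[i], lty = 2)
    graphics::points(d$error_pct / 100, d$mitigated, col = cols[i], pch = 16)
    graphics::abline(h = d$baseline[1], col = cols[i], lty = 3)
  }
  graphics::legend("bottomleft",
    legend = c(
      paste(pairs, "(unmitigated)"), paste(pairs, "(mitigated)")
    ),
    col = rep(cols[seq_along(pairs)], 2),
    lty = rep(c(1, 2), each = length(pairs)), bty = "n", cex = 0.8
  )
  invisible(x)
}

#' Write a sweep report to CSV or JSON
#'
#' CSV uses the standard benchmark column order with a commented provenance
#' header (seed, shots, mode, noise arity, mitigation policy); JSON nests the
#' same provenance in a `config` block. Output is bit-stable for fixed
#' inputs. [read_report()] round-trips both formats.
#'
#' @param table A `"noise_sweep"`.
#' @param path Output file path.
#' @param format `"csv"` or `"json"` (default from the file extension).
#' @export
write_report <- function(table, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(table, "noise_sweep"), nrow(table) >= 1L)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  cfg <- attr(table, "config")
  df <- as.data.frame(table)
  if (format == "csv") {
    hdr <- c(
      sprintf("# qtanimoto noise sweep"),
      sprintf("# seed: %d", cfg$seed),
      sprintf("# shots: %d", cfg$shots),
      sprintf("# mode: %s", cfg$mode),
      sprintf("# noise_arity: %s", cfg$noise_arity),
      sprintf("# mitigation_policy: %s", cfg$mitigation_policy),
      sprintf("# bit_order: leftmost = qubit 0"),
      sprintf("# r_version: %s", paste(R.version$major, R.version$minor, sep = "."))
    )
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    numfmt <- function(v) {
      if (is.numeric(v)) vapply(v, function(x) format(x, digits = 17), character(1)) else v
    }
    out <- as.data.frame(lapply(df, numfmt), stringsAsFactors = FALSE)
    names(out) <- names(df)
    utils::write.table(out, con,
      sep = ",", row.names = FALSE, quote = FALSE
    )
  } else {
    obj <- list(
      config = cfg[c(
        "seed", "shots", "mode", "noise_arity", "mitigation_policy"
      )],
      bit_order = "leftmost = qubit 0",
      rows = df
    )
    writeLines(
      jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, dataframe = "rows"),
      path
    )
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  } else {
    obj <- jsonlite::fromJSON(path)
    obj$rows
  }
}

#' Generate a synthetic fingerprint pair with a prescribed similarity
#'
#' Constructs two binary fingerprints whose Tanimoto similarity equals a
#' rational `i/u` as close as possible to `target_t`: `i` shared on-bits and
#' `u - i` exclusive on-bits (split between the two vectors) are placed at
#' seeded random positions. When `union_size` is not given, `u` is searched
#' over `1:n_bits` minimizing `|i/u - target_t|` with `i = round(target_t*u)`
#' (smallest `u` on ties), so the achieved error is at most `1/(2u)`.
#'
#' This generator replaces the chemistry toolkit in tests: it produces pairs
#' at exactly known similarities without any molecular structure.
#'
#' @param n_bits Fingerprint length (default 2048).
#' @param target_t Desired similarity in `[0, 1]`.
#' @param seed RNG seed for bit placement.
#' @param union_size Optional fixed union size `u`.
#' @return List with `fp_a`, `fp_b` ([fingerprint()]s), `achieved_t` (`i/u`
#'   exactly), `union_size`, `intersection`.
#' @examples
#' p <- generate_synthetic_pair(2048, 0.035, seed = 7)
#' p$achieved_t
#' @export
generate_synthetic_pair <- function(n_bits = 2048L, target_t, seed = 1L,
                                    union_size = NULL) {
  stopifnot(is.numeric(target_t), length(target_t) == 1L)
  if (target_t < 0 || target_t > 1) stop("target_t must lie in [0, 1]")
  n_bits <- as.integer(n_bits)
  if (n_bits < 1L) stop("n_bits too small to host any on-bit")
  if (is.null(union_size)) {
    u_grid <- seq_len(n_bits)
    i_grid <- pmin(u_grid, pmax(0L, as.integer(round(target_t * u_grid))))
    err <- abs(i_grid / u_grid - target_t)
    u <- u_grid[which.min(err)] # which.min takes the first (smallest u) on ties
    i <- i_grid[u]
  } else {
    u <- as.integer(union_size)
    if (u < 1L || u > n_bits) stop("union_size must lie in [1, n_bits]")
    i <- min(u, max(0L, as.integer(round(target_t * u))))
  }
  pos <- with_seed(seed, sample.int(n_bits, u))
  shared <- pos[seq_len(i)]
  excl <- if (u > i) pos[(i + 1L):u] else integer(0)
  a_excl <- excl[seq_along(excl) %% 2L == 1L]
  b_excl <- excl[seq_along(excl) %% 2L == 0L]
  mk <- function(on) {
    bits <- integer(n_bits)
    bits[on] <- 1L
    fingerprint(bits, provenance = sprintf(
      "synthetic u=%d i=%d seed=%d", u, i, seed
    ))
  }
  list(
    fp_a = mk(c(shared, a_excl)), fp_b = mk(c(shared, b_excl)),
    achieved_t = i / u, union_size = u, intersection = i
  )
}
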