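---
title: "Quantum-encoded Tanimoto similarity: model, noise, and mitigation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum-encoded Tanimoto similarity: model, noise, and mitigation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtanimoto)
```

## The procedure

qtanimoto implements a five-stage pipeline:

1. **Classical similarity.** Morgan (ECFP-style) fingerprints hash circular
   atom neighborhoods up to a radius (default 2) into a fixed-length bit
   vector (default 2048 bits); the Tanimoto coefficient
   $T = |A \cap B| / |A \cup B|$ compares two such vectors. Fingerprinting
   goes through a toolkit adapter (`morgan_fingerprint()` shells out to
   rdkit via `python`); `direct_similarity()` and the synthetic pair
   generator bypass chemistry entirely.
2. **Encoding.** $T$ becomes the rotation angle
   $\theta = 2\arccos\sqrt{T} \in [0, \pi]$ of an RY gate on qubit 0
   (so $\cos^2(\theta/2) = T$); CNOTs from qubit 0 to qubits 1 and 2 prepare
   $|\psi\rangle = \sqrt{T}\,|000\rangle + \sqrt{1-T}\,|111\rangle$.
3. **Noisy simulation.** The 3-qubit register is evolved exactly as an
   $8\times 8$ density matrix; a depolarizing channel with probability $p$
   fires after each CNOT. Measurement is a seeded multinomial draw over the
   final diagonal (1000 shots by default), or skipped entirely in exact mode.
4. **Estimation.** Pauli expectations come from counts as parity averages,
   $\langle O \rangle = S^{-1}\sum_i s_i C_i$ with
   $s_i = (-1)^{\#\{1\text{-bits on the support}\}}$, or from the trace rule
   $\mathrm{Tr}(\rho O)$. On the ideal state
   $\langle ZZZ\rangle = 2T - 1$.
5. **Mitigation and decoding.** The noisy parity is rescaled,
   $\langle ZZZ\rangle_{\text{mit}} = \langle ZZZ\rangle_{\text{noisy}}
   \, e^{\varepsilon}$, clipped to $[-1, 1]$, and decoded as
   $T = (1 + \langle ZZZ\rangle)/2$. Errors are absolute deviations from
   the classical baseline; effectiveness is the percent error reduction.

`quantum_similarity()` runs stages 2–5 and returns a classed fit;
`noise_sweep()` maps it over a pair × error-rate grid.

## Assumptions

- The similarity is computed classically and *encoded*; the circuit does not
  accelerate the Tanimoto computation. Its value is as a chemically
  motivated, minimal benchmark for noise and mitigation studies.
- Noise is depolarizing, gate-located, and restricted to the entangling
  gates: the RY rotation and the readout are noiseless by default (hardware
  CNOT error dominates single-qubit and readout error by roughly an order of
  magnitude on current superconducting devices). Amplitude damping,
  crosstalk and readout bias are out of scope.
- Amplitudes stay real and non-negative (RY on $|0\rangle$), so the state is
  fully characterized by the two populations and one coherence; global phase
  is ignored.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `radius`, `n_bits` | 2, 2048 | Fingerprint neighborhood radius (bonds) and folded length (bits). 2048 is the toolkit convention; the radius matches ECFP4. |
| `noise_p` | — | Depolarizing probability per noise event, in $[0,1]$. The studied range is $10^{-3}$–$10^{-1}$; 0.5–2% mimics current hardware. |
| `arity` | `two_qubit` | The channel acts on each CNOT's qubit pair. The literature phrase "depolarizing errors on (CX) gates, including 3-qubit errors" admits a second reading, so `three_qubit` applies a global channel after each CNOT instead; both shrink $\langle ZZZ\rangle$ by $(1-p)$ per event. |
| `shots` | 1000 | Measurement repetitions per simulation (the standard protocol size). Parity standard error is $\sqrt{(1-v^2)/S}$. |
| `seed` | 1 | Every sampling call records its seed; identical config + seed gives byte-identical reports. |
| `mitigation` policy | `from_noise_p` | $\varepsilon = p$ — the simplest reading of "scale factor $e^{0.015}$ for a 1.5% error chance". `calibrated` uses $\varepsilon = -n\ln(1-p)$ ($n = 2$ CNOTs), the exact channel inverse; `fixed` takes a user exponent. |

## Why $\varepsilon = -2\ln(1-p)$ inverts the channel

Each depolarizing event multiplies every traceless Pauli expectation on its
support by $(1-p)$; two events give
$\langle ZZZ\rangle_{\text{noisy}} = (1-p)^2 (2T-1)$. Rescaling by
$e^{-2\ln(1-p)} = (1-p)^{-2}$ restores $2T - 1$ identically, so in exact
mode the decoded similarity equals the encoded one to numerical precision
for every $T$ and $p < 1$. The `from_noise_p` policy ($\varepsilon = p$)
under-corrects — $e^p < (1-p)^{-2}$ — but still strictly shrinks the error
for small $p$; its appeal is that it needs no channel model, only an error
estimate. Neither policy bit-reproduces the published simulated similarity
table, whose noise parameterization is under-specified (its unmitigated
value 0.98 at 1% noise is incompatible with $(1-p)^2$-decay, which gives
0.99005); that table's arithmetic identities (its percent-error-reduction
column) are reproduced exactly instead.

```{r}
fit <- quantum_similarity(1.0, noise_p = 0.01, mode = "exact",
                          mitigation = mitigation_config("calibrated"))
coef(fit)
```

## What the synthetic generator emulates

`generate_synthetic_pair()` builds two fingerprints whose Tanimoto value is
an exact rational $i/u$ ($i$ shared, $u - i$ split exclusive on-bits at
seeded random positions), as close to a target as the grid allows
(error $\le 1/(2u)$). It emulates only the *combinatorics* of fingerprint
overlap — exactly what the encoding consumes — and none of the chemistry:
no bit correlations from recurring substructures, no popcount distribution
of real molecules, no toolkit hashing. Tests passing on synthetic pairs
therefore validate the encoding/noise/mitigation pipeline for any $T$, but
say nothing about fingerprint quality for a particular compound class; the
aspirin/butane checks cover the real-toolkit path.

When no union size is forced, the generator searches $u$ minimizing
$|i/u - t|$ (smallest $u$ on ties), e.g. $t = 0.035$ yields $7/200$ exactly.
A fixed `union_size` reproduces coarser grids (57 bits gives $2/57 \approx
0.0351$). At $t = 0$ with $u = 1$ one vector is empty; the pair is still
valid (union 1), but callers wanting two nonzero vectors should set
`union_size >= 2`.

## Numerical choices

- **Tolerances.** Density matrices are validated after every gate:
  Hermiticity and unit trace to $10^{-8}$ during evolution (accumulated
  float error), $10^{-10}$ at rest; eigenvalues in $[-10^{-10}, 0)$ are
  treated as roundoff and clipped at sampling time, anything more negative
  is an error.
- **Bit order.** Outcome labels read qubit 0 leftmost, everywhere. The
  encoded state is permutation-symmetric so both common conventions agree on
  `000`/`111`, but parity support sets need one fixed rule; every serialized
  artifact states it.
- **Degenerate inputs.** Two all-zero fingerprints raise (0/0 similarity is
  undefined; silently returning 0 would corrupt the encoding). Zero
  unmitigated error makes the percent reduction undefined: reported as `NA`
  unless the mitigated error is also zero, where 0 is the convention.
- **Clipping.** Mitigation can push $|\langle ZZZ\rangle| > 1$; values are
  projected onto $[-1,1]$ (flagged in the fit) so decoded similarities stay
  in $[0,1]$ by construction. The same projection backs the product
  approximation $\langle ZIZ\rangle\langle IZI\rangle$ used to reconstruct
  $\langle ZZZ\rangle$ from single-observable measurements; the three-factor
  composition $\langle IIZ\rangle\langle IZI\rangle\langle ZIZ\rangle$ is
  kept behind a flag since the published composition is not stated.
- **RNG.** One generator (R's default Mersenne–Twister via
  `set.seed()`), scoped so sampling never disturbs the caller's RNG state.

## Problem sizes used in the checks

The test suite runs entirely on the 8-dimensional state space, so exact
grids are cheap: the encoding round trip uses 1001 points, the closed-form
decay a 6 × 5 $(T, p)$ grid against a brute-force matrix oracle, shot-noise
consistency 100 seeds × 1000 shots (three $(T,p)$ settings), goodness-of-fit
5 seeds × 10⁴ shots, and the uniformity check one 4 × 10⁴-shot draw. These
sizes give comfortable statistical resolution (3-standard-error bands at
1000 shots resolve $\Delta\langle ZZZ\rangle \approx 0.1$) while keeping the
whole suite in seconds.

## Known limitations

- Depolarizing-only noise; no amplitude damping, crosstalk, readout error or
  hardware execution. The mitigation exponent is assumed known or
  calibrated, not estimated from data.
- The product approximation assumes independence of the factored
  observables; on strongly correlated states it is a biased estimator and is
  always flagged `approximate`.
- Fingerprints are binary and folded; count-based ECFPs, 3D descriptors and
  drug-likeness scoring are out of scope.
- The circuit is fixed at 3 qubits; deeper registers would need a sparse
  backend and per-gate noise placement beyond the CNOT filter.
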