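# qtanimoto

Quantum-encoded molecular similarity for the NISQ era: encode a classically
computed Tanimoto coefficient into a 3-qubit entangled state, simulate it
under depolarizing noise, estimate the encoded similarity from measurement
outcomes, and recover it with exponential error mitigation.

## Who this is for

Researchers benchmarking noise resilience and error-mitigation protocols on
near-term quantum hardware with a chemically meaningful payload, and
chemoinformaticians curious how a standard 2D similarity survives a round
trip through a noisy quantum register. The Tanimoto value itself is computed
classically (that part is maximally efficient already); the quantum circuit
is a minimal, entangled benchmark whose readout *is* the similarity.

## The model

For binary Morgan/ECFP fingerprints *A*, *B*, the Tanimoto (Jaccard)
coefficient is

    T(A,B) = |A ∩ B| / |A ∪ B|  ∈ [0, 1]

*T* is stored in the rotation angle **θ = 2·arccos√T** (so cos²(θ/2) = T) of
an RY gate on qubit 0; two CNOTs fan the superposition out to qubits 1 and 2,
preparing the GHZ-like state

    |ψ⟩ = √T |000⟩ + √(1−T) |111⟩

Ideal Z-basis measurements are perfectly correlated: P(000) = T,
P(111) = 1−T, and the three-qubit parity satisfies **⟨ZZZ⟩ = 2T − 1**, so
the similarity is decoded as **T = (1 + ⟨ZZZ⟩)/2**. Depolarizing noise with
probability *p* after each CNOT attenuates the parity to
⟨ZZZ⟩ = (1−p)²(2T−1), which inflates the apparent similarity of dissimilar
pairs and deflates that of similar pairs. Exponential mitigation rescales
the noisy expectation, ⟨ZZZ⟩·e^ε, and clips to [−1, 1]; with the calibrated
exponent ε = −2·ln(1−p) the rescaling inverts the channel exactly in
expectation. Errors are scored as ε = |T_base − T_est| and mitigation
effectiveness as the percent reduction of that error.

The simulator is an exact 8×8 density-matrix backend (no circuit toolkit
required); measurement shots are seeded multinomial draws from the final
diagonal. X-basis observables (IIX, IXI, XIX), identically zero on the ideal
state for every *T*, are available as a decoherence diagnostic.

## Worked example

```r
library(qtanimoto)

rec <- similarity_from_pair("CC(=O)OC1=CC=CC=C1C(=O)O", "CCCC",
                            label = "aspirin-butane")
rec
#> Tanimoto similarity record
#>   pair:   aspirin-butane
#>   method: morgan_tanimoto
#>   T:      0.0357143

fit <- quantum_similarity(rec, noise_p = 0.01, shots = 1000, seed = 42)
summary(fit)
#> Quantum-encoded Tanimoto similarity
#>   pair: aspirin-butane  (morgan_tanimoto)
#>   encoding: theta = 2.761 rad; backend: shots (1000 shots, seed 42)
#>   noise: depolarizing p = 0.01 (two_qubit); mitigation: from_noise_p (epsilon = 0.01)
#>   T  baseline 0.03571 | noisy 0.04 | mitigated 0.03538
#>   <ZZZ>  noisy -0.92 +/- 0.012 | mitigated -0.9292
#>   error  unmitigated 0.004286 | mitigated 0.0003374 | reduction 92.13%
#>   noisy counts: |000> 32, |010> 5, |011> 3, |101> 1, |110> 4, |111> 955
```

Reading this: the aspirin–butane fingerprints share 1 of 28 on-bits
(T = 1/28 ≈ 0.0357). Encoded at θ ≈ 2.76 rad, sampled with 1000 shots under
1% depolarizing noise per CNOT, the raw readout overestimates the similarity
(0.040); rescaling by e^0.01 pulls it back to 0.0354, cutting the error by
92% for this seed.

A full noise sweep in exact-expectation mode, with the calibrated exponent:

```r
noise_sweep(list(1.0, rec), error_rates = c(0.001, 0.01, 0.015, 0.05, 0.1),
            mode = "exact", mitigation = mitigation_config("calibrated"))
#> Noise sweep: 2 pairs x 5 error rates (exact mode, mitigation 'calibrated')
#>  error_pct           pair baseline unmitigated mitigated eps_unmitigated eps_mitigated eps_reduction_pct
#>        0.1 aspirin-butane   0.0357      0.0366    0.0357          0.0009             0               100
#>        0.1            t=1   1.0000      0.9990    1.0000          0.0010             0               100
#>        1.0 aspirin-butane   0.0357      0.0450    0.0357          0.0092             0               100
#>        1.0            t=1   1.0000      0.9900    1.0000          0.0100             0               100
#>        ...
#>       10.0 aspirin-butane   0.0357      0.1239    0.0357          0.0882             0               100
#>       10.0            t=1   1.0000      0.9050    1.0000          0.0950             0               100
```

The unmitigated column shows the characteristic distortion: the similar pair
decays toward 0.9 at 10% noise while the dissimilar pair inflates toward
0.12; calibrated mitigation undoes the channel exactly in this mode.
`write_report()` exports the table to CSV/JSON with full provenance
(seed, shots, policy), and `plot()` draws the sweep.

A thin CLI over the same functions ships in `inst/cli/qtanimoto.R`
(`similarity`, `encode`, `simulate`, `sweep`, `synth` subcommands).

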