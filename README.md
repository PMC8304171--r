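# strikentropy

Entropy analysis of striking positions in badminton match event logs.

## The problem

In elite singles, where a player hits the shuttlecock from is a tactical
signature: do strokes come overwhelmingly from the four corners of the half
court, or from everywhere? Is the pattern different when a player wins the
point, leads the score, or plays the final stretch of a match? This package
answers those questions quantitatively for stroke-level event logs (set,
point, stroke number, striker, hitting zone, x/y position, running score),
with three measures and a generative model:

* **Standard entropy** of the 12-zone strike distribution,
  `H = -Σ p_i ln p_i / ln 12 ∈ [0, 1]` — 0 for a single striking zone, 1 for
  a uniform spread.
* **Receiving entropy** — for each origin zone, the normalized entropy of
  the zone of the next stroke in the rally.
* **Spatial entropy** of the raw strike coordinates, the Clark–Evans ratio
  `Hs = <r> / r_ran` with `r_ran = (1/2)√(S/N)`: ≪ 1 clustered, ≈ 1
  spatially random, up to the triangular-lattice ceiling
  `2√(2/√3) = 2.149` for a regular arrangement.
* A **γ-mixture model** of striking strategies: each stroke is four-corner
  (probability γ, uniform over zones 1, 4, 9, 12) or uniform-random
  (probability 1 − γ), giving per-zone probabilities
  `p4c = (1 + 2γ)/12`, `pn4c = (1 − γ)/12` and the closed-form entropy
  `H(γ) = −(4 p4c ln p4c + 8 pn4c ln pn4c)/ln 12`, which `fit_gamma()`
  inverts to express an observed entropy as a corner-preference weight.

Because corpora of professional stroke logs are proprietary, the package
includes a seeded synthetic generator (`generate_corpus()`) reproducing the
assumed structure — corner-dominated zone shares, ~9-stroke rallies,
best-of-3 sets to 21, running scores, per-point winners — at the reference
scale of 259 matches / ~2.2e5 strokes. All analyses, tests and examples run
on generated data.

## Worked example

```r
library(strikentropy)

corpus <- generate_corpus(synthetic_config(n_matches = 259, seed = 20210623))
report <- run_pipeline(corpus)
print(report)
#> Strike-entropy analysis: 259 matches, 220362 strokes
#>   mean per-match standard entropy: 0.9224
#>   fitted mixture gamma: 0.46
#>   standard H, won vs lost: 0.9198 vs 0.9193 (p = 0.617)
#>   spatial Hs, won vs lost: 0.9652 vs 0.9650 (p = 0.949)
#>   spatial Hs, leading vs behind: 0.9655 vs 0.9679 (p = 0.347)
#>   spatial Hs, initial vs final: 0.9673 vs 0.9638 (p = 0.168)
```

Reading the output: per-match zone distributions are highly but not fully
random (H̄ ≈ 0.92); inverting the mixture curve says the synthetic players
behave like a 46% four-corner / 54% random mix. Winners' and losers' strokes
have statistically indistinguishable entropies — as they must here, since
the default generator gives both the same zone distribution (the null
model); `winner_zone_probabilities` injects a real effect when you want a
positive control. Spatial entropies sit just below 1 (between clustered and
random, nowhere near the regular regime's 2.149).

The regime anchors behind that interpretation:

```r
spatial_entropy(generate_clustered_pattern(500, spread = 0.4, seed = 1))$Hs  # ~0.59
spatial_entropy(generate_random_pattern(500, seed = 1))$Hs                   # ~1.02
spatial_entropy(generate_lattice_pattern(500))$Hs                            # ~2.09
```

## The analysis workflow

Numbered drivers under `analysis/` run the full study on the synthetic
corpus and write tables under `results/` (the large corpus CSV and report
JSON go to `scratch/`):

```sh
Rscript analysis/01_generate_corpus.R          # corpus + per-match summary
Rscript analysis/02_zone_and_receiving_entropy.R
Rscript analysis/03_spatial_entropy.R          # regimes + split t-tests
Rscript analysis/04_mixture_model.R            # gamma sweep + fit
Rscript analysis/05_report.R                   # consolidated JSON report
```

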