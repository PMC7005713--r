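# rotamerph

Does environmental pH flip the side-chain conformation of the
phosphorylatable histidine in sensor histidine kinases? A "pH-gated" model
claimed that below a pH boundary (≈ 5.2–6.5) the conserved DHp-domain
histidine of HisKA-family kinases (His260 in *Thermotoga maritima* HK853)
switches from a *trans* to a *gauche−* χ1 rotamer and thereby loses
phosphatase activity. `rotamerph` is the analysis toolkit for testing that
claim structurally and kinetically. It is written for structural
bioinformaticians and two-component-system biochemists who want the whole
chain — coordinates in, statistics out — scripted and reproducible.

The package provides:

* **Structure I/O** — PDB and mmCIF reading (via `bio3d`) into tidy atom
  tables with alternate conformers preserved, plus crystallization-pH
  extraction from REMARK 280 / `_exptl_crystal_grow` metadata (a pH range
  becomes its midpoint; absence stays `NA`, never a guess).
* **Geometry kernel** — signed torsions (IUPAC convention), χ1 measurement
  per altloc group, rotamer classification over the partition
  gauche− [−120°, 0°), gauche+ [0°, 120°), trans (the remainder), distance
  contacts, and Kabsch superposition (SVD, reflection-corrected, det +1).
* **Rotamer survey** — per-subunit calls across a structure set, a curated
  28-structure HisKA manifest (66 subunit/conformer calls) with
  crystallization pH, dimer-concordance labels, His–sulfate coordination
  flags, and a two-sided exact 2×2 test of pH bin × rotamer implemented
  from log-factorials:
  p = Σ P(T) over margin-consistent tables T with P(T) ≤ P(observed),
  P hypergeometric.
* **Phospho-decay kinetics** — the semilog estimator (OLS of ln S on t,
  k = −slope, t½ = ln 2/k) with infinite-half-life handling, grouped
  fitting, and condition comparison.
* **Synthetic data** — idealized His residues built in internal
  coordinates (χ1 exact by construction), multi-chain PDB fixtures with
  declared pH and placed sulfates, helical Cα traces for
  superposition-scale work, and seeded lognormal-noise decay courses — so
  every pipeline stage is testable without downloading a single file.

## Worked example

```r
library(rotamerph)

survey <- compile_survey(mode = "manifest")   # packaged 28-entry survey
survey
#> <rotamer_survey> manifest mode: 66 calls in 28 structures (gauche- 27, gauche+ 0, trans 39)
#>
#>     distinct    identical mixed-altloc
#>            9           17            2

test_ph_association(survey, threshold = 6.5)
#> pH-rotamer association (subunit level, threshold pH 6.5): p = 1
#>          rot
#> bin       gauche- trans
#>   pH<=6.5      11    15
#>   pH>6.5       16    24
```

The 66 subunit calls split 27 gauche− / 39 trans; binned at the proposed
gating boundary (pH 6.5) the table is almost exactly what independence
predicts — the exact two-sided p-value is 1, i.e. no evidence that
crystallization pH selects the rotamer. Concordance shows the same thing
from another angle: in 9 structures the two subunits of one dimer carry
*different* rotamers at a single pH.

The kinetic side uses the same estimator as the gel analysis:

```r
tc <- simulate_decay(10, sigma = 0.05, seed = 2, condition = "HK853-P pH 5")
fit_decay(tc)
#> First-order decay fit (semilog, n = 6): k = 0.06903 /min, t1/2 = 10 min

sim  <- simulate_decay(10, sigma = 0.05, reps = 200, seed = 1)
fits <- fit_decay_by(sim, replicate)
median(fits$half_life)
#> [1] 10.01182
```

A 10-minute true half-life sampled at the experimental grid
(t = 0, 1, 3, 5, 15, 30 min) with 5% multiplicative noise is recovered to
about 0.1% in the median over 200 replicates.

Coordinate-mode surveys (`compile_survey(mode = "coordinates",
structures_dir = ...)`) and complex superposition
(`run_superposition(ref, mobile)`) run identically on real deposited files
when you have them locally; the test suite exercises them on generated
fixtures. A thin command-line wrapper lives at `inst/cli/rotamerph.R`
(subcommands `survey`, `superpose`, `kinetics`, `simulate`).

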