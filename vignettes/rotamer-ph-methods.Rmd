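---
title: "Methods: His rotamer surveys, pH association and phospho-decay kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: His rotamer surveys, pH association and phospho-decay kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotamerph)
```

## The scientific question

Sensor histidine kinases (HKs) of the HisKA family autophosphorylate on a
conserved histidine in their DHp domain (His260 in *Thermotoga maritima*
HK853) and pass the phosphoryl group to a response regulator (RR). A
"pH-gated" model proposed that environmental pH — with a boundary between
roughly 5.2 and 6.5 — flips the first side-chain torsion (χ1) of this
histidine between a *gauche−* and a *trans* rotamer, and thereby gates the
kinase's phosphatase activity. `rotamerph` implements the structural
counter-analysis: classify the His χ1 rotamer per subunit across the
family's deposited crystal structures, relate the calls to crystallization
pH with an exact test, detect His–anion (sulfate) coordination that offers
an alternative, pH-independent explanation of rotamer choice, superpose
HK–RR complexes to quantify global similarity, and fit first-order
phospho-His decay to estimate half-lives — the chemical (protonation-based)
explanation of pH sensitivity.

## χ1 measurement and rotamer classification

χ1 is the torsion of N–CA–CB–CG about the CA–CB bond, measured with the
IUPAC sign convention (cis = 0°, clockwise positive looking down the bond).
The classifier partitions (−180°, 180°] into three half-open bins:

* gauche−: [−120°, 0°)
* gauche+: [0°, 120°)
* trans: [120°, 180°] together with (−180°, −120°)

Every angle receives exactly one label; a bin edge belongs to the bin whose
lower edge it is, and values within 10⁻⁹ degrees of an edge are snapped to
it so that edge-constructed geometries classify deterministically. The
literature rarely states whether "gauche−" means χ1 ≈ −60° or +60°; we
adopt the IUPAC/penultimate-library convention (gauche− ≈ −60°, the "m"
rotamer) and expose `mirror = TRUE` throughout as the single permitted
alternative. Per-subunit concordance of the curated survey's printed calls
with coordinate-derived calls is the check that would falsify the choice.

Alternate conformers ("altlocs") matter: two survey entries model the
phosphoacceptor His in both rotamers at once. Each altloc group with
occupancy ≥ 0.2 yields an independent call (this is what brings the
family-wide tally to 27 gauche− and 39 trans over 66 calls); groups below
0.2 are skipped with a message.

## The curated survey and its pH column

The package ships a manifest of 28 HisKA-family structures with one row per
subunit/conformer call (66 rows), the crystallization pH and mother-liquor
text. The manifest — not the coordinate header — is the pH source of truth,
because deposition headers are free text and occasionally disagree with the
curated conditions (one entry's final pH was adjusted after mixing; another
reports only a 7.6–8.6 range, which we reduce to its midpoint 8.1 and keep
as a range). In coordinate mode the header-extracted pH is reported next to
the manifest value for auditing, never silently substituted. A missing pH is
represented as `NA` and excluded from association testing — it is never
defaulted to 7.

Concordance per structure is reported as `identical`, `distinct` or
`mixed-altloc` (any subunit carrying two labels). Counting from the
per-subunit calls, the packaged survey yields 17 identical, 9 distinct and
2 mixed-altloc structures. Per-structure tallies are sensitive to the
counting rule (how mixed-altloc subunits and the four-dimer entry are
attributed), and tallies quoted elsewhere for this structure set differ
slightly from ours; the package always reports the tally implied by its
stated rule rather than adjusting the rule to match a quoted figure.

## Exact association test

The hypothesis has a natural 2×2 form: pH bin (≤ 6.5 vs > 6.5, the upper
edge of the proposed gating window) crossed with rotamer (gauche− vs
trans). Because the expected cell counts are small, we use the exact
conditional test: with margins fixed, the count in one cell is
hypergeometric, and the two-sided p-value sums the probabilities of all
margin-consistent tables no more probable than the observed one. The
implementation works from log-factorials (`lgamma`) and is validated
against full hypergeometric enumeration for all 2×2 tables with total ≤ 12
plus hundreds of random tables up to total 40, and against
`stats::fisher.test`. A zero margin returns p = 1 with a `degenerate` flag.

On the packaged survey at threshold 6.5 the binned table is 11/15 (low pH,
gauche−/trans) vs 16/24, which is essentially the independence expectation:
the observed table is the modal one given its margins and the two-sided
p-value is 1 — no evidence that crystallization pH selects the rotamer.
Unit of analysis is the subunit call, matching the per-subunit notation of
the survey; a structure-level majority-label mode exists as an option
(ties excluded). Only the single pre-registered threshold is tested by
default; `sweep_ph_thresholds()` reports unadjusted p-values and is
documented as exploratory.

## Contacts and superposition

His–anion coordination is a heavy-atom distance criterion: any sulfate (or
configured anion) atom within 3.6 Å — a typical hydrogen-bond upper bound,
configurable — of the imidazole Nδ1 or Nε2 of the called conformer. No
hydrogens are placed and no geometry beyond distance is scored.

Complex similarity uses the Kabsch algorithm: centroids removed, SVD of the
cross-covariance, reflection-corrected proper rotation (det = +1), RMSD of
the residual pair distances. Cα atoms are paired by (chain, residue-number)
intersection after an optional chain-correspondence map; no sequence
alignment is attempted because the compared structures share author
numbering. The implementation is property-tested (recovery of planted
rotations to 10⁻⁸, optimality against 10⁴ random trial rotations,
invariance to pre-rotation and consistent permutation) and cross-checked
against `bio3d::fit.xyz`.

## Decay kinetics

Phospho-His stability is summarised by the semilog estimator: ordinary
least squares of ln(signal) on time, k = −slope (min⁻¹), t½ = ln 2 / k.
This mirrors how gel time courses are normally analysed; a nonlinear
least-squares mode exists behind `method = "nls"` for comparison but is not
the canonical path. Signals at or below zero are dropped with a warning
(gels can read zero) and at least three points must survive. A nonnegative
slope reports t½ = ∞, printed as "exceeds the observation window"; no
extrapolation is attempted.

## What the synthetic generator emulates — and what it does not

The generator provides every input the pipeline needs without downloads:

* **Idealized His residues** built in internal coordinates (each atom
  placed by bond length, bond angle and torsion from three reference
  atoms), so the target χ1 is exact by construction — the build/measure
  round trip over a 5° grid is the module's defining invariant. Default
  geometry: N–CA 1.46 Å, CA–CB 1.53 Å, CB–CG 1.50 Å; angles N–CA–CB 110.5°,
  CA–CB–CG 113.8°. The imidazole beyond CG is completed with planar ideal
  geometry at a fixed χ2 of −75° (a common His value) solely so Nδ1/Nε2
  exist for contact tests; χ2 is not a studied variable.
* **Multi-chain fixtures** with one target His per chain, REMARK 280
  carrying the declared pH, optional double conformers (altloc A/B sharing
  the backbone), and an optional sulfate whose nearest oxygen sits at a
  prescribed distance from Nε2 along the exocyclic bisector.
* **Survey-profile batches**: for each manifest entry a fixture whose
  subunits are drawn at χ1 = −60° ± 25° (gauche−) or 180° ± 25° (trans) —
  a spread chosen once as a realistic within-bin rotamer scatter that can
  never cross a bin edge — under a fixed seed.
* **Helical Cα traces** (1.5 Å rise, 100° twist) at arbitrary chain sizes,
  used to exercise superposition at the ~707-matched-residue scale of a
  full HK-dimer-plus-two-RR asymmetric unit.
* **Decay courses**: signal(t) = 100·exp(−ln 2·t/t½)·exp(ε) with
  ε ~ N(0, σ²) i.i.d. per point — multiplicative lognormal noise, because
  band intensities are positive with error roughly proportional to signal.
  Defaults: the experimental grid t = 0, 1, 3, 5, 15, 30 min and σ = 5%.

Synthetic structures are not physically realistic proteins: single residues
per chain, no packing, no symmetry mates, no waters, idealized geometry.
Passing tests therefore demonstrate that the measurement, classification,
metadata and bookkeeping chain is correct — they do not validate rotamer
assignment against real crystallographic disorder, nor the specific RMSD
values of real deposits, which require the public coordinate files. When
those files are available locally, `compile_survey(mode = "coordinates")`
and `run_superposition()` run unchanged on them.

## Numerical choices and degenerate inputs

* Torsion and superposition are exact linear algebra; no iterative fitting.
  Collinear torsion frames and rank-deficient clouds raise errors rather
  than returning junk.
* The exact test ties at log-probability are resolved with a 10⁻⁷ relative
  tolerance, the standard guard against `lgamma` round-off.
* Occupancy floor 0.2, contact cutoff 3.6 Å, association threshold 6.5 and
  the decay grid are all arguments with these defaults; none is read from
  global state.
* Problem sizes used by the test suite: 28-structure synthetic surveys,
  707-residue superpositions, 200-replicate decay simulations, exhaustive
  exact-test enumeration to total 12 with random tables to 40 — sizes
  chosen to mirror the real analysis while keeping the suite quick on one
  CPU.

## Known limitations

* Rotamer calls use χ1 only; χ2/ring-flip analysis and rotamer-library
  probabilities are out of scope.
* The selector table records the phosphoacceptor residue number only where
  it is established in this package's sources (HK853, EnvZ, CpxA); for the
  remaining proteins coordinate-mode runs on real deposits need a
  user-supplied selector.
* The survey treats each subunit call as exchangeable in the exact test;
  subunits of one crystal are not strictly independent observations, so
  the p-value is descriptive of the tabulated calls rather than a
  population-level inference.
* No symmetry expansion: contacts are intra-asymmetric-unit, which matches
  the contacts analysed here but would miss lattice contacts in general.
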