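---
title: "Potts threading of kinase conformational penalties: models and methods"
author: "kinthread authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Potts threading of kinase conformational penalties: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinthread)
```

# The model

Protein kinase catalytic domains switch between an active DFG-in
conformation with an extended activation loop and an inactive, classical
DFG-out conformation in which the loop folds ~17 Å away. Type-II
inhibitors bind only the latter, so the free-energy cost of the
transition, ΔG_reorg, gates their affinity. `kinthread` estimates a
statistical-energy analogue of this cost from sequence alone.

The sequence model is a Potts Hamiltonian over an L-column fixed-width
alignment with q = 21 states (20 amino acids plus the gap, which is an
ordinary state so that all couplings are defined):

$$H(S) = \sum_{i<j}^{L} J_{ij}(s_i, s_j) + \sum_i^L h_i(s_i),
\qquad P(S) \propto e^{-H(S)}.$$

Lower energy means more probable; we state this convention explicitly
because it fixes the sign of everything downstream: a positive threaded
penalty disfavours DFG-out. Inference of `h` and `J` from natural
alignments is out of scope — the package consumes fitted parameters
through a documented plain-text container (`readPottsModel`).

The structural side reduces each ensemble (per kinase class) to weighted
contact frequencies. A contact is a residue pair whose nearest side-chain
heavy atoms lie strictly within 6 Å, restricted to alignment separation
|i − j| > 4 to remove trivial backbone neighbours. Chains are
down-weighted by 1/u, u being the number of chains sharing their UniProt
accession across both conformational clusters, so heavily crystallized
kinases do not dominate. The threading penalty for sequence S in class X
is the inner product of its couplings with the contact-frequency
difference map:

$$\Delta E(S \in X) = -\sum_{i<j,\,|i-j|>4} J_{ij}(s_i,s_j)\,
\Delta c_{ij}(X), \qquad \Delta c = c^{\mathrm{active}} -
c^{\mathrm{DFG\text{-}out}}.$$

The class divergence ΔΔE = ⟨ΔE⟩_STK − ⟨ΔE⟩_TK uses phylogenetically
weighted means, and decomposes exactly into pair terms through the
weighted bivariate marginals $f^{ij}_{\alpha\beta}$; the package computes
the per-sequence route and the marginal route independently and verifies
they agree to 1e-8, which holds as an algebraic identity whenever both
use the same weights.

# Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| contact cutoff | 6 | Å | strict inequality at the cutoff; nearest side-chain heavy atoms |
| sequence separation | > 4 | columns | excludes backbone-adjacent pairs from contact maps and from ΔΔE_ij |
| identity neighbourhood | 0.40 | divergence fraction | sequences within 40% divergence (identity ≥ 60%) share weight 1/n |
| gap filter | 31 | max gaps | sequences with 32+ gaps are removed before kinome-scale threading |
| hit threshold | 1e-5 | molar | K_d ≤ 10 µM counts as a type-II "hit", inclusive |
| gatekeeper volume | 110 | Å³ | small/large side-chain split |
| temperature | 298.15 | K | K_d → ΔG conversion; k_B = 0.0019872041 kcal/(mol·K) |

The TK/STK classifier reads three diagnostic columns (defaults 126, 128,
165 in the canonical 259-column alignment, 1-based everywhere): TK
requires Ala/Arg, Arg, Trp at the three positions; STK requires Lys at
the first and non-Arg at the second. A gap at any diagnostic column gives
"other" rather than a guess. The positions are an argument so that
reduced synthetic alignments can carry the same signature logic.

# Design choices at genuinely open points

* **"Within 40% identity."** The phrase admits two readings: identity ≥
  40% or divergence ≤ 40%. We default to divergence ≤ 40% (identity ≥
  0.60), computed as exact Hamming identity over all L columns with the
  gap as an ordinary symbol; both the threshold and the direction are
  arguments of `phyloWeights`. The neighbour count includes the sequence
  itself, so weights never exceed 1 and N_eff = Σw is interpretable as a
  deduplicated sample size. We use exact all-pairs counting, not a
  clustering heuristic, for determinism and oracle-checkability.
* **Aspartate gatekeepers.** Asp appears in neither the small nor the
  large membership set, so it is resolved against a standard side-chain
  van der Waals volume table (91 Å³ < 110 Å³ → small). The printed sets
  take precedence for all other residues even where the volume table
  would disagree (e.g. Asn at 96 Å³ remains "large" by set membership).
* **Zero gauge.** Potts parameters are gauge-degenerate; threading
  differences are only meaningful in a fixed gauge. We use the standard
  zero-sum gauge (all row and column sums of every coupling block vanish,
  to 1e-10 absolute), pushing removed means into the fields and a scalar
  offset so that H is preserved exactly for every sequence; the transform
  is idempotent. `threadEnergy` auto-applies it with a warning if given a
  raw model.
* **Gaps in threading.** Natural kinase sequences are gappy. By default
  the gap threads through the model's own gap-state couplings
  (`gapPolicy = "model"`); `"zero"` silences any pair containing a gap.
  A model without a gap state routes gaps to a zero-coupling sink under
  either policy. The decomposition identity holds under every
  combination because the marginal route uses the same encoding.
* **Per-pair normalization.** An unresolved residue is missing data, not
  a non-contact: both the numerator and denominator of c_ij run only over
  chains resolving both columns. A `"global"` mode (full-weight
  denominator) exists for comparison. Pairs with no resolved support are
  flagged and contribute Δc = 0 downstream, with a warning.
* **Weighted Welch test.** The standard error of a weighted mean is not
  uniquely defined in the source literature; we use s² = Σw(x − x̄_w)² /
  (N_eff − 1) and SE = s/√N_eff, with ν_i = N_eff,i − 1 in the standard
  Welch–Satterthwaite formula (the printed variant of that formula in the
  source material is typographically corrupted; we implement the textbook
  form). With unit weights this reduces exactly to `t.test`, which the
  tests verify to 1e-10, and the one-tailed null rejection rate at α =
  0.05 is checked to be 0.05 ± 0.01 over 2000 replicates. p-values below
  1e-15 are reported as a bound, which is both the double-precision
  reality and the field's reporting style.
* **Calibration regression.** Whether the Potts-to-kcal/mol calibration
  includes an intercept is not determined by the data we bundle; the
  through-origin slope Σxy/Σx² is the headline number (it is the one
  consistent with ΔE = 0 ⇒ ΔG_reorg = 0) but `calibratePottsScale` emits
  the unconstrained fit alongside it.
* **IC50 as K_d.** Literature affinities mix IC50 and K_d; both run
  through the same ΔG = k_B T ln(K_d/1 M) conversion, a documented
  simplification.

# The synthetic generator

`plantedScenario` builds a complete ground-truth world: a Potts model
with small Gaussian background couplings (sd 0.02) and `nPlanted`
structured blocks of magnitude `contrast` at |i − j| > 4 pairs; a
two-class alignment Gibbs-sampled from that model (sequential-scan
heat-bath, single chain, seeded — identical seeds give byte-identical
output) with class signatures written into diagnostic columns and
planted-pair columns biased so the STK-like class is enriched in state
pairs with strongly favourable active-state couplings; and synthetic
contact-map ensembles whose Δc is +1 exactly on the planted pairs and 0
elsewhere, with optional pseudo-UniProt redundancy and random
missing-residue masks. All randomness flows from one master seed through
named substreams.

What it emulates: the statistical structure the analysis assumes —
class-dependent bivariate marginals at conformation-sensitive pairs,
structure redundancy, missing residues. What it does not: real kinase
phylogeny, real contact topology, the 259-column geometry, or
inference error in the Potts parameters. Passing the planted-recovery
tests therefore demonstrates the correctness of the machinery, not the
biological conclusions on natural data, which additionally require a
fitted kinome-scale model and curated structural ensembles.

Default study sizes are chosen to be desk-scale while leaving no
ambiguity in the planted signal: L = 60 columns, q = 6 states, 500
sequences per class, 5 planted pairs at contrast 2, marginal shift 0.8,
8 chains per class/state ensemble. The null-calibration checks run 200
pipeline replicates at L = 24 with 30 sequences per class, and the
sign-stability check 50 replicates at the default scale.

# Numerical and degenerate-input behaviour

Gauge checks use 1e-10 absolute tolerance (double precision with
headroom); decomposition identities 1e-8; the threading oracle comparison
1e-10. Ranked pair reports break ties by ascending (i, j) after the
descending contribution sort, so output is deterministic. Ragged
alignments fail naming the offending record; unknown residue codes (X,
B, Z, J, U, O) map to the gap by default or abort under
`unknown = "error"`. Empty classes, zero-variance samples, non-positive
binding constants and missing decoupling legs are hard errors naming the
problem; a glycine with no side-chain heavy atoms contributes contacts
through its Cα proxy (switchable), and a residue with no mapped column
contributes nothing rather than crashing.

# Limitations

The package computes statistical energies, not free energies; the
kcal/mol scale comes only through the bundled regression benchmark
(`kinaseReorgData`), which contains ten kinases. Conformational-state
labels (active DFG-in vs classical DFG-out) and residue-to-column maps
are consumed as inputs, not inferred. The Hamiltonian evaluation is exact
but O(L²) per sequence; kinome-scale threading is fast because Δc maps
are sparse, while full-H evaluation on 259-column models is intended for
model diagnostics rather than bulk scoring.
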