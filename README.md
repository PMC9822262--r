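# kinthread

Sequence-based analysis of the conformational free-energy landscape of
protein kinase catalytic domains.

## The problem

Type-II kinase inhibitors bind only the inactive "classical DFG-out"
conformation, in which the DFG motif has flipped and the ~20-residue
activation loop has folded ~17 Å away from its active, extended
arrangement. Whether a kinase is druggable this way therefore depends on
the free-energy cost of that reorganization, ΔG_reorg — a quantity that is
prohibitively expensive to simulate directly. Tyrosine kinases (TKs) tend
to pay a small penalty; serine/threonine kinases (STKs) a large one.

`kinthread` implements a sequence-based route to this penalty. A Potts
Hamiltonian inferred from residue covariation in a fixed-width multiple
sequence alignment (L columns, q = 21 states),

    H(S) = Σ_{i<j} J_ij(s_i, s_j) + Σ_i h_i(s_i),    P(S) ∝ exp(−H(S)),

is threaded over two structural ensembles: active DFG-in and classical
DFG-out. With weighted contact frequencies c_ij per ensemble (contacts =
nearest side-chain heavy atoms < 6 Å, |i−j| > 4; chains down-weighted
1/u by UniProt multiplicity; unresolved residues excluded per pair) and
their difference Δc_ij = c_ij(active) − c_ij(DFG-out), the threaded
penalty of a sequence S in class X is

    ΔE(S ∈ X) = − Σ_{i<j, |i−j|>4} J_ij(s_i, s_j) · Δc_ij(X).

Positive ΔE disfavours DFG-out. The TK/STK divergence
ΔΔE = ⟨ΔE⟩_STK − ⟨ΔE⟩_TK (phylogenetically weighted means) decomposes
*exactly* into residue-pair terms

    ΔΔE_ij = − Σ_{α,β} J_ij(α,β) [ f_ij^{αβ}(STK) Δc_ij(STK) − f_ij^{αβ}(TK) Δc_ij(TK) ],

where f are weighted bivariate marginals, so the pairs driving the
divergence (activation-loop anchors, the RD pocket) can be ranked. A
weighted Welch test gives the significance of ΔΔE, and a small free-energy
bookkeeping module (K_d → ΔG_exp, double-decoupling leg combination,
ΔG_reorg = ΔG_exp − ΔG_bind^ABFE, slope-one and through-origin
regressions) calibrates the Potts scale in kcal/mol.

The package also ships a synthetic-data generator (`plantedScenario`) that
plants conformation-sensitive couplings in a ground-truth model, samples
two sequence classes by Gibbs sampling, and emits matching synthetic
contact ensembles — so the entire pipeline is testable end to end without
any downloads.

## Worked example

```r
library(kinthread)

## Calibration: ten kinases with measured type-II panels and ABFE-derived
## reorganization free energies
cal <- calibratePottsScale(kinaseReorgData())
cal$r2            # 0.7492 -> one Potts unit tracks dG_reorg well
cal$slope_origin  # 1.29 kcal/mol per Potts unit
cal$class_means   #  STK    TK
                  # 6.42  0.80   (kcal/mol)

## Synthetic end-to-end run: 60 columns, 500 sequences/class, 5 planted
## conformation-sensitive pairs
sc <- plantedScenario(seed = 1)
dv <- scenarioDivergence(sc)
dv
#> DivergenceResult: <dE>_STK = 4.589, <dE>_TK = -4.148, ddE = 8.737
#>   Welch one-tailed p < 1e-15; top pairs:
#>    i  j    ddE_ij cumulative_fraction
#> 1 39 45 2.1864513           0.2502549
#> 2 37 51 2.1311845           0.4941842
#> 3  1 58 2.1220582           0.7370689
#> 4 29 38 2.0730780           0.9743474
#> 5 37 50 0.2241238           1.0000000
```

The STK class was generated with an excess of strongly coupled
active-state contacts at the planted pairs, so it pays a positive
penalty to reach DFG-out while the TK class does not; the ranked
ΔΔE_ij report recovers exactly the five planted pairs, and the
cumulative fractions show how much of the total divergence each
interaction explains. On real data the same report ranks the
activation-loop anchor and RD-pocket interactions.

File-based runs (`runPipeline`) read a FASTA alignment, a Potts
parameter container and structure contact tables, and write
fixed-schema TSVs plus a JSON manifest; see `?runPipeline`.

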