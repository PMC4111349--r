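---
title: "Diagnosing hybrid origin from multi-copy ITS polymorphism: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing hybrid origin from multi-copy ITS polymorphism: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itshybrid)
```

## The problem

The internal transcribed spacers (ITS1, ITS2) of nuclear ribosomal DNA occur
in hundreds of tandem copies per genome. In sexually reproducing plants,
concerted evolution homogenizes these copies, so a species usually shows one
dominant ribotype. Two processes disrupt this picture and make ITS a powerful
forensic marker for reticulate evolution:

* **Hybridization** places two parental ribotype families in one nucleus. A
  direct Sanger read of such a genome shows *additive* polymorphisms — IUPAC
  ambiguity codes at exactly the positions where the parents differ.
* **Apomixis** (asexual seed production) removes the meiotic machinery that
  drives homogenization, so hybrid additivity and newly arising mutations
  (including non-functional, "pseudogenized" copies) persist over
  generations.

`itshybrid` implements the full chain of analyses used to exploit these
signals: polymorphic-site detection under IUPAC semantics, hybrid additivity
classification, distance and network inference (NeighborNet split networks,
statistical-parsimony haplotype networks), secondary-structure-aware
substitution classification with pseudogene and chimera screening, and a
companion landmark geometric-morphometric analysis of leaf shape. A seeded
synthetic-data module generates data with the statistical structure this
chain assumes, so every stage is testable without downloads.

## Polymorphism with IUPAC semantics

A direct Sanger read of a multi-copy template reports the superposition of
the copies. We therefore treat an ambiguity code as a *set* of bases
(`R = {A,G}`), and define a column of an alignment to be polymorphic when the
union of expanded state sets across the selected sequences — gaps and `N`
excluded — contains at least two bases. A single `Y` in a single individual
suffices: it records two co-occurring intragenomic states. Columns that vary
only by gaps are not polymorphic, because the analysis counts nucleotide
polymorphisms, not alignment artifacts.

Hybrid additivity at a polymorphic site is classified from the expanded state
sets of the maternal group, the paternal group, and the hybrid:

* `additive_combination` — the hybrid carries at least one maternal-specific
  and one paternal-specific state (e.g. parents fixed `C` vs `T`, hybrid
  `Y`);
* `parental_shared` — the hybrid's state set equals a polymorphism already
  present within a parent;
* `maternal_only` / `paternal_only` — the hybrid falls entirely inside one
  parent's states;
* `novel` — the hybrid carries a state absent from both parents (mutation or
  artifact).

These five classes partition all sites at which the three groups are
observed; this partition property is enforced by tests.

**Consensus emulation.** `call_consensus()` inverts the direct-sequencing
process: per column, states with pooled frequency at or above
`minor_threshold` are kept and encoded as the minimal covering IUPAC code.
The default threshold of 0.25 reflects the practical detection floor of
secondary peaks in Sanger chromatograms; it is configurable. A consequence,
enforced as an invariant, is that consensus records can never reveal a site
invisible in the underlying copy set — which is exactly why cloning detects
more polymorphic sites than direct sequencing.

## Distances, ribotypes and networks

**Uncorrected p distance with ambiguity averaging.** For each column where
both sequences carry an informative state (pairwise deletion of gaps and
`N`), the expected mismatch is `1 - |Sa ∩ Sb| / (|Sa|·|Sb|)` under uniform
resolution of the ambiguity sets; the distance is the mean over comparable
columns. This matches the "ambiguities as average" convention of split
network software. The Kimura 2-parameter distance uses the same averaging to
obtain expected transition (`P`) and transversion (`Q`) fractions, then
`d = -1/2 ln(1-2P-Q) - 1/4 ln(1-2Q)`. Saturated pairs (non-positive log
argument) are an error, never a stored infinity. Pairwise deletion was chosen
because it is the default of the distance software this workflow
traditionally relies on; identity summaries are reported rounded half-up to
three decimals, the convention of published identity tables.

**Ribotypes** are equivalence classes under exact identity over columns where
both sequences are non-gap. By default `N` matches nothing (a sequencing
failure should not merge ribotypes); `permissive_n = TRUE` relaxes this.

**Statistical parsimony connection limit.** Haplotype networks connect
ribotypes only up to the number of steps that can be accepted as
non-homoplastic with probability ≥ 0.95. We model the number of
substitutions per site along the path between two haplotypes as Poisson with
mean `mu`, base changes following the equal-rates (Jukes–Cantor) chain.
Calibrating `mu` so that the expected fraction of visibly different sites
equals the observed `j/L` gives the probability that one visible difference
reflects exactly one substitution,

\[ r(\mu) = \frac{\mu e^{-\mu}}{\tfrac34\,(1 - e^{-4\mu/3})}, \]

and independence across the `j` differing sites gives
`P(parsimony | j) = r(mu)^j`. The connection limit is the largest `j` with
this probability ≥ 0.95. The closed form is checked against an independent
series enumeration of the same model in the tests. For an alignment of 501
comparable columns the default limit evaluates to 8 steps; the limit grows
with `L` and shrinks as the probability threshold rises, both enforced as
monotonicity tests.

**Network construction** agglomerates ribotypes by ascending pairwise
difference count; an edge is added when its endpoints are not already
connected through strictly shorter edges, ties at one distance being
evaluated simultaneously against the pre-tie components. This reproduces the
minimum-spanning-network construction exactly (verified against a brute-force
oracle), with multi-step edges materializing unlabeled intermediate nodes and
components disconnecting naturally at the limit.

**NeighborNet.** The agglomeration and non-negative least-squares split
weighting are delegated to `phangorn::neighborNet()`, an established
implementation of the published algorithm; `neighbor_net()` normalizes its
output into the package's `split_set` container, handles the degenerate
(star/tree) and small-`n` cases, and drops splits with weight below `1e-6`
(numerical-noise splits that would only clutter the diagram). On additive
tree metrics the recovered splits equal the tree's bipartitions with weights
equal to branch lengths to `1e-6`, which the tests assert on random 4–8 taxon
trees. Bootstrap supports resample alignment columns with replacement,
recompute the ambiguity-averaged distances and the network, and report the
fraction of replicates containing each split; the whole procedure is
deterministic under a seed.

## Secondary structure, pseudogenes, chimeras

Substitutions at helical positions of an ITS transcript can retain or destroy
the base-pair bond. With the bond set `{A-U, U-A, G-C, C-G, G-U, U-G}`
(G·U wobble counts as a bond by default, configurable off):

* **CBC** — both partners change, bond retained (`G-C → A-U`);
* **hemi-CBC** — one partner changes, bond retained (`G-C → G-U`);
* **non-compensatory** — the new pair is not in the bond set;
* **unpaired** — the column has no partner in the template.

The classifier is exhaustively verified against an independently coded truth
table over all 256 ordered pair transitions. When a site shows several
variant states, the site is assigned one class by maximal severity
(CBC > non-compensatory > hemi-CBC > unpaired). The severity rule is this
package's choice: published per-site tallies do not state how multi-variant
sites were collapsed, so the rule is explicit, documented and applied
uniformly (a sensitivity analysis only needs the per-variant classifications,
which `classify_base_change()` exposes).

**Pseudogene screening** reflects the standard diagnostics for ITS copies
that escaped concerted evolution: substitutions in the strictly conserved
5.8S, failures of the conserved angiosperm motifs (the ITS1 motif
`GGCRY(4–7n)GYGYCAAGGAA`, scanned over spacer lengths 4–7, and the 5.8S
motifs M1–M3, all matched IUPAC-aware), and depressed GC content (z-score
below −3 against the clone library, per region). Any one of these yields the
verdict `putative_nonfunctional`. Clones whose variants are all singletons in
their library and all non-compensatory are flagged `putative_artifact`
instead, mirroring the observation that most non-compensatory changes occur
in single clones and likely arise during PCR and cloning.

**Chimera scanning** replaces a multi-method recombination-detection suite
with one defined, testable computation: at informative sites (parents fixed
for different bases) the query is assigned to one parent or the other, the
2×2 chi-square statistic (left/right of breakpoint × parental origin) is
maximized over all breakpoints, and significance is calibrated by permuting
the site assignments (default 999 permutations, seed required). Planted
breakpoints are localized to within ±2 informative sites in the recovery
tests, and the type-I error of the permutation calibration is checked on
breakpoint-free mosaics.

## Landmark morphometrics

Leaf shape is analyzed from 14 fixed 2D landmarks per leaf.

* **GPA**: iterative centering, scaling to unit centroid size, and rotation
  to the running consensus, until the consensus moves by less than `1e-8`
  (root sum of squares). Rotations never include reflection — leaves are
  oriented objects. The two-configuration residual agrees with the
  singular-value closed form to `1e-8`, and the residual is invariant to
  pre-transforming any input configuration.
* **Bilateral symmetrization** (object symmetry): each configuration is
  averaged with its reflected, relabeled copy after optimal alignment. The
  operation is idempotent and its output is exactly invariant under the
  reflection-relabel map. The landmark pairing (6 left/right pairs, apex and
  base on the midline) is user configuration; `leaf_pairing()` is the
  fixture scheme.
* **Relative warps** are principal components of the flattened aligned
  coordinates with no bending-energy weighting (the `alpha = 0` convention
  of the standard software), so variance fractions are eigenvalue shares.
* **Procrustes distance**: after superimposition, `full = sin(rho)`
  (default), `partial = 2 sin(rho/2)`, or the Riemannian `rho` itself. All
  three are offered because published distance tables rarely state which
  definition was used; tests check symmetry and the triangle inequality
  numerically.
* **Two-group permutation tests** use the Euclidean distance between group
  mean score vectors on the first 12 relative warps (configurable), with the
  valid `(b + 1)/(N + 1)` p-value estimator — chosen over `b/N` because it
  is exact regardless of the reference software's convention. Null
  uniformity of the p-values is verified by a Kolmogorov–Smirnov check over
  500 seeded null datasets.
* **Tangent-space adequacy**: correlation and through-origin slope of
  tangent (Euclidean) versus Procrustes distances; near 1 for small shape
  variation, reported `NA` for degenerate (identical-shape) data.

## The synthetic-data generator

The generator produces data with the statistical structure the analysis
assumes; its defaults are the study conditions of a two-parent
hybridization design in a buttercup-like ITS system, chosen once and fixed:

| parameter | default | rationale |
|---|---|---|
| region lengths | 241 / 164 / 212 | ITS1 and ITS2 lengths of the template system; 164 nt is a typical angiosperm 5.8S |
| `divergence` | 0.02 | between-parent consensus p-distance of closely related congeners |
| `dosage` | 2:1 | a tetraploid seed parent contributes two genome copies to a triploid hybrid, the diploid pollen parent one |
| `pool_size` | 30 | copies represented per genome pool (enough to express 5% variants) |
| `n_parental_variants` | 5 | one dominant + 4 minor intragenomic variants |
| `minor_variant_freq` | 0.05 | minor variants sit below the 0.25 consensus threshold, so direct sequencing hides them |
| `intragenomic_poly_rate` | 0.0015 | yields within-library identities near 0.997, the level observed in real clone libraries |
| `n_clones` | 20 | clones sequenced per library |
| `clone_error_rate` | 1e-4 | effective per-site PCR + cloning error of a standard amplification |
| `methylation_bias` | 0.5 | half of the errors at C/G are deamination-type (C→T, G→A) |
| `pseudogene_rate` | 0.16 | fraction of clones carrying a pseudogenized copy, calibrated so roughly 16% of clones show 5.8S variants; the `ranunculus_preset()` preset raises it to 0.2 |
| `gc_shift` | 0.015 | fraction of spacer sites converted G/C→A/T in a pseudogenized copy |
| `kappa` | 2 | transition/transversion bias, so K2P estimation is exercised |
| `landmark_n` | 28/26/41 | the field-realistic sampling design of the three leaf-shape groups |
| `landmark_sigma` | 0.02 | isotropic landmark noise on unit-centroid-size shapes |

Design points worth stating explicitly:

* **The 5.8S of functional copies is frozen.** Parental divergence and
  intragenomic variants are confined to the spacers, because the 5.8S of
  functional ITS arrays is under strong purifying selection and observed to
  be strictly conserved in directly sequenced material. Only pseudogenized
  copies and random PCR errors touch the 5.8S — which is precisely what the
  screen exploits.
* **Motifs are planted and protected.** The template embeds the ITS1
  angiosperm motif and the 5.8S motifs M1–M3, and no generator mutation ever
  hits them, so motif checks separate cleanly from the planted signals.
* **The structure template is self-consistent.** Hairpins (6 in ITS1, 3
  helices in the 5.8S, 4 in ITS2) are complementary in the ancestor,
  giving paired fractions of roughly 58% (ITS1) and 72% (ITS2), the level
  seen in ITS transcript models.
* **Additivity is true by construction.** Hybrid pools mix whole parental
  copies at the dosage ratio; at a 2:1 dosage the paternal fraction (1/3)
  sits above the consensus threshold, so additivity is visible even in
  direct-sequence records.
* **Leaf mean shapes** are bilaterally symmetric 14-landmark configurations
  with pairwise full Procrustes distances between 0.13 and 0.27. The
  separations were fixed from the generator's own geometry so that
  distances between estimated group means are recoverable within 10% at
  realistic group sizes, given the sampling bias of order
  `k·sigma^2·(1/n1 + 1/n2)` that inflates distances between noisy means;
  smaller separations would drown in that bias at these sample sizes.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: insertions/deletions and alignment uncertainty
(sequences are fixed-length by construction; the pipeline accepts but does
not produce alignments), coalescent population structure within taxa,
chromatogram-level peak calling, secondary-structure refolding of mutated
copies (the template is fixed), and digitization error structure beyond
isotropic Gaussian noise. Conclusions about those failure modes require real
data.

## Numerical choices and degenerate inputs

* GPA convergence `1e-8`; split-weight threshold `1e-6`; identity rounding
  half-up to 3 decimals; GC z cutoff −3; wobble bond on by default.
* Ties in network agglomeration are joined simultaneously against the
  pre-tie components, so the result does not depend on input order.
* Saturated K2P pairs, all-gap regions, empty groups, degenerate
  (coincident-landmark) configurations and unpaired columns with supplied
  partner states are errors with named positions, never silent `NA`s or
  infinities.
* Equal-distance (star) inputs to NeighborNet return the pendant splits with
  equal weights; `n = 3` is handled by the three-point formulas; `n = 2` is
  a single split.

## Problem sizes used by the tests and the acceptance script

The test suite runs entirely on generated data: property checks use 4–8
taxon trees, ≤ 6-haplotype networks, 40–60-column toy alignments and 500
seeded null datasets for the permutation-test calibration. The acceptance
script (`scripts/acceptance.R`) runs the buttercup study preset end to end —
pools of 30 copies over 617 columns, 20-clone libraries, 50 replicate
libraries (1000 clones) for the pseudogene sensitivity/FDR estimate, 5
planted chimeras, 100 bootstrap replicates for the parental split, and
landmark datasets of 95 (warp spectrum, permutation test) and 120 (40 per
group, mean-shape recovery at the generator's stated recovery size)
specimens. These sizes are the package's choices: large enough that binomial
noise does not dominate the reported rates, small enough to run comfortably
on one CPU.

## Known limitations

* The statistical-parsimony limit uses a documented Poisson/Jukes–Cantor
  formulation; legacy software computed the same quantity from a related but
  differently parameterized recursion, so limits may differ by a step for
  some lengths. The network construction itself is unaffected by how the
  limit is obtained.
* NeighborNet split weights come from a least-squares fit; on strongly
  non-circular distance data different circular orderings can fit equally
  well, and only the split system — not the planar drawing — is provided.
* The pseudogene verdict is a rule-based screen, not a probabilistic
  classifier; a single PCR error in the 5.8S is indistinguishable from a
  genuine 5.8S substitution at the single-clone level, which bounds the
  achievable false-discovery rate by the product of error rate and 5.8S
  length.
* Morphometric mean-shape distances between estimated means are biased
  upward by sampling noise; the package reports the raw estimator (as the
  field's standard software does) rather than attempting bias correction.
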