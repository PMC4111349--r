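# itshybrid

Diagnosing hybrid origin and incomplete concerted evolution from
intragenomic polymorphism of the nuclear ribosomal internal transcribed
spacers (ITS1–5.8S–ITS2), with a companion landmark geometric-morphometric
analysis of leaf shape.

## The problem and who this is for

ITS occurs in hundreds of tandem copies per plant genome. Concerted
evolution normally homogenizes them; hybridization superimposes two parental
ribotype families in one nucleus, and apomixis (asexual seed production)
lets that additivity — and newly arising pseudogenized copies — persist.
For systematists working on hybrid and apomictic plant complexes, the
intragenomic polymorphism of ITS is therefore evidence: direct Sanger reads
show IUPAC ambiguities exactly where the parents differ, clone libraries
reveal the underlying copy spectrum, and secondary-structure context
separates functional variation from PCR artifacts and pseudogenes.

`itshybrid` implements that whole chain as tested, reusable R functions:

* **Polymorphism & additivity** — polymorphic-site detection with IUPAC
  set semantics (`find_polymorphic_sites()`), hybrid additivity classes
  (`classify_additivity()`, `additivity_table()`), Sanger-consensus
  emulation (`call_consensus()`), region annotation and GC content.
* **Distances & networks** — uncorrected p and Kimura 2-parameter distances
  with ambiguities handled as averages (`p_distance()`, `k2p_distance()`;
  for p, the per-column expected mismatch is
  `1 − |Sa ∩ Sb|/(|Sa|·|Sb|)` over the expanded state sets), group identity
  summaries, ribotype delimitation, statistical-parsimony haplotype
  networks with the 95% connection limit (`build_parsimony_network()`,
  `parsimony_limit()`), NeighborNet split networks and column-bootstrap
  supports (`neighbor_net()`, `bootstrap_support()`), NEXUS/DOT export.
* **Structure QC** — CBC / hemi-CBC / non-compensatory classification of
  substitutions on a secondary-structure template
  (`classify_base_change()`), conserved-motif checks (`check_motifs()`),
  pseudogene screening (`screen_pseudogenes()`), maximum chi-square chimera
  scanning with permutation calibration (`chimera_scan()`).
* **Morphometrics** — generalized Procrustes analysis (`gpa()`), bilateral
  symmetrization (`symmetrize()`), relative warps (`relative_warps()`),
  group mean shapes, full/partial Procrustes distances
  (`procrustes_distance()`), two-group permutation tests
  (`permutation_test()`), tangent-space checks.
* **Synthetic data** — seeded generators for parental ribotype pools,
  dosage-weighted hybrid copy mixtures, clone libraries with planted
  pseudogenes/chimeras/PCR errors, direct-sequence records, matching
  structure templates and leaf landmark datasets (`sim_config()`,
  `ranunculus_preset()`, `gen_parents()`, `gen_hybrid()`,
  `gen_clone_library()`, `gen_landmarks()`, ...), each with ground truth
  attached for recovery testing.

File formats: FASTA (sequences), CT and Vienna dot-bracket (structure),
TPS (landmarks), NEXUS splits (SplitsTree-compatible), DOT (networks),
TSV (labels).

## Worked example

Simulate the study conditions of a triploid hybridization design (two
parents at 2% divergence, hybrid dosage 2 maternal : 1 paternal), then ask
the central question — are the hybrid's polymorphisms additive between its
parents?

```r
library(itshybrid)

cfg <- ranunculus_preset(seed = 1)
par <- gen_parents(cfg)
hyb <- gen_hybrid(par, cfg)

aln <- aligned_set(rbind(par$maternal, par$paternal, hyb$pool))
aln
#> aligned_set: 90 sequences x 617 columns
#> groups: hybrid (30), maternal (30), paternal (30)

tab <- additivity_table(aln, "maternal", "paternal", "hybrid",
                        regions = par$regions)
table(tab$additivity)
#> additive_combination      parental_shared
#>                   22                   12

head(tab[, c("column", "region", "states.maternal", "states.paternal",
             "states.hybrid", "additivity")], 4)
#>   column region states.maternal states.paternal states.hybrid           additivity
#> 1      2   ITS1             G,T               T           G,T      parental_shared
#> 2     32   ITS1               C               A           A,C additive_combination
#> 3     34   ITS1               A             A,G             A      parental_shared
#> 4     68   ITS1               T               A           A,T additive_combination
```

Every informative site is either an additive maternal+paternal combination
(the hybrid carries both parental states, e.g. column 32: `C` vs `A` gives
`A,C`) or a polymorphism already present in a parent — the signature of a
genome that contains both parental ITS families. Clone a library from the
hybrid and screen it for non-functional copies:

```r
lib <- gen_clone_library(hyb$pool, cfg, par$regions, origin = hyb$origin,
                         library = "X", protected = par$protected)
direct <- gen_direct_record(hyb$pool, cfg)
scr <- screen_pseudogenes(aligned_set(lib$clones), direct, par$regions,
                          template = par$template)
table(scr$verdict)
#>                     ok putative_nonfunctional
#>                     16                      4

build_parsimony_network(aligned_set(lib$clones))
#> haplotype_network: 7 ribotypes, 5 connections (limit 9 steps), 2 component(s)
```

The screen flags the four clones whose copies carry 5.8S substitutions and
depressed spacer GC (here exactly the planted pseudogenes — `lib$truth`
holds the ground truth), and the 20 clones collapse to 7 ribotypes whose
parsimony network splits into a maternal-type and a paternal-type component.
The companion leaf-shape analysis runs the same way:

```r
lm <- gen_landmarks(cfg)
g <- gpa(lm$configs)
g
#> gpa_shapes: 95 configurations, 14 landmarks; residual SS = 2.13795 in 5 iterations
relative_warps(g)
#> relative_warps: 25 warps; RW1 = 59.46%, RW2 = 3.90%
```

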