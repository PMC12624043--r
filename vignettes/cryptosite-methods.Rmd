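---
title: "Methods: mining cryptic phosphosites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining cryptic phosphosites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cryptosite)
```

This vignette is the package's own account of the models it implements:
what each stage assumes, which tunable parameters matter and why their
defaults are what they are, what the synthetic generators do and do not
emulate, and where the numerically delicate choices lie.

## The problem

A phosphosite whose side chain is buried in the native core cannot be
reached by a kinase in the folded state. If such a site is nonetheless
phosphorylated in vivo, the modification must have been deposited on a
partially folded chain — during translation, stress-time unfolding or a
large conformational excursion. The pipeline identifies these *cryptic*
sites on predicted structures and then strips out candidates that only
look buried in a static model.

## Accessibility stage

**SASA.** Shrake–Rupley: every atom is inflated by the probe radius
(1.4 Å, water) and covered with a deterministic golden-spiral lattice of
test points; a point is occluded iff it falls *strictly* inside another
atom's inflated sphere (a point exactly on a neighbouring surface counts
exposed — this makes the coincident-sphere corner case well defined).
The exposed fraction times the inflated sphere area is the atomic SASA.

Numerical choices:

* `n_sphere_points = 960` by default. The quadrature error of a
  960-point lattice is below 2 % for residue-level areas (checked in the
  test suite against a 3840-point lattice and against the closed-form
  two-sphere solution); individual atoms exposing thin slivers can
  deviate by a few per cent more, which is inherent to the method, so
  all downstream decisions use residue sums.
* The point lattice is attached in one fixed global orientation, never
  re-randomized per atom: output is bit-reproducible and exactly
  translation invariant. Exact rotation invariance holds when the
  lattice is co-rotated (`sasa_params(lattice_rotation = )`); under a
  fixed lattice a rotation perturbs areas only at the quadrature level.
* Heavy-atom van der Waals radii C 1.70, N 1.55, O 1.52, S 1.80, P
  1.80 Å. Predicted models carry no hydrogens, so heavy-atom radii with
  a 1.4 Å probe is the standard convention. Any element outside the
  table is a configuration error, never a silent default.

**RSA.** Residue SASA divided by the residue's maximum SASA in an
extended Gly-X-Gly tripeptide (the embedded theoretical MaxASA table).
RSA is deliberately *not* clamped at 1: an isolated terminal residue can
exceed its tripeptide maximum, and clamping would hide that signal (it
is logged instead).

**Thresholds.** `rsa_cryptic = 0.15` and `plddt_min = 65`, both
*inclusive* on the keep side: RSA exactly 0.15 is cryptic, pLDDT exactly
65 is kept. The sources of these conventions state the cuts both as
strict and non-strict in different places; the package fixes one
reading, documents it, and exposes both values in `cp_thresholds()`.

## Dynamical filter

Buried-in-the-static-model is not buried-in-the-dynamic-ensemble. The
filter removes candidates that native-state dynamics would expose:

1. **Prune** maximal runs of residues with pLDDT below 65 (loops,
   linkers, disorder) — normal-mode analysis is meaningless there.
2. **Merge** the remaining segments when at least five inter-segment
   residue *pairs* have minimal heavy-atom distance ≤ 5 Å, transitively
   (connected components). Pair counting is the only reading of the
   "five residues within 5 Å" rule that is symmetric in the two
   segments; this is a documented interpretation choice.
3. **Size-gate**: entries under 40 residues are dropped (normal modes of
   very short polypeptides are unreliable); their sites are excluded
   with provenance `excluded:small_domain`.
4. **Re-filter RSA** on the isolated entry: a site that was buried only
   under a pruned loop now shows RSA > 0.15 and is excluded as
   `excluded:exposed_after_pruning`.
5. **Quasi-rigid decomposition.** A β-Gaussian elastic network (Cα
   nodes plus one side-chain centroid per residue that has side-chain
   heavy atoms; glycine contributes only its Cα) with uniform springs
   inside 7.5 Å. Side-chain nodes are integrated out by a Schur
   complement, the effective Cα Hessian is diagonalized, and the six
   near-zero rigid-body modes are verified and discarded. Pairwise
   distance fluctuations to quadratic order,
   σ_ij² = Σ_m λ_m⁻¹ [(v_m,i − v_m,j)·ê_ij]², feed a similarity matrix
   s_ij = exp(−σ_ij²/σ̄²) (σ̄ = mean σ over pairs within the spring
   cutoff). Spectral clustering (normalized-Laplacian embedding,
   k-medoids with 25 seeded restarts) is run for k = 2…10 and each
   subdivision scored by the mean silhouette of residues under the
   fluctuation dissimilarity σ itself — a quasi-rigid domain is by
   definition a group whose internal distances fluctuate little, so a
   good subdivision has small within-domain and large between-domain σ.
   Scoring in σ-space rather than in the embedding is what stops a
   floppy linker from being carved off as a "domain" while two
   counter-moving bodies stay merged. The best k wins; ties and flat
   profiles resolve to k = 2.
   Labels are emitted even when no subdivision is convincing, matching
   the always-use-the-top-subdivision convention of the workflow.
6. **Pidc.** Neighbours of a site are all residues with any heavy atom
   within 6 Å of the site's side-chain heavy atoms (sequence-adjacent
   residues are *not* excluded — a documented choice; excluding them
   would only raise Pidc uniformly). A site is kept iff the fraction of
   neighbours sharing its domain is ≥ 0.80 (inclusive); a buried site
   with zero neighbours is physically impossible and is flagged rather
   than silently kept.

The eigen-decomposition and clustering are deterministic given the seed
(default 1, configurable in `default_config()`/`quasi_rigid_decompose()`).

## Conservation stage

The entropic score of an alignment column is the Shannon entropy of its
symbol frequencies normalized by ln K, with **K fixed at the alphabet
size** (20 amino acids + gap + pooled ambiguity 'X', K = 22), not the
per-column count of distinct letters. Only the fixed-K reading
reproduces both limit cases — a conserved column must score 0 (needs
ln K > 0) and a uniformly occupied column must score 1. Ambiguity codes
B/Z/U/O are pooled into 'X' with a warning. The score is independent of
the logarithm base (ratio form) and permutation invariant in sequence
order; both are asserted in the test suite.

Orthogroup inference and alignment are consumed, not reimplemented: the
package reads Clustal-style aligned FASTA. Proteome QC follows the Tukey
fence: organisms with completeness score strictly below Q1 − 1.5·IQR are
dropped, with quartiles by linear interpolation (type 7) — the most
common convention, stated explicitly because the rule is silent on it.
Effect sizes use the pooled-variance Cohen's d; location comparison uses
the Mann–Whitney test.

## Mutation cross-referencing

Raw screen rows are cleaned by removing negative screens and collapsing
identical (accession, position, amino-acid change, CDS change) rows into
one record with a sample count. Protein changes parse in both the
`p.S417E` and bare `S417E` dialects. A cryptic-site hit requires
matching accession *and* position *and* reference residue; reference
mismatches are rejected and logged, never silently joined.
Phosphomimetic means exactly S/T/Y → D/E (aspartate/glutamate mimic the
phosphate's charge); phosphoablative substitutions such as S → A are
counted as ordinary hits. Rate comparisons between site groups are
emitted as two proportions with a two-proportion z statistic.

## Ratchet-and-pawl folding toy

The biased-dynamics mathematics is exercised on a 30-bead Gō-like chain
(harmonic bonds and 1–3 bends, 12-10 attractions on native contacts,
r⁻¹² excluded volume), integrated by overdamped Langevin dynamics in
reduced units (contact strength = thermal energy scale; no claim of
physical kJ/mol fidelity).

* **Switching function**: rational form for r < r_c with the removable
  singularity at r0 filled by its limit 6/10; 0 beyond r_c = 12.3 Å.
  The ≈0.13 jump left at r_c by these constants is part of the
  definition and kept as printed.
* **Progress variable**: Q = Σ [C_nat² − (C − C_nat)²] over pairs with
  index separation > `sep_min`. The all-atom convention restricts to
  atomic separations > 35; for a one-bead-per-residue chain the package
  uses `sep_min = 3` — a scale adaptation, not the all-atom value.
* **Bias**: active only while Q < Q_m (the running best), with
  F_i = −k ∇_iQ (Q − Q_m); plain dynamics whenever the system
  progresses spontaneously. The printed piecewise definition carries
  the same condition on both branches; the package resolves it in the
  only way consistent with "plain MD whenever it spontaneously
  progresses".
* **Toy bias strength**: `k = 2` in reduced units for the 30-bead toy.
  At this scale (Q_nat ≈ 113, |∇Q| of order one) the typical bias force
  stays below the physical bonded/contact forces while still converting
  thermal fluctuations into ratcheted progress; the all-atom default
  `1e-4` is far too small to matter on a chain this stiff and short.
* **Score**: T accumulates |F^B|²/(mγ) dτ per step; exactly 0 for
  unbiased runs, non-decreasing in time, additive over trajectory
  segments.

Unfolded starts are produced by plain dynamics at high reduced
temperature (30) from the native state. The uplift experiment in the
acceptance suite runs 20 paired seeds (biased k = 2 vs unbiased) of
6000 steps at dt = 2×10⁻³ and temperature 1.0, scoring success as
Q_m ≥ 0.9 Q_nat, and tests the paired difference with a one-sided
binomial test on discordant pairs. These sizes keep the whole
experiment within a few minutes on one core while giving the test
better than 99 % power at the observed effect (≈15/20 vs ≈2/20).

## Synthetic generators

All generators are pure functions of their arguments and seed and emit
the same text formats the readers consume. They are *geometric
constructions*, not physical simulations — ground truth must be exact:

* `make_globule_fixture`: a snake path through an elongated 5×5×nz
  lattice box (3.8 Å spacing, ±0.15 Å jitter). Elongation makes the
  softest elastic deformations run along the long axis, so the forced
  two-way quasi-rigid cut falls at the transverse mid-plane —
  predictable, hence core sites can be planted provably far from it,
  deep inside each half. Surface serines sit proud of an end face;
  lysine decoys (full side-chain arms) on a side face; the optional
  low-confidence loop hovers over one more side-face serine, burying it
  until pruned.
* `make_hinge_fixture`: two 4×4×3 lattice bodies facing across a 6.2 Å
  gap, joined by a linker arcing outside the gap. The gap width is the
  fixture's load-bearing choice: wide enough that inter-body springs are
  sparse (the lowest modes are genuine inter-body motion and the
  decomposition separates the bodies at every seed), narrow enough that
  a serine on the gap-facing surface stays buried between the bodies.
  One serine is planted deep in body 1 (all contacts intra-domain), that
  interface serine on the gap face (contacts split across the domain
  boundary — Pidc ≈ 0.5–0.6).
* `make_msa_fixture` / `make_ptm_fixture` / `make_mutation_fixture`:
  planted conserved/noisy/human-gap columns, planted phospho rows plus
  decoy PTM classes plus exactly one malformed row, planted
  phosphomimetic hits plus negative screens and duplicates.
* `make_toy_chain_native`: a compact lattice chain whose centre bead is
  the designated buried site; native contacts are pairs with sequence
  separation ≥ 3 within 8 Å.

What passing the planted-truth tests shows: the pipeline's logic —
classification boundaries, provenance bookkeeping, decomposition and
Pidc arithmetic — is correct on noiseless geometry. What it does not
show: performance on real structures, where confidence scores are
noisy, domains are irregular, side chains have rotameric freedom and
alignments carry phylogenetic correlation. The generators make no
attempt to emulate those features.

## Problem sizes and runtime

Defaults were chosen so the full fixture battery (200-residue globule +
102-residue hinge, five seeds) runs the complete pipeline in well under
two minutes on one core, and the folding uplift experiment in under
five; the heaviest single step is the 600-dimensional effective-Hessian
eigenproblem of the globule entry.

## Known limitations

* Single chains only; no mmCIF, no altLocs/insertion codes (hard
  errors by design — site mapping relies on clean 1-based numbering).
* The quality score for subdivisions is a mean silhouette in the
  spectral embedding; the original quasi-rigid-domain literature uses a
  random-reference-normalized score whose exact form is not public.
  Rankings agree on the fixtures (hinge ≫ compact cube), but absolute
  quality values are not comparable across scoring conventions.
* RSA uses whole-residue heavy atoms, not side-chain-only atoms.
* The toy folding model is two orders of magnitude smaller than any
  real protein; its purpose is to exercise the bias mathematics, not to
  predict folding pathways.
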