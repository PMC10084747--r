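---
title: "Classifying Gpx-like proteins: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying Gpx-like proteins: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The classification model

Glutathione peroxidase (Gpx)-like proteins split into two catalytic styles
that are nearly indistinguishable by overall sequence similarity but differ
in a handful of residues and architectural elements. Canonical,
GSH-dependent Gpx (the mammalian style) carry selenocysteine (`U`) at the
catalytic-tetrad position, lack a resolving cysteine, and oligomerize via
two interface elements: a dimer loop containing the `PGGG` motif (the
"functional helix") and a C-terminal oligomerization loop. TRX-dependent,
Gpx-like peroxiredoxins carry a plain cysteine at the tetrad position, a
second "resolving" cysteine in the Cys block on helix α1a that can form an
intramolecular disulfide with the peroxidatic Cys, and neither interface
loop — a monomeric, peroxiredoxin-like architecture.

`classify()` turns these observations into three booleans per sequence,
read off a multiple alignment anchored to a reference numbering
(tetrad 61/95/150/151, resolving Cys 107, TRX-binding 97/106/111,
GSH-binding 57/185/147 in the bovine convention):

* criterion 1 — the residue at the peroxidatic position is `C`;
* criterion 2 — a Cys is present at position 107 or anywhere in the
  Cys-block window (default 103–113);
* criterion 3 — neither interface loop is present.

The decision table is total and pure: all three criteria →
`TRX_GPXLIKE_PRX`; `U` at the peroxidatic site, or `C` with no resolving
Cys and at least one loop → `CANONICAL_GSH_GPX`; every remaining
combination (including a peroxidatic residue that is neither `C` nor `U`,
and 1-Cys architectures) → `AMBIGUOUS`. We deliberately refuse to guess in
the residual cases: a mutated-away catalytic residue is not evidence for
either catalytic style.

### Loop detection

`has_dimer_loop` requires a `PGGG`-like match (at most one mismatch by
default) among the residues the row places inside the dimer-loop region,
and that the row is less than 50% gapped there — a mostly deleted region
must not yield a motif call from flanking residues. `has_oligo_loop`
requires an ungapped insertion of at least 8 residues relative to the
reference row inside the oligomerization-loop region; 8 residues is the
shortest insertion we consider structurally meaningful for a loop that
mediates dimer–dimer contacts, and it is configurable. The region
intervals themselves (defaults 126–146 and 155–175) are configuration
placeholders: when classifying real data the user should supply intervals
appropriate to their reference; synthetic cohorts use the generator's own
coordinates, so the truth is exact by construction.

## The synthetic-family generator

Because the sequence sets behind published Gpx surveys are generally not
deposited, validation here rests on synthetic families with planted truth.
`make_scaffold()` draws a 190-residue background uniformly from the 20
canonical amino acids — a conservative null for consensus statistics,
since any real positional preference only makes conserved columns easier
to find — and places a neutral `A` at every diagnostic position.
`plant_class()` then overwrites the diagnostics with one class signature
(deleting both loop regions for the TRX-like and 1-Cys-like classes;
planting `U`, `PGGG` and a 10-residue oligomerization-loop insertion for
the canonical class). `mutate_family()` applies independent per-site
substitution at a chosen rate, drawing replacements uniformly from the 19
other residues, with the diagnostic positions protected.

Two generator choices deserve emphasis:

* The whole Cys-block window is treated as diagnostic (neutralized in the
  scaffold and protected during mutation), not just position 107. The
  classifier reads "a Cys anywhere in the block", so an uncontrolled
  background Cys there would silently flip the planted truth of canonical
  and 1-Cys families.
* Uniform substitution has no indel process and no substitution-matrix
  bias. Passing tests therefore demonstrate correctness of the machinery
  (coordinate mapping, motif and insertion detection, decision logic)
  under controlled divergence — they do not demonstrate robustness to the
  alignment ambiguity of real indel-rich families, which is why
  `import_alignment()` accepts externally curated alignments.

Determinism: every stochastic step takes an integer seed and restores the
caller's RNG state, so identical seeds reproduce cohorts, bootstraps and
whole pipeline runs byte for byte.

## Alignment

`global_align()` implements Needleman–Wunsch with the Gotoh three-state
recurrences; a gap run of length $k$ costs $g_o + (k-1)\,g_e$ with
defaults $g_o = 10$, $g_e = 1$ on BLOSUM62. All transitions between the
three states are allowed, so the optimum is exact even for adjacent
opposite-strand gaps; the test suite checks optimality against exhaustive
enumeration over all alignments of short sequences. Traceback ties resolve
deterministically (diagonal over up over left). Selenocysteine is scored
as Cys — BLOSUM62 has no `U` column, and `U` occupies the Cys column in
Gpx alignments — but is preserved verbatim in output; `X` scores zero
against everything.

`progressive_msa()` builds a neighbor-joining guide tree from pairwise
global-alignment identity distances ($1 - \mathrm{identity}$), midpoint
roots it, and merges frequency profiles from the leaves inward
(profile–profile Gotoh alignment with expected-score columns;
"once a gap, always a gap"). There is no iterative refinement and no
attempt to reproduce any particular external aligner column-for-column;
for expert-curated input the importer is the intended path. Terminal or
global gap masking is available via `mask_gap_columns()` (default mask:
columns more than 50% gapped; terminus trimming conventionally uses 0.8).

## Clustering

`greedy_cluster()` follows the cd-hit scheme: records sorted by decreasing
length (ties broken lexicographically by id for reproducibility), each
record joining the first representative with fractional identity strictly
above the threshold. Identity is computed on the global alignment
(matches / alignment columns). Because published "similarity" thresholds
are ambiguous, a `similarity` mode (fraction of positively scoring
ungapped columns) is exposed alongside the default identity mode. Greedy
assignment is order-dependent by construction; determinism is promised for
a fixed input order, invariance under permutation is not.

## Conservation profiling

`column_consensus()` reports, per column, the modal residue among non-gap
rows (ties alphabetical), optionally extended to a residue-type group:
the modal letter is greedily joined by other members of its
physicochemical partition cell — {ILVMF}, {WY}, {ST}, {DE}, {KRH}, {NQ},
{AG}, {C,U}, {P}, chosen to reproduce the residue-type sets conventionally
printed in conservation tables (Leu/Val, Ser/Thr, …) — keeping letters
that contribute at least 5% of rows. Proportions are over non-gap rows;
an all-gap column reports proportion 0 with gap fraction 1.

`conserved_domains()` segments the profile into maximal runs of columns
with proportion ≥ 0.7 (the conventional reporting threshold), bridging
interior below-threshold stretches of at most 2 columns, discarding runs
shorter than 5 columns, and excluding columns more than 50% gapped.
Segment count is emergent from the data, never forced. The segmentation is
idempotent on its own mask, and coverage is reported against the reference
length.

## Phylogeny

Distances are p-distances over shared non-gap columns, by default
Poisson-corrected ($-\ln(1-p)$); both models are exposed because the
distance model behind published Gpx trees is typically unstated. The NJ
topology and branch lengths come from `ape::nj` (negative estimates
clamped to zero and counted, the usual presentation convention); the
package's own consistency tests require exact recovery of random additive
trees. `bootstrap_support()` resamples alignment columns with replacement
(default 1000 replicates for a full analysis; desk-scale runs use
100–200), skips degenerate all-identical replicates, and attaches
percentage supports per internal bipartition. `star_likeness()` is the
fraction of internal edges with support below 70 — the conventional cutoff
separating trustworthy from unreliable branches. `phylum_mixing()` counts,
per phylum, the maximal monophyletic same-phylum clades under the tree's
stored rooting (1 = clustered, leaf count = fully scattered) and averages
the per-phylum clade/leaf ratios into a mixing index in (0, 1]. A
parsimony-based variant was considered and rejected: a minimum-change
labeling under-counts the scattering of a phylum interleaved leaf-by-leaf,
which is precisely the star-like pattern the statistic must expose.

## Structure metrics

`kabsch_superpose()` is the standard SVD solution with reflection
correction; collinear point sets are flagged as degenerate rather than
silently returning one of the infinitely many optima.
`shrake_rupley_sasa()` uses a golden-section spiral (default 960 points
per atom, within 1% of the analytic sphere area; the error decreases
roughly as $1/n$), water probe 1.4 Å, and van der Waals radii C 1.70,
N 1.55, O 1.52, S 1.80 Å. `relative_accessibility()` normalizes summed
residue SASA by published theoretical maxima of residue X in an extended
Gly-X-Gly tripeptide (Tien et al. 2013), the field's standard convention;
the table is user-replaceable. For disulfide geometry,
`residue_pair_distance()` defaults to the SG sulfur atoms (the atoms that
actually bond), with any atom name selectable. RMSD comparisons default to
Cα atoms. The package computes metrics only — homology modeling,
electrostatics and rendering are out of scope, so published RMSD/SASA
values for undeposited models cannot be regenerated here and are not
asserted anywhere.

## Problem sizes and operating points

The shipped validation runs at desk scale, chosen to exercise every code
path with comfortable statistical margins: classification cohorts of
3 × 50 sequences at divergence 0 and 0.15 (recovery 100% and ≥ 95%);
alignment optimality on 500 random pairs of length ≤ 8 against exhaustive
enumeration; clustering against a brute-force reference on 50 independent
20-record inputs; NJ consistency on 100 random additive trees of 6–10
taxa; bootstrap behavior with 200 replicates on planted two-clade
(within-divergence 0.02, between 0.5) and 14-lineage star designs; and a
100-sequence demonstration pipeline (83% TRX-like / 17% canonical, the
oligomerization-loop fraction reported for isolated bacteria) run with 100
bootstrap replicates. `scripts/acceptance.R` recomputes all of these from
scratch for any seed.

## Known limitations

* The aligner is a straightforward progressive method; highly divergent or
  indel-rich real families should be aligned externally and imported.
* Interface-loop region coordinates for real data are the user's
  responsibility; defaults are placeholders tied to the conventional
  numbering.
* Uniform-substitution synthetics do not model rate heterogeneity,
  compositional bias, or indels; accuracy figures transfer to real data
  only to the extent the alignment is trustworthy.
* The greedy clustering is quadratic — appropriate for thousands of
  sequences, not millions; no k-mer prefilter is provided.
* `phylum_mixing()` depends on the stored rooting of the (unrooted) NJ
  tree; for the radiating topologies it is meant to characterize the
  effect of rerooting is negligible.
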