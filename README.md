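# gpxlike

Tools for deciding whether glutathione peroxidase (Gpx)-like protein
sequences are **thioredoxin (TRX)-dependent, Gpx-like peroxiredoxins** or
**canonical glutathione (GSH)-dependent peroxidases**, together with the
supporting analyses that usually accompany the call: redundancy reduction,
multiple alignment, conservation profiling, neighbor-joining phylogenies
with bootstrap, and structural readouts.

## The classification problem

Bacterial and environmental-microbiome proteins annotated as "glutathione
peroxidase" frequently are not GSH-dependent at all. The sequence-level
evidence that separates the two catalytic styles is compact:

1. **Peroxidatic residue** — TRX-dependent Gpx-like peroxiredoxins carry a
   cysteine at the catalytic-tetrad position (Cys/SeCys, Gln, Trp, Asn;
   conventional numbering 61/95/150/151); canonical mammalian-style Gpx
   carry selenocysteine (`U`) there.
2. **Resolving Cys** — a second cysteine in the "Cys block" on helix α1a
   (conventional position 107) that forms an intramolecular disulfide with
   the peroxidatic Cys. Its presence is diagnostic for TRX dependence; it
   is absent in canonical Gpx.
3. **Interface loops** — canonical Gpx oligomerize through a dimer loop
   (the "PGGG"-motif functional helix) and a C-terminal oligomerization
   loop; both are absent in the monomeric TRX-dependent proteins.

`classify()` applies the three criteria to per-sequence feature profiles
read off a reference-anchored multiple alignment: a sequence with all
three marks is a TRX-dependent Gpx-like peroxiredoxin; `U` at the
peroxidatic site (or a Cys with no resolving Cys plus interface loops)
marks a canonical GSH-dependent Gpx; anything else — e.g. 1-Cys-like
architectures — is reported `AMBIGUOUS`.

Around the classifier the package provides:

* `read_fasta()` / `filter_by_length()` / `greedy_cluster()` — cd-hit-style
  greedy identity clustering for non-redundant representative sets
  (e.g. 80% and 70% merges).
* `global_align()` (Needleman–Wunsch with Gotoh affine gaps; gap run of
  length *k* costs `gap_open + (k-1)·gap_extend`), `progressive_msa()`
  (NJ guide tree + profile–profile merging), `import_alignment()` for
  externally curated alignments.
* `map_reference_columns()`, `extract_features()`, `summarize_cohort()`.
* `conservation_profile()` / `conserved_domains()` / `residue_report()` —
  consensus-proportion profiling with physicochemical residue grouping and
  conserved-domain segmentation (default threshold 0.7).
* `distance_matrix()` (p-distance / Poisson), `nj_tree()`,
  `bootstrap_support()` (column resampling), `star_likeness()`,
  `phylum_mixing()`, Newick I/O.
* `read_pdb()`, `kabsch_superpose()`, `residue_pair_distance()`,
  `shrake_rupley_sasa()`, `relative_accessibility()` — RMSD, residue–pair
  distances (e.g. the two catalytic Cys sulfurs) and relative solvent
  accessibility on user-supplied coordinates.
* `scaffold_spec()` / `synth_cohort()` / `gpx_demo()` — a synthetic-family
  generator that plants the diagnostic features at controlled divergence
  with known truth labels, so the whole pipeline is testable end to end
  without external data.

## Worked example

```r
library(gpxlike)

spec   <- scaffold_spec(seed = 7)                      # reference geometry
cohort <- synth_cohort(spec,
                       c(TRX_GPXLIKE_PRX = 10, CANONICAL_GSH_GPX = 5),
                       divergence = 0.05, seed = 7)
recs <- rbind(cohort$reference, cohort$records)
class(recs) <- c("protein_records", "data.frame")

aln <- progressive_msa(recs)
cm  <- map_reference_columns(aln, "scaffold")
ft  <- feature_table(aln, cm, feature_config_from_spec(spec))
cl  <- classify(ft)
summarize_cohort(cl, ft)
```

```
<cohort_summary> n = 15
  TRX_GPXLIKE_PRX      10 (66.7%)
  CANONICAL_GSH_GPX     5 (33.3%)
  AMBIGUOUS             0 (0.0%)
  oligomerization loop: 33.3%  resolving Cys: 66.7%
```

All ten TRX-planted sequences are called by their conserved peroxidatic and
resolving Cys and absent loops; the five canonical-planted sequences are
called by SeCys plus both interface loops (hence the 33.3% loop fraction).
The one-command version, with outputs on disk and a bootstrapped tree:

```r
rep <- gpx_demo(seed = 7, outdir = "demo_out")
print(rep)
```

which reports the stage funnel, 100% planted-truth recovery, the cohort's
17% oligomerization-loop fraction, conserved-domain coverage and the tree's
star-likeness. A shell entry point with `simulate` / `run` / `demo`
subcommands is installed at `inst/scripts/gpxlike.R`.

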