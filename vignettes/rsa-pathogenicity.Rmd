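---
title: "Methods: relative solvent accessibility as a pathogenicity feature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relative solvent accessibility as a pathogenicity feature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsapath)
```

## The model

A missense variant that destabilizes a tightly packed helical protein does so
mostly by forcing a bulkier side chain into the core; a variant on the
solvent-exposed surface is usually tolerated. `rsapath` quantifies "core
versus surface" per residue as relative solvent accessibility,

$$\mathrm{RSA}_i = \frac{\mathrm{ASA}_i}{\mathrm{maxASA}(\mathrm{type}_i)},$$

where ASA is the whole-residue (backbone plus side chain) solvent accessible
surface area and maxASA is the residue type's theoretical maximum, so RSA is
approximately 0 for buried and approximately 1 for fully exposed residues.
Values slightly above 1 occur for unusually extended conformations and are
legitimate; values above 1.5 trigger a warning because they usually indicate
wrong units or radii.

The statistical claim being evaluated is that RSA distributions differ
between variant groups (population, cancer, neurodevelopmental disorder) and
that low RSA predicts membership in a disease group. The battery is
rank-based throughout: Kruskal–Wallis across the three groups, pairwise
two-sided Wilcoxon rank-sum tests with Bonferroni correction (m = 3 for three
groups), both run protein-wide and within each protein domain, and ROC/AUC
where each variant is scored by $-\mathrm{RSA}$.

### Score orientation

The literature this package follows reports disease variants as *more buried*
but does not state the ROC scoring direction. We define the pathogenicity
score as $-\mathrm{RSA}$, so a discriminative feature yields AUC > 0.5; the
orientation is printed in every ROC result (`low_rsa_is_positive`), and the
opposite convention would report $1 - \mathrm{AUC}$.

### NDD sub-phenotypes

Sub-phenotype labels (SKS, FCD, megalencephaly) are carried on NDD variants
as display metadata only. The tests always compare exactly three groups;
sub-phenotypes never form extra test groups.

## Accessibility computation

ASA is computed by the Shrake–Rupley method: each atom's solvent-expanded
sphere (van der Waals radius + probe radius) is sampled with a deterministic
golden-spiral lattice, and the accessible fraction is the fraction of points
not inside any neighboring expanded sphere. The method is deterministic for
fixed parameters, which makes runs byte-reproducible.

Tunable parameters (`sasa_params()`):

- `probe_radius` (Å, default 1.4): the water-sized probe standard in the
  field.
- `n_sphere_points` (default 960): the area estimate error scales roughly as
  $1/\sqrt{n}$. At 960 points the two-sphere closed-form oracle is matched
  within 2%, and doubling the density changes total model ASA by well under
  1% on the helix fixture.
- `radius_set_name` (default `"single"`): Bondi-style per-element radii
  (C 1.70, N 1.55, O 1.52, S 1.80 Å). This choice matches the "Single" set of
  an independent reference implementation, which the test suite uses as a
  cross-check oracle on the helix fixture (agreement well under 1%). A
  coarser group-style `"protor"` set is available.

Conventions: hydrogens are always dropped (the motivating structures are
cryo-EM without hydrogens, and heavy-atom SASA is the standard convention);
waters are always removed; other hetero atoms are removed unless requested;
for alternate locations the highest-occupancy conformer wins with file order
breaking ties; author residue numbering is preserved end-to-end so variant
positions join directly.

Numerical notes:

- Translations leave per-atom ASA exactly unchanged, because the lattice is
  atom-centered. Rotations change sampled directions relative to neighbors;
  at 960 points the total-model ASA moves by < 0.5%, while individual
  nearly-buried atoms (a few Å² of exposed area) can move by several percent
  of their own small value. Per-residue and group-level statistics are
  insensitive to this.
- A sample point exactly on a neighbor's sphere is counted occluded
  (strict `>=` accessibility test); the boundary has measure zero and the
  choice is invisible at any finite lattice density.
- Residues missing expected heavy atoms (backbone N/CA/C/O, plus CB except
  glycine) still get an ASA but are flagged `complete_atoms = FALSE`, because
  a truncated side chain biases ASA low.

### Consensus and differential RSA

Proteins with distinct active and inactive conformations have one RSA per
state. The consensus is defined here as the arithmetic mean over the states
in which the residue is resolved; residues resolved in no state are absent,
and the exported tables carry the `-1` sentinel for unresolved residues so
downstream exclusion is explicit. The upstream resource that popularized
consensus RSA does not publish its exact combination rule; the mean is the
simplest symmetric choice and is isolated in one function
(`consensus_rsa()`) so it can be swapped. Differential RSA is
active − inactive for residues resolved in both.

For exact reproduction of numbers computed by other ASA engines (e.g. the
DSSP server), `read_rsa_table()` ingests precomputed per-residue RSA tables
directly, and the `analyze` stage runs unchanged on them; algorithmic
differences between ASA engines (radius sets, treatment of incomplete
residues) otherwise shift absolute values by a few percent.

## Variant curation

- Population (gnomAD-style export): allele count ≥ 2 (singletons may be
  unrecognized pathogenic variants) and no overgrowth/cancer annotation in
  other databases. "Single individual" is operationalized as allele count
  = 1, the exported quantity closest to that phrase. Duplicate protein
  changes are merged with allele counts summed — deduplication is by protein
  change, not underlying codon, since the analysis is residue-level.
- Cancer (COSMIC-style export): recurrence ≥ 3 and absence from the
  population catalog, with recurrence read from the export's per-variant
  count column.
- NDD: a frozen packaged catalog of 33 literature variants with phenotype
  evidence flags; extending it means editing the fixture, not code.

Every filter decision is logged (`provenance_log`), so kept + dropped =
input is checkable per filter, and the population and cancer sets are
disjoint by construction.

Domain boundaries live in a versioned configuration file
(`mtor-6bcx-lit-1.0`), transcribed from the structure-literature convention
for the MTOR cryo-EM deposition family (N-HEAT 1–928, M-HEAT 929–1381, FAT
1382–2014, FRB 2015–2114, kinase N-lobe 2115–2252, kinase C-lobe 2253–2516,
FATC 2517–2549). These reproduce every domain label in the packaged catalog
but are provisional at the exact boundaries; every statistical output records
the map version. Positions outside all intervals are labeled `unassigned`
and participate in full-protein statistics only.

## Statistical choices

- The log(x+1) transform accommodates exact zeros and reduces skew; the
  rank-based tests and AUC are invariant to it (asserted to 1e-12 in the
  suite), so it only affects exported values, not inference. Negative input
  is an error because it means an unfiltered `-1` sentinel escaped upstream.
- Kruskal–Wallis and Wilcoxon use the standard tie-corrected machinery;
  Wilcoxon p-values are exact (full enumeration) when the smaller group has
  ≤ 10 observations and there are no ties, and otherwise use the normal
  approximation with tie and continuity corrections — the defaults of the
  statistical environment the motivating analysis used, so small
  discrepancies in reproduced p-values are expected but H statistics match
  the rank formula exactly.
- AUC is the midrank Mann–Whitney probability; the threshold-sweep ROC
  polygon's trapezoidal area equals it identically (asserted on random
  tables with ties).
- Strata in which any group is empty are skipped with a logged reason rather
  than failing the run.

## Reporter-assay quantification

Activity per lane is phospho/total; each blot is normalized to its own
wild-type lane, so the wild-type relative ratio is exactly 1 per blot and
between-blot scale (exposure, transfer) cancels — multiplying all signals in
a blot by any constant changes nothing. The paired t-test pairs within blot,
equivalently testing relative ratios against 1. The Bonferroni family is the
set of constructs tested in the invoking batch, and m is printed with the
output because the original family definition is not recoverable. Zero
variance across replicates (possible with noiseless synthetic data) is
reported at the machine floor with a `degenerate_variance` flag rather than
as an error.

## What the synthetic generators emulate

- **Structures**: geometric archetypes (isolated atom, two-sphere pair,
  extended tripeptide, ideal helix with rise 1.5 Å and 100° twist, four-helix
  bundle with a genuinely buried core) built from a reduced heavy-atom
  backbone plus Cβ. They exercise the accessibility engine against
  closed-form and high-density oracles; they do not mimic any real fold,
  rotamer distribution, or experimental artifacts (missing density,
  alternate conformations beyond the test fixtures).
- **Variant tables**: group RSA values drawn from normal distributions
  clipped at 0, with the disease-group means placed below the population mean
  so the two-normal closed form $\Phi(\Delta/\sigma\sqrt{2})$ gives a chosen
  AUC. Defaults are the calibrated study conditions: 300 population, 60
  cancer, and 33 NDD variants (the catalog size; the other two are
  realistic-magnitude catalog yields), population mean RSA 0.55, common SD
  0.15, AUC targets 0.76 (NDD) and 0.67 (cancer). With these parameters the
  sub-zero clip mass is negligible (< 0.5%), so the closed form holds to
  within the tolerances tested. Real RSA is bounded and right-skewed rather
  than normal; a Beta family is available, and because the statistics are
  rank-based the distributional family mostly matters through the implied
  AUC.
- **Blot tables**: per-blot baseline ratio with lane-level lognormal noise
  applied to the normalized construct ratio under the mean-one convention
  $\varepsilon \sim \mathcal{N}(-\sigma^2/2, \sigma^2)$, so the expected
  relative ratio equals the true fold-change. The wild-type lane carries the
  blot baseline exactly — measurement error of the reference lane is treated
  as absorbed into the per-blot normalization, a simplification that makes
  "noise σ" mean noise of the normalized readout. Defaults (5 replicates,
  σ = 0.2) reflect the assay design being emulated; at a true 3-fold
  activation they give ≥ 95% probability of landing in [2.4, 3.6] with
  adjusted p < 0.05, and at fold 1 the p-values are uniform (both asserted
  in the suite over seeded runs).

Truth sidecars (expected AUC, true fold-changes, designated buried residues)
are written separately from the generated data files and never enter the
analyzed tables.

Passing these tests demonstrates that the pipeline's machinery is correct
and well-calibrated under its stated model; it does not demonstrate that any
particular real protein's variant groups separate, which depends on the real
structures and catalogs supplied by the user.

## Problem sizes used in validation

The suite validates AUC recovery at 2,000 variants per group (empirical AUC
within ±0.02 of the closed form), fold-change recovery over 500 seeded
simulations, occlusion monotonicity over 100 random atom clusters, and the
two-sphere oracle over 20 random configurations — sizes chosen so sampling
error is well below the asserted tolerances.

## Known limitations

- The Shrake–Rupley implementation is pure R with an all-pairs neighbor
  search, comfortable for chains of a few thousand atoms; very large
  complexes would want a spatial grid.
- Chain extraction analyzes a monomer in isolation; binding partners that
  occlude surface in the assembly are not modeled, so absolute ASA near
  interfaces is higher than in the complex.
- No secondary-structure assignment, rotamer modeling, or clash scoring —
  only accessibility.
- No confidence intervals on AUC; no covariate-adjusted or multivariate
  models.
- HGVS support is deliberately limited to single-residue missense
  substitutions; coding-DNA notations are carried as opaque metadata.
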