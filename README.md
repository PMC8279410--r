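# rsapath

Structure-based evaluation of missense-variant pathogenicity from relative
solvent accessibility (RSA).

Missense variants that cause disease by disrupting a protein's fold tend to
sit in the packed core, while benign population variants tend to sit on the
solvent-exposed surface. `rsapath` turns that observation into a quantitative,
testable pipeline for a single protein (the motivating case is the MTOR
kinase, with its population, somatic-cancer, and neurodevelopmental-disorder
variant groups):

1. **Accessibility** — parse a PDB/mmCIF structure (one chain, one model,
   waters/hydrogens removed, highest-occupancy altloc kept), compute per-atom
   solvent accessible surface area with a Shrake–Rupley calculation on a
   deterministic golden-spiral lattice, sum to whole-residue ASA, and
   normalize by the residue type's theoretical maximum ASA:

   RSA(i) = ASA(i) / maxASA(restype(i)),

   with a consensus RSA (mean over conformational states in which the residue
   is resolved) and a differential RSA (active − inactive). Unresolved
   residues carry the `-1` sentinel and are excluded from all statistics.
2. **Curation** — parse HGVS p. notations, keep population variants with
   allele count ≥ 2 and no disease annotation, cancer variants with catalog
   recurrence ≥ 3 that are absent from the population catalog, and load the
   packaged literature catalog of 33 NDD-associated MTOR variants; assign
   protein domains from a versioned domain map and join per-residue RSA.
3. **Statistics** — on log(x+1)-transformed RSA: Kruskal–Wallis across the
   three groups (full protein and per domain), pairwise Wilcoxon rank-sum
   tests with Bonferroni correction, and ROC/AUC with the low-RSA-is-positive
   score orientation, AUC computed as the midrank Mann–Whitney probability
   U/(n₁n₂).
4. **Reporter assay** — phospho/total immunoblot ratios (T389/S6K for MTORC1,
   S473/AKT for MTORC2) normalized per blot to wild-type, with paired t-tests
   against wild-type and Bonferroni correction.
5. **Synthetic data** — generators for toy structures with analytically known
   burial, variant tables with a chosen closed-form AUC
   (Φ(Δ/(σ√2)) for two normal RSA distributions), and blot tables with known
   fold-changes, so every stage is testable without downloads.

## Worked example

```r
library(rsapath)

# accessibility of a synthetic four-helix bundle
bundle <- make_structure("helix_bundle", path = "bundle.pdb")
model  <- read_structure("bundle.pdb", chain_id = "A")
prof   <- accessibility_profile(model, sasa_params())
head(prof, 3)
#>   resseq resname      asa       rsa complete_atoms
#> 1      1     ALA 81.42296 0.6311858           TRUE
#> 2      2     ALA 34.95733 0.2709870           TRUE
#> 3      3     ALA 79.58373 0.6169281           TRUE
sum(prof$rsa < 0.05)   # buried core residues
#> [1] 11

# variant statistics on a synthetic study at the package's calibrated
# conditions (33 NDD, 60 cancer, 300 population variants)
tab <- make_variant_table(variant_spec(seed = 1))$table
res <- stratified_compare(tab)
res$full_protein$kruskal
#> Kruskal-Wallis [full_protein]: H = 41.19, df = 2, p = 1.14e-09
#>   (n: cancer=60, NDD=33, population=300)
roc_auc(tab, "NDD")
#> ROC NDD (n=33) vs population (n=300): AUC = 0.7861
#>   [score orientation: low_rsa_is_positive]
roc_auc(tab, "cancer")
#> ROC cancer (n=60) vs population (n=300): AUC = 0.6674
#>   [score orientation: low_rsa_is_positive]
```

The Kruskal–Wallis H of ~41 with df = 2 says the three groups' RSA
distributions differ strongly; the AUCs near 0.79 and 0.67 say a buried
residue is a moderately good predictor that a variant is disease-associated
rather than a population variant.

A command-line entry point wraps the same stages
(`sasa | analyze | assay | simulate`):

```sh
exec/rsapath analyze --config run.yaml --out results/
```

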