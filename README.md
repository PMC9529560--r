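# vrascreen

Concentrated monoclonal-antibody (mAb) formulations for subcutaneous
injection (~150 mg/mL protein) are often too viscous to push through a thin
needle. A practical remedy is a small-molecule excipient — a
**viscosity-reducing agent (VRA)** — that weakens the protein–protein
interactions driving viscosity. `vrascreen` is an R package for the
computational side of finding such excipients: ligand-based virtual
screening of compound libraries, physicochemical filtering built around an
ionizable-group ("charge group") calculus, dipeptide dual-excipient design,
and the statistical analysis that connects screening descriptors to measured
viscosity reduction.

The package is written for formulation scientists and cheminformaticians who
want a transparent, fully scriptable version of this screening workflow, and
it ships a synthetic-data generator that emulates the two-antibody viscosity
study design so every stage can be exercised and tested without laboratory
data.

## The methods at the core

* **Path fingerprint + Tanimoto search.** Each molecule is fragmented into
  all linear paths of 1–7 atoms (single C/N/O atoms ignored; a path closing
  a ring is terminated and flagged). Canonical fragments are hashed to
  0–1020 and set bits in a 1024-bit vector. Similarity between fingerprints
  is the Tanimoto index *T = c/(a + b − c)* over set-bit counts, with a
  screening threshold of 0.7 and a popcount prescreen
  (*T ≤ min(a,b)/max(a,b)*) that prunes the search without changing its
  result. Diverse subsets are picked by k-means in fingerprint space.
* **Charge groups.** Ionizable groups are assigned pKa values from a
  transparent functional-group table (overridable per compound). Under the
  screening rule, an acid with pKa < 6.4 is a negative charge group and a
  base with pKa > 8.4 a positive one; a Henderson–Hasselbalch "window" rule
  (charged fraction ≥ 0.10 at the target pH) reproduces the amino-acid
  counting in which histidine's imidazole is a third group at pH 6. The
  headline screening rule of thumb is **≥ 3 charge groups**.
* **Filter cascade.** Composable stages — molecular weight 100–300 Da, SlogP
  −2..2 (neutral species), charge-group count, substructure exclusions and a
  pluggable structural-alert gate — reported stage by stage.
* **Dipeptide dual excipients.** All 20² = 400 dipeptides of the canonical
  amino acids, kept when at least one pKa falls in [5, 7] (buffering
  capacity at pH 6.0) and they carry ≥ 3 charge groups.
* **Viscosity model.** Protein-in-water baselines follow η = a·e^{b·c};
  the fit is linear least squares on ln η. Relative viscosity is η/η₀ at
  the measurement's own protein concentration, and a compound is a VRA when
  its average relative viscosity over the two model mAbs is ≤ 0.8.
* **Analysis.** Point-biserial (Pearson) correlation of the binary VRA label
  with descriptors, two-sided Mann–Whitney U comparison of the ≥ 3 versus
  ≤ 2 charge-group strata (exact enumeration for small groups), and
  confusion-matrix metrics for the charge-group rule.

## Worked example

Simulate the default two-antibody study (94 compounds, 25 mM excipient,
150 mg/mL protein target), classify VRAs, and test the charge-group rule:

```r
library(vrascreen)

cfg  <- sim_config(seed = 42)
lib  <- generate_library(cfg)
sim  <- generate_measurements(lib, cfg)

fits <- fit_baseline(sim$measurements)
glance(fits)
#> # A tibble: 2 × 4
#>   mab_id n_points rms_log_residual eta_150
#> 1 mabA          6           0.0197    25.3
#> 2 mabB          6           0.0120    14.4

records <- classify_vra(sim$measurements, fits)
head(records, 4)
#>   compound_id rel_visc_mabA rel_visc_mabB avg_rel_visc is_vra
#> 1 S001                0.863         0.955        0.909 FALSE
#> 2 S002                0.980         0.961        0.971 FALSE
#> 3 S003                0.459         0.473        0.466 TRUE
#> 4 S004                0.507         0.590        0.548 TRUE

tab <- build_analysis_table(
  records,
  compute_descriptors(lib[, c("id", "smiles")], which = c("mw", "slogp")),
  lib[, c("id", "n_charge_groups")]
)
group_comparison(tab, k = 3)
#> Mann-Whitney U test (normal_approx): U = 248, n = (48, 46),
#> two-sided p = 9.757e-11
evaluate_rule(tab, 3)
#>       k    tp    fp    tn    fn sensitivity specificity precision accuracy
#> 1     3    42     6    39     7       0.857       0.867     0.875    0.862
```

The fitted baselines land at 25.3 and 14.4 cP at 150 mg/mL (inside the
10–30 cP band the generator enforces), compounds with ≥ 3 charge groups
reduce viscosity far more often than the rest, and the confusion matrix
shows the ≥ 3-charge-group rule recovering the planted VRAs with ~86%
balanced accuracy.

The amino-acid census behind the dipeptide design:

```r
census <- count_charge_groups(aa_groups(), charge_rule("window", ph = 6.0))
census[census$n_charge_groups >= 3, ]
#>   id    n_pos n_neg n_charge_groups
#> 1 D         1     2               3
#> 2 E         1     2               3
#> 3 H         2     1               3
#> 4 K         2     1               3
#> 5 R         2     1               3
```

Exactly five amino acids qualify — Asp, Glu, His, Lys, Arg — and the 400
dipeptides reduce to 39 histidine-containing buffering candidates, all of
which pass the ≥ 3-charge-group dual-excipient filter.

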