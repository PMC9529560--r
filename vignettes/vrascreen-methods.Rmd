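---
title: "Screening for viscosity-reducing excipients: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for viscosity-reducing excipients: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vrascreen)
library(dplyr)
```

`vrascreen` implements a computational pipeline for discovering
viscosity-reducing agents (VRAs) for concentrated monoclonal-antibody
formulations. This vignette is the package's account of the science inside
it: the models, their assumptions, the tunable parameters, and the places
where a design decision had to be made.

## 1. Why viscosity, and what counts as a reducer

The viscosity of a protein solution grows roughly exponentially with protein
concentration, because transient networks of reversibly self-associating
antibody molecules resist flow. At the ~150 mg/mL concentrations needed for
subcutaneous dosing this regularly exceeds the ~20 cP syringeability limit.
Small-molecule excipients can disrupt the underlying electrostatic and
hydrophobic protein–protein contacts.

The package's measurement model has three parts:

1. **Baseline.** Protein-in-water viscosity follows
   $\eta_0(c) = a\,e^{bc}$, fitted per antibody over a 120–200 mg/mL design
   range. `fit_baseline()` fits by linear least squares on
   $\ln \eta = \ln a + b c$. Fitting in log space is deliberate: the
   measurement error of viscometry is multiplicative (a few percent of the
   reading), so least squares on $\ln\eta$ weights relative error evenly,
   and it makes the fit a closed-form linear problem with no initialisation
   or convergence concerns.
2. **Relative viscosity.** Each excipient measurement is divided by the
   baseline evaluated at that sample's own (spectrophotometrically
   determined, hence jittered) protein concentration:
   $\eta/\eta_0(c_{\text{obs}})$. Concentrations more than 10% outside the
   fitted range trigger a warning, not an error — excipient samples target
   150 mg/mL, the middle of the range, so extrapolation signals a data
   problem rather than an expected condition.
3. **Classification.** A compound is a VRA when its average relative
   viscosity over the antibodies tested is **≤ 0.8** (inclusive). The 0.8
   cutoff sits between an arginine-like effect (relative viscosity 0.5–0.6
   at 25 mM, the field's reference VRA) and the ~0.1 experimental spread of
   the ratio, so a compound roughly as good as arginine is always caught.
   The average is the unweighted arithmetic mean of the per-antibody ratios;
   with two antibodies and ratios near 1 the difference from a geometric
   mean is well below measurement error, and the arithmetic mean keeps the
   classifier linear in the measured ratios.

## 2. The path fingerprint

Similarity screening uses a 1024-bit path fingerprint built in the package
(`enumerate_fragments()`, `fingerprint()`):

* every simple path of 1–7 atoms in the hydrogen-suppressed graph is a
  fragment; single-atom fragments consisting of C, N or O are ignored
  (they carry no discriminating information and would saturate the vector);
* a walk that reaches an atom adjacent to an atom already on the path is
  terminated there and the fragment flagged as a ring closure;
* fragments are encoded from (element, aromatic flag) atom codes and
  bond-order codes, canonicalised as the lexicographic minimum of the
  forward and reversed encodings, hashed with a fixed base-31 polynomial
  rolling hash modulo 1021, and the hash sets a bit.

The encoding alphabet — atomic element plus aromatic flag, bond order plus
aromatic bond code — is the minimal choice that makes chemically identical
fragments collide and distinct ones usually not; 1021 is the largest prime
not exceeding the vector length, which spreads the hash uniformly and
leaves bits 1021–1023 permanently clear. No bit-compatibility with any
external fingerprint implementation is claimed; what matters downstream is
the Tanimoto geometry, not the specific bit assignments.

`tanimoto()` implements $T = c/(a+b-c)$. Two all-zero fingerprints (e.g.
methane vs methane) compare at 1.0 by convention, avoiding 0/0; empty
versus non-empty is 0. The default search threshold is 0.7 and is applied
as $T \ge 0.7$ — the non-strict reading — with a `strict` flag for the
alternative. `similarity_search()` prunes candidate pairs with the popcount
bound $T \le \min(a,b)/\max(a,b)$; the pruned search is tested to be
identical to the exhaustive scan.

Diverse-subset selection (`cluster_and_pick()`) is k-means on the 0/1 bit
coordinates with k-means++ initialisation under a caller-supplied seed, a
100-iteration cap, and up-to-`per_cluster` members nearest each centroid
(ties broken by lowest index). It stands in for the manual "pick a few per
cluster" steps of a real campaign; those manual choices are unrecoverable,
so the package makes the selection seeded and reproducible instead.

## 3. Charge groups and the pKa table

The central mechanistic quantity is the number of *charge groups* —
ionizable functional groups expected to be charged in the formulation.
Commercial pKa predictors are opaque; `assign_pkas()` instead matches a
small, inspectable functional-group table (carboxylic, phosphonic and
sulfonic acids, tetrazole, phenol, thiol, aliphatic amines, guanidine,
amidine, imidazole, pyridine, aniline) against the molecular graph and
attaches representative literature pKa values, with a per-compound override
table (CSV) taking precedence. This trades absolute pKa accuracy for
determinism and auditability, which is the right trade for rule-level
screening: the rules below depend on which side of a threshold a group
falls, not on its second decimal.

Two counting rules are exposed (`charge_rule()`):

* **threshold** (screening default): acid pKa < 6.4 counts negative, base
  pKa > 8.4 counts positive. These cutoffs demand ≥ 99% ionisation at
  pH 6.4 (one pH unit of margin around the formulation pH), and are pH-free
  by construction.
* **window**: a group counts when its Henderson–Hasselbalch charged
  fraction at the target pH is at least `min_charged_fraction` (default
  0.10 at pH 6.0). This rule exists because the threshold rule misses
  histidine: its imidazole (pKa ≈ 6.0) is half-protonated at pH 6 and
  plainly relevant to both charge and buffering, and the amino-acid census
  that motivates the dipeptide design counts histidine as a three-group
  amino acid. Under the window rule exactly five canonical amino acids have
  ≥ 3 charge groups: Arg, His, Lys, Glu, Asp.

Expected charges at a pH (`charge_at_ph()`) use the independent-groups
model: each group's charged fraction is $1/(1+10^{\mathrm{p}K_a-\mathrm{pH}})$
for acids and $1/(1+10^{\mathrm{pH}-\mathrm{p}K_a})$ for bases; the net
charge is the signed sum, the absolute charge the unsigned sum, and the
major-species charge rounds each group independently (fractions of exactly
0.5 round to uncharged). Site–site interactions and true microstate
enumeration are knowingly ignored — a documented limitation that matters
little for the ≤ 6-group molecules screened here.

The formulation pH appears in two places in the screening story (6.0 for
most campaigns, 7.4 in one restatement of the Chemspace filter); the
package takes pH as a parameter with default 6.0 everywhere rather than
hard-coding either value.

## 4. The filter cascade and campaigns

`apply_physchem_filter()` runs MW → SlogP → charge groups → structural
alerts, in that fixed order, reporting removals per stage. The stages are
conjunctive, so the surviving set is order-independent; the order is fixed
(cheap descriptor windows first) only so the per-stage counts are
reproducible. All printed windows ("between 100 and 300 Da", "between −2
and 2") are treated as inclusive bounds; boundary compounds pass.

SlogP is computed on the neutral species — structures are interpreted as
drawn, and the package's libraries are written uncharged. Descriptors come
from the OpenBabel engine (MW, logP, TPSA, H-bond donors/acceptors) plus
graph-derived counts; absolute logP values differ between descriptor
engines by small constants, which shifts no conclusion that depends on a
±2 window.

The `run_campaign()` presets mirror the three library campaigns (similarity
search then seeded diverse sampling; exclusion patterns then the
MW/SlogP/charge windows; pooled safe-compound libraries with deduplication,
SlogP ≤ 2, ≥ 3 charge groups and a toxicity-alert gate) plus the dipeptide
design. The alert gate (`toxicity_alerts()`) replaces a proprietary
expert system with a user-supplied table of SMARTS patterns carrying an
endpoint and a likelihood level; a compound is alert-free iff nothing
matches at likelihood ≥ "plausible". The shipped alert and exclusion lists
are small illustrative starters, not a reproduction of any commercial
knowledge base.

## 5. Dipeptide dual excipients

`enumerate_dipeptides()` builds all ordered pairs of the 20 canonical amino
acids — direction matters (AB ≠ BA), which is what makes the library 400
compounds — by string condensation of amine-first/carboxyl-last SMILES, so
each structure is the residue pair minus one water (the MW identity
MW(AB) = MW(A) + MW(B) − 18.02 Da is tested across the library). Ionisation
uses the independent-groups model with backbone defaults: N-terminal amine
pKa 8.2, C-terminal carboxyl 3.1 (peptide-bond formation shifts both
relative to free amino acids), side chains inheriting free-amino-acid
values from the shipped table (standard biochemistry reference values).

`buffering_filter()` keeps dipeptides with at least one pKa in [5, 7] —
buffering capacity within one unit of pH 6.0; with the shipped table that
selects exactly the 39 histidine-containing sequences.
`dual_excipient_candidates()` then requires ≥ 3 charge groups under the
window rule; all 39 qualify (N-terminal amine + C-terminal carboxyl +
imidazole). Which handful of qualifiers to purchase is a wet-lab judgement
the package does not model; it reports all of them with their (n⁺, n⁻)
patterns.

## 6. Statistics

* `correlate_classifier()` reports Pearson correlations between the 1/0 VRA
  label and each descriptor — the point-biserial coefficient, tested
  against its closed form. Constant columns are flagged undefined rather
  than reported as 0. Correlations are descriptive and deliberately
  uncorrected for multiplicity.
* `group_comparison()` is a two-sided Mann–Whitney U test of average
  relative viscosity between the ≥ 3 and ≤ 2 charge-group strata. For group
  sizes up to 8 without ties the null distribution of U is enumerated
  exactly (≤ 12 870 arrangements; the two-sided p doubles the smaller tail).
  Larger or tied samples use the normal approximation with tie-corrected
  variance and continuity correction, sharpened by an Edgeworth kurtosis
  term (excess kurtosis
  $-\tfrac{6}{5}(n_1^2+n_2^2+n_1 n_2+N)/(n_1 n_2 (N+1))$, verified against
  enumeration) for moderate deviates; the correction is dropped beyond
  |z| = 4 where the polynomial term would corrupt an already-negligible
  tail. At 8 + 8 the two paths agree within 0.001 in p.
* `evaluate_rule()` scores the predictor "n_charge_groups ≥ k" against the
  VRA label as a confusion matrix with sensitivity, specificity, precision,
  accuracy and balanced accuracy, sweepable over k.

## 7. The synthetic study design

`sim_config()` encodes the study conditions the generator emulates, and its
defaults are fixed study parameters, not tuning knobs:

* **Library**: 94 compounds (the size of the tested set), built by a
  scaffold grammar — a short alkyl core decorated with ionizable
  substituents (carboxylate and sulfonate carriers for acids, amine and
  guanidine carriers for bases) plus neutral decorations. Each carrier
  group is charged under both counting rules at pH 6, so the
  construction-time charge-group count is exact ground truth. The default
  count distribution (10/15/20/25/20/10% over 0–5 groups) spreads the
  library across strata the way a mixed screening set is.
* **Effect model**: a compound is a true reducer with probability
  $\mathrm{logit}^{-1}(\beta_0 + \beta_1 n_{\text{cg}})$, defaults
  $\beta_0 = -4$, $\beta_1 = 1.8$: near-zero probability with no charge
  groups, ~80% at three, >99% at five — the minimal generative story for
  "reducers concentrate at ≥ 3 charge groups" with realistic exceptions on
  both sides.
* **Magnitudes**: reducers draw a true relative-viscosity ratio from
  N(0.6, 0.1) (the arginine benchmark with the stated ~0.1 experimental
  spread), non-reducers from N(1.0, 0.1), truncated at 0.05; the ratio is a
  compound property shared across antibodies.
* **Measurement layer**: two antibodies with baselines a = 0.278, b = 0.030
  and a = 0.350, b = 0.025 (25.0 and 14.9 cP at 150 mg/mL, inside the
  stated 10–30 cP band); baseline design points at
  {120, 135, 150, 165, 180, 200} mg/mL; excipient samples at
  c ~ N(150, 5) mg/mL representing per-sample concentration determination;
  multiplicative log-normal noise with 5% CV on every viscosity (noise is
  multiplicative because the fit is log-linear); 25 mM excipient at pH 6
  recorded as metadata.

What the generator does **not** emulate: real vendor-catalog chemistry
(scaffold diversity, tautomers, salts), pKa prediction error, site–site
ionisation coupling, shear-rate dependence, or the +0.2 pH drift of
up-concentration. Passing tests therefore demonstrate that the pipeline
recovers structure it is pointed at under the stated error model — not that
the charge-group rule generalises to any particular real library.

Determinism: every stochastic step runs under `withr::with_seed` on the
config seed (the measurement layer offsets the seed so library and
measurements are independent draws), so a config reproduces its data
byte-for-byte.

## 8. Numerical and edge-case conventions

* Duplicate structures are defined by stereo-aware canonical SMILES
  equality (OpenBabel canonicalisation); the first occurrence is kept.
* Average (not monoisotopic) atomic masses everywhere, matching
  conventional MW filters.
* The approximate SASA is an overlapping-spheres atomic-contribution model
  (Bondi radii, 1.4 Å probe, caps subtracted at idealised bond lengths,
  implicit hydrogens included; 1–3 overlaps ignored). It requires no 3D
  conformer and is used only to normalise polar surface area (`psa_sasa`),
  where ordering, not absolute area, matters.
* Invalid library records are skipped and counted, never silently dropped;
  an entirely invalid library is an error.
* Mann–Whitney ties always route to the tie-corrected approximation; exact
  enumeration requires tie-free data.
* `classify_vra()` averages replicate measurements per compound–antibody
  pair before averaging across antibodies, and compounds with no
  measurements are skipped with a warning.

## 9. Problem sizes used in the checks

The packaged tests and the acceptance script run the oracle equivalences on
500-compound generated libraries, parameter recovery on 200 replicates of
50-point baselines, planted-effect recovery on 100 replicates of the
94-compound study, and type-I calibration on 400 null replicates — sizes
chosen to make the Monte-Carlo rates stable at the thresholds being
checked while keeping a desk-scale run.

## 10. Known limitations

* The pKa table is coarse by design; compounds dominated by unusual
  ionisable chemistry need override entries.
* Fingerprint bits are not comparable with any external FP2
  implementation, only internally.
* The independent-groups charge model overstates simultaneous ionisation
  of strongly coupled sites (e.g. EDTA-like polyacids).
* The screening-scale search index is a popcount prescreen, adequate for
  10³–10⁵ compounds; screening tens of millions of vendor compounds would
  need an inverted index and is out of scope.
* Wet-lab steps of a real campaign — visual inspection, purchasing
  decisions, assay execution — are represented by seeded random stand-ins
  or data files, and carry no claim of equivalence to any expert's choices.
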