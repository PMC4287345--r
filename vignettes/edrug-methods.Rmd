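---
title: "Region-centric association testing: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-centric association testing: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edrug)
```

## Why regions, not genes

Gene-centric pharmacogenomic tests pool every mutation in a gene into one
binary covariate. That pooling is lossy in two ways. First, mutations in
different functional regions of a protein can perturb different functions
(ligand binding vs catalysis vs regulatory disorder), so their phenotypic
consequences need not agree. Second, when two regions shift drug response
in *opposite* directions the pooled contrast cancels and the gene shows
nothing, although each region carries a real, clinically meaningful
signal. `edrug` therefore takes the protein functional region (PFR) — an
annotated domain, a predicted domain, or an intrinsically disordered
region — as the unit of association testing, and treats overlapping
regions independently (they come from independent annotation sources and
are never merged).

## The testing model

For a PFR $r$ in gene $g$ and a drug $d$ with activity-area vector $y$
(area above the dose–response curve; unitless, non-negative, higher =
more effective), define sample groups by missense mutation status:
$M_r$ (mutated in $r$), $M_g$ (mutated anywhere in $g$), and
$U_g$ (no missense in $g$). Samples lacking an activity value for $d$
are dropped from that drug's contrasts only. Samples mutated both inside
and outside $r$ count as region-mutated only — the region perturbation is
present, and double counting is avoided.

A pair is reported `significant` when all three hold:

1. **Stage I**: two-sided Wilcoxon rank-sum of $y[M_r]$ vs the comparison
   group, $p < p_1$ (default 0.01). The comparison group is $U_g$ by
   default (`gene_unmutated`); the complement of $M_r$
   (`region_unmutated`) is selectable.
2. **Gene-level exclusion**: rank-sum of $y[M_g]$ vs $y[U_g]$ must *not*
   fall below $p_g$ (default 0.01); otherwise the pair is a whole-gene
   signal and is labelled `gene_level`.
3. **Stage II**: rank-sum of $y[M_r]$ vs $y[M_g \setminus M_r]$,
   $p < p_2$ (default 0.05). The within-gene contrast involves fewer
   samples and fewer tests, which motivates the laxer level. When
   $M_g \setminus M_r$ is empty the stage is recorded as absent and the
   pair cannot be called significant (conservative).

Pairs with fewer than `min_mutated` (default 2) region-mutated profiled
samples are not tested at all (`insufficient_mutations`). The decision
rule intentionally uses raw p-values — the multistage design is the
false-positive control — but Benjamini–Hochberg q-values across stage-I
tests are emitted as an informational column (`q_stage1`) for readers who
want a conventional FDR view; they never affect calls.

The direction label comes from the median difference
$\Delta = \mathrm{med}(y[M_r]) - \mathrm{med}(y[\text{comparison}])$:
$\Delta > 0$ is `sensitizing`, $\Delta < 0$ is `resistance` (mutated
samples respond worse), $\Delta = 0$ is `undetermined`.

On stage-I thresholds: the method's descriptions give 0.01 in prose and
0.001 in one figure legend; the package defaults to 0.01 and exposes the
level as `association_thresholds(p_stage1 = )`. The comparison group for
stage I is likewise described in two ways (no mutation in the region vs
no mutation in the protein); the default is the cleaner gene-unmutated
contrast, with the alternative selectable, so both published readings are
runnable.

### The rank-sum primitive

`rank_sum_test()` uses the exact Mann–Whitney null distribution when both
groups have at most 8 observations and the pooled sample is tie-free
(enumeration is cheap there, and that is precisely the small-mutated-group
regime); otherwise the normal approximation with tie-corrected variance
and continuity correction, with average ranks for ties. A pooled sample
with zero rank variance returns $p = 1$. The exact path is checked in the
test suite against full enumeration of all two-group partitions of up to
14 distinct values; the approximate path against an independent
implementation of the tie-corrected normal form.

## Disorder prediction

`foldindex_profile()` scores each residue by the charge/hydropathy
unfoldability index $FI = 2.785\,\langle H\rangle - |\langle q\rangle| -
1.151$, where $\langle H\rangle$ is the window mean of Kyte–Doolittle
hydropathy rescaled to $[0,1]$ by $(h+4.5)/9$ and $\langle q\rangle$ the
window mean net charge (K, R = +1; D, E = −1, others 0; histidine is
treated as neutral). Defaults:

* `window = 51` residues — the customary default of the original
  disorder tool; windows are truncated at the termini so every residue is
  scored. The source method states only the −0.1 threshold, so the window
  is a declared package default, exposed in the configuration.
* `threshold = -0.1` — residues scoring below it count as disordered.
* `min_length = 10` — IDRs shorter than this are discarded. The source
  method is silent here; 10 residues suppresses single-residue noise
  segments while remaining permissive, and the value is configurable.
* Ambiguous `X` residues contribute neutral hydropathy (0.5 scaled) and
  zero charge; any other non-standard letter is rejected rather than
  guessed.

Window sums are accumulated in integer arithmetic (hydropathy tenths), so
the profile of a reversed sequence is the bit-for-bit reversal of the
original profile — a cheap invariant that catches windowing asymmetries.

Coordinates are 1-based inclusive residue intervals throughout (the
protein convention); the only 0-based half-open surface is the BED
exporter at the I/O boundary.

## The synthetic cohort generator

`generate_proteome()` + `generate_cohort()` emulate the data a
region-centric analysis consumes: genes with non-overlapping domain
intervals (optionally one disorder-tagged interval), per-sample missense
mutations, and an activity-area matrix. Defaults, chosen once as a
realistic desk-scale regime:

* protein lengths 500–900 aa, domains 90–160 aa, 1–2 domains per gene,
  25% of genes with an extra IDR-tagged interval;
* per-(sample, gene) mutation probability 0.2 — the regime of recurrently
  mutated cancer genes in pan-cancer panels. At 400 samples this puts a
  typical region at roughly 10–20 mutated samples, matching the
  mutation-count regime in which most tested pairs of a real panel sit,
  and large enough for the asymptotic rank-sum path to be well
  calibrated;
* activity area ~ Normal(3.0, 0.5), comparable to the 0–8 scale of
  cell-line panels, clipped at 0 (the clip preserves the activity-table
  invariant and is negligible six standard deviations from the mean);
* planted effects add a constant `delta` to carriers of a region for one
  drug; `min_mutated_per_effect` tops up carrier groups from gene-naive
  samples so designed case groups (e.g. two disjoint opposite-shift
  groups in one gene) are guaranteed, with every draw taken from the one
  seeded stream.

All draws derive from a single integer seed; the same truth and seed
reproduce the cohort bit-for-bit, and the generator restores the caller's
RNG state.

What the simulator does **not** model: mutational signatures and
hotspots beyond a simple optional hotspot placement mode, copy-number
and expression covariation, panel-specific missingness structure, and
dose–response curve fitting (activity areas are drawn directly). Passing
tests therefore demonstrate the engine's statistical behaviour under
clean Gaussian response noise, not robustness to the full messiness of
real panels.

## Downstream validation analyses

* **Survival**: patients treated with a drug are stratified into three
  groups — mutated in a resistance-direction PFR for that drug, mutated
  elsewhere in the same genes, or unmutated in those genes — with the
  resistance label taking precedence for patients in both categories
  (presence of the resistance lesion dominates; the stratification is
  restricted to resistance-direction regions, which are the more numerous
  direction class). `kaplan_meier()` implements the product-limit
  estimator (events before censorings at ties) and `logrank_test()` the
  standard unweighted k-sample log-rank; since the single published
  contrast is not specified, `survival_stratification()` emits the
  3-group statistic plus all pairwise tests. Both estimators are
  cross-checked in the suite against the survival package on random data
  and against hand-computed tables.
* **Proteomics**: `expression_group_test()` is the same rank-sum
  machinery applied to expression by mutation status;
  `expression_activity_correlation()` is the Pearson correlation with
  the t-transform p-value (≥ 3 complete pairs; zero variance is an
  error, not a silent `NA`).
* **Chemistry**: `target_overlap_test()` asks, per drug, whether
  associated proteins are enriched among interaction partners at a score
  threshold (customary 700/800/900 on the 0–1000 scale) with a one-sided
  Fisher exact test against the tested-gene background;
  `expand_targets_by_similarity()` unions the targets of chemicals with
  Tanimoto similarity strictly above 0.70 (the "over 0.70" reading; a
  chemical at exactly the cutoff does not contribute). All-zero
  fingerprints are declared identical (similarity 1) rather than
  undefined.
* **Enrichment**: `go_enrichment()` runs per-term one-sided Fisher tests
  against a background with BH q-values; no correction is imposed on the
  decision rule because none is prescribed for the published analysis —
  both raw p and q are reported.

## Numerical and degenerate-input choices

* Exact vs approximate rank-sum switches at group size 8 without ties;
  the exact two-sided p doubles the smaller tail and caps at 1.
* Fisher exact p-values come from hypergeometric tail sums; the
  two-sided variant sums all tables no more probable than the observed
  one, with the usual $1+10^{-7}$ relative guard against floating-point
  equality. The suite checks every table with margins ≤ 20 against
  direct enumeration from binomial coefficients.
* Empty comparison or carrier groups make a pair untestable rather than
  producing a p-value; empty other-region groups record stage II as
  absent and block significance.
* Result tables are completely ordered by (drug, region) with fixed
  column order, so identical inputs produce byte-identical files.
* Ties in `select_largest_isoform()` break to the lexicographically
  smallest isoform identifier, making isoform selection order-invariant.

## Reference study conditions

The acceptance checks run at these problem sizes, stated here as the
package's reference conditions: calibration on ten null cohorts of 200
genes × 2 regions × 4 drugs × 400 samples (≈ 16,000 tested pairs);
recovery on 100 replicates of the one-gene opposed-shift construction
(±1.0 activity-area units, ≥ 15 carriers per region, noise sd 0.5);
rank-sum enumeration up to 7 + 7 values; Fisher enumeration up to margins
of 20. Under the continuity-corrected normal approximation the null
stage-I rejection rate at 0.01 sits slightly below nominal (≈ 0.008–0.009
for carrier groups of 10–20), a deliberate mild conservatism inherited
from the corrected test.

## Known limitations

* The engine consumes protein-level mutations; mapping genomic
  coordinates to protein positions (and filtering to missense) is
  upstream of this package, as is de-novo domain detection — domain
  intervals are inputs.
* Raw-threshold decision rules replicate the published procedure; users
  wanting FDR-controlled calls should filter on `q_stage1` themselves.
* Stage correlations mean the three-stage filter's false-positive rate
  under the null is close to the stage-I rate (the gene-level and
  stage-II filters remove little that stage I admits by chance); the
  design's value is region specificity, not additional type-I
  stringency.
* Activity areas are treated as exchangeable across samples; no
  covariates (tissue, lineage) are modelled.
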