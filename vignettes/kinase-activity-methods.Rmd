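---
title: "Inferring differential kinase activity from phosphoproteomic site tables"
author: "inkaflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring differential kinase activity from phosphoproteomic site tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inkaflow)
```

## The problem

Label-free phosphoproteomics quantifies tens of thousands of phosphosites,
but the biological question is usually one level up: *which kinases changed
activity* between two conditions? A kinase's activity is not measured
directly; it must be inferred from the phosphorylation of the kinase itself
and of its known substrates. `inkaflow` implements a complete inference
chain for two-group comparisons of MaxQuant-style site tables:

1. parsing and quality filtering of `Phospho (STY)Sites`-style tables;
2. chemistry-specific normalization (phosphotyrosine immunoprecipitation
   versus global Ser/Thr enrichment);
3. empirical-Bayes moderated two-group testing per site;
4. INKA (integrative inferred kinase activity) scoring from four evidence
   arms, with group aggregation and a hybrid combination of the two
   chemistries;
5. phosphosite-signature enrichment on a signed rank-value statistic.

Because raw mass-spectrometry data are too heavy for routine testing, the
package ships a synthetic-data generator that emulates the site-table
dialect and plants known hyperactive kinases, so every stage can be
validated against ground truth.

## Data model and preprocessing

A *phosphosite record* is one residue (S/T/Y) at a position within a
protein, with a localization probability (the confidence that the phosphate
sits on that exact residue), a 15-mer sequence window centred on the site,
decoy/contaminant flags, and per-sample intensities resolved by peptide
*multiplicity* (the number of phosphates on the quantified peptide form;
the `___1` columns are the singly phosphorylated forms). Missing values are
written as 0 on disk, following the MaxQuant convention, and held as `NA`
in memory. Both the triple-underscore (`___1`) and double-underscore
(`__1`) multiplicity suffixes are accepted on input.

Filtering keeps *class-I* sites: localization probability at or above 0.75
— the standard class-I definition, applied inclusively at the boundary —
with decoy and contaminant rows removed (`filter_class1()`; the threshold
is configurable).

Two normalizations reflect the two enrichment chemistries:

* **pY** (antibody-based phosphotyrosine capture): each sample's site
  intensities are divided by the summed total intensity of the matching
  whole-lysate run. We rescale the quotient by the median lysate total
  across samples so values keep intensity-like magnitudes; any positive
  rescaling cancels in downstream ratio statistics, so this choice is
  cosmetic but makes intermediate tables interpretable.
* **pSTY** (global metal-affinity capture): intensities are
  log10-transformed and median-normalized — every sample column is shifted
  so its median equals the grand median of the per-column medians. This
  preserves within-sample rank order exactly.

For kinase-activity scoring the pSTY branch is exponentiated back to the
linear scale after median normalization (`delog_matrix()`): arm scores are
intensity sums, and sums of log values have no intensity meaning.

Three imputation methods are provided. The enrichment branch imputes
missing values by 1 *before* the log10 transform, so imputed entries become
exactly 0 on the log scale — a deliberate, visible floor rather than a
guess. The differential branch defaults to a seeded per-sample Gaussian
downshift (mean minus 1.8 column SDs, width 0.3 SD), the de facto standard
for intensity-dependent missingness; `half_min` is available as a simpler
alternative. Sites observed in fewer than two samples per group are dropped
before testing.

## Moderated two-group testing

Per matrix row we compute the difference of group means and the pooled
within-group variance $s^2$ on $d = n_A + n_B - 2$ degrees of freedom. The
moderated statistic shrinks each row variance toward a prior:

$$\tilde{s}^2 = \frac{d_0 s_0^2 + d\, s^2}{d_0 + d}, \qquad
t = \frac{\bar{x}_B - \bar{x}_A}{\tilde{s}\sqrt{1/n_A + 1/n_B}},$$

with $t$ referred to a t distribution on $d + d_0$ degrees of freedom (a
normal when $d_0$ is unbounded). The hyperparameters $(d_0, s_0^2)$ are
estimated by moment matching of $\log s^2$ against its scaled-F sampling
distribution, using digamma/trigamma identities and a Newton inversion of
the trigamma function. On identical inputs this reproduces the standard
empirical-Bayes implementation to numerical precision (the test suite
cross-checks against `limma` on a ~2000-row null dataset), while the
package remains self-contained. Degenerate rows with zero variance and zero
difference get $p = 1$ by convention. Raw $p < 0.05$ defines "significant"
in the headline counts; Benjamini–Hochberg q-values are computed and
exported alongside.

### The rank-value statistic

The enrichment branch converts each site's fold change and p-value into

$$\mathrm{rank.value} = 10 \cdot \mathrm{sign}(FC) \cdot \log_{10}(p),$$

implemented verbatim. Note the formula's quirk: because $\log_{10} p \le
0$, *up*-regulated significant sites receive *negative* rank values. We
judge this a likely sign slip in the source convention but implement it as
printed; `sign_convention = "negated"` flips it for consumers that expect
up-regulation at the top of a descending ranking. Only the sign of the fold
change enters, so the log base of the fold change is immaterial.

## INKA scoring

For each kinase and sample, four evidence arms are summed on the linear
intensity scale:

* **kinome** — all observed phosphosites on the kinase's own protein;
* **activation loop** — the subset of own sites inside the annotated
  activation-loop interval (phosphorylation there typically switches the
  kinase on);
* **PSP** — substrate sites under curated kinase–substrate edges;
* **NWK** — substrate sites under predicted edges whose prediction score
  passes a cutoff (default 2.0, configurable; no published cutoff exists).

The kinase-centric arm is $C = (\mathrm{kinome} + \mathrm{loop})/2$, the
substrate-centric arm $S = (\mathrm{PSP} + \mathrm{NWK})/2$, and the
combined score $\sqrt{C \cdot S}$ — the geometric mean deliberately
propagates zeros, so a kinase needs both self-evidence and
substrate-evidence to score at all. This two-level combination follows the
published INKA scheme; the arm combiner is a configurable seam.

Scores are scaled to 100 within each sample (so a "score > 75" threshold
for high-activity kinases is meaningful across samples) and kinases are
ranked per sample, ties broken lexicographically for determinism. Raw
scores are exported alongside; the absolute scale of published INKA scores
is not pinned down anywhere, so per-sample max-100 scaling is an explicit
package choice.

## Group aggregation and the hybrid table

Differential activity between two groups is summarized per kinase by the
difference of group means of scaled scores (treated minus control), with
kinase–sample pairs absent from a table scored 0 — absence of evidence is
informative when ranking activity. The top-*n* ranking (default 10) sorts
by this difference.

The two chemistries are combined *as a direct sum*: the four arm scores are
added componentwise per (kinase, sample) and the combined score is
recomputed from the summed arms. We interpret the direct sum at the level
of the component tables rather than the final scores because the component
tables are what the two analyses share; `hybrid_mode = "sum_scores"`
exposes the alternative (adding final scores), since it is not documented
which variant published hybrid analyses used. The direct sum is commutative
and degenerates to the single-chemistry table when the partner is empty.

Kinase–substrate networks are exported (edge-list TSV and Graphviz DOT)
for any kinase set; kinases without observed substrates are kept as
isolated nodes so high-scoring kinases with no covered substrates remain
visible.

## Signature enrichment

Signatures are sets of phosphosites keyed by 15-mer flanking windows with
the phosphoresidue in lower case, read from GMT files; a `;u`/`;d` member
suffix marks directed membership. Matching against the rank matrix is
case-insensitive string equality of windows; signatures with fewer than
`min_overlap` matches (default 5) are excluded.

Scoring is a weighted running sum over the descending-sorted rank values:
hits increment by $|r|^\alpha$ normalized over hits (default $\alpha =
0.75$, the cited tool's default), misses decrement by $1/(N - N_h)$, and
the enrichment score is the running sum at its maximal absolute deviation
(first occurrence on ties; sorting ties are broken by site key so results
are deterministic). At $\alpha = 0$ this reduces exactly to the classical
Kolmogorov–Smirnov-style statistic, which the tests exploit as an
independent oracle. Down-directed members contribute with their value sign
flipped before ranking.

Significance uses *site-label permutation*: the null is built from random
same-size site sets. A single contrast column leaves no sample labels to
permute — the two-group comparison happens upstream in the moderated test —
so site permutation is the only available scheme; its p-values are
empirically uniform under a random-membership null (verified by a KS test
in the suite). The p-value is the same-sign exceedance fraction with an
add-one correction, the normalized score divides by the mean absolute
same-sign null score, and q-values are Benjamini–Hochberg across
signatures.

## The synthetic-data generator

The generator emulates what the analysis consumes, not the spectra:

* a kinase–substrate database with a configurable number of kinases, exact
  out-degree, curated/predicted evidence mix, autophosphorylation sites,
  and one activation-loop interval per kinase containing at least one own
  site;
* per-site baseline intensities drawn log-normally (defaults: log10 mean
  6.5, SD 0.8 — typical magnitudes for label-free site intensities);
* per-observation multiplicative noise (log10 SD 0.25, a realistic
  between-replicate spread for cultured-cell replicates);
* missing-not-at-random dropout: an observation at log10 intensity $x$ is
  missing with probability $\mathrm{logit}^{-1}((m - x) \cdot k)$, defaults
  $m = 5.5$, $k = 1.5$, placing heavy dropout one decade below the typical
  intensity; a midpoint of $-\infty$ disables dropout for calibration
  studies;
* site multiplicities drawn with probabilities (0.70, 0.25, 0.05) for
  1/2/3 phosphates, matching the usual dominance of singly phosphorylated
  forms;
* localization probabilities with a configurable fraction (default 10%)
  below the class-I threshold, plus small decoy and contaminant fractions.

Hyperactivity is planted by multiplying the treated-group intensities of a
kinase's own sites and a configurable fraction of its substrate sites by
the effect size *before* noise and dropout. Two datasets are derived from
one shared truth by residue restriction — tyrosine sites form the pY
dataset, serine/threonine sites the pSTY dataset — each acquired with
independent noise, mirroring how the two chemistries sample one underlying
phosphoproteome. A signature database is derived from the same ground
truth (one signature per kinase, keyed by substrate flanking windows).

What the generator does **not** emulate: peptide-level evidence and shared
peptides, retention-time structure, batch effects, correlated noise across
sites of one protein, realistic kinase–substrate topology (hubs, shared
substrates beyond random collisions), or biological covariation between
kinases. Passing tests therefore demonstrate that the chain recovers
planted signal under idealized independence assumptions — necessary, not
sufficient, evidence for performance on real data.

## Numerical and design choices

* All randomness is seeded; seeded helpers restore the caller's RNG state.
* Intensity sums treat missing as zero contribution; log-scale input to
  arm scoring is rejected outright rather than silently exponentiated.
* The running-sum score is computed from cumulative hit/miss fractions
  rather than signed increments, which keeps it bit-identical to a direct
  per-position evaluation of the definition.
* Ranking ties anywhere in the package are broken lexicographically.
* GCT export writes the magic line `#1.3` and a two-number dimensions line
  (rows, columns) with rank values at full precision; the reader also
  accepts the four-number dimensions variant.
* The test suite sizes its simulations to run in seconds: the null
  calibration uses ~2000 multiplicity-resolved rows of complete data (so
  it measures the statistic's calibration, not the imputation), recovery
  uses 20 replicates of a 100-kinase study, and enrichment calibration
  uses 200 random memberships at 1000 permutations each.

## Known limitations

* Only two-group designs; no paired tests or covariates.
* Activity inference is limited to kinases present in the database;
  no motif-based remapping of unexplained sites.
* The enrichment branch scores a single contrast column; multi-sample
  ssGSEA-style projection is out of scope.
* Calibration of the moderated test under heavy missingness depends on the
  imputation method; the downshift imputation is conservative by
  construction (it widens within-group variance for rows with dropout).
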