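---
title: "Methods: three-track archaeological sex estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-track archaeological sex estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleosex)
```

## Overview

`paleosex` implements the three approaches available for estimating the
biological sex of archaeological skeletal remains — shotgun-genomic read
ratios, enamel amelogenin proteomics, and osteological trait assessment —
together with the cross-method concordance framework needed to interpret
them jointly. The package's organizing idea is that the three signals have
different, largely independent failure modes: DNA abundance decays with
burial age, enamel peptides do not, and osteological markers require adult,
well-preserved skeletons. Conflicts therefore carry information about data
quality, and the certainty tier of each estimate (definitive, conditional,
indeterminate) must travel with the call.

## Genomic track

### The two statistics

Let $n_c$ be the number of reads mapped to chromosome $c$ and $L_c$ its
reference length (hg19).

* **Ry** $= n_Y / (n_X + n_Y)$ with the Wald binomial 95% interval
  $\mathrm{Ry} \pm z\,\sqrt{\mathrm{Ry}(1-\mathrm{Ry})/(n_X+n_Y)}$,
  clipped to $[0,1]$, $z = 1.96$. Male region $> 0.075$, female region
  $< 0.016$. XX individuals show small nonzero Ry from reads mismapped
  onto X/Y homologous regions; no homology masking is applied — the
  method's robustness comes from read depth.
* **Rx** $= \tfrac{1}{22}\sum_{i=1}^{22} \rho_X/\rho_i$ where
  $\rho_c = n_c/L_c$, with interval
  $\mathrm{Rx} \pm z\,s/\sqrt{22}$, $s$ the sample SD of the 22 ratios.
  Male region $< 0.60$, female region $> 0.80$. Expected $\approx 0.5$
  for XY (one X copy) and $\approx 1$ for XX.

Two choices here were genuinely open and are package decisions:

* The Rx dispersion uses the normal multiplier 1.96 rather than a $t_{21}$
  quantile, matching the published description of the method; this is
  mildly anti-conservative (a $t$ quantile would widen the CI by ~9%) and
  is configurable through `threshold_config(ci_multiplier =)`.
* No winsorization of autosomal ratios is applied.

### Interval classification

`classify_interval()` compares the CI with the two disjoint definitive
regions: entirely inside one region is **definitive**; touching or
crossing exactly one boundary is **conditional** ("consistent with ..."),
with the sex of the crossed region; entirely between the regions — or
spanning both — is **indeterminate**. Two tie-break rules:

* a CI endpoint exactly on a threshold counts as crossing (definitive
  calls require strict containment; conservative);
* a CI spanning both boundaries is indeterminate, not conditional: a
  "consistent with" call must single out one sex.

Degenerate inputs never raise from the classifiers: zero sex-chromosome
reads or an autosome with zero reads produce an indeterminate estimate
carrying a diagnostic string, because real cohorts contain failed
extractions and the concordance stage must see those rows.

### The read-depth minima

The published minima — 100,000 total mapped reads *or* 3,000
sex-chromosome reads — are advisory in this package: a sample below both
is flagged `low_data` but still classified, because the reference study
itself reports and then evaluates low-read estimates; reproducing that
evaluation requires making the calls. The "or" is read as: clearing either
minimum suffices for confidence.

## Proteomic track

Peptides are assigned specificity by substring containment against the X
and Y amelogenin isoforms after stripping PTM annotations (`"(+.98)"`,
`"[+15.99]"`, trailing `" + Oxidation (M)"`). Shared (homologous) and
unmatched peptides are excluded from the combined signal. I/L equivalence
(the residues are isobaric) is off by default — in practice diagnostic
amelogenin peptides differ by more than I/L — but available as a flag.

The **bundled isoform FASTA is a synthetic stand-in** (marked `_SYNTH` in
the headers and `synthetic` in the filename): a shared core with divergent
segments, structured so that the specificity filter is genuinely exercised
by the generator and tests. It is not the canonical pair of UniProt
entries, which the package cannot redistribute; substitute real sequences
via `amelogenin_isoforms(path =)` for production use. No packaged-cohort
statistic depends on the isoform sequences.

Classification: strictly more than 2 unique AMELY peptides (distinct
stripped sequences; PTM variants count once for the tally but all
contribute intensity) is a definitive XY call. The male rule takes
precedence over Pr(F) because AMELY detection is chromosome-diagnostic
while AMELX intensity is probabilistic. Otherwise

$$\Pr(F) = 1 + \frac{0.059 - 1}{1 + (x/7.54)^{13.99}},
\qquad x = \log_{10}(\text{AMELX CI/mg}),$$

with $\Pr(F) \ge 0.5$ giving XX and below giving indeterminate. The
equation as published has unbalanced parentheses; the four-parameter
logistic reading (floor 0.059, midpoint 7.54, Hill slope 13.99, ceiling 1)
is the only self-consistent one and is what `prf_model()` encodes. At the
midpoint $\Pr(F) = (1+0.059)/2$ exactly. The boundary case
$\Pr(F) = 0.5$ exactly is unspecified in the source ("greater than 0.5"
for females, "< 0.5" indeterminate); the package includes it in the
female call. `pr_female()` requires $x > 0$: sub-unity CI/mg lies outside
the calibrated domain, and numerically the curve plateaus at the floor
several log-units below the midpoint anyway.

A missing enamel mass never yields a silently wrong CI/mg: intensities
remain raw sums flagged `unnormalized`, the Pr(F) branch is disabled, and
only the peptide-count rule can still call the sample.

Replicate runs of one individual are not merged automatically; the higher
signal run should be treated as authoritative and corroborated against
DNA — as the reference study did for its one repeated burial.

## Osteological track

The fixture path ingests expert categorical labels verbatim
(`ingest_expert_estimate()`), with the table dialect `F*`/`M*` mapped to
the *probable* tier. The source table does not distinguish probable from
possible, and all cross-method accounting collapses both onto the
conditional tier, so this choice cannot affect any reported count.

`aggregate_traits()` is an explicitly package-defined surrogate: the
published scheme scores 20 traits (9 pelvic, 6 cranio-mandibular, 5
robusticity) but delegates their aggregation to expert judgment relative
to the local population. The surrogate uses a five-point score scale
(−2..+2), double weight for pelvic traits (the most dimorphic elements),
and |weighted-mean| cutoffs 1.5 / 0.75 / 0.25 for definitive / probable /
possible. These are conventions, all configurable, chosen to make the
osteological track testable end to end; the packaged-cohort statistics
never touch them. Juveniles are always indeterminate, reflecting the
absence of developed dimorphic markers before puberty.

## Concordance statistics

* **Denominator convention**: a pair's denominator is the samples where
  *both* methods are non-indeterminate. This reproduces every published
  pairwise cell from the packaged cohort (e.g. osteology–Ry 18/22: the 28
  osteological calls minus 6 with indeterminate Ry). Where the source
  text and its summary table disagree (an "18 of 23" in prose), the
  table's accounting — which is the one derivable from the sample-level
  data — is followed.
* **Conflict tiers**: a conflict is *definitive* only when both calls are
  definitive; any conflict involving a conditional-tier call (including
  osteological probable/possible) is *conditional*.
* **Depth stratification** uses a strict `>` comparison at the threshold,
  and zero conflicts above threshold is a computed result, never an
  assumption.
* **Preservation statistics**: group comparison of log10 total reads uses
  the *pooled-variance* Student t (df $= n_1+n_2-2$) — not Welch — since
  that is the published df accounting (53 usable samples, df = 51); zero-
  read samples are excluded, not imputed. The site grouping keeps the one
  late burial of the older site in its site group; regrouping it by
  period is not resolvable from the main text and would slightly move the
  older group's mean (the package computes 4.01; the source prints 4.05).
  Cross-signal correlation uses OLS on log-log scale with pairwise
  exclusion of zeros.

## Synthetic cohort generator

The generator's defaults encode the stated world of the reference study;
they were fixed before the acceptance checks were run and are not tuning
knobs:

| parameter | default | basis |
|---|---|---|
| depth decay | 5e-4 log10/yr | one order of magnitude lost over ~2,000 years |
| depth at age 0 | log10 mean 5.3, sd 1.1 | site group means 5.13/4.05 at cluster ages, sds 1.10/1.25 |
| DNA failure rate | 2/55 | two failed extractions in 55 |
| AMELX CI/mg | log10 mean 9.0, sd 0.6, age-invariant | printed 9.03 ± 0.56 and 9.08 ± 0.63 |
| AMELY unique peptides | NB mean 80, floor 3 | printed range 6–251, mean 81 |
| age clusters | 100–600, 1,610–2,240 cal BP | the two sites' occupation spans |
| `y_mappability` | 0.25 | places true-XY Ry near the empirical male band rather than the naive length ratio |
| `epsilon_y` | 0.002 | XX samples get small nonzero Ry, exercising the conditional-XX branch |
| juvenile fraction | 0.3 | typical for these burial populations |
| enamel mass | lognormal, ~16 mg median | plausible single-tooth enamel yields |

Chromosome counts are multinomial over the 24 canonical chromosomes with
weights copy-number × effective length; peptide tables are genuine
substrings of the bundled isoforms (so specificity assignment is really
executed, not mocked), with shared-peptide distractors; osteological trait
scores are sex-conditional Gaussians on the five-point scale with 35%
per-trait missingness.

What the generator does *not* emulate: sequence-level reads, aDNA damage
patterns, spectral-level noise, contamination, non-XX/XY karyotypes, and
any dependence of proteomic signal on age (deliberately: the reference
finding is its absence). A green synthetic test therefore establishes
that the estimators behave correctly *under the stated statistical
model* — multinomial counts, lognormal intensities — not that they are
robust to artifacts upstream of count tables and peptide tables. The
generative truth table is returned separately from the cohort and never
serialized into reports, so pipeline tests cannot leak it.

## Numerical and interface choices

* Wald rather than Clopper–Pearson intervals for Ry, matching the
  published method's behavior; at the depths where the choice matters the
  estimate is already flagged low-data.
* Down-sampling is multivariate hypergeometric (without replacement),
  preserving expected proportions exactly; it is sequential over 24
  chromosomes, deterministic under seed.
* The CLI accepts JSON configuration (thresholds, simulator); exit codes
  are 0 / 2 / 3 for success / input error / config error, logging goes to
  stderr, and every file report carries `# tool / seed / thresholds`
  provenance headers.
* Report TSVs round-trip losslessly through `read_report()`;
  indeterminate labels serialize as `"Indet"`, conditional tiers as a
  trailing `*`.

## Known limitations

* The packaged cohort transcribes the published per-sample table only;
  per-sample AMELX/AMELY intensities and replicate runs live in that
  study's supplementary material and are not included, so the proteomic
  regression against depth can be reproduced only on synthetic data.
* `aggregate_traits()` is a surrogate, not a validated scoring standard;
  use expert labels where available.
* Binary XX/XY plus indeterminate only; aneuploidies are out of scope.
* The Rx low-depth floor observed empirically (no definitive estimate
  below ~5,000 reads) emerges from, but is not enforced by, the
  classifier.
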