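---
title: "Methods: mutation-expression integration for pan-cancer driver discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutation-expression integration for pan-cancer driver discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driverscan)
```

## The discovery procedure

`driverscan` identifies candidate cancer driver genes by asking a functional
question rather than a frequency question: does mutation of a gene perturb
the expression of *other* genes, consistently, in several independent tumor
cohorts? The funnel is:

1. **Pre-selection.** Per cohort, somatic calls (MAF) are filtered to
   potentially pathogenic `Variant_Classification` values and collapsed into
   a binary gene x sample mutation matrix. Only genes mutated in *every*
   cohort are taken forward.
2. **Per-gene differential expression.** For each pre-selected gene and each
   cohort, samples are split into mutated vs unmutated and the whole
   z-scored expression matrix is tested with a two-class SAM permutation
   procedure at a target FDR of 0.2. The counts of significantly over- and
   under-expressed genes (excluding the tested gene's own transcript) are
   recorded, and normalized by the number of genes in the expression matrix.
3. **Candidate rule.** A gene is a candidate driver iff it is testable and
   affects at least `min_affected` other genes (either direction) in every
   cohort.
4. **Known-gene-free re-analysis.** The same funnel is repeated on the
   subset of patients carrying no retained mutation in any known cancer
   gene (COSMIC-style list), which removes the possibility that an apparent
   effect rides along with a co-occurring known driver.
5. **Characterization.** Candidates are profiled with the 20/20 rule,
   gene/protein length comparisons (K-S tests), chi-square contrasts of
   group rates, and hypergeometric gene-set over-representation.

## The SAM statistic and its null

For gene $i$ with unmutated class 1 ($n_1$ samples) and mutated class 2
($n_2$ samples):

$$d_i = \frac{\bar{x}_{2i} - \bar{x}_{1i}}{s_i + s_0}, \qquad
s_i = \sqrt{\left(\tfrac{1}{n_1}+\tfrac{1}{n_2}\right)
\frac{\sum_1 (x-\bar{x}_{1i})^2 + \sum_2 (x-\bar{x}_{2i})^2}{n_1+n_2-2}}$$

With $s_0 = 0$ this is exactly the pooled-variance two-sample t statistic
(a property the tests exploit as an oracle). The fudge factor $s_0$
stabilizes low-scatter genes: candidates are the percentiles
$0, 5, \dots, 100$ of the $s_i$; genes are stratified into up to 100
equal-count windows by $s$; and the chosen $s_0$ minimizes the coefficient
of variation of the within-window median absolute deviations of $d(s_0)$,
ties going to the smallest percentile. Below 20 genes the procedure falls
back to $s_0 = \mathrm{median}(s)$.

The null is built from label permutations: all $\binom{n}{n_2}$ distinct
assignments when there are at most $B$ of them (the test is then exact and
seed-invariant), otherwise $B$ distinct assignments drawn uniformly without
replacement ($B = 100$ by default, the conventional SAM default). Sorting
each permutation's statistics and averaging by rank gives the expected
order statistics $\bar{d}_{(k)}$; an observed quantile plot against them is
the procedure's decision surface (`plot()` on a `sam_fit`).

For a threshold $\delta$: scanning upward from the smallest positive
$d_{(k)}$, the upper cutpoint is the first $d_{(k)}$ with
$d_{(k)} - \bar{d}_{(k)} > \delta$; the symmetric downward scan over
negative $d$ gives the lower cutpoint; genes at or beyond the cutpoints are
called. $\pi_0$ is estimated as
$\min\!\left(1, \#\{q_{25} < d_i < q_{75}\} / (0.5\,n)\right)$ with
quartiles over all permuted values, and the FDR of a call set is
$\pi_0 \cdot \mathrm{median}_b(V_b) / n_{called}$, where $V_b$ counts
permuted statistics beyond the cutpoints (0 when nothing is called).

### Automatic delta selection and the degenerate-call guard

`run_sam()` walks a 51-point grid from 0 to
$\max_k |d_{(k)} - \bar{d}_{(k)}|$ and returns the smallest $\delta$ whose
call set meets the target FDR. The median-based estimate alone makes this
search degenerate at the extreme tail: $\mathrm{median}_b(V_b)$ is an
integer, so for a lone extreme gene it is exactly 0 whenever more than half
of the permutations show no exceedance — an event with probability near one
half under a complete null. An unguarded search would therefore "discover"
one gene in roughly half of all null datasets, defeating the FDR the
procedure exists to control. The search consequently also requires the
conservative envelope estimate $\pi_0 \cdot \max_b(V_b) / n_{called}$ to
meet the target: a borderline single-gene call survives only if the
observed statistic is beyond anything seen in any permutation, while large
call sets are essentially unaffected. The reported `fdr_estimate` remains
the median-based quantity. With the guard in place, the package's null
calibration test (1,000 genes, 60 samples, 15 mutated, 200 replicates)
requires zero calls in at least 95% of replicates.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `target_fdr` | 0.2 | SAM's estimated proportion of falsely called genes per run |
| `n_permutations` | 100 | label permutations; exact enumeration when feasible |
| `s0_mode` | automatic | CV-minimizing fudge factor as above |
| `min_group_size` | 3 | variance needs >= 2 per class; 3 guards degenerate nulls; smaller groups are reported "untestable", never dropped silently |
| `min_affected` | 1 | "affects other genes" read as >= 1 significant other gene per cohort; exposed because the threshold is a judgment call |
| retained classes | non-synonymous set | Missense, Nonsense, Nonstop, Frame_Shift_Del/Ins, In_Frame_Del/Ins, Splice_Site, Translation_Start_Site; configurable |
| `min_mutations` (20/20) | 5 | below this the fractions are noise-dominated; reported "unclassified" |
| recurrence depth (20/20) | >= 2 missense at one protein position | "same locus" at protein-position resolution, genomic-start fallback |

No multiple-testing correction is applied *across* the per-gene SAM runs:
the FDR is controlled within each run, and the cross-cohort consistency
requirement is the guard against run-level false positives. This is stated
in every run report.

## What the synthetic generator emulates — and what it does not

`simulate_multi_cancer()` draws a shared truth (gene universe, shared
mutated pool, drivers, per-driver target sets with a recorded +/- effect
direction each, baseline means, known-gene labels, per-cohort mutated
samples) and then per-cohort expression and variant records. Expression is
Gaussian: baseline $\mu_g \sim N(0,1)$ plus $N(0, \sigma^2)$ noise, with a
signed shift of `effect_size_delta` x `noise_sd` for a driver's targets in
its mutated samples. Mutation records carry a configurable
variant-classification mix and per-gene missense hotspots.

Default study conditions: 3 cohorts x 150 samples, 500 genes, 100 shared
mutated genes of which 20 are drivers (mutation frequency 0.2, 30 targets
each, effect 1.5 SD) and 80 are passengers (frequency 0.05). Effect 1.5 SD
with ~30 mutated samples gives per-target pooled-t magnitudes around 6-7 —
strong but not degenerate, a regime where recovery is informative about the
pipeline rather than about luck. Design choices worth knowing:

* every pool gene is guaranteed at least one mutated sample per cohort
  (one forced draw when the binomial gives none), so the cross-cohort
  intersection equals the pool when passenger noise is off;
* drivers are drawn outside the known-gene labels — planted drivers emulate
  the *novel* genes the procedure is meant to find, and this keeps the
  known-gene-free re-analysis informative;
* one variant record per (gene, sample) event; record multiplicity can
  never change the binary matrix.

Deliberately **not** modeled: copy-number variation, tumor purity, batch
effects, and count-distributed (negative binomial) expression. The pipeline
consumes per-gene z-scores, so Gaussian generation exercises every code
path the analysis has; passing recovery tests therefore demonstrates the
machinery's correctness and calibration, not robustness to the technical
artifacts of real tumor data.

## Numerical conventions

* z-scores use the sample SD ($n-1$) over the analysis sample set only
  (after intersecting mutation and expression barcodes); zero-variance
  genes are untestable and dropped (recorded in an attribute and in logs).
* Category counts in fixtures use round-half-even, reproducible across
  platforms.
* Per-gene SAM runs derive their permutation seed from
  (run seed, cohort, gene) via a 31-bit string hash, so results are
  independent of gene iteration order.
* Ties: smallest percentile for $s_0$; first candidate for the
  expression-source control experiment (which reuses one permutation
  stream per control gene across candidates so identical tables tie
  exactly); inclusive comparisons at SAM cutpoints; TSG priority when both
  20/20 flags fire (truncating evidence dominates; both raw flags are
  always emitted).
* Known-gene-free eligibility counts retained (pathogenicity-filtered)
  mutations only; switch the filter off upstream to count all records.

## Problem sizes used by the test suite

The suite checks oracle equivalence on 100 random 50 x 20 instances, exact
permutation invariance at $\binom{8}{3} = 56$, null calibration on 200
replicates of 1,000 x 60, driver recovery on the default 3 x 500 x 150
scenario, subset logic on 100 random cohorts, and the Fisher-equivalence of
the enrichment test on 1,000 random triples — sizes chosen so each
statistical property is measured with enough replication to be stable while
the whole suite stays comfortably runnable on a laptop.

## Known limitations

* The candidate rule with `min_affected = 1` is permissive by construction;
  the cross-cohort requirement does the heavy lifting. With many cohorts or
  lax FDR targets, raise `min_affected`.
* SAM assumes exchangeable samples within classes; confounding between a
  passenger's mutated set and a co-occurring driver's mutated set can
  produce genuine-but-indirect associations. The known-gene-free
  re-analysis mitigates only the known-gene version of this.
* Gene identifier harmonization is uppercase-and-strip; cross-vocabulary
  alias mapping must be done upstream.
* The enrichment module is an over-representation test on unranked sets; it
  is not a ranked GSEA.
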