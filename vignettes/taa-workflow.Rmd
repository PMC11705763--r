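---
title: "Single-sample expression state inference and TAA screening: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-sample expression state inference and TAA screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taascreen)
options(taascreen.log_level = "warn")
```

# The problem

Cancer/testis-like tumor-associated antigens (TAAs) are gene products that
are silent in normal somatic tissues — at most expressed in testicular germ
cells — but aberrantly reactivated in tumors. Finding them from RNA-seq
requires a *binary* decision per gene and per sample: expressed or not.
Fixed TPM cutoffs ignore the measurement noise that dominates low abundances
and behave inconsistently across tissues, so `taascreen` instead infers the
expression state probabilistically, one sample at a time, and then aggregates
single-sample calls into tissue-level statistics.

# The mixture model and the posterior

Within one sample, the abundances of all genes are modeled as a two-component
lognormal mixture,

$$f(x) = \pi_{ne} f_{ne}(x) + \pi_e f_e(x),$$

where $f_{ne}$ and $f_e$ are the densities of the not-expressed and expressed
populations and $\pi_{ne} + \pi_e = 1$. On the $\log_2$ scale both components
are normal: $\log_2 X \mid ne \sim N(\mu_{ne}, \sigma_{ne}^2)$ and
$\log_2 X \mid e \sim N(\mu_e, \sigma_e^2)$, with the convention that the
component with the larger location is the expressed one. The probability that
a gene with abundance $x$ is expressed follows from Bayes' rule, with a
special case at zero:

$$P(\text{expressed} \mid X = x) =
\begin{cases}
0 & x = 0,\\[2pt]
\dfrac{\pi_e f_e(x)}{\pi_{ne} f_{ne}(x) + \pi_e f_e(x)} & x > 0.
\end{cases}$$

A gene is *called* expressed when the posterior is at least 0.5 (ties go to
expressed because the rule is an inclusive inequality). Because both
components share the lognormal Jacobian $1/(x\ln 2)$, the ratio is computed
from the two normal densities of $\log_2 x$ directly; the implementation and
its tests check this against an oracle that keeps the Jacobians explicit.

Two consequences of the piecewise definition are worth spelling out: no
pseudocount is ever added (zeros are handled exactly, not smoothed), and
zeros are excluded from parameter estimation — a zero carries no information
about the shape of either lognormal component.

# Parameter estimation

The five free parameters are fitted by expectation-maximization on the
$\log_2$ abundances of the strictly positive genes. EM is sensitive to
initialization, and this is where housekeeping genes earn their keep: they
are constitutively expressed, so their abundances sit squarely in the
expressed component. The initialization recipe is:

* $\mu_e^{(0)}, \sigma_e^{(0)}$: mean and SD of the $\log_2$ abundances of
  the detected housekeeping genes (at least 10 must be present with positive
  abundance);
* $\mu_{ne}^{(0)}, \sigma_{ne}^{(0)}$: mean and SD of the lowest quartile of
  the remaining positive genes;
* $\pi_e^{(0)}$: the fraction of positive genes above the midpoint of the two
  initial locations.

A bundled list of 50 widely used constitutive genes (HGNC symbols) ships with
the package (`system.file("extdata", "housekeeping_default.txt", package =
"taascreen")`); any study using other identifier schemes supplies its own.

EM stops when the relative change of the observed-data log likelihood falls
below `tol` ($10^{-8}$ by default) or after 1,000 iterations. The
log-likelihood trace is retained on the fit object, and its monotone
non-decrease is asserted in the tests — a cheap but sharp correctness check,
since any M-step error breaks it. If a component collapses (weight below
$10^{-3}$, a vanishing scale, or locations closer than $10^{-4}$), the fit
restarts up to 3 times from jittered initial values before raising a
non-convergence error that carries the collapse diagnostics. Fits require at
least 500 positive genes; below that the mixture is considered
unidentifiable and a degenerate-input error is raised rather than a fragile
estimate returned.

The EM implementation is the package's own (vectorized R; a 20,000-gene
sample fits in well under a second). An independent general-purpose mixture
fitter (`mclust`) is used in the test suite as a cross-check on simulated
data — never as the implementation.

# Tissue aggregation, dormant genes, and TAA prediction

For gene $i$ in tissue $j$ with $m$ samples, the non-expressed ratio is

$$\mathrm{Ratio}_{ij} = \frac{\sum_{n=1}^{m} (1 - \mathrm{state}_{in})}{m}.$$

A gene is **dormant** when this ratio is at least 0.9 in *every* normal
tissue except testis. Dormant genes split into two categories by testicular
expression: **testis-exclusive** when the testis expressed ratio is strictly
greater than 10%, **silent everywhere** otherwise. If the atlas has no
testis-labeled tissue, every tissue must pass the 0.9 rule and all dormant
genes are silent-everywhere (the testis ratio is recorded as missing rather
than invented).

A dormant gene becomes a **candidate TAA** in a cancer type when it is called
expressed in at least 5% of that cohort's tumor samples. All three boundary
conventions follow the published wording literally: $\ge 0.9$ and $\ge 0.05$
inclusive, $> 0.10$ strict. Each candidate carries the identifiers of the
tumors expressing it, which is what makes per-patient antigen assignment
possible, plus optional membership flags against membrane-protein, known-CTA
and testis-specific gene lists. Prediction runs per cancer type and results
are concatenated, never pooled. Tissues with very few samples (GTEx goes
down to 4) are aggregated as-is — no small-sample correction is applied
because none is part of the method — but `m` travels with every record and a
warning is logged below a configurable floor (default 10).

Genes present in a dormant list but absent from a tumor matrix are excluded
from prediction and reported in the log; silently treating them as
non-expressed would bias the candidate set. A gene missing a summary for a
required tissue is an error (`incomplete atlas`), not a silent pass.

# Comparator methods

* **Fixed threshold**: not expressed iff TPM strictly below the cutoff
  (the "TPM < 1" and "TPM < 2" conventions).
* **zFPKM-style z-score**: the active peak's location is the mode of a
  Gaussian kernel density over positive $\log_2$ abundances and its scale is
  the RMS deviation of the values above the mode (symmetric-peak
  assumption); a gene is expressed when $z \ge -3$. The bandwidth is the
  Sheather–Jones plug-in inflated threefold (`bw_adjust = 3`): under the
  symmetric-peak assumption oversmoothing leaves the mode unbiased while
  roughly halving its sampling error twice over, and at realistic peak
  separations (about 5 $\log_2$ units and more) the two expression modes are
  not merged. Zeros map to $z = -\infty$.
* **EnB**: an exponential component for inactive transcripts plus a negative
  binomial for active ones, fitted by EM. TPM values are continuous, so the
  negative-binomial mass is evaluated at the nearest integer while the
  exponential uses raw values — an explicit approximation inherited from
  applying a count distribution to normalized abundances. The calling
  threshold is the abundance at which the active-component posterior crosses
  $1 - p$ (default $p = 0.01$), solved on a continuous gamma-interpolated
  surrogate of the negative-binomial density.

# Benchmarking protocols

Two protocols mirror how such methods are compared against an
epigenomics-derived reference standard.

**Reference standard.** From a 15-state chromHMM-style segmentation, a gene
is *active* when (1) a state-1/2 promoter mark overlaps its exons, (2) a
state-3/4/5 transcription mark overlaps its transcription span, and (3) no
state-9..15 repressed mark overlaps it; *inactive* when no state-1..5 mark
overlaps it and at least one repressed mark does; *ambiguous* otherwise.
Ambiguous genes are excluded from every metric — the protocol defines only
two classes, and scoring ambiguity as error would conflate annotation
uncertainty with method error. The span that transcription marks must
overlap is not pinned by the rule's source, so it is a switch
(`transcription_span`), defaulting to the whole gene body.

**Per-sample metrics.** Precision and recall are computed per sample and per
class — non-expressed (reference inactive = positive) and expressed
(reference active = positive) — then summarized as mean and sample SD
(n−1 denominator) across samples. A sample with zero predicted positives in
a class has undefined precision there; it is excluded from the summary with
a logged count rather than scored as zero.

**Tissue-level PR curves.** The non-expressed ratio is swept over all its
distinct observed values; at each threshold, genes at or above it are
predicted non-expressed and scored against the inactive class. The curve is
anchored at recall 0 with the precision of the top-ranked prediction set and
integrated by trapezoid over recall. This integration rule is a documented
choice (the convention is not universal); what matters for comparisons is
that the same rule is applied to every method, and the tests pin it to an
exhaustive hand enumeration on a 6-gene example (AUPRC $= 65/72$). Precision
at the fixed operating threshold 0.9 — the dormancy cutoff — is reported
alongside the area.

# The simulator: what it emulates, and what it does not

`simulate_cohorts()` generates a multi-tissue normal atlas plus tumor
cohorts with fully known truth. Latent layout: housekeeping genes are
expressed everywhere; a `dormant_fraction` of genes is silent in all
non-testis tissues, with a `testis_exclusive_fraction` of those expressed in
testis; every other gene is expressed in a guaranteed non-testis "home"
tissue plus a random subset of other tissues, calibrated so the per-sample
expressed fraction matches `pi_e`. The home-tissue guarantee means chance
alone can never create an unplanted dormant gene, so recovery tests can
demand *exact* set equality. Tumor cohorts inherit an origin tissue's latent
states; planted TAA genes are reactivated in exactly
`max(1, round(prevalence * m))` seeded-randomly chosen samples, so the
configured prevalence is realized exactly and the recorded truth is the
oracle for ratio arithmetic downstream.

Abundances follow the assumed model: expressed entries are
$2^{N(\mu_e + \delta_t,\ \sigma_e)}$, silent entries are exactly zero with
probability `zero_inflation` (default 0.7) and otherwise
$2^{N(\mu_{ne} + \delta_t,\ \sigma_{ne})}$, where $\delta_t$ is a small
per-tissue location shift (SD 0.2 $\log_2$ units, disable with
`tissue_shift_sd = 0`) that keeps samples from being unrealistically
interchangeable. Zero inflation is an addition to the pure two-lognormal
model: real TPM matrices contain exact zeros and the posterior has a special
case there, so the generator must produce them. Default mixture parameters
($\pi_e = 0.55$, $\mu_{ne} = -1$, $\sigma_{ne} = 0.8$, $\mu_e = 4.5$,
$\sigma_e = 1.6$ on $\log_2$ TPM) give moderately overlapping components —
enough that state calling is non-trivial; end-to-end exact-recovery checks
use a well-separated variant ($\mu_e - \mu_{ne} \ge 5$, scales $\le 1$)
where perfect calling is attainable, because only there is exact set
equality a fair demand. The testis-exclusive share defaults to 0.32,
matching the reported split of dormant genes (about one third
testis-exclusive).

The simulator deliberately does **not** emulate: gene–gene correlation,
batch and library-size effects, isoform structure, or any relationship
between a gene's identity and its expression level. Passing tests on this
synthetic data therefore demonstrate correctness of the *inference and
aggregation machinery under the stated model*, not performance on real
GTEx/TCGA cohorts — reproducing the published cohort-level numbers would
require the original large downloads and is explicitly out of scope.

`simulate_chromatin_reference()` emits toy interval fixtures (a state-1 exon
mark plus state-4 body mark for expressed genes, a single state-13 segment
for silent ones, a contradictory state-1 + state-10 pair for noise-flipped
genes) so the reference-standard builder and the file readers can be
exercised round-trip through real BED4/BED12 files.

# Problem sizes and runtime choices

The test suite and the acceptance script size their simulations so the whole
battery stays comfortable on a single CPU: parameter-recovery checks use
20,000 genes (10 replicates), calling-accuracy checks 5,000, and the
end-to-end pipeline runs a 1,500-gene atlas over five tissues (46 normal
samples) plus a 40-sample tumor cohort at three seeds. These sizes were
chosen as the smallest at which the estimators' sampling error is clearly
inside the tolerances being asserted; recovery accuracy only improves at
GTEx-scale gene counts.

# Degenerate inputs and numerical choices

* All-identical positive abundances: unidentifiable, degenerate-input error.
* Fewer than 500 positive genes (or 10 detected housekeeping genes):
  degenerate-input / initialization error, never a silent fit.
* Posterior at exactly 0.5: expressed (inclusive cutoff).
* Log base: $\log_2$ throughout — mathematically immaterial for the
  posterior (any base cancels), chosen to match the z-score baseline's
  convention.
* Likelihood computations use the log-sum-exp form; posteriors are computed
  as $1/(1 + e^{\ell_{ne} - \ell_e})$, which is exact at both tails.
* EM restart jitter draws from the session RNG, so pipeline runs are
  reproducible from the single `seed` in the run configuration.

# Known limitations

* Single-sample inference assumes enough genes per sample to estimate a
  5-parameter mixture; targeted panels are out of scope.
* The method is as good as its housekeeping anchor: a list that does not
  match the matrix's identifier scheme fails loudly at initialization.
* The EnB comparator's rounding approximation degrades for samples whose
  active component sits at very low abundances.
* Tissue ratios weight every sample equally; no modeling of per-sample
  quality or purity.
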