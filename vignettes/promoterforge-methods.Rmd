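---
title: "Methods: mining stable promoters and engineering NOR-gate variants"
author: "promoterforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining stable promoters and engineering NOR-gate variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promoterforge)
```

# Overview

`promoterforge` implements a desk-scale screen for constitutive plant
promoters and their conversion into dCas9-repressible NOR-gate promoters,
together with the ratio-metric assay statistics used to validate such parts
in transient expression assays. The screen runs as a filtering cascade:

1. keep genes expressed (raw count > 0) in every RNA-seq sample;
2. normalize the count matrix by median-of-ratios size factors and rank
   genes by the coefficient of variation (CV = sd/mean) of normalized
   expression, retaining the lowest-CV fraction (3% by default);
3. extract each candidate's promoter+5'UTR and 3'UTR+terminator from the
   genome, truncating at neighbouring genes;
4. drop genes whose parts overlap another gene's annotation or contain
   BsaI/BbsI recognition sites (Golden Gate/MoClo domestication);
5. scan promoters with a PWM motif library and keep genes that can host two
   23-bp gRNA target sites, at least 67 bp apart, within 500 bp of the TSS,
   without interrupting any predicted motif.

Every stage is also exposed as a standalone function, and seeded
synthetic-data generators make the whole pipeline testable offline.

# Stability ranking

## Size factors

Per-sample scaling factors use the median-of-ratios estimator: the
pseudo-reference for gene $i$ is the geometric mean of its counts across
samples, computed over genes with no zero count, and
$s_j = \exp\{\mathrm{median}_i(\log K_{ij} - \log \bar K_i)\}$.
The median is taken on the log scale and exponentiated, matching the
published estimator in the DESeq2 family of tools; for reference sets of
even size this differs from an arithmetic ratio-scale median in the fifth
decimal, and the package pins the log-scale convention by test. Genes with
any zero count are excluded from the reference set but still receive
normalized values.

Size factors are only identified up to a common scale; the synthetic count
generator therefore records its true factors rescaled to geometric mean 1,
which is the scale on which the estimator converges. A consequence worth
noting: rescaling one sample's raw counts changes all normalized values by
one global constant (the pseudo-reference absorbs part of the rescaling),
so normalized values are only scale-invariant jointly — but per-gene CVs
and the resulting ranking are exactly invariant, and that is what the
screen consumes.

## CV and retention

The CV uses the sample (n−1) standard deviation divided by the arithmetic
mean of normalized counts; whether the original analysis used n or n−1 is
not stated anywhere we could pin it, so the package documents and tests the
n−1 convention. Retention keeps $n = \lceil fN \rceil$ genes: with
$N = 10{,}096$ expressed genes and $f = 0.03$ this yields 303 genes, which
fixes the ceiling convention. Ties at the cutoff break lexicographically by
gene id so reruns are deterministic.

Stress-condition stability is reported as an annotation only: the stress
samples plus one designated reference sample are renormalized as a
standalone submatrix and the CV is computed across the stress samples. The
reference construction (single sample vs a replicate pool) is ambiguous in
the source protocol; the package takes a single reference sample id and
leaves pooling to the caller, since `stress_cv()` accepts any column
subset.

# Part extraction

Gene models are read from GFF3 (1-based inclusive coordinates, as the
format specifies) via `rtracklayer`; all internal coordinates stay 1-based
inclusive — the native convention of the R/Bioconductor interval stack this
package is built on — and BED exports convert to 0-based half-open at the
boundary. TSS/TES come from explicit UTR features when present and fall
back to the gene-span ends with a warning otherwise.

The promoter part runs from min(2,000 bp upstream of the TSS, the nearest
annotated gene boundary on either strand) down to the base before the start
codon, so the clone carries the promoter plus the entire 5'UTR; the
terminator part runs from the base after the stop codon to min(250 bp past
the TES, nearest neighbour). "Room" is counted as bases strictly between
the TSS/TES and the neighbouring span; an overlapping neighbour leaves zero
room, and a zero-length promoter segment flags the part and excludes the
gene rather than aborting the run. When the 5'UTR itself is long the part
can exceed 2,000 bp — the cap applies to the upstream extent only, which is
how we resolve the tension between anchoring at the TSS and cloning from
before the start codon.

Restriction screening scans both strands for BsaI (`GGTCTC`) and BbsI
(`GAAGAC`) recognition sequences; both enzymes are non-palindromic, so the
reverse complements are searched explicitly. Recognition sequences come
from standard enzyme catalogues and live in `moclo_enzymes()` so other
type IIS enzymes can be added. The overlap and domestication filters
commute (both are per-gene predicates), which the tests assert on fixtures.

# Motif scanning

The original screen used a web service for binding-site prediction; this
package substitutes standard log-odds PWM scanning as a functional
stand-in, so motif calls will differ from any specific service's output.
Probability matrices are read from MEME minimal format. Log odds are
$\log_2\big(((p + \epsilon\, b)/(1+\epsilon))/b\big)$ with pseudocount
weight $\epsilon = 10^{-3}$ and uniform background unless the file provides
one.

Score thresholds derive from a p-value (default $10^{-4}$) under the exact
null distribution of window scores, computed by dynamic programming over
scores discretized to $10^{-3}$ log2 units; scanning uses the same
discretized matrix so threshold and scan are mutually consistent, and a
seeded shuffled-sequence empirical null is available as an alternative
(`pwm_score_threshold(method = "empirical")`). Windows containing `N`
never match. Hits are computed over the whole promoter part; the 500-bp
TSS window constraint is enforced downstream at placement, not at scan
time.

# gRNA site placement

A placement is an ordered pair of 23-bp windows (20-bp protospacer + NGG
PAM, the SpCas9 convention), each wholly inside a motif-free interval of
the 500-bp window immediately upstream of the TSS, separated edge-to-edge
by at least 67 bp. Separation is measured between window1's end and
window2's start; with these defaults the smallest feasible motif-free span
is $2 \times 23 + 67 = 113$ bp, which the tests use to pin the convention
(the source protocol says only "at least 67 bp apart"). Containment — not
midpoint — decides whether a site is "within 500 bp of the TSS".

The default placement maximizes the smaller of the two windows' distances
to the nearest forbidden-interval edge (ties broken 5'-most): deterministic
and explainable, and it keeps the sites away from predicted motifs.
Candidate site sequences are screened for genome orthogonality by exact
substring search over both strands; no mismatch tolerance is applied, since
the intended use mirrors literature-validated guides. Modified promoters
overwrite only the two windows, a property asserted bytewise. Note that
sequence replacement can create *new* motif matches at window junctions —
re-scanning modified promoters is supported and recommended.

# Assay statistics

Transient-assay normalization is
$(\mathrm{YFP} - \mathrm{median\ neg\ YFP\ on\ the\ leaf}) / \mathrm{mTURQ}$
per datapoint, with the negative control an injection carrying only the
internal-control fluorophore. For visualisation and testing, the three
biological replicates whose median signals sit closest to the median of
replicate medians are retained.

Many-to-one comparisons against the negative control use Dunnett's
procedure: pooled-variance t statistics referred to the equicorrelated
multivariate-t distribution, with two-sided adjusted p-values from
`mvtnorm::pmvt` (deterministically seeded internally; the user's RNG state
is preserved). The analysis unit is the per-replicate (leaf) median, not
the 24 technical disc reads — those are pseudo-replicates, and using them
would overstate the degrees of freedom; the choice is configurable simply
by passing datapoint-level signals instead. With one treatment group the
procedure reduces exactly to the pooled two-sample t test, and
`multcomp::glht` serves as an independent cross-check in the test suite.

NOR-gate analysis divides each datapoint's YFP/mTURQ ratio by the median
ratio of the unrepressed (0,0) injection on the same leaf, so leaf-level
multiplicative effects cancel exactly and each leaf's control centres on 1.
Variant (0,0) injections (one vs two non-matching guides) are treated as a
single pooled class. Fold repression is the (0,0) median divided by the
(1,1) median of normalized signal. All-pairs comparisons within a gate use
one-way ANOVA, Tukey HSD at 0.05, and a compact letter display built by
insert-and-absorb, with letters ordered down the group means; the letter
cover is validated against the significance matrix (groups share a letter
iff not significantly different). Degenerate within-group variance is an
error unless all observations are identical, in which case all groups
trivially share one letter.

# Synthetic data: what it emulates, and what it does not

The generators are pure functions of their arguments and a seed;
regeneration is byte-identical, which the tests assert on the written
FASTA/GFF3/TSV/MEME/CSV files.

**Counts** follow $K_{ij} \sim \mathrm{NB}(\mu_i s_j, \alpha_i)$ with true
size factors log-uniform in [0.5, 2] (rescaled to geometric mean 1), means
log-uniform in [50, 2000], and background dispersions log-uniform in
[0.1, 2] — typical cross-tissue CVs of roughly 0.3–1.5, so that, as in real
tissue panels, only a few percent of background genes approach the
stable-gene CV range. Planted stable genes get constant means and
dispersion 0.005 (at most a tenth of the smallest background dispersion).
Defaults are 1,000 genes × 10 samples; the original tissue panel had ~160
samples, which tightens CV estimates considerably, so the 10-sample default
is the harder setting for separating planted genes. The size-factor
recovery property is evaluated at 2,000 genes with moderate dispersions
(0.05–0.5), comfortably inside its stated "at least 500 all-positive
genes" condition. The generator does not model tissue-specific expression
programs, transcript-length effects, or count correlation between samples.

**Genomes** are one chromosome of alternating intergenic spacers and gene
bodies with explicit UTR/CDS features, controllable spacing (to exercise
both the 2 kb and 250 bp truncations and overlap cases), strand mixes, and
planted restriction sites and motif consensus matches at recorded
positions. Backbone sequence is scrubbed of type IIS sites so planted
sites are the only ones present. Base composition is uniform — no isochore
structure, repeats, or realistic promoter elements.

**Plate tables** emulate the 2 discs × 12 reads = 24 datapoints per
injection per leaf scheme with multiplicative lognormal leaf gains and
per-datapoint noise plus an additive autofluorescence floor, so both the
control subtraction and the ratio-metric division are exercised. Defaults:
3 leaves, leaf gain log-SD 0.3, noise log-SD 0.15, autofluorescence 50 on
an mTURQ level of 1000.

Passing tests on these fixtures demonstrates the *rules* (truncation,
screening, placement, normalization arithmetic, error control), not
biological performance on real genomes or assay data.

# Numerical choices and limitations

* Score discretization at $10^{-3}$ log2 units bounds threshold error at
  ~0.02 log2 units for a 20-column PWM; scanning and p-values share the
  grid, so no hit can straddle the threshold inconsistently.
* `pmvt` tail probabilities are quasi-Monte-Carlo with tolerance
  $10^{-5}$, seeded internally for reproducibility.
* Placement enumeration counts pairs by sorted cumulative counting over
  allowed window starts; the exhaustive double loop is the test oracle.
* Problem sizes in the test and acceptance runs: count matrices up to
  11,000 × 10; toy genomes of ~30 kb; 2,000-replicate null simulations for
  the Dunnett family-wise error rate; 200 generator seeds for
  fold-repression unbiasedness.
* The headline biological results of the original screen (candidate counts
  against a real genome and annotation, in-planta expression, measured
  repression strengths) depend on external data and wet-lab assays and are
  out of scope by design; the package reproduces the decision rules and
  their statistics.
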