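---
title: "Methods: the alternative splicing ratio and its comparative toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the alternative splicing ratio and its comparative toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceratio)
```

## The model

Index the genome by nucleotide position and let $f(i,j)$ be the number of
protein-coding isoforms (CDS sets) containing both positions $i$ and $j$.
The transcription matrix $M_{ij} = f(i,j)$ is symmetric; its binarization
$A_{ij} = \mathbf{1}[M_{ij} > 0]$ has, on the diagonal, exactly the coding
DNA — the projection of every CDS onto the genome. The alternative
splicing ratio is the trace ratio

$$\rho = \frac{\operatorname{tr}(M)}{\operatorname{tr}(A)},$$

the average number of isoforms each coding nucleotide participates in.
Two identities make $\rho$ computable genome-wide without ever forming
$M$ (which is quadratic in genome length):

* $\operatorname{tr}(M) = \sum_{\text{isoforms}} (\text{CDS length})$,
  because each isoform contributes 1 to $M_{ii}$ for every position it
  contains;
* $\operatorname{tr}(A)$ is the length of the genomic union of all CDS
  intervals.

`asr_genomewide()` implements the interval form; `build_transcription_
matrix()` materializes $M$ for small inputs only and exists so the two
routes can be checked against each other exactly. Both numerator and
denominator are integers, carried as attributes on the result, so the
ratio is an exact rational reduced only at the final division; the test
suite compares the two routes on those integers, not on floats.

$\rho \ge 1$ always, with equality exactly when no coding nucleotide is
annotated in two isoforms — the single-isoform limit typical of
prokaryotes and most unicellular eukaryotes, whose annotations rarely
carry alternative isoforms.

## Annotation input and inclusion rules

`parse_gff3()` reads GFF3 (NCBI RefSeq dialect) and rebuilds the
gene→mRNA→CDS hierarchy from `ID`/`Parent` links. Feature records are
parsed by `rtracklayer`; `##sequence-region` pragmas are scanned from the
header directly because the importer does not surface them. The filters
mirror a conservative reading of RefSeq practice:

* **pseudogenes** — `pseudogene`-typed records, or genes with
  `pseudo=true` — are dropped with their children;
* **duplicated genes** — more than one gene record sharing an identity
  key (`Dbxref` `GeneID:`, falling back to the `gene` symbol, then `ID`)
  — are all dropped by default (`keep-first` is available). The upstream
  definition of "duplicated" is not published; dropping every copy is the
  choice least likely to double-count coding DNA;
* **orphan CDSs** whose parent chain cannot be traced CDS→mRNA→gene are
  dropped individually; a gene survives if another isoform is valid;
* genes left with no CDS-bearing mRNA are dropped (`no_cds`);
* transcripts whose CDSs sit on multiple sequences cannot be projected
  and are dropped (`multi_seqid`).

Every exclusion is counted by reason, and retained genes plus gene-level
exclusions always add up to the number of gene-like records parsed. Only
`mRNA`-typed transcripts contribute isoforms by default, since the metric
counts protein isoforms; the allowlist is configurable.

Within one isoform, overlapping and book-ended CDS segments are merged
before any length is taken, so a nucleotide never counts twice toward one
isoform. Merging is deliberately *not* applied across isoforms — sharing
across isoforms is the signal.

Three conventions were genuinely open and are fixed as follows. Genome
size is taken per sequence with precedence `##sequence-region` pragma >
`region` feature span > maximum feature end (the last with a warning,
being only a lower bound). Gene content is the union, not the sum, of
gene spans, so overlapping genes are not double-counted. Strand is
ignored when projecting CDSs onto the genome — the projection is
positional — but `per_strand = TRUE` computes unions per (sequence,
strand) for genomes where antisense overlap matters; overlap of that kind
is rare enough that the default is the simpler positional reading.

## Support normalization (ASR*)

Annotated isoform counts reflect the evidence behind the annotation:
genomes annotated mostly from computational models under-report splicing,
and the fraction of fully supported CDSs is the dominant predictor of
that bias. `fit_support_model()` fits a polynomial least-squares trend
$\hat f(c)$ of ASR on the support fraction $c \in [0,1]$ across species;
`normalize_asr()` applies

$$\mathrm{ASR}^* = \mathrm{ASR} - \hat f(c) + \hat f(c_{\mathrm{ref}}),$$

with $c_{\mathrm{ref}}$ defaulting to the cross-species mean. The scheme
guarantees identity at the reference and preserves ordering and spacing
among species of equal support; ASR* is a standardized estimate for
comparison, not an absolute measurement. The polynomial degree defaults
to 2 — flexible enough to bend, too stiff to chase outliers in cohorts
of tens to hundreds of species — with optional minimum-AIC selection
over degrees 1–4 and an additive multivariate mode over all three support
fractions (fully supported, known, model-derived). A fit needs at least
degree + 1 species; a saturated fit is legitimate (it interpolates), and
anything smaller is unidentifiable. Support fractions arrive as a TSV
side table rather than being scraped from annotation reports, whose
format is out of scope.

## Group comparisons

`perm_test()` shuffles group labels and reports the proportion of
permuted statistics (mean or median difference) at least as large as the
observed one — by default in absolute value, since cross-taxa
comparisons are direction-agnostic; a one-sided mode exists. The
empirical p is the plain proportion $k/n$; `plus_one = TRUE` gives
$(k+1)/(n+1)$ when a guaranteed-positive estimate is preferred. For
small samples `exhaustive = TRUE` enumerates all label assignments and
returns the exact permutation p. `compare_groups()` runs every pair ×
variable × statistic and applies Bonferroni over the whole family.
Welch's t and Welch's ANOVA (`stats::t.test`, `stats::oneway.test`)
cover the parametric route; `cv()` and `cv_ratio()` (sample sd over
mean, and the ratio of two CVs) quantify relative variability, the
scale-free comparison used across taxonomic groups. `summary_table()`
reports per-group mean, 5th–95th percentile range (linear interpolation
between order statistics — Table-style ranges depend on the rule, so it
is fixed and documented) and sample sd; singleton groups report sd 0
with a flag.

## PGLS with Pagel's lambda

`pgls_fit()` fits $y = \alpha + \beta x + \varepsilon$ with
$\operatorname{Cov}(\varepsilon) = \sigma^2 C(\lambda)$, where $C$ is the
Brownian covariance implied by the tree (shared root-to-MRCA branch
length) and $\lambda$ multiplies the off-diagonal. For fixed $\lambda$
the GLS estimates are closed-form via a Cholesky whitening; $\lambda$ is
the only free parameter and is estimated by maximizing the profile
log-likelihood over $[0,1]$ with `stats::optimize` (tolerance $10^{-6}$)
plus explicit endpoint evaluation, so boundary maxima at 0 or 1 are
returned exactly. ML (not REML) is used: a single $\lambda$ per fit is
reported and the difference is immaterial at the $n$ involved. Inference
on $\beta$ uses the t-statistic with $n - 2$ degrees of freedom and the
unbiased residual variance; $R^2_{\mathrm{adj}}$ is computed in the GLS
metric against the intercept-only model at the same $\lambda$. Species
missing from the tree are dropped with a count; non-ultrametric trees
are accepted unchanged. Rescaling all branch lengths leaves $\beta$, p
and $\hat\lambda$ invariant (only $\sigma^2$ moves), and on ultrametric
trees $\lambda = 0$ reduces exactly to OLS, since $C(0)$ is then
proportional to the identity.

## What the generators emulate — and what they do not

`make_annotation()` builds non-overlapping genes on one scaffold, each
with an exon skeleton and isoforms drawn as random exon subsets (default
keep probability 0.7, 1–4 isoforms and 2–6 exons per gene, exons 30–150
nt, introns 20–120 nt, intergenic gaps 50–300 nt — magnitudes chosen to
resemble compact eukaryotic annotations while keeping fixtures small).
The true ASR, gene content and coding content are accumulated during
construction, not by running the pipeline, so generator and pipeline are
independent implementations whose exact agreement is a meaningful test.
Defect injection switches add pseudogenes, orphan CDSs or duplicated
genes that the filters must remove without touching the truth.

The generator does not emulate: overlapping or nested genes, trans- or
antisense arrangements, UTRs, non-`mRNA` transcript types, or any
sequence content. Passing tests therefore demonstrate the arithmetic and
the filter logic, not robustness to every annotation pathology in
RefSeq; the paired fixtures in the unit tests cover the pathological
cases individually.

`simulate_group_table()` draws Gaussian groups at stated means and sds
for calibrating the permutation machinery. `simulate_tree_traits()`
generates a pure-birth (Yule) tree, a Brownian predictor, and a response
with residual covariance $\sigma^2 C(\lambda)$ — ground truth
($\beta, \lambda, \sigma$) known by construction.

## Numerical choices and problem sizes

All randomness is seed-controlled; `perm_test()` restores the caller's
RNG state. The explicit transcription matrix refuses inputs beyond
`max_positions` (default 2000) rather than silently allocating $L^2$.
The validation suite uses sizes chosen to exercise each property
decisively while keeping a full run in minutes: exact oracle equivalence
on 100 random annotations of ≤ 200 gene positions; permutation-test
type-I calibration with 500 null replicates of $n = 30$ per group at
2,000 permutations (rejection rate checked against the binomial band
[0.032, 0.071] at $\alpha = 0.05$); permutation-count stability across
20 seeds at 10,000 vs 20,000 permutations (within 3 Monte Carlo SEs);
PGLS slope recovery on 100 replicates of 64-tip trees with
$\beta = 0.5, \lambda = 1$; and bias removal at $n = 200$ species
(|correlation of ASR* with support| < 0.1).

## Limitations

The metric counts *annotated* isoforms: it inherits every bias of the
annotation pipeline, which is precisely why ASR* exists — and ASR* can
only correct the trend that support fractions capture. Empirical results
on real genome corpora (per-clade means, PGLS tables) require the
corresponding RefSeq downloads and are outside what this package's tests
establish; what they do establish is that the implementation computes
the defined quantities exactly and that the statistical machinery is
calibrated and recovers known parameters under its stated models.
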