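# spliceratio

Genome-scale quantification of alternative splicing from annotation files.

Comparing splicing activity across hundreds of species is hard because most
splicing metrics are defined per gene or per event and depend on expression
data. `spliceratio` implements a genome-level summary, the **alternative
splicing ratio (ASR)**, computable from a standard GFF3 annotation alone,
for anyone doing comparative genomics of gene architecture: how strongly a
genome reuses its coding DNA across mRNA isoforms.

## The metric

Let `f(i, j)` be the number of CDSs (protein-coding isoforms) that contain
both genomic nucleotides `i` and `j`. The symmetric *transcription matrix*
`M` with `M_ij = f(i, j)` encodes nucleotide co-occurrence across isoforms,
and its binarization `A` (`A_ij = 1` iff `M_ij > 0`) marks the coding DNA:
the diagonal of `A` is the projection of all CDSs onto the genome. The ASR
is the trace ratio

```
rho = tr(M) / tr(A)
```

i.e. the total number of annotated coding nucleotides summed over every
isoform, divided by the number of genomic positions covered by at least one
CDS. `rho = 1` means no coding nucleotide is reused (one isoform per gene);
`rho = 2` means the average coding position appears in two isoforms. The
production implementation never materializes `M`: the numerator is the
summed CDS length over isoforms and the denominator an interval-union
length, which equals the trace ratio exactly. The explicit matrix exists as
a small-instance oracle for testing.

Around the core metric the package provides:

- **`parse_gff3()` / `apply_filters()`** — NCBI RefSeq-dialect GFF3 input,
  gene→mRNA→CDS hierarchy reconstruction, and the inclusion filters
  (pseudogenes, duplicated genes, orphan CDSs excluded, with counts).
- **`genome_profile()`** — genome size, gene content, coding content, their
  percentages, and the ASR, one row per species.
- **`fit_support_model()` / `normalize_asr()`** — ASR\*, a polynomial
  regression correction for annotation-support bias (genomes annotated
  mostly from computational models under-report splicing).
- **`perm_test()`, `welch_pairwise()`, `welch_anova()`, `cv()`,
  `cv_ratio()`, `summary_table()`, `compare_groups()`** — cross-taxa
  comparisons: Monte Carlo permutation tests on means and medians with
  Bonferroni correction, Welch tests, and coefficient-of-variation ratios.
- **`pgls_fit()`** — phylogenetic generalized least squares with Pagel's
  lambda estimated by maximum likelihood on [0, 1], plus Newick parsing and
  pruning (`parse_newick()`, `prune_to()`).
- **`make_annotation()`, `simulate_group_table()`,
  `simulate_tree_traits()`** — synthetic-data generators whose ground truth
  is tracked at construction time, so every stage of the pipeline can be
  validated against an independent oracle.

## Worked example

The packaged single-gene fixture has one 33-nt scaffold and three isoforms
whose CDS segments are `[1,9]+[27,33]` (16 nt), `[5,13]` (9 nt) and
`[1,13]+[22,27]` (19 nt); their genomic union covers 25 positions:

```r
library(spliceratio)

ann <- parse_gff3(text = make_fig1_fixture())
ann
#> <annotation_set> 1 genes, 3 isoforms, 5 CDS segments
#>   sequences: 1  (filtered)

asr_genomewide(ann)
#> [1] 1.76
#> attr(,"numerator")
#> [1] 44
#> attr(,"denominator")
#> [1] 25

genome_profile(ann, species_id = "fig1")
#>   species_id genome_size gene_content coding_content gene_over_genome
#> 1       fig1          33           33             25              100
#>   coding_over_gene coding_over_genome n_genes n_isoforms  asr
#> 1         75.75758           75.75758       1          3 1.76
```

The ASR is (16 + 9 + 19) / 25 = 1.76: on average each coding nucleotide is
used by 1.76 isoforms. `coding_over_gene` says 75.8% of the gene's span is
coding; on real genomes these composition percentages are the covariates
the comparative analyses regress ASR against.

A command-line wrapper with subcommands `compute`, `normalize`, `compare`,
`pgls` and `synth` is installed at `inst/cli/spliceratio`:

```sh
Rscript inst/cli/spliceratio compute genome.gff3 --out profile.tsv
```

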