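#' The worked single-gene example annotation
#'
#' A 33-nucleotide scaffold carrying one gene with three mRNA isoforms whose
#' CDS segments are \[1,9\]+\[27,33\] (16 nt), \[5,13\] (9 nt), and
#' \[1,13\]+\[22,27\] (19 nt). The coding projection onto the genome covers
#' 25 positions, so the ASR is (16 + 9 + 19) / 25 = 1.76.
#'
#' @return GFF3 text (character scalar).
#' @examples
#' asr_genomewide(parse_gff3(text = make_fig1_fixture()))
#' @export
make_fig1_fixture <- function() {
  paste(c(
    "##gff-version 3",
    "##sequence-region chr1 1 33",
    "chr1\tsynthetic\tgene\t1\t33\t.\t+\t.\tID=gene-1;Dbxref=GeneID:1;gene=G1",
    "chr1\tsynthetic\tmRNA\t1\t33\t.\t+\t.\tID=rna-1;Parent=gene-1",
    "chr1\tsynthetic\tCDS\t1\t9\t.\t+\t0\tID=cds-1;Parent=rna-1",
    "chr1\tsynthetic\tCDS\t27\t33\t.\t+\t0\tID=cds-1;Parent=rna-1",
    "chr1\tsynthetic\tmRNA\t1\t33\t.\t+\t.\tID=rna-2;Parent=gene-1",
    "chr1\tsynthetic\tCDS\t5\t13\t.\t+\t0\tID=cds-2;Parent=rna-2",
    "chr1\tsynthetic\tmRNA\t1\t33\t.\t+\t.\tID=rna-3;Parent=gene-1",
    "chr1\tsynthetic\tCDS\t1\t13\t.\t+\t0\tID=cds-3;Parent=rna-3",
    "chr1\tsynthetic\tCDS\t22\t27\t.\t+\t0\tID=cds-3;Parent=rna-3",
    ""), collapse = "\n")
}

#' Specification for a synthetic annotation
#'
#' Bundles the generator's tunables. Ranges are inclusive integer bounds
#' sampled uniformly per gene/isoform/exon.
#'
#' @param n_genes number of genes to place on one scaffold.
#' @param isoforms_per_gene integer range `c(min, max)`.
#' @param exons_per_gene integer range for the gene's exon skeleton.
#' @param exon_length,intron_length,intergenic integer ranges (nt).
#' @param exon_keep_prob probability each exon enters a given isoform
#'   (at least one always does).
#' @param share_all_isoforms every isoform uses the full exon skeleton, so a
#'   gene with k isoforms has per-gene ASR exactly k.
#' @param inject character subset of `c("pseudogene", "orphan_cds",
#'   "duplicate_gene")`: append defective records (excluded by the filters,
#'   and absent from the ground truth) for filter testing.
#' @param seed RNG seed; generation is deterministic given the spec.
#' @return object of class `annotation_spec` (a validated list).
#' @export
annotation_spec <- function(n_genes = 10, isoforms_per_gene = c(1, 4),
                            exons_per_gene = c(2, 6),
                            exon_length = c(30, 150),
                            intron_length = c(20, 120),
                            intergenic = c(50, 300),
                            exon_keep_prob = 0.7,
                            share_all_isoforms = FALSE,
                            inject = character(), seed = 1) {
  rng <- function(r) if (length(r) == 1) c(r, r) else r
  spec <- list(n_genes = n_genes, isoforms_per_gene = rng(isoforms_per_gene),
               exons_per_gene = rng(exons_per_gene),
               exon_length = rng(exon_length),
               intron_length = rng(intron_length),
               intergenic = rng(intergenic),
               exon_keep_prob = exon_keep_prob,
               share_all_isoforms = share_all_isoforms,
               inject = inject, seed = seed)
  with(spec, stopifnot(
    n_genes >= 1, all(isoforms_per_gene >= 1), all(exons_per_gene >= 1),
    all(exon_length >= 1), all(intron_length >= 1), all(intergenic >= 1),
    exon_keep_prob > 0, exon_keep_prob <= 1,
    all(inject %in% c("pseudogene", "orphan_cds", "duplicate_gene"))))
  structure(spec, class = "annotation_spec")
}

.runif_int <- function(n, r) if (r[1] == r[2]) rep(r[1], n) else
  sample(seq(r[1], r[2]), n, replace = TRUE)

#' Generate a synthetic GFF3 annotation with known ground truth
#'
#' Places `n_genes` non-overlapping genes along one scaffold. Each gene gets
#' an exon skeleton (exons separated by introns); each mRNA isoform selects
#' a random non-empty subset of the skeleton as its CDS segments. The true
#' ASR, gene content, coding content and genome size are tracked during
#' construction — by bookkeeping, not by running the parsing/ASR pipeline —
#' so the returned `truth` is an independent oracle for the pipeline.
#'
#' @param spec an [annotation_spec()].
#' @return list with `gff3` (text), `truth` (list: `asr`, `numerator`,
#'   `denominator`, `genome_size`, `gene_content`, `coding_content`,
#'   `n_genes`, `n_isoforms`), and `spec`.
#' @export
make_annotation <- function(spec = annotation_spec()) {
  stopifnot(inherits(spec, "annotation_spec"))
  set.seed(spec$seed)
  lines <- character(0)
  cursor <- 0
  numerator <- 0; denominator <- 0; gene_content <- 0; n_iso_total <- 0L

  for (g in seq_len(spec$n_genes)) {
    cursor <- cursor + .runif_int(1, spec$intergenic)
    k <- .runif_int(1, spec$exons_per_gene)
    ex_len <- .runif_int(k, spec$exon_length)
    in_len <- if (k > 1) .runif_int(k - 1, spec$intron_length) else integer(0)
    ex_start <- cursor + 1 + c(0, cumsum(ex_len[-k] + in_len))
    ex_end <- ex_start + ex_len - 1
    gene_start <- ex_start[1]; gene_end <- ex_end[k]
    cursor <- gene_end

    n_iso <- .runif_int(1, spec$isoforms_per_gene)
    sel <- vector("list", n_iso)
    for (i in seq_len(n_iso)) {
      s <- if (spec$share_all_isoforms) rep(TRUE, k) else
        stats::runif(k) < spec$exon_keep_prob
      if (!any(s)) s[sample.int(k, 1)] <- TRUE
      sel[[i]] <- s
      numerator <- numerator + sum(ex_len[s])
    }
    used <- Reduce(`|`, sel)
    denominator <- denominator + sum(ex_len[used])
    gene_content <- gene_content + (gene_end - gene_start + 1)
    n_iso_total <- n_iso_total + n_iso

    gid <- sprintf("gene-g%d", g)
    lines <- c(lines, sprintf(
      "seq1\tsynthetic\tgene\t%d\t%d\t.\t+\t.\tID=%s;Dbxref=GeneID:%d;gene=g%d",
      gene_start, gene_end, gid, g, g))
    for (i in seq_len(n_iso)) {
      rid <- sprintf("rna-g%d.t%d", g, i)
      s <- sel[[i]]
      lines <- c(lines, sprintf(
        "seq1\tsynthetic\tmRNA\t%d\t%d\t.\t+\t.\tID=%s;Parent=%s",
        min(ex_start[s]), max(ex_end[s]), rid, gid),
        sprintf("seq1\tsynthetic\tCDS\t%d\t%d\t.\t+\t0\tID=cds-%s;Parent=%s",
                ex_start[s], ex_end[s], rid, rid))
    }
  }
  genome_size <- cursor + .runif_int(1, spec$intergenic)
  lines <- c(lines, .injected_records(spec$inject, genome_size))
  if (length(spec$inject)) genome_size <- genome_size + 1000

  gff3 <- paste(c("##gff-version 3",
                  sprintf("##sequence-region seq1 1 %d", genome_size),
                  lines, ""), collapse = "\n")
  list(gff3 = gff3,
       truth = list(asr = numerator / denominator, numerator = numerator,
                    denominator = denominator, genome_size = genome_size,
                    gene_content = gene_content,
                    coding_content = denominator,
                    n_genes = spec$n_genes, n_isoforms = n_iso_total),
       spec = spec)
}

# defective records appended past the genes; all are dropped by the filters
.injected_records <- function(inject, offset) {
  out <- character(0)
  base <- offset + 100
  if ("pseudogene" %in% inject)
    out <- c(out, sprintf(
      "seq1\tsynthetic\tpseudogene\t%d\t%d\t.\t+\t.\tID=gene-ps1;gene=ps1",
      base, base + 99), sprintf(
      "seq1\tsynthetic\tmRNA\t%d\t%d\t.\t+\t.\tID=rna-ps1;Parent=gene-ps1",
      base, base + 99), sprintf(
      "seq1\tsynthetic\tCDS\t%d\t%d\t.\t+\t0\tID=cds-ps1;Parent=rna-ps1",
      base, base + 49))
  if ("orphan_cds" %in% inject)
    out <- c(out, sprintf(
      "seq1\tsynthetic\tCDS\t%d\t%d\t.\t+\t0\tID=cds-orphan;Parent=rna-missing",
      base + 200, base + 259))
  if ("duplicate_gene" %in% inject)
    out <- c(out, sprintf(
      "seq1\tsynthetic\tgene\t%d\t%d\t.\t+\t.\tID=gene-dupA;gene=dup1",
      base + 300, base + 399), sprintf(
      "seq1\tsynthetic\tmRNA\t%d\t%d\t.\t+\t.\tID=rna-dupA;Parent=gene-dupA",
      base + 300, base + 399), sprintf(
      "seq1\tsynthetic\tCDS\t%d\t%d\t.\t+\t0\tID=cds-dupA;Parent=rna-dupA",
      base + 300, base + 359), sprintf(
      "seq1\tsynthetic\tgene\t%d\t%d\t.\t+\t.\tID=gene-dupB;gene=dup1",
      base + 500, base + 599), sprintf(
      "seq1\tsynthetic\tmRNA\t%d\t%d\t.\t+\t.\tID=rna-dupB;Parent=gene-dupB",
      base + 500, base + 599), sprintf(
      "seq1\tsynthetic\tCDS\t%d\t%d\t.\t+\t0\tID=cds-dupB;Parent=rna-dupB",
      base + 500, base + 559))
  out
}

#' Simulate a grouped species table with known group effects
#'
#' Draws Gaussian per-species values for each group at stated means and
#' standard deviations, for calibrating and power-testing the group
#' comparison machinery.
#'
#' @param groups named list: `label = list(n, mean, sd)` (or a data.frame
#'   with columns `group`, `n`, `mean`, `sd`).
#' @param seed RNG seed.
#' @param value name of the value column (default `"asr"`).
#' @return data.frame with `species_id`, `group`, and the value column.
#' @export
simulate_group_table <- function(groups, seed = 1, value = "asr") {
  if (is.data.frame(groups))
    groups <- stats::setNames(
      lapply(seq_len(nrow(groups)), function(i)
        list(n = groups$n[i], mean = groups$mean[i], sd = groups$sd[i])),
      groups$group)
  set.seed(seed)
  rows <- lapply(names(groups), function(lab) {
    gp <- groups[[lab]]
    stopifnot(gp$n >= 2, gp$sd >= 0)
    data.frame(species_id = sprintf("%s_sp%03d", lab, seq_len(gp$n)),
               group = lab,
               val = stats::rnorm(gp$n, gp$mean, gp$sd),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[3] <- value
  out
}

#' Simulate a tree and a pair of phylogenetically structured traits
#'
#' Generates a Yule (pure-birth) tree, a Brownian-motion predictor x, and a
#' response `y = beta * x + e` where `e` is multivariate normal with
#' covariance `sigma^2 * C(lambda)` — the tree's Brownian covariance with
#' Pagel's lambda applied to the off-diagonal. Ground truth (`beta`,
#' `lambda`, `sigma`) is known by construction, making this the recovery
#' oracle for [pgls_fit()].
#'
#' @param n_tips number of species (>= 3).
#' @param beta true slope.
#' @param lambda true phylogenetic signal of the residuals, in \[0, 1\].
#' @param sigma residual scale.
#' @param seed RNG seed.
#' @return list with `tree` (`phylo`), `x`, `y` (named numeric vectors).
#' @export
simulate_tree_traits <- function(n_tips = 64, beta = 0.5, lambda = 1,
                                 sigma = 1, seed = 1) {
  stopifnot(n_tips >= 3, lambda >= 0, lambda <= 1)
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  C <- ape::vcv.phylo(tree)
  Lt <- t(chol(C))
  x <- as.vector(Lt %*% stats::rnorm(n_tips))
  Cl <- C
  off <- row(Cl) != col(Cl)
  Cl[off] <- Cl[off] * lambda
  e <- as.vector(t(chol(Cl)) %*% stats::rnorm(n_tips)) * sigma
  y <- beta * x + e
  names(x) <- names(y) <- tree$tip.label
  list(tree = tree, x = x, y = y)
}
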