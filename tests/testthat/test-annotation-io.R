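test_that("a gene with three isoforms and five CDS rows parses cleanly", {
  ann <- parse_gff3(text = make_fig1_fixture())
  expect_s3_class(ann, "annotation_set")
  expect_equal(nrow(ann$genes), 1)
  expect_equal(ann$genes$n_isoforms, 3)
  expect_equal(length(unique(ann$cds$mrna_id)), 3)
  expect_equal(sum(ann$excluded), 0)
  expect_equal(ann$n_gene_features, 1)
})

test_that("a header-only file yields an empty annotation set", {
  ann <- parse_gff3(text = "##gff-version 3\n")
  expect_equal(nrow(ann$genes), 0)
  expect_equal(sum(ann$excluded), 0)
})

test_that("missing gff-version pragma warns but parsing proceeds", {
  txt <- paste(gff_simple_gene(1, cbind(10, 30)), collapse = "\n")
  expect_warning(ann <- parse_gff3(text = txt), "gff-version")
  expect_equal(nrow(ann$genes), 1)
})

test_that("pseudogenes are excluded with their children, however flagged", {
  txt <- gff_text(
    gff_row("chr1", "pseudogene", 1, 100, "ID=gene-ps;gene=ps1"),
    gff_row("chr1", "mRNA", 1, 100, "ID=rna-ps;Parent=gene-ps"),
    gff_row("chr1", "CDS", 1, 50, "ID=cds-ps;Parent=rna-ps"),
    gff_simple_gene(2, cbind(200, 400)))
  ann <- parse_gff3(text = txt)
  expect_equal(unname(ann$excluded["pseudogene"]), 1)
  expect_equal(nrow(ann$genes), 1)
  expect_false("gene-ps" %in% ann$cds$gene_id)

  # same gene flagged via the pseudo=true attribute on a gene record
  txt2 <- gff_text(
    gff_row("chr1", "gene", 1, 100, "ID=gene-p2;gene=p2;pseudo=true"),
    gff_row("chr1", "mRNA", 1, 100, "ID=rna-p2;Parent=gene-p2"),
    gff_row("chr1", "CDS", 1, 50, "ID=cds-p2;Parent=rna-p2"))
  ann2 <- parse_gff3(text = txt2)
  expect_equal(unname(ann2$excluded["pseudogene"]), 1)
  expect_equal(nrow(ann2$genes), 0)
})

test_that("genes whose mRNAs lack CDS children are dropped as no_cds", {
  txt <- gff_text(
    gff_row("chr1", "gene", 1, 100, "ID=gene-1;gene=a"),
    gff_row("chr1", "mRNA", 1, 100, "ID=rna-1;Parent=gene-1"),
    gff_simple_gene(2, cbind(200, 300)))
  ann <- parse_gff3(text = txt)
  expect_equal(unname(ann$excluded["no_cds"]), 1)
  expect_equal(ann$genes$gene_id, "gene-2")
})

test_that("a CDS with a dangling Parent is orphaned; the gene survives via
           its valid isoform", {
  txt <- gff_text(
    gff_row("chr1", "gene", 1, 300, "ID=gene-1;gene=a"),
    gff_row("chr1", "mRNA", 1, 300, "ID=rna-1;Parent=gene-1"),
    gff_row("chr1", "CDS", 1, 90, "ID=cds-1;Parent=rna-1"),
    gff_row("chr1", "CDS", 100, 190, "ID=cds-x;Parent=rna-gone"))
  ann <- parse_gff3(text = txt)
  expect_equal(unname(ann$excluded["orphan_cds"]), 1)
  expect_equal(nrow(ann$genes), 1)
  expect_equal(nrow(ann$cds), 1)
})

test_that("one gene identity annotated twice is excluded as duplicated", {
  two_copies <- gff_text(pragmas = c("##sequence-region chr1 1 1000",
                                     "##sequence-region chr2 1 1000"),
    gff_row("chr1", "gene", 1, 100, "ID=gene-A;Dbxref=GeneID:7;gene=dup"),
    gff_row("chr1", "mRNA", 1, 100, "ID=rna-A;Parent=gene-A"),
    gff_row("chr1", "CDS", 1, 60, "ID=cds-A;Parent=rna-A"),
    gff_row("chr2", "gene", 1, 100, "ID=gene-B;Dbxref=GeneID:7;gene=dup"),
    gff_row("chr2", "mRNA", 1, 100, "ID=rna-B;Parent=gene-B"),
    gff_row("chr2", "CDS", 1, 60, "ID=cds-B;Parent=rna-B"))
  ann <- parse_gff3(text = two_copies)
  expect_equal(unname(ann$excluded["duplicated_gene"]), 2)
  expect_equal(nrow(ann$genes), 0)

  kept <- parse_gff3(text = two_copies, duplicate_policy = "keep-first")
  expect_equal(unname(kept$excluded["duplicated_gene"]), 1)
  expect_equal(nrow(kept$genes), 1)
})

test_that("non-mRNA transcripts are ignored unless allowlisted", {
  txt <- gff_text(
    gff_row("chr1", "gene", 1, 100, "ID=gene-1;gene=a"),
    gff_row("chr1", "transcript", 1, 100, "ID=tx-1;Parent=gene-1"),
    gff_row("chr1", "CDS", 1, 60, "ID=cds-1;Parent=tx-1"))
  ann <- parse_gff3(text = txt)
  expect_equal(nrow(ann$genes), 0)   # no mRNA isoform -> no_cds
  ann2 <- parse_gff3(text = txt, transcript_types = c("mRNA", "transcript"))
  expect_equal(nrow(ann2$genes), 1)
})

test_that("genome length uses pragma > region > max-end precedence", {
  ann <- parse_gff3(text = make_fig1_fixture())
  expect_equal(genome_length(ann), 33)

  two <- gff_text(pragmas = c("##sequence-region c1 1 100",
                              "##sequence-region c2 1 50"),
                  gff_simple_gene(1, cbind(10, 40), seqid = "c1"))
  expect_equal(genome_length(parse_gff3(text = two)), 150)

  region_only <- gff_text(pragmas = character(0),
    gff_row("chr1", "region", 1, 500, "ID=chr1"),
    gff_simple_gene(1, cbind(10, 40)))
  ann3 <- parse_gff3(text = region_only)
  expect_equal(genome_length(ann3), 500)

  bare <- paste(c(gff_simple_gene(1, cbind(10, 444)), ""), collapse = "\n")
  ann4 <- parse_gff3(text = paste0("##gff-version 3\n", bare))
  expect_warning(len <- genome_length(ann4), "max feature end")
  expect_equal(len, 444)
})

test_that("malformed coordinates are skipped or fatal per configuration", {
  txt <- gff_text(
    gff_simple_gene(1, cbind(10, 40)),
    "chr1\ttest\tCDS\t50\tnotanumber\t.\t+\t.\tID=bad;Parent=rna-1.1",
    "chr1\ttest\tCDS\t90\t60\t.\t+\t.\tID=bad2;Parent=rna-1.1")
  expect_warning(ann <- parse_gff3(text = txt, on_error = "skip"),
                 "malformed")
  expect_equal(nrow(ann$cds), 1)
  expect_error(parse_gff3(text = txt, on_error = "fail"), "malformed")
})

test_that("retained + excluded gene counts add up to genes parsed", {
  txt <- gff_text(
    gff_row("chr1", "pseudogene", 1, 50, "ID=g-ps;gene=ps"),
    gff_row("chr1", "gene", 60, 80, "ID=g-empty;gene=e"),
    gff_simple_gene(3, cbind(100, 200)),
    gff_row("chr1", "gene", 300, 350, "ID=g-d1;gene=dd"),
    gff_row("chr1", "mRNA", 300, 350, "ID=r-d1;Parent=g-d1"),
    gff_row("chr1", "CDS", 300, 340, "ID=c-d1;Parent=r-d1"),
    gff_row("chr1", "gene", 400, 450, "ID=g-d2;gene=dd"),
    gff_row("chr1", "mRNA", 400, 450, "ID=r-d2;Parent=g-d2"),
    gff_row("chr1", "CDS", 400, 440, "ID=c-d2;Parent=r-d2"))
  ann <- parse_gff3(text = txt)
  gene_level <- ann$excluded[c("pseudogene", "duplicated_gene", "no_cds")]
  expect_equal(nrow(ann$genes) + sum(gene_level), ann$n_gene_features)
})

test_that("filtering is idempotent", {
  ma <- make_annotation(annotation_spec(n_genes = 4, seed = 11,
                                        inject = "pseudogene"))
  ann <- parse_gff3(text = ma$gff3)
  again <- apply_filters(ann)
  expect_equal(again$genes, ann$genes)
  expect_equal(again$cds, ann$cds)
  expect_equal(again$excluded, ann$excluded)
})

test_that("write -> re-parse round-trips the retained gene models", {
  ma <- make_annotation(annotation_spec(n_genes = 6, seed = 5))
  ann <- parse_gff3(text = ma$gff3)
  back <- parse_gff3(text = write_gff3(ann))
  ord <- function(d) d[order(d$gene_id, d$mrna_id, d$start), ]
  expect_equal(ord(back$cds)[, c("gene_id", "mrna_id", "seqid", "start", "end")],
               ord(ann$cds)[, c("gene_id", "mrna_id", "seqid", "start", "end")],
               ignore_attr = TRUE)
  expect_equal(back$genes[order(back$genes$gene_id), c("gene_id", "start", "end")],
               ann$genes[order(ann$genes$gene_id), c("gene_id", "start", "end")],
               ignore_attr = TRUE)
  expect_equal(genome_length(back), genome_length(ann))
})

test_that("shuffling feature-line order changes nothing downstream", {
  ma <- make_annotation(annotation_spec(n_genes = 5, seed = 21))
  lines <- strsplit(ma$gff3, "\n")[[1]]
  hdr <- lines[startsWith(lines, "#")]
  feats <- lines[!startsWith(lines, "#") & nzchar(lines)]
  set.seed(1)
  shuffled <- paste(c(hdr, sample(feats), ""), collapse = "\n")
  a <- parse_gff3(text = ma$gff3)
  b <- parse_gff3(text = shuffled)
  expect_equal(as.numeric(asr_genomewide(b)), as.numeric(asr_genomewide(a)))
  expect_equal(genome_profile(b), genome_profile(a))
})

test_that("CDS segments within one isoform merge at book-ended junctions", {
  txt <- gff_text(
    gff_row("chr1", "gene", 1, 100, "ID=gene-1;gene=a"),
    gff_row("chr1", "mRNA", 1, 100, "ID=rna-1;Parent=gene-1"),
    gff_row("chr1", "CDS", 1, 30, "ID=c1;Parent=rna-1"),
    gff_row("chr1", "CDS", 31, 60, "ID=c1;Parent=rna-1"),  # book-ended
    gff_row("chr1", "CDS", 50, 80, "ID=c1;Parent=rna-1"))  # overlapping
  ann <- parse_gff3(text = txt)
  expect_equal(nrow(ann$cds), 1)
  expect_equal(ann$cds$start, 1)
  expect_equal(ann$cds$end, 80)
})
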