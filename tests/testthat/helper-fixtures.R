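# GFF3 text builders shared across test files. Feature rows are written
# through one formatter so fixtures stay syntactically uniform.

gff_row <- function(seqid, type, start, end, attrs, strand = "+",
                    source = "test") {
  sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
          seqid, source, type, start, end, strand, attrs)
}

gff_text <- function(..., pragmas = "##sequence-region chr1 1 1000") {
  paste(c("##gff-version 3", pragmas, ..., ""), collapse = "\n")
}

# one gene, one mRNA, CDS segments given as a 2-column matrix
gff_simple_gene <- function(g = 1, cds, seqid = "chr1", strand = "+") {
  gid <- sprintf("gene-%d", g)
  rid <- sprintf("rna-%d.1", g)
  c(gff_row(seqid, "gene", min(cds[, 1]), max(cds[, 2]),
            sprintf("ID=%s;Dbxref=GeneID:%d;gene=g%d", gid, g, g), strand),
    gff_row(seqid, "mRNA", min(cds[, 1]), max(cds[, 2]),
            sprintf("ID=%s;Parent=%s", rid, gid), strand),
    gff_row(seqid, "CDS", cds[, 1], cds[, 2],
            sprintf("ID=cds-%d;Parent=%s", g, rid), strand))
}

# brute-force union length by enumerating positions (independent oracle)
brute_union <- function(intervals) {
  seqid <- if ("seqid" %in% names(intervals)) intervals$seqid else "s"
  length(unique(unlist(mapply(
    function(sq, s, e) paste(sq, s:e),
    seqid, intervals$start, intervals$end, SIMPLIFY = FALSE))))
}

# small random annotation spec that stays within the matrix oracle's reach
small_spec <- function(seed, n_genes = 2) {
  annotation_spec(n_genes = n_genes, isoforms_per_gene = c(1, 3),
                  exons_per_gene = c(1, 3), exon_length = c(4, 15),
                  intron_length = c(2, 8), intergenic = c(3, 12),
                  seed = seed)
}
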