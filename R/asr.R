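#' Number of distinct nucleotide positions covered by a set of intervals
#'
#' Computes the length of the genomic union of a set of intervals, i.e. the
#' number of positions covered by at least one interval. Intervals are
#' 1-based inclusive; overlapping and book-ended intervals are merged per
#' seqid before summing widths.
#'
#' @param intervals a data.frame with columns `start` and `end` (and
#'   optionally `seqid`; a single sequence is assumed when absent), or a
#'   two-column matrix of starts and ends.
#' @return total number of covered positions (numeric scalar).
#' @examples
#' interval_union_length(data.frame(start = c(1, 5, 1, 27, 22),
#'                                  end   = c(9, 13, 13, 33, 27)))
#' @export
interval_union_length <- function(intervals) {
  if (is.matrix(intervals))
    intervals <- data.frame(start = intervals[, 1], end = intervals[, 2])
  if (!nrow(intervals)) return(0)
  stopifnot(all(c("start", "end") %in% names(intervals)))
  if (any(is.na(intervals$start)) || any(is.na(intervals$end)) ||
      any(intervals$start > intervals$end) || any(intervals$start < 1))
    stop("invalid interval: require 1 <= start <= end")
  seqid <- if ("seqid" %in% names(intervals)) intervals$seqid else "seq"
  gr <- GenomicRanges::GRanges(seqid,
                               IRanges::IRanges(intervals$start, intervals$end))
  sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(gr))))
}

# all CDS rows of an annotation (optionally one gene), as GRanges
.cds_granges <- function(x, gene_id = NULL) {
  cds <- x$cds
  if (!is.null(gene_id)) cds <- cds[cds$gene_id == gene_id, , drop = FALSE]
  GenomicRanges::GRanges(cds$seqid, IRanges::IRanges(cds$start, cds$end),
                         strand = ifelse(cds$strand %in% c("+", "-"),
                                         cds$strand, "*"))
}

.asr_components <- function(x, per_strand = FALSE, gene_id = NULL) {
  cds <- x$cds
  if (!is.null(gene_id)) cds <- cds[cds$gene_id == gene_id, , drop = FALSE]
  numerator <- sum(as.numeric(cds$end - cds$start + 1))
  gr <- .cds_granges(x, gene_id)
  red <- GenomicRanges::reduce(gr, ignore.strand = !per_strand)
  denominator <- sum(as.numeric(GenomicRanges::width(red)))
  list(numerator = numerator, denominator = denominator)
}

#' Genome-wide alternative splicing ratio
#'
#' The ASR is the total number of annotated coding nucleotides summed over
#' every mRNA isoform, divided by the number of genomic positions covered by
#' at least one CDS (the projection of the coding DNA onto the genome). It
#' equals the trace ratio tr(M)/tr(A) of the nucleotide co-occurrence
#' ("transcription") matrix and its binarization, and measures the average
#' number of isoforms in which each coding nucleotide participates: 1 means
#' no reuse, larger values mean more extensive isoform sharing.
#'
#' Both the numerator and the denominator are integers; the returned value
#' carries them as attributes `numerator` and `denominator` so that exact
#' rational comparisons remain possible.
#'
#' @param x an `annotation_set` with at least one retained isoform.
#' @param per_strand when `TRUE` the genomic union is taken per
#'   (seqid, strand), so antisense-overlapping CDSs do not share positions.
#'   The default treats the projection as purely positional.
#' @return the ASR (numeric scalar >= 1), with attributes `numerator` and
#'   `denominator`.
#' @examples
#' ann <- parse_gff3(text = make_fig1_fixture())
#' asr_genomewide(ann)   # 44 / 25 = 1.76
#' @export
asr_genomewide <- function(x, per_strand = FALSE) {
  stopifnot(inherits(x, "annotation_set"))
  comp <- .asr_components(x, per_strand = per_strand)
  if (comp$denominator == 0)
    stop("ASR undefined: annotation contains no coding positions")
  structure(comp$numerator / comp$denominator,
            numerator = comp$numerator, denominator = comp$denominator)
}

#' Per-gene alternative splicing ratios
#'
#' @inheritParams asr_genomewide
#' @return named numeric vector of per-gene ASR values.
#' @export
asr_per_gene <- function(x, per_strand = FALSE) {
  stopifnot(inherits(x, "annotation_set"))
  ids <- x$genes$gene_id
  vapply(ids, function(g) {
    comp <- .asr_components(x, per_strand = per_strand, gene_id = g)
    if (comp$denominator == 0) NA_real_ else comp$numerator / comp$denominator
  }, 0, USE.NAMES = TRUE)
}

#' Build the nucleotide co-occurrence (transcription) matrix
#'
#' Explicitly materializes the symmetric matrix M in which `M[i, j]` counts
#' the isoforms whose CDS set contains both genomic positions i and j, along
#' with its binarization A (`A[i, j] = 1` iff `M[i, j] > 0`). Positions are
#' all nucleotides within retained gene spans. The matrix is quadratic in
#' the number of positions and exists as a small-instance oracle for the
#' interval implementation ([asr_genomewide()]); it refuses inputs beyond
#' `max_positions`.
#'
#' @param x an `annotation_set`.
#' @param max_positions refuse to build a matrix over more positions than
#'   this (default 2000).
#' @return object of class `transcription_matrix`: list with `positions`
#'   (data.frame of `seqid`, `pos`), `M`, and `A`.
#' @export
build_transcription_matrix <- function(x, max_positions = 2000) {
  stopifnot(inherits(x, "annotation_set"))
  g <- x$genes
  if (!nrow(g)) stop("no retained genes")
  span <- GenomicRanges::reduce(
    GenomicRanges::GRanges(g$seqid, IRanges::IRanges(g$start, g$end)))
  total <- sum(as.numeric(GenomicRanges::width(span)))
  if (total > max_positions)
    stop("transcription matrix is an O(L^2) small-instance oracle; ",
         total, " gene positions exceed max_positions = ", max_positions,
         ". Use asr_genomewide() for full-size inputs.")
  pos <- data.frame(
    seqid = rep(as.character(GenomicRanges::seqnames(span)),
                GenomicRanges::width(span)),
    pos = unlist(mapply(seq, GenomicRanges::start(span),
                        GenomicRanges::end(span), SIMPLIFY = FALSE))
  )
  key <- paste(pos$seqid, pos$pos)
  n <- nrow(pos)
  M <- matrix(0L, n, n)
  for (m in unique(x$cds$mrna_id)) {
    seg <- x$cds[x$cds$mrna_id == m, , drop = FALSE]
    pk <- unlist(mapply(function(s, e, sq) paste(sq, s:e),
                        seg$start, seg$end, seg$seqid, SIMPLIFY = FALSE))
    idx <- match(pk, key)
    idx <- idx[!is.na(idx)]
    M[idx, idx] <- M[idx, idx] + 1L
  }
  A <- (M > 0L) + 0L
  structure(list(positions = pos, M = M, A = A),
            class = "transcription_matrix")
}

#' ASR from an explicit transcription matrix
#'
#' Computes the trace ratio tr(M)/tr(A). The diagonal of M counts, for each
#' genomic position, the number of isoforms containing it; the diagonal of A
#' marks the coding positions.
#'
#' @param tm a `transcription_matrix` from [build_transcription_matrix()].
#' @return the ASR, with attributes `numerator` (tr(M)) and `denominator`
#'   (tr(A)).
#' @export
asr_from_matrix <- function(tm) {
  stopifnot(inherits(tm, "transcription_matrix"))
  tr_m <- sum(diag(tm$M))
  tr_a <- sum(diag(tm$A))
  if (tr_a == 0)
    stop("ASR undefined: no coding positions (tr(A) = 0)")
  structure(tr_m / tr_a, numerator = tr_m, denominator = tr_a)
}

#' Genomic composition profile of an annotation
#'
#' Summarizes one species' annotation into the quantities used throughout
#' the comparative analysis: genome size; gene content (genomic union of
#' retained gene spans); coding content (genomic union of all retained CDS
#' intervals); the derived percentages gene/genome, coding/gene and
#' coding/genome; gene and isoform counts; and the ASR.
#'
#' @inheritParams asr_genomewide
#' @param species_id label for the profile row.
#' @return one-row data.frame with columns `species_id`, `genome_size`,
#'   `gene_content`, `coding_content`, `gene_over_genome`,
#'   `coding_over_gene`, `coding_over_genome`, `n_genes`, `n_isoforms`,
#'   `asr` (NA when no coding positions exist).
#' @export
genome_profile <- function(x, species_id = "species", per_strand = FALSE) {
  stopifnot(inherits(x, "annotation_set"))
  gsize <- genome_length(x)
  g <- x$genes
  gene_content <- if (nrow(g)) interval_union_length(
    data.frame(seqid = g$seqid, start = g$start, end = g$end)) else 0
  comp <- .asr_components(x, per_strand = per_strand)
  coding_content <- comp$denominator
  asr <- if (comp$denominator > 0) comp$numerator / comp$denominator else NA_real_
  data.frame(
    species_id = species_id,
    genome_size = gsize,
    gene_content = gene_content,
    coding_content = coding_content,
    gene_over_genome = 100 * gene_content / gsize,
    coding_over_gene = if (gene_content > 0)
      100 * coding_content / gene_content else NA_real_,
    coding_over_genome = 100 * coding_content / gsize,
    n_genes = nrow(g),
    n_isoforms = length(unique(x$cds$mrna_id)),
    asr = asr,
    stringsAsFactors = FALSE
  )
}
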