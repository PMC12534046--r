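#' Parse a GFF3 annotation file into an annotation set
#'
#' Reads GFF3 (version 3, NCBI RefSeq attribute dialect) and reconstructs the
#' gene -> mRNA -> CDS hierarchy through `ID`/`Parent` links. Feature records
#' are parsed with \pkg{rtracklayer}; `##sequence-region` pragmas are read
#' directly from the header so that sequence lengths are available even when
#' no `region` feature is annotated.
#'
#' By default the study's inclusion filters are applied on the way in (see
#' [apply_filters()]): pseudogenes, duplicated genes, genes without any valid
#' CDS-bearing mRNA, and CDS records whose parent chain cannot be traced are
#' excluded, with per-reason counts kept in the result.
#'
#' @param file path to a GFF3 file. Exactly one of `file`/`text` must be given.
#' @param text GFF3 content as a character scalar (or vector of lines).
#' @param filter apply [apply_filters()] before returning (default `TRUE`).
#' @param on_error `"skip"` drops malformed feature lines (non-integer or
#'   reversed coordinates, wrong column count) with a warning naming the line
#'   numbers; `"fail"` stops at the first malformed line.
#' @param transcript_types feature types treated as isoform-bearing
#'   transcripts. The default, `"mRNA"`, restricts the metric to protein
#'   isoforms; ncRNA-style transcripts are ignored.
#' @param duplicate_policy passed to [apply_filters()].
#' @return An object of class `annotation_set`: a list with elements
#'   \describe{
#'     \item{genes}{data.frame of retained genes (`gene_id`, `gene_key`,
#'       `seqid`, `start`, `end`, `strand`, `n_isoforms`).}
#'     \item{cds}{data.frame with one row per CDS segment after merging
#'       overlapping/book-ended segments within each isoform (`gene_id`,
#'       `mrna_id`, `seqid`, `start`, `end`, `strand`). Coordinates are
#'       1-based inclusive, as in GFF3.}
#'     \item{excluded}{named integer vector of exclusion counts by reason:
#'       `pseudogene`, `orphan_cds`, `duplicated_gene`, `no_cds`,
#'       `multi_seqid`.}
#'     \item{seqinfo}{data.frame per seqid with `pragma_length`,
#'       `region_length` and `max_end` (used by [genome_length()]).}
#'     \item{n_gene_features}{number of gene-like records parsed (genes plus
#'       pseudogenes); retained genes + gene-level exclusions always add up
#'       to this count.}
#'   }
#' @seealso [apply_filters()], [genome_length()], [asr_genomewide()]
#' @examples
#' gff <- make_fig1_fixture()
#' ann <- parse_gff3(text = gff)
#' ann
#' asr_genomewide(ann)
#' @export
parse_gff3 <- function(file = NULL, text = NULL, filter = TRUE,
                       on_error = c("skip", "fail"),
                       transcript_types = "mRNA",
                       duplicate_policy = c("drop-all", "keep-first")) {
  on_error <- match.arg(on_error)
  duplicate_policy <- match.arg(duplicate_policy)
  if (is.null(file) == is.null(text))
    stop("supply exactly one of `file` or `text`")
  lines <- if (!is.null(file)) readLines(file, warn = FALSE) else
    unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)

  if (!any(grepl("^##gff-version\\s+3", lines[seq_len(min(5L, length(lines)))])))
    warning("missing '##gff-version 3' pragma; proceeding anyway")

  pragma <- .parse_sequence_regions(lines)
  feat_idx <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  feat_lines <- lines[feat_idx]
  bad <- .malformed_feature_lines(feat_lines)
  if (length(bad)) {
    msg <- sprintf("malformed GFF3 feature line(s) at: %s",
                   paste(feat_idx[bad], collapse = ", "))
    if (on_error == "fail") stop(msg)
    warning(msg, "; skipped")
    feat_lines <- feat_lines[-bad]
  }

  gr <- .import_gff3_records(lines[startsWith(lines, "##")], feat_lines)
  ann <- .assemble_hierarchy(gr, pragma, transcript_types)
  if (filter) ann <- apply_filters(ann, duplicate_policy = duplicate_policy)
  ann
}

# seqid, start, end from ##sequence-region pragmas; length = end - start + 1
.parse_sequence_regions <- function(lines) {
  sr <- grep("^##sequence-region\\b", lines, value = TRUE)
  if (!length(sr))
    return(data.frame(seqid = character(), pragma_length = numeric()))
  parts <- strsplit(trimws(sr), "\\s+")
  ok <- lengths(parts) >= 4
  parts <- parts[ok]
  data.frame(
    seqid = vapply(parts, `[[`, "", 2L),
    pragma_length = vapply(parts, function(p)
      as.numeric(p[[4]]) - as.numeric(p[[3]]) + 1, 0)
  )
}

.malformed_feature_lines <- function(feat_lines) {
  if (!length(feat_lines)) return(integer())
  fields <- strsplit(feat_lines, "\t", fixed = TRUE)
  bad_ncol <- lengths(fields) != 9L
  start <- suppressWarnings(as.numeric(vapply(
    fields, function(f) if (length(f) >= 4) f[[4]] else NA_character_, "")))
  end <- suppressWarnings(as.numeric(vapply(
    fields, function(f) if (length(f) >= 5) f[[5]] else NA_character_, "")))
  bad_coord <- is.na(start) | is.na(end) | start > end | start < 1 |
    start != floor(start) | end != floor(end)
  which(bad_ncol | bad_coord)
}

.import_gff3_records <- function(pragmas, feat_lines) {
  tf <- tempfile(fileext = ".gff3")
  on.exit(unlink(tf))
  writeLines(c("##gff-version 3", feat_lines), tf)
  if (!length(feat_lines)) return(GenomicRanges::GRanges())
  suppressWarnings(rtracklayer::import(tf, format = "gff3"))
}

.first_or_na <- function(cl) {
  vapply(cl, function(x) if (length(x)) x[[1]] else NA_character_, "")
}

.mcol_chr <- function(gr, name) {
  mc <- S4Vectors::mcols(gr)
  if (!name %in% names(mc)) return(rep(NA_character_, length(gr)))
  v <- mc[[name]]
  if (is(v, "List") || is.list(v)) .first_or_na(v) else as.character(v)
}

# gene identity key for duplicate detection: GeneID dbxref > gene symbol > ID
.gene_keys <- function(gr) {
  key <- rep(NA_character_, length(gr))
  mc <- S4Vectors::mcols(gr)
  if ("Dbxref" %in% names(mc)) {
    key <- vapply(mc$Dbxref, function(x) {
      hit <- grep("^GeneID:", x, value = TRUE)
      if (length(hit)) hit[[1]] else NA_character_
    }, "")
  }
  sym <- .mcol_chr(gr, "gene")
  key[is.na(key)] <- sym[is.na(key)]
  id <- .mcol_chr(gr, "ID")
  key[is.na(key)] <- id[is.na(key)]
  key
}

.assemble_hierarchy <- function(gr, pragma, transcript_types) {
  excluded <- c(pseudogene = 0L, orphan_cds = 0L, duplicated_gene = 0L,
                no_cds = 0L, multi_seqid = 0L)
  seqinfo_tbl <- .build_seqinfo(gr, pragma)
  if (length(gr) == 0) {
    return(.new_annotation_set(.empty_genes(), .empty_cds(), excluded,
                               seqinfo_tbl, 0L))
  }
  type <- as.character(S4Vectors::mcols(gr)$type)
  id <- .mcol_chr(gr, "ID")
  parent <- .first_or_na(if ("Parent" %in% names(S4Vectors::mcols(gr)))
    S4Vectors::mcols(gr)$Parent else replicate(length(gr), character(0),
                                               simplify = FALSE))
  pseudo_attr <- .mcol_chr(gr, "pseudo")

  is_gene_like <- type %in% c("gene", "pseudogene")
  is_pseudo <- type == "pseudogene" |
    (is_gene_like & !is.na(pseudo_attr) & tolower(pseudo_attr) == "true")

  gi <- which(is_gene_like)
  genes <- data.frame(
    gene_id = id[gi],
    gene_key = .gene_keys(gr[gi]),
    seqid = as.character(GenomicRanges::seqnames(gr[gi])),
    start = GenomicRanges::start(gr[gi]),
    end = GenomicRanges::end(gr[gi]),
    strand = as.character(GenomicRanges::strand(gr[gi])),
    pseudo = is_pseudo[gi],
    stringsAsFactors = FALSE
  )

  mi <- which(type %in% transcript_types)
  mrna <- data.frame(
    mrna_id = id[mi], gene_id = parent[mi],
    seqid = as.character(GenomicRanges::seqnames(gr[mi])),
    stringsAsFactors = FALSE
  )
  # transcripts must trace to a parsed gene-like record
  orphan_mrna <- !(mrna$gene_id %in% genes$gene_id)
  mrna <- mrna[!orphan_mrna, , drop = FALSE]

  ci <- which(type == "CDS")
  cds <- data.frame(
    mrna_id = parent[ci],
    seqid = as.character(GenomicRanges::seqnames(gr[ci])),
    start = GenomicRanges::start(gr[ci]),
    end = GenomicRanges::end(gr[ci]),
    strand = as.character(GenomicRanges::strand(gr[ci])),
    stringsAsFactors = FALSE
  )
  orphan <- is.na(cds$mrna_id) | !(cds$mrna_id %in% mrna$mrna_id)
  excluded["orphan_cds"] <- sum(orphan)
  cds <- cds[!orphan, , drop = FALSE]
  cds$gene_id <- mrna$gene_id[match(cds$mrna_id, mrna$mrna_id)]

  # transcripts whose CDSs sit on more than one sequence cannot be projected
  nseq <- tapply(cds$seqid, cds$mrna_id, function(s) length(unique(s)))
  multi <- names(nseq)[nseq > 1]
  excluded["multi_seqid"] <- length(multi)
  if (length(multi)) cds <- cds[!(cds$mrna_id %in% multi), , drop = FALSE]

  cds <- .merge_within_isoform(cds)
  genes$n_isoforms <- as.integer(
    tapply(cds$mrna_id, factor(cds$gene_id, levels = genes$gene_id),
           function(m) length(unique(m))))
  genes$n_isoforms[is.na(genes$n_isoforms)] <- 0L

  .new_annotation_set(genes, cds, excluded, seqinfo_tbl,
                      n_gene_features = length(gi), filtered = FALSE)
}

# merge overlapping and book-ended CDS segments within each isoform, so a
# nucleotide never counts twice toward one isoform's length
.merge_within_isoform <- function(cds) {
  if (!nrow(cds)) return(.empty_cds())
  gr <- GenomicRanges::GRanges(cds$seqid, IRanges::IRanges(cds$start, cds$end),
                               strand = cds$strand)
  sp <- GenomicRanges::split(gr, cds$mrna_id)
  red <- GenomicRanges::reduce(sp, ignore.strand = TRUE)
  flat <- unlist(red, use.names = TRUE)
  out <- data.frame(
    mrna_id = names(flat),
    seqid = as.character(GenomicRanges::seqnames(flat)),
    start = GenomicRanges::start(flat),
    end = GenomicRanges::end(flat),
    strand = as.character(GenomicRanges::strand(flat)),
    stringsAsFactors = FALSE
  )
  key <- match(out$mrna_id, cds$mrna_id)
  out$gene_id <- cds$gene_id[key]
  out$strand <- cds$strand[key]   # reduce(ignore.strand) loses strand
  rownames(out) <- NULL
  out[order(out$gene_id, out$mrna_id, out$seqid, out$start),
      c("gene_id", "mrna_id", "seqid", "start", "end", "strand")]
}

.build_seqinfo <- function(gr, pragma) {
  seqids <- unique(c(pragma$seqid,
                     if (length(gr)) as.character(GenomicRanges::seqnames(gr))))
  if (!length(seqids))
    return(data.frame(seqid = character(), pragma_length = numeric(),
                      region_length = numeric(), max_end = numeric()))
  tbl <- data.frame(seqid = seqids,
                    pragma_length = pragma$pragma_length[match(seqids, pragma$seqid)],
                    region_length = NA_real_, max_end = NA_real_)
  if (length(gr)) {
    type <- as.character(S4Vectors::mcols(gr)$type)
    sq <- as.character(GenomicRanges::seqnames(gr))
    reg <- type == "region"
    if (any(reg)) {
      rl <- tapply(GenomicRanges::end(gr[reg]) -
                     GenomicRanges::start(gr[reg]) + 1, sq[reg], max)
      tbl$region_length <- as.numeric(rl[tbl$seqid])
    }
    me <- tapply(GenomicRanges::end(gr), sq, max)
    tbl$max_end <- as.numeric(me[tbl$seqid])
  }
  rownames(tbl) <- NULL
  tbl
}

.empty_genes <- function() data.frame(
  gene_id = character(), gene_key = character(), seqid = character(),
  start = integer(), end = integer(), strand = character(),
  pseudo = logical(), n_isoforms = integer(), stringsAsFactors = FALSE)

.empty_cds <- function() data.frame(
  gene_id = character(), mrna_id = character(), seqid = character(),
  start = integer(), end = integer(), strand = character(),
  stringsAsFactors = FALSE)

.new_annotation_set <- function(genes, cds, excluded, seqinfo_tbl,
                                n_gene_features, filtered = FALSE) {
  structure(list(genes = genes, cds = cds, excluded = excluded,
                 seqinfo = seqinfo_tbl, n_gene_features = n_gene_features,
                 filtered = filtered),
            class = "annotation_set")
}

#' Apply the study's gene inclusion filters
#'
#' Retains only genes whose isoforms each trace CDS -> mRNA -> gene, and
#' excludes, with counted reasons: pseudogenes (`pseudogene`-typed records or
#' genes flagged `pseudo=true`), duplicated genes (more than one gene record
#' sharing the same gene identity key -- `Dbxref` GeneID, falling back to the
#' `gene` symbol, then `ID`), and genes left without any CDS-bearing mRNA.
#' Filtering is idempotent.
#'
#' @param x an `annotation_set` from [parse_gff3()].
#' @param duplicate_policy `"drop-all"` excludes every record of a duplicated
#'   gene identity (the conservative default); `"keep-first"` retains the
#'   first record encountered.
#' @return a filtered `annotation_set`; `$excluded` accumulates counts.
#' @export
apply_filters <- function(x, duplicate_policy = c("drop-all", "keep-first")) {
  stopifnot(inherits(x, "annotation_set"))
  duplicate_policy <- match.arg(duplicate_policy)
  genes <- x$genes
  cds <- x$cds
  excluded <- x$excluded

  drop_pseudo <- genes$pseudo
  excluded["pseudogene"] <- excluded["pseudogene"] + sum(drop_pseudo)
  genes <- genes[!drop_pseudo, , drop = FALSE]

  dup <- if (duplicate_policy == "drop-all")
    genes$gene_key %in% genes$gene_key[duplicated(genes$gene_key)]
  else duplicated(genes$gene_key)
  excluded["duplicated_gene"] <- excluded["duplicated_gene"] + sum(dup)
  genes <- genes[!dup, , drop = FALSE]

  cds <- cds[cds$gene_id %in% genes$gene_id, , drop = FALSE]
  no_cds <- !(genes$gene_id %in% cds$gene_id)
  excluded["no_cds"] <- excluded["no_cds"] + sum(no_cds)
  genes <- genes[!no_cds, , drop = FALSE]
  genes$n_isoforms <- as.integer(
    tapply(cds$mrna_id, factor(cds$gene_id, levels = genes$gene_id),
           function(m) length(unique(m))))

  rownames(genes) <- rownames(cds) <- NULL
  .new_annotation_set(genes, cds, excluded, x$seqinfo, x$n_gene_features,
                      filtered = TRUE)
}

#' Total genome length of an annotation set
#'
#' Sums one length per sequence over every seqid in the annotation, with
#' precedence: `##sequence-region` pragma, then the span of a `region`
#' feature, then the maximum feature end coordinate (with a warning, since
#' that is only a lower bound on the true sequence length).
#'
#' @param x an `annotation_set`.
#' @return total length in nucleotides.
#' @export
genome_length <- function(x) {
  stopifnot(inherits(x, "annotation_set"))
  si <- x$seqinfo
  if (!nrow(si)) stop("no sequences in annotation; genome length unknown")
  len <- si$pragma_length
  use_region <- is.na(len)
  len[use_region] <- si$region_length[use_region]
  use_max <- is.na(len)
  if (any(use_max)) {
    len[use_max] <- si$max_end[use_max]
    if (any(is.na(len)))
      stop("no length derivable for seqid(s): ",
           paste(si$seqid[is.na(len)], collapse = ", "))
    warning("no ##sequence-region pragma or region feature for seqid(s) ",
            paste(si$seqid[use_max], collapse = ", "),
            "; using max feature end as sequence length")
  }
  sum(len)
}

#' Serialize an annotation set back to GFF3
#'
#' Writes the retained gene/mRNA/CDS hierarchy (post-filtering) as GFF3 text,
#' including `##sequence-region` pragmas where lengths are known. Re-parsing
#' the output reproduces the same gene models.
#'
#' @param x an `annotation_set`.
#' @param file optional path; when `NULL` the GFF3 text is returned.
#' @return invisibly (or visibly when `file` is `NULL`) the GFF3 text.
#' @export
write_gff3 <- function(x, file = NULL) {
  stopifnot(inherits(x, "annotation_set"))
  gff_strand <- function(s) ifelse(s %in% c("+", "-"), s, ".")
  out <- "##gff-version 3"
  si <- x$seqinfo[!is.na(x$seqinfo$pragma_length), , drop = FALSE]
  if (nrow(si))
    out <- c(out, sprintf("##sequence-region %s 1 %d", si$seqid,
                          as.integer(si$pragma_length)))
  for (i in seq_len(nrow(x$genes))) {
    g <- x$genes[i, ]
    out <- c(out, sprintf("%s\tspliceratio\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene=%s",
                          g$seqid, g$start, g$end, gff_strand(g$strand), g$gene_id,
                          g$gene_key))
    gcds <- x$cds[x$cds$gene_id == g$gene_id, , drop = FALSE]
    for (m in unique(gcds$mrna_id)) {
      mc <- gcds[gcds$mrna_id == m, , drop = FALSE]
      out <- c(out,
               sprintf("%s\tspliceratio\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       mc$seqid[1], min(mc$start), max(mc$end),
                       gff_strand(mc$strand[1]),
                       m, g$gene_id),
               sprintf("%s\tspliceratio\tCDS\t%d\t%d\t.\t%s\t0\tID=cds-%s;Parent=%s",
                       mc$seqid, mc$start, mc$end, gff_strand(mc$strand), m, m))
    }
  }
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (is.null(file)) return(txt)
  writeLines(out, file)
  invisible(txt)
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("<annotation_set>", nrow(x$genes), "genes,",
      length(unique(x$cds$mrna_id)), "isoforms,",
      nrow(x$cds), "CDS segments\n")
  cat("  sequences:", nrow(x$seqinfo),
      if (x$filtered) " (filtered)" else " (unfiltered)", "\n")
  ex <- x$excluded[x$excluded > 0]
  if (length(ex))
    cat("  excluded:", paste(names(ex), ex, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
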