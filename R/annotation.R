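#' Parse a GFF3 annotation into gene models
#'
#' Builds, for every gene feature: the union of all annotated exon
#' coordinates across isoforms ("exon blocks"), the set of annotated introns
#' (gaps between consecutive exons within each transcript, deduplicated per
#' gene), and the extreme CDS coordinates across isoforms (minimum CDS start,
#' maximum CDS end) used to separate coding-region introns from UTR introns.
#' An exon-boundary index supports gene assignment of introns within a small
#' tolerance.
#'
#' Coordinates are 1-based and fully closed throughout (GFF3 convention).
#'
#' @param gff3_path Path to a GFF3 file with gene/mRNA (or transcript)/exon/
#'   CDS features linked by ID/Parent.
#' @param feature_config Optional list overriding feature/attribute names:
#'   `gene_types` (default `"gene"`), `transcript_types` (default
#'   `c("mRNA", "transcript")`), `exon_type` (`"exon"`), `cds_type` (`"CDS"`),
#'   `gene_id_attr` (tried in order; default `c("ID", "gene_id", "Name")`),
#'   `boundary_tolerance` (default 1).
#'
#' @return An object of class `"annotation"`: a list with data.tables
#'   `genes` (gene_id, chrom, start, end, strand, cds_min_start,
#'   cds_max_stop, exonic_length), `exon_blocks`, `annotated_introns`,
#'   `exon_boundaries` (all exon start/end positions across isoforms), and
#'   the boundary tolerance.
#' @export
load_annotation <- function(gff3_path, feature_config = list()) {
  fc <- utils::modifyList(list(
    gene_types = "gene",
    transcript_types = c("mRNA", "transcript"),
    exon_type = "exon",
    cds_type = "CDS",
    gene_id_attr = c("ID", "gene_id", "Name"),
    boundary_tolerance = 1L
  ), feature_config)

  .validate_gff3_lines(gff3_path)
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  m <- S4Vectors::mcols(gr)

  feat <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(m$type),
    id = if ("ID" %in% names(m)) as.character(m$ID) else NA_character_,
    parent = vapply(if ("Parent" %in% names(m)) m$Parent else
      replicate(length(gr), character(0), simplify = FALSE),
      function(p) if (length(p)) p[[1]] else NA_character_, character(1))
  )

  genes_ft <- feat[feat$type %in% fc$gene_types, ]
  if (nrow(genes_ft) == 0) stop("no gene features of type ",
                                paste(fc$gene_types, collapse = "/"),
                                " in ", gff3_path)
  # resolve gene identity: first available attribute among gene_id_attr
  gid <- genes_ft$id
  if (anyNA(gid) && "gene_id" %in% names(m)) {
    alt <- as.character(m$gene_id)[feat$type %in% fc$gene_types]
    gid[is.na(gid)] <- alt[is.na(gid)]
  }
  if (anyNA(gid)) stop("gene features without resolvable identifier")
  genes_ft$gene_id <- gid

  tx_ft <- feat[feat$type %in% fc$transcript_types, ]
  tx2gene <- stats::setNames(tx_ft$parent, tx_ft$id)
  id2gene <- stats::setNames(genes_ft$gene_id, genes_ft$id)

  resolve_gene <- function(parent) {
    # parent may be a transcript or directly a gene
    out <- id2gene[parent]
    miss <- is.na(out)
    out[miss] <- id2gene[tx2gene[parent[miss]]]
    out
  }

  ex <- feat[feat$type == fc$exon_type, ]
  ex$gene_id <- resolve_gene(ex$parent)
  n_orphans <- sum(is.na(ex$gene_id))
  if (n_orphans > 0) {
    warning(n_orphans, " exon feature(s) with no resolvable gene parent skipped")
    ex <- ex[!is.na(ex$gene_id), ]
  }

  cds <- feat[feat$type == fc$cds_type, ]
  cds$gene_id <- resolve_gene(cds$parent)
  cds <- cds[!is.na(cds$gene_id), ]

  # exon blocks: per-gene interval union, maximal (adjacent intervals merged)
  gene_id <- chrom <- start <- end <- NULL  # data.table NSE
  blocks <- .union_blocks(ex)
  exonic_len <- blocks[, list(exonic_length = sum(end - start + 1L)), by = gene_id]

  # annotated introns: gaps between consecutive exons within a transcript,
  # deduplicated per gene
  introns <- .transcript_introns(ex)

  cds_ext <- if (nrow(cds) > 0) {
    cds[, list(cds_min_start = min(start), cds_max_stop = max(end)),
        by = gene_id]
  } else {
    data.table::data.table(gene_id = character(), cds_min_start = integer(),
                           cds_max_stop = integer())
  }

  genes <- data.table::data.table(
    gene_id = genes_ft$gene_id, chrom = genes_ft$chrom,
    start = genes_ft$start, end = genes_ft$end, strand = genes_ft$strand)
  genes <- merge(genes, cds_ext, by = "gene_id", all.x = TRUE)
  genes <- merge(genes, exonic_len, by = "gene_id", all.x = TRUE)
  genes$exonic_length[is.na(genes$exonic_length)] <- 0L

  boundaries <- unique(data.table::rbindlist(list(
    ex[, list(chrom, pos = start, gene_id)],
    ex[, list(chrom, pos = end, gene_id)])))

  ann <- list(genes = genes,
              exon_blocks = blocks,
              annotated_introns = introns,
              exon_boundaries = boundaries,
              boundary_tolerance = as.integer(fc$boundary_tolerance),
              n_orphan_exons = n_orphans)
  class(ann) <- "annotation"
  ann
}

.validate_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^\\s*(#|$)", lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nf != 9L]
  if (length(bad))
    stop(sprintf("malformed GFF3 line %d in %s (expected 9 tab-separated fields)",
                 bad[1], path))
  invisible(TRUE)
}

.union_blocks <- function(ex) {
  gene_id <- chrom <- start <- end <- NULL
  if (nrow(ex) == 0)
    return(data.table::data.table(gene_id = character(), chrom = character(),
                                  start = integer(), end = integer()))
  gr <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start, ex$end))
  spl <- GenomicRanges::split(gr, ex$gene_id)
  red <- GenomicRanges::reduce(spl)
  flat <- unlist(red, use.names = TRUE)
  out <- data.table::data.table(
    gene_id = names(flat),
    chrom = as.character(GenomicRanges::seqnames(flat)),
    start = GenomicRanges::start(flat),
    end = GenomicRanges::end(flat))
  data.table::setorder(out, gene_id, chrom, start)
  out
}

.transcript_introns <- function(ex) {
  gene_id <- chrom <- start <- end <- NULL
  ex_tx <- ex[!is.na(ex$parent), ]
  if (nrow(ex_tx) == 0)
    return(data.table::data.table(gene_id = character(), chrom = character(),
                                  start = integer(), end = integer(),
                                  strand = character()))
  data.table::setorder(ex_tx, parent, start)
  introns <- ex_tx[, {
    if (.N > 1) {
      s <- end[-.N] + 1L
      e <- start[-1] - 1L
      keep <- e >= s
      list(gene_id = gene_id[-.N][keep], chrom = chrom[-.N][keep],
           start = s[keep], end = e[keep], strand = strand[-.N][keep])
    } else {
      list(gene_id = character(0), chrom = character(0),
           start = integer(0), end = integer(0), strand = character(0))
    }
  }, by = "parent"][, c("gene_id", "chrom", "start", "end", "strand"), with = FALSE]
  unique(introns)
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf("annotation: %d genes, %d exon blocks, %d annotated introns\n",
              nrow(x$genes), nrow(x$exon_blocks), nrow(x$annotated_introns)))
  invisible(x)
}
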