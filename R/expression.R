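#' Per-gene exonic read coverage
#'
#' Computes, for each gene, the total number of aligned bases falling inside
#' its exon blocks (per-base coverage summed over block positions) and the
#' mean per-base exonic coverage (`coverage_sum / exonic_length`).
#'
#' @param blocks Aligned blocks (`ridx`, `start`, `end`) of passing reads
#'   (from [decompose_alignments()]).
#' @param block_chrom Chromosome per block row.
#' @param annotation A [load_annotation()] result.
#' @return A `data.table` (`gene_id`, `exonic_length`, `coverage_sum`,
#'   `mean_per_base_coverage`) with one row per annotated gene.
#' @export
exonic_coverage <- function(blocks, block_chrom, annotation) {
  eb <- annotation$exon_blocks
  out <- data.table::data.table(
    gene_id = annotation$genes$gene_id,
    exonic_length = annotation$genes$exonic_length,
    coverage_sum = 0)
  if (nrow(blocks) > 0 && nrow(eb) > 0) {
    for (ch in unique(eb$chrom)) {
      bi <- blocks[block_chrom == ch, ]
      ei <- eb[eb$chrom == ch, ]
      if (nrow(bi) == 0) next
      cov <- IRanges::coverage(IRanges::IRanges(bi$start, bi$end))
      maxpos <- max(ei$end)
      if (length(cov) < maxpos)
        cov <- c(cov, S4Vectors::Rle(0L, maxpos - length(cov)))
      v <- IRanges::Views(cov, IRanges::IRanges(ei$start, ei$end))
      sums <- IRanges::viewSums(v)
      agg <- stats::aggregate(sums, list(ei$gene_id), sum)
      out$coverage_sum[match(agg[[1]], out$gene_id)] <- agg[[2]]
    }
  }
  out$mean_per_base_coverage <- ifelse(out$exonic_length > 0,
                                       out$coverage_sum / out$exonic_length, 0)
  out
}

#' Assign reads to genes by majority exonic overlap
#'
#' A read is assigned to the gene holding the majority (> 50%) of its
#' aligned bases within that gene's exon blocks; reads split between genes
#' with no majority, or tied, stay unassigned. Each read is assigned to at
#' most one gene.
#'
#' @inheritParams exonic_coverage
#' @param aligned_span Per-read total aligned reference span (bp), indexed
#'   by `ridx`.
#' @return A `data.table` (`ridx`, `gene_id`) of assigned reads.
#' @export
assign_reads_to_genes <- function(blocks, block_chrom, aligned_span, annotation) {
  eb <- annotation$exon_blocks
  if (nrow(blocks) == 0 || nrow(eb) == 0)
    return(data.table::data.table(ridx = integer(), gene_id = character()))
  ov_list <- list()
  for (ch in unique(eb$chrom)) {
    sel <- block_chrom == ch
    bi <- blocks[sel, ]
    ei <- eb[eb$chrom == ch, ]
    if (nrow(bi) == 0) next
    q <- IRanges::IRanges(bi$start, bi$end)
    s <- IRanges::IRanges(ei$start, ei$end)
    ov <- IRanges::findOverlaps(q, s)
    if (length(ov) == 0) next
    w <- IRanges::width(IRanges::pintersect(q[S4Vectors::queryHits(ov)],
                                            s[S4Vectors::subjectHits(ov)]))
    ov_list[[ch]] <- data.table::data.table(
      ridx = bi$ridx[S4Vectors::queryHits(ov)],
      gene_id = ei$gene_id[S4Vectors::subjectHits(ov)],
      w = w)
  }
  if (!length(ov_list))
    return(data.table::data.table(ridx = integer(), gene_id = character()))
  ov <- data.table::rbindlist(ov_list)
  per <- ov[, list(w = sum(w)), by = c("ridx", "gene_id")]
  data.table::setorder(per, ridx, -w)
  best <- per[!duplicated(per$ridx), ]
  # majority rule: strictly more than half the read's aligned bases, no tie
  second <- per[duplicated(per$ridx), ][!duplicated(ridx), list(ridx, w2 = w)]
  best <- merge(best, second, by = "ridx", all.x = TRUE)
  keep <- best$w > aligned_span[best$ridx] / 2 &
    (is.na(best$w2) | best$w2 < best$w)
  best[keep, c("ridx", "gene_id"), with = FALSE]
}

#' FPKM from read counts
#'
#' `FPKM = count / (exonic_length / 1e3) / (total_assigned / 1e6)`, a
#' union-exon (exon-block) expression measure.
#'
#' @param assigned_read_count Reads (or fragments) assigned to the gene.
#' @param exonic_length Exon-block length of the gene (bp, > 0).
#' @param total_assigned Total reads assigned to any gene in the sample.
#' @return Numeric FPKM (0 when the count is 0; NA when `total_assigned`
#'   is 0).
#' @export
fpkm <- function(assigned_read_count, exonic_length, total_assigned) {
  ifelse(total_assigned > 0 & exonic_length > 0,
         assigned_read_count / (exonic_length / 1e3) / (total_assigned / 1e6),
         NA_real_)
}

#' Depth-weighted mean FPKM across samples
#'
#' `sum(fpkm_s * depth_s) / sum(depth_s)`, the cross-sample representative
#' expression level where deeper samples weigh more. With equal depths this
#' is the arithmetic mean.
#'
#' @param per_sample_fpkm Numeric vector (one gene across samples) or matrix
#'   (genes x samples).
#' @param per_sample_depth Numeric vector of sample depths (length = number
#'   of samples, at least one > 0).
#' @return Numeric scalar (or per-gene vector for matrix input); NA when all
#'   depths are zero.
#' @export
weighted_fpkm <- function(per_sample_fpkm, per_sample_depth) {
  if (all(per_sample_depth == 0)) {
    if (is.matrix(per_sample_fpkm)) return(rep(NA_real_, nrow(per_sample_fpkm)))
    return(NA_real_)
  }
  if (is.matrix(per_sample_fpkm)) {
    as.vector(per_sample_fpkm %*% per_sample_depth) / sum(per_sample_depth)
  } else {
    sum(per_sample_fpkm * per_sample_depth) / sum(per_sample_depth)
  }
}

#' Read a BUSCO-to-gene mapping table
#'
#' Tab-delimited with columns `gene_id`, `busco_id`, `set` (one of
#' eukaryota/metazoa/embryophyta; free-form labels accepted). A gene may map
#' to at most one BUSCO identifier within a set.
#'
#' @param path File path.
#' @return A `data.table` (`gene_id`, `busco_id`, `set`).
#' @export
read_busco_map <- function(path) {
  bm <- data.table::fread(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  need <- c("gene_id", "busco_id", "set")
  if (!all(need %in% names(bm)))
    stop("BUSCO map must have columns: ", paste(need, collapse = ", "))
  dup <- bm[, list(n = length(unique(busco_id))), by = c("gene_id", "set")]
  if (any(dup$n > 1))
    stop("gene mapped to multiple BUSCO ids within one set: ",
         dup$gene_id[dup$n > 1][1])
  bm[, need, with = FALSE]
}

#' Per-sample sequencing depth over BUSCO genes
#'
#' The sequencing depth of a sample is the median per-base exonic read
#' coverage across BUSCO-mapped genes (midpoint of the central pair for an
#' even count), a standardized depth measure comparable across species.
#'
#' @param gene_coverage A `data.table` from [exonic_coverage()].
#' @param busco_map A `data.table` from [read_busco_map()] (or with at least
#'   a `gene_id` column).
#' @return Numeric scalar depth, with attribute `busco_coverages` (the
#'   per-gene means it is the median of).
#' @export
sample_depth <- function(gene_coverage, busco_map) {
  genes <- intersect(unique(busco_map$gene_id), gene_coverage$gene_id)
  if (!length(genes))
    stop("no BUSCO-mapped genes with coverage; supply a BUSCO-to-gene mapping")
  covs <- gene_coverage$mean_per_base_coverage[match(genes, gene_coverage$gene_id)]
  d <- stats::median(covs)
  attr(d, "busco_coverages") <- stats::setNames(covs, genes)
  d
}

#' Per-sample gene expression table
#'
#' Combines coverage, majority-overlap read assignment and FPKM for one
#' sample.
#'
#' @param quant Result of [quantify_sample()] (its attributes carry the
#'   decomposed blocks of the passing reads).
#' @param annotation A [load_annotation()] result.
#' @return A `data.table` (`gene_id`, `exonic_length`, `coverage_sum`,
#'   `mean_per_base_coverage`, `assigned_read_count`, `fpkm`) with attribute
#'   `total_assigned`.
#' @export
gene_expression <- function(quant, annotation) {
  blocks <- attr(quant, "blocks")
  bch <- attr(quant, "block_chrom")
  cov <- exonic_coverage(blocks, bch, annotation)
  span <- blocks[, list(s = sum(end - start + 1L)), by = "ridx"]
  aligned_span <- integer(max(c(0L, span$ridx)))
  aligned_span[span$ridx] <- span$s
  asg <- assign_reads_to_genes(blocks, bch, aligned_span, annotation)
  cnt <- table(asg$gene_id)
  cov$assigned_read_count <- 0L
  cov$assigned_read_count[match(names(cnt), cov$gene_id)] <- as.integer(cnt)
  total <- sum(cov$assigned_read_count)
  cov$fpkm <- if (total > 0)
    fpkm(cov$assigned_read_count, cov$exonic_length, total) else NA_real_
  cov$fpkm[cov$assigned_read_count == 0 & total > 0 & cov$exonic_length > 0] <- 0
  attr(cov, "total_assigned") <- total
  cov
}
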