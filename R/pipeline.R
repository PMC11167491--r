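#' Run the full per-sample analysis and write its tables
#'
#' Applies read filters, quantifies every catalogue intron (Ns/Na/Nu, RAS,
#' RANS, class), computes per-gene exonic coverage and FPKM, measures the
#' sample's BUSCO-median sequencing depth, and writes `by_intron_db.tab.gz`,
#' `by_gene_db.tab.gz` and `manifest.json` into `out_dir/<sample_id>/`.
#' Deterministic and idempotent for identical inputs and configuration.
#'
#' @param alignment_path SAM or BAM file for one sample.
#' @param genome `DNAStringSet` or FASTA path.
#' @param annotation [load_annotation()] result or GFF3 path.
#' @param busco_map [read_busco_map()] result, path, or NULL (depth NA).
#' @param cfg A [filter_config()].
#' @param out_dir Output directory; tables land in a per-sample subfolder.
#' @param catalogue Optional pre-built species-level catalogue
#'   ([build_catalog()]); when NULL, the catalogue is built from this sample
#'   alone plus the annotation.
#' @param sample_id Sample label (default: file name).
#' @return Invisibly, a list: `intron_table`, `gene_table`, `depth`,
#'   `manifest`, and the written paths.
#' @export
run_sample <- function(alignment_path, genome, annotation, busco_map = NULL,
                       cfg = filter_config(), out_dir = NULL,
                       catalogue = NULL, sample_id = NULL) {
  if (is.character(genome)) genome <- read_genome(genome)
  if (is.character(annotation)) annotation <- load_annotation(annotation)
  if (is.character(busco_map)) busco_map <- read_busco_map(busco_map)

  sam_chroms <- alignment_chroms(alignment_path)
  known <- union(names(genome), unique(annotation$exon_blocks$chrom))
  missing <- setdiff(sam_chroms, names(genome))
  if (length(missing))
    stop("chromosome name mismatch: alignment declares [",
         paste(missing, collapse = ", "), "] absent from the genome FASTA (",
         paste(utils::head(names(genome), 5), collapse = ", "), " ...)")

  reads <- read_alignments(alignment_path,
                           sample_id = if (is.null(sample_id))
                             sub("\\.(sam|bam)$", "", basename(alignment_path),
                                 ignore.case = TRUE) else sample_id)
  sid <- if (nrow(reads)) reads$sample_id[1] else
    if (is.null(sample_id)) sub("\\.(sam|bam)$", "", basename(alignment_path),
                                ignore.case = TRUE) else sample_id

  if (is.null(catalogue))
    catalogue <- build_catalog(alignment_path, genome, annotation, cfg)

  quant <- quantify_sample(reads, catalogue, cfg)
  gene_tab <- gene_expression(quant, annotation)
  depth <- if (!is.null(busco_map))
    tryCatch(as.numeric(sample_depth(gene_tab, busco_map)),
             error = function(e) NA_real_) else NA_real_

  manifest <- list(
    sample_id = sid,
    inputs = list(alignment = alignment_path),
    config_hash = config_hash(cfg),
    config = unclass(cfg),
    reads = attr(quant, "counts"),
    depth = depth,
    total_assigned = attr(gene_tab, "total_assigned"),
    tool = paste0("splicefreq ", as.character(utils::packageVersion("splicefreq"))))

  paths <- NULL
  if (!is.null(out_dir)) {
    d <- file.path(out_dir, sid)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    pi <- file.path(d, "by_intron_db.tab.gz")
    pg <- file.path(d, "by_gene_db.tab.gz")
    pm <- file.path(d, "manifest.json")
    write_table_gz(quant, pi)
    write_table_gz(gene_tab, pg)
    jsonlite::write_json(manifest, pm, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    paths <- list(intron = pi, gene = pg, manifest = pm)
  }
  invisible(list(intron_table = quant, gene_table = gene_tab, depth = depth,
                 manifest = manifest, paths = paths))
}

#' Write a table as gzip tab-delimited with "NA" for missing values
#' @param dt A data.frame/data.table.
#' @param path Output path (`.gz`).
#' @return `path`, invisibly.
#' @export
write_table_gz <- function(dt, path) {
  con <- gzfile(path, "w")
  on.exit(close(con))
  utils::write.table(dt, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a gzip tab-delimited table written by [write_table_gz()]
#' @param path File path.
#' @return A `data.table`.
#' @export
read_table_gz <- function(path) {
  df <- utils::read.table(gzfile(path), sep = "\t", header = TRUE,
                          na.strings = "NA", stringsAsFactors = FALSE)
  data.table::as.data.table(df)
}

#' Aggregate per-sample intron counts
#'
#' Field-wise sums of Ns/Na/Nu across samples with ratios and classes
#' recomputed on the summed counts (never averaged across samples). All
#' tables must share the same catalogue rows in the same order; aggregation
#' is associative and commutative over samples.
#'
#' @param tables List of per-sample intron tables ([quantify_sample()] or
#'   [read_table_gz()] of `by_intron_db.tab.gz`).
#' @param cfg A [filter_config()].
#' @return Aggregated intron table (`sample_id = "ALL"`).
#' @export
aggregate_intron_counts <- function(tables, cfg = filter_config()) {
  stopifnot(length(tables) >= 1)
  key <- function(t) paste(t$chrom, t$start, t$end)
  k0 <- key(tables[[1]])
  for (t in tables[-1])
    if (!identical(key(t), k0))
      stop("per-sample tables have mismatched catalogue keys")
  agg <- data.table::copy(tables[[1]])
  sum_col <- function(col) Reduce(`+`, lapply(tables, `[[`, col))
  agg$Ns <- sum_col("Ns"); agg$Na <- sum_col("Na"); agg$Nu <- sum_col("Nu")
  if ("discovered" %in% names(agg))
    agg$discovered <- Reduce(`|`, lapply(tables, `[[`, "discovered"))
  agg$sample_id <- "ALL"
  rt <- splicing_ratios(agg$Ns, agg$Na, agg$Nu, cfg)
  agg$RAS <- rt$RAS; agg$RANS <- rt$RANS
  agg$intron_class <- classify_intron(rt$RAS, rt$RANS, cfg)
  agg
}

#' Aggregate a species directory of per-sample runs
#'
#' Reads every `<sample>/by_intron_db.tab.gz` and `by_gene_db.tab.gz` under
#' `species_dir`, sums intron counts (ratios/classes recomputed on sums),
#' summarizes FPKM across samples (mean, median, and sequencing-depth-
#' weighted mean), and writes `by_intron_analysis.tab.gz` and
#' `by_gene_analysis.tab.gz` with rows positionally matching the per-sample
#' files.
#'
#' @param species_dir Directory containing per-sample subdirectories
#'   produced by [run_sample()].
#' @param cfg A [filter_config()].
#' @param weight `"depth"` (BUSCO-median depth from each sample's manifest;
#'   default) or `"total_assigned"` as the weighted-FPKM weight.
#' @return Invisibly, list with `intron_table`, `gene_table` and paths.
#' @export
aggregate_samples <- function(species_dir, cfg = filter_config(),
                              weight = c("depth", "total_assigned")) {
  weight <- match.arg(weight)
  dirs <- list.dirs(species_dir, recursive = FALSE)
  dirs <- dirs[file.exists(file.path(dirs, "by_intron_db.tab.gz"))]
  if (!length(dirs)) stop("no per-sample tables under ", species_dir)

  itabs <- lapply(file.path(dirs, "by_intron_db.tab.gz"), read_table_gz)
  gtabs <- lapply(file.path(dirs, "by_gene_db.tab.gz"), read_table_gz)
  mans <- lapply(file.path(dirs, "manifest.json"), jsonlite::read_json)

  intron_agg <- aggregate_intron_counts(itabs, cfg)

  g0 <- gtabs[[1]]$gene_id
  for (g in gtabs[-1])
    if (!identical(g$gene_id, g0)) stop("gene tables have mismatched keys")
  fpkm_mat <- do.call(cbind, lapply(gtabs, `[[`, "fpkm"))
  w <- vapply(mans, function(m) {
    v <- if (weight == "depth") m$depth else m$total_assigned
    if (is.null(v) || is.na(v)) 0 else as.numeric(v)
  }, numeric(1))
  if (all(w == 0)) w <- rep(1, length(mans))
  gene_agg <- data.table::data.table(
    gene_id = g0,
    exonic_length = gtabs[[1]]$exonic_length,
    total_coverage = Reduce(`+`, lapply(gtabs, `[[`, "coverage_sum")),
    mean_fpkm = rowMeans(fpkm_mat, na.rm = TRUE),
    median_fpkm = apply(fpkm_mat, 1, stats::median, na.rm = TRUE),
    weighted_fpkm = weighted_fpkm(fpkm_mat, w))

  pi <- file.path(species_dir, "by_intron_analysis.tab.gz")
  pg <- file.path(species_dir, "by_gene_analysis.tab.gz")
  write_table_gz(intron_agg, pi)
  write_table_gz(gene_agg, pg)
  invisible(list(intron_table = intron_agg, gene_table = gene_agg,
                 paths = list(intron = pi, gene = pg)))
}
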