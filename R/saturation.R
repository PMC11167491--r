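#' Sequencing-depth saturation analysis by sample subsampling
#'
#' Repeatedly subsamples the available RNA-seq samples, recomputes pooled
#' sequencing depth and intron classes on the summed counts, and reports how
#' the number of major/minor/unclassified introns grows with depth. Within a
#' replicate, subsets are nested (a random permutation of the samples is
#' drawn and the first `n` are used), so detected-intron sets are monotone
#' along a replicate; across replicates draws are independent. A single seed
#' governs the whole grid.
#'
#' By default the intron catalogue is subset-restricted: a discovered
#' (unannotated) intron is only counted when some sample in the subset
#' contains a discovery-grade observation of it; annotated introns are
#' always kept. Set `subset_catalog = FALSE` to classify against the full
#' catalogue instead.
#'
#' @param intron_tables List of per-sample intron tables
#'   ([quantify_sample()] results or `by_intron_db.tab.gz` reads), all on
#'   the same catalogue.
#' @param gene_tables List of matching per-sample gene tables
#'   ([gene_expression()]), used for pooled BUSCO depth.
#' @param busco_map A [read_busco_map()] table (or NULL: depth NA).
#' @param n_range Integer vector of subset sizes (default `1:20`, capped at
#'   the number of samples -- an error if it exceeds it).
#' @param replicates Number of repetitions (default 10).
#' @param seed Integer seed.
#' @param subset_catalog Restrict discovered introns to the subset (default
#'   TRUE).
#' @param cfg A [filter_config()].
#' @return A `data.table` with one row per (n_samples, replicate):
#'   `replicate`, `n_samples`, `sample_ids` (comma-separated), `depth`,
#'   `n_major`, `n_minor`, `n_unclassified`, `annotated_fraction_major`,
#'   `annotated_fraction_minor`.
#' @export
run_saturation <- function(intron_tables, gene_tables = NULL,
                           busco_map = NULL, n_range = 1:20,
                           replicates = 10L, seed = 1L,
                           subset_catalog = TRUE, cfg = filter_config()) {
  S <- length(intron_tables)
  if (max(n_range) > S)
    stop("n_range requests up to ", max(n_range), " samples but only ", S,
         " per-sample tables are available")
  sample_ids <- vapply(seq_len(S), function(i) {
    sid <- intron_tables[[i]]$sample_id[1]
    if (is.null(sid) || is.na(sid)) paste0("s", i) else as.character(sid)
  }, character(1))

  cat0 <- intron_tables[[1]]
  ns_mat <- do.call(cbind, lapply(intron_tables, `[[`, "Ns"))
  nu_mat <- do.call(cbind, lapply(intron_tables, `[[`, "Nu"))
  disc_mat <- if ("discovered" %in% names(cat0))
    do.call(cbind, lapply(intron_tables, `[[`, "discovered"))
  else ns_mat > 0
  annotated <- cat0$annotated

  cov_mat <- busco_idx <- NULL
  if (!is.null(gene_tables) && !is.null(busco_map)) {
    cov_mat <- do.call(cbind, lapply(gene_tables, `[[`, "mean_per_base_coverage"))
    busco_idx <- which(gene_tables[[1]]$gene_id %in% busco_map$gene_id)
  }

  set.seed(seed)
  perms <- lapply(seq_len(replicates), function(r) sample.int(S))

  out <- vector("list", replicates * length(n_range))
  k <- 0L
  for (r in seq_len(replicates)) {
    for (n in n_range) {
      sel <- perms[[r]][seq_len(n)]
      ns <- rowSums(ns_mat[, sel, drop = FALSE])
      nu <- rowSums(nu_mat[, sel, drop = FALSE])
      keep <- if (subset_catalog)
        annotated | rowSums(disc_mat[, sel, drop = FALSE]) > 0
      else rep(TRUE, length(ns))
      sub_cat <- cat0[keep, c("chrom", "start", "end", "annotated"), with = FALSE]
      na <- count_alternative(sub_cat, as.integer(ns[keep]))
      rt <- splicing_ratios(ns[keep], na, nu[keep], cfg)
      cls <- classify_intron(rt$RAS, rt$RANS, cfg)
      depth <- NA_real_
      if (!is.null(cov_mat) && length(busco_idx))
        depth <- stats::median(rowSums(cov_mat[busco_idx, sel, drop = FALSE]))
      maj <- cls == "major"; mnr <- cls == "minor"
      k <- k + 1L
      out[[k]] <- data.table::data.table(
        replicate = r, n_samples = n,
        sample_ids = paste(sample_ids[sel], collapse = ","),
        depth = depth,
        n_major = sum(maj), n_minor = sum(mnr),
        n_unclassified = sum(cls == "unclassified"),
        annotated_fraction_major =
          if (any(maj)) mean(sub_cat$annotated[maj]) else NA_real_,
        annotated_fraction_minor =
          if (any(mnr)) mean(sub_cat$annotated[mnr]) else NA_real_)
    }
  }
  data.table::rbindlist(out)
}
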