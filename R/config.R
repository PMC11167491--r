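#' Read-level and junction-level filter configuration
#'
#' Bundles the thresholds applied when filtering alignments and building the
#' intron catalogue. Defaults follow a conservative protocol: only uniquely
#' mapped reads with a mismatch fraction of at most 0.02 are used; new introns
#' require a minimum anchor of 8 bp while quantification accepts 5 bp anchors;
#' junctions longer than 2 Mb are discarded; intron retention is measured from
#' co-linear reads spanning at least 10 bp on both sides of an exon-intron
#' boundary.
#'
#' @param max_mismatch_fraction Maximum `NM / aligned length` for a read to be
#'   kept (default 0.02).
#' @param min_anchor_discovery Minimum anchor (bp) on *both* sides of a
#'   junction for the junction to seed a new catalogue intron (default 8).
#' @param min_anchor_quantification Minimum anchor (bp) on both sides for a
#'   junction observation to count towards `Ns` (default 5).
#' @param max_intron_length Junctions spanning more than this many bp on the
#'   reference are dropped at extraction time (default 2e6).
#' @param min_flank_unspliced Required co-linear coverage (bp) on each side of
#'   an exon-intron boundary for a read to count towards `Nu` (default 10).
#' @param mismatch_denominator `"aligned"` (M/=/X bases, the default) or
#'   `"read"` (full read length incl. soft clips) as the denominator of the
#'   mismatch fraction.
#' @param unique_by `"nh"` (NH tag == 1, MAPQ fallback when NH absent) or
#'   `"mapq"` (MAPQ threshold only).
#' @param min_unique_mapq MAPQ floor used when NH is absent or
#'   `unique_by = "mapq"` (default 60, the value HISAT2 assigns to uniquely
#'   mapped reads).
#' @param missing_nm_policy What to do with reads lacking an NM tag:
#'   `"reject"` (default) or `"zero"` (assume 0 mismatches).
#' @param boundary_tolerance Gene-assignment tolerance (bp) around annotated
#'   exon boundaries (default 1).
#' @param major_threshold Ratio threshold for the major/minor classification
#'   (default 0.5; both RAS and RANS must exceed it for a major call).
#' @param min_denominator Minimum denominator for RAS/RANS to be defined
#'   (default 10).
#'
#' @return A list of class `"filter_config"`.
#' @export
filter_config <- function(max_mismatch_fraction = 0.02,
                          min_anchor_discovery = 8L,
                          min_anchor_quantification = 5L,
                          max_intron_length = 2000000L,
                          min_flank_unspliced = 10L,
                          mismatch_denominator = c("aligned", "read"),
                          unique_by = c("nh", "mapq"),
                          min_unique_mapq = 60L,
                          missing_nm_policy = c("reject", "zero"),
                          boundary_tolerance = 1L,
                          major_threshold = 0.5,
                          min_denominator = 10) {
  stopifnot(max_mismatch_fraction >= 0,
            min_anchor_discovery >= 0,
            min_anchor_quantification >= 0,
            min_anchor_discovery >= min_anchor_quantification,
            max_intron_length >= 0,
            min_flank_unspliced >= 0,
            boundary_tolerance >= 0)
  cfg <- list(
    max_mismatch_fraction = max_mismatch_fraction,
    min_anchor_discovery = as.integer(min_anchor_discovery),
    min_anchor_quantification = as.integer(min_anchor_quantification),
    max_intron_length = as.integer(max_intron_length),
    min_flank_unspliced = as.integer(min_flank_unspliced),
    mismatch_denominator = match.arg(mismatch_denominator),
    unique_by = match.arg(unique_by),
    min_unique_mapq = as.integer(min_unique_mapq),
    missing_nm_policy = match.arg(missing_nm_policy),
    boundary_tolerance = as.integer(boundary_tolerance),
    major_threshold = major_threshold,
    min_denominator = min_denominator
  )
  class(cfg) <- "filter_config"
  cfg
}

#' @export
print.filter_config <- function(x, ...) {
  cat("filter_config:\n")
  for (k in names(x)) cat(sprintf("  %-26s %s\n", k, format(x[[k]])))
  invisible(x)
}

config_hash <- function(cfg) {
  # stable short provenance tag embedded in output manifests
  s <- paste(names(cfg), vapply(cfg, function(v) paste(format(v), collapse = ","),
                                character(1)), sep = "=", collapse = ";")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% .Machine$integer.max)
}
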