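#' Count spliced reads (Ns) per catalogue intron
#'
#' `Ns` for an intron is the number of junction observations whose skipped
#' interval equals the intron exactly and whose anchors are both at or above
#' the quantification threshold (5 bp by default). Observations matching no
#' catalogue intron are tallied as orphan junctions (attribute
#' `n_orphan`), not counted anywhere.
#'
#' @param junctions Junction observations (`chrom`, `start`, `end`,
#'   `left_anchor`, `right_anchor`).
#' @param catalogue Intron catalogue ([discover_introns()]).
#' @param cfg A [filter_config()].
#' @return Integer vector of `Ns` aligned with the catalogue rows, with
#'   attribute `n_orphan`.
#' @export
count_spliced <- function(junctions, catalogue, cfg = filter_config()) {
  left_anchor <- right_anchor <- NULL
  ns <- integer(nrow(catalogue))
  ok <- junctions[pmin(left_anchor, right_anchor) >= cfg$min_anchor_quantification]
  if (nrow(ok) > 0) {
    key_cat <- paste(catalogue$chrom, catalogue$start, catalogue$end)
    key_obs <- paste(ok$chrom, ok$start, ok$end)
    hit <- match(key_obs, key_cat)
    tab <- table(hit[!is.na(hit)])
    ns[as.integer(names(tab))] <- as.integer(tab)
    attr(ns, "n_orphan") <- sum(is.na(hit))
  } else {
    attr(ns, "n_orphan") <- 0L
  }
  ns
}

#' Count alternative-variant reads (Na) per catalogue intron
#'
#' `Na` for a focal intron is the sum of `Ns` over all catalogue introns that
#' share exactly one of its two boundaries (same chromosome, same start xor
#' same end). Since the catalogue is unique by coordinates, the only intron
#' sharing both boundaries is the focal intron itself, which is excluded.
#'
#' @param catalogue Intron catalogue.
#' @param ns Integer vector of `Ns` aligned with the catalogue.
#' @return Integer vector of `Na` aligned with the catalogue.
#' @export
count_alternative <- function(catalogue, ns) {
  if (nrow(catalogue) == 0) return(integer(0))
  ks <- paste(catalogue$chrom, catalogue$start)
  ke <- paste(catalogue$chrom, catalogue$end)
  sum_start <- stats::ave(ns, ks, FUN = sum)
  sum_end <- stats::ave(ns, ke, FUN = sum)
  as.integer((sum_start - ns) + (sum_end - ns))
}

#' Count unspliced (intron-retention) reads (Nu) per catalogue intron
#'
#' A read contributes to `Nu` at an intron boundary when one of its
#' contiguous aligned blocks covers the boundary window co-linearly (at
#' least `min_flank_unspliced` bp on both sides, no junction inside). Both
#' boundaries are counted additively, so a single read spanning a short
#' intron end to end contributes 2 -- the reason `Nu` is halved inside RANS.
#'
#' @param blocks Aligned blocks (`ridx`, `start`, `end`) from
#'   [decompose_alignments()] of the *passing* reads.
#' @param block_chrom Chromosome of each block row (character vector aligned
#'   with `blocks`).
#' @param catalogue Intron catalogue.
#' @param cfg A [filter_config()].
#' @return Integer vector of `Nu` aligned with the catalogue.
#' @export
count_unspliced <- function(blocks, block_chrom, catalogue,
                            cfg = filter_config()) {
  f <- cfg$min_flank_unspliced
  n <- nrow(catalogue)
  nu <- integer(n)
  if (n == 0 || nrow(blocks) == 0) return(nu)
  windows <- data.table::data.table(
    iidx = rep(seq_len(n), 2L),
    chrom = rep(catalogue$chrom, 2L),
    lo = c(catalogue$start - f, catalogue$end - f + 1L),
    hi = c(catalogue$start + f - 1L, catalogue$end + f))
  for (ch in unique(windows$chrom)) {
    wi <- windows[windows$chrom == ch, ]
    bi <- blocks[block_chrom == ch, ]
    if (nrow(bi) == 0) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(wi$lo, wi$hi),
      IRanges::IRanges(bi$start, bi$end), type = "within")
    if (length(ov) == 0) next
    # one hit per (window, read): blocks of a read are disjoint
    cnt <- table(S4Vectors::queryHits(ov))
    idx <- wi$iidx[as.integer(names(cnt))]
    add <- stats::aggregate(as.integer(cnt), list(idx), sum)
    nu[add[[1]]] <- nu[add[[1]]] + add[[2]]
  }
  nu
}

#' Splicing ratios RAS and RANS
#'
#' `RAS = Ns / (Ns + Na)` measures the relative abundance of the focal
#' splicing event against variants sharing one boundary; `RANS = Ns /
#' (Ns + Nu/2)` measures it against intron retention (`Nu` is halved because
#' an unspliced read spanning both boundaries reflects a single retention
#' event). Each ratio is defined only when its denominator reaches the
#' minimum read support (10 by default); otherwise `NA`.
#'
#' @param ns,na,nu Integer vectors of per-intron counts.
#' @param cfg A [filter_config()].
#' @return A `data.table` with columns `RAS` and `RANS` (`NA` when
#'   undefined).
#' @export
splicing_ratios <- function(ns, na, nu, cfg = filter_config()) {
  d_ras <- ns + na
  d_rans <- ns + nu / 2
  data.table::data.table(
    RAS = ifelse(d_ras >= cfg$min_denominator, ns / d_ras, NA_real_),
    RANS = ifelse(d_rans >= cfg$min_denominator, ns / d_rans, NA_real_))
}

#' Major / minor / unclassified intron classification
#'
#' An intron is a major-isoform intron when both RAS and RANS are defined
#' and both exceed the threshold (0.5); a minor-isoform intron when at least
#' one defined ratio is at or below the threshold; otherwise unclassified
#' (including undefined ratios).
#'
#' @param ras,rans Numeric vectors (NA = undefined).
#' @param cfg A [filter_config()].
#' @return Character vector: `"major"`, `"minor"` or `"unclassified"`.
#' @export
classify_intron <- function(ras, rans, cfg = filter_config()) {
  t <- cfg$major_threshold
  major <- !is.na(ras) & !is.na(rans) & ras > t & rans > t
  minor <- (!is.na(ras) & ras <= t) | (!is.na(rans) & rans <= t)
  out <- rep("unclassified", length(ras))
  out[minor] <- "minor"
  out[major] <- "major"
  out
}

#' Quantify one sample against a fixed intron catalogue
#'
#' Applies the read filters, decomposes passing reads, and computes per-
#' intron `Ns`, `Na`, `Nu` plus a `discovered` flag (the sample contains at
#' least one discovery-grade observation of the intron, i.e. both anchors at
#' or above the discovery threshold). Ratios and classes are computed on the
#' per-sample counts.
#'
#' @param reads A `data.table` from [read_alignments()] (or a SAM/BAM path).
#' @param catalogue Intron catalogue ([discover_introns()] /
#'   [build_catalog()]).
#' @param cfg A [filter_config()].
#' @return A `data.table` with the catalogue columns plus `sample_id`, `Ns`,
#'   `Na`, `Nu`, `discovered`, `RAS`, `RANS`, `intron_class`; attributes
#'   `counts` (reads seen/passed/rejected-by-reason, orphan junctions) and
#'   `blocks`/`block_chrom`/`aligned_len`/`pass_reads` for downstream reuse.
#' @export
quantify_sample <- function(reads, catalogue, cfg = filter_config()) {
  if (is.character(reads)) reads <- read_alignments(reads)
  left_anchor <- right_anchor <- NULL
  fr <- passes_read_filters(reads, cfg)
  passing <- fr[fr$pass, ]
  dec <- decompose_alignments(passing, max_intron_length = cfg$max_intron_length)

  ns <- count_spliced(dec$junctions, catalogue, cfg)
  na <- count_alternative(catalogue, ns)
  nu <- count_unspliced(dec$blocks, passing$chrom[dec$blocks$ridx], catalogue, cfg)

  disc <- logical(nrow(catalogue))
  dq <- dec$junctions[pmin(left_anchor, right_anchor) >= cfg$min_anchor_discovery]
  if (nrow(dq) > 0) {
    hit <- match(paste(dq$chrom, dq$start, dq$end),
                 paste(catalogue$chrom, catalogue$start, catalogue$end))
    disc[unique(hit[!is.na(hit)])] <- TRUE
  }

  rt <- splicing_ratios(ns, na, nu, cfg)
  out <- data.table::copy(catalogue)
  out[, c("sample_id", "Ns", "Na", "Nu", "discovered", "RAS", "RANS",
          "intron_class") :=
        list(if (nrow(reads)) reads$sample_id[1] else NA_character_,
             as.integer(ns), na, nu, disc, rt$RAS, rt$RANS,
             classify_intron(rt$RAS, rt$RANS, cfg))]

  rej <- table(fr$reason[!fr$pass])
  attr(out, "counts") <- list(
    seen = nrow(fr), passed = nrow(passing),
    rejected = as.list(rej),
    orphan_junctions = attr(ns, "n_orphan"),
    overlong_junctions = attr(dec, "n_overlong"))
  attr(out, "blocks") <- dec$blocks
  attr(out, "block_chrom") <- passing$chrom[dec$blocks$ridx]
  attr(out, "aligned_len") <- dec$aligned_len
  attr(out, "pass_reads") <- passing
  out
}
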