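#' Discover introns from junction observations
#'
#' A junction enters the catalogue as a discovered intron when at least one
#' observation has both anchors at or above the discovery threshold (8 bp by
#' default) and its terminal dinucleotides match one of the canonical splice
#' signals (GT-AG, GC-AG, AT-AC) in either orientation; the strand is set
#' from the matching orientation. Annotated introns are always included,
#' regardless of RNA-seq support, and are trusted even when their signal is
#' non-canonical (then flagged `signal = "none"`).
#'
#' @param junctions A `data.table` of junction observations
#'   (`chrom`, `start`, `end`, `left_anchor`, `right_anchor`), e.g. the
#'   `junctions` element of [decompose_alignments()] pooled over samples.
#' @param genome A `DNAStringSet` ([read_genome()]); required for the
#'   splice-signal check.
#' @param annotation Optional [load_annotation()] result supplying annotated
#'   introns and (via [assign_to_genes()]) gene assignment.
#' @param cfg A [filter_config()].
#' @return A `data.table` catalogue: `chrom`, `start`, `end`, `strand`,
#'   `signal`, `annotated`, `gene_id`, `status`, `location`, ordered by
#'   position. Strand `"*"` means unresolved (palindromic signal with no
#'   assigned gene, or a trusted annotated intron without canonical signal
#'   and no strand in the annotation).
#' @export
discover_introns <- function(junctions, genome, annotation = NULL,
                             cfg = filter_config()) {
  if (is.null(genome)) stop("a genome is required to check splice signals")
  chrom <- start <- end <- left_anchor <- right_anchor <- NULL

  disc <- junctions[pmin(left_anchor, right_anchor) >= cfg$min_anchor_discovery,
                    unique(data.table::data.table(chrom, start, end))]
  if (nrow(disc) > 0) {
    sig <- .signal_table(genome, disc)
    disc <- cbind(disc, sig)
    disc <- disc[disc$signal != "none", ]
    disc$annotated <- FALSE
  } else {
    disc <- data.table::data.table(chrom = character(), start = integer(),
                                   end = integer(), signal = character(),
                                   strand = character(), annotated = logical())
  }

  if (!is.null(annotation) && nrow(annotation$annotated_introns) > 0) {
    ai <- unique(annotation$annotated_introns[, c("chrom", "start", "end",
                                                  "strand"), with = FALSE])
    data.table::setnames(ai, "strand", "ann_strand")
    ai <- ai[ai$chrom %in% names(genome), ]
    sig <- .signal_table(genome, ai)
    ai <- cbind(ai, sig)
    # annotation is trusted: keep its strand when the signal is uninformative
    ai$strand[ai$strand == "*"] <- ai$ann_strand[ai$strand == "*"]
    ai$ann_strand <- NULL
    ai$annotated <- TRUE
    # an intron both annotated and RNA-seq-discovered is annotated
    cat <- rbind(ai, disc[!paste(disc$chrom, disc$start, disc$end) %in%
                            paste(ai$chrom, ai$start, ai$end), ])
  } else {
    cat <- disc
  }

  cat$gene_id <- NA_character_
  cat$status <- "unassigned"
  cat$location <- "unassigned"
  data.table::setorder(cat, chrom, start, end)
  data.table::setcolorder(cat, c("chrom", "start", "end", "strand", "signal",
                                 "annotated", "gene_id", "status", "location"))
  if (!is.null(annotation)) cat <- assign_to_genes(cat, annotation)
  cat
}

.signal_table <- function(genome, iv) {
  res <- lapply(seq_len(nrow(iv)), function(i)
    classify_signal(genome, iv$chrom[i], iv$start[i], iv$end[i]))
  data.table::data.table(
    signal = vapply(res, `[[`, character(1), "signal"),
    strand = vapply(res, `[[`, character(1), "strand"))
}

#' Assign catalogue introns to genes
#'
#' An intron's flanking exonic positions are `start - 1` and `end + 1`.
#' Candidate genes are those with any annotated exon boundary (across all
#' isoforms) within the boundary tolerance (1 bp by default) of either
#' flanking position. Exactly one candidate gives a unique assignment;
#' several give `status = "ambiguous"` (gene_id unset); none leaves the
#' intron `"unassigned"`. Introns with unresolved strand adopt the strand of
#' their uniquely assigned gene. CDS/UTR location is filled in via
#' [classify_location()].
#'
#' @param catalogue A catalogue `data.table` (see [discover_introns()]).
#' @param annotation A [load_annotation()] result.
#' @return The catalogue with `gene_id`, `status`, `location` (and strand for
#'   resolved palindromic introns) filled in.
#' @export
assign_to_genes <- function(catalogue, annotation) {
  catalogue <- data.table::copy(catalogue)
  if (nrow(catalogue) == 0) return(catalogue)
  tol <- annotation$boundary_tolerance
  bd <- annotation$exon_boundaries

  flanks <- data.table::rbindlist(list(
    data.table::data.table(iidx = seq_len(nrow(catalogue)),
                           chrom = catalogue$chrom, pos = catalogue$start - 1L),
    data.table::data.table(iidx = seq_len(nrow(catalogue)),
                           chrom = catalogue$chrom, pos = catalogue$end + 1L)))
  # each flank matches boundaries within +/- tol
  shift_grid <- seq(-tol, tol)
  q <- flanks[rep(seq_len(nrow(flanks)), each = length(shift_grid))]
  q$pos <- q$pos + rep(shift_grid, times = nrow(flanks))
  hits <- merge(q, bd, by = c("chrom", "pos"), allow.cartesian = TRUE)
  cand <- unique(hits[, c("iidx", "gene_id"), with = FALSE])
  ngenes <- cand[, list(n = .N), by = "iidx"]

  catalogue$status <- "unassigned"
  catalogue$gene_id <- NA_character_
  uniq <- ngenes$iidx[ngenes$n == 1L]
  amb <- ngenes$iidx[ngenes$n > 1L]
  catalogue$status[uniq] <- "unique"
  catalogue$status[amb] <- "ambiguous"
  g1 <- cand[cand$iidx %in% uniq, ]
  catalogue$gene_id[g1$iidx] <- g1$gene_id

  # strand of the gene resolves palindromic/unknown intron strands
  gstr <- stats::setNames(annotation$genes$strand, annotation$genes$gene_id)
  fix <- which(catalogue$status == "unique" & catalogue$strand == "*")
  catalogue$strand[fix] <- gstr[catalogue$gene_id[fix]]

  catalogue$location <- "unassigned"
  assigned <- which(catalogue$status == "unique")
  if (length(assigned)) {
    gi <- annotation$genes[match(catalogue$gene_id[assigned],
                                 annotation$genes$gene_id), ]
    catalogue$location[assigned] <- classify_location(
      catalogue$start[assigned], catalogue$end[assigned],
      gi$cds_min_start, gi$cds_max_stop)
  }
  catalogue
}

#' Classify intron location relative to the coding region
#'
#' Uses the extreme CDS coordinates of the host gene (minimum CDS start and
#' maximum CDS end across isoforms). Introns strictly upstream or downstream
#' of these extremes interrupt untranslated regions; all others -- including
#' introns straddling an extreme -- are coding-region introns. Genes without
#' CDS features yield `"non-coding gene"`.
#'
#' @param start,end Intron interval (first/last intronic base), vectorised.
#' @param cds_min_start,cds_max_stop Gene CDS extremes (NA for non-coding
#'   genes), recycled along the introns.
#' @return Character vector: `"coding-region"`, `"UTR"` or
#'   `"non-coding gene"`.
#' @export
classify_location <- function(start, end, cds_min_start, cds_max_stop) {
  out <- data.table::fifelse(
    is.na(cds_min_start) | is.na(cds_max_stop), "non-coding gene",
    data.table::fifelse(end < cds_min_start | start > cds_max_stop,
                        "UTR", "coding-region"))
  out
}

#' Build the species-level intron catalogue from alignment files
#'
#' Streams every sample, applies the read-level filters, pools discovery-
#' grade junction observations, and merges them with the annotated introns.
#'
#' @param sample_paths Character vector of SAM/BAM paths.
#' @param genome A `DNAStringSet`.
#' @param annotation A [load_annotation()] result.
#' @param cfg A [filter_config()].
#' @return A catalogue `data.table` (see [discover_introns()]).
#' @export
build_catalog <- function(sample_paths, genome, annotation,
                          cfg = filter_config()) {
  jn <- data.table::rbindlist(lapply(sample_paths, function(p) {
    reads <- passes_read_filters(read_alignments(p), cfg)
    dec <- decompose_alignments(reads[reads$pass, ],
                                max_intron_length = cfg$max_intron_length)
    dec$junctions
  }))
  if (nrow(jn) == 0)
    jn <- data.table::data.table(chrom = character(), start = integer(),
                                 end = integer(), left_anchor = integer(),
                                 right_anchor = integer())
  discover_introns(jn, genome, annotation, cfg)
}
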