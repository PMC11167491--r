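#' Simulation configuration
#'
#' Parameters of the synthetic ground-truthed data generator. The generator
#' emits a random genome, a matching GFF3 annotation (gene/mRNA/exon/CDS), a
#' BUSCO-to-gene map, a per-intron truth table (including the true spliced
#' fraction `f`), and per-sample pre-aligned SAM reads: junction-spanning
#' reads with probability `f` and co-linear intron-retaining reads with
#' probability `1 - f` (one read per intron boundary per retention event, so
#' that `Nu/2` estimates the retention rate). Alignment is outside the
#' toolkit's scope, so reads are emitted directly as minimal standard SAM
#' (with `@SQ` header lines, NH and NM tags).
#'
#' @param seed Integer seed governing every random choice.
#' @param n_genes Number of genes.
#' @param exons_per_gene Integer range (min, max) of exons per gene.
#' @param exon_length,intron_length Ranges (bp).
#' @param signal_mix Named proportions over GT-AG / GC-AG / AT-AC (sum 1).
#' @param f_range True spliced fraction range; each intron draws `f`
#'   uniformly from it (a single value may be given as `c(f, f)`).
#' @param alt_boundary_prob Probability that an intron also has an
#'   alternative-donor variant (shifted 5' boundary).
#' @param annotate_variant_prob Probability that such a variant is written to
#'   the GFF3 as a second transcript; unannotated variants are still
#'   expressed in the reads and must be discovered from junctions alone.
#' @param alt_expression Junction depth of the variant intron relative to
#'   the main intron's spliced depth.
#' @param read_length Read length (bp).
#' @param per_intron_depth Expected number of transcript "events" (spliced
#'   or retained) sampled per intron per sample.
#' @param n_samples Number of samples.
#' @param busco_fraction Fraction of genes flagged as BUSCO orthologs.
#' @param minus_strand_prob Probability a gene lies on the minus strand.
#' @param decoy_multi_prob Fraction of extra multi-mapped (NH=2) decoy reads.
#' @param decoy_mismatch_prob Fraction of extra high-mismatch decoy reads.
#' @param short_anchor_prob Probability a junction read draws a short (4-7
#'   bp) anchor, exercising the discovery/quantification anchor thresholds.
#' @param intergenic_length Range of intergenic spacer lengths (bp).
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 20L,
                              exons_per_gene = c(2L, 5L),
                              exon_length = c(80L, 250L),
                              intron_length = c(60L, 300L),
                              signal_mix = c("GT-AG" = 0.96, "GC-AG" = 0.03,
                                             "AT-AC" = 0.01),
                              f_range = c(0.05, 0.95),
                              alt_boundary_prob = 0.15,
                              annotate_variant_prob = 0.5,
                              alt_expression = 0.25,
                              read_length = 100L,
                              per_intron_depth = 50L,
                              n_samples = 1L,
                              busco_fraction = 0.5,
                              minus_strand_prob = 0.4,
                              decoy_multi_prob = 0,
                              decoy_mismatch_prob = 0,
                              short_anchor_prob = 0.02,
                              intergenic_length = c(200L, 400L)) {
  stopifnot(abs(sum(signal_mix) - 1) < 1e-8,
            all(exon_length > 0), all(intron_length >= 20),
            f_range[1] >= 0, f_range[2] <= 1,
            read_length >= 40)
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  cfg
}

.rint <- function(n, range) {
  if (range[1] == range[2]) rep(as.integer(range[1]), n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

.signal_dinucs <- function(signal, strand) {
  # genomic forward-strand dinucleotides at the intron's first/last two bases
  parts <- strsplit(signal, "-")[[1]]
  if (strand == "+") c(parts[1], parts[2])
  else {
    rc <- function(x) as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(x)))
    c(rc(parts[2]), rc(parts[1]))
  }
}

#' Simulate a genome, annotation, BUSCO map and intron truth table
#'
#' @param cfg A [simulation_config()].
#' @return A list of class `"simulated_genome"`: `genome` (DNAStringSet),
#'   `gff` (data.table of GFF3 fields), `busco` (data.table), `truth`
#'   (data.table: one row per annotated intron with gene, strand, signal,
#'   true `f`, and whether it is the alternative-boundary variant of another
#'   intron).
#' @export
simulate_genome_annotation <- function(cfg = simulation_config()) {
  set.seed(cfg$seed)
  chrom <- "chr1"
  seq_parts <- list()
  gff <- list()
  truth <- list()
  pos <- 1L
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

  for (g in seq_len(cfg$n_genes)) {
    gid <- sprintf("gene%03d", g)
    strand <- if (stats::runif(1) < cfg$minus_strand_prob) "-" else "+"
    n_ex <- .rint(1, cfg$exons_per_gene)
    ex_len <- .rint(n_ex, cfg$exon_length)
    in_len <- if (n_ex > 1) .rint(n_ex - 1, cfg$intron_length) else integer(0)

    gap <- .rint(1, cfg$intergenic_length)
    seq_parts[[length(seq_parts) + 1L]] <- rand_seq(gap)
    pos <- pos + gap

    ex_start <- integer(n_ex); ex_end <- integer(n_ex)
    p <- pos
    for (i in seq_len(n_ex)) {
      ex_start[i] <- p; ex_end[i] <- p + ex_len[i] - 1L
      seq_parts[[length(seq_parts) + 1L]] <- rand_seq(ex_len[i])
      p <- ex_end[i] + 1L
      if (i < n_ex) {
        sig <- sample(names(cfg$signal_mix), 1, prob = cfg$signal_mix)
        din <- .signal_dinucs(sig, strand)
        body <- rand_seq(in_len[i] - 4L)
        seq_parts[[length(seq_parts) + 1L]] <- paste0(din[1], body, din[2])
        istart <- p; iend <- p + in_len[i] - 1L
        truth[[length(truth) + 1L]] <- data.table::data.table(
          gene_id = gid, chrom = chrom, start = istart, end = iend,
          strand = strand, signal = sig,
          f = stats::runif(1, cfg$f_range[1], cfg$f_range[2]),
          is_variant = FALSE, annotated = TRUE, variant_of = NA_character_)
        p <- iend + 1L
      }
    }
    pos <- p
    gene_start <- ex_start[1]; gene_end <- ex_end[n_ex]

    # CDS extremes leave short UTR margins inside the terminal exons
    utr5 <- min(30L, ex_len[1] %/% 3L)
    utr3 <- min(30L, ex_len[n_ex] %/% 3L)
    cds_lo <- gene_start + utr5
    cds_hi <- gene_end - utr3

    tid <- paste0(gid, ".t1")
    gff[[length(gff) + 1L]] <- data.table::data.table(
      seqid = chrom, type = "gene", start = gene_start, end = gene_end,
      strand = strand, attr = sprintf("ID=%s", gid))
    gff[[length(gff) + 1L]] <- data.table::data.table(
      seqid = chrom, type = "mRNA", start = gene_start, end = gene_end,
      strand = strand, attr = sprintf("ID=%s;Parent=%s", tid, gid))
    for (i in seq_len(n_ex)) {
      gff[[length(gff) + 1L]] <- data.table::data.table(
        seqid = chrom, type = "exon", start = ex_start[i], end = ex_end[i],
        strand = strand, attr = sprintf("Parent=%s", tid))
      cs <- max(ex_start[i], cds_lo); ce <- min(ex_end[i], cds_hi)
      if (cs <= ce)
        gff[[length(gff) + 1L]] <- data.table::data.table(
          seqid = chrom, type = "CDS", start = cs, end = ce,
          strand = strand, attr = sprintf("Parent=%s", tid))
    }

    # optional alternative-donor variant transcript for one internal intron
    if (n_ex > 1 && stats::runif(1) < cfg$alt_boundary_prob) {
      i <- sample(n_ex - 1L, 1L)
      main <- truth[[length(truth) - (n_ex - 1L) + i]]
      shift <- 12L
      if (main$end - (main$start + shift) + 1L >= 20L) {
        vstart <- main$start + shift
        # write the variant donor dinucleotide inside the main intron body
        din <- .signal_dinucs(main$signal, strand)
        part <- seq_parts[[length(seq_parts) - 2L * (n_ex - 1L - i) - 1L]]
        substr(part, shift + 1L, shift + 2L) <- din[1]
        seq_parts[[length(seq_parts) - 2L * (n_ex - 1L - i) - 1L]] <- part
        ann_var <- stats::runif(1) < cfg$annotate_variant_prob
        if (ann_var) {
          tid2 <- paste0(gid, ".t2")
          gff[[length(gff) + 1L]] <- data.table::data.table(
            seqid = chrom, type = "mRNA", start = gene_start, end = gene_end,
            strand = strand, attr = sprintf("ID=%s;Parent=%s", tid2, gid))
          for (j in seq_len(n_ex)) {
            es <- ex_start[j]
            ee <- if (j == i) ex_end[j] + shift else ex_end[j]
            gff[[length(gff) + 1L]] <- data.table::data.table(
              seqid = chrom, type = "exon", start = es, end = ee,
              strand = strand, attr = sprintf("Parent=%s", tid2))
          }
        }
        truth[[length(truth) + 1L]] <- data.table::data.table(
          gene_id = gid, chrom = chrom, start = vstart, end = main$end,
          strand = strand, signal = main$signal, f = NA_real_,
          is_variant = TRUE, annotated = ann_var,
          variant_of = sprintf("%s:%d-%d", chrom, main$start, main$end))
      }
    }
  }
  seq_parts[[length(seq_parts) + 1L]] <- rand_seq(200L)

  genome <- Biostrings::DNAStringSet(paste(unlist(seq_parts), collapse = ""))
  names(genome) <- chrom
  truth <- data.table::rbindlist(truth)
  gff <- data.table::rbindlist(gff)

  busco_genes <- sort(sample(sprintf("gene%03d", seq_len(cfg$n_genes)),
                             round(cfg$busco_fraction * cfg$n_genes)))
  busco <- data.table::data.table(
    gene_id = busco_genes,
    busco_id = sprintf("BUSCO%04d", seq_along(busco_genes)),
    set = "eukaryota")

  out <- list(genome = genome, gff = gff, busco = busco, truth = truth,
              cfg = cfg)
  class(out) <- "simulated_genome"
  out
}

#' Write a simulated annotation as GFF3
#' @param sim A [simulate_genome_annotation()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_simulated_gff3 <- function(sim, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t.\t%s",
                     sim$gff$seqid, sim$gff$type, sim$gff$start, sim$gff$end,
                     sim$gff$strand, sim$gff$attr))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate per-sample spliced reads as SAM records
#'
#' For every non-variant intron, `per_intron_depth` transcript events are
#' sampled: with probability `f` the event is spliced and yields one
#' junction-spanning read (CIGAR `aM nN bM`), otherwise it is an intron
#' retention and yields one co-linear read over each intron boundary
#' (spanning well beyond the 10 bp flanks). Variant introns receive
#' junction reads at `alt_expression` times the focal intron's spliced
#' depth. Optional decoy reads (multi-mapped NH=2, or high-mismatch) and
#' occasional short anchors exercise the read filters.
#'
#' @param sim A [simulate_genome_annotation()] result.
#' @param sample_id Sample label (also the SAM read-name prefix).
#' @param seed Integer seed for this sample.
#' @return A `data.table` of SAM fields (`qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `seq`, `nm`, `nh`).
#' @export
simulate_reads <- function(sim, sample_id = "s1", seed = sim$cfg$seed + 1L) {
  set.seed(seed)
  cfg <- sim$cfg
  rl <- cfg$read_length
  genome <- sim$genome
  chrom <- names(genome)[1]
  glen <- Biostrings::width(genome)[1]
  recs <- vector("list", 4096L); nr <- 0L
  push <- function(pos, cigar, seqstr, nm = 0L, nh = 1L) {
    nr <<- nr + 1L
    if (nr > length(recs)) length(recs) <<- 2L * nr
    recs[[nr]] <<- list(pos = pos, cigar = cigar, seq = seqstr,
                        nm = nm, nh = nh)
  }
  gseq <- function(s, e) genome_sequence(genome, chrom, s, e)

  junction_read <- function(istart, iend, nh = 1L, nm = 0L, short = FALSE) {
    ilen <- iend - istart + 1L
    a <- if (short) sample(4:7, 1L) else sample(10:(rl - 10L), 1L)
    b <- rl - a
    pos <- istart - a
    if (pos < 1L || iend + b > glen) return(invisible(NULL))
    seqstr <- paste0(gseq(pos, istart - 1L), gseq(iend + 1L, iend + b))
    push(pos, sprintf("%dM%dN%dM", a, ilen, b), seqstr, nm = nm, nh = nh)
  }
  colinear_read <- function(boundary) {
    # cover [boundary-9, boundary+10] contiguously with margin
    off <- sample(0:(rl - 21L), 1L)
    pos <- boundary - 10L - off + 1L
    if (pos < 1L || pos + rl - 1L > glen) return(invisible(NULL))
    push(pos, sprintf("%dM", rl), gseq(pos, pos + rl - 1L))
  }

  main <- sim$truth[!sim$truth$is_variant, ]
  for (i in seq_len(nrow(main))) {
    istart <- main$start[i]; iend <- main$end[i]; f <- main$f[i]
    spliced <- stats::rbinom(1L, cfg$per_intron_depth, f)
    retained <- cfg$per_intron_depth - spliced
    for (k in seq_len(spliced))
      junction_read(istart, iend,
                    short = stats::runif(1) < cfg$short_anchor_prob)
    for (k in seq_len(retained)) {
      colinear_read(istart - 1L)
      colinear_read(iend)
    }
    if (cfg$decoy_multi_prob > 0 && stats::runif(1) < cfg$decoy_multi_prob)
      junction_read(istart, iend, nh = 2L)
    if (cfg$decoy_mismatch_prob > 0 && stats::runif(1) < cfg$decoy_mismatch_prob)
      junction_read(istart, iend, nm = as.integer(ceiling(0.03 * rl)))
  }
  vars <- sim$truth[sim$truth$is_variant, ]
  for (i in seq_len(nrow(vars))) {
    key <- vars$variant_of[i]
    mf <- main$f[match(key, sprintf("%s:%d-%d", main$chrom, main$start, main$end))]
    nvar <- stats::rbinom(1L, cfg$per_intron_depth,
                          min(1, cfg$alt_expression * mf))
    for (k in seq_len(nvar)) junction_read(vars$start[i], vars$end[i])
  }

  if (nr == 0L)
    return(data.table::data.table(qname = character(), flag = integer(),
                                  rname = character(), pos = integer(),
                                  mapq = integer(), cigar = character(),
                                  seq = character(), nm = integer(),
                                  nh = integer()))
  recs <- recs[seq_len(nr)]
  data.table::data.table(
    qname = sprintf("%s.r%06d", sample_id, seq_len(nr)),
    flag = 0L,
    rname = chrom,
    pos = vapply(recs, `[[`, numeric(1), "pos"),
    mapq = 60L,
    cigar = vapply(recs, `[[`, character(1), "cigar"),
    seq = vapply(recs, `[[`, character(1), "seq"),
    nm = vapply(recs, function(r) as.integer(r$nm), integer(1)),
    nh = vapply(recs, function(r) as.integer(r$nh), integer(1)))
}

#' Write simulated reads as a SAM file
#' @param reads A `data.table` from [simulate_reads()].
#' @param genome The `DNAStringSet` the reads were simulated from (for the
#'   `@SQ` header).
#' @param path Output `.sam` path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                   Biostrings::width(genome)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tNM:i:%d\tNH:i:%d",
                  reads$qname, reads$flag, reads$rname, reads$pos, reads$mapq,
                  reads$cigar, reads$seq, reads$nm, reads$nh)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate a complete dataset on disk
#'
#' Writes `genome.fa`, `annotation.gff3`, `busco_map.tab`, `truth.tab` and
#' one `sample_NN.sam` per sample into `out_dir`. Byte-identical for
#' identical seeds.
#'
#' @param cfg A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @return A list of file paths plus the in-memory `sim` object, invisibly.
#' @export
simulate_dataset <- function(cfg = simulation_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_genome_annotation(cfg)
  fa <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(sim$genome, fa)
  gff <- write_simulated_gff3(sim, file.path(out_dir, "annotation.gff3"))
  busco <- file.path(out_dir, "busco_map.tab")
  data.table::fwrite(sim$busco, busco, sep = "\t")
  truth <- file.path(out_dir, "truth.tab")
  data.table::fwrite(sim$truth, truth, sep = "\t")
  sams <- character(cfg$n_samples)
  for (s in seq_len(cfg$n_samples)) {
    sid <- sprintf("sample_%02d", s)
    reads <- simulate_reads(sim, sid, seed = cfg$seed + s)
    sams[s] <- file.path(out_dir, paste0(sid, ".sam"))
    write_sam(reads, sim$genome, sams[s])
  }
  invisible(list(genome = fa, gff3 = gff, busco = busco, truth = truth,
                 samples = sams, sim = sim))
}
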