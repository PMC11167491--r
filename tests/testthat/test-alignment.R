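test_that("read filters pass/reject on mismatch fraction and uniqueness", {
  cfg <- filter_config()
  rds <- reads_table(
    sam_record("ok", cigar = "100M", nm = 2L, nh = 1L),
    sam_record("mm", cigar = "100M", nm = 3L, nh = 1L),
    sam_record("multi", cigar = "100M", nm = 0L, nh = 2L),
    sam_record("sec", flag = 256L, cigar = "100M"),
    sam_record("unmap", flag = 4L, cigar = "100M"))
  fr <- passes_read_filters(rds, cfg)
  expect_equal(fr$pass, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(fr$reason[2:5],
               c("mismatch-fraction", "not-unique", "secondary", "unmapped"))
})

test_that("mismatch denominator is the aligned length, soft clips excluded", {
  cfg <- filter_config()
  # 10S90M with NM=2: 2/90 > 0.02 on aligned length
  fr <- passes_read_filters(reads_table(
    sam_record("a", cigar = "10S90M", nm = 2L)), cfg)
  expect_false(fr$pass)
  # full-read denominator accepts it (2/100 = 0.02)
  cfg2 <- filter_config(mismatch_denominator = "read")
  fr2 <- passes_read_filters(reads_table(
    sam_record("a", cigar = "10S90M", nm = 2L)), cfg2)
  expect_true(fr2$pass)
})

test_that("missing NM follows the configured policy and MAPQ backs up NH", {
  rds <- reads_table(sam_record("a", cigar = "100M", nm = NA_integer_,
                                nh = NA_integer_, mapq = 60L))
  expect_equal(passes_read_filters(rds, filter_config())$reason, "no-NM")
  expect_true(passes_read_filters(rds,
    filter_config(missing_nm_policy = "zero"))$pass)
  low <- reads_table(sam_record("a", cigar = "100M", nh = NA_integer_,
                                mapq = 10L))
  expect_equal(passes_read_filters(low, filter_config())$reason, "not-unique")
})

test_that("junction extraction matches the CIGAR worked examples", {
  dec <- decompose_alignments(reads_table(
    sam_record("a", pos = 100L, cigar = "10M50N10M")))
  expect_equal(dec$junctions$start, 110L)
  expect_equal(dec$junctions$end, 159L)
  expect_equal(dec$junctions$left_anchor, 10L)
  expect_equal(dec$junctions$right_anchor, 10L)

  dec2 <- decompose_alignments(reads_table(
    sam_record("b", pos = 100L, cigar = "10M50N20M30N10M")))
  expect_equal(dec2$junctions$start, c(110L, 180L))
  expect_equal(dec2$junctions$end, c(159L, 209L))
  expect_equal(dec2$junctions$left_anchor, c(10L, 20L))
  expect_equal(dec2$junctions$right_anchor, c(20L, 10L))

  # soft clip consumes no reference and contributes no anchor
  dec3 <- decompose_alignments(reads_table(
    sam_record("c", pos = 100L, cigar = "5S10M50N10M")))
  expect_equal(dec3$junctions$start, 110L)
  expect_equal(dec3$junctions$left_anchor, 10L)
})

test_that("N at a read edge is a malformed record", {
  expect_error(decompose_alignments(reads_table(
    sam_record("bad", cigar = "50N10M"))), "malformed")
  expect_error(decompose_alignments(reads_table(
    sam_record("bad2", cigar = "10M50N"))), "malformed")
})

test_that("junctions and blocks partition the reference span (per-base oracle)", {
  set.seed(21)
  ops_pool <- c("M", "N", "M", "D", "M", "I", "S")
  for (rep in 1:30) {
    # random plausible spliced CIGAR
    n_j <- sample(0:2, 1)
    parts <- c(sprintf("%dM", sample(5:40, 1)))
    for (j in seq_len(n_j))
      parts <- c(parts, sprintf("%dN", sample(30:200, 1)),
                 sprintf("%dM", sample(5:40, 1)))
    cigar <- paste(parts, collapse = "")
    pos <- sample(1000:5000, 1)
    dec <- decompose_alignments(reads_table(sam_record("r", pos = pos,
                                                       cigar = cigar)))
    w <- oracle_walk(pos, cigar)
    block_pos <- unlist(mapply(seq, dec$blocks$start, dec$blocks$end,
                               SIMPLIFY = FALSE))
    expect_equal(sort(block_pos), sort(w$covered))
    jn_pos <- if (nrow(dec$junctions)) unlist(mapply(
      seq, dec$junctions$start, dec$junctions$end, SIMPLIFY = FALSE)) else integer(0)
    span <- seq(pos, pos + sum(w$seg_spans) +
                  sum(vapply(w$junctions, function(j) j[2] - j[1] + 1L,
                             integer(1))) - 1L)
    expect_equal(sort(c(block_pos, jn_pos)), span)
    expect_equal(dec$aligned_len, w$aligned)
  }
})

test_that("anchors are mirror-symmetric under CIGAR reversal", {
  set.seed(5)
  for (rep in 1:10) {
    a <- sample(5:30, 1); b <- sample(5:30, 1); n <- sample(50:200, 1)
    fwd <- decompose_alignments(reads_table(
      sam_record("f", pos = 100L, cigar = sprintf("%dM%dN%dM", a, n, b))))
    rev <- decompose_alignments(reads_table(
      sam_record("r", pos = 100L, cigar = sprintf("%dM%dN%dM", b, n, a))))
    expect_equal(fwd$junctions$left_anchor, rev$junctions$right_anchor)
    expect_equal(fwd$junctions$right_anchor, rev$junctions$left_anchor)
  }
})

test_that("junction extraction agrees with GenomicAlignments on simulated reads", {
  skip_if_not_installed("GenomicAlignments")
  sim <- simulate_genome_annotation(simulation_config(seed = 9, n_genes = 5))
  reads <- simulate_reads(sim, "s1", seed = 10)
  rt <- data.table::data.table(read_id = reads$qname, flag = reads$flag,
                               chrom = reads$rname, pos = as.integer(reads$pos),
                               mapq = reads$mapq, cigar = reads$cigar,
                               nm = reads$nm, nh = reads$nh, sample_id = "s1")
  dec <- decompose_alignments(rt)
  ga <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    rt$cigar, pos = rt$pos, ops = "N")
  flat <- unlist(ga)
  idx <- rep(seq_along(ga), lengths(ga))
  ref <- data.table::data.table(ridx = idx,
                                start = IRanges::start(flat),
                                end = IRanges::end(flat))
  got <- dec$junctions[, c("ridx", "start", "end"), with = FALSE]
  data.table::setorder(ref, ridx, start); data.table::setorder(got, ridx, start)
  expect_equal(as.data.frame(got), as.data.frame(ref))
})

test_that("overlong junctions are discarded at extraction", {
  dec <- decompose_alignments(reads_table(
    sam_record("a", pos = 100L, cigar = "10M2000001N10M")))
  expect_equal(nrow(dec$junctions), 0L)
  expect_equal(attr(dec, "n_overlong"), 1L)
  dec2 <- decompose_alignments(reads_table(
    sam_record("a", pos = 100L, cigar = "10M2000000N10M")))
  expect_equal(nrow(dec2$junctions), 1L)
})

test_that("covers_junction_unspliced requires a contiguous window", {
  expect_true(covers_junction_unspliced(list(pos = 95L, cigar = "30M"), 109L, 10L))
  expect_false(covers_junction_unspliced(list(pos = 101L, cigar = "30M"), 109L, 10L))
  expect_false(covers_junction_unspliced(list(pos = 95L, cigar = "10M50N10M"),
                                         109L, 10L))
})

test_that("filter decisions are order-independent and match the oracle", {
  set.seed(31)
  for (rep in 1:40) {
    rec <- sam_record("r",
                      flag = sample(c(0L, 4L, 256L), 1, prob = c(.8, .1, .1)),
                      mapq = sample(c(1L, 60L), 1),
                      cigar = sprintf("%dM", sample(50:150, 1)),
                      nm = sample(c(NA, 0:4), 1),
                      nh = sample(c(NA, 1L, 2L), 1))
    got <- passes_read_filters(reads_table(rec), filter_config())$pass
    expect_identical(got, oracle_pass(rec$flag, rec$mapq, rec$nm, rec$nh,
                                      rec$cigar))
  }
})
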