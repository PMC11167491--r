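test_that("Ns counts exact-match junctions with quantification-grade anchors", {
  catg <- fixture_catalogue(110, 159)
  jn <- data.table::data.table(
    chrom = "chr1", start = rep(110L, 14), end = rep(159L, 14),
    left_anchor = c(rep(10L, 12), 4L, 4L),
    right_anchor = c(rep(10L, 12), 20L, 20L))
  ns <- count_spliced(jn, catg, filter_config())
  expect_equal(as.integer(ns), 12L)
  expect_equal(attr(ns, "n_orphan"), 0L)

  # an observation matching no catalogue intron is an orphan
  jn2 <- data.table::data.table(chrom = "chr1", start = 500L, end = 700L,
                                left_anchor = 10L, right_anchor = 10L)
  ns2 <- count_spliced(jn2, catg, filter_config())
  expect_equal(as.integer(ns2), 0L)
  expect_equal(attr(ns2, "n_orphan"), 1L)
})

test_that("multi-junction reads contribute one count per junction", {
  catg <- fixture_catalogue(c(110, 180), c(159, 209))
  dec <- decompose_alignments(reads_table(
    sam_record("r", pos = 100L, cigar = "10M50N20M30N10M")))
  ns <- count_spliced(dec$junctions, catg, filter_config())
  expect_equal(as.integer(ns), c(1L, 1L))
})

test_that("Na sums Ns over introns sharing exactly one boundary", {
  catg <- fixture_catalogue(c(100, 100, 150), c(200, 250, 200))
  ns <- c(30L, 10L, 5L)
  expect_equal(count_alternative(catg, ns), c(15L, 30L, 30L))
  # identical intron is itself; no boundary sharers means zero
  expect_equal(count_alternative(fixture_catalogue(100, 200), 7L), 0L)
})

test_that("Nu adds both boundary windows; a spanning read contributes 2", {
  catg <- fixture_catalogue(200, 239)  # 40 bp intron
  # 4 reads over the left boundary only, 6 over the right only
  recs <- do.call(rbind, c(
    lapply(1:4, function(i) sam_record(paste0("L", i), pos = 185L, cigar = "30M")),
    lapply(1:6, function(i) sam_record(paste0("R", i), pos = 225L, cigar = "30M"))))
  q <- quantify_sample(reads_table(recs), catg)
  expect_equal(q$Nu, 10L)

  # one read spanning the whole intron with >= 10 bp on both outer sides
  span <- quantify_sample(reads_table(
    sam_record("S", pos = 185L, cigar = "70M")), catg)
  expect_equal(span$Nu, 2L)

  # no overlapping co-linear reads
  none <- quantify_sample(reads_table(
    sam_record("N", pos = 1000L, cigar = "50M")), catg)
  expect_equal(none$Nu, 0L)
})

test_that("a 9 bp flank does not count towards Nu", {
  catg <- fixture_catalogue(200, 400)
  # read covers 191..220: only 9 bp left of the 199|200 boundary
  q <- quantify_sample(reads_table(sam_record("r", pos = 191L, cigar = "30M")),
                       catg)
  expect_equal(q$Nu, 0L)
  q2 <- quantify_sample(reads_table(sam_record("r", pos = 190L, cigar = "30M")),
                        catg)
  expect_equal(q2$Nu, 1L)
})

test_that("ratio formulas and definedness thresholds are exact", {
  cfg <- filter_config()
  r <- splicing_ratios(9L, 1L, 0L, cfg)
  expect_equal(r$RAS, 0.9)
  expect_true(is.na(r$RANS))
  r2 <- splicing_ratios(5L, 4L, 0L, cfg)
  expect_true(is.na(r2$RAS))
  r3 <- splicing_ratios(10L, 0L, 20L, cfg)
  expect_equal(r3$RAS, 1.0)
  expect_equal(r3$RANS, 0.5)
})

test_that("ratios and classes match direct evaluation over the exhaustive grid", {
  grid <- expand.grid(ns = 0:30, na = 0:30, nu = 0:30)
  cfg <- filter_config()
  rt <- splicing_ratios(grid$ns, grid$na, grid$nu, cfg)
  cls <- classify_intron(rt$RAS, rt$RANS, cfg)
  idx <- seq_len(nrow(grid))
  exp <- lapply(idx, function(i) oracle_stats(grid$ns[i], grid$na[i], grid$nu[i]))
  expect_equal(rt$RAS, vapply(exp, `[[`, numeric(1), "ras"))
  expect_equal(rt$RANS, vapply(exp, `[[`, numeric(1), "rans"))
  expect_equal(cls, vapply(exp, `[[`, character(1), "class"))
  # partition: exactly one class each
  expect_true(all(cls %in% c("major", "minor", "unclassified")))
})

test_that("classification handles undefined ratios as unclassified", {
  cfg <- filter_config()
  expect_equal(classify_intron(0.9, 0.8, cfg), "major")
  expect_equal(classify_intron(0.9, 0.3, cfg), "minor")
  expect_equal(classify_intron(0.9, NA, cfg), "unclassified")
  expect_equal(classify_intron(NA, NA, cfg), "unclassified")
  expect_equal(classify_intron(NA, 0.2, cfg), "minor")
})

test_that("Ns conservation: catalogue total plus orphans equals qualifying observations", {
  cfg <- simulation_config(seed = 17, n_genes = 6, per_intron_depth = 30)
  d <- simulate_dataset(cfg, tempfile())
  genome <- read_genome(d$genome)
  ann <- load_annotation(d$gff3)
  catg <- build_catalog(d$samples, genome, ann)
  reads <- read_alignments(d$samples[1])
  fr <- passes_read_filters(reads, filter_config())
  dec <- decompose_alignments(fr[fr$pass, ], 2000000L)
  q <- quantify_sample(reads, catg)
  qualifying <- sum(pmin(dec$junctions$left_anchor,
                         dec$junctions$right_anchor) >= 5L)
  expect_equal(sum(q$Ns) + attr(q, "counts")$orphan_junctions, qualifying)
})

test_that("aggregated ratios use summed counts, not averaged ratios", {
  catg <- fixture_catalogue(110, 159)
  t1 <- data.table::copy(catg)[, c("sample_id", "Ns", "Na", "Nu", "discovered") :=
                                 list("s1", 3L, 0L, 4L, TRUE)]
  t2 <- data.table::copy(catg)[, c("sample_id", "Ns", "Na", "Nu", "discovered") :=
                                 list("s2", 9L, 0L, 2L, FALSE)]
  for (t in list(t1, t2)) {
    rt <- splicing_ratios(t$Ns, t$Na, t$Nu)
    t[, c("RAS", "RANS", "intron_class") :=
        list(rt$RAS, rt$RANS, classify_intron(rt$RAS, rt$RANS))]
  }
  agg <- aggregate_intron_counts(list(t1, t2))
  expect_equal(agg$Ns, 12L)
  expect_equal(agg$Nu, 6L)
  expect_equal(agg$RAS, 1.0)        # 12/(12+0), defined on sums
  expect_equal(agg$RANS, 12 / 15)   # 12/(12+3)
  expect_true(agg$discovered)
  # per-sample RANS were both undefined (denominators 5 and 10 -> s2 defined)
  expect_true(is.na(t1$RANS))
})

test_that("adding samples never turns a defined ratio undefined (monotonicity)", {
  set.seed(41)
  catg <- fixture_catalogue(110, 159)
  tabs <- lapply(1:5, function(s) {
    t <- data.table::copy(catg)
    t[, c("sample_id", "Ns", "Na", "Nu", "discovered") :=
        list(paste0("s", s), sample(0:6, 1), sample(0:3, 1), sample(0:8, 1),
             TRUE)]
    rt <- splicing_ratios(t$Ns, t$Na, t$Nu)
    t[, c("RAS", "RANS", "intron_class") :=
        list(rt$RAS, rt$RANS, classify_intron(rt$RAS, rt$RANS))]
    t
  })
  prev_ras_defined <- FALSE; prev_rans_defined <- FALSE
  for (k in 1:5) {
    agg <- aggregate_intron_counts(tabs[1:k])
    if (prev_ras_defined) expect_false(is.na(agg$RAS))
    if (prev_rans_defined) expect_false(is.na(agg$RANS))
    prev_ras_defined <- !is.na(agg$RAS)
    prev_rans_defined <- !is.na(agg$RANS)
  }
})

test_that("RANS recovers the simulated spliced fraction within binomial error", {
  cfg <- simulation_config(seed = 23, n_genes = 12, per_intron_depth = 400,
                           f_range = c(0.5, 0.5), alt_boundary_prob = 0,
                           exons_per_gene = c(2L, 2L))
  d <- simulate_dataset(cfg, tempfile())
  genome <- read_genome(d$genome)
  ann <- load_annotation(d$gff3)
  catg <- build_catalog(d$samples, genome, ann)
  q <- quantify_sample(d$samples[1], catg)
  m <- merge(q, d$sim$truth[, c("chrom", "start", "end", "f")],
             by = c("chrom", "start", "end"))
  ok <- vapply(seq_len(nrow(m)), function(i) {
    ci <- wilson_interval(m$Ns[i], m$Ns[i] + m$Nu[i] / 2)
    m$f[i] >= ci[1] && m$f[i] <= ci[2]
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})
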