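#' Read spliced alignments from SAM or BAM
#'
#' Loads the fields and tags needed by the pipeline (QNAME, FLAG, RNAME, POS,
#' MAPQ, CIGAR, NM, NH). Plain SAM files are converted on the fly with
#' [Rsamtools::asBam()]. Alignment itself is out of scope: the input is
#' expected to come from a spliced aligner such as HISAT2.
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @param sample_id Sample label attached to every record (default: file name
#'   without extension).
#' @return A `data.table` with one row per alignment record: `read_id`,
#'   `flag`, `chrom`, `pos` (1-based leftmost mapped base), `mapq`, `cigar`,
#'   `nm`, `nh`, `sample_id`.
#' @export
read_alignments <- function(path, sample_id = sub("\\.(sam|bam)$", "", basename(path),
                                                  ignore.case = TRUE)) {
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else path
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    tag = c("NM", "NH"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(b$qname)
  tag_int <- function(x) if (is.null(x)) rep(NA_integer_, n) else as.integer(x)
  data.table::data.table(
    read_id = b$qname,
    flag = as.integer(b$flag),
    chrom = as.character(b$rname),
    pos = as.integer(b$pos),
    mapq = as.integer(b$mapq),
    cigar = b$cigar,
    nm = tag_int(b$tag$NM),
    nh = tag_int(b$tag$NH),
    sample_id = sample_id)
}

#' Reference sequence names declared in a SAM/BAM header
#' @param path Path to a `.sam` or `.bam` file.
#' @return Character vector of `@SQ` sequence names.
#' @export
alignment_chroms <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    sq <- grep("^@SQ\t", lines, value = TRUE)
    vapply(strsplit(sq, "\t", fixed = TRUE), function(p) {
      sn <- p[startsWith(p, "SN:")]
      if (length(sn)) substring(sn[1], 4L) else NA_character_
    }, character(1))
  } else {
    names(Rsamtools::scanBamHeader(path)[[1]]$targets)
  }
}

.parse_cigar_ops <- function(cigar) {
  m <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))
  n_ops <- lengths(m)
  flat <- unlist(m, use.names = FALSE)
  data.table::data.table(
    idx = rep(seq_along(cigar), n_ops),
    len = as.integer(sub(".$", "", flat)),
    op = substring(flat, nchar(flat)))
}

#' Decompose alignments into aligned blocks and junction observations
#'
#' Walks each CIGAR string along the reference: `M`, `=`, `X` and `D`
#' operations extend the current aligned block, `N` operations close it and
#' open a junction (the skipped region of a spliced read). Anchors are the
#' reference spans of the aligned segments immediately flanking each
#' junction, measured up to the adjacent junction or the read end.
#'
#' @param reads A `data.table` as returned by [read_alignments()].
#' @param max_intron_length Junctions longer than this are dropped (their
#'   count is reported in the `n_overlong` attribute of the result).
#' @return A list with:
#'   \describe{
#'   \item{blocks}{`data.table` (`ridx` row index into `reads`, `seg` segment
#'     index, `start`, `end`) of contiguous reference-aligned blocks;}
#'   \item{junctions}{`data.table` (`ridx`, `chrom`, `start`, `end`,
#'     `left_anchor`, `right_anchor`, `read_id`, `sample_id`) with the
#'     first/last skipped base of each `N` operation;}
#'   \item{aligned_len}{per-read aligned length (sum of M/=/X);}
#'   \item{read_len}{per-read full read length (sum of read-consuming ops).}
#'   }
#' @export
decompose_alignments <- function(reads, max_intron_length = 2000000L) {
  idx <- len <- op <- ref <- ref_off <- seg <- start <- end <- NULL
  n <- nrow(reads)
  empty <- list(
    blocks = data.table::data.table(ridx = integer(), seg = integer(),
                                    start = integer(), end = integer()),
    junctions = data.table::data.table(ridx = integer(), chrom = character(),
                                       start = integer(), end = integer(),
                                       left_anchor = integer(),
                                       right_anchor = integer(),
                                       read_id = character(),
                                       sample_id = character()),
    aligned_len = integer(0), read_len = integer(0))
  if (n == 0) return(empty)

  cig <- reads$cigar
  cig[is.na(cig) | cig == "*"] <- ""
  ops <- .parse_cigar_ops(cig)
  bad <- !ops$op %in% c("M", "I", "D", "N", "S", "H", "P", "=", "X")
  if (any(bad)) stop("unsupported CIGAR operation: ", ops$op[bad][1])
  ops[, ref := op %chin% c("M", "D", "N", "=", "X")]
  ops[, ref_off := {rl <- ifelse(ref, len, 0L); cumsum(rl) - rl}, by = idx]

  al <- ops[, list(a = sum(len[op %chin% c("M", "=", "X")]),
                   r = sum(len[op %chin% c("M", "I", "S", "=", "X")])), by = idx]
  aligned_len <- read_len <- integer(n)
  aligned_len[al$idx] <- al$a
  read_len[al$idx] <- al$r

  refops <- ops[ref == TRUE]
  refops[, seg := cumsum(op == "N"), by = idx]
  pos <- reads$pos[refops$idx]
  refops[, c("rstart", "rend") := list(pos + ref_off, pos + ref_off + len - 1L)]

  blocks <- refops[op != "N",
                   list(start = min(rstart), end = max(rend)),
                   by = c("idx", "seg")]
  data.table::setnames(blocks, "idx", "ridx")

  jn <- refops[op == "N", list(ridx = idx, jidx = seg, start = rstart, end = rend)]
  if (nrow(jn) > 0) {
    # a junction must be flanked by an aligned block on each side
    left <- blocks[jn[, list(ridx, seg = jidx - 1L)], on = c("ridx", "seg")]
    right <- blocks[jn[, list(ridx, seg = jidx)], on = c("ridx", "seg")]
    if (anyNA(left$start) || anyNA(right$start))
      stop("malformed CIGAR: N operation at read edge or adjacent N ops (read ",
           reads$read_id[jn$ridx[which(is.na(left$start) | is.na(right$start))[1]]], ")")
    jn[, c("left_anchor", "right_anchor") := list(
      left$end - left$start + 1L, right$end - right$start + 1L)]
    jn[, c("chrom", "read_id", "sample_id") := list(
      reads$chrom[ridx], reads$read_id[ridx], reads$sample_id[ridx])]
    overlong <- jn$end - jn$start + 1L > max_intron_length
    n_overlong <- sum(overlong)
    jn <- jn[!overlong]
  } else {
    jn[, c("left_anchor", "right_anchor") := list(integer(0), integer(0))]
    jn[, c("chrom", "read_id", "sample_id") := list(character(0), character(0),
                                                    character(0))]
    n_overlong <- 0L
  }
  jn <- jn[, c("ridx", "chrom", "start", "end", "left_anchor", "right_anchor",
               "read_id", "sample_id"), with = FALSE]
  out <- list(blocks = blocks, junctions = jn,
              aligned_len = aligned_len, read_len = read_len)
  attr(out, "n_overlong") <- n_overlong
  out
}

#' Apply read-level filters
#'
#' A read passes when it is a mapped primary alignment, uniquely mapped
#' (NH == 1, or MAPQ at least the configured floor when NH is absent), and
#' its mismatch fraction `NM / aligned length` does not exceed the threshold.
#'
#' @param reads A `data.table` from [read_alignments()].
#' @param cfg A [filter_config()].
#' @return `reads` with logical column `pass` and character column `reason`
#'   (`NA` for passing reads; otherwise one of `"unmapped"`, `"secondary"`,
#'   `"not-unique"`, `"no-NM"`, `"mismatch-fraction"`).
#' @export
passes_read_filters <- function(reads, cfg = filter_config()) {
  reads <- data.table::copy(reads)
  n <- nrow(reads)
  if (n == 0) {
    reads[, c("pass", "reason") := list(logical(0), character(0))]
    return(reads)
  }
  dec <- decompose_alignments(reads, max_intron_length = .Machine$integer.max)
  denom <- if (cfg$mismatch_denominator == "aligned") dec$aligned_len else dec$read_len

  reason <- rep(NA_character_, n)
  unmapped <- bitwAnd(reads$flag, 0x4L) != 0L | is.na(reads$pos)
  secondary <- bitwAnd(reads$flag, 0x100L) != 0L | bitwAnd(reads$flag, 0x800L) != 0L
  if (cfg$unique_by == "nh") {
    not_unique <- data.table::fifelse(!is.na(reads$nh), reads$nh != 1L,
                                      reads$mapq < cfg$min_unique_mapq)
  } else {
    not_unique <- reads$mapq < cfg$min_unique_mapq
  }
  no_nm <- is.na(reads$nm) & cfg$missing_nm_policy == "reject"
  nm_eff <- data.table::fifelse(is.na(reads$nm), 0L, reads$nm)
  mm_frac <- nm_eff / pmax(denom, 1L)
  high_mm <- mm_frac > cfg$max_mismatch_fraction

  reason[high_mm] <- "mismatch-fraction"
  reason[no_nm] <- "no-NM"
  reason[not_unique] <- "not-unique"
  reason[secondary] <- "secondary"
  reason[unmapped] <- "unmapped"
  reads[, c("pass", "reason") := list(is.na(reason), reason)]
  reads
}

#' Does a read cover an exon-intron boundary co-linearly?
#'
#' True when the read has a contiguous aligned block covering
#' `[boundary - side_flank + 1, boundary + side_flank]` with no junction
#' inside the window. The boundary is the position of the last exonic base;
#' the junction lies between `boundary` and `boundary + 1`.
#'
#' @param read A one-row `data.table` from [read_alignments()] (or any list
#'   with `pos` and `cigar`).
#' @param boundary Reference position of the last exonic base.
#' @param side_flank Required flank on each side (bp).
#' @return Logical scalar.
#' @export
covers_junction_unspliced <- function(read, boundary, side_flank = 10L) {
  rd <- data.table::data.table(read_id = "r", chrom = "c", pos = read$pos,
                               cigar = read$cigar, sample_id = "s")
  dec <- decompose_alignments(rd)
  lo <- boundary - side_flank + 1L
  hi <- boundary + side_flank
  any(dec$blocks$start <= lo & dec$blocks$end >= hi)
}
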