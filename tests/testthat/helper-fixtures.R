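# Hand-built micro-fixtures used across the unit tests.

# Write a SAM file from a data.frame of records; returns the path.
fixture_sam <- function(records, chroms = c(chr1 = 100000L),
                        path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chroms), chroms))
  seqs <- if (!is.null(records$seq)) records$seq else
    vapply(records$cigar, function(cg) {
      n <- sum(as.integer(regmatches(cg, gregexpr("\\d+(?=[MIS=X])", cg,
                                                  perl = TRUE))[[1]]))
      strrep("A", max(n, 1L))
    }, character(1))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tNM:i:%d\tNH:i:%d",
                  records$read_id, records$flag, records$chrom, records$pos,
                  records$mapq, records$cigar, seqs, records$nm, records$nh)
  writeLines(c(hdr, body), path)
  path
}

sam_record <- function(read_id = "r1", flag = 0L, chrom = "chr1", pos = 100L,
                       mapq = 60L, cigar = "50M", nm = 0L, nh = 1L) {
  data.frame(read_id = read_id, flag = flag, chrom = chrom, pos = pos,
             mapq = mapq, cigar = cigar, nm = nm, nh = nh,
             stringsAsFactors = FALSE)
}

# A minimal in-memory reads table matching read_alignments() output.
reads_table <- function(...) {
  recs <- rbind(...)
  data.table::data.table(read_id = recs$read_id, flag = recs$flag,
                         chrom = recs$chrom, pos = recs$pos,
                         mapq = recs$mapq, cigar = recs$cigar,
                         nm = recs$nm, nh = recs$nh, sample_id = "s1")
}

# Write a GFF3 file from (type, start, end, strand, attr) rows on chr1.
fixture_gff3 <- function(rows, path = tempfile(fileext = ".gff3")) {
  lines <- c("##gff-version 3",
             sprintf("chr1\ttest\t%s\t%d\t%d\t.\t%s\t.\t%s",
                     rows$type, rows$start, rows$end, rows$strand, rows$attr))
  writeLines(lines, path)
  path
}

gff_row <- function(type, start, end, strand = "+", attr = "") {
  data.frame(type = type, start = start, end = end, strand = strand,
             attr = attr, stringsAsFactors = FALSE)
}

# A genome where chr1 is a supplied string (padded with A's to min_len).
fixture_genome <- function(chr1_seq, min_len = 1000L,
                           path = tempfile(fileext = ".fa")) {
  if (nchar(chr1_seq) < min_len)
    chr1_seq <- paste0(chr1_seq, strrep("A", min_len - nchar(chr1_seq)))
  g <- Biostrings::DNAStringSet(chr1_seq)
  names(g) <- "chr1"
  if (!is.null(path)) {
    Biostrings::writeXStringSet(g, path)
    attr(g, "path") <- path
  }
  g
}

# Genome string with specified dinucleotides at an intron's ends.
genome_with_intron <- function(istart, iend, donor = "GT", acceptor = "AG",
                               len = 2000L) {
  set.seed(42)
  s <- paste(sample(c("A", "C"), len, replace = TRUE), collapse = "")
  substr(s, istart, istart + 1L) <- donor
  substr(s, iend - 1L, iend) <- acceptor
  s
}

# Catalogue data.table from bare coordinates.
fixture_catalogue <- function(start, end, chrom = "chr1",
                              annotated = FALSE) {
  n <- length(start)
  data.table::data.table(
    chrom = rep(chrom, n), start = as.integer(start), end = as.integer(end),
    strand = rep("+", n), signal = rep("GT-AG", n),
    annotated = rep(annotated, length.out = n),
    gene_id = rep(NA_character_, n), status = rep("unassigned", n),
    location = rep("unassigned", n))
}
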