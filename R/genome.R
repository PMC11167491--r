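#' Load a genome FASTA
#'
#' Reads a (multi-)FASTA into a `DNAStringSet`, uppercased, with sequence
#' names truncated at the first whitespace (the convention used by aligners
#' and by GFF3 seqids).
#'
#' @param fasta_path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome <- function(fasta_path) {
  g <- Biostrings::readDNAStringSet(fasta_path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Fetch the sequence of a genomic interval
#'
#' 1-based, fully closed coordinates on the forward strand.
#'
#' @param genome A `DNAStringSet`.
#' @param chrom Sequence name.
#' @param start,end 1-based first and last base.
#' @return A character string of length `end - start + 1`.
#' @export
genome_sequence <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome))
    stop("chromosome not in genome: ", chrom)
  if (start < 1 || end > length(genome[[chrom]]) || end < start)
    stop(sprintf("interval out of range: %s:%d-%d", chrom, start, end))
  as.character(Biostrings::subseq(genome[[chrom]], start, end))
}

#' Donor/acceptor dinucleotides of an intron in both orientations
#'
#' Returns the first two and last two intronic bases read on the forward
#' strand, plus the reverse-complement reading, so the caller can decide the
#' splice-signal class and infer strand.
#'
#' @param genome A `DNAStringSet`.
#' @param chrom,start,end Intron interval; `start`/`end` are the first/last
#'   *intronic* bases.
#' @return A list with `fwd = c(donor, acceptor)` and `rev = c(donor,
#'   acceptor)` (the reverse-complement reading).
#' @export
splice_signal <- function(genome, chrom, start, end) {
  if (end - start + 1 < 4)
    return(list(fwd = c(NA_character_, NA_character_),
                rev = c(NA_character_, NA_character_)))
  donor <- genome_sequence(genome, chrom, start, start + 1L)
  acceptor <- genome_sequence(genome, chrom, end - 1L, end)
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  list(fwd = c(donor, acceptor), rev = c(rc(acceptor), rc(donor)))
}

CANONICAL_SIGNALS <- c("GT-AG", "GC-AG", "AT-AC")

#' Classify a splice signal and infer strand
#'
#' Checks the intron's terminal dinucleotides against the canonical classes
#' GT-AG, GC-AG and AT-AC in both orientations. A dinucleotide containing an
#' ambiguous base (N) never matches.
#'
#' @inheritParams splice_signal
#' @return A list with `signal` (one of `"GT-AG"`, `"GC-AG"`, `"AT-AC"`,
#'   `"none"`) and `strand` (`"+"`, `"-"`, or `"*"` when the signal matches in
#'   both orientations or in none).
#' @export
classify_signal <- function(genome, chrom, start, end) {
  ss <- splice_signal(genome, chrom, start, end)
  sig_of <- function(pair) {
    if (anyNA(pair) || grepl("[^ACGT]", paste0(pair[1], pair[2]))) return(NA_character_)
    key <- paste0(pair[1], "-", pair[2])
    key <- sub("GT-AG", "GT-AG", key)
    if (key %in% c("GT-AG", "GC-AG", "AT-AC")) key else NA_character_
  }
  f <- sig_of(ss$fwd)
  r <- sig_of(ss$rev)
  if (!is.na(f) && !is.na(r)) {
    # palindromic: canonical in both orientations, strand unresolved
    list(signal = f, strand = "*")
  } else if (!is.na(f)) {
    list(signal = f, strand = "+")
  } else if (!is.na(r)) {
    list(signal = r, strand = "-")
  } else {
    list(signal = "none", strand = "*")
  }
}
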