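# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: CIGARs are walked character by character, counts are
# accumulated with nested loops over per-base position sets.

# Walk one CIGAR string along the reference, one op at a time.
# Returns covered reference positions (M/=/X/D), junction intervals (N),
# per-segment reference spans, aligned length (M/=/X) and read length.
oracle_walk <- function(pos, cigar) {
  covered <- integer(0)
  junctions <- list()
  seg_spans <- integer(0)
  cur_span <- 0L
  aligned <- 0L
  readlen <- 0L
  p <- pos
  num <- ""
  for (ch in strsplit(cigar, "")[[1]]) {
    if (ch %in% as.character(0:9)) {
      num <- paste0(num, ch)
      next
    }
    n <- as.integer(num); num <- ""
    if (ch %in% c("M", "=", "X")) {
      covered <- c(covered, seq(p, p + n - 1L))
      cur_span <- cur_span + n
      aligned <- aligned + n
      readlen <- readlen + n
      p <- p + n
    } else if (ch == "D") {
      covered <- c(covered, seq(p, p + n - 1L))
      cur_span <- cur_span + n
      p <- p + n
    } else if (ch == "N") {
      junctions[[length(junctions) + 1L]] <- c(p, p + n - 1L)
      seg_spans <- c(seg_spans, cur_span)
      cur_span <- 0L
      p <- p + n
    } else if (ch %in% c("I", "S")) {
      readlen <- readlen + n
    } # H, P: nothing
  }
  seg_spans <- c(seg_spans, cur_span)
  list(covered = covered, junctions = junctions, seg_spans = seg_spans,
       aligned = aligned, readlen = readlen)
}

# Read-level filter decision, re-derived from first principles.
oracle_pass <- function(flag, mapq, nm, nh, cigar,
                        max_mm = 0.02, mapq_floor = 60L) {
  if (bitwAnd(flag, 0x4) != 0) return(FALSE)
  if (bitwAnd(flag, 0x100) != 0 || bitwAnd(flag, 0x800) != 0) return(FALSE)
  unique_ok <- if (!is.na(nh)) nh == 1 else mapq >= mapq_floor
  if (!unique_ok) return(FALSE)
  if (is.na(nm)) return(FALSE)
  w <- oracle_walk(1L, cigar)
  nm / w$aligned <= max_mm
}

# Brute-force Ns / Na / Nu for one sample against a catalogue data.frame
# with columns chrom, start, end. reads: data.frame with read_id, flag,
# chrom, pos, mapq, cigar, nm, nh.
oracle_counts <- function(reads, catalogue,
                          min_anchor_quant = 5L, flank = 10L,
                          max_mm = 0.02) {
  n <- nrow(catalogue)
  ns <- integer(n); nu <- integer(n)
  for (r in seq_len(nrow(reads))) {
    if (!oracle_pass(reads$flag[r], reads$mapq[r], reads$nm[r], reads$nh[r],
                     reads$cigar[r], max_mm = max_mm)) next
    w <- oracle_walk(reads$pos[r], reads$cigar[r])
    # spliced support
    for (j in seq_along(w$junctions)) {
      jc <- w$junctions[[j]]
      la <- w$seg_spans[j]; ra <- w$seg_spans[j + 1L]
      if (la < min_anchor_quant || ra < min_anchor_quant) next
      for (i in seq_len(n)) {
        if (catalogue$chrom[i] == reads$chrom[r] &&
            catalogue$start[i] == jc[1] && catalogue$end[i] == jc[2])
          ns[i] <- ns[i] + 1L
      }
    }
    # unspliced coverage of each boundary window
    for (i in seq_len(n)) {
      if (catalogue$chrom[i] != reads$chrom[r]) next
      for (boundary in c(catalogue$start[i] - 1L, catalogue$end[i])) {
        win <- seq(boundary - flank + 1L, boundary + flank)
        if (all(win %in% w$covered)) nu[i] <- nu[i] + 1L
      }
    }
  }
  # Na: pairwise boundary sharing
  na <- integer(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (catalogue$chrom[i] != catalogue$chrom[j]) next
    share_s <- catalogue$start[i] == catalogue$start[j]
    share_e <- catalogue$end[i] == catalogue$end[j]
    if (xor(share_s, share_e)) na[i] <- na[i] + ns[j]
  }
  list(ns = ns, na = na, nu = nu)
}

# Direct evaluation of the splicing ratios and the classification rules.
oracle_stats <- function(ns, na, nu) {
  ras <- if (ns + na >= 10) ns / (ns + na) else NA_real_
  rans <- if (ns + nu / 2 >= 10) ns / (ns + nu / 2) else NA_real_
  cls <- if (!is.na(ras) && !is.na(rans) && ras > 0.5 && rans > 0.5) "major"
  else if ((!is.na(ras) && ras <= 0.5) || (!is.na(rans) && rans <= 0.5)) "minor"
  else "unclassified"
  list(ras = ras, rans = rans, class = cls)
}

# Wilson score interval for a binomial proportion.
wilson_interval <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  c2 <- z^2 / n
  centre <- (p + c2 / 2) / (1 + c2)
  half <- z * sqrt(p * (1 - p) / n + c2 / (4 * n)) / (1 + c2)
  c(centre - half, centre + half)
}
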