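# Independent oracles and small fixture builders used across the suite.

# Naive per-position motif scan: double loop over windows and positions,
# substring comparison only. Returns integer total match counts per start
# column (1 .. window length). Deliberately independent of the package's
# character-matrix implementation.
naive_scan_counts <- function(seqs, motifs) {
  L <- nchar(seqs[1L])
  counts <- integer(L)
  for (s in seqs) {
    for (m in motifs) {
      k <- nchar(m)
      for (j in seq_len(L - k + 1L)) {
        if (substr(s, j, j + k - 1L) == m) counts[j] <- counts[j] + 1L
      }
    }
  }
  counts
}

random_windows <- function(n, len, seed,
                           alphabet = c("A", "C", "G", "T")) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
  structure(data.frame(name = sprintf("w%04d", seq_len(n)), seq = seqs,
                       stringsAsFactors = FALSE),
            flank = len %/% 2L, n_dropped = 0L,
            class = c("flank_windows", "data.frame"))
}

# Mirror a genome and its sites: reverse-complement every contig, remap
# coordinates pos -> L - 1 - pos (intervals: [L - end, L - start)), flip
# strands. Oriented windows, and hence profiles, must be unchanged.
mirror_genome <- function(genome) {
  out <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(genome))
  )
  names(out) <- names(genome)
  out
}

mirror_sites <- function(sites, genome) {
  L <- nchar(genome)[sites$chrom]
  data.frame(
    chrom = sites$chrom,
    start = as.integer(L - sites$end),
    end = as.integer(L - sites$start),
    name = sites$name,
    score = sites$score,
    strand = ifelse(sites$strand == "+", "-", "+"),
    stringsAsFactors = FALSE
  )
}

write_fasta_tmp <- function(lines) {
  f <- tempfile(fileext = ".fa")
  writeLines(lines, f)
  f
}

write_bed_tmp <- function(lines) {
  f <- tempfile(fileext = ".bed")
  writeLines(lines, f)
  f
}

toy_sites <- function(chrom, start, end, strand, score = 0) {
  n <- length(start)
  data.frame(chrom = rep_len(chrom, n), start = as.integer(start),
             end = as.integer(end), name = sprintf("s%03d", seq_len(n)),
             score = rep_len(score, n), strand = rep_len(strand, n),
             stringsAsFactors = FALSE)
}
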