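#' Consensus polyadenylation-signal hexamers
#'
#' The five consensus polyA-signal motifs scanned by default (DNA
#' alphabet): AATAAA, ATTAAA, AAATAA, ATAAAA, ATAAAT.
#'
#' @return Character vector of five hexamers.
#' @export
pas_motifs <- function() {
  c("AATAAA", "ATTAAA", "AAATAA", "ATAAAA", "ATAAAT")
}

validate_motifs <- function(motifs) {
  if (length(motifs) == 0L) stop("empty motif set")
  if (anyDuplicated(motifs)) stop("duplicate motif in motif set")
  if (any(nchar(motifs) < 4L)) stop("motifs must be at least 4 nt long")
  if (any(grepl("[^ACGT]", motifs)))
    stop("motifs must be uppercase DNA over A,C,G,T")
  invisible(motifs)
}

#' Anchor position of each binding site
#'
#' The anchor is the 5' end of the binding site in RNA orientation: the
#' `start` coordinate on the plus strand and `end - 1` on the minus strand
#' (0-based).
#'
#' @param sites Site `data.frame` (see [read_sites()]).
#' @return Integer vector of 0-based genomic anchor coordinates.
#' @export
anchor_position <- function(sites) {
  validate_sites(sites)
  ifelse(sites$strand == "+", sites$start, sites$end - 1L)
}

#' Extract oriented flanking windows around site anchors
#'
#' For every site, takes `flank` nt on each side of the anchor and returns
#' the sequence in the site's RNA 5'->3' orientation, so that increasing
#' offset always means transcriptionally downstream: plus-strand windows
#' are `genome[anchor - flank, anchor + flank)` (0-based half-open);
#' minus-strand windows are the reverse complement of
#' `genome[anchor - flank + 1, anchor + flank + 1)`. Offset 0 is the
#' anchor base itself; offsets run `-flank .. flank - 1`. Sites whose
#' window would cross a contig boundary are dropped (not padded) and
#' counted.
#'
#' @param sites Site `data.frame`.
#' @param genome Named character vector from [read_genome()].
#' @param flank Half-window size in nt (default 100).
#' @return Object of class `flank_windows`: a `data.frame` with columns
#'   `name`, `seq` (each of length `2 * flank`), plus attributes `flank`
#'   and `n_dropped`.
#' @export
extract_flanks <- function(sites, genome, flank = 100L) {
  validate_sites(sites)
  flank <- as.integer(flank)
  if (flank < 1L) stop("flank must be positive")
  miss <- setdiff(unique(sites$chrom), names(genome))
  if (length(miss)) stop("contig not in genome: ", miss[1L])

  anchor <- anchor_position(sites)
  clen <- nchar(genome)[sites$chrom]
  plus <- sites$strand == "+"
  # 0-based half-open genomic slice [lo, hi)
  lo <- ifelse(plus, anchor - flank, anchor - flank + 1L)
  hi <- lo + 2L * flank
  keep <- lo >= 0L & hi <= clen
  n_dropped <- sum(!keep)
  if (!any(keep)) stop("all ", length(keep), " sites dropped at contig edges")

  seqs <- substr(genome[sites$chrom[keep]], lo[keep] + 1L, hi[keep])
  mins <- !plus[keep]
  if (any(mins)) {
    seqs[mins] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[mins]))
    )
  }
  windows <- data.frame(name = sites$name[keep], seq = unname(seqs),
                        stringsAsFactors = FALSE)
  structure(windows, flank = flank, n_dropped = n_dropped,
            class = c("flank_windows", "data.frame"))
}

#' Scan one window for motif occurrences
#'
#' Reports every exact, possibly overlapping occurrence of every motif
#' whose full length lies inside the window, at its start offset relative
#' to the anchor. Several motifs may start at the same offset. `N` never
#' matches.
#'
#' @param seq Window sequence (length `2 * flank`).
#' @param motifs Character vector of motifs (default [pas_motifs()]).
#' @param flank Half-window size; offset 0 is position `flank + 1` of
#'   `seq`. Default: half the sequence length.
#' @return `data.frame` with columns `offset`, `motif`, sorted by offset.
#' @export
scan_motif_starts <- function(seq, motifs = pas_motifs(),
                              flank = nchar(seq) %/% 2L) {
  validate_motifs(motifs)
  hits <- lapply(motifs, function(m) {
    # lookahead regex finds overlapping occurrences
    st <- gregexpr(paste0("(?=", m, ")"), seq, perl = TRUE)[[1L]]
    st <- st[st > 0L]
    if (length(st) == 0L) return(NULL)
    data.frame(offset = st - 1L - flank, motif = m,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    return(data.frame(offset = integer(0), motif = character(0)))
  out[order(out$offset, out$motif), , drop = FALSE]
}

new_positional_profile <- function(offsets, raw_density,
                                   smoothed_density = NULL, z = NULL,
                                   n_sites = NA_integer_, meta = list()) {
  structure(
    list(offsets = as.integer(offsets),
         raw_density = as.numeric(raw_density),
         smoothed_density = if (is.null(smoothed_density)) NULL
                            else as.numeric(smoothed_density),
         z = if (is.null(z)) NULL else as.numeric(z),
         n_sites = n_sites, meta = meta),
    class = "positional_profile"
  )
}

#' @export
print.positional_profile <- function(x, ...) {
  cat("positional_profile: offsets", min(x$offsets), "..", max(x$offsets),
      "| n_sites", x$n_sites,
      "| total matches", round(sum(x$raw_density) * x$n_sites, 6), "\n")
  if (!is.null(x$z))
    cat("  permutation z: peak", format(max(x$z), digits = 4),
        "at offset", x$offsets[which.max(x$z)], "\n")
  invisible(x)
}

# Character matrix (n windows x window length), one base per cell.
window_char_matrix <- function(windows) {
  L <- unique(nchar(windows$seq))
  if (length(L) != 1L) stop("windows differ in length")
  matrix(unlist(strsplit(windows$seq, ""), use.names = FALSE),
         nrow = nrow(windows), ncol = L, byrow = TRUE)
}

# Per-window, per-start-column motif match counts. circular = TRUE counts
# matches that wrap around the window end (used by the permutation null).
match_count_matrix <- function(M, motifs, circular = FALSE) {
  n <- nrow(M); L <- ncol(M)
  counts <- matrix(0L, n, L)
  for (m in motifs) {
    k <- nchar(m)
    bases <- strsplit(m, "")[[1L]]
    last <- if (circular) L else L - k + 1L
    if (last < 1L) next
    ok <- matrix(TRUE, n, last)
    for (j in seq_len(k)) {
      col <- (seq_len(last) - 1L + j - 1L) %% L + 1L
      ok <- ok & (M[, col, drop = FALSE] == bases[j])
    }
    counts[, seq_len(last)] <- counts[, seq_len(last)] + ok
  }
  counts
}

#' Aggregate per-site motif density across windows
#'
#' Counts all motif occurrences at each offset across windows and
#' normalizes by the number of windows, giving occurrences per site at
#' each position relative to the anchor. Offsets where no full motif fits
#' (within `motif length - 1` of the downstream window end) report 0.
#'
#' @param windows A `flank_windows` object from [extract_flanks()].
#' @param motifs Motif set (default [pas_motifs()]).
#' @return A `positional_profile` with `raw_density` filled.
#' @export
aggregate_density <- function(windows, motifs = pas_motifs()) {
  stopifnot(inherits(windows, "flank_windows"))
  validate_motifs(motifs)
  if (nrow(windows) == 0L) stop("empty window list")
  flank <- attr(windows, "flank")
  if (flank < max(nchar(motifs)))
    stop("flank (", flank, ") smaller than the longest motif")
  M <- window_char_matrix(windows)
  counts <- match_count_matrix(M, motifs, circular = FALSE)
  new_positional_profile(
    offsets = seq_len(ncol(M)) - 1L - flank,
    raw_density = colSums(counts) / nrow(M),
    n_sites = nrow(M),
    meta = list(motifs = motifs, flank = flank)
  )
}

#' Smooth a positional profile with a centered moving average
#'
#' Centered moving average of width `w`; at the profile edges the window
#' truncates to the offsets that exist. `raw_density` is kept unchanged.
#' Applies to the raw density (and recomputes nothing else).
#'
#' @param profile A `positional_profile`.
#' @param w Odd window width (default 11).
#' @return The profile with `smoothed_density` filled.
#' @export
smooth_profile <- function(profile, w = 11L) {
  stopifnot(inherits(profile, "positional_profile"))
  w <- as.integer(w)
  n <- length(profile$offsets)
  if (w %% 2L == 0L) stop("smoothing window must be odd")
  if (w < 1L || w > n) stop("smoothing window must be in 1..", n)
  h <- (w - 1L) %/% 2L
  x <- profile$raw_density
  profile$smoothed_density <- vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
  profile$meta$smooth_w <- w
  profile
}

#' Offset of the profile peak
#'
#' Smallest offset attaining the maximum of the smoothed density (raw
#' density if the profile is unsmoothed). Ties resolve to the smallest
#' offset, deterministically.
#'
#' @param profile A `positional_profile`.
#' @return Integer offset.
#' @export
profile_argmax <- function(profile) {
  y <- if (is.null(profile$smoothed_density)) profile$raw_density
       else profile$smoothed_density
  profile$offsets[which.max(y)]
}

#' Permutation z-scores for a positional motif profile
#'
#' Builds a positional null by circularly rotating each window's sequence
#' by an independent uniform shift and re-aggregating, `n_perm` times.
#' Rotation preserves each window's base composition while destroying
#' positional structure. `z[o] = (obs[o] - mean_null[o]) / sd_null[o]`,
#' with `z = 0` wherever the null sd is 0 (including offsets where no full
#' motif fits). Reproducible for a given seed.
#'
#' @param windows A `flank_windows` object.
#' @param motifs Motif set.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed (mandatory).
#' @return A `positional_profile` with `raw_density` and `z` filled.
#' @export
permutation_z <- function(windows, motifs = pas_motifs(), n_perm = 1000L,
                          seed) {
  if (missing(seed)) stop("seed is required for the permutation null")
  n_perm <- as.integer(n_perm)
  if (n_perm < 100L) stop("n_perm must be at least 100")
  obs <- aggregate_density(windows, motifs)
  M <- window_char_matrix(windows)
  n <- nrow(M); L <- ncol(M)

  # Rotating a window by s and scanning linearly at start j is the same as
  # scanning the original window circularly at start (j + s) mod L, for
  # every j at which the motif still fits linearly. So one circular match
  # count per window serves all permutations.
  lens <- sort(unique(nchar(motifs)))
  circ <- lapply(lens, function(k) {
    match_count_matrix(M, motifs[nchar(motifs) == k], circular = TRUE)
  })

  set.seed(seed)
  null_sum <- numeric(L)
  null_sq <- numeric(L)
  for (p in seq_len(n_perm)) {
    s <- sample.int(L, n, replace = TRUE) - 1L
    tot <- numeric(L)
    for (gi in seq_along(lens)) {
      k <- lens[gi]
      last <- L - k + 1L
      G <- rowsum(circ[[gi]], group = s)
      shifts <- as.integer(rownames(G))
      for (r in seq_along(shifts)) {
        idx <- (seq_len(last) - 1L + shifts[r]) %% L + 1L
        tot[seq_len(last)] <- tot[seq_len(last)] + G[r, idx]
      }
    }
    d <- tot / n
    null_sum <- null_sum + d
    null_sq <- null_sq + d * d
  }
  mu <- null_sum / n_perm
  sdv <- sqrt(pmax(0, (null_sq - n_perm * mu * mu) / (n_perm - 1L)))
  z <- ifelse(sdv > 0, (obs$raw_density - mu) / sdv, 0)
  obs$z <- z
  obs$meta$n_perm <- n_perm
  obs$meta$seed <- seed
  obs
}

#' Positional density of one factor's sites around another's
#'
#' For each anchor site, counts the anchor positions of query sites at
#' every relative offset in `[-flank, flank - 1]`, measured in the anchor
#' site's RNA orientation (on the minus strand, offset = anchor position -
#' query position). Only pairs on the same contig and same strand are
#' counted. Density is normalized by the number of anchor sites; smooth
#' with [smooth_profile()] if desired.
#'
#' @param anchor_sites,query_sites Site `data.frame`s.
#' @param flank Half-window (default 100).
#' @return A `positional_profile`.
#' @export
cross_site_profile <- function(anchor_sites, query_sites, flank = 100L) {
  validate_sites(anchor_sites)
  validate_sites(query_sites)
  if (nrow(anchor_sites) == 0L || nrow(query_sites) == 0L)
    stop("empty site set")
  flank <- as.integer(flank)
  offsets <- seq.int(-flank, flank - 1L)
  counts <- integer(2L * flank)
  apos <- anchor_position(anchor_sites)
  qpos <- anchor_position(query_sites)
  akey <- paste(anchor_sites$chrom, anchor_sites$strand)
  qkey <- paste(query_sites$chrom, query_sites$strand)
  for (key in intersect(unique(akey), unique(qkey))) {
    a <- apos[akey == key]
    q <- qpos[qkey == key]
    minus <- endsWith(key, "-")
    d <- as.vector(outer(q, a, "-"))
    if (minus) d <- -d
    d <- d[d >= -flank & d <= flank - 1L]
    if (length(d))
      counts <- counts + tabulate(d + flank + 1L, nbins = 2L * flank)
  }
  new_positional_profile(
    offsets = offsets,
    raw_density = counts / nrow(anchor_sites),
    n_sites = nrow(anchor_sites),
    meta = list(kind = "cross_site", flank = flank)
  )
}
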