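#' Read a genome from a FASTA file
#'
#' Loads a (small) genome into memory as a named character vector of
#' uppercase sequences, one element per FASTA record. The contig id is the
#' header token before the first whitespace. Only the unambiguous DNA
#' alphabet plus `N` is accepted; `N` bases are retained (they never match
#' a motif) so coordinates are preserved.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector: contig id -> uppercase sequence over
#'   `A,C,G,T,N`.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (any(!nzchar(ids))) stop("empty contig id in FASTA header")
  if (anyDuplicated(ids)) {
    stop("duplicate contig id: ", ids[duplicated(ids)][1L])
  }
  # readDNAStringSet accepts the full IUPAC alphabet; restrict to A,C,G,T,N
  af <- Biostrings::alphabetFrequency(seqs, collapse = TRUE)
  bad <- af[!names(af) %in% c("A", "C", "G", "T", "N") & af > 0]
  if (length(bad) > 0) {
    stop("disallowed character in genome sequence: '", names(bad)[1L],
         "' (only A, C, G, T, N are accepted)")
  }
  out <- toupper(as.character(seqs))
  names(out) <- ids
  out
}

#' Write a genome to a FASTA file
#'
#' @param genome Named character vector as returned by [read_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Read binding sites from a BED6 file
#'
#' Parses a BED6 file of strand-aware binding-site intervals. Coordinates
#' are kept 0-based half-open, exactly as in the file, and record order is
#' preserved. Because the downstream analyses are orientation-critical,
#' strand must be `+` or `-`: a `.` strand is an error, never a default.
#'
#' @param path Path to a tab-separated BED file with at least 6 columns.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`; 0-based half-open intervals.
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stop("sites file not found: ", path)
  raw <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 6L) stop("BED6 required: found ", ncol(raw), " columns")
  sites <- data.frame(
    chrom  = raw[[1L]],
    start  = as.integer(raw[[2L]]),
    end    = as.integer(raw[[3L]]),
    name   = raw[[4L]],
    score  = as.numeric(raw[[5L]]),
    strand = raw[[6L]],
    stringsAsFactors = FALSE
  )
  validate_sites(sites)
  sites
}

#' Validate a site table
#'
#' Checks the SiteSet invariants: integer 0-based half-open intervals with
#' `start < end` and strand strictly `+` or `-`.
#'
#' @param sites Site `data.frame` (see [read_sites()]).
#' @return `sites`, invisibly, or an error.
#' @export
validate_sites <- function(sites) {
  need <- c("chrom", "start", "end", "name", "score", "strand")
  miss <- setdiff(need, names(sites))
  if (length(miss)) stop("site table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(is.na(sites$start)) || any(is.na(sites$end)))
    stop("non-integer start/end in site table")
  if (any(sites$start < 0L)) {
    stop("negative start at line ", which(sites$start < 0L)[1L])
  }
  bad <- which(sites$start >= sites$end)
  if (length(bad)) {
    stop("start >= end at line ", bad[1L],
         " (BED is 0-based half-open; intervals must be non-empty)")
  }
  badstr <- which(!sites$strand %in% c("+", "-"))
  if (length(badstr)) {
    stop("strand required ('+' or '-') at line ", badstr[1L],
         "; got '", sites$strand[badstr[1L]], "'")
  }
  invisible(sites)
}

#' Write binding sites to a BED6 file
#'
#' Inverse of [read_sites()]: `read_sites(write_sites(x, f))` reproduces
#' `x` record for record.
#'
#' @param sites Site `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  validate_sites(sites)
  utils::write.table(
    sites[, c("chrom", "start", "end", "name", "score", "strand")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Write a positional profile to TSV
#'
#' One row per offset, ascending, with columns `offset`, `raw_density`,
#' `smoothed_density`, `z`. Columns not yet computed (no smoothing, no
#' permutation null) are written empty. Numbers are written with 15
#' significant digits so a read-back reproduces the profile.
#'
#' @param profile A `positional_profile` (see [aggregate_density()]).
#' @param path Output path.
#' @param comment Optional character vector of comment lines (written as
#'   `# ...` above the header).
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, comment = NULL) {
  stopifnot(inherits(profile, "positional_profile"))
  if (length(profile$offsets) == 0L) stop("empty profile")
  fmt <- function(x) {
    if (is.null(x)) return(rep("", length(profile$offsets)))
    formatC(x, digits = 15, format = "g")
  }
  df <- data.frame(
    offset = profile$offsets,
    raw_density = fmt(profile$raw_density),
    smoothed_density = fmt(profile$smoothed_density),
    z = fmt(profile$z),
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a positional profile written by [write_profile()]
#'
#' @param path Path to a profile TSV.
#' @return A `positional_profile`. `n_sites` and metadata are not stored in
#'   the file and come back as `NA`/empty.
#' @export
read_profile <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          colClasses = c("integer", rep("character", 3L)),
                          stringsAsFactors = FALSE)
  num_or_null <- function(x) {
    if (all(!nzchar(x))) NULL else as.numeric(x)
  }
  new_positional_profile(
    offsets = df$offset,
    raw_density = as.numeric(df$raw_density),
    smoothed_density = num_or_null(df$smoothed_density),
    z = num_or_null(df$z),
    n_sites = NA_integer_,
    meta = list()
  )
}
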