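#' Derive per-stage seeds from one master seed
#'
#' Each generator in a multi-stage run gets its own deterministic seed:
#' `(master + 1000003 * index) mod (2^31 - 1)`. One master seed then
#' reproduces an entire simulated study.
#'
#' @param master Integer master seed.
#' @param n Number of seeds to derive.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(master, n) {
  as.integer((as.double(master) + 1000003 * seq_len(n)) %% (2^31 - 1))
}

#' Generate an i.i.d. random genome
#'
#' @param length Contig length (>= 1).
#' @param base_probs Probabilities of A, C, G, T (must sum to 1).
#' @param seed Integer seed.
#' @param contig Contig name (default `"chr1"`).
#' @return Named character vector (a one-contig genome).
#' @export
gen_genome <- function(length, base_probs = rep(0.25, 4), seed,
                       contig = "chr1") {
  if (length < 1L) stop("length must be >= 1")
  if (length(base_probs) != 4L || abs(sum(base_probs) - 1) > 1e-9)
    stop("base_probs must be 4 probabilities summing to 1")
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                      prob = base_probs), collapse = "")
  stats::setNames(seq, contig)
}

#' Generate random binding sites away from contig edges
#'
#' Anchors are placed uniformly, strands are Bernoulli(0.5), and every
#' site is kept at least `flank` nt from both contig ends so that no
#' downstream flank extraction drops a window.
#'
#' @param genome One-contig genome (named character vector).
#' @param n Number of sites.
#' @param flank Flank size the windows will use.
#' @param site_len Binding-site length in nt (default 10).
#' @param seed Integer seed.
#' @return Site `data.frame` (BED6 columns, 0-based half-open).
#' @export
gen_sites <- function(genome, n, flank, site_len = 10L, seed) {
  contig <- names(genome)[1L]
  L <- nchar(genome[[1L]])
  lo <- flank + site_len
  hi <- L - flank - site_len
  if (n > 0L && hi < lo)
    stop("contig too short for ", n, " sites with flank ", flank)
  set.seed(seed)
  if (n == 0L) {
    starts <- integer(0); strands <- character(0)
  } else {
    starts <- sample(lo:hi, n, replace = TRUE)
    strands <- sample(c("+", "-"), n, replace = TRUE)
  }
  data.frame(
    chrom = rep(contig, n),
    start = as.integer(starts),
    end = as.integer(starts + site_len),
    name = sprintf("site_%04d", seq_len(max(n, 0L))[seq_len(n)]),
    score = rep(0, n),
    strand = strands,
    stringsAsFactors = FALSE
  )
}

#' Plant a polyA-signal motif downstream of binding sites
#'
#' Each site is independently selected with probability `q`; selected
#' sites have `motif` written into the genome starting at window offset
#' `round(Normal(mu, sigma))` in RNA orientation (on the minus strand the
#' reverse complement is written at the mirrored genomic coordinates). An
#' offset whose motif span would leave the `[-flank, flank)` window is
#' redrawn, up to 100 times.
#'
#' @param genome One-contig genome.
#' @param sites Site `data.frame`.
#' @param motif Motif to plant (default `"AATAAA"`).
#' @param mu,sigma Mean / sd of the planted offset (nt downstream of the
#'   anchor).
#' @param q Planting probability per site.
#' @param flank Flank size of the downstream analysis window.
#' @param seed Integer seed.
#' @return List with `genome` (modified) and `truth`: a `data.frame` of
#'   `name`, `planted`, `offset` (NA when not planted).
#' @export
plant_pas <- function(genome, sites, motif = "AATAAA", mu, sigma, q,
                      flank, seed) {
  if (q < 0 || q > 1) stop("q must be in [0, 1]")
  k <- nchar(motif)
  if (mu + k > flank) stop("mu + motif length must be <= flank")
  set.seed(seed)
  planted <- stats::runif(nrow(sites)) < q
  offs <- rep(NA_integer_, nrow(sites))
  anchors <- anchor_position(sites)
  seq <- genome[[1L]]
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  for (i in which(planted)) {
    o <- NA_integer_
    for (try in seq_len(100L)) {
      cand <- as.integer(round(stats::rnorm(1L, mu, sigma)))
      if (cand >= -flank && cand + k <= flank) { o <- cand; break }
    }
    if (is.na(o)) stop("could not draw an in-window offset for site ",
                       sites$name[i])
    offs[i] <- o
    if (sites$strand[i] == "+") {
      g <- anchors[i] + o            # 0-based genomic start
      substr(seq, g + 1L, g + k) <- motif
    } else {
      g <- anchors[i] - o - (k - 1L)
      substr(seq, g + 1L, g + k) <- rc
    }
  }
  genome[[1L]] <- seq
  list(
    genome = genome,
    truth = data.frame(name = sites$name, planted = planted, offset = offs,
                       stringsAsFactors = FALSE)
  )
}

#' Generate co-factor sites at controlled offsets from anchor sites
#'
#' Places one query site per anchor site, displaced downstream (in the
#' anchor's RNA orientation) by `round(Normal(mu, sigma))` nt, on the same
#' contig and strand. Used to emulate a 3'-end-processing factor binding
#' at a characteristic distance from another factor's sites.
#'
#' @param sites Anchor site `data.frame`.
#' @param mu,sigma Offset mean / sd in nt (sigma 0 gives a fixed shift).
#' @param site_len Length of the generated sites (default 10).
#' @param seed Integer seed.
#' @return List with `sites` (query site `data.frame`) and `truth`
#'   (`name`, `offset`).
#' @export
gen_cofactor_sites <- function(sites, mu, sigma = 0, site_len = 10L, seed) {
  set.seed(seed)
  offs <- as.integer(round(stats::rnorm(nrow(sites), mu, sigma)))
  anchors <- anchor_position(sites)
  plus <- sites$strand == "+"
  qanchor <- ifelse(plus, anchors + offs, anchors - offs)
  # query anchor is its 5' end: start on +, end-1 on -
  qstart <- ifelse(plus, qanchor, qanchor - site_len + 1L)
  out <- data.frame(
    chrom = sites$chrom,
    start = as.integer(qstart),
    end = as.integer(qstart + site_len),
    name = sprintf("cofactor_%04d", seq_len(nrow(sites))),
    score = rep(0, nrow(sites)),
    strand = sites$strand,
    stringsAsFactors = FALSE
  )
  list(sites = out,
       truth = data.frame(name = out$name, offset = offs,
                          stringsAsFactors = FALSE))
}

#' Generate a PPAU table with a planted set of shifted events
#'
#' Control samples draw around a common baseline; a fraction of events
#' additionally shift their condition-group mean by `effect`
#' percentage points, with random sign. Values are clipped to `[0, 100]`
#' (rare by construction at sensible baselines and noise levels).
#'
#' @param n_events Number of polyA events.
#' @param n_per_group Samples per group.
#' @param frac_shifted Fraction of truly shifted events.
#' @param effect Shift size in dPPAU units (default 30).
#' @param noise_sd Per-cell Gaussian noise sd (percentage points).
#' @param baseline Baseline PPAU (default 50).
#' @param seed Integer seed.
#' @return List with `ppau` (`event_id`, `gene`, sample columns), `groups`
#'   (named vector) and `truth` (`event_id`, `shifted`, `sign`).
#' @export
gen_ppau <- function(n_events, n_per_group, frac_shifted, effect = 30,
                     noise_sd = 5, baseline = 50, seed) {
  if (frac_shifted < 0 || frac_shifted > 1)
    stop("frac_shifted must be in [0, 1]")
  set.seed(seed)
  n_shift <- round(n_events * frac_shifted)
  shifted <- seq_len(n_events) <= n_shift   # ids are arbitrary; no bias
  sign <- ifelse(shifted, sample(c(1, -1), n_events, replace = TRUE), 0)
  ctrl_cols <- sprintf("ctrl_%d", seq_len(n_per_group))
  cond_cols <- sprintf("cond_%d", seq_len(n_per_group))
  ctrl <- matrix(baseline + stats::rnorm(n_events * n_per_group, 0, noise_sd),
                 n_events, n_per_group)
  cond <- matrix(baseline + rep(sign * effect, n_per_group) +
                   stats::rnorm(n_events * n_per_group, 0, noise_sd),
                 n_events, n_per_group)
  clip <- function(x) `dim<-`(pmin(100, pmax(0, x)), dim(x))
  ppau <- data.frame(
    event_id = sprintf("event_%05d", seq_len(n_events)),
    gene = sprintf("gene_%05d", seq_len(n_events)),
    clip(ctrl), clip(cond),
    stringsAsFactors = FALSE
  )
  names(ppau)[-(1:2)] <- c(ctrl_cols, cond_cols)
  groups <- stats::setNames(
    c(rep("control", n_per_group), rep("condition", n_per_group)),
    c(ctrl_cols, cond_cols)
  )
  list(
    ppau = ppau, groups = groups,
    truth = data.frame(event_id = ppau$event_id, shifted = shifted,
                       sign = sign, stringsAsFactors = FALSE)
  )
}

#' Generate a protein quantification table with planted interactors
#'
#' Log2 intensities are Gaussian around a common baseline; true
#' interactors gain `effect_log2` in the bait channel. Peptide counts and
#' coverage are drawn to pass the evidence filters for true interactors
#' (peptides >= 5, coverage > 20 percent) and over a mixed range for the
#' null proteins.
#'
#' @param n_proteins Total proteins.
#' @param n_true Number of true interactors (first `n_true` rows).
#' @param reps_per_group Replicates per channel (default 3).
#' @param effect_log2 Bait enrichment of true interactors in log2 units.
#' @param noise_sd_log2 Replicate noise sd in log2 units.
#' @param baseline_log2 Baseline log2 intensity (default 25).
#' @param seed Integer seed.
#' @return List with `quant` (`protein_id`, `razor_unique_peptides`,
#'   `coverage_pct`, `bait_*`, `control_*`) and `truth` (`protein_id`,
#'   `interactor`).
#' @export
gen_quant <- function(n_proteins, n_true, reps_per_group = 3L,
                      effect_log2 = 3, noise_sd_log2 = 0.2,
                      baseline_log2 = 25, seed) {
  if (n_true > n_proteins) stop("n_true exceeds n_proteins")
  set.seed(seed)
  true <- seq_len(n_proteins) <= n_true
  peptides <- ifelse(true, sample(5:40, n_proteins, replace = TRUE),
                     sample(0:40, n_proteins, replace = TRUE))
  coverage <- ifelse(true, stats::runif(n_proteins, 25, 90),
                     stats::runif(n_proteins, 1, 90))
  bait <- matrix(stats::rnorm(n_proteins * reps_per_group,
                              baseline_log2 + ifelse(true, effect_log2, 0),
                              noise_sd_log2),
                 n_proteins, reps_per_group)
  ctrl <- matrix(stats::rnorm(n_proteins * reps_per_group, baseline_log2,
                              noise_sd_log2),
                 n_proteins, reps_per_group)
  quant <- data.frame(
    protein_id = sprintf("prot_%04d", seq_len(n_proteins)),
    razor_unique_peptides = as.integer(peptides),
    coverage_pct = coverage,
    2^bait, 2^ctrl,
    stringsAsFactors = FALSE
  )
  names(quant)[-(1:3)] <- c(sprintf("bait_%d", seq_len(reps_per_group)),
                            sprintf("control_%d", seq_len(reps_per_group)))
  list(quant = quant,
       truth = data.frame(protein_id = quant$protein_id, interactor = true,
                          stringsAsFactors = FALSE))
}

#' Generate a pair of fold-change tables with a chosen correlation
#'
#' Paired log2 fold changes are drawn from a bivariate normal with
#' correlation `r_true` (unit marginal sd). All p-values are set below
#' 0.05 so the significance filter is neutral unless exercised on purpose.
#'
#' @param n_genes Number of shared genes.
#' @param r_true Target Pearson correlation in `[-1, 1]`.
#' @param seed Integer seed.
#' @return List with `a`, `b` (FC `data.frame`s: `gene_id`, `log2fc`,
#'   `p_value`) and `truth` (`r_true`).
#' @export
gen_fc_pair <- function(n_genes, r_true, seed) {
  if (abs(r_true) > 1) stop("r_true must be in [-1, 1]")
  set.seed(seed)
  x <- stats::rnorm(n_genes)
  y <- r_true * x + sqrt(1 - r_true^2) * stats::rnorm(n_genes)
  genes <- sprintf("gene_%05d", seq_len(n_genes))
  list(
    a = data.frame(gene_id = genes, log2fc = x,
                   p_value = stats::runif(n_genes, 1e-6, 0.049),
                   stringsAsFactors = FALSE),
    b = data.frame(gene_id = genes, log2fc = y,
                   p_value = stats::runif(n_genes, 1e-6, 0.049),
                   stringsAsFactors = FALSE),
    truth = list(r_true = r_true)
  )
}
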