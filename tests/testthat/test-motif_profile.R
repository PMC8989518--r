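test_that("anchor is the 5' end of the site in RNA orientation", {
  s <- toy_sites("c", c(10L, 10L, 0L), c(20L, 20L, 1L), c("+", "-", "-"))
  expect_identical(anchor_position(s), c(10L, 19L, 0L))
})

test_that("extract_flanks slices plus-strand windows directly", {
  set.seed(4)
  g <- c(c1 = paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""))
  s <- toy_sites("c1", 150L, 160L, "+")
  fw <- extract_flanks(s, g, flank = 5L)
  expect_identical(unname(fw$seq[1L]), substr(g[[1L]], 146L, 155L))
  expect_identical(attr(fw, "n_dropped"), 0L)
})

test_that("minus-strand windows read base-by-base as g(anchor - o)", {
  set.seed(5)
  g <- c(c1 = paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""))
  s <- toy_sites("c1", 100L, 110L, "-")   # anchor 109 (0-based)
  fw <- extract_flanks(s, g, flank = 5L)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # brute-force oracle: window base at offset o is the complement of the
  # genome base at coordinate anchor - o
  oracle <- paste(vapply(-5:4, function(o) {
    comp[[substr(g[[1L]], 109L - o + 1L, 109L - o + 1L)]]
  }, character(1)), collapse = "")
  expect_identical(unname(fw$seq[1L]), oracle)
  expect_identical(nchar(fw$seq[1L]), 10L)
})

test_that("edge sites are dropped and counted, never padded", {
  g <- c(c1 = strrep("ACGT", 25))
  s <- toy_sites("c1", c(3L, 50L), c(13L, 60L), c("+", "+"))
  fw <- extract_flanks(s, g, flank = 5L)
  expect_identical(nrow(fw), 1L)
  expect_identical(attr(fw, "n_dropped"), 1L)
  expect_error(extract_flanks(toy_sites("c1", 1L, 3L, "+"), g, flank = 50L),
               "dropped")
})

test_that("scan_motif_starts reports overlapping matches at offsets", {
  hits <- scan_motif_starts("AAATAAA")         # offsets -3..3
  expect_identical(hits$offset, c(-3L, -2L))
  expect_identical(hits$motif, c("AAATAA", "AATAAA"))

  hits2 <- scan_motif_starts("AATAAATAAA", flank = 0L)  # offsets 0..9
  expect_identical(nrow(hits2), 4L)
  expect_identical(hits2$offset, c(0L, 1L, 3L, 4L))
  expect_setequal(hits2$motif[hits2$offset %in% c(0L, 4L)], "AATAAA")

  expect_identical(nrow(scan_motif_starts(strrep("C", 30))), 0L)
  # N poisons any candidate span
  expect_identical(nrow(scan_motif_starts("AATNAAATAA", flank = 0L)), 1L)
})

test_that("aggregate_density matches the naive per-position oracle", {
  for (seed in c(1, 2)) {
    w <- random_windows(60, 50, seed = seed)
    prof <- aggregate_density(w)
    oracle <- naive_scan_counts(w$seq, pas_motifs())
    expect_identical(prof$raw_density * nrow(w), as.numeric(oracle))
    # mass conservation: total density * n is the integer match count
    expect_identical(sum(prof$raw_density) * nrow(w), as.numeric(sum(oracle)))
    expect_identical(prof$offsets, seq.int(-25L, 24L))
  }
})

test_that("aggregate_density handles forced and degenerate cases", {
  fw <- structure(
    data.frame(name = c("a", "b"),
               seq = c(paste0(strrep("C", 30), "AATAAA", strrep("C", 4)),
                       paste0(strrep("G", 30), "AATAAA", strrep("G", 4))),
               stringsAsFactors = FALSE),
    flank = 20L, n_dropped = 0L, class = c("flank_windows", "data.frame"))
  prof <- aggregate_density(fw)
  expect_identical(prof$raw_density[prof$offsets == 10L], 1.0)
  expect_identical(sum(prof$raw_density), 1.0)

  nw <- structure(
    data.frame(name = "n", seq = strrep("N", 40), stringsAsFactors = FALSE),
    flank = 20L, n_dropped = 0L, class = c("flank_windows", "data.frame"))
  expect_true(all(aggregate_density(nw)$raw_density == 0))

  expect_error(aggregate_density(fw[0, , drop = FALSE]))
  expect_error(aggregate_density(fw, motifs = "AATAAA"[0]), "empty")
})

test_that("smoothing is a truncated centered moving average", {
  mk <- function(y) apashift:::new_positional_profile(
    seq_along(y) - 1L - length(y) %/% 2L, y, n_sites = 1L)
  const <- smooth_profile(mk(rep(2, 21)), w = 11)
  expect_equal(const$smoothed_density, rep(2, 21))

  unit <- smooth_profile(mk(c(rep(0, 10), 1, rep(0, 10))), w = 11)
  expect_equal(unit$smoothed_density[6:16], rep(1 / 11, 11))
  expect_equal(unit$smoothed_density[c(1:5, 17:21)], rep(0, 10))

  ident <- smooth_profile(mk(rnorm(15)), w = 1)
  expect_equal(ident$smoothed_density, ident$raw_density)

  expect_error(smooth_profile(mk(rep(0, 10)), w = 4), "odd")
  expect_error(smooth_profile(mk(rep(0, 10)), w = 13), "1..")
})

test_that("argmax ties resolve to the smallest offset", {
  p <- apashift:::new_positional_profile(-2:2, c(0, 1, 0, 1, 0))
  expect_identical(profile_argmax(p), -1L)
})

test_that("permutation z is seeded, reproducible and null-calibrated", {
  w <- random_windows(150, 80, seed = 31)
  z1 <- permutation_z(w, n_perm = 200, seed = 99)
  z2 <- permutation_z(w, n_perm = 200, seed = 99)
  expect_identical(z1$z, z2$z)
  # unplanted uniform sequence: the vast majority of offsets are null
  expect_gte(mean(abs(z1$z) < 3), 0.95)
  expect_error(permutation_z(w, n_perm = 50, seed = 1), "at least 100")
  expect_error(permutation_z(w, n_perm = 200), "seed")
})

test_that("profiles are invariant under a genome strand mirror", {
  genome <- gen_genome(20000L, seed = 71)
  sites <- gen_sites(genome, 80L, flank = 50L, seed = 72)
  planted <- plant_pas(genome, sites, mu = 15L, sigma = 4, q = 0.6,
                       flank = 50L, seed = 73)
  prof <- aggregate_density(extract_flanks(sites, planted$genome, 50L))

  mg <- mirror_genome(planted$genome)
  ms <- mirror_sites(sites, planted$genome)
  mprof <- aggregate_density(extract_flanks(ms, mg, 50L))
  expect_identical(mprof$raw_density, prof$raw_density)
})

test_that("cross_site_profile counts same-strand co-binding offsets", {
  a <- toy_sites("c1", c(100L, 300L), c(110L, 310L), "+")
  shifted <- a; shifted$start <- a$start + 7L; shifted$end <- a$end + 7L
  p <- cross_site_profile(a, shifted, flank = 20L)
  expect_identical(p$raw_density[p$offsets == 7L], 1.0)
  expect_identical(sum(p$raw_density), 1.0)

  ident <- cross_site_profile(a, a, flank = 20L)
  expect_identical(ident$raw_density[ident$offsets == 0L], 1.0)

  minus <- a; minus$strand <- "-"
  expect_true(all(cross_site_profile(a, minus, 20L)$raw_density == 0))
  expect_error(cross_site_profile(a[0, ], a, 20L), "empty")
})

test_that("minus-strand cross-site offsets are transcript-downstream", {
  # anchor at end-1; a query whose 5' end lies 7 nt downstream in RNA
  # orientation sits 7 nt to the genomic left
  a <- toy_sites("c1", 200L, 210L, "-")          # anchor 209
  q <- toy_sites("c1", 193L, 203L, "-")          # anchor 202 = 209 - 7
  p <- cross_site_profile(a, q, flank = 20L)
  expect_identical(p$offsets[p$raw_density > 0], 7L)
})
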