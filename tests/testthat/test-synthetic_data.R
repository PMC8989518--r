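test_that("generators are pure functions of their seeds", {
  expect_identical(gen_genome(500, seed = 5), gen_genome(500, seed = 5))
  g <- gen_genome(5000, seed = 6)
  expect_identical(gen_sites(g, 20, flank = 30, seed = 7),
                   gen_sites(g, 20, flank = 30, seed = 7))
  expect_identical(gen_ppau(50, 3, 0.2, seed = 8)$ppau,
                   gen_ppau(50, 3, 0.2, seed = 8)$ppau)
  expect_identical(gen_quant(30, 5, seed = 9)$quant,
                   gen_quant(30, 5, seed = 9)$quant)
  expect_identical(gen_fc_pair(30, 0.4, seed = 10)$b,
                   gen_fc_pair(30, 0.4, seed = 10)$b)
  expect_identical(derive_seeds(17, 5), derive_seeds(17, 5))
  expect_true(all(derive_seeds(2, 8) < 2^31))
})

test_that("gen_genome respects base probabilities", {
  allA <- gen_genome(200, base_probs = c(1, 0, 0, 0), seed = 1)
  expect_identical(unname(allA), strrep("A", 200))
  expect_error(gen_genome(10, base_probs = c(0.5, 0.5, 0.5, 0.5), seed = 1),
               "summing to 1")

  g <- gen_genome(1e6, seed = 2)
  freq <- table(strsplit(g[[1L]], "")[[1L]]) / 1e6
  se3 <- 3 * sqrt(0.25 * 0.75 / 1e6)
  expect_true(all(abs(freq - 0.25) < se3))
})

test_that("gen_sites places sites clear of contig edges", {
  g <- gen_genome(4000, seed = 3)
  s <- gen_sites(g, 50, flank = 40, seed = 4)
  fw <- extract_flanks(s, g, flank = 40)
  expect_identical(attr(fw, "n_dropped"), 0L)
  expect_identical(nrow(fw), 50L)
  expect_identical(nrow(gen_sites(g, 0, flank = 40, seed = 4)), 0L)
  expect_error(gen_sites(gen_genome(50, seed = 1), 5, flank = 40, seed = 1),
               "too short")
})

test_that("plant_pas writes the motif at the planted offset, both strands", {
  g <- gen_genome(30000, base_probs = c(0, 0.5, 0.5, 0), seed = 12)  # C/G only
  s <- gen_sites(g, 40, flank = 50, seed = 13)
  pl <- plant_pas(g, s, mu = 20, sigma = 0, q = 1, flank = 50, seed = 14)
  expect_true(all(pl$truth$planted))
  expect_true(all(pl$truth$offset == 20L))
  fw <- extract_flanks(s, pl$genome, flank = 50)
  # on a C/G background the only A/T run is the planted AATAAA at +20
  for (seq in fw$seq) {
    expect_identical(substr(seq, 50 + 20 + 1, 50 + 26), "AATAAA")
  }
  prof <- aggregate_density(fw, motifs = "AATAAA")
  expect_identical(prof$raw_density[prof$offsets == 20L], 1.0)

  untouched <- plant_pas(g, s, mu = 20, sigma = 0, q = 0, flank = 50,
                         seed = 14)
  expect_identical(untouched$genome, g)
  expect_false(any(untouched$truth$planted))
})

test_that("noiseless PPAU tables are classified back to the planted sets", {
  sim <- gen_ppau(500, 4, frac_shifted = 0.2, effect = 30, noise_sd = 0,
                  seed = 15)
  d <- compute_dppau(sim$ppau, sim$groups)
  for (t in c(0, 20)) {
    expect_identical(d$event_id[d$dppau > t],
                     sim$truth$event_id[sim$truth$sign > 0])
    expect_identical(d$event_id[d$dppau < -t],
                     sim$truth$event_id[sim$truth$sign < 0])
  }
})

test_that("unshifted PPAU tables stay near-balanced around zero", {
  sim <- gen_ppau(2000, 4, frac_shifted = 0, noise_sd = 5, seed = 16)
  d <- compute_dppau(sim$ppau, sim$groups)
  # dPPAU ~ Normal(0, noise_sd * sqrt(2 / n_per_group))
  expect_lt(abs(mean(d$dppau)), 3 * 5 * sqrt(2 / 4) / sqrt(2000))
  cls <- classify_dppau(d, thresholds = 0)
  expect_lt(abs(cls$proximal_up - cls$proximal_down),
            3 * sqrt(2000))
})

test_that("co-factor sites land at the requested offset on both strands", {
  set.seed(17)
  s <- toy_sites("chr1", seq(500L, by = 300L, length.out = 60L),
                 seq(510L, by = 300L, length.out = 60L),
                 sample(c("+", "-"), 60, replace = TRUE))
  cof <- gen_cofactor_sites(s, mu = 7, sigma = 0, seed = 19)
  expect_true(all(cof$truth$offset == 7L))
  p <- cross_site_profile(s, cof$sites, flank = 50)
  expect_identical(p$raw_density[p$offsets == 7L], 1.0)
  expect_identical(sum(p$raw_density), 1.0)
})
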