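splice_row <- function(type, ijc1, ijc2, sjc, fdr, id = "e") {
  data.frame(event_id = id, type = type, IJC_1 = ijc1, IJC_2 = ijc2,
             SJC = sjc, FDR = fdr, stringsAsFactors = FALSE)
}

test_that("junction-count filter follows the per-type rules exactly", {
  # RI/SE/MXE: SJC >= 10, or IJC 10-and-5
  expect_identical(nrow(filter_splice_events(splice_row("RI", 0, 0, 12, 0.01))), 1L)
  expect_identical(nrow(filter_splice_events(splice_row("RI", 11, 6, 3, 0.01))), 1L)
  expect_identical(nrow(filter_splice_events(splice_row("RI", 11, 4, 3, 0.01))), 0L)
  expect_identical(nrow(filter_splice_events(splice_row("SE", 4, 12, 0, 0.04))), 0L)
  expect_identical(nrow(filter_splice_events(splice_row("SE", 5, 12, 0, 0.04))), 1L)
  # A3SS/A5SS: sum of all junction reads >= 10
  expect_identical(nrow(filter_splice_events(splice_row("A3SS", 4, 3, 2, 0.01))), 0L)
  expect_identical(nrow(filter_splice_events(splice_row("A3SS", 4, 3, 3, 0.01))), 1L)
  # FDR is strict
  expect_identical(nrow(filter_splice_events(splice_row("MXE", 20, 20, 20, 0.05))), 0L)
  expect_identical(nrow(filter_splice_events(splice_row("MXE", 20, 20, 20, 0.06))), 0L)
  expect_error(filter_splice_events(splice_row("XX", 1, 1, 1, 0.01)),
               "unknown")
})

test_that("the filter is idempotent and tallies conserve rows", {
  set.seed(8)
  tab <- data.frame(
    event_id = sprintf("e%03d", 1:200),
    type = sample(splice_event_types(), 200, TRUE),
    IJC_1 = rpois(200, 8), IJC_2 = rpois(200, 8), SJC = rpois(200, 8),
    FDR = runif(200), stringsAsFactors = FALSE
  )
  once <- filter_splice_events(tab)
  expect_identical(filter_splice_events(once), once)
  tally <- tally_event_types(once)
  expect_identical(sum(tally), nrow(once))
  expect_identical(names(tally), c("SE", "MXE", "RI", "A3SS", "A5SS"))
  expect_identical(sum(tally_event_types(tab[0, ])), 0L)
})

test_that("dPPAU is condition minus control group mean", {
  ppau <- data.frame(event_id = c("e1", "e2", "e3"), gene = c("g1", "g2", "g3"),
                     c1 = c(40, 50, 0), c2 = c(50, 50, 0), c3 = c(60, 50, 0),
                     k1 = c(80, 50, 100), k2 = c(70, 50, 100), k3 = c(90, 50, 100))
  groups <- setNames(c(rep("control", 3), rep("condition", 3)),
                     c("c1", "c2", "c3", "k1", "k2", "k3"))
  d <- compute_dppau(ppau, groups)
  expect_equal(d$dppau, c(30, 0, 100))

  bad <- ppau; bad$c1[1] <- 120
  expect_error(compute_dppau(bad, groups), "\\[0, 100\\]")
  expect_error(compute_dppau(ppau, groups[groups == "control"]),
               "both a control and a condition")
})

test_that("dPPAU classification uses strict inequalities per threshold", {
  cls <- classify_dppau(c(30, -25, 5, 0), thresholds = c(0, 20))
  expect_identical(cls$proximal_up, c(2L, 1L))
  expect_identical(cls$proximal_down, c(1L, 1L))

  zeros <- classify_dppau(rep(0, 10), thresholds = c(0, 20))
  expect_true(all(zeros$proximal_up == 0L & zeros$proximal_down == 0L))

  # exactly at threshold: uncounted
  at <- classify_dppau(c(20, -20), thresholds = 20)
  expect_identical(at$proximal_up + at$proximal_down, 0L)
  expect_error(classify_dppau(1:3, thresholds = -1), "non-negative")
})

test_that("classification counts never increase with the threshold", {
  set.seed(21)
  for (i in 1:5) {
    d <- runif(300, -100, 100)
    cls <- classify_dppau(d, thresholds = sort(runif(4, 0, 50)))
    expect_true(all(diff(cls$proximal_up) <= 0))
    expect_true(all(diff(cls$proximal_down) <= 0))
  }
})
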