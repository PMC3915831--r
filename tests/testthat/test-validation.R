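make_universe <- function(n) sprintf("U%04d", seq_len(n))

test_that("regulon classification is exact set arithmetic", {
  uni <- make_universe(100)
  pos <- uni[1:30]
  reg <- c(uni[21:24], uni[51:56])  # 4 positives, 6 others
  cls <- classify_regulon(reg, pos, uni, tf = "TFX")
  expect_equal(cls$tp, 4L)
  expect_equal(cls$fp, 6L)
  expect_equal(cls$size, 10L)

  all_pos <- classify_regulon(uni[5:9], pos, uni, tf = "TFX")
  expect_equal(all_pos$fp, 0L)

  expect_error(classify_regulon("zz", pos, uni), "contained")
  expect_error(classify_regulon(reg, pos, character()), "empty")

  for (seed in 1:25) {
    withr::with_seed(seed, {
      reg <- sample(uni, 20)
      pos <- sample(uni, 35)
    })
    cls <- classify_regulon(reg, pos, uni, tf = "T")
    expect_equal(cls$tp, length(intersect(reg, pos)))
    expect_equal(cls$fp, length(setdiff(reg, pos)))
  }
})

test_that("gain arithmetic reproduces published regulon comparisons", {
  # helper: classified rows straight from counts
  cls <- function(tp, fp, tf = "TF") {
    uni <- make_universe(2000)
    classify_regulon(
      c(uni[seq_len(tp)], uni[1000 + seq_len(fp)]),
      positives = uni[1:600], universe = uni, tf = tf
    )
  }
  # MYC regulon vs Burkitt ChIP binding (Ramos assays): 472 -> 454 targets
  ramos <- gain_statistics(cls(214, 258), cls(209, 245))
  expect_equal(ramos$tp_gain, 5L)
  expect_equal(ramos$fp_gain, 13L)
  expect_equal(ramos$removed_total, 18L)
  # Mutu assays over the same pruning
  mutu <- gain_statistics(cls(170, 302), cls(166, 288))
  expect_equal(mutu$tp_gain, 4L)
  expect_equal(mutu$fp_gain, 14L)
  # BCL6 regulon vs knockdown response, no net additions
  pfeiffer <- gain_statistics(cls(144, 190), cls(144, 174))
  expect_equal(pfeiffer$tp_gain, 0L)
  expect_equal(pfeiffer$fp_gain, 16L)
  # consensus scoring added two true targets while 18 FPs were removed
  ly7 <- gain_statistics(cls(54, 280), cls(56, 262))
  expect_equal(ly7$tp_gain, -2L)
  expect_equal(ly7$fp_gain, 18L)
  expect_equal(ly7$removed_total, 16L)

  same <- gain_statistics(cls(10, 5), cls(10, 5))
  expect_equal(same$tp_gain, 0L)
  expect_equal(same$fp_gain, 0L)
  expect_equal(same$gain_p, 1)

  expect_error(
    gain_statistics(cls(5, 5, tf = "A"), cls(5, 5, tf = "B")),
    "same TF"
  )
})

test_that("hypergeometric tails are exact and monotone", {
  expect_equal(hypergeometric_tail(50, 10, 8, 0), 1)
  expect_equal(hypergeometric_tail(10, 5, 5, 5), 1 / choose(10, 5))
  expect_equal(
    hypergeometric_tail(472, 258, 18, 13),
    oracle_hyper_tail(472, 258, 18, 13)
  )
  tail_seq <- vapply(
    0:12, function(k) hypergeometric_tail(60, 25, 12, k), numeric(1)
  )
  expect_true(all(diff(tail_seq) < 0))
  expect_error(hypergeometric_tail(10, 5, 12, 3), "inconsistent")

  for (seed in 1:50) {
    v <- withr::with_seed(seed, {
      N <- sample(5:80, 1)
      K <- sample(0:N, 1)
      n <- sample(0:N, 1)
      k <- sample(0:min(n, K), 1)
      c(N, K, n, k)
    })
    expect_equal(
      hypergeometric_tail(v[1], v[2], v[3], v[4]),
      oracle_hyper_tail(v[1], v[2], v[3], v[4]),
      tolerance = 1e-12
    )
  }
})

test_that("Fisher's exact test matches margin enumeration", {
  expect_equal(fisher_exact(matrix(c(10, 10, 10, 10), 2)), 1)
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2)), 2 / choose(10, 5))
  expect_error(fisher_exact(matrix(0, 2, 2)), "all-zero")
  expect_error(fisher_exact(matrix(c(1.5, 1, 1, 1), 2)), "integer")

  for (seed in 1:100) {
    tab <- withr::with_seed(seed, matrix(sample(0:15, 4, replace = TRUE), 2))
    if (all(rowSums(tab) == 0) || all(colSums(tab) == 0)) next
    expect_equal(
      fisher_exact(tab),
      oracle_fisher_two_sided(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
      tolerance = 1e-9
    )
  }
})

test_that("validation reports track regulon quality across pruning stages", {
  uni <- make_universe(500)
  pos <- uni[1:120]
  reg0 <- c(uni[1:40], uni[200:279])   # 40 TP, 80 FP
  reg1 <- c(uni[1:40], uni[200:239])   # pruning removed 40 FPs
  reg2 <- c(uni[1:38], uni[200:229])   # then 2 TPs and 10 FPs more

  rep <- validation_report(
    list(dpi1 = reg0, dpi2 = reg1, dpi3 = reg2),
    positives = pos, universe = uni, tf = "TFZ"
  )
  expect_equal(rep$stages$stage, c("dpi1", "dpi2", "dpi3"))
  expect_equal(rep$stages$tp, c(40L, 40L, 38L))
  expect_equal(rep$stages$fp, c(80L, 40L, 30L))
  expect_true(all(rep$stages$fisher_p > 0 & rep$stages$fisher_p <= 1))
  expect_equal(rep$gain$tp_gain, 2L)
  expect_equal(rep$gain$fp_gain, 50L)

  flat <- validation_report(list(a = reg0, b = reg0), pos, uni, tf = "TFZ")
  expect_equal(flat$gain$tp_gain, 0L)
  expect_equal(flat$gain$fp_gain, 0L)
  expect_equal(flat$stages$fisher_p[1], flat$stages$fisher_p[2])

  # a pruning step that removes only planted false edges is pure FP gain
  truth_like <- validation_report(
    list(before = c(uni[1:10], uni[300:310]), after = uni[1:10]),
    positives = uni[1:50], universe = uni, tf = "T"
  )
  expect_equal(truth_like$gain$tp_gain, 0L)
  expect_equal(truth_like$gain$fp_gain, 11L)
  expect_equal(truth_like$gain$removed_total, 11L)
})
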