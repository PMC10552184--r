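test_that("percentages round half away from zero", {
  expect_identical(round_half_up(43.54), 44)
  expect_identical(round_half_up(80.77), 81)
  expect_identical(round_half_up(86.49), 86)
  expect_identical(round_half_up(0.5), 1)
  expect_identical(round_half_up(2.5), 3)   # not banker's rounding
  expect_identical(round_half_up(19.23), 19)
  expect_identical(pct(26, 47), 55)
  expect_identical(pct(13, 47), 28)
  expect_true(is.na(pct(0, 0)))
})

test_that("crossmatch consensus needs 80% agreement and 10 laboratories", {
  g <- grade_crossmatch(rep(c("positive", "negative"), c(81, 19)))
  expect_identical(g$consensus_call, "positive")
  expect_identical(g$percent_agreement, 81)
  expect_true(g$graded)
  # 79% positive: agreement reported but no consensus, not graded
  g79 <- grade_crossmatch(rep(c("positive", "negative"), c(79, 21)))
  expect_identical(g79$consensus_call, "none")
  expect_identical(g79$percent_agreement, 79)
  expect_false(g79$graded)
  # unanimity of 9 laboratories is below the grading minimum
  g9 <- grade_crossmatch(rep("positive", 9))
  expect_identical(g9$consensus_call, "positive")
  expect_false(g9$graded)
  # exactly at threshold counts (inclusive rule)
  g80 <- grade_crossmatch(rep(c("positive", "negative"), c(80, 20)))
  expect_true(g80$graded)
})

test_that("other/indeterminate answers leave the consensus denominator", {
  g <- grade_crossmatch(c(rep("positive", 16), rep("negative", 4),
                          rep("other", 10)))
  expect_identical(g$n_labs, 20L)
  expect_identical(g$n_other, 10L)
  expect_identical(g$percent_agreement, 80)
  expect_true(g$graded)
})

test_that("specificity consensus uses the 90% rule", {
  expect_identical(
    grade_specificity(rep(c("positive", "negative"), c(99, 1)))$consensus_call,
    "positive")
  # reported by only 34%: majority negative at 66% is still below 90%
  g34 <- grade_specificity(rep(c("positive", "negative"), c(34, 66)))
  expect_identical(g34$consensus_call, "none")
  expect_false(g34$graded)
  g90 <- grade_specificity(rep(c("positive", "negative"), c(90, 10)))
  expect_identical(g90$consensus_call, "positive")  # boundary inclusive
})

test_that("consensus grading is monotone in agreeing/disagreeing reports", {
  set.seed(13)
  for (rep in 1:30) {
    n_pos <- sample(5:40, 1)
    n_neg <- sample(0:10, 1)
    reports <- rep(c("positive", "negative"), c(n_pos, n_neg))
    g <- grade_crossmatch(reports)
    if (g$consensus_call == "positive") {
      expect_identical(
        grade_crossmatch(c(reports, "positive"))$consensus_call, "positive")
    }
    if (g$consensus_call == "none") {
      expect_identical(
        grade_crossmatch(c(reports, "negative"))$consensus_call %in%
          c("none", "negative"), TRUE)
      # adding a disagreeing report cannot create positive consensus
      expect_false(
        grade_crossmatch(c(reports, "negative"))$consensus_call == "positive")
    }
  }
  # threshold 100 is unanimity
  expect_identical(
    grade_crossmatch(rep("positive", 12), threshold = 100)$consensus_call,
    "positive")
  expect_identical(
    grade_crossmatch(c(rep("positive", 11), "negative"),
                     threshold = 100)$consensus_call, "none")
})

test_that("DSA summaries use the sample SD and the %CV convention", {
  s <- summarize_dsa(c(1000, 2000, 3000), n_submitters = 3)
  expect_identical(s$mean_mfi, 2000)
  expect_identical(s$sd_mfi, 1000)
  expect_identical(s$cv_percent, 50)
  expect_identical(s$percent_labs, 100)
  # single reporter: SD undefined by default, zero on request
  one <- summarize_dsa(1500, n_submitters = 10)
  expect_true(is.na(one$sd_mfi))
  expect_identical(one$percent_labs, 10)
  one0 <- summarize_dsa(1500, n_submitters = 10, single_sd = "zero")
  expect_identical(one0$sd_mfi, 0)
  expect_identical(one0$cv_percent, 0)
  # zero reporters
  none <- summarize_dsa(numeric(), n_submitters = 10)
  expect_identical(none$percent_labs, 0)
  expect_true(is.na(none$mean_mfi))
})

test_that("summary %CV always matches the rounding invariant", {
  set.seed(5)
  for (rep in 1:30) {
    mfis <- runif(sample(2:30, 1), 100, 20000)
    s <- summarize_dsa(mfis, n_submitters = length(mfis))
    expect_identical(s$cv_percent, round_half_up(100 * s$sd_mfi / s$mean_mfi))
  }
})

test_that("concordance tables report per-field percentages", {
  sub <- tibble::tibble(
    lab_id = sprintf("lab%02d", 1:37),
    cell_id = "cell-1", serum_id = "serum-1",
    t_vxm = rep(c("positive", "negative"), c(32, 5)),
    b_vxm = rep(c("positive", "negative"), c(30, 7)),
    t_fcxm = rep(c("positive", NA), c(11, 26)),
    b_fcxm = rep(c("positive", "negative", NA), c(10, 1, 26)))
  tab <- concordance(list(submissions = sub))
  t_row <- tab[tab$cell_type == "t" & tab$assay == "fcxm", ]
  expect_identical(t_row$pct_vxm_pos, 86)   # 32/37
  expect_identical(t_row$n_pxm, 11L)
  expect_identical(t_row$pct_pxm_pos, 100)
  b_row <- tab[tab$cell_type == "b" & tab$assay == "fcxm", ]
  expect_identical(b_row$pct_vxm_pos, 81)   # 30/37
  expect_identical(b_row$pct_pxm_pos, 91)   # 10/11
  # invariant to submission order
  shuffled <- concordance(list(submissions = sub[sample(nrow(sub)), ]))
  expect_identical(tab, shuffled)
})

test_that("participation totals sum component VXM counts", {
  records <- vxm_participation()
  s <- participation_summary(records)
  expect_identical(s$total_vxm, sum(records$n_vxm))
  expect_identical(s$n_components, nrow(records))
  expect_identical(participation_summary(records[0, ])$total_vxm, 0)
})

test_that("entry trends give per-year category percentages", {
  resp <- tibble::tibble(
    year = rep(c(2018, 2022), c(50, 45)),
    serum_treatment = c(rep(c("untreated", "EDTA", "DTT"), c(13, 26, 11)),
                        rep(c("untreated", "EDTA", "DTT"), c(4, 32, 9))))
  tr <- entry_trends(resp, "serum_treatment")
  expect_identical(tr$pct[tr$year == 2018 & tr$category == "untreated"], 26)
  expect_identical(tr$pct[tr$year == 2018 & tr$category == "EDTA"], 52)
  for (y in unique(tr$year)) {
    expect_lte(abs(sum(tr$pct[tr$year == y]) - 100), 2)  # rounding slack
  }
  # all one category
  solo <- entry_trends(tibble::tibble(year = 2020,
                                      serum_treatment = rep("EDTA", 8)),
                       "serum_treatment")
  expect_identical(solo$pct, 100)
})
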