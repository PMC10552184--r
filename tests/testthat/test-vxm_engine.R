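test_that("allele-exact beads yield allele-mode DSA calls sorted by MFI", {
  donor <- donor_typing("AC-153", c("DRB1*12:01", "DRB1*13:04", "DRB3*01:01",
                                    "DRB3*02:02", "DQA1*01:04/DQB1*05:01"))
  panel <- mk_panel(c("DRB1*12:01", "DRB1*13:04", "DRB3*01:01", "DRB3*02:02",
                      "DQA1*01:04/DQB1*05:01"),
                    c(2560, 4577, 1135, 1390, 10939))
  dsa <- identify_dsa(donor, panel, cutoff_policy(1000),
                      include_eplet_calls = FALSE)
  expect_identical(dsa$match_mode, rep("allele", 5))
  expect_identical(dsa$mfi, sort(dsa$mfi, decreasing = TRUE))
  expect_identical(dsa$donor_target[1], "DQA1*01:04/DQB1*05:01")
  expect_identical(dsa$mfi[1], 10939)
})

test_that("off-panel donor alleles get surrogate calls from same-group beads", {
  donor <- donor_typing("AC-168", "A*02:05")
  panel <- mk_panel(c("A*02:01", "A*01:01"), c(1377, 100))
  dsa <- identify_dsa(donor, panel, cutoff_policy(1000))
  expect_identical(nrow(dsa), 1L)
  expect_identical(dsa$match_mode, "surrogate")
  expect_identical(dsa$donor_target, "A*02:05")
  expect_identical(dsa$mfi, 1377)
  # the same surrogate beads may support several off-panel donor alleles
  donor2 <- donor_typing("d2", c("A*02:05", "A*02:02"))
  dsa2 <- identify_dsa(donor2, panel, cutoff_policy(1000))
  expect_setequal(dsa2$donor_target, c("A*02:05", "A*02:02"))
  expect_identical(dsa2$match_mode, rep("surrogate", 2))
})

test_that("allele representation suppresses surrogate matching", {
  # donor allele present on the panel but negative: no call at all
  donor <- donor_typing("d", "A*02:01")
  panel <- mk_panel(c("A*02:01", "A*02:02"), c(400, 1500))
  dsa <- identify_dsa(donor, panel, cutoff_policy(1000))
  expect_identical(nrow(dsa), 0L)
  # all matched beads negative -> empty call list
  donor2 <- donor_typing("d2", c("B*08:01", "C*02:02"))
  panel2 <- mk_panel(c("B*08:01", "C*02:02"), c(100, 200))
  expect_identical(nrow(identify_dsa(donor2, panel2)), 0L)
})

test_that("heterodimer matching requires both chains when both are typed", {
  panel <- mk_panel(c("DQA1*01:04/DQB1*05:01", "DQB1*06:02"), c(15164, 3000))
  both <- identify_dsa(donor_typing("d", "DQA1*01:04/DQB1*05:01"), panel)
  expect_identical(both$match_mode[1], "allele")
  expect_identical(both$mfi[1], 15164)
  # same beta, different alpha: not an allele match, falls to surrogate
  other_alpha <- identify_dsa(donor_typing("d", "DQA1*05:01/DQB1*05:01"),
                              panel)
  expect_identical(other_alpha$match_mode[1], "surrogate")
  # beta-only donor typing matches the heterodimer bead, with a note
  beta_only <- identify_dsa(donor_typing("d", "DQB1*05:01"), panel)
  expect_identical(beta_only$match_mode[1], "allele")
  expect_identical(beta_only$note[1], "beta_chain_only")
})

test_that("serologic and group-level donor entries match at antigen level", {
  panel <- mk_panel(c("A*02:01", "A*02:02", "A*01:01"), c(1500, 1800, 90))
  by_group <- identify_dsa(donor_typing("d", "HLA-A*02"), panel)
  expect_identical(by_group$match_mode, "antigen")
  expect_identical(by_group$n_beads, 2L)
  expect_identical(by_group$mfi, 1800)
  by_antigen <- identify_dsa(donor_typing("d", "A2"), panel)
  expect_identical(by_antigen$match_mode, "antigen")
})

test_that("shared-eplet stacking is flagged only when all carriers react", {
  # Bw6 pattern: B65 and B18 beads plus another Bw6 carrier all positive
  p <- mk_panel(c("B*14:02", "B*18:01", "B*07:02", "B*44:02"),
                c(918, 1820, 1100, 200))
  calls <- call_positive(p, cutoff_policy(900))
  flags <- flag_shared_eplet("B*18:01", calls)
  expect_identical(flags$eplet, "Bw6")
  expect_identical(flags$n_beads, 3L)
  expect_identical(flags$mfi_max, 1820)
  # one Bw6 carrier below cutoff kills the flag
  calls_hi <- call_positive(p, cutoff_policy(1000))   # B*14:02 at 918 negative
  expect_identical(nrow(flag_shared_eplet("B*18:01", calls_hi)), 0L)
  # Bw4 donor allele is not flagged by a Bw6 pattern
  expect_identical(nrow(flag_shared_eplet("B*44:02", calls)), 0L)
  # no positive beads -> nothing
  none <- call_positive(p, cutoff_policy(5000))
  expect_identical(nrow(flag_shared_eplet("B*18:01", none)), 0L)
})

test_that("DR eplet stacking yields eplet-inferred candidate calls", {
  specs <- c("DRB1*08:01", "DRB1*11:01", "DRB1*12:01", "DRB1*13:01",
             "DRB1*13:03", "DRB1*14:01", "DRB1*03:01", "DRB1*03:02",
             "DRB1*01:01", "DRB3*01:01")
  mfis <- c(1250, 1280, 1220, 1201, 1336, 1260, 1300, 1310, 90, 120)
  donor <- donor_typing("case", "DRB1*13:02")   # off the panel
  dsa <- identify_dsa(donor, mk_panel(specs, mfis), cutoff_policy(1000))
  expect_setequal(unique(dsa$match_mode), c("surrogate", "eplet_inferred"))
  ep <- dsa[dsa$match_mode == "eplet_inferred", ]
  expect_setequal(unlist(ep$eplets), c("96HK", "11STS"))
  expect_identical(ep$n_beads[unlist(ep$eplets) == "96HK"], 8L)
  # surrogate call comes from the two DR13 beads
  surr <- dsa[dsa$match_mode == "surrogate", ]
  expect_identical(surr$n_beads, 2L)
  expect_identical(surr$mfi, 1336)
})

test_that("FCXM prediction separates T- and B-cell compartments", {
  th <- prediction_thresholds()
  # class-II-only DSA never predicts a positive T-cell FCXM
  donor <- donor_typing("AC-153", c("DRB1*12:01", "DRB1*13:04", "DRB3*01:01",
                                    "DRB3*02:02", "DQA1*01:04/DQB1*05:01"))
  panel <- mk_panel(c("DRB1*12:01", "DRB1*13:04", "DRB3*01:01", "DRB3*02:02",
                      "DQA1*01:04/DQB1*05:01"),
                    c(2560, 4577, 1135, 1390, 10939))
  dsa <- identify_dsa(donor, panel, cutoff_policy(1000),
                      include_eplet_calls = FALSE)
  fc <- predict_fcxm(dsa, th)
  expect_identical(fc$t, "negative")
  expect_identical(fc$b, "positive")
  # strong C-locus DSA carries the halved locus weight but still converts
  dsa_c <- identify_dsa(donor_typing("d", c("C*05:01", "C*06:02")),
                        mk_panel(c("C*05:01", "C*06:02"), c(10024, 8924)))
  fc_c <- predict_fcxm(dsa_c, th)
  expect_identical(fc_c$t, "positive")
  expect_identical(fc_c$b, "positive")
  # low-level C-locus DSA: 2122 * 0.5 clears no threshold
  dsa_low <- identify_dsa(donor_typing("d", "C*02:02"),
                          mk_panel("C*02:02", 2122))
  fc_low <- predict_fcxm(dsa_low, th)
  expect_identical(fc_low$t, "negative")
  expect_identical(fc_low$b, "negative")
  # no DSA
  empty <- identify_dsa(donor_typing("d", "A*01:01"),
                        mk_panel("A*01:01", 100))
  expect_identical(predict_fcxm(empty, th), list(t = "negative",
                                                 b = "negative"))
})

test_that("borderline inferential calls make the prediction indeterminate", {
  th <- prediction_thresholds()
  # surrogate at 1800 sits inside the B-cell band [1500, 2500]
  dsa <- identify_dsa(donor_typing("d", "A*02:05"),
                      mk_panel(c("A*02:01", "A*01:01"), c(1800, 50)),
                      cutoff_policy(1000))
  expect_identical(predict_fcxm(dsa, th)$b, "indeterminate")
  # an equally strong allele-match call stays negative
  dsa2 <- identify_dsa(donor_typing("d", "A*02:01"),
                       mk_panel(c("A*02:01", "A*01:01"), c(1800, 50)),
                       cutoff_policy(1000))
  expect_identical(predict_fcxm(dsa2, th)$b, "negative")
})

test_that("CDC prediction needs complement information to turn positive", {
  dsa <- identify_dsa(donor_typing("AC-174", "B*08:01"),
                      mk_panel("B*08:01", 12235))
  th <- prediction_thresholds()
  unknown <- predict_cdcxm(dsa, th)
  expect_identical(unknown, list(t = "indeterminate", b = "indeterminate"))
  fixing <- predict_cdcxm(dsa, th, complement_binding = TRUE)
  expect_identical(fixing, list(t = "positive", b = "positive"))
  not_fixing <- predict_cdcxm(dsa, th, complement_binding = FALSE)
  expect_identical(not_fixing, list(t = "negative", b = "negative"))
  # weak DSA: no FCXM-positive signal, so unknown complement stays negative
  weak <- identify_dsa(donor_typing("d", "C*02:02"), mk_panel("C*02:02", 2122))
  expect_identical(predict_cdcxm(weak, th), list(t = "negative",
                                                 b = "negative"))
  empty <- identify_dsa(donor_typing("d", "A*01:01"), mk_panel("A*01:01", 10))
  expect_identical(predict_cdcxm(empty, th), list(t = "negative",
                                                  b = "negative"))
})

test_that("risk bands on peak weighted MFI with kidney/liver downgrade", {
  dsa <- identify_dsa(donor_typing("AC-149", c("A*01:01", "B*38:01")),
                      mk_panel(c("A*01:01", "B*38:01"), c(18705, 2040)))
  for (organ in c("kidney", "heart", "lung", "pancreas", "kidney_pancreas")) {
    expect_identical(risk_stratify(dsa, organ), "high")
  }
  expect_identical(risk_stratify(dsa, "kidney_liver"), "moderate")
  # moderate band
  mid <- identify_dsa(donor_typing("d", "B*38:01"), mk_panel("B*38:01", 2040))
  expect_identical(risk_stratify(mid, "kidney"), "moderate")
  expect_identical(risk_stratify(mid, "kidney_liver"), "low")
  # no DSA -> low everywhere, downgrade floors at low
  empty <- identify_dsa(donor_typing("d", "A*01:01"), mk_panel("A*01:01", 10))
  expect_identical(risk_stratify(empty, "kidney"), "low")
  expect_identical(risk_stratify(empty, "kidney_liver"), "low")
  expect_error(risk_stratify(dsa, "cornea"))
})

test_that("PXM recommendation fires on inference, indeterminacy, borderline", {
  # off-panel DR13 with stacking: both off_panel and shared_eplet reasons
  specs <- c("DRB1*08:01", "DRB1*11:01", "DRB1*12:01", "DRB1*13:01",
             "DRB1*13:03", "DRB1*14:01", "DRB1*03:01", "DRB1*03:02")
  res <- vxm_assess(donor_typing("case", "DRB1*13:02"),
                    mk_panel(specs, c(1250, 1280, 1220, 1201, 1336, 1260,
                                      1300, 1310)))
  expect_true(res$recommend_pxm)
  expect_true(all(c("off_panel_allele", "shared_eplet") %in% res$reasons))

  # strong allele-matched DSA: recommendation only through the CDC rule
  with_cdc <- vxm_assess(donor_typing("d", "B*08:01"),
                         mk_panel("B*08:01", 12235))
  expect_true(with_cdc$recommend_pxm)
  expect_true("indeterminate_prediction" %in% with_cdc$reasons)
  no_cdc <- vxm_assess(donor_typing("d", "B*08:01"),
                       mk_panel("B*08:01", 12235), predict_cdc = FALSE)
  expect_false(no_cdc$recommend_pxm)

  # clean negative assessment with full representation
  clean <- vxm_assess(donor_typing("d", "A*01:01"),
                      mk_panel(c("A*01:01", "B*07:02"), c(100, 50)),
                      predict_cdc = FALSE)
  expect_false(clean$recommend_pxm)
  expect_identical(clean$reasons, character())

  # donor entry with zero representation on a supplied panel of its class
  unrep <- vxm_assess(donor_typing("d", c("A*01:01", "C*07:01")),
                      mk_panel(c("A*01:01", "B*07:02"), c(100, 50)),
                      predict_cdc = FALSE)
  expect_true(unrep$recommend_pxm)
  expect_true("locus_unrepresented" %in% unrep$reasons)
})

test_that("adding a DSA never flips a prediction from positive to negative", {
  th <- prediction_thresholds()
  set.seed(7)
  pool <- c("A*01:01", "A*02:01", "B*07:02", "B*08:01", "C*02:02",
            "C*05:01", "B*18:01", "A*24:02")
  for (rep in 1:20) {
    k <- sample(2:7, 1)
    specs <- sample(pool, k)
    mfis <- runif(k, 0, 9000)
    donor_small <- donor_typing("d", specs[1])
    donor_big <- donor_typing("d", specs[1:min(2, k)])
    panel <- mk_panel(specs, mfis)
    small <- predict_fcxm(identify_dsa(donor_small, panel,
                                       include_eplet_calls = FALSE), th)
    big <- predict_fcxm(identify_dsa(donor_big, panel,
                                     include_eplet_calls = FALSE), th)
    for (cell in c("t", "b")) {
      if (small[[cell]] == "positive") expect_true(big[[cell]] != "negative")
    }
  }
})

test_that("identify_dsa agrees with the brute-force oracle on small cases", {
  set.seed(11)
  for (rep in 1:60) expect_true(compare_to_oracle(random_instance()))
})

test_that("result objects serialize to JSON", {
  res <- vxm_assess(donor_typing("d", "B*08:01"), mk_panel("B*08:01", 12235))
  path <- withr::local_tempfile(fileext = ".json")
  write_vxm_result(res, path)
  back <- jsonlite::read_json(path)
  expect_identical(back$predictions$t_fcxm, "positive")
  expect_identical(back$donor_id, "d")
})
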