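dict <- demo_dictionary()

test_that("percent_int rounds half-up", {
  expect_equal(percent_int(0, 100), 0L)
  expect_equal(percent_int(79, 200), 40L)   # 39.5 rounds up
  expect_equal(percent_int(1, 3), 33L)
  expect_equal(percent_int(2, 3), 67L)
  expect_equal(percent_int(c(1, 3), c(2, 4)), c(50L, 75L))
  expect_error(percent_int(1, 0), "positive")
})

test_that("characteristics of a single case", {
  st <- icsr_store(mk_report("R1", seriousness = "serious"),
                   mk_drug("R1"),
                   mk_reaction("R1", flags = "hospitalization"))
  ch <- case_characteristics(st, tki_drugs(), dict)
  expect_equal(ch$n[["All"]], 1L)
  expect_equal(ch$n[["IMATINIB"]], 1L)
  bl <- ch$blocks
  male <- bl[bl$block == "sex" & bl$level == "male" & bl$drug == "All", ]
  expect_equal(male$n, 1L); expect_equal(male$pct, 100L)
  ser <- bl[bl$block == "seriousness" & bl$level == "serious" &
              bl$drug == "All", ]
  expect_equal(ser$pct, 100L)
  hlt <- bl[bl$block == "hlt" & bl$drug == "IMATINIB" &
              bl$level == "Renal failure and impairment", ]
  expect_equal(hlt$n, 1L)
  disc <- bl[bl$block == "discontinuation" & bl$drug == "All", ]
  expect_equal(disc$n, 1L)  # action_taken = withdrawn
})

test_that("age summary uses the sample (n-1) standard deviation", {
  st <- icsr_store(rbind(mk_report("R1", age = 60),
                         mk_report("R2", age = 64)),
                   rbind(mk_drug("R1"), mk_drug("R2")),
                   rbind(mk_reaction("R1"), mk_reaction("R2")))
  ch <- case_characteristics(st, "IMATINIB", dict)
  all_row <- ch$age[ch$age$drug == "All", ]
  expect_equal(all_row$mean, 62)
  expect_equal(all_row$sd, sqrt(8), tolerance = 1e-12)  # 2.8284
})

test_that("a case without an index drug violates the selection contract", {
  st <- icsr_store(mk_report("R1"), mk_drug("R1", code = "COMP01"),
                   mk_reaction("R1"))
  expect_error(case_characteristics(st, tki_drugs(), dict), "index drug")
})

test_that("tto_summary computes interpolated quartiles per (drug, HLT)", {
  onsets <- format(as.Date("2015-01-01") + c(10, 20, 30, 40))
  st <- icsr_store(
    mk_report("R1"),
    mk_drug("R1", start = "2015-01-01"),
    rbind(mk_reaction("R1", pt = "PT_AKI", onset = onsets[1]),
          mk_reaction("R1", pt = "PT_CKD", onset = onsets[2]),
          mk_reaction("R1", pt = "PT_OLIGURIA", onset = onsets[3]),
          mk_reaction("R1", pt = "PT_RENAL_FAILURE", onset = onsets[4])))
  tt <- tto_summary(st, "IMATINIB", dict)
  row <- tt[tt$drug == "IMATINIB" & tt$hlt_code == "HLT_RENAL_FAIL", ]
  expect_equal(row$median, 25)
  expect_equal(row$q25, 17.5)
  expect_equal(row$q75, 32.5)
  expect_equal(row$n_with_tto, 1L)   # one case contributed the pool
  expect_equal(row$n_total, 1L)
  expect_false(row$display)          # n_total not above 3
  expect_false(row$tto_known)        # single case: rendered as UNK
})

test_that("display and known flags follow the strict thresholds", {
  # three cases in one HLT: display stays FALSE (threshold is strict);
  # four cases: display TRUE
  build <- function(k) {
    ids <- sprintf("R%d", 1:k)
    icsr_store(do.call(rbind, lapply(ids, mk_report)),
               do.call(rbind, lapply(ids, mk_drug)),
               do.call(rbind, lapply(ids, function(i) {
                 mk_reaction(i, pt = "PT_AKI")
               })))
  }
  t3 <- tto_summary(build(3L), "IMATINIB", dict)
  expect_false(t3$display[t3$hlt_code == "HLT_RENAL_FAIL" &
                            t3$drug == "IMATINIB"])
  t4 <- tto_summary(build(4L), "IMATINIB", dict)
  expect_true(t4$display[t4$hlt_code == "HLT_RENAL_FAIL" &
                           t4$drug == "IMATINIB"])
  # single observed TTO in a cell of many cases is still "UNK"
  expect_true(all(t4$n_with_tto <= t4$n_total))
})

test_that("summaries are stable under report reordering", {
  st <- generate_icsr_store(default_synthetic_config(n_reports = 4000L,
                                                     seed = 61L))
  sel <- select_cases(st, selection_config(), dict)
  cases <- sel$cases
  ch1 <- case_characteristics(cases, tki_drugs(), dict)
  perm <- withr::with_seed(3L, sample(nrow(cases$reports)))
  cases2 <- icsr_store(cases$reports[perm, ], cases$drugs, cases$reactions,
                       validate = FALSE)
  ch2 <- case_characteristics(cases2, tki_drugs(), dict)
  expect_equal(ch2$n, ch1$n)
  expect_equal(ch2$age$mean, ch1$age$mean)
  b1 <- ch1$blocks[order(ch1$blocks$block, ch1$blocks$level, ch1$blocks$drug), ]
  b2 <- ch2$blocks[order(ch2$blocks$block, ch2$blocks$level, ch2$blocks$drug), ]
  rownames(b1) <- rownames(b2) <- NULL
  expect_equal(b2, b1)

  # conservation: sex counts sum to n per drug
  sex <- ch1$blocks[ch1$blocks$block == "sex", ]
  for (g in names(ch1$n)) {
    expect_equal(sum(sex$n[sex$drug == g]), unname(ch1$n[[g]]))
  }
  # quantiles are permutation-invariant
  t1 <- suppressWarnings(tto_summary(cases, tki_drugs(), dict))
  t2 <- suppressWarnings(tto_summary(cases2, tki_drugs(), dict))
  expect_equal(t2[order(t2$drug, t2$hlt_code), "median"],
               t1[order(t1$drug, t1$hlt_code), "median"])
})
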