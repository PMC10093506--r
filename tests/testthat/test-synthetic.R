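test_that("generation is a pure function of the configuration", {
  cfg <- default_synthetic_config(n_reports = 500L, seed = 9L,
                                  signals = signal_spec("DASATINIB",
                                                        "PT_TMA", 4))
  s1 <- generate_icsr_store(cfg)
  s2 <- generate_icsr_store(cfg)
  expect_identical(s1, s2)
  # a different seed changes the draw
  cfg2 <- default_synthetic_config(n_reports = 500L, seed = 10L)
  expect_false(identical(generate_icsr_store(cfg2)$reports, s1$reports))
})

test_that("configuration validation rejects malformed inputs", {
  dm <- c(A = 0.5, B = 0.6)
  expect_error(synthetic_config(10, dm, c(P = 0.1)), "sum to 1")
  expect_error(synthetic_config(10, c(A = 1), c(P = 0)), "\\(0, 1\\)")
  expect_error(synthetic_config(10, c(A = 1), c(P = 0.1),
                                signals = signal_spec("NOPE", "P", 2)),
               "undeclared")
  expect_error(synthetic_config(10, c(A = 1), c(P = 0.1),
                                duplicate_rate = 1), "rates")
  expect_error(signal_spec("A", "P", -1))
})

test_that("expected_ror is the closed-form truth of the model", {
  null_cfg <- default_synthetic_config(n_reports = 10L)
  expect_equal(expected_ror(null_cfg, "IMATINIB", "PT_AKI"), 1)
  cfg <- default_synthetic_config(
    n_reports = 10L,
    signals = signal_spec("NILOTINIB", "PT_NEPHROTIC_SYNDROME", 5))
  expect_equal(expected_ror(cfg, "NILOTINIB", "PT_NEPHROTIC_SYNDROME"), 5)
  # independence across drugs: other pairs stay null
  expect_equal(expected_ror(cfg, "IMATINIB", "PT_NEPHROTIC_SYNDROME"), 1)
  expect_equal(expected_ror(cfg, "NILOTINIB", "PT_AKI"), 1)
  expect_error(expected_ror(cfg, "NOPE", "PT_AKI"), "unknown drug")
  expect_error(expected_ror(cfg, "IMATINIB", "NOPE"), "unknown PT")
})

test_that("the decorated store reproduces the exposure core draw exactly", {
  cfg <- default_synthetic_config(
    n_reports = 3000L, seed = 11L, duplicate_rate = 0,
    signals = signal_spec("IMATINIB", "PT_AKI", 4))
  st <- generate_icsr_store(cfg)
  ex <- withr::with_seed(cfg$seed, rorscreen:::.draw_exposure(cfg))
  tab <- build_contingency_table(st, "IMATINIB", "PT_AKI")
  dpos <- ex$drug == "IMATINIB"
  epos <- ex$pts[, "PT_AKI"]
  expect_equal(tab$a, sum(dpos & epos))
  expect_equal(tab$b, sum(!dpos & epos))
  expect_equal(tab$c, sum(dpos & !epos))
  expect_equal(tab$d, sum(!dpos & !epos))
  # every report carries at least one reaction (redraw invariant)
  expect_true(all(st$reports$report_id %in% st$reactions$report_id))
})

test_that("null model: empirical odds ratios sit near 1", {
  cfg <- default_synthetic_config(n_reports = 50000L, seed = 13L,
                                  duplicate_rate = 0)
  st <- generate_icsr_store(cfg)
  # pairs with common PTs, so Monte-Carlo error on log-ROR is small
  for (pair in list(c("IMATINIB", "PT_NAUSEA"),
                    c("DASATINIB", "PT_HEADACHE"),
                    c("NILOTINIB", "PT_FATIGUE"))) {
    tab <- build_contingency_table(st, pair[1L], pair[2L])
    est <- ror_ci(tab)
    expect_true(est$computable)
    expect_lt(abs(log(est$ror)), 0.35)
  }
})

test_that("inject_duplicates plants recoverable exact copies", {
  cfg <- default_synthetic_config(n_reports = 200L, seed = 21L,
                                  duplicate_rate = 0)
  st <- generate_icsr_store(cfg)

  none <- inject_duplicates(st, 0, seed = 1L)
  expect_identical(none$store, st)
  expect_equal(nrow(none$mapping), 0L)

  dup <- inject_duplicates(st, 0.1, seed = 2L)
  expect_equal(n_reports(dup$store), 220L)
  expect_equal(nrow(dup$mapping), 20L)
  # a planted copy shares every matched field with its original
  orig <- dup$store$reports[dup$store$reports$report_id %in%
                              dup$mapping$original_id, ]
  copy <- dup$store$reports[dup$store$reports$report_id %in%
                              dup$mapping$duplicate_id, ]
  expect_equal(orig$country, copy$country)
  expect_equal(orig$age_years, copy$age_years)
  expect_equal(orig$report_date, copy$report_date)

  # deduplication recovers the original store size
  dd <- deduplicate_reports(dup$store)
  expect_equal(n_reports(dd$store), n_reports(st))
  expect_setequal(dd$removed_ids, dup$mapping$duplicate_id)
})

test_that("the 95% interval covers the true ROR at its nominal rate", {
  # 200 replicates at n = 50,000, injected odds multiplier 3; the binomial
  # acceptance band at R = 200 is 91-98%
  cfg <- coverage_config(n_reports = 50000L, lambda = 3)
  cov <- simulate_ror_coverage(cfg, "IMATINIB", "PT_NEPHROTIC_SYNDROME",
                               n_rep = 200L, seed = 101L)
  expect_equal(cov$true_ror, 3)
  expect_gte(cov$coverage, 0.91)
  expect_lte(cov$coverage, 0.98)
  # the estimator is centred on the truth on the log scale
  expect_lt(abs(mean(log(cov$estimates$ror)) - log(3)), 0.1)
})
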