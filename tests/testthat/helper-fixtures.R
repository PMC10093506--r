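# Independent reference implementation of the odds ratio and its log-scale
# (Woolf) confidence interval, coded from scratch for oracle comparisons.
# Deliberately uses a different formulation (log-sum arithmetic, quantile
# from the confidence level) than ror_ci().
oracle_or_ci <- function(a, b, c, d, conf = 0.95) {
  est <- exp((log(a) + log(d)) - (log(b) + log(c)))
  z <- qnorm(1 - (1 - conf) / 2)
  hw <- z * sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = est, lo = est * exp(-hw), hi = est * exp(hw))
}

# minimal 6-term dictionary: one SOC, two HLTs, three PTs, p2 multi-parent
hand_dict <- function() {
  term_dictionary(
    terms = data.frame(
      code = c("S", "HA", "HB", "p1", "p2", "p3"),
      name = c("Some SOC", "Hlt A", "Hlt B", "P one", "P two", "P three"),
      level = c("SOC", "HLT", "HLT", "PT", "PT", "PT")),
    links = data.frame(
      child_code = c("HA", "HB", "p1", "p2", "p2", "p3"),
      parent_code = c("S", "S", "HA", "HA", "HB", "HB")))
}

mk_report <- function(id, date = "2015-06-01", reporter = "physician",
                      age = 60, sex = "male", country = "FR",
                      seriousness = "not_serious") {
  data.frame(report_id = id, report_date = date, country = country,
             reporter = reporter, age_years = age, sex = sex,
             seriousness = seriousness, stringsAsFactors = FALSE)
}
mk_drug <- function(id, code = "IMATINIB", role = "suspected",
                    start = "2015-01-01", action = "withdrawn",
                    indication = "Chronic myeloid leukemia") {
  data.frame(report_id = id, drug_code = code, role = role,
             start_date = start, action_taken = action,
             indication = indication, stringsAsFactors = FALSE)
}
mk_reaction <- function(id, pt = "PT_RENAL_FAILURE", onset = "2015-05-01",
                        outcome = "recovered", flags = "") {
  data.frame(report_id = id, pt_code = pt, onset_date = onset,
             outcome = outcome, serious_flags = flags,
             stringsAsFactors = FALSE)
}

# eight reports: one violating each selection rule, two compliant; ages
# differ so no two reports share the duplicate key
hand8_store <- function() {
  reports <- rbind(
    mk_report("R1"),
    mk_report("R2", age = 45, sex = "female"),
    mk_report("R3", date = "2022-01-01", age = 61),
    mk_report("R4", reporter = "consumer", age = 62),
    mk_report("R5", age = 63),
    mk_report("R6", age = 64),
    mk_report("R7", age = NA),
    mk_report("R8", sex = "unknown", age = 65))
  drugs <- rbind(
    mk_drug("R1"),
    mk_drug("R2", code = "DASATINIB", role = "interacting"),
    mk_drug("R2", code = "COMP01", role = "concomitant"),
    mk_drug("R3"),
    mk_drug("R4"),
    mk_drug("R5", code = "COMP01", role = "suspected"),
    mk_drug("R5", role = "concomitant"),
    mk_drug("R6"),
    mk_drug("R7"),
    mk_drug("R8"))
  reactions <- rbind(
    mk_reaction("R1"),
    mk_reaction("R2", pt = "PT_AKI"),
    mk_reaction("R3"),
    mk_reaction("R4"),
    mk_reaction("R5"),
    mk_reaction("R6", pt = "PT_FLUID_RETENTION"),
    mk_reaction("R7"),
    mk_reaction("R8"))
  icsr_store(reports, drugs, reactions)
}

empty_store <- function() {
  icsr_store(
    data.frame(report_id = character(0), report_date = character(0),
               country = character(0), reporter = character(0),
               age_years = numeric(0), sex = character(0),
               seriousness = character(0)),
    data.frame(report_id = character(0), drug_code = character(0),
               role = character(0), start_date = character(0),
               action_taken = character(0), indication = character(0)),
    data.frame(report_id = character(0), pt_code = character(0),
               onset_date = character(0), outcome = character(0),
               serious_flags = character(0)))
}

# stores are equal up to the writer's canonical row order (stable sort by
# report_id, within-report order preserved)
expect_store_equal <- function(x, y) {
  strip <- function(df) {
    df <- df[order(df$report_id), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  expect_equal(strip(x$reports), strip(y$reports))
  expect_equal(strip(x$drugs), strip(y$drugs))
  expect_equal(strip(x$reactions), strip(y$reactions))
}
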