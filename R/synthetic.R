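#' Specification of an injected drug-event association
#'
#' A signal multiplies the reporting odds of one PT, for reports whose
#' suspected drug is the given one, by `lambda`. With one suspected drug
#' per report and independent PT inclusion, the population reporting odds
#' ratio of the injected pair is exactly `lambda` (and 1 for non-injected
#' pairs), giving an analytic truth for recovery and coverage experiments.
#'
#' @param drug_code,pt_code codes declared in the generator configuration.
#' @param lambda positive odds multiplier; 1 means no association.
#' @return one-row data.frame usable as the `signals` argument of
#'   [synthetic_config()].
#' @export
signal_spec <- function(drug_code, pt_code, lambda) {
  stopifnot(is.numeric(lambda), all(lambda > 0))
  data.frame(drug_code = as.character(drug_code),
             pt_code = as.character(pt_code),
             lambda = as.numeric(lambda),
             stringsAsFactors = FALSE)
}

#' Configuration of the synthetic spontaneous-report generator
#'
#' Defines the generative model: each report draws one suspected drug from
#' `drug_marginals`; each PT is included independently with probability
#' `pt_marginals[p]`, except injected (drug, PT) pairs whose inclusion
#' odds are multiplied by `lambda`; reports with no reaction are redrawn
#' (every ICSR carries at least one reaction). Demographics, dates,
#' outcomes and seriousness are drawn from fixed documented distributions
#' that loosely emulate published cohort characteristics; the `*_rate`
#' parameters plant records that each case-selection rule must reject.
#' Identical configurations (including `seed`) yield identical stores.
#'
#' @param n_reports number of reports before duplication.
#' @param drug_marginals named probability vector over drug codes, summing
#'   to 1 (one suspected drug per report).
#' @param pt_marginals named vector of per-PT independent inclusion
#'   probabilities, each in (0, 1).
#' @param signals data.frame from [signal_spec()] (possibly 0 rows).
#' @param duplicate_rate fraction of near-copy reports appended, in \[0, 1).
#' @param missing_age_rate,missing_sex_rate,consumer_reporter_rate,out_of_window_rate
#'   rates in \[0, 1) exercising the age, sex, reporter and date-window
#'   exclusion rules.
#' @param date_window length-2 vector of reporting-window dates.
#' @param tto_report_rate fraction of reports carrying a drug start date
#'   (hence a computable time to onset).
#' @param concomitant_rate fraction of reports decorated with an extra
#'   concomitant drug (never enters case/non-case classification).
#' @param seed integer seed; the generator is a pure function of the
#'   configuration including the seed.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_reports,
                             drug_marginals,
                             pt_marginals,
                             signals = signal_spec(character(0), character(0),
                                                   numeric(0)),
                             duplicate_rate = 0,
                             missing_age_rate = 0.05,
                             missing_sex_rate = 0.03,
                             consumer_reporter_rate = 0.10,
                             out_of_window_rate = 0.02,
                             date_window = c("2001-11-07", "2021-06-02"),
                             tto_report_rate = 0.4,
                             concomitant_rate = 0.3,
                             seed = 1L) {
  stopifnot(is.numeric(n_reports), length(n_reports) == 1L, n_reports >= 1)
  if (is.null(names(drug_marginals)) || anyNA(names(drug_marginals))) {
    stop("drug_marginals must be a named probability vector")
  }
  if (abs(sum(drug_marginals) - 1) > 1e-8 || any(drug_marginals < 0)) {
    stop("drug_marginals must be nonnegative and sum to 1")
  }
  if (is.null(names(pt_marginals)) || any(pt_marginals <= 0) ||
      any(pt_marginals >= 1)) {
    stop("pt_marginals must be named with all probabilities in (0, 1)")
  }
  signals <- as.data.frame(signals, stringsAsFactors = FALSE)
  if (nrow(signals)) {
    stopifnot(all(c("drug_code", "pt_code", "lambda") %in% names(signals)))
    if (any(signals$lambda <= 0)) stop("signal lambda must be positive")
    bad_d <- setdiff(signals$drug_code, names(drug_marginals))
    bad_p <- setdiff(signals$pt_code, names(pt_marginals))
    if (length(bad_d) || length(bad_p)) {
      stop("signal references undeclared code(s): ",
           paste(c(bad_d, bad_p), collapse = ", "))
    }
  }
  rates <- c(duplicate_rate, missing_age_rate, missing_sex_rate,
             consumer_reporter_rate, out_of_window_rate)
  if (any(rates < 0) || any(rates >= 1)) {
    stop("all rates must lie in [0, 1)")
  }
  date_window <- as.Date(date_window)
  stopifnot(length(date_window) == 2L, !anyNA(date_window),
            date_window[1L] <= date_window[2L])
  structure(list(n_reports = as.integer(n_reports),
                 drug_marginals = drug_marginals,
                 pt_marginals = pt_marginals,
                 signals = signals,
                 duplicate_rate = duplicate_rate,
                 missing_age_rate = missing_age_rate,
                 missing_sex_rate = missing_sex_rate,
                 consumer_reporter_rate = consumer_reporter_rate,
                 out_of_window_rate = out_of_window_rate,
                 date_window = date_window,
                 tto_report_rate = tto_report_rate,
                 concomitant_rate = concomitant_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# the stated default world: 5 index TKIs at 2% each, 9 comparator drugs,
# rare renal PTs plus common decoy PTs so that conditioning on >=1
# reaction stays mild
.default_drug_marginals <- function() {
  c(setNames(rep(0.02, 5L), tki_drugs()),
    setNames(rep(0.9 / 9, 9L), sprintf("COMP%02d", 1:9)))
}

.default_pt_marginals <- function() {
  c(PT_TIN = 0.002, PT_AKI = 0.008, PT_CKD = 0.006, PT_OLIGURIA = 0.002,
    PT_RENAL_FAILURE = 0.010, PT_RENAL_IMPAIRMENT = 0.006,
    PT_FLUID_RETENTION = 0.010, PT_RENAL_DISORDER = 0.008,
    PT_NEPHROPATHY = 0.003, PT_TOXIC_NEPHROPATHY = 0.002,
    PT_NEPHROTIC_SYNDROME = 0.010, PT_RAS = 0.002, PT_TMA = 0.003,
    PT_NAUSEA = 0.25, PT_VOMITING = 0.15, PT_DIARRHOEA = 0.15,
    PT_HEADACHE = 0.20, PT_FATIGUE = 0.20, PT_RASH = 0.15,
    PT_OEDEMA_PERIPH = 0.10, PT_CYSTITIS = 0.05)
}

#' Default synthetic-database configuration
#'
#' The package's stated synthetic world: five index tyrosine kinase
#' inhibitors at 2% of reports each, nine comparator drugs sharing the
#' remaining 90%, the thirteen renally screened PTs at rare inclusion
#' probabilities (0.002-0.01) plus eight common decoy PTs, and default
#' missingness/duplication rates exercising every exclusion rule. All PT
#' codes exist in [demo_dictionary()].
#'
#' @param n_reports,seed,signals,... passed to [synthetic_config()].
#' @return a [synthetic_config()].
#' @export
default_synthetic_config <- function(n_reports = 50000L, seed = 1L,
                                     signals = signal_spec(character(0),
                                                           character(0),
                                                           numeric(0)),
                                     duplicate_rate = 0.02, ...) {
  synthetic_config(n_reports = n_reports,
                   drug_marginals = .default_drug_marginals(),
                   pt_marginals = .default_pt_marginals(),
                   signals = signals, seed = seed,
                   duplicate_rate = duplicate_rate, ...)
}

#' Configuration for the interval-coverage experiment
#'
#' The default world with a single injected signal of odds multiplier
#' `lambda` on the (imatinib, nephrotic syndrome) pair, the signal PT at
#' inclusion probability 0.01, and no planted duplicates, so the 2x2
#' table built directly from a generated store estimates a true reporting
#' odds ratio of exactly `lambda`.
#'
#' @param n_reports database size per replicate.
#' @param lambda true reporting odds ratio of the injected pair.
#' @param seed integer seed.
#' @return a [synthetic_config()].
#' @export
coverage_config <- function(n_reports = 50000L, lambda = 3, seed = 1L) {
  default_synthetic_config(
    n_reports = n_reports, seed = seed,
    signals = signal_spec("IMATINIB", "PT_NEPHROTIC_SYNDROME", lambda),
    duplicate_rate = 0)
}

#' Population reporting odds ratio of the generative model
#'
#' Closed-form truth: with one suspected drug per report and independent
#' PT inclusion, the reporting odds ratio of an injected pair equals its
#' odds multiplier `lambda` and that of any other pair equals 1. The
#' redraw of zero-reaction reports leaves this unchanged when at most one
#' signal involves the queried PT, because the conditioning factor (the
#' probability of carrying some other reaction) is identical in the
#' drug-positive and drug-negative groups; with several overlapping
#' signals the value is approximate (the comparator group is then slightly
#' contaminated, the usual masking phenomenon of spontaneous-report
#' databases).
#'
#' @param config a [synthetic_config()].
#' @param drug_code,pt_code declared codes.
#' @return positive scalar.
#' @export
expected_ror <- function(config, drug_code, pt_code) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!(drug_code %in% names(config$drug_marginals))) {
    stop("unknown drug code: ", drug_code)
  }
  if (!(pt_code %in% names(config$pt_marginals))) {
    stop("unknown PT code: ", pt_code)
  }
  s <- config$signals
  hit <- which(s$drug_code == drug_code & s$pt_code == pt_code)
  if (length(hit)) s$lambda[hit[1L]] else 1
}

# Core exposure draw: suspected drug per report and the report x PT
# inclusion matrix, with zero-reaction reports redrawn. This is the exact
# sampling step of generate_icsr_store(); simulate_ror_coverage() calls it
# directly so coverage replicates share the generator's code path without
# paying for demographic decoration.
.draw_exposure <- function(config) {
  n <- config$n_reports
  q <- config$pt_marginals
  npt <- length(q)
  drug <- sample(names(config$drug_marginals), n, replace = TRUE,
                 prob = config$drug_marginals)
  draw_block <- function(block_drugs) {
    k <- length(block_drugs)
    m <- matrix(runif(k * npt), nrow = k, ncol = npt) < rep(q, each = k)
    s <- config$signals
    for (i in seq_len(nrow(s))) {
      rows <- which(block_drugs == s$drug_code[i])
      if (!length(rows)) next
      j <- match(s$pt_code[i], names(q))
      odds <- s$lambda[i] * q[j] / (1 - q[j])
      m[rows, j] <- runif(length(rows)) < odds / (1 + odds)
    }
    m
  }
  pts <- draw_block(drug)
  repeat {
    empty <- which(rowSums(pts) == 0L)
    if (!length(empty)) break
    pts[empty, ] <- draw_block(drug[empty])
  }
  colnames(pts) <- names(q)
  list(drug = drug, pts = pts)
}

.sample_truncnorm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  repeat {
    bad <- which(x < lo | x > hi)
    if (!length(bad)) break
    x[bad] <- rnorm(length(bad), mean, sd)
  }
  x
}

.COUNTRIES <- c(US = 0.35, JP = 0.15, DE = 0.08, FR = 0.08, GB = 0.05,
                IT = 0.05, ES = 0.05, AU = 0.05, CA = 0.04, BR = 0.10)
.INDICATIONS <- c("Chronic myeloid leukemia" = 0.50,
                  "Gastrointestinal tumor" = 0.08,
                  "Acute lymphoid leukemia" = 0.04,
                  "Other" = 0.18)  # remaining 0.20: indication missing

#' Generate a synthetic ICSR store
#'
#' Draws `n_reports` reports from the generative model of
#' [synthetic_config()], decorates them with demographics, dates, drug and
#' reaction attributes, and (if `duplicate_rate > 0`) appends planted
#' near-duplicate reports. The result is a fully validated
#' [icsr_store()]; the same configuration always yields the same store.
#'
#' @param config a [synthetic_config()].
#' @return an [icsr_store()].
#' @export
generate_icsr_store <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, .generate_impl(config))
}

.generate_impl <- function(config) {
  n <- config$n_reports
  ex <- .draw_exposure(config)

  report_id <- sprintf("R%07d", seq_len(n))
  win <- config$date_window
  span <- as.integer(win[2L] - win[1L])
  report_date <- win[1L] + (sample.int(span + 1L, n, replace = TRUE) - 1L)
  oow <- runif(n) < config$out_of_window_rate
  if (any(oow)) {
    k <- sum(oow)
    off <- sample.int(365L, k, replace = TRUE)
    before <- runif(k) < 0.5
    d <- report_date[oow]
    d[before] <- win[1L] - off[before]
    d[!before] <- win[2L] + off[!before]
    report_date[oow] <- d
  }

  reporter <- ifelse(runif(n) < config$consumer_reporter_rate, "consumer",
                     sample(c("physician", "pharmacist",
                              "other_health_professional"),
                            n, replace = TRUE, prob = c(0.62, 0.18, 0.20)))
  age <- round(.sample_truncnorm(n, 64, 14, 18, 100), 1L)
  age[runif(n) < config$missing_age_rate] <- NA_real_
  sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.54, 0.46))
  sex[runif(n) < config$missing_sex_rate] <- "unknown"
  country <- sample(names(.COUNTRIES), n, replace = TRUE, prob = .COUNTRIES)
  seriousness <- sample(SERIOUSNESS_LEVELS, n, replace = TRUE,
                        prob = c(0.79, 0.17, 0.04))

  # reaction rows from the inclusion matrix, grouped by report
  hit <- which(ex$pts, arr.ind = TRUE)
  hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
  r_row <- hit[, 1L]
  rx_n <- nrow(hit)
  pt_code <- colnames(ex$pts)[hit[, 2L]]
  onset <- report_date[r_row] - sample.int(61L, rx_n, replace = TRUE) + 1L
  onset[runif(rx_n) > 0.9] <- NA
  outcome <- sample(OUTCOME_LEVELS, rx_n, replace = TRUE,
                    prob = c(0.16, 0.10, 0.10, 0.01, 0.14, 0.49))

  # a fatal reaction forces report seriousness and the death criterion
  fatal_rep <- unique(r_row[outcome == "fatal"])
  seriousness[fatal_rep] <- "serious"
  flags <- character(rx_n)
  is_serious_rep <- seriousness[r_row] == "serious"
  first_of_report <- !duplicated(r_row)
  lead <- is_serious_rep & first_of_report
  flags[lead] <- ifelse(runif(sum(lead)) < 0.6, "hospitalization",
                        "other_medically_significant")
  is_fatal <- outcome == "fatal"
  flags[is_fatal] <- ifelse(nzchar(flags[is_fatal]),
                            paste(flags[is_fatal], "death", sep = "|"),
                            "death")

  reactions <- data.frame(report_id = report_id[r_row], pt_code = pt_code,
                          onset_date = onset, outcome = outcome,
                          serious_flags = flags, stringsAsFactors = FALSE)

  # index drug entry: one suspected drug per report
  first_onset <- rep(as.Date(NA), n)
  has_onset <- !is.na(onset)
  fo <- tapply(as.integer(onset[has_onset]), r_row[has_onset], min)
  first_onset[as.integer(names(fo))] <- as.Date(fo, origin = "1970-01-01")
  anchor <- first_onset
  anchor[is.na(anchor)] <- report_date[is.na(anchor)]
  tto <- pmax(0L, as.integer(round(rlnorm(n, log(120), 1.1))))
  start_date <- anchor - tto
  start_date[runif(n) > config$tto_report_rate] <- NA
  action <- sample(ACTION_LEVELS, n, replace = TRUE,
                   prob = c(0.39, 0.08, 0.27, 0.26))
  ind_draw <- runif(n)
  indication <- rep(NA_character_, n)
  known_ind <- ind_draw < sum(.INDICATIONS)
  indication[known_ind] <- sample(names(.INDICATIONS), sum(known_ind),
                                  replace = TRUE, prob = .INDICATIONS)
  drugs <- data.frame(report_id = report_id, drug_code = ex$drug,
                      role = "suspected", start_date = start_date,
                      action_taken = action, indication = indication,
                      stringsAsFactors = FALSE)

  comparators <- grep("^COMP", names(config$drug_marginals), value = TRUE)
  with_con <- which(runif(n) < config$concomitant_rate)
  if (length(with_con) && length(comparators)) {
    drugs <- rbind(drugs, data.frame(
      report_id = report_id[with_con],
      drug_code = sample(comparators, length(with_con), replace = TRUE),
      role = "concomitant", start_date = as.Date(NA),
      action_taken = "unknown", indication = NA_character_,
      stringsAsFactors = FALSE))
    drugs <- drugs[order(drugs$report_id), , drop = FALSE]
  }

  reports <- data.frame(report_id = report_id, report_date = report_date,
                        country = country, reporter = reporter,
                        age_years = age, sex = sex,
                        seriousness = seriousness, stringsAsFactors = FALSE)
  store <- icsr_store(reports, drugs, reactions)
  if (config$duplicate_rate > 0) {
    store <- .plant_duplicates(store, config$duplicate_rate)$store
  }
  store
}

.plant_duplicates <- function(store, rate) {
  n <- n_reports(store)
  k <- floor(rate * n)
  if (k == 0L) {
    return(list(store = store,
                mapping = data.frame(original_id = character(0),
                                     duplicate_id = character(0))))
  }
  originals <- sort(sample(store$reports$report_id, k, replace = FALSE))
  dup_id <- paste0(originals, "-DUP")
  cp <- function(df) {
    out <- df[df$report_id %in% originals, , drop = FALSE]
    out$report_id <- setNames(dup_id, originals)[out$report_id]
    out
  }
  list(store = icsr_store(rbind(store$reports, cp(store$reports)),
                          rbind(store$drugs, cp(store$drugs)),
                          rbind(store$reactions, cp(store$reactions)),
                          validate = FALSE),
       mapping = data.frame(original_id = originals, duplicate_id = dup_id,
                            stringsAsFactors = FALSE))
}

#' Plant near-duplicate reports
#'
#' Appends `floor(rate * n)` exact-field copies of randomly chosen reports
#' under new report identifiers (the original id with a `-DUP` suffix,
#' which sorts after the original so [deduplicate_reports()] keeps the
#' original). Planted duplicates are exact copies of all matched fields, a
#' declared simplification of real-world fuzzy duplicates.
#'
#' @param store an [icsr_store()].
#' @param rate duplication rate in \[0, 1).
#' @param seed integer seed.
#' @return list with elements `store` (augmented) and `mapping`
#'   (data.frame of `original_id`, `duplicate_id` pairs).
#' @export
inject_duplicates <- function(store, rate, seed = 1L) {
  stopifnot(inherits(store, "icsr_store"), rate >= 0, rate < 1)
  withr::with_seed(seed, .plant_duplicates(store, rate))
}

#' Empirical coverage of the ROR confidence interval
#'
#' Repeatedly draws databases from the generative model, builds the 2x2
#' table for one (drug, PT) pair, computes the log-scale Wald interval via
#' [ror_ci()], and reports the fraction of intervals containing the true
#' reporting odds ratio of the model ([expected_ror()]). Each replicate
#' runs the generator's own exposure sampling step (`.draw_exposure`, the
#' code path of [generate_icsr_store()]), skipping only the demographic
#' decoration that cannot affect the table. A replicate whose table is not
#' computable (a zero cell) counts as a miss.
#'
#' @param config a [synthetic_config()]; its `seed` is ignored in favour
#'   of per-replicate seeds derived from `seed`.
#' @param drug_code,pt_code the pair under study.
#' @param n_rep number of replicate databases.
#' @param z normal quantile of the interval (1.96 for 95%).
#' @param seed master seed for the replicate seed sequence.
#' @return list with `coverage` (fraction in \[0, 1\]), `hits` (logical
#'   vector), `estimates` (data.frame of per-replicate a, b, c, d, ror,
#'   ci_low, ci_high), `true_ror` and `n_rep`.
#' @export
simulate_ror_coverage <- function(config, drug_code, pt_code,
                                  n_rep = 200L, z = 1.96, seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  true_ror <- expected_ror(config, drug_code, pt_code)
  j_check <- match(pt_code, names(config$pt_marginals))
  stopifnot(!is.na(j_check))
  rep_seeds <- withr::with_seed(seed, sample.int(2147483646L, n_rep))
  rows <- vector("list", n_rep)
  for (i in seq_len(n_rep)) {
    ex <- withr::with_seed(rep_seeds[i], .draw_exposure(config))
    dpos <- ex$drug == drug_code
    epos <- ex$pts[, pt_code]
    a <- sum(dpos & epos); b <- sum(!dpos & epos)
    cc <- sum(dpos & !epos); d <- sum(!dpos & !epos)
    ci <- ror_ci(a, b, cc, d, z = z)
    rows[[i]] <- data.frame(a = a, b = b, c = cc, d = d, ror = ci$ror,
                            ci_low = ci$ci_low, ci_high = ci$ci_high)
  }
  est <- do.call(rbind, rows)
  hits <- !is.na(est$ci_low) & est$ci_low <= true_ror &
          est$ci_high >= true_ror
  list(coverage = mean(hits), hits = hits, estimates = est,
       true_ror = true_ror, n_rep = n_rep)
}
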