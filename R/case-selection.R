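#' Case-selection configuration
#'
#' Encodes the inclusion/exclusion rules of a case/non-case study: a
#' reporting-date window; health-professional reporters only; an index
#' drug present as the single suspected (or an interacting) drug; at least
#' one reaction under the event HLTs; and, per good pharmacovigilance
#' practice, age and sex documented. "Single suspected or interacting" is
#' read as: the index drug has role suspected or interacting AND no other
#' drug on the report has role suspected (the standard reading isolating
#' drug causality); set `allowed_roles = "suspected"` for the stricter
#' alternative.
#'
#' @param index_drugs character vector of index drug codes.
#' @param event_hlts character vector of HLT codes defining the event, or
#'   `NULL` to resolve [renal_hlt_selection()] at selection time.
#' @param date_window length-2 date vector (inclusive), applied to the
#'   report date.
#' @param allowed_roles nonempty subset of `"suspected"`, `"interacting"`.
#' @param hp_reporters reporter qualifications accepted as health
#'   professionals.
#' @param require_age,require_sex demand a documented age / a known sex.
#' @return an object of class `selection_config`.
#' @export
selection_config <- function(index_drugs = tki_drugs(),
                             event_hlts = NULL,
                             date_window = c("2001-11-07", "2021-06-02"),
                             allowed_roles = c("suspected", "interacting"),
                             hp_reporters = c("physician", "pharmacist",
                                              "other_health_professional"),
                             require_age = TRUE,
                             require_sex = TRUE) {
  date_window <- as.Date(date_window)
  stopifnot(length(index_drugs) >= 1L,
            length(date_window) == 2L, !anyNA(date_window),
            date_window[1L] <= date_window[2L])
  allowed_roles <- match.arg(allowed_roles, c("suspected", "interacting"),
                             several.ok = TRUE)
  hp_reporters <- match.arg(hp_reporters, REPORTER_LEVELS, several.ok = TRUE)
  structure(list(index_drugs = as.character(index_drugs),
                 event_hlts = event_hlts,
                 date_window = date_window,
                 allowed_roles = allowed_roles,
                 hp_reporters = hp_reporters,
                 require_age = isTRUE(require_age),
                 require_sex = isTRUE(require_sex)),
            class = "selection_config")
}

# fixed rule order: rejections are attributed to the first failing rule
SELECTION_RULES <- c("window", "reporter", "drug_role", "event", "age", "sex")

#' Collapse duplicate reports
#'
#' Deterministic stand-in for probabilistic record matching: reports
#' sharing the duplicate key (country, sex, age rounded to whole years,
#' sorted suspected-drug codes, sorted reaction PT codes, report date) are
#' collapsed to the one with the smallest `report_id`. Idempotent.
#'
#' @param store an [icsr_store()].
#' @return list with `store` (collapsed) and `removed_ids` (character).
#' @export
deduplicate_reports <- function(store) {
  stopifnot(inherits(store, "icsr_store"))
  rp <- data.table::as.data.table(store$reports)
  dr <- data.table::as.data.table(store$drugs)
  rx <- data.table::as.data.table(store$reactions)
  report_id <- drug_code <- pt_code <- role <- NULL  # NSE notes

  dkey <- dr[role == "suspected",
             .(dk = paste(sort(unique(drug_code)), collapse = "|")),
             by = report_id]
  pkey <- rx[, .(pk = paste(sort(unique(pt_code)), collapse = "|")),
             by = report_id]
  key <- rp[, .(report_id,
                k1 = paste(country, sex, round(age_years),
                           format(report_date, "%Y-%m-%d"), sep = "\r"))]
  key <- merge(key, dkey, by = "report_id", all.x = TRUE)
  key <- merge(key, pkey, by = "report_id", all.x = TRUE)
  key[is.na(key$dk), "dk"] <- ""
  full <- paste(key$k1, key$dk, key$pk, sep = "\r")
  keep <- tapply(key$report_id, full, min)
  removed <- sort(setdiff(key$report_id, keep))
  list(store = subset_store(store, keep), removed_ids = removed)
}

#' Classify reports against the selection rules
#'
#' Vectorised evaluation of every rule for every report. A report is a
#' case iff all rules hold: report date within the window; reporter a
#' health professional; the index drug present with an allowed role and no
#' other suspected drug; at least one reaction PT under the event HLTs;
#' age documented; sex known. `reasons` lists every failed rule (not just
#' the first), comma-joined, in rule order.
#'
#' @param store an [icsr_store()] (normally already deduplicated).
#' @param config a [selection_config()].
#' @param dict a [term_dictionary()]; every reaction PT in the store must
#'   exist in it, otherwise an error identifies the unknown code.
#' @return data.frame with columns `report_id`, `is_case`, `reasons` plus
#'   one logical column per rule.
#' @export
is_case <- function(store, config, dict) {
  stopifnot(inherits(store, "icsr_store"),
            inherits(config, "selection_config"),
            inherits(dict, "term_dictionary"))
  rp <- store$reports
  dr <- store$drugs
  rx <- store$reactions

  unknown_pt <- setdiff(unique(rx$pt_code), names(dict$level_of))
  if (length(unknown_pt)) {
    stop("reaction PT code(s) absent from dictionary: ",
         paste(unknown_pt, collapse = ", "))
  }
  event_hlts <- config$event_hlts %||% renal_hlt_selection(dict)
  event_pts <- pts_under(dict, event_hlts)

  ok_window <- !is.na(rp$report_date) &
    rp$report_date >= config$date_window[1L] &
    rp$report_date <= config$date_window[2L]
  ok_reporter <- rp$reporter %in% config$hp_reporters

  is_index <- dr$drug_code %in% config$index_drugs
  index_ids <- unique(dr$report_id[is_index & dr$role %in% config$allowed_roles])
  other_suspected_ids <- unique(dr$report_id[!is_index & dr$role == "suspected"])
  ok_drug <- rp$report_id %in% index_ids &
    !(rp$report_id %in% other_suspected_ids)

  event_ids <- unique(rx$report_id[rx$pt_code %in% event_pts])
  ok_event <- rp$report_id %in% event_ids
  ok_age <- if (config$require_age) !is.na(rp$age_years) else TRUE
  ok_sex <- if (config$require_sex) rp$sex != "unknown" else TRUE

  rules <- cbind(window = ok_window, reporter = ok_reporter,
                 drug_role = ok_drug, event = ok_event,
                 age = ok_age, sex = ok_sex)
  flag <- rowSums(!rules) == 0L
  reasons <- apply(rules, 1L, function(r) {
    paste(SELECTION_RULES[!r], collapse = ",")
  })
  data.frame(report_id = rp$report_id, is_case = flag, reasons = reasons,
             rules, stringsAsFactors = FALSE, row.names = NULL)
}

#' Select the case set with an audit trail
#'
#' Deduplicates first, then applies [is_case()]. The audit attributes each
#' rejected report to the *first* failing rule in the fixed order window,
#' reporter, drug_role, event, age, sex, so audit counts reconcile
#' exactly: `n_in - n_out` equals the sum of the per-rule rejections.
#'
#' @inheritParams is_case
#' @param dedup collapse duplicates before selection (default `TRUE`).
#' @return list with `cases` (an [icsr_store()]), `audit` (class
#'   `selection_audit`: `n_dedup_removed`, `n_in`, per-rule rejection
#'   counts, `n_out`) and `flags` (the [is_case()] data.frame).
#' @export
select_cases <- function(store, config, dict, dedup = TRUE) {
  removed <- character(0)
  if (dedup) {
    dd <- deduplicate_reports(store)
    store <- dd$store
    removed <- dd$removed_ids
  }
  flags <- is_case(store, config, dict)
  rule_cols <- as.matrix(flags[SELECTION_RULES])
  first_fail <- apply(rule_cols, 1L, function(r) {
    w <- which(!r)
    if (length(w)) SELECTION_RULES[w[1L]] else NA_character_
  })
  rejected <- table(factor(first_fail, levels = SELECTION_RULES))
  audit <- structure(list(
    n_dedup_removed = length(removed),
    n_in = nrow(flags),
    rejected = setNames(as.integer(rejected), SELECTION_RULES),
    n_out = sum(flags$is_case)
  ), class = "selection_audit")
  list(cases = subset_store(store, flags$report_id[flags$is_case]),
       audit = audit, flags = flags)
}

#' @export
print.selection_audit <- function(x, ...) {
  cat("<selection_audit>\n")
  cat("  duplicates removed:", x$n_dedup_removed, "\n")
  cat("  reports screened:  ", x$n_in, "\n")
  for (r in names(x$rejected)) {
    cat(sprintf("  rejected (%s): %d\n", r, x$rejected[[r]]))
  }
  cat("  cases retained:    ", x$n_out, "\n")
  invisible(x)
}

#' Export a selection audit as a table
#'
#' @param audit a `selection_audit` from [select_cases()].
#' @return data.frame with columns `step` and `n`, in application order.
#' @export
audit_table <- function(audit) {
  stopifnot(inherits(audit, "selection_audit"))
  data.frame(step = c("duplicates_removed", "screened",
                      paste0("rejected_", names(audit$rejected)), "cases"),
             n = c(audit$n_dedup_removed, audit$n_in,
                   unname(audit$rejected), audit$n_out),
             stringsAsFactors = FALSE)
}
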