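#' ICSR stores
#'
#' An `icsr_store` holds a collection of individual case safety reports in
#' three-table normal form, mirroring the ICH E2B structure without the
#' XML: a `reports` table (one row per report: date, country, reporter
#' qualification, age, sex, seriousness), a `drugs` table (one row per
#' drug entry: code, role, start date, action taken, indication) and a
#' `reactions` table (one row per reaction entry: PT code, onset date,
#' outcome, seriousness criteria). Every report has at least one drug and
#' one reaction; `report_id` is unique. Column types, enumeration
#' spellings and the missing-value convention are documented in
#' `system.file("extdata", "dialect.md", package = "rorscreen")`.
#'
#' @param reports,drugs,reactions data.frames in the documented dialect.
#' @param validate run full invariant validation (default `TRUE`).
#' @return an object of class `icsr_store`.
#' @seealso [read_icsr_store()], [write_icsr_store()]
#' @export
icsr_store <- function(reports, drugs, reactions, validate = TRUE) {
  reports <- as.data.frame(reports, stringsAsFactors = FALSE)
  drugs <- as.data.frame(drugs, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)

  need <- list(
    reports = c("report_id", "report_date", "country", "reporter",
                "age_years", "sex", "seriousness"),
    drugs = c("report_id", "drug_code", "role", "start_date",
              "action_taken", "indication"),
    reactions = c("report_id", "pt_code", "onset_date", "outcome",
                  "serious_flags")
  )
  tabs <- list(reports = reports, drugs = drugs, reactions = reactions)
  for (nm in names(need)) {
    missing_cols <- setdiff(need[[nm]], names(tabs[[nm]]))
    if (length(missing_cols)) {
      stop(nm, " table is missing column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    tabs[[nm]] <- tabs[[nm]][need[[nm]]]
  }
  reports <- tabs$reports; drugs <- tabs$drugs; reactions <- tabs$reactions

  for (col in c("report_id", "country", "reporter", "sex", "seriousness")) {
    reports[[col]] <- as.character(reports[[col]])
  }
  reports$report_date <- .as_date(reports$report_date, "report_date", "reports")
  reports$age_years <- suppressWarnings(as.numeric(reports$age_years))
  for (col in c("report_id", "drug_code", "role", "action_taken", "indication")) {
    drugs[[col]] <- as.character(drugs[[col]])
  }
  drugs$start_date <- .as_date(drugs$start_date, "start_date", "drugs")
  drugs$indication[!is.na(drugs$indication) & !nzchar(drugs$indication)] <- NA_character_
  for (col in c("report_id", "pt_code", "outcome", "serious_flags")) {
    reactions[[col]] <- as.character(reactions[[col]])
  }
  reactions$onset_date <- .as_date(reactions$onset_date, "onset_date", "reactions")
  reactions$serious_flags[is.na(reactions$serious_flags)] <- ""

  store <- structure(list(reports = reports, drugs = drugs,
                          reactions = reactions),
                     class = "icsr_store")
  if (validate) validate_icsr_store(store)
  store
}

#' Validate an ICSR store
#'
#' Checks all data-model invariants: unique report identifiers, linkage of
#' child rows, at least one drug and one reaction per report, enumeration
#' vocabularies, nonnegative ages, legal seriousness criteria, and the
#' seriousness consistency rules (flags imply a serious report; a fatal
#' outcome implies the death criterion on the report).
#'
#' @param store an [icsr_store()].
#' @return the store, invisibly; errors describe the first violation found.
#' @export
validate_icsr_store <- function(store) {
  stopifnot(inherits(store, "icsr_store"))
  rp <- store$reports; dr <- store$drugs; rx <- store$reactions

  if (anyNA(rp$report_id) || any(!nzchar(rp$report_id))) {
    stop("reports: report_id must be nonempty")
  }
  dup <- rp$report_id[duplicated(rp$report_id)]
  if (length(dup)) {
    stop("reports: duplicate report_id(s): ",
         paste(unique(dup), collapse = ", "))
  }
  for (child in list(list(dr, "drugs"), list(rx, "reactions"))) {
    orphan <- which(!(child[[1]]$report_id %in% rp$report_id))
    if (length(orphan)) {
      stop(sprintf("%s: row %d references unknown report_id '%s'",
                   child[[2]], orphan[1L], child[[1]]$report_id[orphan[1L]]))
    }
  }
  no_drug <- setdiff(rp$report_id, dr$report_id)
  if (length(no_drug)) {
    stop("report(s) without any drug entry: ",
         paste(head(no_drug, 3L), collapse = ", "))
  }
  no_rx <- setdiff(rp$report_id, rx$report_id)
  if (length(no_rx)) {
    stop("report(s) without any reaction entry: ",
         paste(head(no_rx, 3L), collapse = ", "))
  }

  .check_enum(rp$reporter, REPORTER_LEVELS, "reporter", "reports")
  .check_enum(rp$sex, SEX_LEVELS, "sex", "reports")
  .check_enum(rp$seriousness, SERIOUSNESS_LEVELS, "seriousness", "reports")
  if (any(!is.na(rp$age_years) & rp$age_years < 0)) {
    stop("reports: age_years must be nonnegative")
  }
  .check_enum(dr$role, ROLE_LEVELS, "role", "drugs")
  .check_enum(dr$action_taken, ACTION_LEVELS, "action_taken", "drugs")
  .check_enum(rx$outcome, OUTCOME_LEVELS, "outcome", "reactions")

  flag_list <- strsplit(rx$serious_flags, "|", fixed = TRUE)
  bad_flag <- which(vapply(flag_list, function(f) any(!(f %in% SERIOUS_FLAG_LEVELS)),
                           logical(1L)))
  if (length(bad_flag)) {
    stop(sprintf("reactions: invalid serious_flags '%s' at row %d",
                 rx$serious_flags[bad_flag[1L]], bad_flag[1L]))
  }

  # report-level seriousness consistency
  seriousness_of <- setNames(rp$seriousness, rp$report_id)
  has_flag <- nzchar(rx$serious_flags)
  flagged_not_serious <- unique(rx$report_id[has_flag])[
    seriousness_of[unique(rx$report_id[has_flag])] != "serious"]
  if (length(flagged_not_serious)) {
    stop("seriousness criteria present on a non-serious report: ",
         paste(head(flagged_not_serious, 3L), collapse = ", "))
  }
  fatal_ids <- unique(rx$report_id[rx$outcome == "fatal"])
  if (length(fatal_ids)) {
    death_ids <- unique(rx$report_id[grepl("death", rx$serious_flags, fixed = TRUE)])
    missing_death <- setdiff(fatal_ids, death_ids)
    if (length(missing_death)) {
      stop("fatal outcome without the death seriousness criterion on report(s): ",
           paste(head(missing_death, 3L), collapse = ", "))
    }
  }
  invisible(store)
}

#' @export
print.icsr_store <- function(x, ...) {
  cat("<icsr_store> ", nrow(x$reports), " reports, ",
      nrow(x$drugs), " drug entries, ",
      nrow(x$reactions), " reaction entries\n", sep = "")
  invisible(x)
}

#' Number of reports in a store
#' @param store an [icsr_store()].
#' @return integer count of reports.
#' @export
n_reports <- function(store) nrow(store$reports)

# restrict a store to a set of report ids (preserving row order)
subset_store <- function(store, ids) {
  icsr_store(store$reports[store$reports$report_id %in% ids, , drop = FALSE],
             store$drugs[store$drugs$report_id %in% ids, , drop = FALSE],
             store$reactions[store$reactions$report_id %in% ids, , drop = FALSE],
             validate = FALSE)
}

.store_paths <- function(dir) {
  c(reports = file.path(dir, "reports.csv"),
    drugs = file.path(dir, "drugs.csv"),
    reactions = file.path(dir, "reactions.csv"))
}

#' Read an ICSR store from delimited tables
#'
#' Reads the three dialect tables and validates the full store. Either a
#' directory containing `reports.csv`, `drugs.csv` and `reactions.csv`, or
#' the three paths, may be given. Delimiter (comma or tab) is
#' auto-detected; empty cells are missing values.
#'
#' @param dir directory containing the three standard file names.
#' @param reports_path,drugs_path,reactions_path explicit paths
#'   (override `dir`).
#' @return a validated [icsr_store()].
#' @export
read_icsr_store <- function(dir = NULL, reports_path = NULL,
                            drugs_path = NULL, reactions_path = NULL) {
  if (!is.null(dir)) {
    p <- .store_paths(dir)
    reports_path <- reports_path %||% p[["reports"]]
    drugs_path <- drugs_path %||% p[["drugs"]]
    reactions_path <- reactions_path %||% p[["reactions"]]
  }
  for (p in c(reports_path, drugs_path, reactions_path)) {
    if (is.null(p) || !file.exists(p)) stop("store file not found: ", p)
  }
  rd <- function(p) {
    as.data.frame(data.table::fread(p, colClasses = "character",
                                    na.strings = "", encoding = "UTF-8"))
  }
  icsr_store(rd(reports_path), rd(drugs_path), rd(reactions_path))
}

#' Write an ICSR store to delimited tables
#'
#' Writes `reports.csv`, `drugs.csv` and `reactions.csv` under `dir` in
#' the documented dialect. Rows are sorted by `report_id` (child tables by
#' report then original order) so output is bit-stable for a given store;
#' missing values are empty cells.
#'
#' @param store an [icsr_store()].
#' @param dir output directory (created if absent).
#' @return the three file paths, invisibly.
#' @export
write_icsr_store <- function(store, dir) {
  stopifnot(inherits(store, "icsr_store"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- .store_paths(dir)
  ord <- function(df) df[order(df$report_id), , drop = FALSE]
  wr <- function(df, path) {
    df <- ord(df)
    for (col in names(df)) {
      if (inherits(df[[col]], "Date")) df[[col]] <- format(df[[col]], "%Y-%m-%d")
    }
    data.table::fwrite(df, path, na = "", quote = "auto", bom = FALSE)
  }
  wr(store$reports, p[["reports"]])
  wr(store$drugs, p[["drugs"]])
  wr(store$reactions, p[["reactions"]])
  invisible(p)
}

#' Time to onset in days
#'
#' Whole days from drug start to reaction onset. Undefined (`NA`) when
#' either date is missing; an onset preceding the start yields `NA` with a
#' warning rather than an error, since such records occur in spontaneous
#' reports and must not abort a batch summary.
#'
#' @param start_date,onset_date `Date` vectors (or ISO-8601 strings),
#'   recycled to a common length.
#' @return integer vector of day counts, `NA` where undefined.
#' @examples
#' time_to_onset(as.Date("2020-01-01"), as.Date("2020-03-01"))  # 60
#' @export
time_to_onset <- function(start_date, onset_date) {
  start <- as.Date(start_date)
  onset <- as.Date(onset_date)
  d <- as.integer(onset - start)
  neg <- !is.na(d) & d < 0L
  if (any(neg)) {
    warning(sum(neg), " reaction onset date(s) precede the drug start date; ",
            "time to onset treated as missing")
    d[neg] <- NA_integer_
  }
  d
}
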