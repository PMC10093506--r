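# severity ranking used to derive one outcome per case from its reactions
.OUTCOME_SEVERITY <- c(fatal = 6L, recovered_with_sequelae = 5L,
                       not_recovered = 4L, recovering = 3L,
                       recovered = 2L, unknown = 1L)

# index drug entry per case: the entry with an index code and an allowed
# role, preferring suspected over interacting; errors if a case has none
.index_drug_of <- function(cases, index_drugs,
                           roles = c("suspected", "interacting")) {
  dr <- cases$drugs
  cand <- dr[dr$drug_code %in% index_drugs & dr$role %in% roles, , drop = FALSE]
  cand <- cand[order(cand$report_id, match(cand$role, roles)), , drop = FALSE]
  cand <- cand[!duplicated(cand$report_id), , drop = FALSE]
  missing_ids <- setdiff(cases$reports$report_id, cand$report_id)
  if (length(missing_ids)) {
    stop("case(s) without an index drug entry (selection contract violated): ",
         paste(head(missing_ids, 3L), collapse = ", "))
  }
  cand[match(cases$reports$report_id, cand$report_id), , drop = FALSE]
}

# map each renal reaction to the renal HLT(s) of its PT (a multi-parent PT
# contributes to each of its renal HLTs)
.renal_hlt_hits <- function(cases, dict, renal_hlts) {
  ln <- dict$links
  map <- ln[ln$parent_code %in% renal_hlts, c("child_code", "parent_code")]
  rx <- cases$reactions
  hit <- merge(rx, map, by.x = "pt_code", by.y = "child_code")
  names(hit)[names(hit) == "parent_code"] <- "hlt_code"
  hit
}

.count_block <- function(values, levels, denom) {
  n <- as.integer(table(factor(values, levels = levels)))
  data.frame(level = levels, n = n,
             pct = percent_int(n, max(denom, 1L)) * (denom > 0),
             stringsAsFactors = FALSE)
}

#' Cohort characteristics of the selected cases
#'
#' Summarises the case set per index drug and overall: case counts, age
#' mean and sample (n-1) standard deviation, sex distribution, ADR counts
#' per renal HLT (a case contributes once to each renal HLT reached by any
#' of its reaction PTs, so a case may appear under several HLTs;
#' denominator is the case count), seriousness, per-case outcome (the most
#' severe reaction outcome, severity order fatal > recovered with sequelae
#' > not recovered > recovering > recovered > unknown), drug
#' discontinuation (index drug entry with action `withdrawn`), and the
#' top-k reporting countries and indications. Percentages are half-up
#' integers of counts over the group's case count.
#'
#' @param cases an [icsr_store()] of selected cases.
#' @param index_drugs index drug codes (attribution per case).
#' @param dict a [term_dictionary()].
#' @param top_k how many countries/indications to report (ranked on the
#'   overall cohort).
#' @param roles drug roles accepted for the index drug entry.
#' @return list of class `case_characteristics` with elements `n` (named
#'   integer vector per drug plus `"All"`), `age` (data.frame of mean and
#'   SD per group) and `blocks` (long data.frame: `block`, `level`,
#'   `drug`, `n`, `pct`).
#' @export
case_characteristics <- function(cases, index_drugs, dict, top_k = 5L,
                                 roles = c("suspected", "interacting")) {
  stopifnot(inherits(cases, "icsr_store"), inherits(dict, "term_dictionary"))
  rp <- cases$reports
  idx <- .index_drug_of(cases, index_drugs, roles)
  drug_of <- setNames(idx$drug_code, idx$report_id)
  renal_hlts <- renal_hlt_selection(dict)
  hlt_names <- setNames(dict$terms$name, dict$terms$code)
  hlt_hits <- .renal_hlt_hits(cases, dict, renal_hlts)
  hlt_hits <- unique(hlt_hits[c("report_id", "hlt_code")])

  worst <- tapply(.OUTCOME_SEVERITY[cases$reactions$outcome],
                  cases$reactions$report_id, max)
  outcome_of <- names(.OUTCOME_SEVERITY)[match(worst[rp$report_id],
                                               .OUTCOME_SEVERITY)]
  disc_ids <- unique(idx$report_id[idx$action_taken == "withdrawn"])
  indication_of <- setNames(idx$indication, idx$report_id)

  rank_levels <- function(x, k) {
    tab <- sort(table(x[!is.na(x)]), decreasing = TRUE)
    head(names(tab), k)
  }
  top_countries <- rank_levels(rp$country, top_k)
  top_indications <- rank_levels(indication_of[rp$report_id], top_k)

  groups <- c(setNames(as.list(index_drugs), index_drugs), list(All = index_drugs))
  rows <- list(); age_rows <- list(); n_vec <- integer(0)
  for (g in names(groups)) {
    in_g <- drug_of[rp$report_id] %in% groups[[g]]
    sub <- rp[in_g, , drop = FALSE]
    ng <- nrow(sub)
    n_vec[g] <- ng
    age <- sub$age_years[!is.na(sub$age_years)]
    age_rows[[g]] <- data.frame(drug = g, n = ng, n_age = length(age),
                                mean = if (length(age)) mean(age) else NA_real_,
                                sd = if (length(age) > 1L) sd(age) else NA_real_,
                                stringsAsFactors = FALSE)
    add <- function(block, df) {
      rows[[length(rows) + 1L]] <<- data.frame(block = block, drug = g, df,
                                               stringsAsFactors = FALSE)
    }
    add("sex", .count_block(sub$sex, c("female", "male", "unknown"), ng))
    hl <- hlt_hits[hlt_hits$report_id %in% sub$report_id, , drop = FALSE]
    hlt_df <- .count_block(hl$hlt_code, renal_hlts, ng)
    hlt_df$level <- unname(hlt_names[hlt_df$level])
    add("hlt", hlt_df)
    add("seriousness", .count_block(sub$seriousness, SERIOUSNESS_LEVELS, ng))
    add("outcome", .count_block(outcome_of[in_g], names(.OUTCOME_SEVERITY), ng))
    add("discontinuation",
        .count_block(ifelse(sub$report_id %in% disc_ids, "withdrawn", "other"),
                     "withdrawn", ng))
    add("country", .count_block(sub$country, top_countries, ng))
    add("indication",
        .count_block(indication_of[sub$report_id], top_indications, ng))
  }
  structure(list(n = n_vec,
                 age = do.call(rbind, c(age_rows, make.row.names = FALSE)),
                 blocks = do.call(rbind, c(rows, make.row.names = FALSE))),
            class = "case_characteristics")
}

#' @export
print.case_characteristics <- function(x, ...) {
  cat("<case_characteristics> ", x$n[["All"]], " cases across ",
      length(x$n) - 1L, " drugs\n", sep = "")
  print(x$age, row.names = FALSE)
  invisible(x)
}

#' Time-to-onset summaries per (drug, HLT)
#'
#' Pools, for every index drug and renal HLT, the times to onset (days
#' from the index drug's start date to the reaction's onset date) of all
#' qualifying reactions, and summarises them as median and quartiles
#' (linear-interpolation quantiles, R type 7) plus mean and sample SD.
#' `n_total` counts cases with any reaction under the HLT, `n_with_tto`
#' those contributing at least one defined TTO. Cells are flagged for
#' display only when `n_total > min_display` (strict), and flagged
#' `tto_known` only when more than one TTO was observed; rendering shows
#' "UNK" otherwise.
#'
#' @param cases an [icsr_store()] of selected cases.
#' @param index_drugs index drug codes.
#' @param dict a [term_dictionary()].
#' @param min_display strict lower bound on `n_total` for display
#'   (default 3).
#' @param roles drug roles accepted for the index drug entry.
#' @return data.frame with one row per (drug, HLT): `drug`, `hlt_code`,
#'   `hlt_name`, `n_with_tto`, `n_total`, `median`, `q25`, `q75`, `mean`,
#'   `sd`, `display`, `tto_known`.
#' @export
tto_summary <- function(cases, index_drugs, dict, min_display = 3L,
                        roles = c("suspected", "interacting")) {
  stopifnot(inherits(cases, "icsr_store"), inherits(dict, "term_dictionary"))
  idx <- .index_drug_of(cases, index_drugs, roles)
  drug_of <- setNames(idx$drug_code, idx$report_id)
  start_of <- setNames(idx$start_date, idx$report_id)
  renal_hlts <- renal_hlt_selection(dict)
  hlt_names <- setNames(dict$terms$name, dict$terms$code)
  hits <- .renal_hlt_hits(cases, dict, renal_hlts)
  hits$tto <- time_to_onset(start_of[hits$report_id], hits$onset_date)
  hits$drug <- drug_of[hits$report_id]

  out <- expand.grid(hlt_code = renal_hlts, drug = index_drugs,
                     stringsAsFactors = FALSE)[, c("drug", "hlt_code")]
  stat <- function(i) {
    h <- hits[hits$drug == out$drug[i] & hits$hlt_code == out$hlt_code[i], ]
    tt <- h$tto[!is.na(h$tto)]
    qs <- if (length(tt)) unname(quantile(tt, c(0.25, 0.5, 0.75), type = 7))
          else rep(NA_real_, 3L)
    data.frame(n_with_tto = length(unique(h$report_id[!is.na(h$tto)])),
               n_total = length(unique(h$report_id)),
               median = qs[2L], q25 = qs[1L], q75 = qs[3L],
               mean = if (length(tt)) mean(tt) else NA_real_,
               sd = if (length(tt) > 1L) sd(tt) else NA_real_)
  }
  res <- do.call(rbind, lapply(seq_len(nrow(out)), stat))
  out <- data.frame(out[, "drug", drop = FALSE],
                    hlt_code = out$hlt_code,
                    hlt_name = unname(hlt_names[out$hlt_code]),
                    res, stringsAsFactors = FALSE)
  out$display <- out$n_total > min_display
  out$tto_known <- out$n_with_tto > 1L
  out
}
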