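#' Screening configuration
#'
#' Thresholds of the disproportionality screen: the minimum case count and
#' the normal quantile of the confidence interval. The case-count
#' threshold is exclusive ("strictly greater than five cases"), i.e. a
#' pair needs at least `min_cases + 1` exposed-case reports before an ROR
#' is reported. An optional Haldane-Anscombe 0.5 continuity correction for
#' zero cells exists for comparability with other tools but is off by
#' default (the reference methodology applies none).
#'
#' @param min_cases exclusive threshold on the `a` cell (default 5).
#' @param z normal quantile (default 1.96, a 95% interval).
#' @param haldane apply +0.5 to all cells of tables with a zero cell.
#' @return an object of class `screen_config`.
#' @export
screen_config <- function(min_cases = 5L, z = 1.96, haldane = FALSE) {
  stopifnot(is.numeric(min_cases), min_cases >= 0,
            is.numeric(z), z > 0)
  structure(list(min_cases = as.integer(min_cases), z = z,
                 haldane = isTRUE(haldane)),
            class = "screen_config")
}

#' Build the report-level 2x2 contingency table for one (drug, event) pair
#'
#' Cross-classifies every report of the store exactly once: drug-positive
#' iff the report names `drug_code` with an allowed role; event-positive
#' iff any reaction PT belongs to `event_pts`. Cell `a` counts
#' drug-and-event reports, `b` event-without-drug, `c` drug-without-event
#' and `d` neither, so `a + b + c + d` equals the store size (the table is
#' a true partition of reports). The store should already be deduplicated.
#'
#' @param store an [icsr_store()].
#' @param drug_code index drug code.
#' @param event_pts nonempty character vector of PT codes defining the
#'   event.
#' @param roles drug roles counting as exposure.
#' @return an object of class `contingency_table` with fields `a`, `b`,
#'   `c`, `d`, `n`.
#' @export
build_contingency_table <- function(store, drug_code, event_pts,
                                    roles = c("suspected", "interacting")) {
  stopifnot(inherits(store, "icsr_store"))
  if (!length(event_pts)) stop("event_pts must be nonempty")
  ids <- store$reports$report_id
  dr <- store$drugs
  rx <- store$reactions
  dpos <- ids %in% dr$report_id[dr$drug_code == drug_code & dr$role %in% roles]
  epos <- ids %in% rx$report_id[rx$pt_code %in% event_pts]
  structure(list(a = sum(dpos & epos), b = sum(!dpos & epos),
                 c = sum(dpos & !epos), d = sum(!dpos & !epos),
                 n = length(ids)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2L, 2L,
              dimnames = list(c("event", "no event"),
                              c("drug", "other drugs")))
  print(m)
  invisible(x)
}

#' Reporting odds ratio with log-scale Wald confidence interval
#'
#' For a 2x2 table with cells `a` (drug and event), `b` (event, other
#' drugs), `c` (drug, no event), `d` (neither):
#' \deqn{ROR = \frac{a/c}{b/d} = \frac{ad}{bc}}
#' \deqn{CI = \exp\left(\log ROR \pm z \sqrt{1/a + 1/b + 1/c + 1/d}\right)}
#' The estimate is undefined (all `NA`, `computable = FALSE`) when any
#' cell is below 1, unless the Haldane-Anscombe correction is requested,
#' in which case 0.5 is added to every cell of affected tables. All
#' arguments are vectorised; `a` may also be a single
#' [build_contingency_table()] result.
#'
#' @param a,b,c,d cell counts (vectorised), or `a` a `contingency_table`.
#' @param z normal quantile (1.96 for a 95% interval).
#' @param haldane apply the +0.5 zero-cell correction.
#' @return data.frame with columns `ror`, `ci_low`, `ci_high`,
#'   `computable`.
#' @examples
#' ror_ci(10, 10, 10, 10)          # ROR 1, symmetric interval
#' ror_ci(20, 100, 980, 99900)     # ROR about 20.39
#' @export
ror_ci <- function(a, b = NULL, c = NULL, d = NULL, z = 1.96,
                   haldane = FALSE) {
  if (inherits(a, "contingency_table")) {
    tab <- a
    a <- tab$a; b <- tab$b; c <- tab$c; d <- tab$d
  }
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), is.numeric(d))
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be nonnegative")
  has_zero <- pmin(a, b, c, d) < 1
  if (haldane) {
    a <- a + 0.5 * has_zero; b <- b + 0.5 * has_zero
    c <- c + 0.5 * has_zero; d <- d + 0.5 * has_zero
    computable <- pmin(a, b, c, d) > 0
  } else {
    computable <- !has_zero
  }
  ror <- ifelse(computable, a * d / (b * c), NA_real_)
  se <- ifelse(computable, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  data.frame(ror = ror,
             ci_low = exp(log(ror) - z * se),
             ci_high = exp(log(ror) + z * se),
             computable = computable)
}

#' Signal-of-disproportionate-reporting flag
#'
#' A (drug, event) pair is flagged as an SDR iff the exposed-case count
#' exceeds `min_cases` (strictly), the estimate is computable, the ROR is
#' strictly greater than 1 and the lower 95% confidence bound is strictly
#' greater than 1. All comparisons are strict; a lower bound of exactly 1
#' is not a signal. Vectorised; `NA` estimates yield `FALSE`.
#'
#' @param ror,ci_low point estimate and lower confidence bound.
#' @param a exposed-case count (cell `a`).
#' @param min_cases exclusive case-count threshold (default 5).
#' @return logical vector.
#' @examples
#' flag_sdr(2.52, 1.16, 20)  # TRUE
#' flag_sdr(2.0, 1.0, 10)    # FALSE: bound not strictly above 1
#' @export
flag_sdr <- function(ror, ci_low, a, min_cases = 5L) {
  !is.na(ror) & !is.na(ci_low) & a > min_cases & ror > 1 & ci_low > 1
}

#' Screen a drug-event grid for disproportionality
#'
#' Builds the report-level 2x2 table for every (drug, event) pair,
#' computes ROR and confidence interval where the pair clears the
#' case-count threshold and has no zero cell, and flags SDRs. Events are
#' named PT sets; a single PT per event reproduces a PT-level screen.
#' Results are in stable (drug, then event) input order. No multiplicity
#' adjustment is applied: this is hypothesis-generating screening, not
#' confirmatory testing (recorded in the result's metadata).
#'
#' @param store a deduplicated [icsr_store()].
#' @param drugs character vector of index drug codes.
#' @param events named list of PT-code vectors, or a named character
#'   vector of single PTs (e.g. [studied_pts()]).
#' @param config a [screen_config()].
#' @param roles drug roles counting as exposure.
#' @return data.frame of class `dispro_screen` with columns `drug`,
#'   `event`, `a`, `b`, `c`, `d`, `ror`, `ci_low`, `ci_high`,
#'   `computable`, `sdr`; attributes `n`, `z`, `min_cases`,
#'   `multiplicity`.
#' @export
screen_disproportionality <- function(store, drugs, events,
                                      config = screen_config(),
                                      roles = c("suspected", "interacting")) {
  stopifnot(inherits(store, "icsr_store"), inherits(config, "screen_config"))
  if (is.character(events)) {
    events <- as.list(events)
  }
  if (is.null(names(events)) || any(!nzchar(names(events)))) {
    stop("events must be named")
  }
  ids <- store$reports$report_id
  dr <- store$drugs
  rx <- store$reactions
  dpos <- lapply(drugs, function(dc) {
    ids %in% dr$report_id[dr$drug_code == dc & dr$role %in% roles]
  })
  names(dpos) <- drugs
  epos <- lapply(events, function(pts) {
    ids %in% rx$report_id[rx$pt_code %in% pts]
  })
  grid <- expand.grid(event = names(events), drug = drugs,
                      stringsAsFactors = FALSE)[, c("drug", "event")]
  # stable order: drug, then event, both in input order
  grid <- grid[order(match(grid$drug, drugs), match(grid$event, names(events))), ]
  cells <- t(mapply(function(dc, ev) {
    dp <- dpos[[dc]]; ep <- epos[[ev]]
    c(a = sum(dp & ep), b = sum(!dp & ep), c = sum(dp & !ep),
      d = sum(!dp & !ep))
  }, grid$drug, grid$event))
  est <- ror_ci(cells[, "a"], cells[, "b"], cells[, "c"], cells[, "d"],
                z = config$z, haldane = config$haldane)
  below <- cells[, "a"] <= config$min_cases
  est$ror[below] <- NA_real_
  est$ci_low[below] <- NA_real_
  est$ci_high[below] <- NA_real_
  est$computable <- est$computable & !below
  out <- data.frame(grid, cells, est,
                    sdr = flag_sdr(est$ror, est$ci_low, cells[, "a"],
                                   config$min_cases),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("dispro_screen", "data.frame"),
            n = length(ids), z = config$z, min_cases = config$min_cases,
            multiplicity = "none (signal screening, not confirmatory testing)")
}
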