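#' MedDRA-like term dictionaries
#'
#' The package models the levels of the MedDRA hierarchy that drive case
#' selection and event definition: system organ class (SOC), optional
#' high-level group term (HLGT), high-level term (HLT) and preferred term
#' (PT). Lowest-level terms (LLTs), versioning and SMQs are out of scope.
#' Terms are matched by `code`; `name` is descriptive metadata. Links join
#' adjacent declared levels only (PT to HLT; HLT to HLGT or SOC; HLGT to
#' SOC), every PT has at least one HLT parent and every HLT reaches at
#' least one SOC. A PT may have several HLT parents ("PTs can overlap").
#'
#' @param terms data.frame with columns `code`, `name`, `level`
#'   (one of `"SOC"`, `"HLGT"`, `"HLT"`, `"PT"`).
#' @param links data.frame with columns `child_code`, `parent_code`.
#' @return an object of class `term_dictionary`.
#' @seealso [read_term_dictionary()], [pts_under()], [renal_hlt_selection()]
#' @export
term_dictionary <- function(terms, links) {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  need_t <- c("code", "name", "level")
  need_l <- c("child_code", "parent_code")
  if (!all(need_t %in% names(terms))) {
    stop("terms table must have columns: ", paste(need_t, collapse = ", "))
  }
  if (!all(need_l %in% names(links))) {
    stop("links table must have columns: ", paste(need_l, collapse = ", "))
  }
  terms$code <- as.character(terms$code)
  terms$name <- as.character(terms$name)
  terms$level <- as.character(terms$level)
  links$child_code <- as.character(links$child_code)
  links$parent_code <- as.character(links$parent_code)

  lv <- c("SOC", "HLGT", "HLT", "PT")
  bad <- setdiff(unique(terms$level), lv)
  if (length(bad)) {
    stop("unknown level label(s): ", paste(bad, collapse = ", "))
  }
  dup <- terms$code[duplicated(terms$code)]
  if (length(dup)) {
    stop("duplicate term code(s): ", paste(unique(dup), collapse = ", "))
  }
  level_of <- setNames(terms$level, terms$code)

  dangling <- setdiff(c(links$child_code, links$parent_code), terms$code)
  if (length(dangling)) {
    stop("dangling link code(s) not in term table: ",
         paste(unique(dangling), collapse = ", "))
  }
  # adjacency: PT->HLT, HLT->HLGT|SOC, HLGT->SOC (HLGT layer is optional)
  cl <- level_of[links$child_code]
  pl <- level_of[links$parent_code]
  ok <- (cl == "PT" & pl == "HLT") |
        (cl == "HLT" & pl %in% c("HLGT", "SOC")) |
        (cl == "HLGT" & pl == "SOC")
  if (any(!ok)) {
    i <- which(!ok)[1L]
    stop(sprintf("illegal link %s (%s) -> %s (%s): links must join adjacent levels",
                 links$child_code[i], cl[i], links$parent_code[i], pl[i]))
  }

  pts <- terms$code[terms$level == "PT"]
  orphan_pt <- setdiff(pts, links$child_code[cl == "PT"])
  if (length(orphan_pt)) {
    stop("PT with no HLT parent: ", paste(orphan_pt, collapse = ", "))
  }
  hlts <- terms$code[terms$level == "HLT"]
  orphan_hlt <- setdiff(hlts, links$child_code[cl == "HLT"])
  if (length(orphan_hlt)) {
    stop("HLT with no SOC/HLGT parent: ", paste(orphan_hlt, collapse = ", "))
  }

  structure(list(terms = terms, links = links, level_of = level_of),
            class = "term_dictionary")
}

#' @export
print.term_dictionary <- function(x, ...) {
  tab <- table(factor(x$terms$level, levels = c("SOC", "HLGT", "HLT", "PT")))
  cat("<term_dictionary> ", nrow(x$terms), " terms (",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
      "), ", nrow(x$links), " links\n", sep = "")
  invisible(x)
}

#' Read a term dictionary from delimited files
#'
#' Expects two UTF-8 delimited tables with header rows: a term table
#' (`code,name,level`) and a link table (`child_code,parent_code`).
#' Comma and tab delimiters are auto-detected. All hierarchy invariants
#' are validated; violations abort with the offending code in the message.
#'
#' @param terms_path,links_path file paths.
#' @return a [term_dictionary()].
#' @export
read_term_dictionary <- function(terms_path, links_path) {
  for (p in c(terms_path, links_path)) {
    if (!file.exists(p)) stop("dictionary file not found: ", p)
  }
  terms <- data.table::fread(terms_path, colClasses = "character",
                             na.strings = NULL, encoding = "UTF-8")
  links <- data.table::fread(links_path, colClasses = "character",
                             na.strings = NULL, encoding = "UTF-8")
  term_dictionary(terms, links)
}

#' Bundled demonstration dictionary
#'
#' A small synthetic stand-in for the licensed MedDRA dictionary. It
#' contains the renal SOC with the seven case-defining HLTs, the thirteen
#' renally screened PTs, one HLGT layer, one multi-parent PT, and decoy
#' non-renal terms (including an infectious HLT under the renal SOC that
#' the renal selection must exclude). Term codes and names are invented.
#'
#' @return a [term_dictionary()].
#' @export
demo_dictionary <- function() {
  dir <- system.file("extdata", "meddra_demo", package = "rorscreen",
                     mustWork = TRUE)
  read_term_dictionary(file.path(dir, "terms.csv"), file.path(dir, "links.csv"))
}

.levels_of <- function(dict, codes) {
  unknown <- setdiff(codes, names(dict$level_of))
  if (length(unknown)) {
    stop("unknown term code(s): ", paste(unknown, collapse = ", "))
  }
  dict$level_of[codes]
}

#' Expand HLT codes to their preferred terms
#'
#' Returns the union of all PT codes linked to any of the given HLTs,
#' deduplicated. Used to turn an HLT-level case definition into the PT set
#' actually matched against reaction entries.
#'
#' @param dict a [term_dictionary()].
#' @param hlt_codes character vector of HLT codes (may be empty).
#' @return character vector of PT codes (sorted, unique).
#' @export
pts_under <- function(dict, hlt_codes) {
  stopifnot(inherits(dict, "term_dictionary"))
  hlt_codes <- unique(as.character(hlt_codes))
  if (!length(hlt_codes)) return(character(0))
  lv <- .levels_of(dict, hlt_codes)
  if (any(lv != "HLT")) {
    stop("not HLT-level code(s): ",
         paste(hlt_codes[lv != "HLT"], collapse = ", "))
  }
  ln <- dict$links
  is_pt_link <- dict$level_of[ln$child_code] == "PT"
  sort(unique(ln$child_code[is_pt_link & ln$parent_code %in% hlt_codes]))
}

# HLT -> set of SOCs, traversing an optional HLGT layer
.socs_of_hlt <- function(dict, hlt_code) {
  ln <- dict$links
  parents <- ln$parent_code[ln$child_code == hlt_code]
  socs <- parents[dict$level_of[parents] == "SOC"]
  hlgts <- parents[dict$level_of[parents] == "HLGT"]
  if (length(hlgts)) {
    socs <- c(socs, ln$parent_code[ln$child_code %in% hlgts])
  }
  unique(socs)
}

.norm_term_name <- function(x) {
  x <- tolower(x)
  x <- gsub("not elsewhere classified", "nec", x, fixed = TRUE)
  x <- gsub("ischaemic", "ischemic", x, fixed = TRUE)
  x <- gsub("[^a-z0-9 ]", " ", x)
  gsub(" +", " ", trimws(x))
}

# the seven case-defining renal HLT names (normalised spellings)
RENAL_HLT_NAMES <- c(
  "glomerulonephritis and nephrotic syndrome",
  "nephritis nec",
  "nephropathies and tubular disorders nec",
  "renal disorders nec",
  "renal failure and impairment",
  "renal hypertension and related conditions",
  "renal vascular and ischemic conditions"
)
RENAL_SOC_NAME <- "renal and urinary disorders"

#' Renal high-level-term selection
#'
#' Resolves, by (normalised) name, the seven HLTs under the "Renal and
#' urinary disorders" SOC that define a renal case: glomerulonephritis and
#' nephrotic syndrome; nephritis NEC; nephropathies and tubular disorders
#' NEC; renal disorders NEC; renal failure and impairment; renal
#' hypertension and related conditions; renal vascular and ischemic
#' conditions. Any other HLT under the SOC (urological or infectious
#' groupings such as urinary tract infections) is excluded by design.
#' Name matching tolerates case, punctuation, "NEC" expansion and the
#' ischemic/ischaemic spelling variant.
#'
#' @param dict a [term_dictionary()].
#' @return character vector of exactly seven HLT codes.
#' @export
renal_hlt_selection <- function(dict) {
  stopifnot(inherits(dict, "term_dictionary"))
  tt <- dict$terms
  soc <- tt$code[tt$level == "SOC" & .norm_term_name(tt$name) == RENAL_SOC_NAME]
  if (length(soc) != 1L) {
    stop("dictionary must contain exactly one SOC named 'Renal and urinary disorders'")
  }
  hlts <- tt$code[tt$level == "HLT"]
  under_soc <- hlts[vapply(hlts, function(h) soc %in% .socs_of_hlt(dict, h),
                           logical(1L))]
  nm <- .norm_term_name(setNames(tt$name, tt$code)[under_soc])
  hit <- match(RENAL_HLT_NAMES, nm)
  if (anyNA(hit)) {
    stop("renal SOC is missing required HLT(s): ",
         paste(RENAL_HLT_NAMES[is.na(hit)], collapse = "; "))
  }
  unname(under_soc[hit])
}

#' Preferred terms screened for disproportionality
#'
#' The thirteen renally screened PTs of the demonstration dictionary, as a
#' named character vector (names are display labels, values are PT codes).
#' These form the default event grid of [screen_disproportionality()] and
#' [run_pipeline()].
#'
#' @return named character vector of 13 PT codes.
#' @export
studied_pts <- function() {
  c("Tubulointerstitial nephritis" = "PT_TIN",
    "Acute kidney injury"          = "PT_AKI",
    "Chronic kidney disease"       = "PT_CKD",
    "Oliguria"                     = "PT_OLIGURIA",
    "Renal failure"                = "PT_RENAL_FAILURE",
    "Renal impairment"             = "PT_RENAL_IMPAIRMENT",
    "Fluid retention"              = "PT_FLUID_RETENTION",
    "Renal disorder"               = "PT_RENAL_DISORDER",
    "Nephropathy"                  = "PT_NEPHROPATHY",
    "Toxic nephropathy"            = "PT_TOXIC_NEPHROPATHY",
    "Nephrotic syndrome"           = "PT_NEPHROTIC_SYNDROME",
    "Renal artery stenosis"        = "PT_RAS",
    "Thrombotic microangiopathy"   = "PT_TMA")
}

#' Index drug codes of the demonstration setting
#'
#' The five BCR-ABL tyrosine kinase inhibitors used as index drugs in the
#' bundled configurations.
#'
#' @return character vector of 5 drug codes.
#' @export
tki_drugs <- function() {
  c("IMATINIB", "DASATINIB", "NILOTINIB", "BOSUTINIB", "PONATINIB")
}
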