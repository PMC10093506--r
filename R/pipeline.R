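#' Read a pipeline configuration file
#'
#' The configuration is a JSON object with blocks `store` (either
#' `"synthetic"`, a [synthetic_config()] argument list, or the three table
#' paths), `dictionary` (`terms`/`links` paths, or `"demo"` for the
#' bundled dictionary), `selection`, `screen` and `report`. Relative paths
#' are resolved against the configuration file's directory. Missing
#' blocks fall back to package defaults.
#'
#' @param path path to a JSON configuration file.
#' @return a named list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("pipeline config file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  rebase <- function(p) {
    if (is.null(p) || identical(p, "demo")) return(p)
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  if (is.list(cfg$dictionary)) {
    for (k in c("terms", "links")) {
      cfg$dictionary[[k]] <- rebase(cfg$dictionary[[k]])
    }
  }
  for (k in c("reports", "drugs", "reactions")) {
    cfg$store[[k]] <- rebase(cfg$store[[k]])
  }
  structure(cfg, class = c("pipeline_config", class(cfg)))
}

.load_dictionary <- function(dict_cfg) {
  if (is.null(dict_cfg) || identical(dict_cfg, "demo") ||
      identical(dict_cfg$source, "demo")) {
    return(demo_dictionary())
  }
  for (p in c(dict_cfg$terms, dict_cfg$links)) {
    if (is.null(p) || !file.exists(p)) {
      stop("dictionary file not found: ", p %||% "<missing path>")
    }
  }
  read_term_dictionary(dict_cfg$terms, dict_cfg$links)
}

.load_store <- function(store_cfg, seed = NULL) {
  if (!is.null(store_cfg$synthetic)) {
    args <- store_cfg$synthetic
    if (!is.null(seed)) args$seed <- seed
    if (!is.null(args$signals)) {
      args$signals <- do.call(signal_spec, as.list(args$signals))
    }
    base_args <- c("n_reports", "seed", "signals")
    extra <- args[setdiff(names(args), base_args)]
    cfg <- do.call(default_synthetic_config,
                   c(args[intersect(base_args, names(args))], extra))
    return(generate_icsr_store(cfg))
  }
  read_icsr_store(reports_path = store_cfg$reports,
                  drugs_path = store_cfg$drugs,
                  reactions_path = store_cfg$reactions)
}

#' Export forest-plot data
#'
#' Splits screening results into plot rows (computable pairs only, sorted
#' by event then drug, with point estimate, interval bounds, SDR flag and
#' case count) and a side table of non-computable pairs with their case
#' counts, so the union of the two files is the whole screening grid.
#'
#' @param results a `dispro_screen` data.frame from
#'   [screen_disproportionality()].
#' @param path output path of the plot-data table.
#' @param side_path output path of the non-computable side table (default:
#'   `path` with a `_side` suffix).
#' @return invisible list with elements `plot` and `side` (the two
#'   data.frames).
#' @export
export_forest <- function(results, path, side_path = NULL) {
  stopifnot(inherits(results, "dispro_screen") || is.data.frame(results))
  side_path <- side_path %||% sub("(\\.[^.]*)?$", "_side\\1", path)
  res <- as.data.frame(results)
  res <- res[order(res$event, res$drug), , drop = FALSE]
  plot_rows <- res[res$computable,
                   c("drug", "event", "ror", "ci_low", "ci_high", "sdr", "a"),
                   drop = FALSE]
  names(plot_rows)[names(plot_rows) == "a"] <- "n_cases"
  side_rows <- res[!res$computable, c("drug", "event", "a"), drop = FALSE]
  names(side_rows)[names(side_rows) == "a"] <- "n_cases"
  data.table::fwrite(plot_rows, path, na = "")
  data.table::fwrite(side_rows, side_path, na = "")
  invisible(list(plot = plot_rows, side = side_rows))
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
}

#' Run the full screening pipeline
#'
#' Orchestrates the analysis end to end: load (or synthesise) the store
#' and the dictionary, deduplicate, select cases with an audit trail,
#' screen the (index drug x studied PT) grid on the full deduplicated
#' store, summarise case characteristics and times to onset, and write
#' all artifacts to `out_dir`: `audit.csv`, `screen_results.csv`/`.json`,
#' `forest.csv` + `forest_side.csv`, `characteristics.csv`/`.json`,
#' `tto.csv` and `manifest.json` (configuration, seed, versions and file
#' checksums - enough to reproduce every artifact). Deterministic for a
#' fixed configuration and seed.
#'
#' @param config a `pipeline_config` list ([read_pipeline_config()]) or a
#'   path to the JSON file.
#' @param seed optional integer overriding the configured generator seed.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @param dedup set `FALSE` to skip duplicate collapsing (ablation).
#' @param quiet suppress progress messages.
#' @return invisible list with the main result objects (`store`, `cases`,
#'   `audit`, `screen`, `characteristics`, `tto`, `paths`).
#' @export
run_pipeline <- function(config, seed = NULL, out_dir = NULL, dedup = TRUE,
                         quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out_dir <- out_dir %||% config$out_dir %||% stop("no output directory given")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  say("loading dictionary")
  dict <- .load_dictionary(config$dictionary)
  say("loading store")
  store <- .load_store(config$store, seed = seed)

  sel_args <- config$selection %||% list()
  sel <- do.call(selection_config, sel_args)
  say("selecting cases")
  selected <- select_cases(store, sel, dict, dedup = dedup)
  dd_store <- if (dedup) deduplicate_reports(store)$store else store

  scr_args <- config$screen %||% list()
  event_pts <- scr_args$event_pts %||% studied_pts()
  scr <- screen_config(min_cases = scr_args$min_cases %||% 5L,
                       z = scr_args$z %||% 1.96,
                       haldane = isTRUE(scr_args$haldane))
  say("screening ", length(sel$index_drugs), " drugs x ",
      length(event_pts), " events")
  results <- screen_disproportionality(dd_store, sel$index_drugs, event_pts,
                                       config = scr)

  say("summarising cases")
  top_k <- config$report$top_k %||% 5L
  chars <- case_characteristics(selected$cases, sel$index_drugs, dict,
                                top_k = top_k)
  tto <- suppressWarnings(tto_summary(selected$cases, sel$index_drugs, dict))

  paths <- list(
    audit = file.path(out_dir, "audit.csv"),
    screen_csv = file.path(out_dir, "screen_results.csv"),
    screen_json = file.path(out_dir, "screen_results.json"),
    forest = file.path(out_dir, "forest.csv"),
    forest_side = file.path(out_dir, "forest_side.csv"),
    characteristics_csv = file.path(out_dir, "characteristics.csv"),
    characteristics_json = file.path(out_dir, "characteristics.json"),
    tto = file.path(out_dir, "tto.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  data.table::fwrite(audit_table(selected$audit), paths$audit)
  data.table::fwrite(as.data.frame(results), paths$screen_csv, na = "")
  .write_json(as.data.frame(results), paths$screen_json)
  export_forest(results, paths$forest, paths$forest_side)
  data.table::fwrite(chars$blocks, paths$characteristics_csv, na = "")
  .write_json(list(n = as.list(chars$n), age = chars$age,
                   blocks = chars$blocks), paths$characteristics_json)
  tto_out <- tto
  num <- c("median", "q25", "q75", "mean", "sd")
  tto_out[num] <- lapply(tto_out[num],
                         function(x) ifelse(tto_out$tto_known, x, NA_real_))
  data.table::fwrite(tto_out, paths$tto, na = "UNK")

  artifact_paths <- unlist(paths[names(paths) != "manifest"])
  manifest <- list(
    package = "rorscreen",
    version = as.character(packageVersion("rorscreen")),
    r_version = R.version.string,
    seed = seed,
    config = unclass(config),
    checksums = as.list(tools::md5sum(artifact_paths))
  )
  .write_json(manifest, paths$manifest)
  say("wrote ", length(artifact_paths) + 1L, " artifacts to ", out_dir)

  invisible(list(store = store, cases = selected$cases,
                 audit = selected$audit, screen = results,
                 characteristics = chars, tto = tto, paths = paths))
}
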