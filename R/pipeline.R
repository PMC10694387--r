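# End-to-end orchestration: acquire (or generate) occurrence data,
# pre-process, standardise taxonomy, apply each curation scenario, map
# completeness and well-sampled cells, fit the latitudinal gradients and
# compare scenarios — with per-stage accounting in a machine-readable run
# report.

#' Build a pipeline run configuration
#'
#' Either `synthetic` (a [synthetic_config()]) or `occurrences` plus
#' `lookups` (file paths) must be supplied.
#'
#' @param synthetic optional [synthetic_config()]; when given, inputs are
#'   generated rather than read.
#' @param occurrences path to an occurrence CSV/TSV.
#' @param lookups named character vector of lookup CSV paths, one per
#'   standardisation source.
#' @param countries,gazetteer optional paths to the country-rectangle and
#'   gazetteer CSVs.
#' @param grid a [study_grid()].
#' @param scenarios named list of [curation_scenario()]s.
#' @param thresholds a [well_sampled_thresholds()] list.
#' @param min_votes consensus vote threshold.
#' @param out_dir optional directory for CSV outputs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = NULL, occurrences = NULL,
                            lookups = NULL, countries = NULL,
                            gazetteer = NULL, grid = study_grid(),
                            scenarios = default_scenarios(),
                            thresholds = well_sampled_thresholds(),
                            min_votes = 3, out_dir = NULL) {
  structure(list(synthetic = synthetic, occurrences = occurrences,
                 lookups = lookups, countries = countries,
                 gazetteer = gazetteer, grid = grid, scenarios = scenarios,
                 thresholds = thresholds, min_votes = min_votes,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' @param config a [pipeline_config()].
#' @return Character vector of problems; empty when the config is runnable.
#' @export
validate_config <- function(config) {
  problems <- character()
  say <- function(...) problems <<- c(problems, paste0(...))
  if (is.null(config$synthetic)) {
    if (is.null(config$occurrences)) {
      say("no input: neither `synthetic` nor `occurrences` given")
    } else if (!file.exists(config$occurrences)) {
      say("occurrences file not found: ", config$occurrences)
    }
    if (is.null(config$lookups) || length(config$lookups) == 0) {
      say("no taxonomic lookup sources configured")
    } else {
      for (p in config$lookups) {
        if (!file.exists(p)) say("lookup file not found: ", p)
      }
      if (length(config$lookups) < config$min_votes) {
        say("min_votes (", config$min_votes, ") exceeds the number of sources (",
            length(config$lookups), ")")
      }
    }
    for (fld in c("countries", "gazetteer")) {
      if (!is.null(config[[fld]]) && !file.exists(config[[fld]])) {
        say(fld, " file not found: ", config[[fld]])
      }
    }
  } else {
    if (!inherits(config$synthetic, "synthetic_config")) {
      say("`synthetic` is not a synthetic_config")
    }
    if (length(config$synthetic$synonym_tables$source_labels) < config$min_votes) {
      say("min_votes (", config$min_votes, ") exceeds the number of sources")
    }
  }
  if (!inherits(config$grid, "study_grid")) say("`grid` is not a study_grid")
  nms <- vapply(config$scenarios, `[[`, character(1), "name")
  if (anyDuplicated(nms)) say("scenario names are not unique")
  problems
}

#' Annotate records with every source's accepted name and the consensus
#'
#' Adds one `accepted_<label>` column per standardisation source and the
#' consensus `acceptedName` / `name_tie` columns; records whose name
#' resolves nowhere keep `NA`s and are not dropped (each scenario decides).
#'
#' @param records canonical occurrence tibble.
#' @param maps named list of [standardise()] outputs.
#' @param consensus a [build_consensus()] result.
#' @return The annotated tibble.
#' @export
annotate_taxonomy <- function(records, maps, consensus) {
  rn <- tibble::tibble(raw_norm = as.character(normalise_name(records$scientificName)))
  out <- records
  for (src in names(maps)) {
    m <- dplyr::distinct(maps[[src]][c("raw_norm", "accepted_name")])
    out[[paste0("accepted_", src)]] <-
      dplyr::left_join(rn, m, by = "raw_norm")$accepted_name
  }
  # same per-raw-name majority assignment as apply_consensus, kept as NA
  cons <- .consensus_names(consensus)
  votes <- .norm_level_maps(maps) |>
    dplyr::filter(!is.na(.data$accepted_name), .data$accepted_name %in% cons) |>
    dplyr::count(.data$raw_norm, .data$accepted_name, name = "n_sources") |>
    dplyr::arrange(.data$raw_norm, dplyr::desc(.data$n_sources),
                   .data$accepted_name) |>
    dplyr::group_by(.data$raw_norm) |>
    dplyr::summarise(acceptedName = .data$accepted_name[1],
                     name_tie = sum(.data$n_sources == .data$n_sources[1]) > 1,
                     .groups = "drop")
  ann <- dplyr::left_join(rn, votes, by = "raw_norm")
  out$acceptedName <- ann$acceptedName
  out$name_tie <- ann$name_tie
  out
}

#' Run the full curation-sensitivity pipeline
#'
#' Stages, in order: acquire (generate or read) -> geographic pre-processing
#' and gridding -> taxonomic standardisation and consensus -> per-scenario
#' curation -> per-cell completeness and well-sampled classification ->
#' per-band gradient fits -> scenario comparison. A failing scenario is
#' recorded in the report without aborting the others. Identical
#' configuration (and seed, for synthetic inputs) gives identical output.
#'
#' @param config a [pipeline_config()].
#' @return A `pipeline_run` list: `records` (annotated, pre-processed),
#'   `consensus`, `scenarios` (per scenario: curated records, metrics,
#'   band series and fits per region), `comparison`, `report`,
#'   `errors` (per-scenario failure messages, if any).
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems) > 0) {
    stop("invalid pipeline config:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  report <- list()
  log_stage <- function(stage, n_in, n_removed) {
    report[[length(report) + 1]] <<- tibble::tibble(
      stage = stage, n_in = n_in, n_removed = n_removed,
      n_out = n_in - n_removed)
  }

  if (!is.null(config$synthetic)) {
    sim <- generate_dataset(config$synthetic, grid = config$grid)
    records0 <- sim$records
    lookups <- sim$lookups
    countries <- sim$countries
    gazetteer <- sim$gazetteer
  } else {
    records0 <- read_occurrences(config$occurrences)
    lookups <- lapply(seq_along(config$lookups), function(i) {
      read_taxon_lookup(config$lookups[[i]],
                        source_label = names(config$lookups)[i])
    })
    names(lookups) <- names(config$lookups)
    countries <- if (!is.null(config$countries)) read_countries(config$countries)
    gazetteer <- if (!is.null(config$gazetteer)) read_gazetteer(config$gazetteer)
  }
  log_stage("acquire", nrow(records0), 0L)

  pre <- preprocess(records0, config$grid, countries = countries,
                    gazetteer = gazetteer)
  log_stage("preprocess", nrow(records0), nrow(pre$removed))

  uniq_names <- unique(pre$records$scientificName)
  maps <- lapply(lookups, function(lk) standardise(uniq_names, lk))
  names(maps) <- vapply(lookups, `[[`, character(1), "source_label")
  consensus <- build_consensus(maps, min_votes = config$min_votes)
  ann <- annotate_taxonomy(pre$records, maps, consensus)
  log_stage("taxonomy_annotation", nrow(ann), 0L)

  regions <- c(stats::setNames(as.list(config$grid$region_labels),
                               config$grid$region_labels),
               list(all = config$grid$region_labels))
  scen_out <- list()
  errors <- list()
  fits <- list()
  for (sc in config$scenarios) {
    res <- tryCatch({
      cur <- apply_scenario(ann, sc)
      log_stage(paste0("scenario:", sc$name), nrow(ann), nrow(cur$removed))
      metrics <- completeness_metrics(cur$records,
                                      thresholds = config$thresholds,
                                      species_col = "species_scenario")
      series <- lapply(regions, function(rg) band_series(metrics, region = rg))
      fit <- lapply(series, fit_band_series)
      list(records = cur$records, curation_report = cur$report,
           metrics = metrics, series = series, fits = fit)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[sc$name]] <- conditionMessage(res)
    } else {
      scen_out[[sc$name]] <- res
      fits[[sc$name]] <- res$fits
    }
  }
  comparison <- if (length(fits) > 0) scenario_comparison(fits) else NULL

  run <- list(records = ann, preprocess_report = pre$report,
              consensus = consensus, maps = maps, scenarios = scen_out,
              comparison = comparison,
              report = dplyr::bind_rows(report), errors = errors)
  class(run) <- "pipeline_run"
  if (!is.null(config$out_dir)) .write_run(run, config$out_dir)
  run
}

.write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(run$report, file.path(dir, "run_report.csv"),
                   progress = FALSE)
  readr::write_csv(tibble::as_tibble(run$consensus),
                   file.path(dir, "consensus_list.csv"), progress = FALSE)
  if (!is.null(run$comparison)) {
    readr::write_csv(run$comparison, file.path(dir, "scenario_comparison.csv"),
                     na = "", progress = FALSE)
  }
  for (nm in names(run$scenarios)) {
    readr::write_csv(run$scenarios[[nm]]$metrics,
                     file.path(dir, paste0("metrics_", nm, ".csv")),
                     na = "", progress = FALSE)
  }
  invisible(dir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  print(x$report)
  if (length(x$errors) > 0) {
    cat("failed scenarios:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}
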