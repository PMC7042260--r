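#' Read a pipeline run configuration
#'
#' A single YAML file drives the whole pipeline. Recognised keys (all
#' optional unless noted): `scenario` (preset name) or `consumers`/`sources`
#' (CSV paths) — one of the two is required; `outdir` (default `"isomix_out"`);
#' `seed`; `tef` (`mean_d13C`, `mean_d15N`, `sd_d13C`, `sd_d15N`); `sampler`
#' (`n_chains`, `n_iter`, `burn_in`, `thin`); `residence_times` (`muscle`,
#' `hepatopancreas`); `window_overrides` (window name -> `start_date`/
#' `end_date`); `trophic` (`lambda`, `delta_n`, `tef_n`); `threshold`;
#' `grouping` (`"default"` or taxon -> group map); `aggregates` (source ->
#' aggregate map, default the feeding-mode partition).
#'
#' @param path YAML file path.
#' @return A `run_config` list with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  as_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config A plain list of config values.
#' @export
as_run_config <- function(config = list()) {
  defaults <- list(
    scenario = NULL, consumers = NULL, sources = NULL,
    outdir = "isomix_out", seed = 1,
    tef = list(mean_d13C = 3.0, mean_d15N = 0.9, sd_d13C = 0.6,
               sd_d15N = 0.3),
    sampler = list(n_chains = 4, n_iter = 10000, burn_in = 1000, thin = 10),
    residence_times = list(muscle = 81.1, hepatopancreas = 19.3),
    window_overrides = list(),
    trophic = list(lambda = 1, delta_n = 3.4, tef_n = 0.9),
    threshold = 0.95,
    grouping = "default",
    aggregates = NULL
  )
  for (k in names(defaults)) {
    if (is.null(config[[k]])) {
      config[[k]] <- defaults[[k]]
    } else if (is.list(defaults[[k]]) && is.list(config[[k]]) &&
               k != "window_overrides") {
      for (kk in names(defaults[[k]])) {
        if (is.null(config[[k]][[kk]])) config[[k]][[kk]] <- defaults[[k]][[kk]]
      }
    }
  }
  if (is.null(config$scenario) &&
      (is.null(config$consumers) || is.null(config$sources))) {
    stop("config needs either a 'scenario' name or 'consumers' and 'sources' paths",
         call. = FALSE)
  }
  structure(config, class = "run_config")
}

.config_tef <- function(config) {
  do.call(tef_spec, config$tef)
}

.config_grouping <- function(config) {
  if (identical(config$grouping, "default")) default_grouping()
  else unlist(config$grouping)
}

.config_aggregates <- function(config) {
  if (is.null(config$aggregates)) feeding_mode_aggregation()
  else unlist(config$aggregates)
}

#' Load or simulate the study tables for a configuration
#'
#' @param config A `run_config`.
#' @return List with `consumers` and `sources` tibbles (plus `scenario` when
#'   simulated).
#' @export
load_study <- function(config) {
  if (!is.null(config$scenario)) {
    presets <- preset_scenarios(seed = config$seed)
    if (!config$scenario %in% names(presets)) {
      stop("unknown scenario '", config$scenario, "'; available: ",
           paste(names(presets), collapse = ", "), call. = FALSE)
    }
    simulate_study(presets[[config$scenario]])
  } else {
    list(consumers = read_consumer_table(config$consumers),
         sources = read_source_table(config$sources))
  }
}

#' Simulate scenario tables to disk
#'
#' Writes `consumers.csv`, `sources.csv` and a `manifest.json` (row counts,
#' scenario name, seed) into the output directory. Deterministic per seed.
#'
#' @param config A `run_config` with a `scenario` name.
#' @return The study list, invisibly.
#' @export
run_simulate <- function(config) {
  config <- as_run_config(unclass(config))
  study <- load_study(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  write_consumer_table(study$consumers, file.path(config$outdir,
                                                  "consumers.csv"))
  write_source_table(study$sources, file.path(config$outdir, "sources.csv"))
  manifest <- list(
    scenario = config$scenario, seed = config$seed,
    n_consumer_rows = nrow(study$consumers),
    n_individuals = length(unique(study$consumers$id)),
    n_source_rows = nrow(study$sources),
    sampling_dates = format(sort(unique(study$consumers$sampling_date)))
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(study)
}

#' Fit the mixing model to every consumer group
#'
#' Summarises the source samples of each sampling day, logs the
#' mixing-polygon diagnostic, and fits one posterior per consumer group
#' (sex x size x tissue cell) per sampling day using that day's source
#' summaries. Writes a per-group diet-summary table (percentages) and an
#' rhat report to the output directory.
#'
#' @param config A `run_config`.
#' @param study Optional study list from [load_study()] (loaded if omitted).
#' @return A fit table: `sex`, `size_class`, `tissue`, `sampling_date`,
#'   `period`, `n_consumers`, `max_rhat` and a `fit` list-column.
#' @export
run_fit <- function(config, study = NULL) {
  config <- as_run_config(unclass(config))
  if (is.null(study)) study <- load_study(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  tef <- .config_tef(config)
  grouping <- .config_grouping(config)
  days <- sort(unique(study$consumers$sampling_date))
  windows <- tissue_windows(days, unlist(config$residence_times),
                            config$window_overrides)

  groups <- group_consumers(study$consumers)
  fits <- vector("list", nrow(groups))
  diag_log <- list()
  for (d in seq_along(days)) {
    day_sources <- study$sources %>% filter(.data$date == days[d])
    summ <- suppressWarnings(summarize_sources(day_sources, grouping))
    diag <- withCallingHandlers(
      polygon_diagnostic(study$consumers %>%
                           filter(.data$sampling_date == days[d]),
                         summ, tef),
      warning = function(w) invokeRestart("muffleWarning"))
    diag_log[[d]] <- list(day = format(days[d]), inside = diag$inside_count,
                          n = diag$n, outside_ids = diag$outside_ids)
    spec <- mixing_model(summ, tef)
    idx <- which(groups$sampling_date == days[d])
    for (i in idx) {
      fits[[i]] <- sample_posterior(
        groups$members[[i]], spec,
        n_chains = config$sampler$n_chains,
        n_iter = config$sampler$n_iter,
        burn_in = config$sampler$burn_in,
        thin = config$sampler$thin,
        seed = config$seed + i)
    }
  }
  jsonlite::write_json(diag_log, file.path(config$outdir,
                                           "polygon_diagnostic.json"),
                       auto_unbox = TRUE, digits = NA)

  fit_table <- groups %>%
    mutate(period = period_for(.data$tissue, .data$sampling_date, windows),
           fit = fits,
           max_rhat = vapply(fits, function(f) max(f$rhat, na.rm = TRUE),
                             numeric(1))) %>%
    rename(n_consumers = "n") %>%
    select("sex", "size_class", "tissue", "sampling_date", "period",
           "n_consumers", "max_rhat", "fit")

  summaries <- purrr::map_dfr(seq_len(nrow(fit_table)), function(i) {
    summarize_posterior(fit_table$fit[[i]]) %>%
      mutate(sex = fit_table$sex[i], size_class = fit_table$size_class[i],
             period = fit_table$period[i], .before = 1)
  })
  readr::write_csv(summaries, file.path(config$outdir, "diet_summaries.csv"),
                   progress = FALSE)
  readr::write_csv(fit_table %>% select(-"fit"),
                   file.path(config$outdir, "rhat_report.csv"),
                   progress = FALSE)
  fit_table
}

#' Run the group-comparison hypothesis tests
#'
#' Aggregates every fit with the configured source aggregation and computes
#' the size-related (all sex x period cells, three ordered size pairs each)
#' and sex-related (female vs male per size in the two long periods)
#' posterior comparison probabilities. Results are written to
#' `size_comparisons.csv` and `sex_comparisons.csv`.
#'
#' @param config A `run_config`.
#' @param fit_table Fit table from [run_fit()] (computed if omitted).
#' @return List with `size` and `sex` comparison tibbles.
#' @export
run_compare <- function(config, fit_table = NULL) {
  config <- as_run_config(unclass(config))
  if (is.null(fit_table)) fit_table <- run_fit(config)
  agg <- .config_aggregates(config)
  agg_table <- fit_table %>%
    mutate(fit = purrr::map(.data$fit, combine_sources, aggregation = agg))
  size_res <- run_size_comparisons(agg_table, threshold = config$threshold)
  sex_res <- run_sex_comparisons(agg_table, threshold = config$threshold)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(size_res, file.path(config$outdir, "size_comparisons.csv"),
                   progress = FALSE)
  readr::write_csv(sex_res, file.path(config$outdir, "sex_comparisons.csv"),
                   progress = FALSE)
  list(size = size_res, sex = sex_res)
}

#' Trophic-position table for a configuration
#'
#' Derives the phytoplankton baseline from the source samples, builds the
#' tissue windows (honouring any configured overrides) and writes the
#' per-period and overall trophic-position table.
#'
#' @param config A `run_config`.
#' @param study Optional study list (loaded if omitted).
#' @return The [tp_table()] tibble.
#' @export
run_tp <- function(config, study = NULL) {
  config <- as_run_config(unclass(config))
  if (is.null(study)) study <- load_study(config)
  days <- sort(unique(study$consumers$sampling_date))
  base <- baseline_from_phytoplankton(study$sources, sampling_dates = days)
  params <- trophic_params(lambda_base = config$trophic$lambda,
                           delta_n = config$trophic$delta_n,
                           tef_n = config$trophic$tef_n,
                           d15N_base = base)
  windows <- tissue_windows(days, unlist(config$residence_times),
                            config$window_overrides)
  tab <- tp_table(study$consumers, params, windows)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tab, file.path(config$outdir, "trophic_position.csv"),
                   progress = FALSE)
  tab
}

#' Full pipeline run
#'
#' Simulates (or loads) the study, fits every group, runs both comparison
#' batteries and the trophic-position table, writing all report tables to
#' the output directory. One config and seed give byte-identical outputs.
#'
#' @param config A `run_config` (or path to a YAML config).
#' @return List with `study`, `fits`, `comparisons`, `tp`.
#' @export
run_report <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- as_run_config(unclass(config))
  study <- if (!is.null(config$scenario)) run_simulate(config)
           else load_study(config)
  fit_table <- run_fit(config, study)
  comparisons <- run_compare(config, fit_table)
  tp <- run_tp(config, study)
  invisible(list(study = study, fits = fit_table, comparisons = comparisons,
                 tp = tp))
}
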