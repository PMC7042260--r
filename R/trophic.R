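#' Trophic-position parameters
#'
#' @param lambda_base Trophic level of the isotopic baseline (1 for primary
#'   producers such as phytoplankton).
#' @param delta_n Average delta-15N increase per trophic level (per-mil);
#'   default 3.4, the standard aquatic food-web value.
#' @param tef_n Taxon-specific delta-15N trophic enrichment factor (per-mil)
#'   used by the decapod-corrected estimator; default 0.9 (mantis shrimp
#'   muscle).
#' @param d15N_base Baseline delta-15N (per-mil), e.g. from
#'   [baseline_from_phytoplankton()].
#' @return An object of class `trophic_params`.
#' @export
trophic_params <- function(lambda_base = 1, delta_n = 3.4, tef_n = 0.9,
                           d15N_base = NA_real_) {
  if (delta_n <= 0) stop("delta_n must be positive", call. = FALSE)
  structure(list(lambda_base = lambda_base, delta_n = delta_n,
                 tef_n = tef_n, d15N_base = d15N_base),
            class = "trophic_params")
}

.check_base <- function(params) {
  if (!is.finite(params$d15N_base)) {
    stop("d15N_base is not set; supply it or use baseline_from_phytoplankton()",
         call. = FALSE)
  }
}

#' Trophic position from delta-15N
#'
#' `tp_basic()` is the classical estimator
#' `TP = lambda + (d15N_c - d15N_base) / delta_n`.
#'
#' `tp_corrected()` adapts it to consumers whose own per-level enrichment is
#' much lower than `delta_n` (decapods: 0.9 vs 3.4 per-mil). The consumer's
#' taxon-specific TEF is first subtracted from its signature, which removes
#' the consumer's final trophic step entirely; the lost level is then added
#' back: `TP = 1 + (lambda + ((d15N_c - tef_n) - d15N_base) / delta_n)`.
#' Algebraically `tp_corrected(x) = 1 + tp_basic(x - tef_n)`.
#'
#' @param d15N_c Consumer delta-15N value(s), per-mil (vectorised).
#' @param params A [trophic_params()] with `d15N_base` set.
#' @return Numeric trophic position(s).
#' @export
tp_basic <- function(d15N_c, params) {
  .check_base(params)
  params$lambda_base + (d15N_c - params$d15N_base) / params$delta_n
}

#' @rdname tp_basic
#' @export
tp_corrected <- function(d15N_c, params) {
  .check_base(params)
  1 + (params$lambda_base +
         ((d15N_c - params$tef_n) - params$d15N_base) / params$delta_n)
}

#' Phytoplankton delta-15N baseline
#'
#' Averages the day-level mean delta-15N of the phytoplankton samples across
#' the sampling days with equal day weights (day means are computed first,
#' then averaged, so unbalanced per-day sample counts do not bias the
#' baseline towards the better-sampled day).
#'
#' @param samples Source-sample tibble.
#' @param group Group (or taxon) label identifying phytoplankton rows.
#' @param sampling_dates Optional vector of dates that must each have at
#'   least one sample; defaults to the dates present.
#' @return The baseline delta-15N (per-mil).
#' @export
baseline_from_phytoplankton <- function(samples, group = "Phytoplankton",
                                        sampling_dates = NULL) {
  phyto <- samples %>%
    filter(.data$group == !!group | .data$taxon == !!group)
  if (is.null(sampling_dates)) {
    sampling_dates <- sort(unique(phyto$date))
  }
  sampling_dates <- as.Date(sampling_dates)
  if (length(sampling_dates) == 0) {
    stop("no phytoplankton samples found", call. = FALSE)
  }
  day_means <- vapply(sampling_dates, function(d) {
    v <- phyto$d15N[phyto$date == d]
    if (length(v) == 0) {
      stop("no phytoplankton sample on sampling day ", format(d),
           call. = FALSE)
    }
    mean(v)
  }, numeric(1))
  mean(day_means)
}

#' Per-period and overall trophic-position table
#'
#' Computes a trophic position for every tissue measurement with
#' [tp_corrected()], assigns each measurement to its dietary-integration
#' window by tissue and sampling date, and reports per-period mean, sample SD
#' and n plus an overall row. By default the overall row pools all
#' measurements (mean and SD over every measurement); with
#' `per_individual = TRUE` each individual's tissue values are averaged first
#' and the overall statistics are taken over individuals.
#'
#' @param consumers Consumer tibble.
#' @param params A [trophic_params()] with `d15N_base` set.
#' @param windows Window table from [tissue_windows()].
#' @param per_individual Overall row over individuals rather than
#'   measurements.
#' @return A tibble: `period`, `mean`, `sd`, `n`, ending with an
#'   `"Overall (avg)"` row.
#' @export
tp_table <- function(consumers, params, windows = tissue_windows(),
                     per_individual = FALSE) {
  consumers <- as_tibble(consumers)
  consumers$period <- period_for(consumers$tissue, consumers$sampling_date,
                                 windows)
  if (any(is.na(consumers$period))) {
    bad <- consumers$id[is.na(consumers$period)]
    stop("record(s) not assignable to any window: ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  consumers$tp <- tp_corrected(consumers$d15N, params)
  per_period <- consumers %>%
    mutate(period = factor(.data$period, levels = unique(windows$name))) %>%
    group_by(.data$period) %>%
    summarise(mean = mean(.data$tp),
              sd = ifelse(dplyr::n() > 1, sd(.data$tp), 0),
              n = dplyr::n(), .groups = "drop") %>%
    mutate(period = as.character(.data$period))
  overall_vals <- if (per_individual) {
    consumers %>%
      group_by(.data$id) %>%
      summarise(tp = mean(.data$tp), .groups = "drop") %>%
      pull("tp")
  } else {
    consumers$tp
  }
  bind_rows(
    per_period,
    tibble(period = "Overall (avg)",
           mean = mean(overall_vals),
           sd = ifelse(length(overall_vals) > 1, sd(overall_vals), 0),
           n = length(overall_vals))
  )
}
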