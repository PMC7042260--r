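#' Default taxon-to-source-group map
#'
#' Maps 17 illustrative coastal benthic/planktonic prey taxa onto the seven
#' source groups used throughout the package: Crustaceans, Filter feeders,
#' Fish, Phytoplankton, Polychaeta, POM_susp and Zooplankton.
#'
#' @return A named character vector: names are taxa, values are groups.
#' @export
default_grouping <- function() {
  c(
    "Crangon crangon"     = "Crustaceans",
    "Pagurus bernhardus"  = "Crustaceans",
    "Amphipoda"           = "Crustaceans",
    "Ascidiella aspersa"  = "Filter feeders",
    "Ciona intestinalis"  = "Filter feeders",
    "Mytilus edulis"      = "Filter feeders",
    "Aequipecten opercularis" = "Filter feeders",
    "Callionymus lyra"    = "Fish",
    "Gobiidae"            = "Fish",
    "Pomatoschistus minutus" = "Fish",
    "Phytoplankton"       = "Phytoplankton",
    "Nephtys hombergii"   = "Polychaeta",
    "Glycera alba"        = "Polychaeta",
    "Terebellidae"        = "Polychaeta",
    "POM_susp"            = "POM_susp",
    "Zooplankton"         = "Zooplankton",
    "Calanoida"           = "Zooplankton"
  )
}

#' Summarise source samples into per-group means and SDs
#'
#' Collapses individual source (prey) samples into the per-group isotopic
#' means and standard deviations that the mixing model consumes. The mean is
#' the arithmetic mean and the SD the sample standard deviation (n - 1
#' denominator) per isotope. Groups represented by a single sample get SD 0
#' and are flagged via the `degenerate` column.
#'
#' @param samples A source-sample tibble (columns `taxon`, `d13C`, `d15N`;
#'   `group` used when `grouping` is `NULL`).
#' @param grouping Optional named character vector mapping taxa to groups.
#'   When supplied, every taxon in `samples` must be present in it; when
#'   `NULL`, the existing `group` column is used.
#' @return A tibble with one row per group: `group`, `mean_d13C`, `mean_d15N`,
#'   `sd_d13C`, `sd_d15N`, `n`, `degenerate`.
#' @export
summarize_sources <- function(samples, grouping = NULL) {
  samples <- as_tibble(samples)
  if (!is.null(grouping)) {
    unmapped <- setdiff(unique(samples$taxon), names(grouping))
    if (length(unmapped) > 0) {
      stop("taxa missing from grouping map: ",
           paste(sort(unmapped), collapse = ", "), call. = FALSE)
    }
    samples$group <- unname(grouping[samples$taxon])
  }
  if (any(is.na(samples$group) | samples$group == "")) {
    stop("source samples with empty group", call. = FALSE)
  }
  keep <- is.finite(samples$d13C) & is.finite(samples$d15N)
  if (!all(keep)) {
    warning(sum(!keep), " source sample(s) with missing deltas excluded",
            call. = FALSE)
    samples <- samples[keep, ]
  }
  if (nrow(samples) == 0) stop("no source samples to summarise", call. = FALSE)
  out <- samples %>%
    group_by(.data$group) %>%
    summarise(
      mean_d13C = mean(.data$d13C),
      mean_d15N = mean(.data$d15N),
      sd_d13C = ifelse(dplyr::n() > 1, sd(.data$d13C), 0),
      sd_d15N = ifelse(dplyr::n() > 1, sd(.data$d15N), 0),
      n = dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(degenerate = .data$n == 1L) %>%
    arrange(.data$group)
  if (any(out$degenerate)) {
    warning("single-sample source group(s) with SD 0: ",
            paste(out$group[out$degenerate], collapse = ", "), call. = FALSE)
  }
  out
}

#' Write / read source summaries
#'
#' @param x A source-summary tibble from [summarize_sources()].
#' @param path CSV path.
#' @return The tibble (invisibly for the writer).
#' @export
write_source_summaries <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(x)
}

#' @rdname write_source_summaries
#' @export
read_source_summaries <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    group = "c", mean_d13C = "d", mean_d15N = "d",
    sd_d13C = "d", sd_d15N = "d", n = "i", degenerate = "l"),
    progress = FALSE)
}
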