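#' Plausibility bounds for bulk tissue isotope values
#'
#' Marine food-web delta values outside these ranges almost always indicate a
#' unit or transcription problem, so readers warn (never error) when a value
#' falls outside them.
#'
#' @param d13C,d15N length-2 numeric `c(min, max)` in per-mil.
#' @return A named list with elements `d13C` and `d15N`.
#' @export
isotope_bounds <- function(d13C = c(-50, 0), d15N = c(-5, 30)) {
  stopifnot(length(d13C) == 2, length(d15N) == 2,
            d13C[1] < d13C[2], d15N[1] < d15N[2])
  list(d13C = d13C, d15N = d15N)
}

.check_bounds <- function(x, bounds, what) {
  for (iso in .isotopes) {
    v <- x[[iso]]
    b <- bounds[[iso]]
    bad <- which(is.finite(v) & (v < b[1] | v > b[2]))
    if (length(bad) > 0) {
      warning(sprintf(
        "%d %s %s value(s) outside plausibility bounds [%g, %g] (rows %s)",
        length(bad), what, iso, b[1], b[2],
        paste(head(bad, 5), collapse = ", ")),
        call. = FALSE)
    }
  }
  invisible(x)
}

# applies alias maps like list(sex = c(F = "female")) to enum-like columns
.apply_aliases <- function(x, aliases) {
  for (col in names(aliases)) {
    if (!col %in% names(x)) next
    map <- aliases[[col]]
    hit <- x[[col]] %in% names(map)
    x[[col]][hit] <- unname(map[x[[col]][hit]])
  }
  x
}

.check_enum <- function(x, col, levels) {
  bad <- which(!is.na(x[[col]]) & !(x[[col]] %in% levels))
  if (length(bad) > 0) {
    stop(sprintf(
      "invalid value(s) in column '%s' at data row(s) %s: %s (expected one of %s)",
      col, paste(head(bad, 5), collapse = ", "),
      paste(unique(x[[col]][head(bad, 5)]), collapse = ", "),
      paste(levels, collapse = "/")), call. = FALSE)
  }
  invisible(x)
}

.require_columns <- function(x, cols, what) {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing mandatory column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

# rejects rows with unparseable/missing delta values; reports 1-based file
# rows (header = row 1) so the message matches what a user sees in the file
.reject_missing_deltas <- function(x, what) {
  bad <- which(!is.finite(x$d13C) | !is.finite(x$d15N))
  if (length(bad) > 0) {
    stop(sprintf(
      "%s: missing or non-numeric delta value(s) at file row(s) %s",
      what, paste(bad + 1L, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

.parse_iso_date <- function(x, col) {
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(!is.na(x) & x != "" & is.na(d))
  if (length(bad) > 0) {
    stop(sprintf("column '%s': unparseable ISO-8601 date(s) at data row(s) %s",
                 col, paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  if (any(is.na(d))) {
    stop(sprintf("column '%s': missing date(s)", col), call. = FALSE)
  }
  d
}

#' Read a consumer isotope table
#'
#' Reads a UTF-8 comma-separated table of per-tissue consumer measurements.
#' Mandatory columns: `id`, `sex`, `size_class`, `tissue`, `sampling_date`,
#' `d13C`, `d15N`; optional: `carapace_length` (mm), `weight` (g). Dates must
#' be ISO-8601. Rows with missing delta values are rejected with their file
#' row reported; unknown enum levels are a schema error naming row and column.
#'
#' @param path Path to a CSV file with a header row.
#' @param col_map Optional named character vector renaming file columns to the
#'   canonical names, e.g. `c(d13C = "delta13C")`.
#' @param aliases Optional named list of alias maps for the enum columns,
#'   e.g. `list(sex = c(F = "female", M = "male"))`.
#' @param bounds Plausibility bounds from [isotope_bounds()]; values outside
#'   warn but are kept.
#' @return A tibble with one row per tissue measurement.
#' @export
read_consumer_table <- function(path, col_map = NULL, aliases = NULL,
                                bounds = isotope_bounds()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (col_map[[canon]] %in% names(x)) {
        names(x)[names(x) == col_map[[canon]]] <- canon
      }
    }
  }
  .require_columns(x, c("id", "sex", "size_class", "tissue", "sampling_date",
                        "d13C", "d15N"), "consumer table")
  if (!is.null(aliases)) x <- .apply_aliases(x, aliases)
  .check_enum(x, "sex", .sex_levels)
  .check_enum(x, "size_class", .size_levels)
  .check_enum(x, "tissue", .tissue_levels)
  out <- tibble(
    id = x$id,
    sex = x$sex,
    size_class = x$size_class,
    tissue = x$tissue,
    sampling_date = .parse_iso_date(x$sampling_date, "sampling_date"),
    d13C = suppressWarnings(as.numeric(x$d13C)),
    d15N = suppressWarnings(as.numeric(x$d15N))
  )
  if ("carapace_length" %in% names(x)) {
    out$carapace_length <- suppressWarnings(as.numeric(x$carapace_length))
  }
  if ("weight" %in% names(x)) {
    out$weight <- suppressWarnings(as.numeric(x$weight))
  }
  .reject_missing_deltas(out, "consumer table")
  .check_bounds(out, bounds, "consumer")
  out
}

#' Write a consumer isotope table
#'
#' @param x A consumer tibble as returned by [read_consumer_table()].
#' @param path Output CSV path.
#' @return `x`, invisibly.
#' @export
write_consumer_table <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(x)
}

#' Read a source (putative prey) sample table
#'
#' Mandatory columns: `taxon`, `group`, `date`, `d13C`, `d15N`. The `group`
#' column may be empty strings if a taxon-to-group map is applied later with
#' [summarize_sources()].
#'
#' @inheritParams read_consumer_table
#' @return A tibble with one row per source sample.
#' @export
read_source_table <- function(path, col_map = NULL,
                              bounds = isotope_bounds()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (col_map[[canon]] %in% names(x)) {
        names(x)[names(x) == col_map[[canon]]] <- canon
      }
    }
  }
  .require_columns(x, c("taxon", "group", "date", "d13C", "d15N"),
                   "source table")
  out <- tibble(
    taxon = x$taxon,
    group = x$group,
    date = .parse_iso_date(x$date, "date"),
    d13C = suppressWarnings(as.numeric(x$d13C)),
    d15N = suppressWarnings(as.numeric(x$d15N))
  )
  .reject_missing_deltas(out, "source table")
  .check_bounds(out, bounds, "source")
  out
}

#' Write a source sample table
#'
#' @param x A source tibble as returned by [read_source_table()].
#' @param path Output CSV path.
#' @return `x`, invisibly.
#' @export
write_source_table <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(x)
}

#' Trophic enrichment factor specification
#'
#' The per-trophic-step isotopic shift applied to each source, as a mean and
#' standard deviation per isotope. Defaults are decapod-specific values
#' measured in mantis shrimp muscle: 3.0 +/- 0.6 per-mil for delta-13C and
#' 0.9 +/- 0.3 per-mil for delta-15N.
#'
#' @param mean_d13C,mean_d15N TEF means (per-mil).
#' @param sd_d13C,sd_d15N TEF standard deviations (per-mil, nonnegative).
#' @return An object of class `tef_spec`: a list with numeric vectors `mean`
#'   and `sd`, each named by isotope.
#' @export
tef_spec <- function(mean_d13C = 3.0, mean_d15N = 0.9,
                     sd_d13C = 0.6, sd_d15N = 0.3) {
  sds <- c(d13C = sd_d13C, d15N = sd_d15N)
  if (any(sds < 0)) stop("TEF standard deviations must be nonnegative",
                         call. = FALSE)
  structure(list(mean = c(d13C = mean_d13C, d15N = mean_d15N), sd = sds),
            class = "tef_spec")
}

#' @export
print.tef_spec <- function(x, ...) {
  cat(sprintf("TEF: d13C %.2f +/- %.2f permil; d15N %.2f +/- %.2f permil\n",
              x$mean["d13C"], x$sd["d13C"], x$mean["d15N"], x$sd["d15N"]))
  invisible(x)
}
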