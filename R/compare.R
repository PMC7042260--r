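#' Posterior probability that one group's diet proportion exceeds another's
#'
#' Computes `p_bic = P(proportion in group A > proportion in group B)` for a
#' given (possibly aggregated) source by pairing posterior draws by index
#' after truncating both sets to their common length. Because the two group
#' posteriors are fitted independently, index pairing is an unbiased
#' Monte-Carlo estimate of the probability under the product posterior. Ties
#' count 0.5 so that `p_bic(A, B) + p_bic(B, A) = 1` exactly.
#'
#' @param fit_a,fit_b `isomix_fit` objects for the two groups.
#' @param source Source (or aggregate) label present in both fits.
#' @param threshold Significance threshold on `p_bic` (default 0.95,
#'   one-sided per ordered pair).
#' @param labels Optional length-2 character vector naming the groups in the
#'   output.
#' @return A one-row tibble: `group_a`, `group_b`, `source`, `p_bic`,
#'   `significant`, `n_draws`.
#' @export
compare_groups <- function(fit_a, fit_b, source, threshold = 0.95,
                           labels = c("A", "B")) {
  for (f in list(fit_a, fit_b)) {
    if (!source %in% f$source_names) {
      stop("source '", source, "' not present in both fits", call. = FALSE)
    }
  }
  a <- fit_a$draws[[source]]
  b <- fit_b$draws[[source]]
  n <- min(length(a), length(b))
  if (n == 0) stop("no common draws to compare", call. = FALSE)
  a <- a[seq_len(n)]
  b <- b[seq_len(n)]
  p <- (sum(a > b) + 0.5 * sum(a == b)) / n
  tibble(
    group_a = labels[1],
    group_b = labels[2],
    source = source,
    p_bic = p,
    significant = p > threshold,
    n_draws = n
  )
}

# fetch one fit from a fit table by key, NULL when absent
.lookup_fit <- function(fit_table, sex, size_class, period) {
  hit <- fit_table$sex == sex & fit_table$size_class == size_class &
    fit_table$period == period
  if (!any(hit)) return(NULL)
  fit_table$fit[[which(hit)[1]]]
}

#' Size-related diet comparisons
#'
#' For every sex x period cell of the design, compares the posterior
#' proportion of `source` (by default the suspension-feeding aggregate)
#' between all three ordered size pairs: small vs medium, small vs large,
#' medium vs large. On the full two-sex, four-period design this yields 24
#' comparisons. Cells with a missing group are skipped with a warning.
#'
#' @param fit_table Tibble with columns `sex`, `size_class`, `period` and a
#'   `fit` list-column of `isomix_fit` objects (aggregated so that `source`
#'   is present; see [combine_sources()]).
#' @param periods Periods to include (default all present).
#' @param source Label compared (default `"suspension"`).
#' @param threshold Significance threshold on `p_bic`.
#' @return A tibble of [compare_groups()] rows with `sex`, `period`,
#'   `size_a`, `size_b` key columns, in deterministic order.
#' @export
run_size_comparisons <- function(fit_table, periods = NULL,
                                 source = "suspension", threshold = 0.95) {
  if (is.null(periods)) {
    periods <- sort(unique(fit_table$period))
  }
  pairs <- list(c("small", "medium"), c("small", "large"),
                c("medium", "large"))
  out <- list()
  for (sx in .sex_levels) {
    for (pd in periods) {
      fits <- setNames(
        lapply(.size_levels, function(sz) .lookup_fit(fit_table, sx, sz, pd)),
        .size_levels)
      missing <- names(fits)[vapply(fits, is.null, logical(1))]
      if (length(missing) > 0) {
        warning(sprintf("cell %s x '%s': missing group(s) %s; cell skipped",
                        sx, pd, paste(missing, collapse = ", ")),
                call. = FALSE)
        next
      }
      for (pr in pairs) {
        res <- compare_groups(fits[[pr[1]]], fits[[pr[2]]], source,
                              threshold = threshold, labels = pr)
        out[[length(out) + 1]] <- res %>%
          mutate(sex = sx, period = pd,
                 size_a = pr[1], size_b = pr[2], .before = 1) %>%
          select(-"group_a", -"group_b")
      }
    }
  }
  bind_rows(out)
}

#' Sex-related diet comparisons
#'
#' For each size class in the long-tissue periods (by default "Spring long"
#' and "Summer long", the two windows covering an equivalent number of
#' feeding days), compares the posterior proportion of `source` between
#' females and males: 6 comparisons on the full design.
#'
#' @inheritParams run_size_comparisons
#' @param periods Periods to include (default the two long windows).
#' @return A tibble of comparison rows with `size_class`, `period`, `sex_a`,
#'   `sex_b` key columns.
#' @export
run_sex_comparisons <- function(fit_table,
                                periods = c("Spring long", "Summer long"),
                                source = "suspension", threshold = 0.95) {
  out <- list()
  for (pd in periods) {
    for (sz in .size_levels) {
      fa <- .lookup_fit(fit_table, "female", sz, pd)
      fb <- .lookup_fit(fit_table, "male", sz, pd)
      if (is.null(fa) || is.null(fb)) {
        warning(sprintf("size %s x '%s': missing group; comparison skipped",
                        sz, pd), call. = FALSE)
        next
      }
      res <- compare_groups(fa, fb, source, threshold = threshold,
                            labels = c("female", "male"))
      out[[length(out) + 1]] <- res %>%
        mutate(size_class = sz, period = pd,
               sex_a = "female", sex_b = "male", .before = 1) %>%
        select(-"group_a", -"group_b")
    }
  }
  bind_rows(out)
}
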