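#' Summarise posterior diet proportions
#'
#' Empirical moments and quantiles of the posterior diet proportion of each
#' source, reported both as proportions and percentages. The posterior means
#' sum to 1 (up to floating-point error) because every retained draw lies on
#' the simplex.
#'
#' @param fit An `isomix_fit` from [sample_posterior()] (possibly after
#'   [combine_sources()]).
#' @param probs Quantile probabilities.
#' @return A tibble: `source`, `mean`, `sd`, `q2.5`, `q25`, `q50`, `q75`,
#'   `q97.5`, `mean_pct`.
#' @export
summarize_posterior <- function(fit,
                                probs = c(0.025, 0.25, 0.5, 0.75, 0.975)) {
  stopifnot(inherits(fit, "isomix_fit"))
  pm <- .prop_matrix(fit)
  qs <- unname(apply(pm, 2, quantile, probs = probs, names = FALSE))
  m <- unname(colMeans(pm))
  tibble(
    source = fit$source_names,
    mean = m,
    sd = unname(apply(pm, 2, sd)),
    q2.5 = qs[1, ], q25 = qs[2, ], q50 = qs[3, ],
    q75 = qs[4, ], q97.5 = qs[5, ],
    mean_pct = 100 * m
  )
}

#' @rdname summarize_posterior
#' @param x An `isomix_fit`.
#' @param ... Unused.
#' @method tidy isomix_fit
#' @export
tidy.isomix_fit <- function(x, ...) {
  summarize_posterior(x)
}

#' One-row fit overview
#'
#' @param x An `isomix_fit`.
#' @param ... Unused.
#' @return A one-row tibble: number of sources, consumers, retained draws,
#'   chains, max rhat and mean acceptance rate.
#' @method glance isomix_fit
#' @export
glance.isomix_fit <- function(x, ...) {
  tibble(
    n_sources = length(x$source_names),
    n_consumers = x$n_consumers,
    n_draws = nrow(x$draws),
    n_chains = x$settings$n_chains,
    max_rhat = suppressWarnings(max(x$rhat, na.rm = TRUE)),
    mean_accept = mean(x$accept_rate)
  )
}

#' Posterior density plot of diet proportions
#'
#' @param object An `isomix_fit`.
#' @param ... Unused.
#' @return A ggplot object: one density per source.
#' @method autoplot isomix_fit
#' @export
autoplot.isomix_fit <- function(object, ...) {
  long <- object$draws %>%
    tidyr::pivot_longer(all_of(object$source_names),
                        names_to = "source", values_to = "proportion")
  ggplot2::ggplot(long, ggplot2::aes(.data$proportion,
                                     fill = .data$source)) +
    ggplot2::geom_density(alpha = 0.5, colour = NA) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "Dietary proportion", y = "Posterior density",
                  fill = "Source") +
    ggplot2::theme_minimal()
}
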