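#' Mixing-polygon diagnostic
#'
#' A two-isotope mixing model is only well posed for consumers lying inside
#' the convex hull of the TEF-corrected source means (the "mixing polygon").
#' This diagnostic tests every consumer against the closed hull (boundary
#' counts as inside) and reports the ones that fall outside. Outside points
#' warn but never abort: the polygon is a diagnostic, not a filter.
#'
#' @param consumers A consumer tibble with `id`, `d13C`, `d15N`.
#' @param sources A source-summary tibble from [summarize_sources()].
#' @param tef A [tef_spec()]; its means are added to the source means before
#'   the hull is formed.
#' @return An object of class `polygon_diagnostic`: list with `inside_count`,
#'   `outside_ids`, `n`, and `hull` (tibble of hull vertices in order).
#' @export
polygon_diagnostic <- function(consumers, sources, tef = tef_spec()) {
  if (nrow(sources) < 3) {
    stop("mixing-polygon diagnostic needs at least 3 source groups",
         call. = FALSE)
  }
  px <- sources$mean_d13C + tef$mean["d13C"]
  py <- sources$mean_d15N + tef$mean["d15N"]
  hull_idx <- grDevices::chull(px, py)
  if (length(hull_idx) < 3) {
    stop("TEF-corrected source means are collinear; mixing polygon undefined",
         call. = FALSE)
  }
  hx <- px[hull_idx]
  hy <- py[hull_idx]
  # orient counterclockwise so the half-plane test has a consistent sign
  area2 <- sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)
  if (abs(area2) < 1e-12) {
    stop("TEF-corrected source means are collinear; mixing polygon undefined",
         call. = FALSE)
  }
  if (area2 < 0) {
    hx <- rev(hx)
    hy <- rev(hy)
  }
  scale <- max(abs(c(hx, hy)), 1)
  tol <- 1e-9 * scale
  inside <- vapply(seq_len(nrow(consumers)), function(i) {
    x <- consumers$d13C[i]
    y <- consumers$d15N[i]
    all((c(hx[-1], hx[1]) - hx) * (y - hy) -
          (c(hy[-1], hy[1]) - hy) * (x - hx) >= -tol)
  }, logical(1))
  ids <- if ("id" %in% names(consumers)) consumers$id else
    as.character(seq_len(nrow(consumers)))
  out <- structure(list(
    inside_count = sum(inside),
    outside_ids = ids[!inside],
    n = nrow(consumers),
    hull = tibble(d13C = hx, d15N = hy)
  ), class = "polygon_diagnostic")
  if (length(out$outside_ids) > 0) {
    warning(length(out$outside_ids),
            " consumer(s) outside the mixing polygon: ",
            paste(head(out$outside_ids, 10), collapse = ", "), call. = FALSE)
  }
  out
}

#' @export
print.polygon_diagnostic <- function(x, ...) {
  cat(sprintf("Mixing polygon: %d/%d consumers inside (%d outside)\n",
              x$inside_count, x$n, x$n - x$inside_count))
  invisible(x)
}

#' Isotope bi-plot of consumers and TEF-corrected sources
#'
#' @inheritParams polygon_diagnostic
#' @return A ggplot object.
#' @export
plot_isospace <- function(consumers, sources, tef = tef_spec()) {
  corr <- sources %>%
    mutate(d13C = .data$mean_d13C + tef$mean["d13C"],
           d15N = .data$mean_d15N + tef$mean["d15N"])
  hull <- polygon_diagnostic(consumers[0, , drop = FALSE], sources, tef)$hull
  ggplot2::ggplot() +
    ggplot2::geom_polygon(data = hull,
                          ggplot2::aes(.data$d13C, .data$d15N),
                          fill = NA, colour = "grey40", linetype = 2) +
    ggplot2::geom_point(data = consumers,
                        ggplot2::aes(.data$d13C, .data$d15N),
                        alpha = 0.6, size = 1.5) +
    ggplot2::geom_point(data = corr,
                        ggplot2::aes(.data$d13C, .data$d15N),
                        colour = "red3", shape = 17, size = 3) +
    ggplot2::geom_text(data = corr,
                       ggplot2::aes(.data$d13C, .data$d15N,
                                    label = .data$group),
                       vjust = -1, size = 3, colour = "red3") +
    ggplot2::labs(x = expression(delta^13 * C ~ "(‰)"),
                  y = expression(delta^15 * N ~ "(‰)"),
                  title = "Iso-space: consumers and TEF-corrected sources") +
    ggplot2::theme_minimal()
}
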