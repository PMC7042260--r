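#' Brute-force posterior oracle on a simplex lattice
#'
#' Computes posterior moments of the diet proportions by exhaustive
#' normalised summation over a lattice on the simplex (K <= 3) crossed with a
#' log-spaced grid over the two residual SDs, each grid point weighted by the
#' likelihood times the Dirichlet and half-Normal prior densities (with the
#' local grid spacing as integration measure). Intended as an independent
#' check of [sample_posterior()] on small problems, not for production use.
#'
#' @param consumers Consumer tibble (or matrix) of delta values.
#' @param spec A [mixing_model()] with at most 3 sources.
#' @param grid_step Simplex lattice step (default 0.01).
#' @param eps_grid Optional numeric vector of residual-SD grid points shared
#'   by both isotopes; default 24 log-spaced points spanning the prior.
#' @return A diet-summary tibble as from [summarize_posterior()].
#' @export
grid_posterior_oracle <- function(consumers, spec, grid_step = 0.01,
                                  eps_grid = NULL) {
  stopifnot(inherits(spec, "mixing_model"))
  K <- spec$K
  if (K > 3) stop("grid oracle supports at most 3 sources", call. = FALSE)
  y <- .consumer_matrix(consumers)
  n <- nrow(y)

  # simplex lattice
  g <- seq(0, 1, by = grid_step)
  P <- if (K == 2) {
    cbind(g, 1 - g)
  } else {
    gg <- expand.grid(p1 = g, p2 = g)
    gg <- gg[gg$p1 + gg$p2 <= 1 + 1e-12, ]
    cbind(gg$p1, gg$p2, pmax(1 - gg$p1 - gg$p2, 0))
  }

  if (is.null(eps_grid)) {
    eps_grid <- exp(seq(log(0.02), log(3 * spec$resid_scale),
                        length.out = 24))
  }
  # integration weight per eps point: half-Normal density x local spacing
  deps <- diff(c(0, eps_grid))
  lw_eps <- log(2 * dnorm(eps_grid, 0, spec$resid_scale) * deps)

  # Dirichlet prior kernel on the lattice (normalisation cancels); lattice
  # boundary points get zero mass when any alpha < 1 (density diverges there)
  lprior <- as.vector(log(pmax(P, 1e-300)) %*% (spec$alpha - 1))
  if (any(spec$alpha < 1)) lprior[apply(P == 0, 1, any)] <- -Inf

  mu_g <- P %*% spec$mu_corr   # lattice x 2 mixture means
  v0_g <- (P^2) %*% spec$var_k # lattice x 2 pre-residual variance
  if (n > 0) {
    # ss[g, j] = sum_i (y_ij - mu_gj)^2
    ss <- vapply(1:2, function(j) {
      rowSums((matrix(y[, j], nrow(P), n, byrow = TRUE) - mu_g[, j])^2)
    }, numeric(nrow(P)))
  }

  ne <- length(eps_grid)
  lp_all <- vector("list", ne * ne)
  idx <- 0
  for (a in seq_len(ne)) {
    for (b in seq_len(ne)) {
      lp <- lprior + lw_eps[a] + lw_eps[b]
      if (n > 0) {
        v1 <- v0_g[, 1] + eps_grid[a]^2
        v2 <- v0_g[, 2] + eps_grid[b]^2
        lp <- lp - n / 2 * log(2 * pi * v1) - ss[, 1] / (2 * v1) -
          n / 2 * log(2 * pi * v2) - ss[, 2] / (2 * v2)
      }
      idx <- idx + 1
      lp_all[[idx]] <- lp
    }
  }
  lmax <- max(vapply(lp_all, max, numeric(1)))
  marg <- Reduce(`+`, lapply(lp_all, function(lp) exp(lp - lmax)))
  w <- marg / sum(marg)

  means <- as.vector(t(P) %*% w)
  sds <- sqrt(pmax(as.vector(t(P^2) %*% w) - means^2, 0))
  qs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  qmat <- vapply(seq_len(K), function(k) {
    o <- order(P[, k])
    cw <- cumsum(w[o])
    vapply(qs, function(q) P[o[which(cw >= q)[1]], k], numeric(1))
  }, numeric(length(qs)))

  tibble(
    source = spec$source_names,
    mean = means,
    sd = sds,
    q2.5 = qmat[1, ], q25 = qmat[2, ], q50 = qmat[3, ],
    q75 = qmat[4, ], q97.5 = qmat[5, ],
    mean_pct = 100 * means
  )
}
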