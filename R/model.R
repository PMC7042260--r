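#' Specify a two-isotope Bayesian mixing model
#'
#' Assembles the fixed quantities of the mixing model: per-source
#' TEF-corrected means, per-source variances (source SD^2 + TEF SD^2, floored
#' at 1e-6 per-mil to keep the likelihood proper), the Dirichlet prior on the
#' diet proportions and the half-Normal prior on the per-isotope residual
#' SDs.
#'
#' For consumer signature y_ij (consumer i, isotope j) the likelihood is
#' Normal with mean sum_k p_k (mu_kj + c_j) and variance
#' sum_k p_k^2 (sigma_kj^2 + tau_j^2) + eps_j^2, where mu/sigma are the
#' source moments, c/tau the TEF moments and eps_j the residual SD.
#'
#' @param sources Source-summary tibble from [summarize_sources()] (K >= 2
#'   rows).
#' @param tef A [tef_spec()].
#' @param alpha Dirichlet concentration(s): scalar or length-K positive
#'   vector; default 1 (uniform over the simplex).
#' @param resid_scale Half-Normal prior scale for each residual SD (per-mil).
#' @return An object of class `mixing_model`.
#' @export
mixing_model <- function(sources, tef = tef_spec(), alpha = 1,
                         resid_scale = 5.0) {
  sources <- as_tibble(sources)
  K <- nrow(sources)
  if (K < 2) stop("a mixing model needs at least 2 sources", call. = FALSE)
  if (length(alpha) == 1) alpha <- rep(alpha, K)
  if (length(alpha) != K || any(alpha <= 0)) {
    stop("alpha must be positive, scalar or length K", call. = FALSE)
  }
  if (resid_scale <= 0) stop("resid_scale must be positive", call. = FALSE)
  mu <- cbind(d13C = sources$mean_d13C, d15N = sources$mean_d15N)
  sds <- cbind(d13C = pmax(sources$sd_d13C, 0),
               d15N = pmax(sources$sd_d15N, 0))
  tau <- matrix(tef$sd, nrow = K, ncol = 2, byrow = TRUE,
                dimnames = list(NULL, .isotopes))
  structure(list(
    source_names = sources$group,
    K = K,
    mu_corr = sweep(mu, 2, tef$mean, "+"),     # mu_kj + c_j
    var_k = pmax(sds^2 + tau^2, 1e-12),        # sigma_kj^2 + tau_j^2, floored
    alpha = alpha,
    resid_scale = resid_scale,
    tef = tef
  ), class = "mixing_model")
}

#' @export
print.mixing_model <- function(x, ...) {
  cat(sprintf("Mixing model: %d sources (%s), Dirichlet(%s) prior,\n",
              x$K, paste(x$source_names, collapse = ", "),
              paste(format(x$alpha), collapse = ",")))
  cat(sprintf("  half-Normal(%.1f permil) residual prior\n", x$resid_scale))
  invisible(x)
}

# consumers -> n x 2 matrix of delta values
.consumer_matrix <- function(consumers) {
  if (is.matrix(consumers)) {
    stopifnot(ncol(consumers) == 2)
    colnames(consumers) <- .isotopes
    return(consumers)
  }
  as.matrix(as_tibble(consumers)[, .isotopes])
}

#' Mixing-model log-likelihood
#'
#' Sum over consumers and isotopes of the Normal log-density with mixture
#' mean `sum_k p_k (mu_kj + c_j)` and variance
#' `sum_k p_k^2 (sigma_kj^2 + tau_j^2) + eps_j^2`.
#'
#' @param p Diet proportions: length-K vector on the simplex.
#' @param eps Length-2 nonnegative residual SDs (per-mil), ordered
#'   (d13C, d15N).
#' @param consumers Consumer tibble (or n x 2 matrix) of delta values.
#' @param spec A [mixing_model()].
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(p, eps, consumers, spec) {
  stopifnot(inherits(spec, "mixing_model"))
  if (length(p) != spec$K || any(p < -1e-9) ||
      abs(sum(p) - 1) > 1e-6) {
    stop("p must be a length-K vector on the simplex", call. = FALSE)
  }
  if (length(eps) != 2 || any(eps < 0)) {
    stop("eps must be two nonnegative residual SDs", call. = FALSE)
  }
  y <- .consumer_matrix(consumers)
  if (nrow(y) == 0) return(0)
  mu <- as.vector(p %*% spec$mu_corr)
  v <- as.vector((p^2) %*% spec$var_k) + eps^2
  if (any(v <= 0)) stop("zero total variance in likelihood", call. = FALSE)
  ll <- 0
  for (j in 1:2) {
    ll <- ll + sum(dnorm(y[, j], mu[j], sqrt(v[j]), log = TRUE))
  }
  ll
}
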