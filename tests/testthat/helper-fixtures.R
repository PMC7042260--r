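# Shared fixtures built in code.

# minimal isomix_fit from given proportion draw vectors (one per source);
# used to unit-test statistics that operate on draws
make_fit <- function(..., n_chains = 1) {
  cols <- list(...)
  n <- length(cols[[1]])
  stopifnot(all(vapply(cols, length, integer(1)) == n))
  per_chain <- n / n_chains
  draws <- tibble::tibble(
    .chain = rep(seq_len(n_chains), each = per_chain),
    .draw = rep(seq_len(per_chain), n_chains)
  )
  for (nm in names(cols)) draws[[nm]] <- cols[[nm]]
  draws$resid_d13C <- 0.1
  draws$resid_d15N <- 0.1
  structure(list(
    draws = draws,
    source_names = names(cols),
    rhat = setNames(rep(NA_real_, length(cols)), names(cols)),
    accept_rate = NA_real_,
    settings = list(n_chains = n_chains, n_iter = n, burn_in = 0, thin = 1,
                    seed = 0),
    n_consumers = NA_integer_,
    model = NULL
  ), class = "isomix_fit")
}

# three-source sub-geometry where the model is point-identified (2 tracers)
geometry3 <- function() {
  default_source_geometry()[match(c("POM_susp", "Fish", "Polychaeta"),
                                  default_source_geometry()$group), ]
}

# small consumer table fixture covering the full one-day design
consumer_fixture_one_day <- function(n_per_cell = 1,
                                     date = as.Date("2014-05-29")) {
  grid <- expand.grid(sex = c("female", "male"),
                      size_class = c("small", "medium", "large"),
                      tissue = c("muscle", "hepatopancreas"),
                      rep = seq_len(n_per_cell),
                      stringsAsFactors = FALSE)
  tibble::tibble(
    id = sprintf("c%03d", seq_len(nrow(grid))),
    sex = grid$sex, size_class = grid$size_class, tissue = grid$tissue,
    sampling_date = date,
    d13C = -18 + seq_len(nrow(grid)) * 0.01,
    d15N = 9 + seq_len(nrow(grid)) * 0.01
  )
}

# reduced sampler settings used throughout the tests
fast_fit <- function(consumers, spec, seed = 1) {
  suppressWarnings(sample_posterior(consumers, spec, n_chains = 2,
                                    n_iter = 3000, burn_in = 1000, thin = 5,
                                    seed = seed))
}

tiny_fit <- function(consumers, spec, seed = 1) {
  suppressWarnings(sample_posterior(consumers, spec, n_chains = 2,
                                    n_iter = 900, burn_in = 400, thin = 5,
                                    seed = seed))
}
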