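test_that("combine_sources preserves the per-draw simplex sum exactly", {
  geo <- default_source_geometry()
  spec <- mixing_model(geo)
  cons <- simulate_consumers(.shift <- c(
    Crustaceans = 0.1, `Filter feeders` = 0.1, Fish = 0.2,
    Phytoplankton = 0.1, Polychaeta = 0.1, POM_susp = 0.3,
    Zooplankton = 0.1), geo, n = 6, seed = 2)
  fit <- tiny_fit(cons, spec, seed = 3)

  all_in_one <- setNames(rep("everything", 7), geo$group)
  agg1 <- combine_sources(fit, all_in_one)
  expect_true(all(agg1$draws$everything == 1))

  agg2 <- combine_sources(fit, feeding_mode_aggregation())
  expect_setequal(agg2$source_names, c("active", "suspension"))
  expect_true(all(abs(agg2$draws$active + agg2$draws$suspension - 1) < 1e-12))

  # linearity of expectation: aggregate mean = sum of member means
  s_el <- summarize_posterior(fit)
  s_ag <- summarize_posterior(agg2)
  susp <- c("Phytoplankton", "POM_susp", "Zooplankton")
  expect_equal(s_ag$mean[s_ag$source == "suspension"],
               sum(s_el$mean[s_el$source %in% susp]), tolerance = 1e-12)

  expect_error(combine_sources(fit, feeding_mode_aggregation()[-1]),
               "Crustaceans")
})

test_that("p_bic handles dominance, identity and the tie convention", {
  fa <- make_fit(suspension = rep(0.6, 100))
  fb <- make_fit(suspension = rep(0.4, 100))
  r1 <- compare_groups(fa, fb, "suspension")
  expect_equal(r1$p_bic, 1.0)
  expect_true(r1$significant)
  r2 <- compare_groups(fa, fa, "suspension")
  expect_equal(r2$p_bic, 0.5)
  expect_false(r2$significant)
})

test_that("p_bic is antisymmetric and permutation/monotone invariant", {
  set.seed(31)
  for (i in 1:20) {
    a <- runif(200)
    b <- runif(150) # different lengths exercise truncation
    fa <- make_fit(s = a)
    fb <- make_fit(s = b)
    pab <- compare_groups(fa, fb, "s")$p_bic
    pba <- compare_groups(fb, fa, "s")$p_bic
    expect_equal(pab + pba, 1, tolerance = 1e-15)
    # joint permutation of the paired indices
    n <- min(length(a), length(b))
    perm <- sample(n)
    expect_identical(compare_groups(make_fit(s = a[seq_len(n)][perm]),
                                    make_fit(s = b[seq_len(n)][perm]),
                                    "s")$p_bic, pab)
    # common strictly monotone relabeling
    expect_identical(compare_groups(make_fit(s = qlogis(a)),
                                    make_fit(s = qlogis(b)), "s")$p_bic, pab)
  }
})

test_that("p_bic matches the Normal-difference closed form", {
  set.seed(123)
  n <- 1e5
  a <- pmin(pmax(rnorm(n, 0.5, 0.1), 0), 1)
  b <- pmin(pmax(rnorm(n, 0.4, 0.1), 0), 1)
  p <- compare_groups(make_fit(s = a), make_fit(s = b), "s")$p_bic
  expect_lt(abs(p - pnorm(0.1 / sqrt(0.02))), 0.01)
})

test_that("missing sources and empty draws are errors", {
  fa <- make_fit(x = runif(10))
  fb <- make_fit(y = runif(10))
  expect_error(compare_groups(fa, fb, "x"), "not present")
  expect_error(compare_groups(fa, fb, "zzz"), "not present")
})

test_that("comparison batteries produce the designed counts and orders", {
  # cheap deterministic fits per design cell (draw statistics, not MCMC)
  set.seed(55)
  cells <- tidyr::expand_grid(
    sex = c("female", "male"),
    size_class = c("small", "medium", "large"),
    period = c("Spring long", "Spring short", "Summer long", "Summer short"))
  cells$fit <- lapply(seq_len(nrow(cells)), function(i) {
    make_fit(suspension = runif(50), active = runif(50))
  })
  size_res <- run_size_comparisons(cells)
  expect_equal(nrow(size_res), 24L)
  expect_equal(unique(paste(size_res$size_a, size_res$size_b)),
               c("small medium", "small large", "medium large"))
  sex_res <- run_sex_comparisons(cells)
  expect_equal(nrow(sex_res), 6L)
  expect_setequal(unique(sex_res$period), c("Spring long", "Summer long"))

  # swapped group order reflects p_bic
  i <- 1
  fa <- cells$fit[[which(cells$sex == "female" & cells$size_class == "small" &
                           cells$period == "Spring long")]]
  fb <- cells$fit[[which(cells$sex == "male" & cells$size_class == "small" &
                           cells$period == "Spring long")]]
  expect_equal(compare_groups(fa, fb, "suspension")$p_bic,
               1 - compare_groups(fb, fa, "suspension")$p_bic)

  # a missing cell is skipped with a warning
  incomplete <- cells[-1, ]
  expect_warning(res <- run_size_comparisons(incomplete), "skipped")
  expect_equal(nrow(res), 21L)
})

test_that("posterior summaries match direct order statistics", {
  set.seed(77)
  u <- runif(4000)
  fit <- make_fit(a = u, b = 1 - u)
  s <- summarize_posterior(fit)
  expect_equal(s$mean[s$source == "a"], mean(u), tolerance = 1e-12)
  expect_equal(s$q50[s$source == "a"],
               unname(quantile(u, 0.5)), tolerance = 1e-12)
  expect_equal(s$q2.5[s$source == "b"],
               unname(quantile(1 - u, 0.025)), tolerance = 1e-12)
  expect_equal(sum(s$mean), 1, tolerance = 1e-12)
  # constant draws: exact means, zero sd
  s2 <- summarize_posterior(make_fit(a = rep(0.3, 50), b = rep(0.7, 50)))
  expect_equal(s2$mean, c(0.3, 0.7))
  expect_equal(s2$sd, c(0, 0))
  # monotone quantiles
  qcols <- as.matrix(s[, c("q2.5", "q25", "q50", "q75", "q97.5")])
  expect_true(all(diff(t(qcols)) >= 0))
})
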