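test_that("prior-only posterior recovers the Dirichlet(1) mean", {
  src <- tibble::tibble(group = paste0("S", 1:4),
                        mean_d13C = c(-24, -20, -16, -18),
                        mean_d15N = c(6, 12, 9, 4),
                        sd_d13C = 1, sd_d15N = 1, n = 5L, degenerate = FALSE)
  spec <- mixing_model(src)
  fit <- suppressWarnings(sample_posterior(tibble::tibble(d13C = numeric(),
                                                          d15N = numeric()),
                                           spec, n_chains = 4, n_iter = 6000,
                                           burn_in = 1000, thin = 5,
                                           seed = 5))
  s <- summarize_posterior(fit)
  expect_true(all(abs(s$mean - 0.25) < 0.02))
})

test_that("a consumer at one source's corrected mean pins the posterior", {
  src <- tibble::tibble(group = c("A", "B"),
                        mean_d13C = c(-20, -14), mean_d15N = c(8, 8),
                        sd_d13C = 0.01, sd_d15N = 0.01,
                        n = 5L, degenerate = FALSE)
  tef <- tef_spec(3, 0.9, 0.01, 0.01)
  spec <- mixing_model(src, tef, resid_scale = 0.5)
  cons <- tibble::tibble(d13C = rep(-17, 5), d15N = rep(8.9, 5))
  fit <- suppressWarnings(sample_posterior(cons, spec, n_chains = 2,
                                           n_iter = 6000, burn_in = 2000,
                                           thin = 5, seed = 8))
  s <- summarize_posterior(fit)
  expect_gt(s$mean[s$source == "A"], 0.9)
})

test_that("identical settings and seed give bit-identical draws", {
  geo <- geometry3()
  spec <- mixing_model(geo)
  cons <- simulate_consumers(c(POM_susp = 0.4, Fish = 0.4, Polychaeta = 0.2),
                             geo, n = 6, seed = 3)
  f1 <- fast_fit(cons, spec, seed = 42)
  f2 <- fast_fit(cons, spec, seed = 42)
  expect_identical(f1$draws, f2$draws)
  f3 <- fast_fit(cons, spec, seed = 43)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("every retained draw lies on the simplex", {
  geo <- geometry3()
  spec <- mixing_model(geo)
  cons <- simulate_consumers(c(POM_susp = 0.6, Fish = 0.2, Polychaeta = 0.2),
                             geo, n = 8, seed = 4)
  fit <- fast_fit(cons, spec, seed = 9)
  pm <- as.matrix(fit$draws[, fit$source_names])
  expect_true(all(abs(rowSums(pm) - 1) < 1e-9))
  expect_true(all(pm >= 0 & pm <= 1))
  eps <- as.matrix(fit$draws[, c("resid_d13C", "resid_d15N")])
  expect_true(all(eps >= 0))
})

test_that("settings retaining too few draws are rejected", {
  spec <- mixing_model(geometry3())
  expect_error(sample_posterior(cbind(-18, 9), spec, n_iter = 120,
                                burn_in = 100, thin = 10), "fewer than 10")
  expect_error(sample_posterior(cbind(-18, 9), spec, n_iter = 100,
                                burn_in = 100), "exceed")
})

test_that("draw archives round-trip through CSV plus JSON sidecar", {
  geo <- geometry3()
  spec <- mixing_model(geo)
  cons <- simulate_consumers(c(POM_susp = 0.4, Fish = 0.3, Polychaeta = 0.3),
                             geo, n = 5, seed = 1)
  fit <- tiny_fit(cons, spec, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_draws(fit, path)
  back <- read_draws(path)
  expect_equal(back$draws, fit$draws)
  expect_equal(back$source_names, fit$source_names)
  expect_equal(back$rhat, fit$rhat, tolerance = 1e-12)
})

test_that("grid oracle recovers the prior mean and obvious symmetry", {
  src2 <- tibble::tibble(group = c("L", "R"),
                         mean_d13C = c(-20, -14), mean_d15N = c(8, 10),
                         sd_d13C = 0.8, sd_d15N = 0.8,
                         n = 5L, degenerate = FALSE)
  spec2 <- mixing_model(src2, tef_spec(0, 0, 0, 0))
  # prior only
  o0 <- grid_posterior_oracle(tibble::tibble(d13C = numeric(),
                                             d15N = numeric()), spec2)
  expect_true(all(abs(o0$mean - 0.5) < 0.01))
  # consumer exactly midway between two symmetric sources
  mid <- cbind(-17, 9)
  o1 <- grid_posterior_oracle(mid, spec2)
  expect_equal(o1$mean[1], o1$mean[2], tolerance = 1e-9)
  expect_equal(o1$mean[1], 0.5, tolerance = 1e-9)
  # K > 3 unsupported
  expect_error(grid_posterior_oracle(mid, mixing_model(
    default_source_geometry())), "at most 3")
})

test_that("MCMC posterior means agree with the grid oracle on K<=3 toys", {
  geo <- geometry3()
  spec <- mixing_model(geo)
  cons <- simulate_consumers(c(POM_susp = 0.5, Fish = 0.3, Polychaeta = 0.2),
                             geo, n = 10, seed = 7)
  fit <- suppressWarnings(sample_posterior(cons, spec, seed = 3))
  o <- grid_posterior_oracle(cons, spec)
  expect_lt(mean(abs(summarize_posterior(fit)$mean - o$mean)), 0.02)
})

test_that("tidy, glance and autoplot work on a fit", {
  geo <- geometry3()
  spec <- mixing_model(geo)
  cons <- simulate_consumers(c(POM_susp = 0.4, Fish = 0.3, Polychaeta = 0.3),
                             geo, n = 5, seed = 6)
  fit <- tiny_fit(cons, spec, seed = 6)
  td <- tidy(fit)
  expect_equal(td$source, geo$group)
  expect_equal(sum(td$mean), 1, tolerance = 1e-9)
  gl <- glance(fit)
  expect_equal(gl$n_sources, 3L)
  expect_s3_class(autoplot(fit), "ggplot")
})
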