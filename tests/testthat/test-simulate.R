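test_that("noiseless generation collapses to the corrected source mean", {
  geo <- geometry3()
  geo$sd_d13C <- 0
  geo$sd_d15N <- 0
  tef <- tef_spec(3, 0.9, 0, 0)
  cons <- simulate_consumers(c(POM_susp = 1, Fish = 0, Polychaeta = 0),
                             geo, tef, residual_sd = c(0, 0), n = 5, seed = 1)
  expect_true(all(cons$d13C == geo$mean_d13C[1] + 3))
  expect_true(all(cons$d15N == geo$mean_d15N[1] + 0.9))
})

test_that("generated signatures have the mixture mean (law of large numbers)", {
  geo <- default_source_geometry()
  p <- c(Crustaceans = 0.05, `Filter feeders` = 0.15, Fish = 0.2,
         Phytoplankton = 0.1, Polychaeta = 0.1, POM_susp = 0.25,
         Zooplankton = 0.15)
  tef <- tef_spec()
  n <- 10000
  cons <- simulate_consumers(p, geo, tef, residual_sd = c(0.5, 0.5),
                             n = n, seed = 2)
  p_ord <- p[geo$group]
  expect_mean <- c(sum(p_ord * (geo$mean_d13C + 3)),
                   sum(p_ord * (geo$mean_d15N + 0.9)))
  expect_var <- c(
    sum(p_ord^2 * (geo$sd_d13C^2 + 0.6^2)) + 0.25,
    sum(p_ord^2 * (geo$sd_d15N^2 + 0.3^2)) + 0.25)
  mc_se <- sqrt(expect_var / n)
  expect_lt(abs(mean(cons$d13C) - expect_mean[1]), 3 * mc_se[1])
  expect_lt(abs(mean(cons$d15N) - expect_mean[2]), 3 * mc_se[2])
  # and close to the model-implied variance too
  expect_lt(abs(var(cons$d13C) / expect_var[1] - 1), 0.1)
})

test_that("generation is deterministic per seed", {
  geo <- geometry3()
  p <- c(POM_susp = 0.5, Fish = 0.2, Polychaeta = 0.3)
  expect_identical(simulate_consumers(p, geo, n = 7, seed = 5),
                   simulate_consumers(p, geo, n = 7, seed = 5))
  s1 <- simulate_study(scenario(seed = 8, n_per_cell = 2))
  s2 <- simulate_study(scenario(seed = 8, n_per_cell = 2))
  expect_identical(s1$consumers, s2$consumers)
  expect_identical(s1$sources, s2$sources)
})

test_that("the default study matches the sampling design arithmetic", {
  study <- simulate_study(scenario(seed = 3))
  expect_equal(length(unique(study$consumers$id)), 120L)
  expect_equal(nrow(study$consumers), 240L)
  for (d in unique(study$consumers$sampling_date)) {
    day <- study$consumers[study$consumers$sampling_date == d, ]
    expect_equal(nrow(group_consumers(day)), 12L)
  }
  expect_equal(length(unique(study$sources$taxon)), 17L)
  expect_equal(length(unique(study$sources$group)), 7L)
})

test_that("emitted tables round-trip through the readers", {
  study <- simulate_study(scenario(seed = 4, n_per_cell = 2))
  cpath <- withr::local_tempfile(fileext = ".csv")
  spath <- withr::local_tempfile(fileext = ".csv")
  write_consumer_table(study$consumers, cpath)
  write_source_table(study$sources, spath)
  expect_equal(read_consumer_table(cpath), study$consumers)
  expect_equal(read_source_table(spath), study$sources)
})

test_that("interior true diets keep consumers inside the mixing polygon", {
  study <- simulate_study(scenario(seed = 6))
  summ <- summarize_sources(study$sources)
  d <- suppressWarnings(polygon_diagnostic(study$consumers, summ, tef_spec()))
  # residual + TEF noise can push a few points just over the hull edge
  expect_gte(d$inside_count / d$n, 0.95)
})

test_that("generator and likelihood agree: grid argmax near the true diet", {
  geo <- geometry3()
  p_true <- c(POM_susp = 0.55, Fish = 0.25, Polychaeta = 0.2)
  cons <- simulate_consumers(p_true, geo, n = 400, seed = 10)
  spec <- mixing_model(geo)
  g <- seq(0.02, 0.96, by = 0.02)
  best <- c(NA, -Inf)
  for (p1 in g) for (p2 in g) {
    if (p1 + p2 >= 0.99) next
    ll <- log_likelihood(c(p1, p2, 1 - p1 - p2), c(0.5, 0.5), cons, spec)
    if (ll > best[2]) best <- c(p1, ll, p2)
  }
  expect_lt(abs(best[1] - 0.55), 0.06)
  expect_lt(abs(best[3] - 0.25), 0.06)
})

test_that("preset scenarios encode their advertised structure", {
  pres <- preset_scenarios(seed = 1)
  expect_setequal(names(pres),
                  c("null", "size_effect", "sex_null_size_effect",
                    "pom_dominant"))
  susp_share <- function(diet) {
    agg <- feeding_mode_aggregation()[names(diet)]
    sum(diet[agg == "suspension"])
  }
  # null: identical diets everywhere
  nd <- pres$null$true_diets
  expect_true(all(vapply(nd$diet, function(d) {
    isTRUE(all.equal(d, nd$diet[[1]]))
  }, logical(1))))
  # size_effect: small suspension share 0.30 above large
  sd_ <- pres$size_effect$true_diets
  s_small <- susp_share(sd_$diet[[which(sd_$size_class == "small")[1]]])
  s_large <- susp_share(sd_$diet[[which(sd_$size_class == "large")[1]]])
  expect_equal(s_small - s_large, 0.30, tolerance = 1e-9)
  # sexes identical within the size_effect structure
  f <- sd_[sd_$sex == "female", c("size_class", "period", "diet")]
  m <- sd_[sd_$sex == "male", c("size_class", "period", "diet")]
  expect_equal(f, m)
  # pom_dominant: POM_susp is 0.45 of every diet
  pd <- pres$pom_dominant$true_diets
  expect_true(all(vapply(pd$diet, function(d) d[["POM_susp"]],
                         numeric(1)) == 0.45))
  # every diet lies on the simplex
  for (nm in names(pres)) {
    expect_true(all(vapply(pres[[nm]]$true_diets$diet,
                           function(d) abs(sum(d) - 1) < 1e-9, logical(1))))
  }
})
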