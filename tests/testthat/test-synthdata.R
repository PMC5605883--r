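test_that("flat SDI slopes give identical rates across locations and years", {
  cfg <- small_config(slopes = list(cmnn = 0, ncd = 0, inj = 0),
                      location_noise_sd = 0)
  tr <- simulate_truth(cfg)
  per_cell <- dplyr::summarise(
    dplyr::group_by(tr, age, sex, cause),
    n_rates = dplyr::n_distinct(signif(rate, 12)), .groups = "drop"
  )
  expect_true(all(per_cell$n_rates == 1))
})

test_that("a fixed seed reproduces truth and observation bit-identically", {
  cfg <- small_config(seed = 7L)
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_identical(t1$rate, t2$rate)
  h <- toy_hierarchy(cfg$n_causes)
  r1 <- observe(t1, cfg, h)
  r2 <- observe(t2, cfg, h)
  expect_identical(r1, r2)
})

test_that("the log-linear SDI form gives exp(2) rate ratio for slope -2 over the unit interval", {
  cfg <- small_config(sdi_start = c(0, 1), sdi_trend = 0,
                      slopes = list(cmnn = -2, ncd = -2, inj = -2),
                      location_noise_sd = 0)
  tr <- simulate_truth(cfg)
  lo <- tr[tr$location == "loc_01", ]
  hi <- tr[tr$location == "loc_02", ]
  ratio <- lo$rate / hi$rate[match(paste(lo$age, lo$sex, lo$cause),
                                   paste(hi$age, hi$sex, hi$cause))]
  expect_equal(ratio, rep(exp(2), length(ratio)), tolerance = 1e-9)
})

test_that("non-finite config parameters are rejected by name", {
  expect_error(small_config(sdi_trend = NaN), "sdi_trend")
  expect_error(small_config(slopes = list(cmnn = Inf, ncd = 0, inj = 0)),
               "slopes")
})

test_that("a clean observation process is unbiased for true deaths", {
  # completeness 1, garbage probability 0, identity misclassification
  cfg <- small_config(garbage_max = 0, va_concordance = 1,
                      source_probs = c(VR = 1, VA_national = 0,
                                       VA_subnational = 0, none = 0),
                      completeness_range = c(1, 1),
                      aggregate_prob = c(VR = 0, VA_national = 0,
                                         VA_subnational = 0, none = 0))
  tr <- simulate_truth(cfg)
  h <- toy_hierarchy(cfg$n_causes)
  expected_total <- sum(tr$rate * tr$population)
  n_rep <- 200
  totals <- vapply(seq_len(n_rep), function(i) {
    sum(observe(tr, cfg, h, seed = 1000L + i)$deaths)
  }, numeric(1))
  se <- sqrt(expected_total / n_rep)  # Poisson variance of the mean
  expect_lt(abs(mean(totals) - expected_total), 3 * se)
})

test_that("zero completeness yields no records and full garbage coding only garbage codes", {
  cfg0 <- small_config(completeness_range = c(0, 0),
                       source_probs = c(VR = 1, VA_national = 0,
                                        VA_subnational = 0, none = 0))
  tr0 <- simulate_truth(cfg0)
  rec0 <- observe(tr0, cfg0, toy_hierarchy(cfg0$n_causes))
  expect_equal(nrow(rec0), 0)

  cfg1 <- small_config(garbage_max = 1, garbage_midpoint = -60,
                       source_probs = c(VR = 1, VA_national = 0,
                                        VA_subnational = 0, none = 0))
  tr1 <- simulate_truth(cfg1)
  rec1 <- observe(tr1, cfg1, toy_hierarchy(cfg1$n_causes))
  expect_gt(nrow(rec1), 0)
  expect_true(all(rec1$code %in% c("gc_major", "gc_minor")))
})

test_that("expected recorded deaths scale with completeness", {
  cfg <- small_config(garbage_max = 0, completeness_range = c(0.6, 0.6),
                      source_probs = c(VR = 1, VA_national = 0,
                                       VA_subnational = 0, none = 0),
                      aggregate_prob = c(VR = 0, VA_national = 0,
                                         VA_subnational = 0, none = 0))
  tr <- simulate_truth(cfg)
  h <- toy_hierarchy(cfg$n_causes)
  expected <- 0.6 * sum(tr$rate * tr$population)
  n_rep <- 200
  totals <- vapply(seq_len(n_rep), function(i) {
    sum(observe(tr, cfg, h, seed = 2000L + i)$deaths)
  }, numeric(1))
  se <- sqrt(expected / n_rep)
  expect_lt(abs(mean(totals) - expected), 3 * se)
})

test_that("observation never invents causes or strata absent from truth", {
  cfg <- small_config()
  tr <- simulate_truth(cfg)
  h <- toy_hierarchy(cfg$n_causes)
  rec <- observe(tr, cfg, h)
  parents <- unique(h$causes$parent[h$causes$cause %in% leaf_causes(h)])
  allowed <- c(leaf_causes(h), parents, h$garbage$code)
  expect_true(all(rec$code %in% allowed))
  expect_true(all(paste(rec$location, rec$year) %in%
                    paste(tr$location, tr$year)))
})

test_that("death records round-trip through delimited text", {
  rec <- stratum_records(c("a", "b"), c(3L, 5L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_death_records(rec, path)
  back <- read_death_records(path)
  expect_equal(as.data.frame(back), as.data.frame(rec))
})

test_that("out-of-range completeness is rejected", {
  cfg <- small_config()
  tr <- simulate_truth(cfg)
  comp <- attr(tr, "completeness")
  comp$completeness[1] <- 1.4
  expect_error(observe(tr, cfg, toy_hierarchy(cfg$n_causes),
                       completeness = comp),
               "completeness")
})

test_that("simulation configurations round-trip through YAML", {
  skip_if_not_installed("yaml")
  cfg <- small_config(seed = 9L, garbage_max = 0.2)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back[names(back) != "sdi_start"], cfg[names(cfg) != "sdi_start"],
               ignore_attr = TRUE, tolerance = 1e-6)
  # YAML stores decimals, not bit patterns, so equality is at text precision
  expect_equal(simulate_truth(back)$rate, simulate_truth(cfg)$rate,
               tolerance = 1e-6)
})
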