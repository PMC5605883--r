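test_that("source exclusion applies the completeness and garbage rules", {
  rec <- dplyr::bind_rows(
    stratum_records("cmnn_a_1", 10L, location = "A", year = 2000L),
    stratum_records("cmnn_a_1", 10L, location = "B", year = 2000L),
    stratum_records("cmnn_a_1", 10L, location = "C", year = 2000L),
    stratum_records(c("cmnn_a_1", "gc_major"), c(4L, 6L),
                    location = "D", year = 2000L),
    stratum_records("cmnn_a_1", 10L, location = "E", year = 2000L,
                    source_type = "VA_national")
  )
  comp <- tibble::tibble(location = c("A", "B", "C", "D"), year = 2000L,
                         completeness = c(0.4, 0.6, 0.9, 0.9))
  out <- exclude_low_quality(rec, comp, hierarchy = toy_hierarchy(6))
  log <- out$log
  expect_true(any(log$location == "A" & log$action == "excluded" &
                    log$reason == "completeness"))
  expect_true(any(log$location == "D" & log$action == "excluded" &
                    log$reason == "garbage"))
  expect_true(any(log$location == "B" & log$action == "flagged"))
  kept <- unique(out$records$location)
  expect_setequal(kept, c("B", "C", "E"))
  expect_true(all(out$records$non_representative[out$records$location == "B"]))
  expect_false(any(out$records$non_representative[out$records$location == "C"]))
  # location E has no completeness estimate: VA rules, logged, retained
  expect_true(any(log$location == "E" & log$action == "kept"))
})

test_that("proportional redistribution splits by observed target deaths", {
  h <- toy_hierarchy(6)
  map <- garbage_map(data.frame(code = "gc_major", level = 1L,
                                method = "proportional",
                                targets = "cmnn_a_1;ncd_a_1", props = ""), h)
  rec <- stratum_records(c("cmnn_a_1", "ncd_a_1", "gc_major"),
                         c(30L, 70L, 10L))
  out <- redistribute(rec, map, h)
  expect_equal(out$deaths[out$code == "cmnn_a_1"], 33)
  expect_equal(out$deaths[out$code == "ncd_a_1"], 77)
  expect_false("gc_major" %in% out$code)
})

test_that("records without garbage pass through unchanged", {
  h <- toy_hierarchy(6)
  map <- proportional_map(h)
  rec <- stratum_records(c("cmnn_a_1", "ncd_a_1"), c(30L, 70L))
  expect_equal(as.data.frame(redistribute(rec, map, h)[, names(rec)]),
               as.data.frame(rec))
})

test_that("all-zero proportional targets fall back to a uniform split", {
  h <- toy_hierarchy(6)
  map <- garbage_map(data.frame(code = "gc_major", level = 1L,
                                method = "proportional",
                                targets = "cmnn_a_1;ncd_a_1", props = ""), h)
  rec <- stratum_records(c("inj_a_1", "gc_major"), c(5L, 10L))
  out <- redistribute(rec, map, h)
  expect_equal(out$deaths[out$code == "cmnn_a_1"], 5)
  expect_equal(out$deaths[out$code == "ncd_a_1"], 5)
  expect_equal(sum(out$deaths), sum(rec$deaths))
})

test_that("fixed proportions are applied and validated", {
  h <- toy_hierarchy(6)
  map <- garbage_map(data.frame(code = "gc_major", level = 1L,
                                method = "fixed",
                                targets = "cmnn_a_1;ncd_a_1",
                                props = "0.25;0.75"), h)
  rec <- stratum_records(c("cmnn_a_1", "gc_major"), c(10L, 40L))
  out <- redistribute(rec, map, h)
  expect_equal(out$deaths[out$code == "cmnn_a_1"], 20)
  expect_equal(out$deaths[out$code == "ncd_a_1"], 30)
  expect_error(
    garbage_map(data.frame(code = "gc_major", level = 1L, method = "fixed",
                           targets = "cmnn_a_1;ncd_a_1", props = "0.5;0.4"),
                h),
    "sum to 1")
  expect_error(
    garbage_map(data.frame(code = "gc_major", level = 1L, method = "fixed",
                           targets = "cmnn_a_1;ncd_a_1", props = "1.5;-0.5"),
                h),
    "negative")
  expect_error(
    garbage_map(data.frame(code = "gc_major", level = 1L,
                           method = "proportional", targets = "nope",
                           props = ""), h),
    "valid causes")
})

test_that("a garbage code missing from the map is an error", {
  h <- toy_hierarchy(6)
  map <- garbage_map(data.frame(code = "gc_major", level = 1L,
                                method = "proportional",
                                targets = "cmnn_a_1", props = ""), h)
  rec <- stratum_records(c("cmnn_a_1", "gc_minor"), c(10L, 5L))
  expect_error(redistribute(rec, map, h), "gc_minor")
})

test_that("every method conserves stratum totals on generated records", {
  cfg <- small_config(garbage_max = 0.3, garbage_midpoint = -60)
  tr <- simulate_truth(cfg)
  h <- toy_hierarchy(cfg$n_causes)
  rec <- observe(tr, cfg, h)
  targets <- paste(leaf_causes(h), collapse = ";")
  k <- length(leaf_causes(h))
  props <- paste(rep(1 / k, k), collapse = ";")
  maps <- list(
    proportional = proportional_map(h),
    fixed = garbage_map(data.frame(code = c("gc_major", "gc_minor"),
                                   level = c(1L, 3L), method = "fixed",
                                   targets = targets, props = props), h),
    regression = garbage_map(data.frame(code = c("gc_major", "gc_minor"),
                                        level = c(1L, 3L),
                                        method = "regression",
                                        targets = targets, props = ""), h)
  )
  before <- stratum_totals(rec)
  for (nm in names(maps)) {
    out <- redistribute(rec, maps[[nm]], h)
    expect_false(any(out$code %in% h$garbage$code), info = nm)
    after <- stratum_totals(out)
    m <- dplyr::left_join(before, after,
                          by = c("location", "year", "age", "sex"))
    expect_lt(max(abs(m$deaths.x - m$deaths.y)), 1e-9)
  }
})

test_that("completeness correction rescales cause fractions to the envelope", {
  rec <- stratum_records(c("a", "b"), c(25, 75))
  env <- tibble::tibble(location = "loc_01", year = 2010L, age = 10L,
                        sex = "male", deaths = 200)
  out <- completeness_correct(rec, env)
  expect_equal(sort(out$deaths), c(50, 150))

  # already-consistent records are unchanged
  env2 <- env
  env2$deaths <- 100
  expect_equal(completeness_correct(rec, env2)$deaths, rec$deaths)

  # random cell sums to the envelope exactly
  set.seed(42)
  rec5 <- stratum_records(paste0("c", 1:5), runif(5, 1, 50))
  out5 <- completeness_correct(rec5, env)
  expect_lt(abs(sum(out5$deaths) - 200), 1e-9)

  # invariant to rescaling all counts in the cell
  rec5b <- rec5
  rec5b$deaths <- rec5$deaths * 7.3
  expect_equal(completeness_correct(rec5b, env)$deaths, out5$deaths)

  env0 <- env
  env0$deaths <- 0
  expect_error(completeness_correct(rec, env0), "envelope is zero")
})

test_that("redistribution bias in cause fractions vanishes as garbage coding does", {
  h <- toy_hierarchy(6)
  bias <- vapply(c(0.4, 0.15, 0), function(gmax) {
    cfg <- small_config(garbage_max = gmax, garbage_midpoint = -60,
                        pop_scale = 1e5,
                        source_probs = c(VR = 1, VA_national = 0,
                                         VA_subnational = 0, none = 0),
                        completeness_range = c(1, 1),
                        aggregate_prob = c(VR = 0, VA_national = 0,
                                           VA_subnational = 0, none = 0))
    tr <- simulate_truth(cfg)
    rec <- observe(tr, cfg, h)
    out <- redistribute(rec, proportional_map(h), h)
    truth_frac <- tapply(tr$rate * tr$population, tr$cause, sum) /
      sum(tr$rate * tr$population)
    est_frac <- tapply(out$deaths, out$code, sum)[names(truth_frac)]
    est_frac <- est_frac / sum(est_frac)
    mean(abs(est_frac - truth_frac))
  }, numeric(1))
  # redistribution mixes strata, so bias shrinks as garbage coding shrinks
  expect_true(bias[3] <= bias[1])
  expect_lt(bias[3], 0.01)
})

test_that("garbage maps round-trip through delimited text", {
  h <- toy_hierarchy(6)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("code\tlevel\tmethod\ttargets\tprops",
               "gc_major\t1\tfixed\tcmnn_a_1;ncd_a_1\t0.3;0.7",
               "gc_minor\t3\tproportional\tcmnn_a_1;ncd_a_1\t"), path)
  map <- read_garbage_map(path, h)
  expect_equal(map$props[[1]], c(0.3, 0.7))
  expect_equal(map$targets[[2]], c("cmnn_a_1", "ncd_a_1"))
})
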