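#' Simulation configuration
#'
#' Assembles and validates the configuration for the synthetic truth and its
#' distorted observation. Defaults describe a desk-scale world of 20
#' locations followed for 10 years with 12 most-detailed causes in three
#' Level 1 groups. The epidemiological transition is log-linear in SDI:
#' communicable/maternal/neonatal/nutritional (CMNN) causes decline steeply
#' with development, non-communicable diseases (NCDs) decline only shallowly,
#' injuries sit in between.
#'
#' @param n_locations,n_years,first_year World dimensions.
#' @param n_causes Number of most-detailed causes (>= 6), spread over the
#'   three Level 1 groups by [toy_hierarchy()].
#' @param seed Integer seed; a fixed seed yields bit-identical output.
#' @param sdi_start Numeric vector of length `n_locations` with SDI in the
#'   first year, or NULL to draw uniformly on (0.15, 0.85).
#' @param sdi_trend Annual SDI increment (development rises slowly).
#' @param slopes Named list of log-linear SDI slopes per Level 1 group
#'   (log rate units per unit SDI).
#' @param intercepts Named list of log death rates (per person-year) at
#'   SDI = 0 for each Level 1 group.
#' @param sex_offset Additive male log-rate offset.
#' @param location_noise_sd SD of the location-by-cause log-rate intercept
#'   noise (real between-location heterogeneity, not measurement error).
#' @param pop_scale Persons per location-age-sex cell before the age
#'   distribution is applied.
#' @param source_probs Named probabilities for assigning each location a
#'   source type among `VR`, `VA_national`, `VA_subnational`, `none`.
#' @param completeness_range Range of registration completeness for VR
#'   locations (VA locations use `va_completeness_range`).
#' @param va_completeness_range Completeness range for VA locations.
#' @param garbage_max Maximum garbage-coding probability (reached at the
#'   oldest ages); garbage probability is logistic in the age-group index.
#' @param garbage_midpoint,garbage_steepness Midpoint (age-group index) and
#'   steepness of the logistic garbage-probability curve.
#' @param major_garbage_share Fraction of garbage-coded deaths that land on
#'   the major (Level 1-2 span) garbage code rather than the minor one.
#' @param va_concordance Diagonal mass of the VA misclassification matrix;
#'   off-diagonal mass is spread uniformly over the other causes. Pass a
#'   full matrix via `va_misclassification` to override.
#' @param va_misclassification Optional K x K row-stochastic matrix (rows =
#'   true causes, columns = recorded causes) for VA strata.
#' @param aggregate_prob Named probabilities (per source type) that a death
#'   is recorded at its Level 2 parent rather than the most-detailed cause,
#'   emulating limited cause-list detail.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(n_locations = 20,
                       n_years = 10,
                       first_year = 2007,
                       n_causes = 12,
                       seed = 1L,
                       sdi_start = NULL,
                       sdi_trend = 0.007,
                       slopes = list(cmnn = -3, ncd = -0.7, inj = -1.5),
                       intercepts = list(cmnn = log(1.2e-3), ncd = log(5e-4), inj = log(2.5e-4)),
                       sex_offset = 0.15,
                       location_noise_sd = 0.3,
                       pop_scale = 6e4,
                       source_probs = c(VR = 0.6, VA_national = 0.2, VA_subnational = 0.1, none = 0.1),
                       completeness_range = c(0.7, 1),
                       va_completeness_range = c(0.4, 0.8),
                       garbage_max = 0.35,
                       garbage_midpoint = 14,
                       garbage_steepness = 3,
                       major_garbage_share = 0.7,
                       va_concordance = 0.64,
                       va_misclassification = NULL,
                       aggregate_prob = c(VR = 0.05, VA_national = 0.3, VA_subnational = 0.3, none = 0)) {
  num_ok <- function(x) is.numeric(x) && all(is.finite(x))
  for (nm in c("sdi_trend", "sex_offset", "location_noise_sd", "pop_scale",
               "garbage_max", "garbage_midpoint", "garbage_steepness",
               "major_garbage_share", "va_concordance")) {
    if (!num_ok(get(nm))) stop("non-finite parameter: ", nm)
  }
  if (!all(vapply(slopes, num_ok, logical(1)))) stop("non-finite parameter: slopes")
  if (!all(vapply(intercepts, num_ok, logical(1)))) stop("non-finite parameter: intercepts")
  stopifnot(n_locations >= 1, n_years >= 1, n_causes >= 6)
  if (garbage_max < 0 || garbage_max > 1) stop("garbage_max must be in [0, 1]")
  if (major_garbage_share < 0 || major_garbage_share > 1) {
    stop("major_garbage_share must be in [0, 1]")
  }
  if (abs(sum(source_probs) - 1) > 1e-9 || any(source_probs < 0)) {
    stop("source_probs must be non-negative and sum to 1")
  }
  if (any(aggregate_prob < 0 | aggregate_prob > 1)) {
    stop("aggregate_prob must be in [0, 1]")
  }
  if (!is.null(sdi_start)) {
    stopifnot(length(sdi_start) == n_locations, all(sdi_start >= 0 & sdi_start <= 1))
  }
  if (!is.null(va_misclassification)) {
    stopifnot(is.matrix(va_misclassification),
              nrow(va_misclassification) == n_causes,
              ncol(va_misclassification) == n_causes)
    if (any(va_misclassification < 0) ||
        any(abs(rowSums(va_misclassification) - 1) > 1e-9)) {
      stop("va_misclassification rows must be probabilities summing to 1")
    }
  }
  structure(
    list(
      n_locations = as.integer(n_locations), n_years = as.integer(n_years),
      first_year = as.integer(first_year), n_causes = as.integer(n_causes),
      seed = as.integer(seed), sdi_start = sdi_start, sdi_trend = sdi_trend,
      slopes = slopes, intercepts = intercepts, sex_offset = sex_offset,
      location_noise_sd = location_noise_sd, pop_scale = pop_scale,
      source_probs = source_probs, completeness_range = completeness_range,
      va_completeness_range = va_completeness_range, garbage_max = garbage_max,
      garbage_midpoint = garbage_midpoint, garbage_steepness = garbage_steepness,
      major_garbage_share = major_garbage_share, va_concordance = va_concordance,
      va_misclassification = va_misclassification, aggregate_prob = aggregate_prob
    ),
    class = "sim_config"
  )
}

# age-specific log-rate offsets per Level 1 group: CMNN loads on infancy,
# NCDs rise steeply with age, injuries peak in young adults
age_offset <- function(group, midpoint) {
  switch(group,
    cmnn = 2.2 * exp(-midpoint / 4) + 0.015 * midpoint,
    ncd = 0.055 * (midpoint - 50),
    inj = 0.8 * exp(-((midpoint - 22)^2) / 450) - 0.004 * midpoint,
    stop("unknown cause group: ", group)
  )
}

garbage_probability <- function(config, age_index) {
  config$garbage_max *
    stats::plogis((age_index - config$garbage_midpoint) / config$garbage_steepness)
}

#' Simulate the latent truth
#'
#' Generates true cause-specific death rates for every
#' location-year-age-sex-cause cell. On the log scale the rate is a group
#' intercept plus a group SDI slope times the location-year SDI, plus
#' age/sex offsets, plus a location-by-cause noise term drawn once per
#' location-cause pair. Populations are time-invariant.
#'
#' @param config A [sim_config()].
#' @param hierarchy A `cause_hierarchy`; defaults to
#'   `toy_hierarchy(config$n_causes)`.
#' @return A `truth_cube`: tibble with columns `location`, `year`, `age`,
#'   `sex`, `cause`, `rate` (deaths per person-year), `population`, plus
#'   attributes `sdi` (location-year SDI tibble), `sources` (location source
#'   types), and `completeness` (location-year completeness tibble).
#' @export
simulate_truth <- function(config, hierarchy = toy_hierarchy(config$n_causes)) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    locs <- sprintf("loc_%02d", seq_len(config$n_locations))
    years <- config$first_year + seq_len(config$n_years) - 1L
    ages <- age_groups()
    leaves <- leaf_causes(hierarchy)
    stopifnot(length(leaves) == config$n_causes)
    groups <- cause_group(leaves, hierarchy)

    sdi0 <- config$sdi_start %||% stats::runif(config$n_locations, 0.15, 0.85)
    sdi <- tidyr::expand_grid(location = locs, year = years)
    sdi$sdi <- pmin(1, pmax(0, sdi0[match(sdi$location, locs)] +
                              config$sdi_trend * (sdi$year - config$first_year)))

    src <- sample(names(config$source_probs), config$n_locations,
                  replace = TRUE, prob = config$source_probs)
    names(src) <- locs
    comp <- sdi[, c("location", "year")]
    is_vr <- src[comp$location] == "VR"
    rng <- function(n, r) stats::runif(n, r[1], r[2])
    comp$completeness <- unname(ifelse(
      src[comp$location] == "none", 0,
      ifelse(is_vr, rng(nrow(comp), config$completeness_range),
             rng(nrow(comp), config$va_completeness_range))
    ))

    u <- matrix(stats::rnorm(config$n_locations * length(leaves),
                             sd = config$location_noise_sd),
                nrow = config$n_locations,
                dimnames = list(locs, leaves))

    cube <- tidyr::expand_grid(location = locs, year = years,
                               age = ages$age, sex = c("female", "male"),
                               cause = leaves)
    cube$sdi_val <- sdi$sdi[match(paste(cube$location, cube$year),
                                  paste(sdi$location, sdi$year))]
    grp <- groups[match(cube$cause, leaves)]
    mid <- ages$midpoint[match(cube$age, ages$age)]
    off <- numeric(nrow(cube))
    for (g in unique(grp)) {
      sel <- grp == g
      off[sel] <- age_offset(g, mid[sel])
    }
    lograte <- unlist(config$intercepts[grp], use.names = FALSE) +
      unlist(config$slopes[grp], use.names = FALSE) * cube$sdi_val +
      off + config$sex_offset * (cube$sex == "male") +
      u[cbind(match(cube$location, locs), match(cube$cause, leaves))]
    cube$rate <- exp(lograte)
    age_w <- exp(-ages$midpoint / 45)
    age_w <- age_w / max(age_w)
    cube$population <- config$pop_scale * age_w[match(cube$age, ages$age)]
    cube$sdi_val <- NULL
    out <- tibble::as_tibble(cube)
    attr(out, "sdi") <- tibble::as_tibble(sdi)
    attr(out, "sources") <- src
    attr(out, "completeness") <- tibble::as_tibble(comp)
    class(out) <- c("truth_cube", class(out))
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Observe the truth through a defective registration system
#'
#' Applies the observation model: Poisson counts at the true rates, binomial
#' thinning by registration completeness, multinomial VA misclassification in
#' verbal-autopsy strata, movement of a logistic-in-age fraction of deaths
#' onto garbage codes, and recording of some deaths at the Level 2 parent to
#' emulate limited cause-list detail. Locations with source type `none`
#' produce no records.
#'
#' @param truth A `truth_cube` from [simulate_truth()].
#' @param config The same [sim_config()] used to generate the truth.
#' @param hierarchy The `cause_hierarchy` covering all truth causes.
#' @param completeness Optional location-year completeness tibble overriding
#'   the one attached to `truth`.
#' @param seed Observation seed; defaults to `config$seed + 1` so truth and
#'   observation noise are independent streams. Vary it to replicate the
#'   observation process over a fixed truth.
#' @return A `death_records` tibble: `location`, `year`, `age`, `sex`,
#'   `source_type`, `code`, `deaths` (integer counts; zero rows dropped).
#' @export
observe <- function(truth, config, hierarchy = toy_hierarchy(config$n_causes),
                    completeness = NULL, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  comp <- completeness %||% attr(truth, "completeness")
  if (any(comp$completeness < 0 | comp$completeness > 1)) {
    stop("completeness must be in [0, 1]")
  }
  src <- attr(truth, "sources")
  leaves <- leaf_causes(hierarchy)
  if (!all(unique(truth$cause) %in% leaves)) {
    stop("hierarchy does not cover all truth causes")
  }
  if (any(c("gc_major", "gc_minor") %in% leaves)) {
    stop("garbage codes must be disjoint from true causes")
  }
  parent_of <- stats::setNames(hierarchy$causes$parent, hierarchy$causes$cause)

  withr::with_seed(seed, {
    tr <- truth
    tr$source_type <- unname(src[tr$location])
    tr$completeness <- comp$completeness[match(paste(tr$location, tr$year),
                                               paste(comp$location, comp$year))]
    lambda <- tr$rate * tr$population
    n_true <- stats::rpois(nrow(tr), lambda)
    registered <- stats::rbinom(nrow(tr), n_true, tr$completeness)
    tr$deaths <- registered
    tr <- tr[tr$source_type != "none", ]

    # VA misclassification: reshuffle counts across causes within each cell
    is_va <- tr$source_type %in% c("VA_national", "VA_subnational")
    if (any(is_va) && any(tr$deaths[is_va] > 0)) {
      M <- config$va_misclassification %||% {
        K <- length(leaves)
        m <- matrix((1 - config$va_concordance) / (K - 1), K, K)
        diag(m) <- config$va_concordance
        m
      }
      va <- tr[is_va, ]
      cell <- interaction(va$location, va$year, va$age, va$sex, drop = TRUE)
      counts <- matrix(0L, nlevels(cell), length(leaves),
                       dimnames = list(levels(cell), leaves))
      counts[cbind(as.integer(cell), match(va$cause, leaves))] <- va$deaths
      out <- matrix(0L, nrow(counts), ncol(counts), dimnames = dimnames(counts))
      for (j in seq_along(leaves)) {
        pos <- which(counts[, j] > 0)
        for (i in pos) {
          out[i, ] <- out[i, ] + as.integer(stats::rmultinom(1, counts[i, j], M[j, ]))
        }
      }
      tr$deaths[is_va] <- out[cbind(as.integer(cell), match(va$cause, leaves))]
    }

    # garbage coding, rising with age
    p_g <- garbage_probability(config, tr$age)
    g <- stats::rbinom(nrow(tr), tr$deaths, p_g)
    kept <- tr$deaths - g
    g_major <- stats::rbinom(nrow(tr), g, config$major_garbage_share)
    g_minor <- g - g_major

    # cause-list aggregation: some kept deaths recorded at the Level 2 parent
    p_agg <- unname(config$aggregate_prob[tr$source_type])
    agg <- stats::rbinom(nrow(tr), kept, p_agg)
    kept <- kept - agg

    base <- tr[, c("location", "year", "age", "sex", "source_type")]
    piece <- function(code, deaths) {
      out <- base
      out$code <- code
      out$deaths <- deaths
      out[deaths > 0, ]
    }
    rec <- dplyr::bind_rows(
      piece(tr$cause, kept),
      piece(unname(parent_of[tr$cause]), agg),
      piece("gc_major", g_major),
      piece("gc_minor", g_minor)
    )
    rec <- dplyr::summarise(
      dplyr::group_by(rec, location, year, age, sex, source_type, code),
      deaths = sum(deaths), .groups = "drop"
    )
    class(rec) <- c("death_records", class(rec))
    rec
  })
}

#' Write / read death records as tab-delimited text
#'
#' Column order: location, year, age, sex, source_type, code, deaths.
#' @param x A `death_records` tibble.
#' @param path File path.
#' @export
write_death_records <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_death_records
#' @export
read_death_records <- function(path) {
  out <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  class(out) <- c("death_records", class(out))
  out
}

#' Serialise / restore a simulation configuration
#'
#' Writes the configuration as a YAML document (requires the yaml package)
#' and restores it through [sim_config()], so the restored object is
#' re-validated.
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to serialise configurations")
  }
  x <- unclass(config)
  if (!is.null(x$va_misclassification)) {
    x$va_misclassification <- as.vector(x$va_misclassification)
  }
  # named atomic vectors must become maps, or YAML drops the names
  x$source_probs <- as.list(x$source_probs)
  x$aggregate_prob <- as.list(x$aggregate_prob)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read configurations")
  }
  x <- yaml::read_yaml(path)
  if (!is.null(x$va_misclassification)) {
    x$va_misclassification <- matrix(unlist(x$va_misclassification),
                                     x$n_causes, x$n_causes)
  }
  x$source_probs <- unlist(x$source_probs)
  x$aggregate_prob <- unlist(x$aggregate_prob)
  x$completeness_range <- unlist(x$completeness_range)
  x$va_completeness_range <- unlist(x$va_completeness_range)
  do.call(sim_config, x)
}
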