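#' A single covariate model specification
#'
#' Each candidate model regresses either the log death rate or the logit
#' cause fraction on a covariate subset, with an optional location random
#' intercept. A fitted specification is retained only when every covariate
#' coefficient matches its expected sign (when one is declared) and is
#' significant at the configured level.
#'
#' @param response `"log_rate"` or `"logit_fraction"`.
#' @param covariates Non-empty character vector of covariate column names.
#' @param random_intercept Include a location random intercept.
#' @param expected_signs Named vector with values -1/+1 for covariates whose
#'   coefficient direction is constrained (others unconstrained).
#' @param id Model identifier.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(response = c("log_rate", "logit_fraction"),
                       covariates, random_intercept = TRUE,
                       expected_signs = NULL, id = NULL) {
  response <- match.arg(response)
  if (length(covariates) == 0) stop("covariate subset must be non-empty")
  structure(
    list(response = response, covariates = covariates,
         random_intercept = random_intercept,
         expected_signs = expected_signs,
         id = id %||% paste0(response, ":", paste(covariates, collapse = "+"))),
    class = "model_spec"
  )
}

#' Enumerate the candidate model pool
#'
#' All non-empty covariate subsets crossed with both response spaces, in a
#' deterministic order (subset size, then lexicographic, log-rate before
#' logit-fraction), optionally capped.
#'
#' @param covariates Character vector of available covariates (>= 1).
#' @param response_spaces Response spaces to include.
#' @param max_models Cap on pool size (deterministic truncation).
#' @param random_intercept Passed to every [model_spec()].
#' @param expected_signs Passed to every [model_spec()].
#' @return List of `model_spec` objects.
#' @export
enumerate_models <- function(covariates,
                             response_spaces = c("log_rate", "logit_fraction"),
                             max_models = Inf, random_intercept = TRUE,
                             expected_signs = NULL) {
  if (length(covariates) == 0) stop("at least one covariate is required")
  subsets <- unlist(lapply(seq_along(covariates), function(k) {
    m <- utils::combn(sort(covariates), k, simplify = FALSE)
    m[order(vapply(m, paste, "", collapse = "+"))]
  }), recursive = FALSE)
  pool <- list()
  for (s in subsets) {
    for (r in response_spaces) {
      pool[[length(pool) + 1]] <- model_spec(r, s, random_intercept,
                                             expected_signs)
    }
  }
  if (length(pool) > max_models) pool <- pool[seq_len(max_models)]
  pool
}

logit <- function(p) log(p / (1 - p))

model_response <- function(spec, data, eps = 1e-6, rate_floor = 1e-12) {
  if (spec$response == "log_rate") {
    log(pmax(data$deaths / data$population, rate_floor))
  } else {
    logit(pmin(pmax(data$deaths / data$envelope, eps), 1 - eps))
  }
}

# back-transform a linear predictor to a death rate
response_to_rate <- function(spec, eta, data) {
  if (spec$response == "log_rate") exp(eta)
  else stats::plogis(eta) * data$envelope / data$population
}

#' Fit one model specification
#'
#' Fits by least squares (or REML with a location random intercept) in the
#' spec's response space, applying the sign/significance screen. Rows
#' flagged `non_representative` are downweighted by `var_inflation`
#' (observation variance multiplied by that factor).
#'
#' @param spec A [model_spec()].
#' @param data Modelling tibble with `location`, `year`, `deaths`,
#'   `population`, `envelope`, the covariate columns, and optionally
#'   `non_representative`.
#' @param alpha Two-sided significance level of the coefficient screen.
#' @param var_inflation Variance multiplier for non-representative rows.
#' @return List with the spec, fitted object, `ok` (passed the screen),
#'   coefficient estimates and covariance, and residual/random-effect
#'   variances.
#' @export
fit_model_spec <- function(spec, data, alpha = 0.05, var_inflation = 2) {
  y <- model_response(spec, data)
  dat <- data.frame(data[, spec$covariates, drop = FALSE])
  dat$.y <- y
  dat$location <- data$location
  w <- rep(1, nrow(dat))
  if ("non_representative" %in% names(data)) {
    w[data$non_representative] <- 1 / var_inflation
  }
  dat$.w <- w
  rhs <- paste(spec$covariates, collapse = " + ")
  if (spec$random_intercept && length(unique(dat$location)) > 1) {
    fit <- lme4::lmer(stats::as.formula(paste(".y ~", rhs, "+ (1 | location)")),
                      data = dat, weights = .w, REML = TRUE)
    beta <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    sigma <- stats::sigma(fit)
    vc <- as.data.frame(lme4::VarCorr(fit))
    sigma_u <- sqrt(vc$vcov[vc$grp == "location"][1])
    se <- sqrt(diag(V))
    z <- beta / se
    p <- 2 * stats::pnorm(-abs(z))
    re <- lme4::ranef(fit, condVar = TRUE)$location
    u_hat <- stats::setNames(re[["(Intercept)"]], rownames(re))
    u_var <- stats::setNames(as.vector(attr(re, "postVar")), rownames(re))
  } else {
    fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = dat,
                     weights = .w)
    beta <- stats::coef(fit)
    V <- stats::vcov(fit)
    sigma <- stats::sigma(fit)
    sigma_u <- 0
    p <- summary(fit)$coefficients[, 4]
    u_hat <- NULL
    u_var <- NULL
  }
  ok <- TRUE
  for (cv in spec$covariates) {
    want <- spec$expected_signs[[cv]] %||% 0
    if (want != 0 && sign(beta[[cv]]) != sign(want)) ok <- FALSE
    if (is.na(p[[cv]]) || p[[cv]] > alpha) ok <- FALSE
  }
  list(spec = spec, fit = fit, ok = ok, beta = beta, vcov = V, sigma = sigma,
       sigma_u = sigma_u, u_hat = u_hat, u_var = u_var)
}

predict_eta <- function(fitted, newdata, use_ranef = TRUE) {
  X <- stats::model.matrix(
    stats::as.formula(paste("~", paste(fitted$spec$covariates, collapse = " + "))),
    data = newdata
  )
  eta <- as.vector(X %*% fitted$beta)
  if (use_ranef && !is.null(fitted$u_hat)) {
    u <- fitted$u_hat[newdata$location]
    u[is.na(u)] <- 0
    eta <- eta + unname(u)
  }
  eta
}

#' Out-of-sample predictive validity of a model pool
#'
#' Location-years are partitioned into folds at random under the given
#' seed. Each model is fit on each training set; models failing the
#' sign/significance screen on any training fold are dropped (and logged in
#' the `dropped` attribute). Retained models are scored on the root mean
#' square error of held-out log rates (levels) and of held-out year-on-year
#' first differences of log rates within location (trends; a year pair
#' counts when at least one of its years is held out).
#'
#' @param pool List of [model_spec()]s.
#' @param data Modelling tibble (see [fit_model_spec()]).
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed for fold assignment.
#' @param alpha,var_inflation Passed to [fit_model_spec()].
#' @return Tibble with `id`, `rmse_level`, `rmse_trend`, one row per
#'   retained model; attribute `dropped` lists screened-out model ids.
#' @export
holdout_pv <- function(pool, data, folds = 5, seed = 1, alpha = 0.05,
                       var_inflation = 2) {
  stopifnot(folds >= 2)
  ly <- unique(data[, c("location", "year")])
  fold_of <- withr::with_seed(seed, {
    sample(rep_len(seq_len(folds), nrow(ly)))
  })
  data$.fold <- fold_of[match(paste(data$location, data$year),
                              paste(ly$location, ly$year))]
  obs_lograte <- log(pmax(data$deaths / data$population, 1e-12))
  ord <- order(data$location, data$year)
  loc_o <- data$location[ord]
  yr_o <- data$year[ord]
  consecutive <- loc_o[-1] == loc_o[-length(loc_o)] &
    yr_o[-1] == yr_o[-length(yr_o)] + 1

  ids <- vapply(pool, function(s) s$id, "")
  err_lv <- matrix(NA_real_, length(pool), folds)
  err_tr <- matrix(NA_real_, length(pool), folds)
  screened <- rep(FALSE, length(pool))
  for (f in seq_len(folds)) {
    train <- data[data$.fold != f, , drop = FALSE]
    hold <- data$.fold == f
    for (m in seq_along(pool)) {
      if (screened[m]) next
      fitted <- fit_model_spec(pool[[m]], train, alpha, var_inflation)
      if (!fitted$ok) { screened[m] <- TRUE; next }
      eta <- predict_eta(fitted, data)
      pred_lograte <- log(pmax(response_to_rate(fitted$spec, eta, data), 1e-300))
      err_lv[m, f] <- sqrt(mean((pred_lograte[hold] - obs_lograte[hold])^2))
      # trends: first differences within location
      in_pair <- hold[ord][-1] | hold[ord][-length(ord)]
      dd_obs <- diff(obs_lograte[ord])[consecutive & in_pair]
      dd_pred <- diff(pred_lograte[ord])[consecutive & in_pair]
      err_tr[m, f] <- if (length(dd_obs)) sqrt(mean((dd_pred - dd_obs)^2)) else NA
    }
  }
  if (all(screened)) {
    stop("all models failed the sign/significance screen; relax the constraints")
  }
  keep <- !screened
  out <- tibble::tibble(
    id = ids[keep],
    rmse_level = rowMeans(err_lv[keep, , drop = FALSE], na.rm = TRUE),
    rmse_trend = rowMeans(err_tr[keep, , drop = FALSE], na.rm = TRUE)
  )
  attr(out, "dropped") <- ids[screened]
  out
}

#' Ensemble weights from predictive-validity ranks
#'
#' Models are ranked on level error and on trend error; the combined rank is
#' the mean of the two. Weights are proportional to `exp(-rank /
#' temperature)` and sum to 1.
#'
#' @param scores Output of [holdout_pv()].
#' @param temperature Positive spread parameter; small values concentrate
#'   weight on the best-ranked model. The default 0.5 (weight ratio
#'   `exp(-2)` between adjacent ranks) keeps the ensemble's 95% draw
#'   interval calibrated in parameter-recovery experiments
#'   ([codem_recovery_experiment()]); larger values let poorly ranked
#'   models widen the intervals.
#' @return Tibble `id`, `combined_rank`, `weight`.
#' @export
ensemble_weights <- function(scores, temperature = 0.5) {
  if (temperature <= 0) stop("temperature must be positive")
  if (nrow(scores) == 0) stop("no scored models")
  r_lv <- rank(scores$rmse_level, ties.method = "average")
  r_tr <- rank(scores$rmse_trend, ties.method = "average")
  combined <- (r_lv + r_tr) / 2
  w <- exp(-combined / temperature)
  tibble::tibble(id = scores$id, combined_rank = combined, weight = w / sum(w))
}

#' Fit every pool member on the full data
#'
#' @inheritParams holdout_pv
#' @param ids Restrict to these model ids (e.g. the retained set from
#'   [holdout_pv()]).
#' @return Named list of fitted models (see [fit_model_spec()]).
#' @export
fit_pool <- function(pool, data, ids = NULL, alpha = 0.05, var_inflation = 2) {
  fits <- lapply(pool, fit_model_spec, data = data, alpha = alpha,
                 var_inflation = var_inflation)
  names(fits) <- vapply(pool, function(s) s$id, "")
  if (!is.null(ids)) fits <- fits[ids]
  fits
}

#' Draws from the weighted ensemble
#'
#' Each draw first samples a model by ensemble weight, then samples the
#' coefficients from their fitted sampling distribution, samples location
#' effects from their conditional distribution (when the model carries a
#' random intercept; unseen locations draw from the marginal), and adds
#' residual noise representing rate heterogeneity the covariates do not
#' explain. Rows flagged `non_representative` draw residual noise inflated
#' by `sqrt(var_inflation)`. Rates are converted to deaths with the row's
#' population.
#'
#' @param fits Named list from [fit_pool()].
#' @param weights Tibble from [ensemble_weights()]; ids must match `fits`.
#' @param newdata Modelling tibble of cells to predict.
#' @param n_draws Number of draws (>= 2).
#' @param seed Integer seed; fixed seed gives a bit-identical cube.
#' @param var_inflation Residual variance multiplier for non-representative
#'   rows.
#' @param key_cols Columns of `newdata` used as the draw-cube key.
#' @return A `draw_cube` of deaths.
#' @export
predict_draws <- function(fits, weights, newdata, n_draws = 1000, seed = 1,
                          var_inflation = 2,
                          key_cols = intersect(c("location", "year", "age",
                                                 "sex", "cause"),
                                               names(newdata))) {
  stopifnot(n_draws >= 2)
  if (!all(weights$id %in% names(fits))) stop("weights refer to unknown models")
  if (abs(sum(weights$weight) - 1) > 1e-9) stop("weights must sum to 1")
  n <- nrow(newdata)
  infl <- rep(1, n)
  if ("non_representative" %in% names(newdata)) {
    infl[newdata$non_representative] <- sqrt(var_inflation)
  }
  withr::with_seed(seed, {
    pick <- sample(weights$id, n_draws, replace = TRUE, prob = weights$weight)
    draws <- matrix(NA_real_, n, n_draws)
    for (id in unique(pick)) {
      cols <- which(pick == id)
      fitted <- fits[[id]]
      nd <- length(cols)
      X <- stats::model.matrix(
        stats::as.formula(paste("~", paste(fitted$spec$covariates, collapse = " + "))),
        data = newdata
      )
      B <- if (all(fitted$vcov == 0)) {
        matrix(fitted$beta, nd, length(fitted$beta), byrow = TRUE)
      } else {
        MASS::mvrnorm(nd, fitted$beta, fitted$vcov)
      }
      if (nd == 1) B <- matrix(B, 1)
      eta <- X %*% t(B)  # n x nd
      if (!is.null(fitted$u_hat)) {
        locs <- unique(newdata$location)
        known <- locs %in% names(fitted$u_hat)
        mu_u <- ifelse(known, fitted$u_hat[locs], 0)
        sd_u <- ifelse(known, sqrt(pmax(fitted$u_var[locs], 0)), fitted$sigma_u)
        U <- matrix(stats::rnorm(length(locs) * nd, mu_u, sd_u),
                    length(locs), nd)
        eta <- eta + U[match(newdata$location, locs), , drop = FALSE]
      }
      if (fitted$sigma > 0) {
        eta <- eta + matrix(stats::rnorm(n * nd, 0, fitted$sigma * infl), n, nd)
      }
      rate <- response_to_rate(fitted$spec, eta, newdata)
      draws[, cols] <- rate * newdata$population
    }
    draw_cube(newdata[, key_cols, drop = FALSE], draws)
  })
}

#' Negative-binomial model for a rare cause
#'
#' Fits an intercept-only negative binomial with a log-exposure offset
#' (mean-dispersion parameterisation) and returns parametric rate draws.
#' When the counts show no overdispersion the negative-binomial fit can
#' fail to converge; a Poisson fit (dispersion 0) is used instead. An
#' all-zero series returns zero-rate draws with a warning.
#'
#' @param counts Non-negative integer death counts.
#' @param exposure Person-years at risk (recycled).
#' @param n_draws Number of rate draws.
#' @param seed Integer seed.
#' @return List with `rate` (point estimate), `dispersion` (1/size; 0 under
#'   the Poisson fallback), and `draws` (rate draws).
#' @export
fit_negative_binomial <- function(counts, exposure, n_draws = 1000, seed = 1) {
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  exposure <- rep_len(exposure, length(counts))
  if (all(counts == 0)) {
    warning("all counts are zero; returning zero-rate draws")
    return(list(rate = 0, dispersion = 0, draws = rep(0, n_draws)))
  }
  df <- data.frame(counts = counts, off = log(exposure))
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(counts ~ 1 + offset(off), data = df)),
    error = function(e) NULL
  )
  if (is.null(fit) || !is.finite(fit$theta)) {
    fit <- stats::glm(counts ~ 1 + offset(off), data = df, family = stats::poisson())
    dispersion <- 0
  } else {
    dispersion <- 1 / fit$theta
  }
  beta <- unname(stats::coef(fit)[1])
  se <- sqrt(stats::vcov(fit)[1, 1])
  draws <- withr::with_seed(seed, exp(stats::rnorm(n_draws, beta, se)))
  list(rate = exp(beta), dispersion = dispersion, draws = draws)
}

#' Generate modelling data from a pool member
#'
#' Parameter-recovery experiments need data whose generating process is a
#' member of the candidate pool: true log rate = intercept + coefficients x
#' covariates + location intercept + cell-level heterogeneity, observed
#' deaths Poisson at the true rate. Covariates follow smooth location
#' trends so levels and trends are both informative.
#'
#' @param n_locations,n_years Panel dimensions.
#' @param coefs Named numeric vector: `"(Intercept)"` plus one entry per
#'   covariate; covariate columns are created for each named coefficient.
#' @param sigma_location SD of the true location intercepts.
#' @param sigma_cell SD of true cell-level log-rate heterogeneity.
#' @param population Persons per cell.
#' @param n_noise_covariates Extra covariates unrelated to the truth.
#' @param seed Integer seed.
#' @return Tibble with `location`, `year`, covariates, `true_rate`,
#'   `deaths`, `population`, `envelope` (set to `deaths`; callers modelling
#'   several causes overwrite it).
#' @export
simulate_from_spec <- function(n_locations = 20, n_years = 10,
                               coefs = c("(Intercept)" = log(4e-4), x1 = -1),
                               sigma_location = 0.2, sigma_cell = 0.2,
                               population = 1e6, n_noise_covariates = 1,
                               seed = 1) {
  withr::with_seed(seed, {
    locs <- sprintf("loc_%02d", seq_len(n_locations))
    d <- tidyr::expand_grid(location = locs, year = seq_len(n_years) + 2000L)
    cov_names <- setdiff(names(coefs), "(Intercept)")
    eta <- rep(coefs[["(Intercept)"]], nrow(d))
    for (cv in cov_names) {
      base <- stats::runif(n_locations, -1, 1)
      trend <- stats::runif(n_locations, -0.05, 0.05)
      d[[cv]] <- base[match(d$location, locs)] +
        trend[match(d$location, locs)] * (d$year - 2000L)
      eta <- eta + coefs[[cv]] * d[[cv]]
    }
    for (j in seq_len(n_noise_covariates)) {
      nm <- paste0("z", j)
      base <- stats::runif(n_locations, -1, 1)
      trend <- stats::runif(n_locations, -0.05, 0.05)
      d[[nm]] <- base[match(d$location, locs)] +
        trend[match(d$location, locs)] * (d$year - 2000L)
    }
    u <- stats::rnorm(n_locations, 0, sigma_location)
    e <- stats::rnorm(nrow(d), 0, sigma_cell)
    d$true_rate <- exp(eta + u[match(d$location, locs)] + e)
    d$population <- population
    d$deaths <- stats::rpois(nrow(d), d$true_rate * d$population)
    d$envelope <- d$deaths
    d
  })
}

#' Restrict modelling data to data-rich locations
#'
#' Models for locations with extensive, complete vital registration are fit
#' without data from other locations, so sparse-data noise does not inflate
#' their uncertainty; models for the remaining locations use everything.
#'
#' @param data Modelling tibble with a `location` column.
#' @param stars Named integer vector of star ratings per location.
#' @param threshold Minimum star rating that counts as data-rich.
#' @return List with `rich` (rows from data-rich locations only) and
#'   `poor` (the full data).
#' @export
split_data_rich <- function(data, stars, threshold = 4) {
  rich_locs <- names(stars)[stars >= threshold]
  list(rich = data[data$location %in% rich_locs, , drop = FALSE],
       poor = data)
}

#' Ensemble parameter-recovery experiment
#'
#' End-to-end calibration check of the estimation chain on data whose
#' generating process is a member of the candidate pool. A shared covariate
#' panel is generated; for each cause, true log rates follow an
#' intercept-plus-covariate member with location intercepts and cell-level
#' heterogeneity, and deaths are Poisson. Each cause is fit with the full
#' pool, scored out of sample, weighted, and predicted as draws; the cause
#' draws are then rescaled to the true all-cause envelope. Reported are the
#' coverage of the true deaths by the corrected 95% draw intervals, and the
#' ensemble's in-fit RMSE against the pool-median held-out RMSE per cause.
#'
#' @param seed Integer seed driving every random stream.
#' @param n_locations,n_years Panel dimensions (default 20 x 10, i.e. 200
#'   location-years).
#' @param n_causes Number of causes sharing the envelope.
#' @param n_draws Posterior draws per cell.
#' @param temperature Ensemble weighting temperature.
#' @param folds Cross-validation folds.
#' @return List: `coverage` (fraction of cells whose corrected 95% draw
#'   interval covers the true deaths), `rmse` (tibble with per-cause
#'   ensemble RMSE and pool-median single-model RMSE), `n_cells`.
#' @export
codem_recovery_experiment <- function(seed = 1, n_locations = 20, n_years = 10,
                                      n_causes = 5, n_draws = 1000,
                                      temperature = 0.5, folds = 5) {
  slopes <- rep_len(c(-1, -0.6, 0.4, -1.5, 0.8), n_causes)
  icepts <- rep_len(log(c(4e-4, 2e-4, 3e-4, 1.5e-4, 2.5e-4)), n_causes)
  base <- simulate_from_spec(n_locations, n_years,
                             coefs = c("(Intercept)" = icepts[1], x1 = slopes[1]),
                             sigma_location = 0.2, sigma_cell = 0.2,
                             population = 1e6, n_noise_covariates = 1,
                             seed = seed)
  panel <- base[, c("location", "year", "x1", "z1", "population")]
  datasets <- vector("list", n_causes)
  for (k in seq_len(n_causes)) {
    d <- panel
    dk <- withr::with_seed(seed * 100 + k, {
      u <- stats::rnorm(n_locations, 0, 0.2)
      names(u) <- unique(panel$location)
      e <- stats::rnorm(nrow(panel), 0, 0.2)
      tr <- exp(icepts[k] + slopes[k] * panel$x1 + u[panel$location] + e)
      list(true_rate = tr, deaths = stats::rpois(nrow(panel), tr * panel$population))
    })
    d$true_rate <- dk$true_rate
    d$deaths <- dk$deaths
    d$cause <- paste0("c", k)
    datasets[[k]] <- d
  }
  all_d <- dplyr::bind_rows(datasets)
  env_tbl <- dplyr::summarise(dplyr::group_by(all_d, location, year),
                              envelope = sum(deaths),
                              true_env = sum(true_rate * population),
                              .groups = "drop")
  all_d <- dplyr::left_join(all_d, env_tbl[, c("location", "year", "envelope")],
                            by = c("location", "year"))
  pool <- enumerate_models(c("x1", "z1"), random_intercept = FALSE)
  cubes <- vector("list", n_causes)
  rmse <- vector("list", n_causes)
  for (k in seq_len(n_causes)) {
    d <- all_d[all_d$cause == paste0("c", k), ]
    pv <- holdout_pv(pool, d, folds = folds, seed = seed + k)
    w <- ensemble_weights(pv, temperature = temperature)
    fits <- fit_pool(pool, d, ids = w$id)
    cubes[[k]] <- predict_draws(fits, w, d, n_draws = n_draws,
                                seed = seed + 10 + k,
                                key_cols = c("location", "year", "cause"))
    eta_mat <- vapply(w$id, function(id) {
      f <- fits[[id]]
      log(pmax(response_to_rate(f$spec, predict_eta(f, d), d), 1e-300))
    }, numeric(nrow(d)))
    ens_pred <- as.vector(eta_mat %*% w$weight)
    obs <- log(pmax(d$deaths / d$population, 1e-12))
    rmse[[k]] <- tibble::tibble(cause = paste0("c", k),
                                rmse_ensemble = sqrt(mean((ens_pred - obs)^2)),
                                rmse_pool_median = stats::median(pv$rmse_level))
  }
  cause_cube <- draw_cube(dplyr::bind_rows(lapply(cubes, function(x) x$key)),
                          do.call(rbind, lapply(cubes, function(x) x$draws)))
  env_cube <- draw_cube(env_tbl[, c("location", "year")],
                        matrix(rep(env_tbl$true_env, n_draws), ncol = n_draws))
  ui <- point_and_ui(rescale_draws(cause_cube, env_cube))
  truth <- all_d$true_rate * all_d$population
  list(coverage = mean(ui$lower <= truth & truth <= ui$upper),
       rmse = dplyr::bind_rows(rmse),
       n_cells = nrow(all_d))
}
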