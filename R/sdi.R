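#' Socio-demographic Index
#'
#' The SDI is the geometric mean of three indices rescaled to `[0, 1]`:
#' lag-dependent income per capita (LDI), mean educational attainment in
#' the population aged 15 and over, and total fertility rate (TFR,
#' inverted: higher fertility lowers the index). Rescaling anchors (min and
#' max of each component) are configuration.
#'
#' @param components Tibble with columns `location`, `year`, `ldi`, `edu`,
#'   `tfr` (positive values).
#' @param anchors List with entries `ldi`, `edu`, `tfr`, each `c(min, max)`.
#'   LDI is rescaled on the log scale, as income spans orders of magnitude.
#' @return The input with `i_ldi`, `i_edu`, `i_tfr`, and `sdi` columns, all
#'   clipped to `[0, 1]`.
#' @export
compute_sdi <- function(components,
                        anchors = list(ldi = c(250, 60000), edu = c(0, 17),
                                       tfr = c(1, 8))) {
  stopifnot(all(c("ldi", "edu", "tfr") %in% names(components)))
  for (nm in c("ldi", "edu", "tfr")) {
    a <- anchors[[nm]]
    if (is.null(a) || length(a) != 2) stop("missing anchors for ", nm)
    if (a[1] == a[2]) stop("degenerate anchors for ", nm, " (min equals max)")
  }
  if (any(components$ldi <= 0 | components$edu < 0 | components$tfr <= 0)) {
    stop("components must be positive")
  }
  clip01 <- function(x) pmin(1, pmax(0, x))
  out <- components
  out$i_ldi <- clip01((log(components$ldi) - log(anchors$ldi[1])) /
                        (log(anchors$ldi[2]) - log(anchors$ldi[1])))
  out$i_edu <- clip01((components$edu - anchors$edu[1]) /
                        (anchors$edu[2] - anchors$edu[1]))
  out$i_tfr <- clip01((anchors$tfr[2] - components$tfr) /
                        (anchors$tfr[2] - anchors$tfr[1]))
  out$sdi <- (out$i_ldi * out$i_edu * out$i_tfr)^(1 / 3)
  out
}

#' Geometric mean of already-rescaled indices
#'
#' @param i_ldi,i_edu,i_tfr Indices in `[0, 1]`.
#' @return SDI values.
#' @export
sdi_from_indices <- function(i_ldi, i_edu, i_tfr) {
  stopifnot(all(i_ldi >= 0 & i_ldi <= 1), all(i_edu >= 0 & i_edu <= 1),
            all(i_tfr >= 0 & i_tfr <= 1))
  (i_ldi * i_edu * i_tfr)^(1 / 3)
}

#' SDI quintile membership
#'
#' Cut-points come from the SDI distribution in a reference year; every
#' location keeps its reference-year quintile in all years (time-invariant
#' membership). Ties at a cut-point fall to the lower quintile.
#'
#' @param sdi Tibble with `location`, `year`, `sdi`.
#' @param reference_year Year whose distribution defines the cut-points.
#' @return Tibble `location`, `quintile` (1 = lowest SDI).
#' @export
sdi_quintiles <- function(sdi, reference_year) {
  ref <- sdi[sdi$year == reference_year, ]
  if (nrow(ref) < 5) stop("at least 5 locations are required")
  if (length(unique(ref$sdi)) == 1) stop("degenerate SDI distribution (all equal)")
  cuts <- stats::quantile(ref$sdi, probs = c(0.2, 0.4, 0.6, 0.8), type = 7,
                          names = FALSE)
  q <- 1L + vapply(ref$sdi, function(x) sum(x > cuts), integer(1))
  tibble::tibble(location = ref$location, quintile = q)
}

# squared-exponential kernel
se_kernel <- function(x1, x2, sf2, ell) {
  d <- outer(x1, x2, "-")
  sf2 * exp(-0.5 * (d / ell)^2)
}

gp_neg_loglik <- function(par, x, y) {
  sf2 <- exp(par[1]); ell <- exp(par[2]); sn2 <- exp(par[3])
  K <- se_kernel(x, x, sf2, ell) + diag(sn2 + 1e-10, length(x))
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  0.5 * sum(y * alpha) + sum(log(diag(ch))) + 0.5 * length(y) * log(2 * pi)
}

#' Expected death-rate curve from Gaussian-process regression on SDI
#'
#' Fits a zero-mean (after centring) Gaussian process with a
#' squared-exponential kernel plus a noise nugget to log death rates as a
#' function of SDI. Hyperparameters (signal variance, length-scale, nugget)
#' maximise the marginal likelihood from a fixed set of starting points, so
#' the fit is deterministic given the data. The posterior mean and variance
#' are evaluated on a grid over `[0, 1]` in log-rate space and
#' back-transformed.
#'
#' @param sdi Numeric vector of SDI values (>= 10 points).
#' @param rates Matching death rates; non-positive rates are floored at
#'   `rate_floor` before the log transform.
#' @param grid SDI grid for the curve (default 101 points on `[0, 1]`).
#' @param rate_floor Floor applied before taking logs.
#' @param mean_fn `"linear"` (default) uses a fitted linear trend in SDI as
#'   the GP mean, so the curve extrapolates along the epidemiological
#'   transition rather than reverting to a constant; `"constant"` centres
#'   on the data mean. The mean's prediction variance is propagated into
#'   the posterior band.
#' @param hyper Optional fixed hyperparameters `c(log_sf2, log_ell,
#'   log_sn2)`, skipping optimisation.
#' @return An `expected_curve`: tibble-backed object with `sdi`, `expected`
#'   (posterior-mean rate), `log_mean`, `log_sd`, and the fitted
#'   hyperparameters as attributes.
#' @export
fit_expected_curve <- function(sdi, rates, grid = seq(0, 1, length.out = 101),
                               rate_floor = 1e-12,
                               mean_fn = c("linear", "constant"),
                               hyper = NULL) {
  mean_fn <- match.arg(mean_fn)
  stopifnot(length(sdi) == length(rates))
  ok <- is.finite(sdi) & is.finite(rates)
  if (!any(ok)) stop("no usable SDI-rate pairs")
  sdi <- sdi[ok]; rates <- rates[ok]
  if (length(sdi) < 10) stop("at least 10 SDI-rate pairs are required")
  y <- log(pmax(rates, rate_floor))
  if (mean_fn == "linear" && length(unique(sdi)) > 2) {
    mfit <- stats::lm(y ~ sdi, data = data.frame(y = y, sdi = sdi))
    pr <- stats::predict(mfit, newdata = data.frame(sdi = grid), se.fit = TRUE)
    mu_train <- stats::fitted(mfit)
    mu_grid <- pr$fit
    mu_var_grid <- pr$se.fit^2
  } else {
    mu_train <- rep(mean(y), length(y))
    mu_grid <- rep(mean(y), length(grid))
    mu_var_grid <- rep(stats::var(y) / length(y), length(grid))
  }
  yc <- y - mu_train
  if (is.null(hyper)) {
    starts <- list(c(log(stats::var(yc) + 1e-12), log(0.3), log(0.05)),
                   c(log(stats::var(yc) + 1e-12), log(1), log(0.5)),
                   c(0, log(0.1), log(0.01)))
    best <- NULL
    for (s in starts) {
      o <- tryCatch(
        stats::optim(s, gp_neg_loglik, x = sdi, y = yc, method = "L-BFGS-B",
                     lower = c(-15, log(0.02), -15), upper = c(10, log(10), 5)),
        error = function(e) NULL
      )
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) stop("hyperparameter optimisation failed")
    hyper <- best$par
  }
  sf2 <- exp(hyper[1]); ell <- exp(hyper[2]); sn2 <- exp(hyper[3])
  K <- se_kernel(sdi, sdi, sf2, ell) + diag(sn2 + 1e-10, length(sdi))
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), yc))
  Ks <- se_kernel(grid, sdi, sf2, ell)
  post_mean <- mu_grid + as.vector(Ks %*% alpha)
  V <- forwardsolve(t(ch), t(Ks))
  post_var <- pmax(sf2 - colSums(V^2), 0) + mu_var_grid
  structure(
    tibble::tibble(sdi = grid, log_mean = post_mean, log_sd = sqrt(post_var),
                   expected = exp(post_mean)),
    hyper = c(sf2 = sf2, ell = ell, sn2 = sn2),
    train = list(sdi = sdi, y = y),
    class = c("expected_curve", "tbl_df", "tbl", "data.frame")
  )
}

#' Evaluate an expected curve at given SDI values
#'
#' Linear interpolation of the posterior mean log rate over the fitted
#' grid, back-transformed to the rate scale.
#'
#' @param curve An `expected_curve`.
#' @param sdi SDI values in `[0, 1]`.
#' @return Expected rates.
#' @export
expected_rate <- function(curve, sdi) {
  exp(stats::approx(curve$sdi, curve$log_mean, xout = sdi, rule = 2)$y)
}

#' Observed / expected ratio
#'
#' Compares the observed burden of a cause with the burden expected from
#' development alone: observed and expected values are aggregated over age
#' before the ratio is taken. Rows with zero aggregate expected value get a
#' missing ratio.
#'
#' @param observed Tibble with `location`, `age`, `observed` (e.g. YLLs).
#' @param expected Tibble with `location`, `age`, `expected` on the same
#'   age support, typically built from [expected_rate()] curves at each
#'   location's SDI times the population at risk and standard life
#'   expectancy.
#' @return Tibble `location`, `observed`, `expected`, `ratio`.
#' @export
observed_expected_ratio <- function(observed, expected) {
  key_o <- paste(observed$location, observed$age)
  key_e <- paste(expected$location, expected$age)
  if (!setequal(key_o, key_e)) {
    stop("observed and expected must share the same location-age support")
  }
  o <- dplyr::summarise(dplyr::group_by(observed, location),
                        observed = sum(observed), .groups = "drop")
  e <- dplyr::summarise(dplyr::group_by(expected, location),
                        expected = sum(expected), .groups = "drop")
  out <- dplyr::left_join(o, e, by = "location")
  out$ratio <- ifelse(out$expected > 0, out$observed / out$expected, NA_real_)
  out
}
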