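#' Construct a garbage-code redistribution map
#'
#' One row per garbage code: the hierarchy span it redistributes across
#' (1-4; 1-2 are major), the redistribution method, its target cause set,
#' and, for the fixed method, the proportions (which must sum to 1). The
#' fixed method also covers fractional reassignment of multi-cause records:
#' the per-cause fractions are the fixed proportions.
#'
#' @param map Data frame with columns `code`, `level`, `method`
#'   (`"proportional"`, `"fixed"`, or `"regression"`), `targets`
#'   (semicolon-separated cause ids), and `props` (semicolon-separated
#'   numbers, fixed method only, empty otherwise).
#' @param hierarchy A `cause_hierarchy` whose causes validate the targets.
#' @return An object of class `garbage_map`.
#' @export
garbage_map <- function(map, hierarchy) {
  map <- tibble::as_tibble(map)
  stopifnot(all(c("code", "level", "method", "targets") %in% names(map)))
  if (!"props" %in% names(map)) map$props <- ""
  if (!all(map$method %in% c("proportional", "fixed", "regression"))) {
    stop("unknown redistribution method")
  }
  map$targets <- lapply(strsplit(map$targets, ";", fixed = TRUE), trimws)
  map$props <- lapply(strsplit(as.character(map$props), ";", fixed = TRUE),
                      function(p) if (length(p) == 0 || all(p == "")) numeric() else as.numeric(p))
  for (i in seq_len(nrow(map))) {
    bad <- setdiff(map$targets[[i]], hierarchy$causes$cause)
    if (length(bad)) stop("targets are not valid causes: ", paste(bad, collapse = ", "))
    if (map$method[i] == "fixed") {
      p <- map$props[[i]]
      if (length(p) != length(map$targets[[i]])) {
        stop("fixed proportions must match targets for code ", map$code[i])
      }
      if (any(p < 0)) stop("negative proportions for code ", map$code[i])
      if (abs(sum(p) - 1) > 1e-9) {
        stop("fixed proportions must sum to 1 for code ", map$code[i])
      }
    }
  }
  structure(map, class = c("garbage_map", class(map)))
}

#' Read a garbage map from delimited text
#'
#' Expects tab-delimited columns `code`, `level`, `method`, `targets`,
#' `props` with semicolon-separated list fields.
#' @param path File path.
#' @param hierarchy A `cause_hierarchy`.
#' @export
read_garbage_map <- function(path, hierarchy) {
  garbage_map(utils::read.delim(path, stringsAsFactors = FALSE,
                                colClasses = "character"), hierarchy)
}

#' Exclude low-quality sources
#'
#' Drops VR location-years below 50% registration completeness and any
#' location-year with more than 50% of deaths on major garbage codes; flags
#' VR location-years between 50% and 70% complete as non-representative
#' (downweighted by the ensemble stage). Location-years with unknown
#' completeness are handled under verbal-autopsy rules: no completeness
#' exclusion, logged.
#'
#' @param records A `death_records` tibble.
#' @param completeness Tibble `location`, `year`, `completeness`.
#' @param garbage_fractions Output of [fraction_major_garbage()]; computed
#'   from `records` when NULL (requires `hierarchy`).
#' @param hierarchy Optional `cause_hierarchy` used when `garbage_fractions`
#'   is NULL.
#' @return List with `records` (retained rows, plus a logical
#'   `non_representative` column), `log` (tibble of exclusions/flags with
#'   reasons).
#' @export
exclude_low_quality <- function(records, completeness, garbage_fractions = NULL,
                                hierarchy = NULL) {
  if (is.null(garbage_fractions)) {
    if (is.null(hierarchy)) stop("supply garbage_fractions or hierarchy")
    garbage_fractions <- fraction_major_garbage(records, hierarchy)
  }
  key <- function(l, y) paste(l, y, sep = "\r")
  comp <- stats::setNames(completeness$completeness,
                          key(completeness$location, completeness$year))
  gfrac <- stats::setNames(garbage_fractions$fraction,
                           key(garbage_fractions$location, garbage_fractions$year))
  ly <- unique(records[, c("location", "year", "source_type")])
  ly$completeness <- unname(comp[key(ly$location, ly$year)])
  ly$gfrac <- unname(gfrac[key(ly$location, ly$year)])
  is_vr <- ly$source_type == "VR"

  log <- tibble::tibble(location = character(), year = integer(),
                        action = character(), reason = character())
  add_log <- function(rows, action, reason) {
    if (!any(rows)) return()
    log <<- dplyr::bind_rows(log, tibble::tibble(
      location = ly$location[rows], year = as.integer(ly$year[rows]),
      action = action, reason = reason))
  }
  miss <- is.na(ly$completeness)
  add_log(miss, "kept", "completeness unknown; VA rules applied")
  drop_comp <- is_vr & !miss & ly$completeness < 0.5
  add_log(drop_comp, "excluded", "completeness")
  drop_garb <- !is.na(ly$gfrac) & ly$gfrac > 0.5
  add_log(drop_garb & !drop_comp, "excluded", "garbage")
  nonrep <- is_vr & !miss & ly$completeness >= 0.5 & ly$completeness < 0.7 &
    !drop_garb
  add_log(nonrep, "flagged", "non-representative (50-70% complete)")

  ly$drop <- drop_comp | drop_garb
  ly$non_representative <- nonrep & !ly$drop
  rec <- dplyr::left_join(records,
                          ly[, c("location", "year", "non_representative", "drop")],
                          by = c("location", "year"))
  rec <- rec[!rec$drop, , drop = FALSE]
  rec$drop <- NULL
  list(records = rec, log = log)
}

#' Redistribute garbage-coded deaths onto true causes
#'
#' Processes each garbage code within each location-year-age-sex stratum.
#' The proportional method splits the garbage deaths across the target
#' causes in proportion to the deaths already observed on those targets in
#' the same stratum (uniformly when all targets are zero there). The fixed
#' method applies the stated proportions. The regression method fits one
#' log-linear model per target cause of the target's within-stratum share on
#' age, sex, and an optional covariate across all strata, then predicts and
#' normalises shares per stratum. Total deaths are conserved per stratum;
#' output rows carry fractional deaths.
#'
#' @param records A `death_records` tibble.
#' @param map A [garbage_map()] covering every garbage code present.
#' @param hierarchy A `cause_hierarchy`.
#' @param covariate Optional tibble `location`, `year`, `value` used by the
#'   regression method.
#' @return Records with zero deaths on garbage codes.
#' @export
redistribute <- function(records, map, hierarchy, covariate = NULL) {
  cls <- classify_codes(records$code, hierarchy)
  is_garbage <- cls != "cause"
  g_codes <- unique(records$code[is_garbage])
  missing_codes <- setdiff(g_codes, map$code)
  if (length(missing_codes)) {
    stop("garbage codes absent from map: ", paste(missing_codes, collapse = ", "))
  }
  if (!any(is_garbage)) return(records)

  keep <- records[!is_garbage, , drop = FALSE]
  garb <- records[is_garbage, , drop = FALSE]
  stratum <- function(df) paste(df$location, df$year, df$age, df$sex, sep = "\r")
  keep_str <- stratum(keep)

  shares_regression <- function(targets, strata_df) {
    # per-target share model: log(share + eps) ~ age + sex (+ covariate)
    train <- keep[keep$code %in% targets, , drop = FALSE]
    tot <- tapply(train$deaths, stratum(train), sum)
    eps <- 1e-6
    pred <- matrix(0, nrow(strata_df), length(targets),
                   dimnames = list(NULL, targets))
    for (j in seq_along(targets)) {
      tj <- train[train$code == targets[j], , drop = FALSE]
      if (nrow(tj) < 3) { pred[, j] <- eps; next }
      share <- tj$deaths / unname(tot[stratum(tj)])
      dat <- data.frame(y = log(share + eps), age = tj$age,
                        male = as.integer(tj$sex == "male"))
      newd <- data.frame(age = strata_df$age,
                         male = as.integer(strata_df$sex == "male"))
      if (!is.null(covariate)) {
        cv <- stats::setNames(covariate$value,
                              paste(covariate$location, covariate$year, sep = "\r"))
        dat$cov <- unname(cv[paste(tj$location, tj$year, sep = "\r")])
        newd$cov <- unname(cv[paste(strata_df$location, strata_df$year, sep = "\r")])
        fit <- stats::lm(y ~ age + male + cov, data = dat)
      } else {
        fit <- stats::lm(y ~ age + male, data = dat)
      }
      pred[, j] <- pmax(exp(stats::predict(fit, newdata = newd)) - eps, 0)
    }
    sw <- rowSums(pred)
    pred[sw == 0, ] <- 1
    pred / rowSums(pred)
  }

  extra <- list()
  for (gi in seq_len(nrow(map))) {
    code <- map$code[gi]
    rows <- garb[garb$code == code, , drop = FALSE]
    if (nrow(rows) == 0) next
    targets <- map$targets[[gi]]
    method <- map$method[gi]
    n <- nrow(rows)
    k <- length(targets)
    if (method == "fixed") {
      w <- matrix(rep(map$props[[gi]], each = n), n, k)
    } else if (method == "proportional") {
      # observed target deaths in the same stratum
      obs <- keep[keep$code %in% targets, , drop = FALSE]
      obs_str <- stratum(obs)
      w <- matrix(0, n, k)
      row_str <- stratum(rows)
      for (j in seq_len(k)) {
        tj <- obs[obs$code == targets[j], , drop = FALSE]
        v <- stats::setNames(tj$deaths, stratum(tj))
        w[, j] <- unname(v[row_str])
      }
      w[is.na(w)] <- 0
      zero <- rowSums(w) == 0
      w[zero, ] <- 1  # uniform split when no target observed in the stratum
      w <- w / rowSums(w)
    } else {
      w <- shares_regression(targets, rows[, c("location", "year", "age", "sex")])
    }
    alloc <- rows$deaths * w
    ex <- rows[rep(seq_len(n), k),
               c("location", "year", "age", "sex", "source_type")]
    ex$code <- rep(targets, each = n)
    ex$deaths <- as.vector(alloc)
    extra[[length(extra) + 1]] <- ex[ex$deaths > 0, , drop = FALSE]
  }
  out <- dplyr::bind_rows(c(list(keep), extra))
  out <- dplyr::summarise(
    dplyr::group_by(out, location, year, age, sex, source_type, code),
    deaths = sum(deaths), .groups = "drop"
  )
  class(out) <- c("death_records", class(out))
  out
}

#' Correct cause-specific deaths to 100% completeness
#'
#' Multiplies each stratum's cause fractions by the all-cause envelope for
#' that location-year-age-sex, so corrected deaths sum exactly to the
#' envelope. Run after redistribution (no garbage codes may remain).
#'
#' @param records A `death_records` tibble free of garbage codes.
#' @param envelope Tibble `location`, `year`, `age`, `sex`, `deaths` of
#'   all-cause deaths; must be positive wherever records exist.
#' @return Records with adjusted (fractional) deaths.
#' @export
completeness_correct <- function(records, envelope) {
  key <- function(df) paste(df$location, df$year, df$age, df$sex, sep = "\r")
  env <- stats::setNames(envelope$deaths, key(envelope))
  rk <- key(records)
  tot <- tapply(records$deaths, rk, sum)
  e <- unname(env[rk])
  if (anyNA(e)) {
    bad <- rk[is.na(e)][1]
    stop("no envelope for cell ", gsub("\r", "/", bad))
  }
  cell_tot <- unname(tot[rk])
  zero_env <- e == 0 & cell_tot > 0
  if (any(zero_env)) {
    stop("envelope is zero with recorded deaths in cell ",
         gsub("\r", "/", rk[zero_env][1]))
  }
  out <- records
  out$deaths <- as.vector(ifelse(cell_tot > 0, records$deaths / cell_tot * e, 0))
  out
}
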