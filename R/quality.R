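#' Star rating from percent well certified
#'
#' Bins the full-period percent-well-certified value into a 0-5 star data
#' quality rating. Bins are left-closed: >= 85 gives 5 stars, 65 to < 85
#' gives 4, 35 to < 65 gives 3, 10 to < 35 gives 2, above 0 but below 10
#' gives 1, and exactly 0 gives 0 stars.
#'
#' @param w Numeric vector of percent well certified, in `[0, 100]`.
#' @return Integer vector of stars in `0..5`.
#' @export
star_rating <- function(w) {
  if (any(!is.finite(w)) || any(w < 0 | w > 100)) {
    stop("percent well certified must be in [0, 100]")
  }
  ifelse(w >= 85, 5L,
  ifelse(w >= 65, 4L,
  ifelse(w >= 35, 3L,
  ifelse(w >= 10, 2L,
  ifelse(w > 0, 1L, 0L)))))
}

#' Star rating resolving one-decimal printing precision
#'
#' Published quality tables print percent well certified to one decimal.
#' A printed value within printing precision (+/- 0.05) of a bin boundary is
#' ambiguous: the pre-rounding value may fall on either side. When the
#' accompanying printed star rating is consistent with some pre-rounding
#' value in that window, the printed rating stands; otherwise the binned
#' value of `w` is returned.
#'
#' @param w Printed percent well certified (one decimal).
#' @param printed_stars Printed star rating, `0..5`.
#' @return Integer vector of resolved star ratings.
#' @export
star_rating_printed <- function(w, printed_stars) {
  stopifnot(length(w) == length(printed_stars),
            all(printed_stars %in% 0:5))
  computed <- star_rating(w)
  lo <- c(0, 0, 10, 35, 65, 85)[printed_stars + 1]
  hi <- c(0, 10, 35, 65, 85, 100)[printed_stars + 1]
  # pre-rounding value lies in [w - 0.05, w + 0.05); printed star s needs a
  # value in [lo_s, hi_s) (for 1 star, strictly above 0; for 0 stars, exactly 0)
  lo_w <- pmax(0, w - 0.05)
  hi_w <- w + 0.05
  feasible <- ifelse(
    printed_stars == 0L, w == 0,
    ifelse(printed_stars == 1L, hi_w > 0 & lo_w < 10,
           hi_w > lo & lo_w < hi)
  )
  ifelse(computed != printed_stars & feasible, as.integer(printed_stars), computed)
}

#' Percent of deaths well certified
#'
#' The product of registration completeness, the fraction of deaths not
#' assigned to major garbage codes, and the fraction of deaths assigned to
#' detailed causes, expressed as a percent. Verbal-autopsy data are
#' multiplied by the chance-corrected physician concordance 0.64; subnational
#' VA is additionally multiplied by 0.10. Source type `none` scores 0.
#'
#' @param completeness,garbage_fraction,detail_fraction Fractions in `[0, 1]`.
#' @param source_type One of `"VR"`, `"VA_national"`, `"VA_subnational"`,
#'   `"none"` (recycled).
#' @param va_concordance,subnational_factor The VA adjustment factors.
#' @return Percent well certified in `[0, 100]`.
#' @export
well_certified_fraction <- function(completeness, garbage_fraction,
                                    detail_fraction, source_type = "VR",
                                    va_concordance = 0.64,
                                    subnational_factor = 0.10) {
  chk <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < 0 | x > 1)) stop(nm, " must be in [0, 1]")
  }
  chk(completeness, "completeness")
  chk(garbage_fraction, "garbage_fraction")
  chk(detail_fraction, "detail_fraction")
  stopifnot(all(source_type %in% c("VR", "VA_national", "VA_subnational", "none")))
  w <- 100 * completeness * (1 - garbage_fraction) * detail_fraction
  w <- w * ifelse(source_type %in% c("VA_national", "VA_subnational"),
                  va_concordance, 1)
  w <- w * ifelse(source_type == "VA_subnational", subnational_factor, 1)
  unname(ifelse(source_type == "none", 0, w))
}

#' Fraction of recorded deaths on major garbage codes
#'
#' Major garbage codes are those redistributed across causes spanning
#' Levels 1-2 of the cause hierarchy (for example heart failure or sepsis).
#'
#' @param records A `death_records` tibble.
#' @param hierarchy A `cause_hierarchy` resolving every code.
#' @return Tibble with `location`, `year`, `fraction` (NA where a
#'   location-year has no recorded deaths).
#' @export
fraction_major_garbage <- function(records, hierarchy) {
  records$.is_major <- classify_codes(records$code, hierarchy) == "major_garbage"
  dplyr::summarise(
    dplyr::group_by(records, location, year),
    fraction = ifelse(sum(deaths) == 0, NA_real_,
                      sum(deaths[.is_major]) / sum(deaths)),
    .groups = "drop"
  )
}

#' Fraction of deaths assigned to detailed causes
#'
#' Detailed causes are Level 3-4 causes of the hierarchy. Garbage-coded
#' deaths are excluded from the numerator only, so the denominator is all
#' recorded deaths.
#'
#' @inheritParams fraction_major_garbage
#' @return Tibble with `location`, `year`, `fraction`.
#' @export
detailed_cause_fraction <- function(records, hierarchy) {
  cls <- classify_codes(records$code, hierarchy)
  lev <- cause_level(records$code, hierarchy)
  records$.is_detailed <- cls == "cause" & !is.na(lev) & lev >= 3
  dplyr::summarise(
    dplyr::group_by(records, location, year),
    fraction = ifelse(sum(deaths) == 0, NA_real_,
                      sum(deaths[.is_detailed]) / sum(deaths)),
    .groups = "drop"
  )
}

#' The seven reporting intervals, 1980-2016
#' @return Tibble with `interval`, `from`, `to` (calendar years, inclusive).
#' @export
quality_intervals <- function() {
  tibble::tibble(
    interval = c("1980-84", "1985-89", "1990-94", "1995-99",
                 "2000-04", "2005-09", "2010-16"),
    from = c(1980L, 1985L, 1990L, 1995L, 2000L, 2005L, 2010L),
    to = c(1984L, 1989L, 1994L, 1999L, 2004L, 2009L, 2016L)
  )
}

assign_interval <- function(year) {
  iv <- quality_intervals()
  idx <- findInterval(year, iv$from)
  bad <- year < iv$from[1] | year > iv$to[nrow(iv)]
  if (any(bad)) stop("years outside 1980-2016: ",
                     paste(unique(year[bad]), collapse = ", "))
  iv$interval[idx]
}

#' Per-location-year quality profile
#'
#' Combines completeness, major-garbage fraction, and detailed-cause
#' fraction into percent well certified per location-year, carrying source
#' type and interval labels.
#'
#' @param records A `death_records` tibble.
#' @param completeness Tibble with `location`, `year`, `completeness`.
#' @param hierarchy A `cause_hierarchy`.
#' @return Tibble: `location`, `year`, `interval`, `source_type`,
#'   `completeness`, `garbage_fraction`, `detail_fraction`, `deaths`, `w`.
#' @export
quality_profile <- function(records, completeness, hierarchy) {
  g <- fraction_major_garbage(records, hierarchy)
  d <- detailed_cause_fraction(records, hierarchy)
  tot <- dplyr::summarise(dplyr::group_by(records, location, year, source_type),
                          deaths = sum(deaths), .groups = "drop")
  p <- dplyr::left_join(tot, g, by = c("location", "year"))
  p <- dplyr::left_join(p, d, by = c("location", "year"),
                        suffix = c("_garbage", "_detail"))
  p <- dplyr::left_join(p, completeness, by = c("location", "year"))
  if (anyNA(p$completeness)) {
    stop("completeness missing for recorded location-years")
  }
  p$interval <- assign_interval(p$year)
  p$w <- well_certified_fraction(p$completeness, p$fraction_garbage,
                                 p$fraction_detail, p$source_type)
  tibble::as_tibble(p[, c("location", "year", "interval", "source_type",
                          "completeness", "fraction_garbage", "fraction_detail",
                          "deaths", "w")])
}

#' Location quality report
#'
#' For each location: the maximum percent well certified within each
#' interval, a full-period value, and the star rating of the full-period
#' value. Intervals with no data score 0 (no usable registration). The
#' full-period value is the deaths-weighted mean of the per-year values
#' (equal weights when death counts are unavailable).
#'
#' @param profiles Output of [quality_profile()].
#' @return Tibble: one row per location with one column per interval
#'   (maximum `w`), `w_full`, and `stars`.
#' @export
rate_location_series <- function(profiles) {
  iv <- quality_intervals()
  if (!all(profiles$interval %in% iv$interval)) {
    stop("unknown interval labels: ",
         paste(setdiff(unique(profiles$interval), iv$interval), collapse = ", "))
  }
  per_iv <- dplyr::summarise(dplyr::group_by(profiles, location, interval),
                             w_max = max(w), .groups = "drop")
  wide <- tidyr::pivot_wider(per_iv, names_from = interval, values_from = w_max)
  for (lab in iv$interval) {
    if (!lab %in% names(wide)) wide[[lab]] <- 0
    wide[[lab]][is.na(wide[[lab]])] <- 0
  }
  wide <- wide[, c("location", iv$interval)]
  has_w <- "deaths" %in% names(profiles) && all(is.finite(profiles$deaths)) &&
    any(profiles$deaths > 0)
  full <- dplyr::summarise(
    dplyr::group_by(profiles, location),
    w_full = if (has_w) stats::weighted.mean(w, deaths) else mean(w),
    .groups = "drop"
  )
  out <- dplyr::left_join(wide, full, by = "location")
  out$stars <- star_rating(out$w_full)
  out
}

#' Packaged transcription of the published country quality table
#'
#' One row per location: printed star rating, maximum percent well certified
#' in each of the seven intervals, the full-period (1980-2016) percent, and
#' a flag for UK subnational rows (excluded from country-level counts).
#'
#' @param national_only Drop the four UK subnational rows (default TRUE).
#' @return A tibble with 195 (or 199) rows.
#' @export
table1_quality <- function(national_only = TRUE) {
  path <- system.file("extdata", "table1_quality.csv", package = "codburden",
                      mustWork = TRUE)
  x <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (national_only) x <- x[x$subnational == 0, ]
  x
}

#' Count countries per star level in the packaged quality table
#'
#' Applies [star_rating_printed()] to the printed full-period column and the
#' printed rating, then tabulates national rows per star level.
#'
#' @return Named integer vector, names `"0"` to `"5"`.
#' @export
table1_star_counts <- function() {
  t1 <- table1_quality(national_only = TRUE)
  s <- star_rating_printed(t1$wc_1980_2016, t1$stars)
  counts <- table(factor(s, levels = 0:5))
  stats::setNames(as.integer(counts), names(counts))
}
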